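#' Bundle expert label maps for one case
#'
#' @param case_id case identifier.
#' @param masks list of [labelmap()]s, one per rater, on one common grid.
#' @param rater_labels character names, defaults to `rater1..raterN`.
#' @return an object of class `rater_set`.
#' @export
rater_set <- function(case_id, masks, rater_labels = NULL) {
  if (length(masks) < 1L) stop("rater_set: need at least one rater")
  if (is.null(rater_labels)) rater_labels <- paste0("rater", seq_along(masks))
  if (length(rater_labels) != length(masks))
    stop("rater_set: one label per mask required")
  for (m in masks[-1L]) stop_if_grid_mismatch(masks[[1L]], m, "rater_set")
  structure(list(case_id = case_id, masks = masks,
                 rater_labels = as.character(rater_labels)),
            class = "rater_set")
}

#' Fuse expert segmentations by per-voxel majority vote
#'
#' A voxel enters the fused reference when at least `threshold` raters marked
#' it. The default threshold is a strict majority, `floor(N/2) + 1` — with
#' three raters, 2 or more votes. For even rater counts ties therefore fall
#' to background (a conservative reference); pass `threshold = N/2` to flip.
#'
#' @param raters a [rater_set()].
#' @param threshold minimum vote count for foreground.
#' @return fused reference [labelmap()].
#' @export
majority_vote <- function(raters, threshold = NULL) {
  n <- length(raters$masks)
  if (is.null(threshold)) threshold <- floor(n / 2) + 1
  votes <- Reduce(`+`, lapply(raters$masks, function(m) m$values))
  g <- raters$masks[[1L]]
  labelmap((votes >= threshold) * 1, g$spacing, g$affine)
}

#' Pairwise inter-rater Dice matrix
#'
#' @param raters a [rater_set()] with at least two raters.
#' @return symmetric matrix of Dice coefficients, dimnames = rater labels.
#' @export
pairwise_agreement <- function(raters) {
  n <- length(raters$masks)
  if (n < 2L) stop("pairwise_agreement: need at least two raters")
  d <- matrix(1, n, n, dimnames = list(raters$rater_labels, raters$rater_labels))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d[i, j] <- d[j, i] <- dice(raters$masks[[i]], raters$masks[[j]])
  }
  for (i in seq_len(n)) d[i, i] <- dice(raters$masks[[i]], raters$masks[[i]])
  d
}
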