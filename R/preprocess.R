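#' Brain foreground mask of a study
#'
#' Skull-stripped inputs are zero-filled outside the brain, so a voxel is
#' foreground iff any of the four channels is nonzero there.
#'
#' @param study a [multimodal_study()].
#' @return a [labelmap()] on the study grid.
#' @export
foreground_mask <- function(study) {
  fg <- (study$t1$values != 0) | (study$t1gad$values != 0) |
    (study$t2$values != 0) | (study$flair$values != 0)
  if (!any(fg))
    stop("foreground_mask: study is entirely zero (no brain present)")
  labelmap(fg * 1, study$t1$spacing, study$t1$affine)
}

#' Z-score intensity normalization within the brain mask
#'
#' Each channel is independently shifted and scaled so that its intensities
#' within the mask have mean 0 and standard deviation 1 (population sd, so
#' renormalizing an already-normalized study is an exact no-op up to
#' floating-point tolerance). Voxels outside the mask are set to exactly 0.
#'
#' @param study a [multimodal_study()].
#' @param mask a [labelmap()]; defaults to [foreground_mask()] of the study.
#' @return list with `study` (normalized [multimodal_study()]) and `params`,
#'   a data.frame with one row per channel (`channel`, `mu`, `sigma`).
#' @export
zscore_normalize <- function(study, mask = NULL) {
  if (is.null(mask)) mask <- foreground_mask(study)
  stop_if_grid_mismatch(study$t1, mask, "zscore_normalize")
  idx <- mask$values != 0
  if (sum(idx) < 2)
    stop("zscore_normalize: mask must contain at least 2 foreground voxels")
  channels <- c("t1", "t1gad", "t2", "flair")
  params <- data.frame(channel = channels, mu = NA_real_, sigma = NA_real_,
                       stringsAsFactors = FALSE)
  out <- study
  for (i in seq_along(channels)) {
    ch <- channels[i]
    v <- study[[ch]]$values
    x <- v[idx]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))  # population sd
    if (sigma <= 0)
      stop("zscore_normalize: channel ", ch, " is constant within the mask")
    v[] <- 0
    v[idx] <- (x - mu) / sigma
    out[[ch]] <- image_volume(v, study[[ch]]$spacing, study[[ch]]$affine)
    params$mu[i] <- mu
    params$sigma[i] <- sigma
  }
  list(study = out, params = params)
}
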