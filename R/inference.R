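# Tri-planar (2.5D) inference: the 2D network is applied slice-wise along
# each of the three orthogonal orientations, the three foreground-probability
# volumes are averaged voxel-wise, and the average is thresholded.

#' Slice-wise prediction along one orientation
#'
#' Forwards every slice of the study along the given orientation in
#' evaluation mode (deterministic) and reassembles the foreground
#' probabilities into a volume on the study grid.
#'
#' @param network trained `rc_network` with `in_channels = 4`.
#' @param study normalized [multimodal_study()].
#' @param orientation `"axial"`, `"coronal"` or `"sagittal"`.
#' @param chunk slices forwarded per batch (throughput knob, no effect on
#'   results).
#' @return a [prob_map()].
#' @export
predict_planewise <- function(network, study,
                              orientation = c("axial", "coronal", "sagittal"),
                              chunk = 16L) {
  orientation <- match.arg(orientation)
  tensor <- study_tensor(study)
  d <- dim(tensor)[1:3]
  axis <- switch(orientation, sagittal = 1L, coronal = 2L, axial = 3L)
  n_slices <- d[axis]
  min_ext <- 2^network$config$levels
  plane <- d[-axis]
  if (any(plane < min_ext))
    stop("predict_planewise: slice extent ", paste(plane, collapse = "x"),
         " below the architecture minimum of ", min_ext, " per axis")
  out <- array(0, d)
  for (start in seq(1L, n_slices, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_slices)
    x <- array(0, c(plane, length(idx), 4L))
    for (j in seq_along(idx))
      x[, , j, ] <- extract_slice(tensor, orientation, idx[j])
    fw <- network_forward(network, x, training = FALSE, keep_cache = FALSE)
    fg <- fw$probs[, , , 2L, drop = FALSE]   # class 2 = foreground
    for (j in seq_along(idx)) {
      sl <- fg[, , j, 1L]
      switch(orientation,
             axial = { out[, , idx[j]] <- sl },
             coronal = { out[, idx[j], ] <- sl },
             sagittal = { out[idx[j], , ] <- sl })
    }
  }
  prob_map(out, study$t1$spacing, study$t1$affine)
}

#' Average the three plane-wise probability volumes
#'
#' Voxel-wise arithmetic mean; symmetric in its arguments.
#'
#' @param p_axial,p_coronal,p_sagittal [prob_map()]s on one grid.
#' @return a [prob_map()].
#' @export
fuse_triplanar <- function(p_axial, p_coronal, p_sagittal) {
  stop_if_grid_mismatch(p_axial, p_coronal, "fuse_triplanar")
  stop_if_grid_mismatch(p_axial, p_sagittal, "fuse_triplanar")
  prob_map((p_axial$values + p_coronal$values + p_sagittal$values) / 3,
           p_axial$spacing, p_axial$affine)
}

#' Threshold a probability map into a binary mask
#'
#' Foreground iff probability >= threshold. The default 0.5 equals the argmax
#' of the averaged two-class output.
#'
#' @param prob a [prob_map()].
#' @param threshold decision threshold in (0, 1).
#' @return a [labelmap()].
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("binarize: threshold must lie strictly between 0 and 1")
  labelmap((prob$values >= threshold) * 1, prob$spacing, prob$affine)
}

#' End-to-end segmentation of one study
#'
#' Composition of the full 2.5D scheme: (optional z-score normalization),
#' slice-wise prediction along the three orientations, voxel-wise fusion,
#' and binarization. `fusion = "average"` averages the three probability
#' volumes (default); `fusion = "vote"` binarizes each orientation first and
#' takes the per-voxel majority of the three binary predictions.
#'
#' @param network trained `rc_network`.
#' @param study a [multimodal_study()], raw or already normalized.
#' @param normalize apply [zscore_normalize()] before prediction.
#' @param threshold decision threshold.
#' @param fusion `"average"` or `"vote"`.
#' @return list with `mask` ([labelmap()]) and `probability` ([prob_map()],
#'   the averaged volume).
#' @export
segment_study <- function(network, study, normalize = TRUE, threshold = 0.5,
                          fusion = c("average", "vote")) {
  fusion <- match.arg(fusion)
  if (normalize) study <- zscore_normalize(study)$study
  p <- lapply(c("axial", "coronal", "sagittal"), function(o)
    predict_planewise(network, study, o))
  avg <- fuse_triplanar(p[[1]], p[[2]], p[[3]])
  mask <- if (fusion == "average") {
    binarize(avg, threshold)
  } else {
    votes <- Reduce(`+`, lapply(p, function(pm) binarize(pm, threshold)$values))
    labelmap((votes >= 2) * 1, avg$spacing, avg$affine)
  }
  list(mask = mask, probability = avg)
}
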