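#' @useDynLib cavityseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median quantile sd shapiro.test kruskal.test wilcox.test setNames
#' @importFrom utils write.csv read.csv head combn
NULL

GEOM_TOL <- 1e-3  # absolute tolerance (mm) for spacing/affine comparisons

default_affine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

#' Construct a 3D image volume
#'
#' An `image_volume` couples a 3D intensity array with its voxel geometry:
#' per-axis spacing in millimetres and a 4x4 NIfTI-style affine placing the
#' 0-based voxel grid in scanner space.
#'
#' @param values 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, voxel size in mm; strictly positive.
#' @param affine 4x4 affine matrix; defaults to a diagonal affine built from
#'   `spacing` with the origin at zero.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("image_volume: `values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("image_volume: all values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("image_volume: spacing must be 3 strictly positive values")
  if (any(dim(values) < 1L))
    stop("image_volume: grid needs at least one voxel per axis")
  if (is.null(affine)) affine <- default_affine(spacing)
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(list(values = values, spacing = spacing, affine = affine),
            class = "image_volume")
}

#' Construct a binary label map
#'
#' A `labelmap` is a binary (0/1) mask on an image grid: a rater contour, the
#' fused reference segmentation, or a model prediction.
#'
#' @inheritParams image_volume
#' @param values 3D array containing exactly 0s and 1s.
#' @return an object of class `labelmap`.
#' @export
labelmap <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("labelmap: `values` must be a 3D array")
  if (!all(values %in% c(0, 1)))
    stop("labelmap: values must be exactly 0 or 1")
  storage.mode(values) <- "double"
  vol <- image_volume(values, spacing, affine)
  class(vol) <- c("labelmap", "image_volume")
  vol
}

#' Construct a per-voxel foreground probability map
#'
#' @inheritParams image_volume
#' @param values 3D array with every value in \[0, 1\].
#' @return an object of class `prob_map`.
#' @export
prob_map <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  values <- as.array(values)
  if (any(values < 0 | values > 1))
    stop("prob_map: probabilities must lie in [0, 1]")
  vol <- image_volume(values, spacing, affine)
  class(vol) <- c("prob_map", "image_volume")
  vol
}

#' Bundle four co-registered MR sequences into one study
#'
#' The four sequences (T1w, T1w-gadolinium, T2w, FLAIR) must share an
#' identical grid: same shape, spacing, and affine (inputs are assumed
#' rigidly registered to the T1w-gadolinium space and skull-stripped
#' upstream; this constructor only checks conformance, it never resamples).
#'
#' @param case_id opaque case identifier.
#' @param t1,t1gad,t2,flair `image_volume`s on one common grid.
#' @return an object of class `multimodal_study`.
#' @export
multimodal_study <- function(case_id, t1, t1gad, t2, flair) {
  vols <- list(t1 = t1, t1gad = t1gad, t2 = t2, flair = flair)
  for (nm in names(vols))
    if (!inherits(vols[[nm]], "image_volume"))
      stop("multimodal_study: ", nm, " is not an image_volume")
  ref <- vols[[1L]]
  for (nm in names(vols)[-1L]) {
    if (!same_grid(ref, vols[[nm]])) {
      shapes <- vapply(vols, function(v) paste(dim(v$values), collapse = "x"), "")
      spac   <- vapply(vols, function(v) paste(signif(v$spacing, 6), collapse = "x"), "")
      stop("multimodal_study: grid mismatch across sequences; shapes: ",
           paste(names(vols), shapes, sep = "=", collapse = ", "),
           "; spacings: ", paste(names(vols), spac, sep = "=", collapse = ", "))
    }
  }
  structure(c(list(case_id = case_id), vols), class = "multimodal_study")
}

#' Test whether two volumes share one voxel grid
#'
#' Grids match when shapes are identical and spacing and affine agree within
#' an absolute tolerance of 1e-3 mm.
#'
#' @param a,b `image_volume`s (or objects with `values`, `spacing`, `affine`).
#' @return logical scalar.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= GEOM_TOL) &&
    all(abs(a$affine - b$affine) <= GEOM_TOL)
}

stop_if_grid_mismatch <- function(a, b, what) {
  if (!same_grid(a, b))
    stop(what, ": grid mismatch (shapes ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), "; spacings ",
         paste(signif(a$spacing, 6), collapse = "x"), " vs ",
         paste(signif(b$spacing, 6), collapse = "x"), ")")
  invisible(TRUE)
}

## ---- NIfTI IO ----

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))   # strip niftiImage attributes
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  list(values = vals, spacing = spacing, affine = affine)
}

write_nifti_volume <- function(values, spacing, affine, path) {
  img <- RNifti::asNifti(as.array(values))
  RNifti::pixdim(img) <- spacing
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a four-sequence study from NIfTI files
#'
#' @param paths named list/vector with entries `t1`, `t1gad`, `t2`, `flair`
#'   giving NIfTI file paths.
#' @param case_id identifier attached to the study (default: basename of the
#'   t1gad path).
#' @return a [multimodal_study()].
#' @export
load_study <- function(paths, case_id = NULL) {
  required <- c("t1", "t1gad", "t2", "flair")
  missing <- setdiff(required, names(paths))
  if (length(missing))
    stop("load_study: missing sequence(s): ", paste(missing, collapse = ", "))
  vols <- lapply(required, function(nm) {
    r <- read_nifti_volume(paths[[nm]])
    image_volume(r$values, r$spacing, r$affine)
  })
  names(vols) <- required
  if (is.null(case_id)) case_id <- sub("\\.nii(\\.gz)?$", "", basename(paths[["t1gad"]]))
  multimodal_study(case_id, vols$t1, vols$t1gad, vols$t2, vols$flair)
}

#' Load a binary label map conforming to a study grid
#'
#' Values within 1e-3 of 0 or 1 are rounded (guards against float dialects of
#' binary masks); anything else is rejected so interpolated masks never enter
#' the pipeline silently.
#'
#' @param path NIfTI file path.
#' @param reference a [multimodal_study()] or `image_volume` defining the grid.
#' @return a [labelmap()].
#' @export
load_labelmap <- function(path, reference = NULL) {
  r <- read_nifti_volume(path)
  v <- r$values
  near0 <- abs(v) <= 1e-3
  near1 <- abs(v - 1) <= 1e-3
  if (!all(near0 | near1))
    stop("load_labelmap: non-binary voxel values beyond tolerance in ", path,
         " (range ", paste(signif(range(v), 6), collapse = " .. "), ")")
  v[near0] <- 0; v[near1] <- 1
  lm <- labelmap(v, r$spacing, r$affine)
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "multimodal_study")) reference$t1gad else reference
    stop_if_grid_mismatch(ref, lm, "load_labelmap")
  }
  lm
}

#' Write a label map (or any volume) to NIfTI
#'
#' Round-tripping through [load_labelmap()] restores voxel-identical values
#' and the affine.
#'
#' @param mask a [labelmap()], [prob_map()] or [image_volume()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @export
write_labelmap <- function(mask, path) {
  write_nifti_volume(mask$values, mask$spacing, mask$affine, path)
}

#' Foreground volume of a mask in cubic centimetres
#'
#' `count(foreground voxels) * prod(spacing in mm) / 1000`.
#'
#' @param mask a [labelmap()].
#' @return volume in cm^3.
#' @export
volume_cm3 <- function(mask) {
  sum(mask$values) * prod(mask$spacing) / 1000
}

## ---- manifests ----

#' Read a plain-text key:path manifest
#'
#' One `key: path` pair per line; blank lines and `#` comments ignored.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest file.
#' @return named character vector of paths (plus a `case_id` entry if present).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  out <- setNames(vals, keys)
  base <- dirname(path)
  pathish <- keys != "case_id"
  rel <- pathish & !grepl("^/", out)
  out[rel] <- file.path(base, out[rel])
  out
}

write_manifest <- function(entries, path) {
  writeLines(paste0(names(entries), ": ", unname(entries)), path)
  invisible(path)
}

#' Load a full case (study + rater masks) from a manifest
#'
#' @param manifest_path manifest with keys `t1`, `t1gad`, `t2`, `flair`, and
#'   optionally `rater1..raterN`, `reference`, `case_id`.
#' @return list with `study`, `raters` (a [rater_set()] or NULL) and
#'   `reference` (a [labelmap()] or NULL).
#' @export
load_case <- function(manifest_path) {
  m <- read_manifest(manifest_path)
  case_id <- if ("case_id" %in% names(m)) m[["case_id"]] else
    basename(dirname(manifest_path))
  study <- load_study(as.list(m[c("t1", "t1gad", "t2", "flair")]), case_id)
  rkeys <- grep("^rater", names(m), value = TRUE)
  raters <- NULL
  if (length(rkeys)) {
    masks <- lapply(m[rkeys], load_labelmap, reference = study)
    raters <- rater_set(case_id, masks, rater_labels = rkeys)
  }
  reference <- if ("reference" %in% names(m))
    load_labelmap(m[["reference"]], reference = study) else NULL
  list(case_id = case_id, study = study, raters = raters, reference = reference)
}
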