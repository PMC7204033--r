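test_that("volume_cm3 converts voxel counts and spacing correctly", {
  m <- mk_mask(array(c(rep(1, 1000), rep(0, 331)), c(11, 11, 11)))
  expect_equal(volume_cm3(m), 1.0)
  expect_equal(volume_cm3(mk_mask(array(0, c(4, 4, 4)))), 0.0)
  m8 <- mk_mask(array(c(rep(1, 8), rep(0, 56)), c(4, 4, 4)), spacing = c(2, 2, 2))
  expect_equal(volume_cm3(m8), 0.064)   # 8 voxels * 8 mm^3 = 64 mm^3
})

test_that("volume_cm3 is additive over disjoint masks and monotone under inclusion", {
  set.seed(42)
  for (i in 1:5) {
    a <- array(runif(6^3) < 0.4, c(6, 6, 6))
    b <- array(runif(6^3) < 0.4, c(6, 6, 6)) & !a
    ma <- mk_mask(a, spacing = c(1.5, 2, 1))
    mb <- mk_mask(b, spacing = c(1.5, 2, 1))
    mab <- mk_mask(a | b, spacing = c(1.5, 2, 1))
    expect_equal(volume_cm3(ma) + volume_cm3(mb), volume_cm3(mab))
    expect_lte(volume_cm3(ma), volume_cm3(mab))
  }
})

test_that("label maps round-trip through NIfTI with values and affine intact", {
  set.seed(1)
  aff <- rbind(c(-2, 0, 0, 31), c(0, 2, 0, -40), c(0, 0, 2, 5), c(0, 0, 0, 1))
  m <- labelmap(array(runif(10 * 12 * 9) < 0.3, c(10, 12, 9)) * 1,
                spacing = c(2, 2, 2), affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_labelmap(m, f)
  m2 <- load_labelmap(f)
  expect_identical(m2$values, m$values)
  expect_true(same_grid(m, m2))
  expect_equal(m2$affine, aff, tolerance = 1e-6)
})

test_that("load_labelmap rounds float dialects and rejects non-binary masks", {
  v <- array(0, c(5, 5, 5)); v[1:10] <- 0.9999
  f <- withr::local_tempfile(fileext = ".nii.gz")
  cavityseg:::write_nifti_volume(v, c(1, 1, 1), diag(4), f)
  m <- load_labelmap(f)
  expect_setequal(unique(as.vector(m$values)), c(0, 1))
  expect_equal(sum(m$values), 10)

  v2 <- v; v2[1] <- 2
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  cavityseg:::write_nifti_volume(v2, c(1, 1, 1), diag(4), f2)
  expect_error(load_labelmap(f2), "non-binary")
})

test_that("load_study validates sequence presence and grid conformance", {
  dirp <- withr::local_tempdir()
  mk <- function(name, shape) {
    p <- file.path(dirp, paste0(name, ".nii.gz"))
    cavityseg:::write_nifti_volume(array(rnorm(prod(shape)), shape),
                                   c(1, 1, 1), diag(4), p)
    p
  }
  paths <- list(t1 = mk("t1", c(8, 8, 8)), t1gad = mk("t1gad", c(8, 8, 8)),
                t2 = mk("t2", c(8, 8, 8)), flair = mk("flair", c(8, 8, 8)))
  st <- load_study(paths, "case1")
  expect_s3_class(st, "multimodal_study")
  expect_identical(dim(st$t2$values), dim(st$t1gad$values))

  expect_error(load_study(paths[c("t1", "t1gad", "t2")]), "flair")

  paths$t2 <- mk("t2bad", c(8, 8, 9))
  expect_error(load_study(paths), "mismatch")
})

test_that("constructors enforce the basic invariants", {
  expect_error(image_volume(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(image_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(labelmap(array(0.5, c(2, 2, 2))), "0 or 1")
  expect_error(prob_map(array(1.5, c(2, 2, 2))), "\\[0, 1\\]")
})

test_that("manifests resolve relative paths and load full cases", {
  dirp <- withr::local_tempdir()
  spec <- noise_free_spec()
  mf <- generate_cohort(1, spec, rater_perturbation(boundary_sd = 0.5),
                        seed = 3, out_dir = dirp)
  cases <- read_cohort_manifest(mf)
  expect_length(cases, 1)
  cs <- load_case(cases[1])
  expect_s3_class(cs$study, "multimodal_study")
  expect_s3_class(cs$raters, "rater_set")
  expect_length(cs$raters$masks, 3)
  expect_s3_class(cs$reference, "labelmap")
  expect_true(same_grid(cs$study$t1, cs$reference))
})
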