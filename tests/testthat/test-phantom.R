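test_that("phantom generation is deterministic per seed", {
  a <- generate_phantom(tiny_spec(), seed = 41)
  b <- generate_phantom(tiny_spec(), seed = 41)
  c <- generate_phantom(tiny_spec(), seed = 42)
  expect_identical(a$study$t2$values, b$study$t2$values)
  expect_identical(a$reference$values, b$reference$values)
  expect_false(identical(a$study$t2$values, c$study$t2$values))
})

test_that("noise-free phantoms are piecewise constant with exact contrast ordering", {
  spec <- noise_free_spec()
  ph <- generate_phantom(spec, seed = 43)
  fluid <- ph$components$fluid$values > 0
  air <- ph$components$air$values > 0
  blood <- ph$components$blood$values > 0
  brain <- ph$brain$values > 0
  par <- brain & ph$reference$values == 0 &
    !(ph$study$t2$values > 150 & ph$study$t1$values < 50)  # exclude ventricle
  ints <- spec$intensities
  expect_true(all(ph$study$t2$values[fluid] == ints["cavity", "t2"]))
  expect_true(all(ph$study$t1$values[fluid] == ints["cavity", "t1"]))
  # cavity bright on T2w, dark on T1w relative to parenchyma
  expect_gt(min(ph$study$t2$values[fluid]), max(ph$study$t2$values[par & !fluid]))
  expect_lt(max(ph$study$t1$values[fluid]), min(ph$study$t1$values[par & !fluid]))
  # air darkest everywhere, blood bright on T1w
  expect_true(sum(air) > 0 && sum(blood) > 0)
  for (ch in c("t1", "t1gad", "t2", "flair"))
    expect_lt(max(ph$study[[ch]]$values[air]),
              min(ph$study[[ch]]$values[brain & !air]))
  expect_gt(min(ph$study$t1$values[blood]), max(ph$study$t1$values[par]))
  # the exterior is exactly zero (skull-stripped convention)
  expect_true(all(ph$study$flair$values[!brain] == 0))
})

test_that("the reference cavity contains its air and blood subregions", {
  ph <- generate_phantom(noise_free_spec(), seed = 44)
  expect_true(all(ph$components$air$values <= ph$reference$values))
  expect_true(all(ph$components$blood$values <= ph$reference$values))
  expect_true(all(ph$components$fluid$values <= ph$reference$values))
  expect_equal(ph$reference$values,
               (ph$components$fluid$values + ph$components$air$values +
                  ph$components$blood$values > 0) * 1)
})

test_that("discretized cavity volume matches the analytic ellipsoid volume", {
  spec <- noise_free_spec(shape = c(48L, 48L, 48L))
  for (s in c(45, 46, 47)) {
    ph <- generate_phantom(spec, seed = s)
    r <- ph$cavity_radii
    v_analytic <- 4 / 3 * pi * prod(r) / 1000            # cm^3
    v_disc <- volume_cm3(ph$reference)
    bound <- 4 * pi * max(r)^2 * max(spec$spacing) / 1000 # surface * spacing
    expect_lt(abs(v_disc - v_analytic), bound)
  }
})

test_that("zero perturbation reproduces the reference exactly", {
  ph <- generate_phantom(tiny_spec(), seed = 48)
  rs <- simulate_raters(ph$reference, ph$components, n = 3,
                        rater_perturbation(boundary_sd = 0, morph_prob = 0),
                        seed = 1)
  for (m in rs$masks) expect_identical(m$values, ph$reference$values)
})

test_that("excluding subregions can only shrink a rater mask", {
  ph <- generate_phantom(noise_free_spec(), seed = 49)
  rs <- simulate_raters(ph$reference, ph$components, n = 2,
                        rater_perturbation(boundary_sd = 0, morph_prob = 0,
                                           exclude_air = TRUE,
                                           exclude_blood = TRUE),
                        seed = 2)
  for (m in rs$masks) {
    expect_true(all(m$values <= ph$reference$values))
    expect_true(all(m$values[ph$components$air$values > 0] == 0))
  }
})

test_that("calibrated default raters agree at the clinical inter-expert level", {
  # aggregate over seeds: per-seed median pairwise Dice, then the median
  meds <- vapply(1:20, function(s) {
    ph <- generate_phantom(phantom_spec(), seed = s)
    rs <- simulate_raters(ph$reference, ph$components, 3,
                          rater_perturbation(), seed = 1000 + s)
    pa <- pairwise_agreement(rs)
    median(pa[upper.tri(pa)])
  }, 0)
  expect_gte(median(meds), 0.80)
  expect_lte(median(meds), 0.90)
})

test_that("cohorts on disk are reloadable, conformant and seed-stable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mf1 <- generate_cohort(2, tiny_spec(), rater_perturbation(), seed = 7,
                         out_dir = d1)
  mf2 <- generate_cohort(2, tiny_spec(), rater_perturbation(), seed = 7,
                         out_dir = d2)
  cases1 <- lapply(read_cohort_manifest(mf1), load_case)
  cases2 <- lapply(read_cohort_manifest(mf2), load_case)
  expect_length(cases1, 2)
  for (i in 1:2) {
    cs <- cases1[[i]]
    expect_true(same_grid(cs$study$t1, cs$study$flair))
    expect_length(cs$raters$masks, 3)
    expect_identical(cs$study$t2$values, cases2[[i]]$study$t2$values)
    expect_identical(cs$reference$values, cases2[[i]]$reference$values)
    # stored reference equals the majority vote of the stored raters
    expect_identical(cs$reference$values, majority_vote(cs$raters)$values)
  }
})
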