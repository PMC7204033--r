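# Voxel-counting oracle for the Dice coefficient (explicit loops).
dice_oracle <- function(a, b) {
  na <- 0; nb <- 0; ni <- 0
  d <- dim(a$values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    va <- a$values[i, j, k]; vb <- b$values[i, j, k]
    na <- na + va; nb <- nb + vb; ni <- ni + va * vb
  }
  if (na + nb == 0) 1 else 2 * ni / (na + nb)
}

test_that("dice handles the canonical cases", {
  set.seed(3)
  m <- random_mask8()
  expect_equal(dice(m, m), 1)
  a <- mk_mask(array(c(rep(1, 4), rep(0, 23)), c(3, 3, 3)))
  bv <- array(0, c(3, 3, 3)); bv[c(1:3, 10:12)] <- 1
  expect_equal(dice(a, mk_mask(bv)), 0.6)
  cv <- array(0, c(3, 3, 3)); cv[20:23] <- 1
  expect_equal(dice(a, mk_mask(cv)), 0)
  empty <- mk_mask(array(0, c(3, 3, 3)))
  expect_equal(dice(empty, empty), 1)   # agreement on emptiness
  expect_equal(dice(a, empty), 0)
  expect_error(dice(a, random_mask8()), "mismatch")
})

test_that("dice is symmetric and matches the voxel-counting oracle", {
  set.seed(21)
  for (rep in 1:4) {
    a <- random_mask8(p = runif(1, 0.2, 0.8))
    b <- random_mask8(p = runif(1, 0.2, 0.8))
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(dice(a, b), dice_oracle(a, b))
  }
})

test_that("relative volume error is signed and spacing-invariant", {
  mk_n <- function(n, spacing = c(1, 1, 1))
    mk_mask(array(c(rep(1, n), rep(0, 1000 - n)), c(10, 10, 10)), spacing)
  expect_equal(relative_volume_error(mk_n(10), mk_n(10)), 0)
  expect_equal(relative_volume_error(mk_n(8), mk_n(10)), -0.2)
  expect_error(relative_volume_error(mk_n(5), mk_n(0)), "empty")
  # same spacing change on both masks leaves the ratio unchanged
  expect_equal(relative_volume_error(mk_n(8, c(2, 2, 2)), mk_n(10, c(2, 2, 2))),
               -0.2)
})

test_that("evaluate_cohort produces every pairing per case", {
  set.seed(31)
  mk_case <- function() {
    masks <- lapply(1:3, function(i) random_mask8(0.4))
    rs <- rater_set("c", masks)
    list(raters = rs, reference = majority_vote(rs))
  }
  c1 <- mk_case(); c2 <- mk_case()
  preds <- list(case1 = c1$reference, case2 = c2$reference)
  raters <- list(case1 = c1$raters, case2 = c2$raters)
  refs <- list(case1 = c1$reference, case2 = c2$reference)
  tab <- evaluate_cohort(preds, raters, refs)
  # per case: 3 auto-rater + 3 rater-rater + 1 auto-reference
  expect_equal(nrow(tab), 2 * 7)
  expect_setequal(unique(tab$pairing),
                  c("auto-rater1", "auto-rater2", "auto-rater3",
                    "rater1-rater2", "rater1-rater3", "rater2-rater3",
                    "auto-reference"))
  expect_true(all(tab$dice[tab$pairing == "auto-reference"] == 1))
  expect_true(all(tab$dice >= 0 & tab$dice <= 1))

  expect_error(evaluate_cohort(preds, raters["case1"], refs), "case2")

  summ <- summarize_metrics(tab)
  expect_true(all(c("pairing", "metric", "median", "iqr") %in% names(summ)))
  expect_equal(summ$median[summ$pairing == "auto-reference" &
                             summ$metric == "dice"], 1)
})

test_that("compare_groups gates pairwise tests on the omnibus result", {
  # identical constant groups: no rank variation
  rep0 <- compare_groups(list(a = rep(1, 5), b = rep(1, 5)))
  expect_equal(rep0$omnibus$statistic, 0)
  expect_null(rep0$pairwise)

  # clearly separated groups: omnibus significant, pairwise runs and matches
  # the reference rank-sum implementation
  g <- list(low = 1:10, high = 11:20)
  rep1 <- compare_groups(lapply(g, as.numeric))
  kw <- kruskal.test(lapply(g, as.numeric))
  expect_equal(rep1$omnibus$statistic, unname(kw$statistic))
  expect_lt(rep1$omnibus$p, 0.05)
  expect_equal(rep1$pairwise$p,
               suppressWarnings(wilcox.test(as.numeric(g$low),
                                            as.numeric(g$high))$p.value))

  # a minuscule alpha suppresses the pairwise stage
  rep2 <- compare_groups(lapply(g, as.numeric), alpha = 1e-12)
  expect_null(rep2$pairwise)

  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "at least 3")
  expect_error(compare_groups(list(a = 1:5)), "two groups")
})
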