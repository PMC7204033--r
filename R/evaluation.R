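#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`, the volumetric overlap in \[0, 1\]; 1 is perfect
#' agreement. Two empty masks are defined to agree perfectly (Dice 1); an
#' empty mask against a nonempty one scores 0.
#'
#' @param a,b [labelmap()]s on one grid.
#' @return Dice coefficient.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b, "dice")
  sa <- sum(a$values); sb <- sum(b$values)
  if (sa + sb == 0) return(1)
  2 * sum(a$values * b$values) / (sa + sb)
}

#' Signed relative volume error of a prediction against a reference
#'
#' `(V_auto - V_ref) / V_ref`; negative values mean the prediction
#' underestimates the reference volume.
#'
#' @param auto predicted [labelmap()].
#' @param ref reference [labelmap()] with nonzero volume.
#' @return signed fraction.
#' @export
relative_volume_error <- function(auto, ref) {
  stop_if_grid_mismatch(auto, ref, "relative_volume_error")
  v_ref <- volume_cm3(ref)
  if (v_ref <= 0)
    stop("relative_volume_error: reference mask is empty; metric undefined")
  (volume_cm3(auto) - v_ref) / v_ref
}

metrics_record <- function(case_id, pairing, a, b) {
  data.frame(case_id = case_id, pairing = pairing,
             dice = dice(a, b),
             rel_vol_err = if (volume_cm3(b) > 0)
               relative_volume_error(a, b) else NA_real_,
             vol_a = volume_cm3(a), vol_b = volume_cm3(b),
             stringsAsFactors = FALSE)
}

#' Per-case metric table over a cohort
#'
#' For every case, records Dice / relative volume error / absolute volumes for
#' each automatic-vs-rater pairing, each rater-vs-rater pairing, and the
#' automatic-vs-reference pairing.
#'
#' @param predictions named list (by case id) of predicted [labelmap()]s.
#' @param raters named list of [rater_set()]s.
#' @param reference named list of fused reference [labelmap()]s.
#' @return data.frame of per-pairing records (one row per case and pairing).
#' @export
evaluate_cohort <- function(predictions, raters, reference) {
  ids <- names(predictions)
  missing_r <- setdiff(ids, names(raters))
  missing_f <- setdiff(ids, names(reference))
  if (length(missing_r) || length(missing_f))
    stop("evaluate_cohort: cases missing from rater/reference maps: ",
         paste(unique(c(missing_r, missing_f)), collapse = ", "))
  rows <- list()
  for (id in ids) {
    pred <- predictions[[id]]
    rs <- raters[[id]]
    labs <- rs$rater_labels
    for (i in seq_along(rs$masks))
      rows[[length(rows) + 1L]] <-
        metrics_record(id, paste0("auto-", labs[i]), pred, rs$masks[[i]])
    if (length(rs$masks) >= 2L)
      for (i in seq_len(length(rs$masks) - 1L))
        for (j in seq(i + 1L, length(rs$masks)))
          rows[[length(rows) + 1L]] <-
            metrics_record(id, paste0(labs[i], "-", labs[j]),
                           rs$masks[[i]], rs$masks[[j]])
    rows[[length(rows) + 1L]] <-
      metrics_record(id, "auto-reference", pred, reference[[id]])
  }
  do.call(rbind, rows)
}

#' Median / IQR summary per pairing
#'
#' IQR is Q3 - Q1 with linear-interpolation quantiles, mirroring the usual
#' "median (interquartile range)" reporting of segmentation studies.
#'
#' @param metrics output of [evaluate_cohort()].
#' @return data.frame with one row per pairing and metric.
#' @export
summarize_metrics <- function(metrics) {
  out <- list()
  for (p in unique(metrics$pairing)) {
    sub <- metrics[metrics$pairing == p, ]
    for (m in c("dice", "rel_vol_err", "vol_a")) {
      x <- sub[[m]]
      x <- x[is.finite(x)]
      out[[length(out) + 1L]] <- data.frame(
        pairing = p, metric = m,
        median = if (length(x)) median(x) else NA_real_,
        iqr = if (length(x)) unname(diff(quantile(x, c(0.25, 0.75), type = 7))) else NA_real_,
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Gated nonparametric group comparison
#'
#' The statistical chain used to compare metric distributions across groups:
#' Shapiro-Wilk normality per group (motivating the nonparametric tests), a
#' Kruskal-Wallis omnibus test across all groups, and — only when the omnibus
#' test is significant at `alpha` — unpaired pairwise Wilcoxon rank-sum tests.
#' Degenerate input in which every value in every group is identical yields an
#' omnibus statistic of 0 with p = 1 (no rank variation) and no pairwise tests.
#'
#' @param metric_values named list: group -> numeric vector (each length >= 3).
#' @param alpha significance level gating the pairwise stage (default 0.05).
#' @return list of class `stat_report`: `groups` (median/IQR/shapiro_p per
#'   group), `omnibus` (chi-squared statistic, df, p), `pairwise` (data.frame
#'   or NULL), `alpha`.
#' @export
compare_groups <- function(metric_values, alpha = 0.05) {
  if (length(metric_values) < 2L)
    stop("compare_groups: need at least two groups")
  ns <- lengths(metric_values)
  if (any(ns < 3L))
    stop("compare_groups: every group needs at least 3 values (got ",
         paste(ns, collapse = ", "), ")")
  if (is.null(names(metric_values)))
    names(metric_values) <- paste0("group", seq_along(metric_values))

  groups <- do.call(rbind, lapply(names(metric_values), function(g) {
    x <- metric_values[[g]]
    sp <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
    data.frame(group = g, n = length(x), median = median(x),
               iqr = unname(diff(quantile(x, c(0.25, 0.75), type = 7))),
               shapiro_p = sp, stringsAsFactors = FALSE)
  }))

  all_vals <- unlist(metric_values, use.names = FALSE)
  if (length(unique(all_vals)) == 1L) {
    omnibus <- list(statistic = 0, df = length(metric_values) - 1L, p = 1)
  } else {
    kw <- kruskal.test(metric_values)
    omnibus <- list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                    p = kw$p.value)
  }

  pairwise <- NULL
  if (is.finite(omnibus$p) && omnibus$p < alpha) {
    cmb <- combn(names(metric_values), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      g1 <- cmb[1, k]; g2 <- cmb[2, k]
      w <- suppressWarnings(wilcox.test(metric_values[[g1]], metric_values[[g2]],
                                        paired = FALSE))
      data.frame(group1 = g1, group2 = g2, p = w$p.value,
                 significant = w$p.value < alpha, stringsAsFactors = FALSE)
    }))
  }

  structure(list(groups = groups, omnibus = omnibus, pairwise = pairwise,
                 alpha = alpha), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("Group summaries (median, IQR, Shapiro-Wilk p):\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("\nKruskal-Wallis: chi-square = %.4g, df = %d, p = %.4g (alpha = %g)\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p, x$alpha))
  if (is.null(x$pairwise)) {
    cat("Pairwise Wilcoxon rank-sum tests: not run (omnibus not significant)\n")
  } else {
    cat("Pairwise Wilcoxon rank-sum tests (unpaired):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
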