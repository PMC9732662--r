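#' Paired velocity table for agreement analysis
#'
#' One row per (investigation, site): the TCD-measured and model-simulated
#' mean velocities plus optional subgroup labels. Velocities must be
#' strictly positive (the log transformation requires it) and (investigation,
#' site) pairs must be unique. The artery class (ICA/MCA/ACA/PCA/BA) is
#' derived from the site.
#'
#' @param investigation_id,site Identifiers of each paired observation.
#' @param v_tcd,v_sim Measured and simulated velocities (cm/s), > 0.
#' @param ... Optional subgroup label columns (e.g. `dci`, `sbp_group`,
#'   `fisher_group`, `aneurysm_location`), each a vector of the same length.
#' @return A data.frame of class `paired_velocity_table`.
#' @export
paired_velocity_table <- function(investigation_id, site, v_tcd, v_sim, ...) {
  if (any(!is.finite(v_tcd)) || any(!is.finite(v_sim)) ||
      any(v_tcd <= 0) || any(v_sim <= 0))
    stop("velocities must be finite and > 0")
  df <- data.frame(investigation_id = as.character(investigation_id),
                   site = as.character(site),
                   v_tcd = v_tcd, v_sim = v_sim, stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("investigation_id", "site")]))
    stop("duplicated (investigation_id, site) pairs")
  df$artery_class <- sub("^[LR]_", "", df$site)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("paired_velocity_table", "data.frame")
  df
}

#' Intraclass correlation: single rater, consistency, two-way random model
#'
#' ICC(C,1) from the two-way ANOVA decomposition with subjects = paired
#' observations and raters = (TCD, simulation):
#' `ICC = (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)` with
#' `k = 2`, so a constant offset between the two methods does not lower it.
#' The 95% confidence interval uses the exact F-distribution method for the
#' consistency form.
#'
#' @param table A [paired_velocity_table()] (or any data.frame with `v_tcd`
#'   and `v_sim`).
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`, `n`,
#'   `ms_subjects`, `ms_error`.
#' @export
icc_consistency <- function(table, conf_level = 0.95) {
  n <- nrow(table)
  if (n < 5) stop("ICC requires at least 5 pairs")
  k <- 2
  long <- data.frame(
    value = c(table$v_tcd, table$v_sim),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("tcd", "sim"), each = n)))
  ms <- suppressWarnings(stats::anova(stats::lm(value ~ subject + rater,
                                                data = long)))
  msr <- ms["subject", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  if (!is.finite(msr) || !is.finite(mse) ||
      (msr + mse) <= 1e-12 * mean(long$value)^2) {
    warning("degenerate table: zero between-subject variance; ICC defined as 0")
    return(structure(list(icc = 0, ci_low = 0, ci_high = 0, n = n,
                          ms_subjects = msr, ms_error = mse),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  alpha <- 1 - conf_level
  if (mse == 0) {
    ci <- c(1, 1)
  } else {
    f <- msr / mse
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], n = n,
                 ms_subjects = msr, ms_error = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(C,1) = %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$icc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Base-10 logarithmic Bland-Altman limits of agreement
#'
#' Computes `d = log10(v_sim) - log10(v_tcd)` and the multiplicative limits
#' `10^(mean(d) +/- 1.96 sd(d))`: in 95% of cases the simulated velocity may
#' differ from the TCD measurement by a factor between `lower_factor` and
#' `upper_factor`, i.e. by `(1 - lower)` below to `(upper - 1)` above.
#'
#' @inheritParams icc_consistency
#' @param z Normal quantile for the limits (1.96 for 95%).
#' @return A list of class `log_loa`: `mean_log_diff`, `sd_log_diff`,
#'   `lower_factor`, `upper_factor`, `n`, and the percent phrasing
#'   `percent_below` / `percent_above`.
#' @export
log_bland_altman <- function(table, z = 1.96) {
  keep <- is.finite(table$v_tcd) & is.finite(table$v_sim) &
    table$v_tcd > 0 & table$v_sim > 0
  if (any(!keep))
    warning(sum(!keep), " row(s) rejected: non-positive velocity")
  d <- log10(table$v_sim[keep]) - log10(table$v_tcd[keep])
  m <- mean(d)
  s <- stats::sd(d)
  lower <- 10^(m - z * s)
  upper <- 10^(m + z * s)
  structure(list(mean_log_diff = m, sd_log_diff = s,
                 lower_factor = lower, upper_factor = upper,
                 percent_below = 1 - lower, percent_above = upper - 1,
                 n = sum(keep)),
            class = "log_loa")
}

#' @export
print.log_loa <- function(x, ...) {
  cat(sprintf("log10 Bland-Altman (n = %d): factors %.2f-%.2f (%.0f%% below to %.0f%% above)\n",
              x$n, x$lower_factor, x$upper_factor,
              100 * x$percent_below, 100 * x$percent_above))
  invisible(x)
}

#' Wilcoxon signed-rank test on the paired velocity differences
#'
#' Tests whether the paired differences `v_sim - v_tcd` are centred on 0:
#' exact distribution for n <= 25 without ties, normal approximation with
#' tie correction otherwise; all differences zero gives p = 1.
#'
#' @inheritParams icc_consistency
#' @return A list: `statistic` (V), `p_value`, `n` (non-zero differences),
#'   `method`.
#' @export
paired_difference_test <- function(table) {
  d <- table$v_sim - table$v_tcd
  if (length(d) < 6) stop("paired test requires n >= 6")
  d_nz <- d[d != 0]
  if (length(d_nz) == 0L)
    return(list(statistic = 0, p_value = 1, n = 0L,
                method = "all differences zero"))
  exact <- length(d_nz) <= 25 && !any(duplicated(abs(d_nz)))
  wt <- suppressWarnings(stats::wilcox.test(table$v_sim, table$v_tcd,
                                            paired = TRUE, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(d_nz),
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Subgroup agreement with confidence-interval overlap
#'
#' Computes the consistency ICC within each level of a subgroup label and
#' flags whether the 95% confidence intervals of the levels intersect --
#' overlapping intervals mean the ICC difference is compatible with chance
#' rather than a true difference.
#'
#' @inheritParams icc_consistency
#' @param label Name of the subgroup column in `table`.
#' @param min_n Minimum pairs per level (levels below it are excluded with a
#'   warning).
#' @return A list of class `subgroup_agreement`: `by_level` (named list of
#'   `icc_result`), `loa_by_level`, `overlap` (logical, for two retained
#'   levels), `excluded`.
#' @export
subgroup_agreement <- function(table, label, min_n = 5L) {
  if (!label %in% names(table)) stop("no such subgroup column: ", label)
  parts <- split(seq_len(nrow(table)), table[[label]])
  small <- names(parts)[vapply(parts, length, integer(1)) < min_n]
  if (length(small))
    warning("level(s) excluded (n < ", min_n, "): ",
            paste(small, collapse = ", "))
  parts <- parts[!names(parts) %in% small]
  by_level <- lapply(parts, function(ix) icc_consistency(table[ix, , drop = FALSE]))
  loa_by_level <- lapply(parts, function(ix) log_bland_altman(table[ix, , drop = FALSE]))
  overlap <- NA
  if (length(by_level) == 2L) {
    a <- by_level[[1]]; b <- by_level[[2]]
    overlap <- a$ci_low <= b$ci_high && b$ci_low <= a$ci_high
  }
  structure(list(by_level = by_level, loa_by_level = loa_by_level,
                 overlap = overlap, excluded = small, label = label),
            class = "subgroup_agreement")
}

#' @export
print.subgroup_agreement <- function(x, ...) {
  cat("Subgroup agreement by '", x$label, "':\n", sep = "")
  for (nm in names(x$by_level)) {
    r <- x$by_level[[nm]]
    cat(sprintf("  %s: ICC = %.3f (%.3f-%.3f), n = %d\n",
                nm, r$icc, r$ci_low, r$ci_high, r$n))
  }
  if (!is.na(x$overlap))
    cat("  95% CIs", if (x$overlap) "overlap" else "do NOT overlap", "\n")
  invisible(x)
}
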