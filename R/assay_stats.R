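# Per-assay summaries and statistical comparisons: one-way ANOVA with
# Dunnett (many-to-one) or Tukey (all-pairs) correction, Benjamini-
# Hochberg adjustment, Student's t tests, chi-squared defect-fraction
# tests (in motility.R), and corrected total nuclear fluorescence.

#' Construct a test-outcome record
#'
#' The common result row used across the package: comparison label,
#' estimate (direction of effect), statistic, raw and adjusted p-values,
#' method tag, significance call at `alpha`, and a degeneracy flag.
#' Adjusted p-values are never below raw p-values.
#'
#' @param comparison Comparison label, e.g. `"Y59C vs wild_type"`.
#' @param estimate Effect estimate (variant minus reference).
#' @param statistic Test statistic.
#' @param p_raw,p_adjusted Raw and multiplicity-adjusted p-values.
#' @param method Method tag (`"dunnett"`, `"tukey"`, `"chi_squared"`,
#'   `"t_test"`, `"wilcoxon_bh"`, ...).
#' @param alpha Significance level for the `significant` flag.
#' @param degenerate `TRUE` when the test was undefined on the data
#'   (zero variance, empty margin) and a conventional value is returned.
#' @return A one-row data frame of class `stat_result`.
#' @export
stat_result <- function(comparison, estimate, statistic, p_raw, p_adjusted,
                        method, alpha = 0.05, degenerate = FALSE) {
  p_adjusted <- pmin(pmax(p_adjusted, p_raw), 1)
  out <- data.frame(comparison = comparison, estimate = estimate,
                    statistic = statistic, p_raw = p_raw,
                    p_adjusted = p_adjusted, method = method,
                    significant = !is.na(p_adjusted) & p_adjusted <= alpha,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  class(out) <- c("stat_result", "data.frame")
  out
}

rbind_stat_results <- function(lst) {
  out <- do.call(rbind, lapply(lst, as.data.frame))
  class(out) <- c("stat_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Total brood size from daily egg counts
#'
#' Mothers are moved to a fresh plate every 24 h for three days; the brood
#' is the sum of the daily egg counts.
#'
#' @param per_day_egg_counts 1 to 3 nonnegative daily counts.
#' @return The total count.
#' @export
brood_size <- function(per_day_egg_counts) {
  x <- per_day_egg_counts
  if (!is.numeric(x) || length(x) < 1 || length(x) > 3)
    stop("expected 1-3 daily egg counts", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("daily egg counts must be nonnegative", call. = FALSE)
  sum(x)
}

#' Percent embryonic lethality
#'
#' `100 * unhatched / total`. A mother with no eggs has no defined
#' lethality: the result is `NA` with a `sterile` attribute flagging those
#' entries (never silently 0).
#'
#' @param unhatched Unhatched egg count(s).
#' @param total Total egg count(s).
#' @return Percentage(s) in `[0, 100]`; `NA` where `total == 0`, with
#'   `attr(, "sterile")` marking those positions.
#' @export
percent_lethality <- function(unhatched, total) {
  stopifnot(is.numeric(unhatched), is.numeric(total),
            length(unhatched) == length(total))
  if (any(unhatched < 0) || any(total < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (any(unhatched > total))
    stop("unhatched cannot exceed total", call. = FALSE)
  sterile <- total == 0
  out <- ifelse(sterile, NA_real_, 100 * unhatched / total)
  attr(out, "sterile") <- sterile
  out
}

#' Corrected total nuclear fluorescence
#'
#' `CTCF = integrated density - area x mean background fluorescence`,
#' where the integrated density is the product of the selected area and
#' its mean grey value. Negative results (background brighter than the
#' selection) are preserved and flagged.
#'
#' @param integrated_density Integrated density (a.u.).
#' @param area Selection area in px^2 (> 0).
#' @param background_mean Mean background fluorescence (a.u./px).
#' @return CTCF value(s); `attr(, "negative")` flags entries below zero.
#' @export
ctcf <- function(integrated_density, area, background_mean) {
  stopifnot(is.numeric(integrated_density), is.numeric(area),
            is.numeric(background_mean))
  if (any(!is.finite(integrated_density)) || any(!is.finite(area)) ||
      any(!is.finite(background_mean)))
    stop("inputs must be finite", call. = FALSE)
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  out <- integrated_density - area * background_mean
  attr(out, "negative") <- out < 0
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR control: adjusted p-values are monotone and capped at 1;
#' hypotheses with adjusted p at or below `fdr` are rejected.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param fdr False discovery rate.
#' @return A list with `adjusted` (same order as the input) and `reject`
#'   (logical flags).
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  if (!length(p_values)) stop("empty p-value list", call. = FALSE)
  stopifnot(is.numeric(p_values), all(is.finite(p_values)),
            all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = adj <= fdr)
}

group_split_values <- function(dataset, value_column) {
  if (!value_column %in% names(dataset))
    stop("no column '", value_column, "' in dataset", call. = FALSE)
  v <- dataset[[value_column]]
  g <- as.character(dataset$genotype)
  keep <- is.finite(v)
  split(v[keep], g[keep])
}

#' One-way ANOVA with Dunnett's many-to-one correction
#'
#' Fits a one-way ANOVA across all genotypes and compares each non-control
#' genotype with the control, adjusting p-values with the single-step
#' Dunnett procedure (multivariate-t). The quadrature is evaluated under a
#' fixed internal RNG state, so results are deterministic.
#'
#' @param dataset An [assay_dataset()] (or data frame with `genotype`).
#' @param value_column Name of the value column to analyse.
#' @param control_genotype Control (reference) genotype label.
#' @param alpha Significance level.
#' @return A `stat_result` data frame, one row per non-control genotype;
#'   `estimate` is the variant-minus-control mean difference. With zero
#'   within-group variance everywhere the family is degenerate and
#'   flagged.
#' @export
anova_dunnett <- function(dataset, value_column, control_genotype,
                          alpha = 0.05) {
  groups <- group_split_values(dataset, value_column)
  if (!control_genotype %in% names(groups))
    stop("control genotype '", control_genotype, "' absent from dataset",
         call. = FALSE)
  if (length(groups) < 2)
    stop("need the control and at least one other genotype", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("every genotype needs at least 2 records", call. = FALSE)
  lev <- c(control_genotype,
           sort(setdiff(names(groups), control_genotype)))
  df <- data.frame(
    y = unlist(groups[lev], use.names = FALSE),
    g = factor(rep(lev, lengths(groups[lev])), levels = lev))
  means <- vapply(groups[lev], mean, numeric(1))
  est <- means[-1] - means[1]
  comparisons <- paste(lev[-1], "vs", control_genotype)
  fit <- stats::aov(y ~ g, data = df)
  if (stats::sigma(fit) <= .Machine$double.eps^0.5) {
    return(rbind_stat_results(lapply(seq_along(comparisons), function(i)
      stat_result(comparisons[i], estimate = unname(est[i]),
                  statistic = NA_real_, p_raw = NA_real_,
                  p_adjusted = NA_real_, method = "dunnett", alpha = alpha,
                  degenerate = TRUE))))
  }
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- with_seed(20230825, summary(gl))
  raw <- summary(gl, test = multcomp::adjusted("none"))
  rbind_stat_results(lapply(seq_along(comparisons), function(i)
    stat_result(comparisons[i], estimate = unname(est[i]),
                statistic = unname(sm$test$tstat[i]),
                p_raw = unname(raw$test$pvalues[i]),
                p_adjusted = unname(sm$test$pvalues[i]),
                method = "dunnett", alpha = alpha)))
}

#' One-way ANOVA with Tukey's all-pairs correction
#'
#' Fits a one-way ANOVA and compares every pair of genotypes, adjusting
#' with the studentized-range (Tukey HSD) distribution. Deterministic
#' (closed-form `ptukey`).
#'
#' @inheritParams anova_dunnett
#' @return A `stat_result` data frame, one row per genotype pair
#'   (`"B vs A"` with `estimate` = mean(B) - mean(A)).
#' @export
anova_tukey <- function(dataset, value_column, alpha = 0.05) {
  groups <- group_split_values(dataset, value_column)
  if (length(groups) < 2)
    stop("need at least two genotypes", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("every genotype needs at least 2 records", call. = FALSE)
  lev <- sort(names(groups))
  k <- length(lev)
  ns <- lengths(groups[lev])
  means <- vapply(groups[lev], mean, numeric(1))
  df_err <- sum(ns) - k
  mse <- sum(vapply(groups[lev], function(v)
    sum((v - mean(v))^2), numeric(1))) / df_err
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(ix) {
    i <- pairs[1, ix]; j <- pairs[2, ix]
    est <- means[j] - means[i]
    comparison <- paste(lev[j], "vs", lev[i])
    if (mse <= .Machine$double.eps)
      return(stat_result(comparison, estimate = unname(est),
                         statistic = NA_real_, p_raw = NA_real_,
                         p_adjusted = NA_real_, method = "tukey",
                         alpha = alpha, degenerate = TRUE))
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tstat <- est / se
    p_raw <- 2 * stats::pt(-abs(tstat), df_err)
    p_adj <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = df_err,
                           lower.tail = FALSE)
    stat_result(comparison, estimate = unname(est),
                statistic = unname(tstat), p_raw = p_raw,
                p_adjusted = p_adj, method = "tukey", alpha = alpha)
  })
  rbind_stat_results(res)
}

#' Two-group Student's t test
#'
#' Two-sided, equal-variance (classical Student) two-sample t test on a
#' value column. Zero pooled variance is degenerate: equal means give
#' statistic 0 and p = 1; unequal means give an infinite statistic and
#' p = 0, both flagged.
#'
#' @inheritParams anova_dunnett
#' @param group_a,group_b Genotype labels to compare (estimate is
#'   `mean(group_a) - mean(group_b)`).
#' @return A one-row `stat_result`.
#' @export
two_group_t <- function(dataset, value_column, group_a, group_b,
                        alpha = 0.05) {
  groups <- group_split_values(dataset, value_column)
  for (g in c(group_a, group_b)) {
    if (!g %in% names(groups))
      stop("genotype '", g, "' absent from dataset", call. = FALSE)
    if (length(groups[[g]]) < 2)
      stop("genotype '", g, "' needs at least 2 records", call. = FALSE)
  }
  a <- groups[[group_a]]; b <- groups[[group_b]]
  comparison <- paste(group_a, "vs", group_b)
  est <- mean(a) - mean(b)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var <= .Machine$double.eps) {
    if (abs(est) <= .Machine$double.eps)
      return(stat_result(comparison, estimate = 0, statistic = 0,
                         p_raw = 1, p_adjusted = 1, method = "t_test",
                         alpha = alpha, degenerate = TRUE))
    return(stat_result(comparison, estimate = est,
                       statistic = sign(est) * Inf, p_raw = 0,
                       p_adjusted = 0, method = "t_test", alpha = alpha,
                       degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  stat_result(comparison, estimate = est, statistic = unname(tt$statistic),
              p_raw = tt$p.value, p_adjusted = tt$p.value,
              method = "t_test", alpha = alpha)
}

#' Per-genotype nuclear-bleb comparisons with BH correction
#'
#' Compares each non-control genotype's per-animal bleb counts with the
#' control by a rank-based two-sample test (Wilcoxon rank-sum, normal
#' approximation), then adjusts the family of raw p-values with
#' [bh_adjust()] at the given false discovery rate.
#'
#' @param dataset A morphology [assay_dataset()] with a `blebs` column.
#' @param control_genotype Control genotype label.
#' @param fdr False discovery rate.
#' @return A `stat_result` data frame, one row per non-control genotype;
#'   `significant` reflects the BH rejection at `fdr`.
#' @export
bleb_defect_tests <- function(dataset, control_genotype, fdr = 0.05) {
  groups <- group_split_values(dataset, "blebs")
  if (!control_genotype %in% names(groups))
    stop("control genotype '", control_genotype, "' absent from dataset",
         call. = FALSE)
  others <- sort(setdiff(names(groups), control_genotype))
  if (!length(others)) stop("no non-control genotypes", call. = FALSE)
  ctrl <- groups[[control_genotype]]
  raw <- numeric(length(others))
  est <- numeric(length(others))
  stat <- numeric(length(others))
  degen <- logical(length(others))
  for (i in seq_along(others)) {
    v <- groups[[others[i]]]
    est[i] <- mean(v) - mean(ctrl)
    if (length(unique(c(v, ctrl))) == 1L) {
      raw[i] <- 1; stat[i] <- 0; degen[i] <- TRUE
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v, ctrl, exact = FALSE,
                                                correct = TRUE))
      raw[i] <- wt$p.value
      stat[i] <- unname(wt$statistic)
    }
  }
  bh <- bh_adjust(raw, fdr = fdr)
  rbind_stat_results(lapply(seq_along(others), function(i)
    stat_result(paste(others[i], "vs", control_genotype),
                estimate = est[i], statistic = stat[i], p_raw = raw[i],
                p_adjusted = bh$adjusted[i], method = "wilcoxon_bh",
                alpha = fdr, degenerate = degen[i])))
}

#' Monte-Carlo Dunnett adjusted p-values
#'
#' Independent route to the single-step many-to-one adjusted p-value:
#' simulates the maximum absolute statistic of the Dunnett multivariate-t
#' family (correlation induced by the shared control) and reports the
#' exceedance probability for each observed |t|. Used as a cross-check of
#' the quadrature route.
#'
#' @param abs_t Observed absolute t statistics (one per comparison).
#' @param n_control Control group size.
#' @param n_groups Vector of non-control group sizes (same order as
#'   `abs_t`).
#' @param df Error degrees of freedom.
#' @param B Number of Monte-Carlo draws.
#' @param seed Seed for the draws.
#' @return Adjusted p-values in `[0, 1]`.
#' @export
dunnett_p_mc <- function(abs_t, n_control, n_groups, df, B = 1e5,
                         seed = 1) {
  k <- length(abs_t)
  stopifnot(length(n_groups) == k, df > 0)
  lam <- sqrt(n_groups / (n_groups + n_control))
  with_seed(derive_seed(seed, "dunnett_mc"), {
    z0 <- stats::rnorm(B)
    s <- sqrt(stats::rchisq(B, df) / df)
    maxt <- rep(-Inf, B)
    for (i in seq_len(k)) {
      zi <- lam[i] * z0 + sqrt(1 - lam[i]^2) * stats::rnorm(B)
      maxt <- pmax(maxt, abs(zi) / s)
    }
    vapply(abs_t, function(t0) mean(maxt >= t0), numeric(1))
  })
}

#' @export
print.stat_result <- function(x, digits = 4, ...) {
  cat("<stat_result> ", nrow(x), " comparison(s), method(s): ",
      paste(unique(x$method), collapse = ", "), "\n", sep = "")
  y <- as.data.frame(x)
  y$estimate <- signif(y$estimate, digits)
  y$statistic <- signif(y$statistic, digits)
  y$p_raw <- signif(y$p_raw, digits)
  y$p_adjusted <- signif(y$p_adjusted, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
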