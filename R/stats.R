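#' Significance symbol convention
#'
#' Maps a p-value to the conventional star symbols: `ns` when p > 0.05, and
#' `*`, `**`, `***`, `****` when p <= 0.05, 0.01, 0.001, 0.0001 respectively.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of symbols.
#' @examples
#' significance_symbol(c(0.05, 0.051, 0.0001)) # "*", "ns", "****"
#' @export
significance_symbol <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_parameter("p-values must lie in [0, 1]")
  }
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[p <= 0.0001] <- "****"
  out
}

#' Normality gate for group comparisons
#'
#' Column statistics preceding a two-group test: each sample is checked for
#' consistency with a Gaussian using the Shapiro-Wilk test at level `alpha`.
#' A sample passes (`TRUE`) when the test does not reject normality.
#' Degenerate samples (n < 3 or zero variance) cannot support the
#' parametric path and return `FALSE` (with a warning for n < 3), which
#' routes the comparison to the rank test.
#'
#' @param samples A list of numeric vectors (typically the two groups).
#' @param alpha Significance level of the normality test (default 0.05).
#' @return Logical vector, one element per sample.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (is.numeric(samples)) samples <- list(samples)
  vapply(samples, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3) {
      warning("sample has n < 3; treating as non-normal (rank test)")
      return(FALSE)
    }
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha
  }, logical(1))
}

group_summary <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(
    mean = mean(x),
    sem = if (n > 1) stats::sd(x) / sqrt(n) else 0,
    n = n
  )
}

#' Two-group comparison with a normality gate
#'
#' Compares two donor-level samples the way the assay's statistics are run:
#' if both samples are consistent with a Gaussian (Shapiro-Wilk at
#' `alpha`), an unpaired two-sided Student's t test (equal variances by
#' default, Welch via `var_equal = FALSE`) estimates the difference;
#' otherwise the non-parametric Mann-Whitney U test is applied. The
#' Mann-Whitney path uses exact enumeration for small samples (both n <= 8)
#' and the tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param a,b Numeric vectors of donor values, each with n >= 3.
#' @param alpha Level of the normality gate (default 0.05).
#' @param var_equal Use the classic equal-variance t statistic
#'   (default `TRUE`).
#' @param label_a,label_b Optional group labels for reporting.
#' @return An object of class `group_comparison`: `test_name`
#'   (`"t_unpaired"` or `"mann_whitney_u"`), `statistic`, `p_value`,
#'   `group_summaries` (mean, SEM, n per group), `significance_symbol`.
#' @export
compare_two_groups <- function(a, b, alpha = 0.05, var_equal = TRUE,
                               label_a = "a", label_b = "b") {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3) stop_analysis(sprintf("group '%s' has n < 3", label_a))
  if (length(b) < 3) stop_analysis(sprintf("group '%s' has n < 3", label_b))
  normal <- suppressWarnings(normality_gate(list(a, b), alpha))
  if (stats::sd(c(a, b)) == 0) {
    # fully degenerate: every observation identical in both groups
    test_name <- "mann_whitney_u"
    statistic <- length(a) * length(b) / 2
    p <- 1
  } else if (all(normal)) {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    test_name <- "t_unpaired"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    test_name <- "mann_whitney_u"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  }
  sums <- list(group_summary(a), group_summary(b))
  names(sums) <- c(label_a, label_b)
  structure(
    list(
      test_name = test_name,
      statistic = statistic,
      p_value = p,
      group_summaries = sums,
      significance_symbol = significance_symbol(p),
      normal = normal
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  s <- x$group_summaries
  cat(sprintf(
    "group_comparison [%s]: statistic %.4g, p = %.4g (%s)\n",
    x$test_name, x$statistic, x$p_value, x$significance_symbol
  ))
  for (nm in names(s)) {
    cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n", nm, s[[nm]]$mean, s[[nm]]$sem, s[[nm]]$n))
  }
  invisible(x)
}

#' Two-way ANOVA on the age x LPS design
#'
#' Fits a two-way factorial ANOVA with interaction on a donor-level
#' response (default: adherent density) over the 2 x 2 design of age group
#' (young/old) and LPS pre-stimulation (control/LPS). Because the emulated
#' cohorts are unbalanced (16 vs 14 donors), Type II sums of squares are
#' used by default.
#'
#' @param records Data frame of donor records with columns `age_group`
#'   (`"young"`/`"old"`), `treatment` (`"control"`/`"LPS"`), and the
#'   response column.
#' @param response Name of the response column (default
#'   `"adherent_density_mm2"`).
#' @param ss_type `"II"` (default) or `"III"`.
#' @return An object of class `anova_result`: `factor_p_values` and
#'   `f_statistics` (named `age`, `lps`, `interaction`), `design_counts`
#'   (2 x 2 table), `symbols`.
#' @export
two_way_anova_age_lps <- function(records,
                                  response = "adherent_density_mm2",
                                  ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  stopifnot(is.data.frame(records))
  if (!response %in% names(records)) {
    stop_analysis(sprintf("no column '%s' in records", response))
  }
  keep <- records$treatment %in% c("control", "LPS")
  records <- records[keep, , drop = FALSE]
  records$age_group <- factor(records$age_group, levels = c("young", "old"))
  records$lps <- factor(
    ifelse(records$treatment == "LPS", "LPS", "control"),
    levels = c("control", "LPS")
  )
  counts <- table(records$age_group, records$lps)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop_analysis(sprintf(
      "empty design cell: age_group='%s', treatment='%s'",
      rownames(counts)[bad[1]], colnames(counts)[bad[2]]
    ))
  }
  y <- records[[response]]
  nm <- c("age", "lps", "interaction")
  if (stats::sd(y) == 0) {
    # degenerate: no variance anywhere -> no evidence of any effect
    f <- stats::setNames(c(0, 0, 0), nm)
    p <- stats::setNames(c(1, 1, 1), nm)
  } else {
    fit <- stats::lm(y ~ age_group * lps, data = records)
    an <- car::Anova(fit, type = ss_type)
    rn <- rownames(an)
    pick <- function(pat) which(grepl(pat, rn))[1]
    rows <- c(pick("^age_group$"), pick("^lps$"), pick("age_group:lps"))
    f <- stats::setNames(an[rows, "F value"], nm)
    p <- stats::setNames(an[rows, "Pr(>F)"], nm)
  }
  structure(
    list(
      factor_p_values = p,
      f_statistics = f,
      design_counts = counts,
      symbols = stats::setNames(significance_symbol(pmin(p, 1)), nm),
      response = response,
      ss_type = ss_type
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("two-way ANOVA (type %s SS) on %s\n", x$ss_type, x$response))
  for (nm in names(x$factor_p_values)) {
    cat(sprintf(
      "  %-12s F = %.4g, p = %.4g (%s)\n",
      nm, x$f_statistics[nm], x$factor_p_values[nm], x$symbols[nm]
    ))
  }
  invisible(x)
}

#' LPS response ratio
#'
#' Relative adhesion response to LPS pre-stimulation: the ratio of the
#' stimulated to the unstimulated (control) adherent density, with the
#' corresponding percent increase `(ratio - 1) * 100`.
#'
#' @param stimulated,control Densities (vectorized; paired per donor or
#'   group means).
#' @return A data frame with `ratio` and `percent_increase`.
#' @examples
#' lps_response_ratio(19, 15) # ratio 1.267, +26.67%
#' @export
lps_response_ratio <- function(stimulated, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop_analysis("control density must be positive for a response ratio")
  }
  ratio <- stimulated / control
  data.frame(ratio = ratio, percent_increase = (ratio - 1) * 100)
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard relative quantification of qPCR expression: dCt is the target
#' Ct minus the reference-gene Ct (here conventionally B2M), ddCt subtracts
#' the calibrator's dCt, and the fold change is `2^-ddCt`.
#'
#' @param ct_target,ct_reference Cycle-threshold values (finite, typically
#'   10-40 cycles; vectorized).
#' @param calibrator_delta_ct The calibrator condition's dCt (scalar or
#'   vector).
#' @param gene Optional gene label(s), e.g. `"ITGAX"`, `"ITGB2"`.
#' @return A data frame of class `expression_result`: `gene`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`.
#' @examples
#' ddct_fold_change(25, 20, 5)  # ddCt 0 -> fold 1
#' ddct_fold_change(26, 20, 5)  # ddCt 1 -> fold 0.5
#' @export
ddct_fold_change <- function(ct_target, ct_reference, calibrator_delta_ct,
                             gene = NA_character_) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)) ||
      any(!is.finite(calibrator_delta_ct))) {
    stop_parameter("Ct values must be finite")
  }
  dct <- ct_target - ct_reference
  ddct <- dct - calibrator_delta_ct
  out <- data.frame(
    gene = gene,
    delta_ct = dct,
    delta_delta_ct = ddct,
    fold_change = 2^(-ddct)
  )
  class(out) <- c("expression_result", class(out))
  out
}

#' Response variance by age group
#'
#' The homogeneity of the LPS response differs between age groups: the
#' sample variance of per-donor response ratios is computed per group, with
#' a flag for whether the young group's response is more heterogeneous.
#'
#' @param ratios Numeric vector of per-donor response ratios.
#' @param age_group Character/factor vector parallel to `ratios` with
#'   levels `"young"`/`"old"`.
#' @return A list: `variance` (named per group), `young_more_heterogeneous`.
#' @export
response_variance_by_group <- function(ratios, age_group) {
  stopifnot(length(ratios) == length(age_group))
  groups <- split(ratios, age_group)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop_analysis("each age group needs n >= 2 for a variance")
  }
  v <- vapply(groups, stats::var, numeric(1))
  young_more <- if (all(c("young", "old") %in% names(v))) {
    unname(v["young"] > v["old"])
  } else {
    NA
  }
  list(variance = v, young_more_heterogeneous = young_more)
}
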