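# Quantitative comparisons: relative abundance profiles, Mann-Whitney group
# tests with Bonferroni family-wise thresholds, diagnostic fatty-acid ratios
# and the error-normalised fold change (ENFC).

#' Relative abundance of a signal profile
#'
#' @param profile non-negative numeric vector with at least one positive
#'   entry.
#' @return proportions summing to 1.
#' @export
relative_abundance <- function(profile) {
  if (length(profile) == 0L || anyNA(profile) || any(profile < 0)) {
    stop("profile must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(profile)
  if (total <= 0) stop("all-zero profile has no relative abundances",
                       call. = FALSE)
  profile / total
}

#' Two-sided Mann-Whitney comparison of two groups
#'
#' Lipidomics signal distributions are treated as unequally distributed and
#' heteroscedastic, so groups are compared with the two-sided Wilcoxon
#' rank-sum (Mann-Whitney) test: the exact null distribution when both
#' groups have at most 8 observations and the data are tie-free, otherwise
#' the normal approximation with tie correction.
#'
#' @param values_g1,values_g2 numeric vectors, each with >= 3 observations.
#' @return list of class `group_comparison` with `statistic` (the
#'   Mann-Whitney U for group 1), `p_raw` and `exact` (whether the exact
#'   distribution was used).
#' @export
compare_groups <- function(values_g1, values_g2) {
  if (length(values_g1) < 3L || length(values_g2) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  pooled <- c(values_g1, values_g2)
  ties <- anyDuplicated(pooled) > 0L
  exact <- length(values_g1) <= 8L && length(values_g2) <= 8L && !ties
  if (all(pooled == pooled[1L])) {
    # degenerate: every observation identical; no evidence either way
    ht <- list(statistic = c(W = length(values_g1) * length(values_g2) / 2),
               p.value = 1)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_g1, values_g2, exact = exact,
                         correct = TRUE, alternative = "two.sided")
    )
  }
  structure(list(statistic = unname(ht$statistic), p_raw = ht$p.value,
                 n1 = length(values_g1), n2 = length(values_g2),
                 exact = exact),
            class = "group_comparison")
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha nominal family-wise error rate, in (0, 1).
#' @param m number of variables tested (>= 1).
#' @return `alpha / m`. With `alpha = 0.05` over 33 fatty acids this is
#'   0.00152 to three significant figures.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)",
                                     call. = FALSE)
  if (length(m) != 1L || is.na(m) || m < 1) {
    stop("'m' must be a positive count", call. = FALSE)
  }
  alpha / m
}

#' Per-variable group comparisons with a Bonferroni threshold
#'
#' Applies [compare_groups()] to every lipid variable of a two-group dataset
#' (optionally within one compartment) and flags significance against the
#' Bonferroni threshold `alpha / m`, where `m` is the number of variables
#' tested. Thresholds are reported to 3 significant figures in the table;
#' p-values are kept at full precision.
#'
#' @param dataset a two-group [lipidomics_dataset()].
#' @param compartment optional compartment to restrict to.
#' @param alpha nominal family-wise error rate.
#' @return data frame: variable, statistic, p_raw, p_threshold_bonferroni,
#'   significant.
#' @export
group_comparison_table <- function(dataset, compartment = NULL,
                                   alpha = 0.05) {
  stopifnot(inherits(dataset, "lipidomics_dataset"))
  groups <- check_two_groups(dataset)
  keep <- rep(TRUE, nrow(dataset$samples))
  if (!is.null(compartment)) {
    keep <- dataset$samples$compartment == compartment
    if (!any(keep)) stop("no samples in compartment ", compartment,
                         call. = FALSE)
  }
  m <- ncol(dataset$abundance)
  thr <- signif(bonferroni_threshold(alpha, m), 3)
  sel1 <- keep & dataset$samples$group == groups[1L]
  sel2 <- keep & dataset$samples$group == groups[2L]
  rows <- lapply(colnames(dataset$abundance), function(v) {
    cg <- compare_groups(dataset$abundance[sel1, v],
                         dataset$abundance[sel2, v])
    data.frame(variable = v, statistic = cg$statistic, p_raw = cg$p_raw,
               p_threshold_bonferroni = thr,
               significant = cg$p_raw < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diagnostic fatty-acid ratio between two lipid variables
#'
#' Computes the numerator/denominator signal ratio per sample within one
#' compartment, then summarises per group and compares the per-sample ratios
#' between groups with [compare_groups()]. Per-sample ratios (rather than a
#' ratio of group means) are used so a sample-level significance value can
#' accompany the group means; `ratio_of_means` switches to the alternative.
#' Samples with a zero denominator are excluded with a warning; if every
#' sample is excluded the ratio is undefined.
#'
#' @param dataset a two-group [lipidomics_dataset()].
#' @param numerator,denominator shorthand names of measured variables, e.g.
#'   `"FA(15:0)"` and `"FA(17:0)"`.
#' @param compartment compartment to evaluate in.
#' @param ratio_of_means if `TRUE`, report mean(numerator)/mean(denominator)
#'   per group instead of the mean per-sample ratio.
#' @return list of class `fa_ratio`: per-group mean ratios, per-sample
#'   ratios, and the comparison `p_raw`.
#' @export
fa_ratio <- function(dataset, numerator, denominator, compartment,
                     ratio_of_means = FALSE) {
  stopifnot(inherits(dataset, "lipidomics_dataset"))
  groups <- check_two_groups(dataset)
  vars <- colnames(dataset$abundance)
  missing_vars <- setdiff(c(numerator, denominator), vars)
  if (length(missing_vars) > 0L) {
    stop("variable(s) not measured: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  keep <- dataset$samples$compartment == compartment
  if (!any(keep)) stop("no samples in compartment ", compartment,
                       call. = FALSE)
  num <- dataset$abundance[keep, numerator]
  den <- dataset$abundance[keep, denominator]
  grp <- dataset$samples$group[keep]
  zero_den <- den == 0
  if (all(zero_den)) {
    stop("denominator ", denominator, " is zero in every sample",
         call. = FALSE)
  }
  if (any(zero_den)) {
    warning(sum(zero_den), " sample(s) with zero denominator excluded",
            call. = FALSE)
    num <- num[!zero_den]; den <- den[!zero_den]; grp <- grp[!zero_den]
  }
  ratios <- split(num / den, factor(grp, levels = groups))
  means <- if (ratio_of_means) {
    vapply(groups, function(g) {
      mean(num[grp == g]) / mean(den[grp == g])
    }, numeric(1))
  } else {
    vapply(ratios, mean, numeric(1))
  }
  cg <- compare_groups(ratios[[1L]], ratios[[2L]])
  structure(list(numerator = numerator, denominator = denominator,
                 compartment = compartment, groups = groups,
                 mean_ratio = means, ratios = ratios, p_raw = cg$p_raw),
            class = "fa_ratio")
}

#' @export
print.fa_ratio <- function(x, ...) {
  cat(sprintf("%s / %s in %s: %s\n  p = %.3g\n", x$numerator, x$denominator,
              x$compartment,
              paste(sprintf("%s %.2g", x$groups, x$mean_ratio),
                    collapse = ", "),
              x$p_raw))
  invisible(x)
}

#' Error-normalised fold change
#'
#' The fold change `mean(case) / mean(control)` expressed on the log2 scale
#' and standardised by its propagated (delta-method) standard error:
#'
#' `ENFC = log2(FC) / se_log2FC`, with
#' `se_log2FC = sqrt(sd_case^2 / (n_case * mean_case^2) +
#'                   sd_control^2 / (n_control * mean_control^2)) / ln 2`.
#'
#' ENFC is dimensionless and antisymmetric — swapping case and control flips
#' its sign exactly — and is 0 precisely when the fold change is 1. Large
#' magnitudes mean the fold change is large relative to the noise on the two
#' group means.
#'
#' @param case,control numeric vectors of signal intensities, each with >= 3
#'   observations and a positive mean.
#' @return list of class `enfc_result`: `fold_change`, `enfc`, `mean_case`,
#'   `mean_control`, `sd_case`, `sd_control`, `n_case`, `n_control`.
#' @export
enfc <- function(case, control) {
  if (length(case) < 3L || length(control) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  m1 <- mean(case); m0 <- mean(control)
  if (m1 <= 0 || m0 <= 0) {
    stop("ENFC is undefined for non-positive group means", call. = FALSE)
  }
  s1 <- stats::sd(case); s0 <- stats::sd(control)
  fc <- m1 / m0
  se_log2 <- sqrt(s1^2 / (length(case) * m1^2) +
                  s0^2 / (length(control) * m0^2)) / log(2)
  structure(list(fold_change = fc,
                 # log2(m1) - log2(m0), not log2(m1/m0): the former makes
                 # antisymmetry exact in floating point
                 enfc = if (se_log2 == 0) {
                   # noise-free groups: sign of the log fold change, scaled
                   # to +/- Inf unless the fold change is exactly 1
                   if (fc == 1) 0 else sign(log(fc)) * Inf
                 } else (log2(m1) - log2(m0)) / se_log2,
                 mean_case = m1, mean_control = m0,
                 sd_case = s1, sd_control = s0,
                 n_case = length(case), n_control = length(control)),
            class = "enfc_result")
}

#' Per-variable ENFC table for a two-group dataset
#'
#' @param dataset a two-group [lipidomics_dataset()].
#' @param control_group which group label is the control (denominator of the
#'   fold change); the other group is the case.
#' @param compartment optional compartment restriction.
#' @return data frame: variable, mean_case, mean_control, fold_change, enfc.
#'   Variables with a non-positive mean in either group get `NA`.
#' @export
enfc_table <- function(dataset, control_group, compartment = NULL) {
  stopifnot(inherits(dataset, "lipidomics_dataset"))
  groups <- check_two_groups(dataset)
  if (!control_group %in% groups) {
    stop("control group ", sQuote(control_group), " not among: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  case_group <- setdiff(groups, control_group)
  keep <- rep(TRUE, nrow(dataset$samples))
  if (!is.null(compartment)) keep <- dataset$samples$compartment == compartment
  sel_case <- keep & dataset$samples$group == case_group
  sel_ctrl <- keep & dataset$samples$group == control_group
  rows <- lapply(colnames(dataset$abundance), function(v) {
    res <- tryCatch(enfc(dataset$abundance[sel_case, v],
                         dataset$abundance[sel_ctrl, v]),
                    error = function(e) NULL)
    data.frame(variable = v,
               mean_case = if (is.null(res)) NA_real_ else res$mean_case,
               mean_control = if (is.null(res)) NA_real_ else res$mean_control,
               fold_change = if (is.null(res)) NA_real_ else res$fold_change,
               enfc = if (is.null(res)) NA_real_ else res$enfc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "case_group") <- case_group
  attr(out, "control_group") <- control_group
  out
}
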