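#' Significance label for a p-value with trend banding
#'
#' Fixed mapping: p < 0.001 "***", p < 0.01 "**", p < 0.05 "*",
#' 0.05 <= p < 0.1 "trend" (reported but not significant), otherwise "NS".
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Character vector of labels.
#' @export
p_label <- function(p) {
  stopifnot(all(is.finite(p)), all(p >= 0), all(p <= 1))
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*",
  ifelse(p < 0.1, "trend", "NS"))))
}

#' Nonparametric group comparisons with trend banding
#'
#' Kruskal-Wallis across all groups, then two-sided Mann-Whitney U tests
#' for the planned pairs (all pairs by default). Pairwise p-values are
#' exact (full rank-permutation null) when both groups have at most
#' `exact_max` observations and no ties are present; otherwise the normal
#' approximation with tie correction is used. No multiple-testing
#' correction is applied by default, mirroring the within-run reporting
#' scheme; set `holm = TRUE` to adjust the pairwise p-values.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups, each
#'   with >= 3 values).
#' @param pairs Optional list of length-2 character vectors naming the
#'   planned pairs; default all unordered pairs.
#' @param exact_max Largest per-group size for exact Mann-Whitney p.
#' @param holm Apply Holm adjustment to the pairwise p-values.
#' @return List with `kruskal` (statistic, df, p, label) and `pairwise`
#'   (data.frame: group_a, group_b, statistic, p, label, test).
#' @export
compare_groups <- function(values_by_group, pairs = NULL, exact_max = 8L,
                           holm = FALSE) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2,
            !is.null(names(values_by_group)))
  ns <- vapply(values_by_group, length, 0L)
  if (any(ns < 3L)) stop("every group needs at least 3 values")
  kw <- stats::kruskal.test(values_by_group)
  if (is.null(pairs)) {
    nm <- names(values_by_group)
    pairs <- utils::combn(nm, 2L, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    a <- values_by_group[[pr[1L]]]; b <- values_by_group[[pr[2L]]]
    if (is.null(a) || is.null(b)) stop("unknown group in planned pair: ",
                                       paste(pr, collapse = " vs "))
    ties <- anyDuplicated(c(a, b)) > 0
    use_exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = use_exact, correct = !use_exact))
    data.frame(group_a = pr[1L], group_b = pr[2L],
               statistic = unname(wt$statistic), p = wt$p.value,
               test = if (use_exact) "mann_whitney_exact"
                      else "mann_whitney_normal",
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  if (holm) pw$p <- stats::p.adjust(pw$p, method = "holm")
  pw$p <- pmin(pw$p, 1)
  pw$label <- p_label(pw$p)
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value,
                      label = p_label(min(kw$p.value, 1))),
       pairwise = pw)
}

#' Median and interquartile range
#'
#' The IQR uses linear interpolation between order statistics
#' (`quantile` type 7), the documented quartile rule for all reported
#' summaries.
#'
#' @param values Numeric vector with at least one finite value.
#' @return List: median, iqr, q1, q3, n.
#' @export
summarize_median_iqr <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2L], iqr = q[3L] - q[1L], q1 = q[1L], q3 = q[3L],
       n = length(values))
}

#' Rigidity-frequency mechanical plane
#'
#' Collects (k_eff, omega_c) per cell and fits the purely descriptive
#' ordinary least-squares line omega_c = alpha + beta k_eff with the
#' standard error of the slope. When D is common across cells the points
#' fall on the exact line of slope D/kBT through the origin, so the plane
#' preserves rigidity ordering by construction.
#'
#' @param records data.frame with columns k_eff, omega_c and optionally
#'   condition (e.g. rbind of [cell_summary()] outputs).
#' @return List: `table` (condition, k_eff, omega_c), `fit` (alpha, beta,
#'   beta_se) or NULL with `fit_skipped = TRUE` when fewer than 2 distinct
#'   k_eff values are available.
#' @export
mech_plane <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("k_eff", "omega_c") %in% names(records)))
  tab <- data.frame(
    condition = if ("condition" %in% names(records)) records$condition
                else NA_character_,
    k_eff = records$k_eff, omega_c = records$omega_c,
    stringsAsFactors = FALSE)
  tab <- tab[is.finite(tab$k_eff) & is.finite(tab$omega_c), , drop = FALSE]
  if (length(unique(tab$k_eff)) < 2L) {
    return(list(table = tab, fit = NULL, fit_skipped = TRUE))
  }
  fit <- stats::lm(omega_c ~ k_eff, data = tab)
  # exact collinear input (common D) triggers a perfect-fit warning
  sm <- suppressWarnings(summary(fit))$coefficients
  list(table = tab,
       fit = list(alpha = unname(sm[1L, 1L]), beta = unname(sm[2L, 1L]),
                  beta_se = unname(sm[2L, 2L])),
       fit_skipped = FALSE)
}
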