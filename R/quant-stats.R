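# Densitometry normalizations and group statistics: marker/loading-control
# ratios, fold changes versus a control group, compartment percentages,
# the two-sided unpaired t-test and one-way ANOVA with Sidak-adjusted
# pairwise comparisons. Formulas are implemented directly; the test suite
# cross-checks them against R's stats routines on fixtures.

#' Normalized band ratio
#'
#' Marker intensity divided by its loading control (e.g. GAPDH or total
#' protein), or one marker by another (e.g. LC3-II/LC3-I,
#' phospho/total).
#'
#' @param numerator positive band intensity (vectorized).
#' @param denominator positive band intensity (loading control or second
#'   marker).
#' @return dimensionless ratio(s).
#' @export
normalized_ratio <- function(numerator, denominator) {
  if (any(!is.finite(denominator)) || any(denominator <= 0))
    stop("denominator band intensities must be positive", call. = FALSE)
  if (any(!is.finite(numerator)) || any(numerator <= 0))
    stop("numerator band intensities must be positive", call. = FALSE)
  numerator / denominator
}

#' Fold change relative to a control group
#'
#' Rescales values (typically normalized ratios) so the control group's
#' mean equals 1.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param control name of the control group.
#' @return numeric vector of fold changes, same order as `values`.
#' @export
fold_change <- function(values, groups, control) {
  if (!control %in% groups)
    stop("control group '", control, "' not present", call. = FALSE)
  m <- mean(values[groups == control])
  if (!is.finite(m) || m <= 0)
    stop("control group mean must be positive", call. = FALSE)
  values / m
}

#' Percentage of total across compartments
#'
#' Expresses band intensities measured across subcellular compartments as
#' percentages of their sum (e.g. percent of a protein associated with
#' each autophagic/lysosomal fraction).
#'
#' @param intensities non-negative numeric vector, at least one positive.
#' @return percentages summing to 100.
#' @export
compartment_percentages <- function(intensities) {
  if (any(intensities < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  s <- sum(intensities)
  if (s <= 0) stop("all band intensities are zero", call. = FALSE)
  100 * intensities / s
}

#' Two-sided unpaired t-test
#'
#' Student's pooled-variance statistic by default (`var_equal = TRUE`);
#' Welch's approximation otherwise. Two identical zero-variance samples
#' return `t = 0`, `p = 1` by convention.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return data frame of class `GroupComparison`: group means, SEMs, n,
#'   `statistic`, `df`, `p`, `p_adj` (= `p`), `method`.
#' @export
unpaired_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  diff <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (diff == 0) {
      aq_log("unpaired_t_test",
             "zero variance in both samples with equal means; p = 1",
             level = "WARN")
      tstat <- 0; df <- na + nb - 2; p <- 1
    } else stop("zero variance in both samples with unequal means",
                call. = FALSE)
  } else if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- diff / se
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    se <- sqrt(va / na + vb / nb)
    tstat <- diff / se
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  out <- data.frame(
    comparison = "a vs b",
    mean_a = mean(a), mean_b = mean(b),
    sem_a = stats::sd(a) / sqrt(na), sem_b = stats::sd(b) / sqrt(nb),
    n_a = na, n_b = nb, statistic = tstat, df = df, p = p, p_adj = p,
    method = if (var_equal) "Student t (pooled)" else "Welch t",
    stringsAsFactors = FALSE)
  class(out) <- c("GroupComparison", "data.frame")
  out
}

#' One-way ANOVA with Sidak-adjusted pairwise comparisons
#'
#' Omnibus F from between/within mean squares; each requested pairwise
#' comparison uses a t statistic on the pooled within-group variance
#' (residual df), with the Sidak adjustment
#' `p_adj = 1 - (1 - p)^m` over the `m` requested comparisons
#' (`adjust = "bonferroni"` gives `p_adj = min(1, m p)` instead).
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each n >= 2).
#' @param comparisons list of length-2 character vectors naming group
#'   pairs; `NULL` = all pairs.
#' @param adjust `"sidak"` (default) or `"bonferroni"`.
#' @return list with `anova` (data frame: `F`, `df1`, `df2`, `p`) and
#'   `comparisons` (a `GroupComparison` data frame, one row per pair).
#' @export
one_way_anova_sidak <- function(values, groups, comparisons = NULL,
                                adjust = c("sidak", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- table(groups)
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)
  k <- length(gl); N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_between <- sum(ns[gl] * (means[gl] - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1; df2 <- N - k
  ms_within <- ss_within / df2
  Fstat <- (ss_between / df1) / ms_within
  p_omni <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  if (ss_within == 0 && ss_between == 0) { Fstat <- 0; p_omni <- 1 }

  if (is.null(comparisons))
    comparisons <- utils::combn(gl, 2, simplify = FALSE)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pr) {
    if (length(pr) != 2 || !all(pr %in% gl))
      stop("bad comparison: ", paste(pr, collapse = ":"), call. = FALSE)
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    se <- sqrt(ms_within * (1 / length(a) + 1 / length(b)))
    tstat <- if (se > 0) (mean(a) - mean(b)) / se else 0
    p <- if (se > 0) 2 * stats::pt(-abs(tstat), df2) else 1
    p_adj <- if (adjust == "sidak") 1 - (1 - p)^m else min(1, m * p)
    data.frame(
      comparison = paste(pr, collapse = " vs "),
      mean_a = mean(a), mean_b = mean(b),
      sem_a = stats::sd(a) / sqrt(length(a)),
      sem_b = stats::sd(b) / sqrt(length(b)),
      n_a = length(a), n_b = length(b),
      statistic = tstat, df = df2, p = p, p_adj = p_adj,
      method = paste0("one-way ANOVA + ", adjust),
      stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, rows)
  class(cmp) <- c("GroupComparison", "data.frame")
  list(anova = data.frame(F = Fstat, df1 = df1, df2 = df2, p = p_omni),
       comparisons = cmp)
}

#' Densitometry analysis of a band table
#'
#' Computes normalized ratios (marker/loading, or marker2/marker when a
#' second marker column is present and `mode = "marker_ratio"`), fold
#' changes versus the control group, and the requested group statistics.
#'
#' @param bands data frame with `lane`, `group`, `marker`, `loading` and
#'   optionally `marker2`.
#' @param control control group name (default: first group in the table).
#' @param mode `"loading"` (marker/loading) or `"marker_ratio"`
#'   (marker2/marker).
#' @param test `"t"` (first two groups / control vs each) or `"anova"`.
#' @param adjust multiple-comparison adjustment for the ANOVA mode.
#' @return list with `per_lane` (ratios and fold changes) and `stats`.
#' @export
analyze_bands <- function(bands, control = NULL,
                          mode = c("loading", "marker_ratio"),
                          test = c("t", "anova"),
                          adjust = c("sidak", "bonferroni")) {
  mode <- match.arg(mode); test <- match.arg(test)
  stopifnot(all(c("group", "marker", "loading") %in% names(bands)))
  if (is.null(control)) control <- bands$group[1]
  ratio <- if (mode == "loading")
    normalized_ratio(bands$marker, bands$loading)
  else {
    if (is.null(bands$marker2))
      stop("mode 'marker_ratio' needs a `marker2` column", call. = FALSE)
    normalized_ratio(bands$marker2, bands$marker)
  }
  fc <- fold_change(ratio, bands$group, control)
  per_lane <- cbind(bands, ratio = ratio, fold_change = fc)
  gl <- unique(bands$group)
  stats_out <- if (test == "t") {
    others <- setdiff(gl, control)
    res <- lapply(others, function(g)
      transform(unpaired_t_test(fc[bands$group == control],
                                fc[bands$group == g]),
                comparison = paste(control, "vs", g)))
    do.call(rbind, res)
  } else {
    one_way_anova_sidak(fc, bands$group,
                        comparisons = lapply(setdiff(gl, control),
                                             function(g) c(control, g)),
                        adjust = match.arg(adjust))
  }
  list(per_lane = per_lane, stats = stats_out)
}
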