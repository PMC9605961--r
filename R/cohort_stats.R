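#' Group descriptive statistics
#'
#' Sample mean and SD (n-1 denominator) per group, with a reference
#' interval in the requested dialect attached. Groups with fewer than two
#' observations are an error.
#'
#' @param values numeric vector.
#' @param labels grouping vector (factor or character), same length.
#' @param dialect interval dialect passed to [reference_interval()].
#' @return data.frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `interval_low`, `interval_high`, `interval_dialect`.
#' @export
describe_groups <- function(values, labels,
                            dialect = c("ci_of_mean", "population_rr")) {
  dialect <- match.arg(dialect)
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  out <- lapply(split(values, labels), function(v) {
    if (length(v) < 2L) stop("group with n < 2", call. = FALSE)
    iv <- reference_interval(mean(v), stats::sd(v), length(v), dialect)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
               interval_low = iv[1], interval_high = iv[2],
               interval_dialect = dialect)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' 95% reference interval of a group
#'
#' Two interval dialects are in circulation for "mean +/- 1.96 x SD"-style
#' cohort tables. `population_rr` is the literal population reference
#' range, `mean +/- 1.96 * sd`, covering ~95% of individual samples.
#' `ci_of_mean` is `mean +/- 1.96 * sd / sqrt(n)`, the 95% confidence
#' interval of the group mean; published opera-cohort tables that print
#' narrow bounds around the mean follow this dialect, so it is the default
#' when reconstructing them. An integer rounding mode reproduces bounds
#' printed in whole Hz.
#'
#' @param mean group mean.
#' @param sd group SD, >= 0.
#' @param n group size (used by `ci_of_mean`), >= 1.
#' @param dialect `"ci_of_mean"` or `"population_rr"`.
#' @param round_int round bounds to integers (for whole-Hz tables).
#' @return numeric length-2 vector `c(low, high)`.
#' @examples
#' reference_interval(3092, 284, 774, "ci_of_mean", round_int = TRUE)
#' @export
reference_interval <- function(mean, sd, n = 1L,
                               dialect = c("ci_of_mean", "population_rr"),
                               round_int = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(sd >= 0, n >= 1)
  half <- if (dialect == "ci_of_mean") 1.96 * sd / sqrt(n) else 1.96 * sd
  out <- c(mean - half, mean + half)
  if (round_int) out <- round(out)
  out
}

#' Two-sample t-test for independent groups
#'
#' Student's pooled-variance statistic by default (`welch = TRUE` for the
#' unequal-variance variant), with a two-tailed p-value. The degenerate
#' case of zero pooled variance with equal means returns t = 0, p = 1 by
#' convention.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch unequal-variance variant.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Sample skewness (adjusted Fisher-Pearson estimator)
#'
#' @param values numeric, n >= 3. A constant sample has skewness 0 by
#'   convention.
#' @return skewness estimate.
#' @export
sample_skewness <- function(values) {
  stopifnot(length(values) >= 3)
  if (stats::sd(values) == 0) return(0)
  e1071::skewness(values, type = 2)
}

#' Near-symmetry gate for parametric testing
#'
#' Passes when the sample skewness lies strictly inside (-1, 1), the usual
#' screen applied before comparing group means with t-tests.
#'
#' @param values numeric sample, n >= 3.
#' @return logical.
#' @export
skewness_gate <- function(values) {
  s <- sample_skewness(values)
  s > -1 && s < 1
}

#' Pairwise Pearson correlation matrix of a feature table
#'
#' @param feature_table data.frame; only numeric columns enter the matrix.
#'   Constant columns yield `NA` correlations (with a warning suppressed).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(feature_table) {
  num <- feature_table[vapply(feature_table, is.numeric, logical(1))]
  if (nrow(num) < 2L) stop("need at least 2 complete rows", call. = FALSE)
  suppressWarnings(m <- stats::cor(as.matrix(num),
                                   use = "pairwise.complete.obs"))
  diag(m) <- ifelse(vapply(num, function(v) stats::sd(v) > 0, logical(1)),
                    1, NA_real_)
  m
}

#' Drop FHE in favour of PHE and SC for classification
#'
#' FHE and PHE carry the same information (PHE is an affine rescaling of
#' FHE within the band), and redundant inputs hurt ensemble robustness.
#' PHE is preferred over FHE on two grounds, both verified numerically on
#' the supplied table: its SD-to-mean ratio is larger (the affine map
#' shrinks the mean while scaling the SD), which helps classifiers place
#' the separating surface, and its correlation with SC is lower. Applied
#' per voice type when the table mixes bands.
#'
#' @param feature_table data.frame containing columns `FHE`, `PHE`, `SC`
#'   (tables without `FHE` are returned unchanged).
#' @return list: `table` (without the FHE column), `retained` (feature
#'   names kept), `justification` (per-voice-type data.frame with the
#'   SD/mean ratios and SC correlations of FHE vs PHE).
#' @export
select_energy_features <- function(feature_table) {
  if (!"FHE" %in% names(feature_table))
    return(list(table = feature_table,
                retained = intersect(c("PHE", "SC"), names(feature_table)),
                justification = NULL))
  stopifnot(all(c("PHE", "SC") %in% names(feature_table)))
  vt <- if ("voice_type" %in% names(feature_table))
    feature_table$voice_type else rep("all", nrow(feature_table))
  just <- do.call(rbind, lapply(split(feature_table, vt), function(g) {
    data.frame(
      voice_type = g$voice_type[1] %||% "all",
      cv_fhe = stats::sd(g$FHE) / mean(g$FHE),
      cv_phe = stats::sd(g$PHE) / mean(g$PHE),
      cor_fhe_sc = stats::cor(g$FHE, g$SC),
      cor_phe_sc = stats::cor(g$PHE, g$SC)
    )
  }))
  rownames(just) <- NULL
  list(table = feature_table[names(feature_table) != "FHE"],
       retained = c("PHE", "SC"),
       justification = just)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
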