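#' Reference cohort statistics for professional opera voices
#'
#' Published descriptive statistics (mean, SD, 95% reference range of the
#' mean, group sizes) of the timbre parameters FHE, PHE and SC for a cohort
#' of 1723 sustained-tone samples from professional opera singers, broken
#' down by voice type (soprano, tenor, baritone, bass) and voice structure
#' (lyric vs dramatic, plus the pooled "all" rows). These constants drive
#' the default parameters of [sample_population()] and serve as comparison
#' values for cohort-statistics checks.
#'
#' @return data.frame with one row per voice type x structure.
#' @export
cohort_reference <- function() {
  utils::read.csv(system.file("extdata", "cohort_reference.csv",
                              package = "cantimbre"),
                  stringsAsFactors = FALSE)
}

#' Reference vibrato statistics by voice type and structure
#'
#' Vibrato rate (VR, Hz) and extent (VE, cents) means and SDs used as
#' documentation constants for the synthetic feature populations. Rows with
#' `source == "published_rr"` are back-derived from published 95% reference
#' ranges of the group means; rows marked `"assumed"` are synthetic
#' stand-ins chosen to be physiologically plausible where no published
#' group value exists.
#'
#' @return data.frame with one row per voice type x structure.
#' @export
vibrato_reference <- function() {
  utils::read.csv(system.file("extdata", "vibrato_reference.csv",
                              package = "cantimbre"),
                  stringsAsFactors = FALSE)
}

#' Default two-class feature population parameters for a voice type
#'
#' Assembles per-feature Gaussian parameters (mean, SD) for the lyric and
#' dramatic structure of one voice type: PHE and SC from the cohort
#' reference table, VR and VE from the vibrato reference constants, and
#' weakly separated jitter/shimmer levels typical of trained voices.
#'
#' @param voice_type `"soprano"`, `"tenor"`, `"baritone"` or `"bass"`.
#' @return data.frame with columns `feature`, `lyric_mean`, `lyric_sd`,
#'   `dramatic_mean`, `dramatic_sd`.
#' @export
default_group_params <- function(voice_type = "baritone") {
  cr <- cohort_reference()
  vr <- vibrato_reference()
  ly <- cr[cr$voice_type == voice_type & cr$structure == "lyric", ]
  dr <- cr[cr$voice_type == voice_type & cr$structure == "dramatic", ]
  vly <- vr[vr$voice_type == voice_type & vr$structure == "lyric", ]
  vdr <- vr[vr$voice_type == voice_type & vr$structure == "dramatic", ]
  if (nrow(ly) != 1L || nrow(dr) != 1L)
    stop("unknown voice type: ", voice_type, call. = FALSE)
  data.frame(
    feature = c("PHE", "SC", "VR", "VE", "jitter", "shimmer"),
    lyric_mean = c(ly$phe_mean, ly$sc_mean, vly$vr_mean, vly$ve_mean,
                   0.45, 3.0),
    lyric_sd = c(ly$phe_sd, ly$sc_sd, vly$vr_sd, vly$ve_sd, 0.15, 1.0),
    dramatic_mean = c(dr$phe_mean, dr$sc_mean, vdr$vr_mean, vdr$ve_mean,
                      0.50, 3.2),
    dramatic_sd = c(dr$phe_sd, dr$sc_sd, vdr$vr_sd, vdr$ve_sd, 0.15, 1.0)
  )
}

#' Sample a labeled two-class feature population
#'
#' Draws independent Gaussian feature vectors per class from per-feature
#' (mean, SD) parameters -- the natural emulation of a cohort reported as
#' means and SDs with near-symmetric distributions. An optional correlation
#' matrix induces within-class dependence between features (applied via its
#' Cholesky factor to the standardized draws) to mimic the strong observed
#' FHE/PHE/SC correlations.
#'
#' @param group_params data.frame as returned by [default_group_params()]:
#'   columns `feature`, `lyric_mean`, `lyric_sd`, `dramatic_mean`,
#'   `dramatic_sd`, all SDs > 0.
#' @param n_per_class samples per class, at least 2.
#' @param seed integer seed.
#' @param voice_type label stored in the table.
#' @param correlation optional feature correlation matrix (shared by both
#'   classes), dimension = number of features.
#' @return data.frame (feature table): `sample_id`, `voice_type`,
#'   `voice_structure` (factor lyric/dramatic) and one numeric column per
#'   feature.
#' @export
sample_population <- function(group_params, n_per_class, seed = 1L,
                              voice_type = "baritone", correlation = NULL) {
  stopifnot(is.data.frame(group_params), n_per_class >= 2)
  if (any(group_params$lyric_sd <= 0) || any(group_params$dramatic_sd <= 0))
    stop("all SDs must be > 0", call. = FALSE)
  d <- nrow(group_params)
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation), nrow(correlation) == d,
              isSymmetric(correlation))
    L <- chol(correlation)
  }
  set.seed(seed)
  draw <- function(mu, sd, n) {
    z <- matrix(stats::rnorm(n * d), n, d)
    if (!is.null(correlation)) z <- z %*% L
    sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
  }
  xl <- draw(group_params$lyric_mean, group_params$lyric_sd, n_per_class)
  xd <- draw(group_params$dramatic_mean, group_params$dramatic_sd,
             n_per_class)
  x <- rbind(xl, xd)
  colnames(x) <- group_params$feature
  out <- data.frame(
    sample_id = sprintf("%s_%05d", voice_type, seq_len(2 * n_per_class)),
    voice_type = voice_type,
    voice_structure = factor(rep(c("lyric", "dramatic"),
                                 each = n_per_class),
                             levels = c("lyric", "dramatic")),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(x))
}
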