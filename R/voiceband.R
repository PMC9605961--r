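#' Singer's formant analysis band for a voice type
#'
#' The timbre parameters (FHE, PHE, SC, spectral moments) are computed over a
#' fixed frequency band \[B1, B2\] chosen per voice type to sit above the vowel
#' formants, where the singer's formant cluster (F3--F5) lives. Band edges are
#' shared within each gender so that lyric and dramatic voices of the same
#' type, and neighbouring voice types, are directly comparable:
#' soprano 2300--4500 Hz; tenor, baritone and bass 2000--3600 Hz.
#'
#' @param voice_type one of `"soprano"`, `"tenor"`, `"baritone"`, `"bass"`,
#'   or `"custom"` when `b1`/`b2` are given explicitly.
#' @param b1,b2 lower/upper band edge in Hz. Defaults come from the voice-type
#'   preset; override only for methodological experiments.
#' @return an object of class `voice_band` with fields `voice_type`, `b1`, `b2`.
#' @examples
#' voice_band("tenor")
#' voice_band("custom", b1 = 2500, b2 = 4000)
#' @export
voice_band <- function(voice_type = c("soprano", "tenor", "baritone", "bass",
                                      "custom"),
                       b1 = NULL, b2 = NULL) {
  voice_type <- match.arg(voice_type)
  preset <- switch(voice_type,
    soprano  = c(2300, 4500),
    tenor    = c(2000, 3600),
    baritone = c(2000, 3600),
    bass     = c(2000, 3600),
    custom   = c(NA_real_, NA_real_)
  )
  if (is.null(b1)) b1 <- preset[1]
  if (is.null(b2)) b2 <- preset[2]
  if (!is.finite(b1) || !is.finite(b2))
    stop("custom voice_band requires explicit b1 and b2", call. = FALSE)
  if (b1 >= b2) stop("voice_band requires b1 < b2", call. = FALSE)
  structure(list(voice_type = voice_type, b1 = as.numeric(b1),
                 b2 = as.numeric(b2)),
            class = "voice_band")
}

#' @export
print.voice_band <- function(x, ...) {
  cat(sprintf("<voice_band> %s: [%g, %g] Hz\n", x$voice_type, x$b1, x$b2))
  invisible(x)
}

as_voice_band <- function(x) {
  if (inherits(x, "voice_band")) return(x)
  if (is.character(x) && length(x) == 1L) return(voice_band(x))
  stop("expected a voice_band or a voice type name", call. = FALSE)
}
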