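#' Parse a sample label code
#'
#' Sample codes are pipe-delimited:
#' `<type_code>|<performer>|<pitch>|<vowel>|<work_title>[|<audio_path>[|<start>|<end>]]`.
#' The type code combines voice type and voice structure in the dialect of
#' singer shorthand: `S` soprano, `T` tenor, `B` baritone, `Bs` bass,
#' followed by `1` = dramatic or `2` = lyric (e.g. `T1` dramatic tenor,
#' `B2` lyric baritone). Pitch is a scientific note name (`f4`, `a#3`,
#' `bb3`), optionally with a measured frequency appended after `@`
#' (`f4@362`); the measured value takes precedence over the equal-tempered
#' conversion at A4 = 440 Hz.
#'
#' @param code label string.
#' @return object of class `sample_record`: `sample_id`, `voice_type`,
#'   `voice_structure`, `performer`, `pitch_label`, `pitch_hz`, `vowel`,
#'   `work_title`, `audio_path`, `start`, `end`.
#' @examples
#' parse_label_code("T1|Domingo|f4@362|a|LuisaMiller")
#' parse_label_code("B2|Cassi|f4|a|DonPasquale")
#' @export
parse_label_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || !nzchar(trimws(code)))
    stop("label parse error: empty code", call. = FALSE)
  parts <- trimws(strsplit(code, "|", fixed = TRUE)[[1]])
  if (length(parts) < 5L)
    stop("label parse error: expected at least 5 fields ",
         "(type|performer|pitch|vowel|work)", call. = FALSE)
  tc <- parts[1]
  m <- regmatches(tc, regexec("^(S|T|B|Bs)([12])$", tc))[[1]]
  if (length(m) == 0)
    stop("label parse error in field voice_type: '", tc, "'", call. = FALSE)
  voice_type <- c(S = "soprano", T = "tenor", B = "baritone",
                  Bs = "bass")[[m[2]]]
  voice_structure <- if (m[3] == "1") "dramatic" else "lyric"
  pitch <- parse_pitch(parts[3])
  start <- if (length(parts) >= 7L) as.numeric(parts[7]) else 0
  end <- if (length(parts) >= 8L) as.numeric(parts[8]) else Inf
  if (is.finite(end) && end - start > 12)
    warning("analysis interval longer than 12 s")
  structure(list(
    sample_id = paste(tc, parts[2], parts[3], parts[5], sep = "_"),
    voice_type = voice_type, voice_structure = voice_structure,
    performer = parts[2], pitch_label = pitch$label,
    pitch_hz = pitch$hz, vowel = parts[4], work_title = parts[5],
    audio_path = if (length(parts) >= 6L && nzchar(parts[6]))
      parts[6] else NA_character_,
    start = start, end = end
  ), class = "sample_record")
}

# note name -> Hz at A4 = 440; measured override via "name@Hz"
parse_pitch <- function(s) {
  if (grepl("@", s, fixed = TRUE)) {
    bits <- strsplit(s, "@", fixed = TRUE)[[1]]
    hz <- suppressWarnings(as.numeric(bits[2]))
    if (!is.finite(hz) || hz <= 0)
      stop("label parse error in field pitch: '", s, "'", call. = FALSE)
    return(list(label = bits[1], hz = hz))
  }
  m <- regmatches(tolower(s),
                  regexec("^([a-g])(#|b)?(-?[0-9])$", tolower(s)))[[1]]
  if (length(m) == 0)
    stop("label parse error in field pitch: '", s, "'", call. = FALSE)
  base <- c(c = -9, d = -7, e = -5, f = -4, g = -2, a = 0, b = 2)[[m[2]]]
  acc <- if (m[3] == "#") 1 else if (m[3] == "b") -1 else 0
  semis <- base + acc + 12 * (as.integer(m[4]) - 4L)
  list(label = s, hz = 440 * 2^(semis / 12))
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record> %s: %s %s, %s (%.1f Hz), vowel /%s/, '%s'\n",
              x$sample_id, x$voice_structure, x$voice_type, x$pitch_label,
              x$pitch_hz, x$vowel, x$work_title))
  invisible(x)
}

#' Extract the full per-sample feature row from audio
#'
#' Runs the whole analysis chain on one sustained tone: averaged spectrum,
#' band timbre parameters (FHE, PHE, SC, moments), vibrato rate/extent from
#' the tracked harmonic nearest the band center, jitter/shimmer, and
#' formant band strength/start/stop.
#'
#' @param samples mono waveform.
#' @param sample_rate Hz.
#' @param voice_type voice type name or `voice_band`.
#' @param f0 fundamental frequency in Hz (from the sample's pitch label or
#'   a measured value).
#' @param ... spectral-estimation settings passed to [extract_timbre()].
#' @return one-row data.frame with columns FHE, PHE, SC, SV, SS, SK, VR,
#'   VE, jitter, shimmer, StreFo, StaFo, StoFo.
#' @export
extract_features <- function(samples, sample_rate, voice_type, f0, ...) {
  band <- as_voice_band(voice_type)
  tf <- extract_timbre(samples, sample_rate, band, ...)
  sp <- compute_spectrum(samples, sample_rate)
  fb <- formant_band_features(sp, band)
  pert <- perturbation(samples, sample_rate, f0)
  # track the harmonic nearest the band center (the partial a vibrato
  # analysis would mark inside the singer's formant region)
  h <- max(1L, round((band$b1 + band$b2) / 2 / f0))
  vib <- tryCatch({
    ctr <- track_harmonic(samples, sample_rate, f0, h)
    vibrato_features(ctr)
  }, error = function(e) list(present = FALSE, vr = NA_real_,
                              ve = NA_real_))
  data.frame(FHE = tf$fhe, PHE = tf$phe, SC = tf$sc,
             SV = tf$spectral_variance, SS = tf$spectral_skewness,
             SK = tf$spectral_kurtosis,
             VR = vib$vr, VE = vib$ve,
             jitter = pert$jitter, shimmer = pert$shimmer,
             StreFo = fb$strength, StaFo = fb$start, StoFo = fb$stop)
}

#' Extract features for every sample of a manifest
#'
#' @param manifest character vector of label codes (each with an audio
#'   path field), or a data.frame with a `code` column.
#' @param base_dir directory against which relative audio paths resolve.
#' @return feature table: one row per sample with identifying columns
#'   followed by the feature columns of [extract_features()].
#' @export
extract_manifest <- function(manifest, base_dir = ".") {
  codes <- if (is.data.frame(manifest)) manifest$code else manifest
  if (length(codes) == 0) stop("empty manifest", call. = FALSE)
  rows <- lapply(codes, function(code) {
    rec <- parse_label_code(code)
    if (is.na(rec$audio_path))
      stop("manifest row without audio path: ", code, call. = FALSE)
    p <- if (file.exists(rec$audio_path)) rec$audio_path
         else file.path(base_dir, rec$audio_path)
    wav <- read_wav(p, rec$start, rec$end)
    feats <- extract_features(wav$samples, wav$sample_rate,
                              rec$voice_type, rec$pitch_hz)
    cbind(data.frame(sample_id = rec$sample_id,
                     voice_type = rec$voice_type,
                     voice_structure = rec$voice_structure,
                     performer = rec$performer,
                     pitch_hz = rec$pitch_hz,
                     stringsAsFactors = FALSE),
          feats)
  })
  do.call(rbind, rows)
}

#' Write / read a feature table CSV
#'
#' Fixed schema, UTF-8, '.' decimal separator; the written file reads back
#' into an identical table.
#'
#' @param table feature table data.frame.
#' @param path CSV path.
#' @return `path` invisibly for the writer, the table for the reader.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if ("voice_structure" %in% names(tab))
    tab$voice_structure <- factor(tab$voice_structure,
                                  levels = c("lyric", "dramatic"))
  tab
}
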