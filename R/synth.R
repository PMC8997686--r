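#' Default BCG beat wave components
#'
#' Canonical lettered deflections of one ballistocardiogram beat (pre-systolic
#' G wave, systolic H/I/J/K complex, diastolic L/M/N waves). Each component is
#' a Gaussian bump; a beat is the sum of its components. Positive amplitudes
#' are headward deflections, negative amplitudes footward. The J wave is the
#' dominant headward wave and carries the largest absolute amplitude.
#'
#' Latencies, amplitudes (arbitrary units) and Gaussian widths are not
#' physiologic measurements; they are chosen to reproduce the familiar G-N
#' beat morphology and can be overridden wholesale.
#'
#' @return A data frame with columns `name`, `latency` (s from beat onset),
#'   `amplitude` (signed, a.u.) and `width` (Gaussian standard deviation, s).
#' @export
#' @examples
#' comps <- bcg_wave_components()
#' beat <- make_wave_template(comps, beat_duration = 0.7, fs = 100)
bcg_wave_components <- function() {
  data.frame(
    name = c("G", "H", "I", "J", "K", "L", "M", "N"),
    latency = c(0.10, 0.17, 0.22, 0.28, 0.35, 0.45, 0.52, 0.60),
    amplitude = c(-0.2, 0.5, -0.6, 1.0, -0.5, 0.25, -0.15, 0.12),
    width = c(0.020, 0.020, 0.015, 0.020, 0.025, 0.030, 0.030, 0.030),
    stringsAsFactors = FALSE
  )
}

# Canonical sign of each lettered wave (headward positive).
.bcg_wave_signs <- c(G = -1, H = 1, I = -1, J = 1, K = -1, L = 1, M = -1, N = 1)

validate_wave_components <- function(components) {
  if (!is.data.frame(components)) {
    stop("`components` must be a data frame", call. = FALSE)
  }
  if (nrow(components) == 0L) {
    return(invisible(components))
  }
  req <- c("name", "latency", "amplitude", "width")
  if (!all(req %in% names(components))) {
    stop("`components` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(components$width <= 0)) {
    stop("wave widths must be positive", call. = FALSE)
  }
  if (is.unsorted(components$latency, strictly = TRUE)) {
    stop("wave latencies must strictly increase in component order",
         call. = FALSE)
  }
  known <- components$name %in% names(.bcg_wave_signs)
  if (any(known)) {
    sg <- .bcg_wave_signs[components$name[known]]
    if (any(sign(components$amplitude[known]) != sg)) {
      bad <- components$name[known][sign(components$amplitude[known]) != sg]
      stop("wave sign convention violated (headward positive) for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if ("J" %in% components$name) {
      aj <- abs(components$amplitude[components$name == "J"])
      if (any(abs(components$amplitude) > aj)) {
        stop("the J wave must carry the largest absolute amplitude",
             call. = FALSE)
      }
    }
  }
  invisible(components)
}

#' Build a single-beat waveform template
#'
#' Sums Gaussian-shaped deflections
#' \eqn{a \exp(-(t - \mu)^2 / (2 w^2))} on the sampling grid of one beat.
#'
#' @param components Data frame as returned by [bcg_wave_components()].
#' @param beat_duration Beat length in seconds; must leave room for the
#'   latest component (latency + 3 widths).
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector of `round(beat_duration * fs)` samples.
#' @export
make_wave_template <- function(components, beat_duration, fs) {
  validate_wave_components(components)
  if (beat_duration <= 0 || fs <= 0) {
    stop("beat_duration and fs must be positive", call. = FALSE)
  }
  n <- round(beat_duration * fs)
  t <- (seq_len(n) - 1) / fs
  beat <- numeric(n)
  if (nrow(components) == 0L) {
    return(beat)
  }
  if (beat_duration < max(components$latency + 3 * components$width)) {
    stop("beat_duration too short for the latest wave component",
         call. = FALSE)
  }
  for (i in seq_len(nrow(components))) {
    beat <- beat + components$amplitude[i] *
      exp(-(t - components$latency[i])^2 / (2 * components$width[i]^2))
  }
  beat
}

#' Synthetic BCG generator configuration
#'
#' Bundles every knob of the synthetic recording generator. Defaults describe
#' a resting adult on a sensing mattress: 70 beats/min with mild sinus
#' variability, quiet breathing at 0.25 Hz modulating beat amplitude by 20%,
#' and broadband sensor noise. The hypertensive (HPT) class differs from
#' healthy controls (HC) only through documented morphology knobs: sporadic
#' per-beat amplitude jumps (abrupt rises and falls) and inflated
#' beat-to-beat interval variability (fast variations along the time axis).
#'
#' @param n_hc,n_hpt Number of healthy-control / hypertensive subjects.
#' @param duration Recording length per subject, seconds.
#' @param fs Sampling frequency, Hz.
#' @param hr_mean,hr_sd Heart rate mean and standard deviation, beats/min.
#' @param resp_freq Respiratory frequency, Hz.
#' @param resp_depth Fractional respiratory amplitude modulation in [0, 1).
#' @param noise_sd Additive white Gaussian noise standard deviation (a.u.).
#' @param hpt_amp_jump_prob Per-beat probability that an HPT beat's amplitude
#'   is multiplied by `hpt_amp_jump_scale`.
#' @param hpt_amp_jump_scale Multiplicative amplitude factor (> 1) for
#'   jumped HPT beats.
#' @param hpt_hr_sd_scale Factor (>= 1) inflating `hr_sd` for HPT subjects.
#' @param components Beat morphology table, see [bcg_wave_components()].
#' @param beat_duration Length of one beat template, seconds.
#' @param seed Integer seed; fully determines the generated dataset.
#' @return An object of class `bcg_synth_config`.
#' @export
synth_config <- function(n_hc = 50, n_hpt = 50, duration = 120, fs = 100,
                         hr_mean = 70, hr_sd = 3, resp_freq = 0.25,
                         resp_depth = 0.2, noise_sd = 0.1,
                         hpt_amp_jump_prob = 0.25, hpt_amp_jump_scale = 2.5,
                         hpt_hr_sd_scale = 3, components = bcg_wave_components(),
                         beat_duration = 0.7, seed = 1L) {
  cfg <- list(
    n_hc = as.integer(n_hc), n_hpt = as.integer(n_hpt),
    duration = duration, fs = fs, hr_mean = hr_mean, hr_sd = hr_sd,
    resp_freq = resp_freq, resp_depth = resp_depth, noise_sd = noise_sd,
    hpt_amp_jump_prob = hpt_amp_jump_prob,
    hpt_amp_jump_scale = hpt_amp_jump_scale,
    hpt_hr_sd_scale = hpt_hr_sd_scale,
    components = components, beat_duration = beat_duration,
    seed = as.integer(seed)
  )
  class(cfg) <- "bcg_synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "bcg_synth_config"))
  if (cfg$n_hc < 0 || cfg$n_hpt < 0) stop("subject counts must be >= 0", call. = FALSE)
  if (cfg$duration <= 0) stop("duration must be positive", call. = FALSE)
  if (cfg$fs <= 0) stop("fs must be positive", call. = FALSE)
  if (cfg$hr_mean <= 0) stop("hr_mean must imply a positive inter-beat interval", call. = FALSE)
  if (cfg$hr_sd < 0) stop("hr_sd must be >= 0", call. = FALSE)
  if (cfg$resp_depth < 0 || cfg$resp_depth >= 1) stop("resp_depth must be in [0, 1)", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$hpt_amp_jump_prob < 0 || cfg$hpt_amp_jump_prob > 1) {
    stop("hpt_amp_jump_prob must be a probability", call. = FALSE)
  }
  if (cfg$hpt_amp_jump_scale <= 1) stop("hpt_amp_jump_scale must exceed 1", call. = FALSE)
  if (cfg$hpt_hr_sd_scale < 1) stop("hpt_hr_sd_scale must be >= 1", call. = FALSE)
  validate_wave_components(cfg$components)
  invisible(cfg)
}

new_bcg_record <- function(subject_id, label, fs, samples, meta = list()) {
  stopifnot(label %in% c("HC", "HPT"), fs > 0)
  structure(list(subject_id = subject_id, label = label, fs = fs,
                 samples = samples, meta = meta),
            class = "bcg_record")
}

#' @export
print.bcg_record <- function(x, ...) {
  cat(sprintf("<bcg_record> %s [%s], %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Generate one synthetic BCG recording
#'
#' Concatenates beat templates at normally distributed inter-beat intervals
#' (mean `60/hr_mean` s; the interval standard deviation is mapped from
#' `hr_sd` in beats/min by the delta rule `60 * hr_sd / hr_mean^2`), applies
#' sinusoidal respiratory amplitude modulation
#' `1 + resp_depth * sin(2 * pi * resp_freq * t)` and adds white Gaussian
#' noise. For `label = "HPT"` the interval standard deviation is inflated by
#' `hpt_hr_sd_scale` and each beat's amplitude is multiplied by
#' `hpt_amp_jump_scale` with probability `hpt_amp_jump_prob`.
#'
#' @param config A [synth_config()] object.
#' @param label `"HC"` or `"HPT"`.
#' @param subject_id Subject identifier string.
#' @param seed Integer seed for this recording's random stream.
#' @return A `bcg_record`.
#' @export
generate_recording <- function(config, label = c("HC", "HPT"),
                               subject_id = "S001", seed = config$seed) {
  validate_synth_config(config)
  label <- match.arg(label)
  n <- round(config$duration * config$fs)
  template <- make_wave_template(config$components, config$beat_duration,
                                 config$fs)
  ibi_mean <- 60 / config$hr_mean
  ibi_sd <- 60 * config$hr_sd / config$hr_mean^2
  if (label == "HPT") ibi_sd <- ibi_sd * config$hpt_hr_sd_scale

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # draw enough beats to cover the recording, place templates additively
  n_beats_max <- ceiling(config$duration / max(ibi_mean - 4 * ibi_sd, 0.3)) + 2L
  ibis <- stats::rnorm(n_beats_max, ibi_mean, ibi_sd)
  ibis <- pmax(ibis, 0.3)  # physiologic floor, keeps onsets ordered
  onsets <- cumsum(c(0, ibis))
  onsets <- onsets[onsets < config$duration]
  jumps <- if (label == "HPT") {
    stats::runif(length(onsets)) < config$hpt_amp_jump_prob
  } else {
    rep(FALSE, length(onsets))
  }

  x <- numeric(n)
  lt <- length(template)
  for (b in seq_along(onsets)) {
    i0 <- round(onsets[b] * config$fs) + 1L
    i1 <- min(i0 + lt - 1L, n)
    if (i0 > n) break
    amp <- if (jumps[b]) config$hpt_amp_jump_scale else 1
    x[i0:i1] <- x[i0:i1] + amp * template[seq_len(i1 - i0 + 1L)]
  }
  t <- (seq_len(n) - 1) / config$fs
  x <- x * (1 + config$resp_depth * sin(2 * pi * config$resp_freq * t))
  if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)

  new_bcg_record(subject_id, label, config$fs, x,
                 meta = list(seed = seed, n_beats = length(onsets)))
}

# save/restore the global RNG state so generator calls do not perturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a labeled synthetic BCG dataset
#'
#' Produces `n_hc` healthy-control and `n_hpt` hypertensive recordings with
#' unique subject ids. Each subject's random stream is seeded by a child seed
#' derived deterministically from `config$seed`, so the whole dataset is a
#' pure function of the configuration.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `records` (list of `bcg_record`) and
#'   `manifest` (data frame: subject_id, label, fs, duration, seed).
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  n_tot <- config$n_hc + config$n_hpt
  labels <- c(rep("HC", config$n_hc), rep("HPT", config$n_hpt))
  ids <- sprintf("%s%03d", ifelse(labels == "HC", "HC", "HPT"),
                 c(seq_len(config$n_hc), seq_len(config$n_hpt)))
  old <- .Random.seed_get()
  set.seed(config$seed)
  child_seeds <- if (n_tot > 0) sample.int(.Machine$integer.max - 1L, n_tot) else integer(0)
  .Random.seed_restore(old)

  records <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    records[[i]] <- generate_recording(config, labels[i], ids[i],
                                       seed = child_seeds[i])
  }
  manifest <- data.frame(
    subject_id = ids, label = labels, fs = rep(config$fs, n_tot),
    duration = rep(config$duration, n_tot),
    seed = if (n_tot > 0) child_seeds else integer(0),
    stringsAsFactors = FALSE
  )
  list(records = records, manifest = manifest)
}

#' Write a BCG dataset to disk
#'
#' Each recording becomes a two-column CSV (`time_s`, `amplitude`) named
#' `<subject_id>.csv`; the manifest is written as JSON.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_bcg_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in dataset$records) {
    tt <- (seq_along(rec$samples) - 1) / rec$fs
    utils::write.csv(data.frame(time_s = tt, amplitude = rec$samples),
                     file.path(dir, paste0(rec$subject_id, ".csv")),
                     row.names = FALSE)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(dataset$manifest, mpath, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA)
  invisible(mpath)
}

#' Read a BCG dataset written by [write_bcg_dataset()]
#'
#' @param dir Directory holding `manifest.json` and the per-subject CSVs.
#' @return A list with `records` and `manifest`, as [generate_dataset()].
#' @export
read_bcg_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest.json not found in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  records <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, paste0(manifest$subject_id[i], ".csv"))
    df <- utils::read.csv(path)
    if (!all(c("time_s", "amplitude") %in% names(df)) ||
        !is.numeric(df$amplitude) || !all(is.finite(df$amplitude))) {
      stop("corrupt recording CSV: ", path, call. = FALSE)
    }
    records[[i]] <- new_bcg_record(manifest$subject_id[i], manifest$label[i],
                                   manifest$fs[i], df$amplitude)
  }
  list(records = records, manifest = manifest)
}
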