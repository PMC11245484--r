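# Seeded simulator of two-condition PPG cohorts.
#
# Each beat is a two-kernel template (systolic bump plus a delayed, smaller
# dicrotic bump); beats are concatenated with Gaussian inter-beat intervals
# truncated to positive, then contaminated with baseline wander, powerline
# interference and white noise.  The fatigue class differs from the rested
# class only in beat-interval variability (reduced HRV) and dicrotic-wave
# amplitude (attenuated), both scaled by a single `separation` knob.

# KSS / PVT calibration: empirical distributions of a 12-participant,
# two-condition (fatigue / non-fatigue) reference assessment table; see
# inst/extdata/cohort_kss_pvt.csv.
.kss_pvt_cal <- list(
  fatigue     = list(kss_values = c(7L, 8L, 9L), kss_prob = c(8, 3, 1) / 12,
                     pvt_mean = 469.4, pvt_sd = 87.2),
  non_fatigue = list(kss_values = c(2L, 3L), kss_prob = c(2, 10) / 12,
                     pvt_mean = 356.25, pvt_sd = 28.5)
)

#' Simulator configuration
#'
#' Sampling and contamination settings for the synthetic PPG generator.
#' Amplitudes are relative to the unit systolic peak.
#'
#' @param fs_hz Sampling rate in Hz.  The default, 125 Hz, is a common
#'   pulse-oximeter rate and satisfies the Nyquist constraint for 50 Hz
#'   mains interference.
#' @param duration_s Recording length in seconds.
#' @param baseline_amp,baseline_hz Baseline-wander sinusoid amplitude and
#'   frequency (respiratory-range drift, 0.05-0.5 Hz).
#' @param powerline_amp,powerline_hz Mains-interference sinusoid amplitude
#'   and frequency.
#' @param white_sd Standard deviation of additive white Gaussian noise.
#' @param seed Integer seed; every draw the simulator makes derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs_hz = 125, duration_s = 600,
                         baseline_amp = 0.3, baseline_hz = 0.1,
                         powerline_amp = 0.05, powerline_hz = 50,
                         white_sd = 0.05, seed = 1L) {
  stopifnot(fs_hz > 0, duration_s > 0, baseline_amp >= 0, powerline_amp >= 0,
            white_sd >= 0, baseline_hz >= 0.05, baseline_hz <= 0.5)
  if (powerline_amp > 0 && fs_hz <= 2 * powerline_hz) {
    stop("fs_hz must exceed twice the powerline frequency (",
         powerline_hz, " Hz) when powerline_amp > 0")
  }
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 baseline_amp = baseline_amp, baseline_hz = baseline_hz,
                 powerline_amp = powerline_amp, powerline_hz = powerline_hz,
                 white_sd = white_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Beat template: systolic plus dicrotic bump
#'
#' Evaluates the noise-free single-beat PPG template at a phase within the
#' beat.  The template is the sum of two Gaussian kernels: a systolic bump
#' with unit peak amplitude and a delayed dicrotic bump scaled by
#' `dicrotic_amp_rel`.
#'
#' @param phase Beat phase in `[0, 1)` (vectorised).
#' @param dicrotic_amp_rel Dicrotic amplitude as a fraction of the systolic
#'   amplitude, in `[0, 1)`.
#' @param dicrotic_delay_rel Delay of the dicrotic bump after the systolic
#'   peak, as a fraction of the beat.
#' @param systolic_width,dicrotic_width Gaussian widths (fractions of the
#'   beat).
#' @return Template amplitude(s); systolic peak normalised to 1.
#' @export
ppg_pulse <- function(phase, dicrotic_amp_rel = 0.45,
                      dicrotic_delay_rel = 0.35,
                      systolic_width = 0.08, dicrotic_width = 0.12) {
  if (any(phase < 0 | phase >= 1)) stop("phase must lie in [0, 1)")
  if (dicrotic_amp_rel < 0 || dicrotic_amp_rel >= 1) {
    stop("dicrotic_amp_rel must lie in [0, 1)")
  }
  sys_center <- 0.2
  dic_center <- sys_center + dicrotic_delay_rel
  exp(-0.5 * ((phase - sys_center) / systolic_width)^2) +
    dicrotic_amp_rel * exp(-0.5 * ((phase - dic_center) / dicrotic_width)^2)
}

# positive-truncated normal by rejection, hard iteration cap
.rtruncnorm_pos <- function(n, mean, sd, cap = 1000L, lower = 0) {
  if (sd == 0) {
    if (mean <= lower) stop("degenerate truncated normal: mean ", mean,
                            " with sd 0 and lower bound ", lower)
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (i in seq_len(cap)) {
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw > lower])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncated-normal sampling failed after ", cap,
       " rounds (mean = ", mean, ", sd = ", sd, ", lower = ", lower, ")")
}

#' Subject profile for the simulator
#'
#' @param subject_id Short identifier.
#' @param condition `"fatigue"` or `"non_fatigue"`.
#' @param kss Integer sleepiness score.
#' @param pvt_ms Mean reaction latency in ms (> 0).
#' @param mean_ibi_s Mean inter-beat interval in seconds (> 0).
#' @param ibi_sd_s SD of inter-beat intervals (>= 0).
#' @param dicrotic_amp_rel Dicrotic amplitude fraction in `[0, 1)`.
#' @param n_windows Number of analysis windows this recording is expected to
#'   yield (>= 1).
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, condition = c("fatigue", "non_fatigue"),
                            kss = 7L, pvt_ms = 470, mean_ibi_s = 0.8,
                            ibi_sd_s = 0.05, dicrotic_amp_rel = 0.3,
                            n_windows = 40L) {
  condition <- match.arg(condition)
  stopifnot(pvt_ms > 0, mean_ibi_s > 0, ibi_sd_s >= 0,
            dicrotic_amp_rel >= 0, dicrotic_amp_rel < 1, n_windows >= 1)
  structure(list(subject_id = as.character(subject_id), condition = condition,
                 kss = as.integer(kss), pvt_ms = pvt_ms,
                 mean_ibi_s = mean_ibi_s, ibi_sd_s = ibi_sd_s,
                 dicrotic_amp_rel = dicrotic_amp_rel,
                 n_windows = as.integer(n_windows)),
            class = "subject_profile")
}

#' Simulate one PPG recording
#'
#' Draws a beat train with Gaussian inter-beat intervals (truncated to
#' positive), evaluates the beat template along it, and adds baseline wander,
#' powerline interference and white Gaussian noise.  Deterministic given
#' `(profile, config)`: all randomness derives from `config$seed` combined
#' with `seed_offset`.
#'
#' @param profile A [subject_profile()].
#' @param config A [synth_config()].
#' @param seed_offset Integer offset added to `config$seed`, used by
#'   [simulate_cohort()] to give each record its own stream.
#' @return An object of class `ppg_record`: list with `subject_id`,
#'   `condition`, `fs_hz`, `samples` (contaminated signal), `clean` (the
#'   noise-free signal), `beat_onsets` (true beat-onset times in seconds),
#'   and `meta` (the profile).
#' @export
simulate_record <- function(profile, config, seed_offset = 0L) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "synth_config"))
  with_seed(config$seed + as.integer(seed_offset), {
    n <- round(config$fs_hz * config$duration_s)
    t <- (seq_len(n) - 1L) / config$fs_hz
    # beat onsets: cumulative truncated-normal IBIs covering the recording
    n_beats <- ceiling(config$duration_s / profile$mean_ibi_s * 1.5) + 5L
    ibis <- .rtruncnorm_pos(n_beats, profile$mean_ibi_s, profile$ibi_sd_s,
                            lower = 0.25 * profile$mean_ibi_s)
    onsets <- cumsum(c(0, ibis))
    while (onsets[length(onsets)] <= config$duration_s) {
      extra <- .rtruncnorm_pos(10L, profile$mean_ibi_s, profile$ibi_sd_s,
                               lower = 0.25 * profile$mean_ibi_s)
      onsets <- c(onsets, onsets[length(onsets)] + cumsum(extra))
    }
    beat_idx <- findInterval(t, onsets)
    phase <- (t - onsets[beat_idx]) /
      (onsets[beat_idx + 1L] - onsets[beat_idx])
    phase <- pmin(pmax(phase, 0), 1 - 1e-12)
    clean <- ppg_pulse(phase, dicrotic_amp_rel = profile$dicrotic_amp_rel)
    noisy <- clean +
      config$baseline_amp *
        sin(2 * pi * config$baseline_hz * t + stats::runif(1, 0, 2 * pi)) +
      config$powerline_amp *
        sin(2 * pi * config$powerline_hz * t + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n, 0, config$white_sd)
    structure(list(subject_id = profile$subject_id,
                   condition = profile$condition,
                   fs_hz = config$fs_hz, samples = noisy, clean = clean,
                   beat_onsets = onsets[onsets <= config$duration_s],
                   meta = profile),
              class = "ppg_record")
  })
}

#' Draw KSS and PVT metadata for a condition
#'
#' Fatigue draws KSS from \{7, 8, 9\} with probabilities 8/12, 3/12, 1/12 and
#' PVT latency from a positive-truncated normal centred near 469 ms;
#' non-fatigue draws KSS from \{2, 3\} with probabilities 2/12, 10/12 and PVT
#' centred near 356 ms.  Uses the caller's RNG stream.
#'
#' @param condition `"fatigue"` or `"non_fatigue"`.
#' @param n Number of draws.
#' @return A tibble with columns `kss` (integer) and `pvt_ms` (double).
#' @export
sample_kss_pvt <- function(condition = c("fatigue", "non_fatigue"), n = 1L) {
  condition <- match.arg(condition)
  cal <- .kss_pvt_cal[[condition]]
  tibble::tibble(
    kss = sample(cal$kss_values, n, replace = TRUE, prob = cal$kss_prob),
    pvt_ms = .rtruncnorm_pos(n, cal$pvt_mean, cal$pvt_sd)
  )
}

#' Simulate a two-condition PPG cohort
#'
#' Generates, per subject, one fatigue and one non-fatigue recording.  The
#' two classes share each subject's mean inter-beat interval; fatigue
#' recordings have lower inter-beat-interval variability and an attenuated
#' dicrotic wave, with the size of both differences scaled by `separation`
#' (0 = identical class distributions, 1 = default study conditions).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config A [synth_config()].
#' @param separation Class-separation knob in `[0, 1]`.
#' @return A tibble with one row per recording: `subject_id`, `condition`,
#'   `kss`, `pvt_ms`, `mean_ibi_s`, `ibi_sd_s`, `dicrotic_amp_rel`, `fs_hz`,
#'   and a `record` list-column of `ppg_record` objects.
#' @export
simulate_cohort <- function(n_subjects = 12L, config = synth_config(),
                            separation = 1) {
  stopifnot(n_subjects >= 1, separation >= 0, separation <= 1)
  base_dicrotic <- 0.45
  base_ibi_sd <- 0.07
  profiles <- with_seed(config$seed, {
    purrr::map(seq_len(n_subjects), function(s) {
      sid <- sprintf("S%02d", s)
      mean_ibi <- .rtruncnorm_pos(1, 0.8, 0.04, lower = 0.55)
      jitter <- stats::runif(2, 0.9, 1.1)
      meta <- list(
        fatigue = sample_kss_pvt("fatigue"),
        non_fatigue = sample_kss_pvt("non_fatigue")
      )
      purrr::map(c("fatigue", "non_fatigue"), function(cond) {
        fat <- cond == "fatigue"
        subject_profile(
          subject_id = sid, condition = cond,
          kss = meta[[cond]]$kss, pvt_ms = meta[[cond]]$pvt_ms,
          mean_ibi_s = mean_ibi,
          ibi_sd_s = (base_ibi_sd - if (fat) 0.045 * separation else 0) *
            jitter[1 + fat],
          dicrotic_amp_rel = max(0, min(0.95,
            base_dicrotic - (if (fat) 0.30 * separation else 0) +
              stats::rnorm(1, 0, 0.02))),
          n_windows = max(1L, floor(round(config$fs_hz * config$duration_s) /
                                      1056))
        )
      })
    })
  })
  profiles <- purrr::flatten(profiles)
  records <- purrr::imap(profiles, function(p, i) {
    simulate_record(p, config, seed_offset = 1000L + i)
  })
  tibble::tibble(
    subject_id = purrr::map_chr(profiles, "subject_id"),
    condition = purrr::map_chr(profiles, "condition"),
    kss = purrr::map_int(profiles, "kss"),
    pvt_ms = purrr::map_dbl(profiles, "pvt_ms"),
    mean_ibi_s = purrr::map_dbl(profiles, "mean_ibi_s"),
    ibi_sd_s = purrr::map_dbl(profiles, "ibi_sd_s"),
    dicrotic_amp_rel = purrr::map_dbl(profiles, "dicrotic_amp_rel"),
    fs_hz = config$fs_hz,
    record = records
  )
}

#' Write a simulated cohort to disk
#'
#' Writes one CSV per recording (`sample_index`, `amplitude`) and a cohort
#' manifest CSV (`subject_id`, `condition`, `kss`, `pvt_ms`, `fs_hz`,
#' `file`).
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::pmap_chr(
    list(cohort$subject_id, cohort$condition, cohort$record),
    function(sid, cond, rec) {
      fn <- file.path(dir, paste0(sid, "_", cond, ".csv"))
      utils::write.csv(
        data.frame(sample_index = seq_along(rec$samples) - 1L,
                   amplitude = rec$samples),
        fn, row.names = FALSE)
      fn
    })
  manifest <- dplyr::mutate(
    cohort[, c("subject_id", "condition", "kss", "pvt_ms", "fs_hz")],
    file = basename(files))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and per-record CSVs.
#' @return A cohort tibble with a `record` list-column (records carry no
#'   clean-signal or beat-onset ground truth, which only the simulator
#'   knows).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  records <- purrr::pmap(manifest, function(subject_id, condition, kss,
                                            pvt_ms, fs_hz, file) {
    amp <- utils::read.csv(file.path(dir, file))$amplitude
    structure(list(subject_id = subject_id, condition = condition,
                   fs_hz = fs_hz, samples = amp, clean = NULL,
                   beat_onsets = NULL,
                   meta = subject_profile(subject_id, condition, kss = kss,
                                          pvt_ms = pvt_ms)),
              class = "ppg_record")
  })
  dplyr::mutate(tibble::as_tibble(manifest), record = records,
                file = NULL)
}

#' @export
print.ppg_record <- function(x, ...) {
  cat("<ppg_record> subject ", x$subject_id, " (", x$condition, "), ",
      length(x$samples), " samples @ ", x$fs_hz, " Hz\n", sep = "")
  invisible(x)
}
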