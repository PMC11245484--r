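# Labelling, window segmentation, derived heart-rate / breathing channels,
# and subject-wise cross-validation planning.

#' Map a KSS score to the fatigue / non-fatigue label
#'
#' Scores of 4 and above ("sleepy" and worse) are labelled fatigue; 3 and
#' below ("alert" and better) non-fatigue.
#'
#' @param kss Integer score(s) >= 1.
#' @return Character vector of `"fatigue"` / `"non_fatigue"`.
#' @export
label_from_kss <- function(kss) {
  if (any(!is.finite(kss)) || any(kss < 1) || any(kss != round(kss))) {
    stop("kss must be integers >= 1")
  }
  ifelse(kss >= 4, "fatigue", "non_fatigue")
}

#' Segment a recording into fixed-length windows
#'
#' Cuts a recording into equal-length windows (the trailing partial window is
#' dropped), each inheriting the recording's subject id and label.
#'
#' @param record A `ppg_record` (from the simulator, [read_cohort()], or a
#'   derived channel from [hr_series()] / [br_series()]).
#' @param window_s Window length in seconds.  `NULL` (default) uses the
#'   canonical model window of 1056 samples.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`.
#' @return A tibble with one row per window: `subject_id`, `window_index`,
#'   `channel`, `label`, and `samples` (list-column of channel-by-length
#'   matrices).
#' @export
segment <- function(record, window_s = NULL, overlap_fraction = 0) {
  stopifnot(inherits(record, "ppg_record"),
            overlap_fraction >= 0, overlap_fraction < 1)
  x <- record$samples
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  win <- if (is.null(window_s)) 1056L else as.integer(round(window_s * record$fs_hz))
  if (win < 2L) stop("window must span at least 2 samples")
  if (win > n) {
    stop("window of ", win, " samples is longer than the ", n,
         "-sample record")
  }
  stride <- max(1L, as.integer(round(win * (1 - overlap_fraction))))
  starts <- seq(1L, n - win + 1L, by = stride)
  label <- record$condition
  channel <- attr(record, "channel") %||% "ppg"
  tibble::tibble(
    subject_id = record$subject_id,
    window_index = seq_along(starts),
    channel = channel,
    label = label,
    samples = purrr::map(starts, function(s) x[, s:(s + win - 1L), drop = FALSE])
  )
}

#' Segment every recording of a cohort
#'
#' @param cohort Cohort tibble with a `record` list-column.
#' @param ... Passed to [segment()].
#' @return Row-bound windows tibble for all recordings.
#' @export
segment_cohort <- function(cohort, ...) {
  dplyr::bind_rows(purrr::map(cohort$record, segment, ...))
}

# systolic peak detection: local maxima above an adaptive threshold
# (fraction of a rolling 2-s maximum) with a refractory period
.detect_peaks <- function(x, fs, threshold_frac = 0.6, roll_s = 2,
                          refractory_s = 0.3) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) == -2) + 1L
  half <- max(1L, as.integer(round(roll_s * fs / 2)))
  roll_max <- vapply(cand, function(i) {
    max(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  # reference the threshold to the local waveform floor, not to zero,
  # so slow baseline drift does not starve troughed regions of peaks
  roll_min <- vapply(cand, function(i) {
    min(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  cand <- cand[x[cand] >= roll_min + threshold_frac * (roll_max - roll_min)]
  keep <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    t <- (i - 1) / fs
    if (t - last_t >= refractory_s) {
      keep <- c(keep, i)
      last_t <- t
    } else if (length(keep) && x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i   # keep the taller of peaks within refractory
      last_t <- t
    }
  }
  keep
}

#' Instantaneous heart-rate channel
#'
#' Detects systolic peaks (local maxima above an adaptive threshold, 60% of
#' the local 2-s dynamic range, with a 0.3-s refractory period), converts
#' inter-beat intervals to instantaneous heart rate in beats/min, and
#' resamples the rate uniformly.
#'
#' @param record A `ppg_record`.
#' @param resample_hz Uniform output rate (default 4 Hz).
#' @return A `ppg_record` whose `samples` are the uniformly sampled HR
#'   series (bpm) at `resample_hz`, tagged with channel `"hr"`.
#' @export
hr_series <- function(record, resample_hz = 4) {
  stopifnot(inherits(record, "ppg_record"))
  peaks <- .detect_peaks(record$samples, record$fs_hz)
  if (length(peaks) < 3L) {
    stop("only ", length(peaks), " peaks detected; need at least 3 beats")
  }
  pt <- (peaks - 1) / record$fs_hz
  ibi <- diff(pt)
  hr <- 60 / ibi
  mid <- (pt[-1] + pt[-length(pt)]) / 2
  dur <- length(record$samples) / record$fs_hz
  grid <- seq(0, dur - 1 / resample_hz, by = 1 / resample_hz)
  out <- stats::approx(mid, hr, xout = grid, rule = 2)$y
  structure(
    list(subject_id = record$subject_id, condition = record$condition,
         fs_hz = resample_hz, samples = out, clean = NULL,
         beat_onsets = pt, meta = record$meta),
    class = "ppg_record", channel = "hr")
}

#' Respiratory (breathing) channel
#'
#' Band-passes the recording to the respiratory band (0.1-0.5 Hz) with a
#' zero-phase second-order Butterworth filter, extracting the baseline /
#' amplitude modulation of the pulse wave, and resamples it uniformly.
#'
#' @inheritParams hr_series
#' @return A `ppg_record` with the zero-mean respiratory waveform at
#'   `resample_hz`, tagged with channel `"br"`.
#' @export
br_series <- function(record, resample_hz = 4) {
  stopifnot(inherits(record, "ppg_record"))
  dur <- length(record$samples) / record$fs_hz
  if (dur < 30) stop("record of ", round(dur, 1), " s is too short; ",
                     "need >= 30 s for the respiratory band")
  bf <- signal::butter(2, c(0.1, 0.5) / (record$fs_hz / 2), type = "pass")
  filt <- signal::filtfilt(bf, record$samples - mean(record$samples))
  grid <- seq(0, dur - 1 / resample_hz, by = 1 / resample_hz)
  t <- (seq_along(filt) - 1) / record$fs_hz
  out <- stats::approx(t, filt, xout = grid, rule = 2)$y
  structure(
    list(subject_id = record$subject_id, condition = record$condition,
         fs_hz = resample_hz, samples = out - mean(out), clean = NULL,
         beat_onsets = NULL, meta = record$meta),
    class = "ppg_record", channel = "br")
}

#' Stacked heart-rate + breathing channel
#'
#' Channel-wise stacking of the [hr_series()] and [br_series()] outputs into
#' a two-channel record (both at the same uniform rate).
#'
#' @inheritParams hr_series
#' @return A two-channel `ppg_record` (samples matrix 2 x n), channel
#'   `"hr_br"`.
#' @export
hr_br_series <- function(record, resample_hz = 4) {
  hr <- hr_series(record, resample_hz)
  br <- br_series(record, resample_hz)
  n <- min(length(hr$samples), length(br$samples))
  structure(
    list(subject_id = record$subject_id, condition = record$condition,
         fs_hz = resample_hz,
         samples = rbind(hr$samples[seq_len(n)], br$samples[seq_len(n)]),
         clean = NULL, beat_onsets = hr$beat_onsets, meta = record$meta),
    class = "ppg_record", channel = "hr_br")
}

#' Subject-wise cross-validation plan
#'
#' Builds subject-disjoint folds: either a k-fold partition of subjects into
#' near-equal groups (shuffled by `seed`) or leave-one-subject-out.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param scheme `"kfold_by_subject"` or `"leave_one_subject_out"`.
#' @param k Number of folds for the k-fold scheme.
#' @param seed Shuffle seed.
#' @return A `fold_plan` tibble with columns `fold`, `train_subjects` and
#'   `test_subjects` (list-columns).
#' @export
make_folds <- function(subject_ids,
                       scheme = c("kfold_by_subject", "leave_one_subject_out"),
                       k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (scheme == "leave_one_subject_out") {
    groups <- as.list(subject_ids)
  } else {
    if (k > n) stop("k = ", k, " exceeds the ", n, " available subjects")
    shuffled <- with_seed(seed, sample(subject_ids))
    groups <- split(shuffled, rep_len(seq_len(k), n))
  }
  plan <- tibble::tibble(
    fold = seq_along(groups),
    test_subjects = purrr::map(groups, identity),
    train_subjects = purrr::map(groups, function(g) setdiff(subject_ids, g))
  )
  structure(plan[, c("fold", "train_subjects", "test_subjects")],
            class = c("fold_plan", class(plan)),
            scheme = scheme, seed = seed)
}

#' Training / test window counts for the folds of a plan
#'
#' @param plan A [make_folds()] plan.
#' @param windows_per_subject Number of windows contributed by each subject.
#' @return A tibble with `fold`, `n_train`, `n_test`.
#' @export
split_counts <- function(plan, windows_per_subject) {
  stopifnot(inherits(plan, "fold_plan"), windows_per_subject >= 0)
  tibble::tibble(
    fold = plan$fold,
    n_train = lengths(plan$train_subjects) * windows_per_subject,
    n_test = lengths(plan$test_subjects) * windows_per_subject
  )
}
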