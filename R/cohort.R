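#' Specify a synthetic two-session ECG cohort
#'
#' Describes the acquisition design to emulate: a fixed number of subjects,
#' each recorded in two sessions separated in time, single-channel ECG at a
#' given sampling rate. Between-subject morphology separation, inter-session
#' drift and the three noise sources (baseline wander, powerline pickup,
#' EMG-like broadband) are all controllable so that downstream matching can be
#' exercised at known difficulty.
#'
#' Defaults emulate an off-the-person, dry-electrode finger-ECG study design:
#' 63 subjects, two sessions, 2 min per record at 1 kHz, with moderate noise
#' and a low inter-session drift.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param duration_s record duration in seconds per subject per session.
#' @param fs sampling frequency in Hz (must exceed twice the 30 Hz band edge).
#' @param between_subject_sd scale of the between-subject morphology
#'   variation (unitless multiplier on the perturbation model; 0 collapses
#'   the cohort onto a single shared morphology).
#' @param session_drift scale of the zero-mean morphology perturbation applied
#'   between session 1 and session 2 (0 means identical sessions).
#' @param baseline_wander_amp peak amplitude (signal units, mV-scale) of the
#'   sub-0.4 Hz baseline wander.
#' @param powerline_amp amplitude of the 50 Hz powerline component.
#' @param broadband_sd standard deviation of the white EMG-like noise.
#' @param seed integer seed; all cohort randomness derives from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 63, duration_s = 120, fs = 1000,
                        between_subject_sd = 0.3, session_drift = 0.05,
                        baseline_wander_amp = 0.2, powerline_amp = 0.05,
                        broadband_sd = 0.05, seed = 1) {
  spec <- list(
    n_subjects = as.integer(n_subjects), sessions = 2L,
    duration_s = duration_s, fs = fs,
    between_subject_sd = between_subject_sd, session_drift = session_drift,
    baseline_wander_amp = baseline_wander_amp, powerline_amp = powerline_amp,
    broadband_sd = broadband_sd, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("not a cohort_spec")
  if (spec$n_subjects < 2L) stop("cohort_spec: n_subjects must be >= 2")
  if (spec$fs <= 60) stop("cohort_spec: fs must exceed 60 Hz (2 x 30 Hz band edge)")
  if (spec$duration_s <= 0) stop("cohort_spec: duration_s must be positive")
  amps <- c(spec$between_subject_sd, spec$session_drift,
            spec$baseline_wander_amp, spec$powerline_amp, spec$broadband_sd)
  if (any(amps < 0)) stop("cohort_spec: scales and amplitudes must be >= 0")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic ECG cohort spec\n")
  cat(sprintf("  %d subjects x 2 sessions, %.0f s @ %g Hz\n",
              x$n_subjects, x$duration_s, x$fs))
  cat(sprintf("  between-subject sd %.3g, session drift %.3g\n",
              x$between_subject_sd, x$session_drift))
  cat(sprintf("  noise: baseline %.3g, 50 Hz %.3g, broadband sd %.3g, seed %d\n",
              x$baseline_wander_amp, x$powerline_amp, x$broadband_sd, x$seed))
  invisible(x)
}

#' Canonical heartbeat morphology
#'
#' One heartbeat is modelled as the sum of five Gaussian bumps (P, Q, R, S, T)
#' placed relative to the R peak at time 0. Amplitudes are mV-scale, centers
#' and widths in seconds. The default is a textbook-shaped sinus beat at
#' 75 bpm with 3 bpm heart-rate variability.
#'
#' @return object of class `morphology` with fields `waves` (data frame with
#'   columns wave, amp, center, width), `hr_bpm` and `hrv_sd_bpm`.
#' @export
default_morphology <- function() {
  m <- list(
    waves = data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      amp    = c(0.15, -0.10, 1.00, -0.18, 0.35),
      center = c(-0.180, -0.035, 0.000, 0.030, 0.260),
      width  = c(0.025, 0.010, 0.012, 0.011, 0.045),
      stringsAsFactors = FALSE
    ),
    hr_bpm = 75, hrv_sd_bpm = 3
  )
  class(m) <- "morphology"
  m
}

validate_morphology <- function(m) {
  w <- m$waves
  if (!all(w$width > 0)) stop("morphology: widths must be positive")
  if (is.unsorted(w$center, strictly = TRUE))
    stop("morphology: wave centers must be ordered P < Q < R < S < T")
  r <- w$amp[w$wave == "R"]
  if (r <= abs(w$amp[w$wave == "Q"]) || r <= abs(w$amp[w$wave == "S"]))
    stop("morphology: R amplitude must dominate |Q| and |S|")
  if (m$hr_bpm < 40 || m$hr_bpm > 180)
    stop("morphology: mean heart rate must lie in [40, 180] bpm")
  invisible(m)
}

# Deterministic per-record seed derived from (cohort seed, subject, session).
# Lehmer-style mixing in double precision; result stays below 2^31 so it is a
# valid set.seed() argument. Cohorts are thereby stable under subsetting.
record_seed <- function(seed, subject_idx, session_idx) {
  m <- 2147483647
  v <- (as.double(seed) %% m)
  v <- (v * 48271 + subject_idx * 69621 + session_idx * 1013904) %% m
  v <- (v * 16807 + 17) %% m
  as.integer(v)
}

# Perturb a morphology: multiplicative log-normal jitter on amplitudes and
# widths, additive jitter on centers (R stays anchored at 0) and heart rate.
# z-draws are truncated at +/- 2.5 and the amplitude-dominance invariant
# (R above |Q| and |S|) is enforced by clamping, so any perturbation scale
# yields a valid morphology.
perturb_morphology <- function(m, scale) {
  z <- function(n) pmax(pmin(stats::rnorm(n), 2.5), -2.5)
  w <- m$waves
  w$amp <- w$amp * exp(scale * z(5))
  r_amp <- w$amp[w$wave == "R"]
  for (wv in c("Q", "S")) {
    i <- which(w$wave == wv)
    if (abs(w$amp[i]) >= 0.9 * r_amp)
      w$amp[i] <- sign(w$amp[i]) * 0.9 * r_amp
  }
  jit <- c(0.020, 0.005, 0, 0.005, 0.030)  # per-wave center jitter (s)
  w$center <- w$center + scale * jit * z(5)
  w$width <- w$width * exp(0.5 * scale * z(5))
  m$waves <- w
  m$hr_bpm <- min(180, max(40, m$hr_bpm + 10 * scale * z(1)))
  m$hrv_sd_bpm <- m$hrv_sd_bpm * exp(0.3 * scale * z(1))
  validate_morphology(m)
  m
}

#' Draw per-subject, per-session heartbeat morphologies
#'
#' Session-1 morphologies are independent perturbations of the canonical
#' beat scaled by `between_subject_sd`; session-2 morphologies are the
#' session-1 parameters plus a zero-mean perturbation scaled by
#' `session_drift`. The drift perturbation is drawn from a stream that does
#' not depend on the drift value, so cohorts at different drift levels share
#' the same underlying draws and differ only in scale.
#'
#' @param spec a [cohort_spec()].
#' @return named list (one entry per subject id) of lists with elements
#'   `session1` and `session2`, each a `morphology`.
#' @export
sample_cohort_morphologies <- function(spec) {
  validate_cohort_spec(spec)
  ids <- subject_ids(spec$n_subjects)
  out <- vector("list", spec$n_subjects)
  names(out) <- ids
  for (i in seq_len(spec$n_subjects)) {
    set.seed(record_seed(spec$seed, i, 101L))
    m1 <- perturb_morphology(default_morphology(), spec$between_subject_sd)
    set.seed(record_seed(spec$seed, i, 102L))
    m2 <- perturb_morphology(m1, spec$session_drift)
    out[[i]] <- list(session1 = m1, session2 = m2)
  }
  out
}

subject_ids <- function(n) {
  sprintf(paste0("S%0", max(2L, nchar(n)), "d"), seq_len(n))
}

#' Synthesize one ECG record
#'
#' Places R times by drawing inter-beat intervals from a Gaussian around
#' 60/HR seconds (sd set by the heart-rate variability, truncated at
#' +/- 3 sd and floored at 0.3 s so beats never overlap), snaps them to the
#' sample grid, and sums the five Gaussian wave bumps per beat. Baseline
#' wander (2-3 sinusoids below 0.4 Hz), 50 Hz powerline pickup and white
#' broadband noise are added afterward.
#'
#' @param morph a `morphology`.
#' @param spec a [cohort_spec()] (supplies fs, duration and noise levels).
#' @param seed integer seed for this record's random stream.
#' @param subject_id,session_id identifiers stored in the record.
#' @return object of class `ecg_record`: list with `subject_id`, `session_id`,
#'   `fs`, `signal` and `true_r_peaks` (1-based sample indices of the
#'   simulated R-bump centers).
#' @export
synthesize_ecg <- function(morph, spec, seed = 1L,
                           subject_id = "S01", session_id = 1L) {
  validate_morphology(morph)
  validate_cohort_spec(spec)
  set.seed(as.integer(seed))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  m_int <- 60 / morph$hr_bpm
  sd_int <- m_int * morph$hrv_sd_bpm / morph$hr_bpm
  if (spec$duration_s / m_int < 2)
    stop("synthesize_ecg: duration and heart rate imply fewer than 2 beats")
  n_max <- ceiling(spec$duration_s / max(0.3, m_int - 3 * sd_int)) + 2L
  ints <- stats::rnorm(n_max, m_int, sd_int)
  ints <- pmax(pmin(ints, m_int + 3 * sd_int), pmax(m_int - 3 * sd_int, 0.3))
  r_times <- 0.5 * m_int + cumsum(c(0, ints))
  r_times <- r_times[r_times < spec$duration_s]
  r_idx <- as.integer(round(r_times * fs)) + 1L   # snap to the sample grid
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]
  r_times <- (r_idx - 1) / fs

  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  w <- morph$waves
  for (b in r_times) {
    for (j in seq_len(nrow(w))) {
      c_j <- b + w$center[j]; s_j <- w$width[j]
      lo <- max(1L, floor((c_j - 5 * s_j) * fs) + 1L)
      hi <- min(n, ceiling((c_j + 5 * s_j) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + w$amp[j] * exp(-0.5 * ((t[idx] - c_j) / s_j)^2)
    }
  }
  if (spec$baseline_wander_amp > 0) {
    k <- sample(2:3, 1)
    f <- stats::runif(k, 0.05, 0.4); ph <- stats::runif(k, 0, 2 * pi)
    for (j in seq_len(k))
      x <- x + (spec$baseline_wander_amp / k) * sin(2 * pi * f[j] * t + ph[j])
  }
  if (spec$powerline_amp > 0)
    x <- x + spec$powerline_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
  if (spec$broadband_sd > 0)
    x <- x + stats::rnorm(n, 0, spec$broadband_sd)

  structure(list(subject_id = subject_id, session_id = as.integer(session_id),
                 fs = fs, signal = x, true_r_peaks = r_idx),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record %s session %d: %d samples @ %g Hz, %d R peaks\n",
              x$subject_id, x$session_id, length(x$signal), x$fs,
              length(x$true_r_peaks)))
  invisible(x)
}

#' Generate a full two-session cohort
#'
#' One record per subject per session. Every record draws from its own
#' random stream derived from (seed, subject index, session index), so the
#' same subjects reappear identically when the cohort is regenerated or
#' subset.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `ecg_cohort`: list with `spec`, `morphologies`
#'   and `records` (list of `ecg_record`, subjects x sessions).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  morphs <- sample_cohort_morphologies(spec)
  ids <- names(morphs)
  records <- vector("list", spec$n_subjects * 2L)
  k <- 0L
  for (i in seq_len(spec$n_subjects)) {
    for (s in 1:2) {
      k <- k + 1L
      records[[k]] <- synthesize_ecg(
        morphs[[i]][[s]], spec, seed = record_seed(spec$seed, i, s),
        subject_id = ids[i], session_id = s)
    }
  }
  structure(list(spec = spec, morphologies = morphs, records = records),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ECG cohort: %d records (%d subjects x 2 sessions)\n",
              length(x$records), x$spec$n_subjects))
  print(x$spec)
  invisible(x)
}

#' Extract the records of one session from a cohort
#'
#' @param cohort an `ecg_cohort`.
#' @param session 1 or 2.
#' @return named list of `ecg_record` keyed by subject id.
#' @export
cohort_session <- function(cohort, session) {
  recs <- Filter(function(r) r$session_id == session, cohort$records)
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  recs
}
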