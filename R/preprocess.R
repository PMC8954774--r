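#' Bandpass filter specification
#'
#' A Butterworth bandpass used to strip baseline wander (below `low`) and
#' powerline/EMG content (above `high`) from raw ECG. `order` is the
#' prototype order handed to [signal::butter()], i.e. the filter has
#' `2 * order` poles; with the default 4 this is the usual reading of a
#' "4th-order Butterworth bandpass".
#'
#' @param low,high cut-off frequencies in Hz, 0 < low < high < fs/2.
#' @param order prototype filter order (>= 1).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.5, high = 30, order = 4) {
  if (order < 1) stop("filter_spec: order must be >= 1")
  if (!(low > 0 && high > low)) stop("filter_spec: need 0 < low < high")
  structure(list(low = low, high = high, order = as.integer(order),
                 family = "butterworth"), class = "filter_spec")
}

# One causal IIR pass started in steady state with respect to x[1]
# (the lfilter_zi idea): a constant input in the stopband then produces no
# start-up transient at all, which plain filtfilt does not guarantee.
filter_steady <- function(b, a, x) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  y0 <- x[1] * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], n - 1),
                            init.y = rep(y0, n - 1)))
}

#' Zero-phase Butterworth bandpass filtering
#'
#' Applies the bandpass forward and backward (zero phase), so fiducial
#' latencies are preserved and the fixed 200/400-sample segmentation window
#' stays centred on the R peak. Both passes start in steady state, removing
#' DC exactly up to numerical precision.
#'
#' @param x numeric signal.
#' @param fs sampling frequency in Hz.
#' @param spec a [filter_spec()].
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  if (spec$low <= 0 || spec$high >= fs / 2)
    stop("bandpass_filter: cut-offs must lie strictly inside (0, fs/2)")
  if (length(x) <= 3 * spec$order)
    stop("bandpass_filter: signal shorter than 3 x filter order")
  bt <- signal::butter(spec$order, c(spec$low, spec$high) / (fs / 2),
                       type = "pass")
  y <- filter_steady(bt$b, bt$a, x)
  rev(filter_steady(bt$b, bt$a, rev(y)))
}

#' Frequency response magnitude of the bandpass
#'
#' Evaluates |H(f)| of the designed Butterworth bandpass directly from its
#' transfer-function coefficients. The effective zero-phase gain of
#' [bandpass_filter()] at frequency f is `|H(f)|^2` (two passes).
#'
#' @param f frequencies in Hz.
#' @param fs sampling frequency in Hz.
#' @param spec a [filter_spec()].
#' @return numeric vector of single-pass magnitude gains.
#' @export
filter_response <- function(f, fs, spec = filter_spec()) {
  bt <- signal::butter(spec$order, c(spec$low, spec$high) / (fs / 2),
                       type = "pass")
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs)
    abs(sum(bt$b * z^(seq_along(bt$b) - 1)) /
        sum(bt$a * z^(seq_along(bt$a) - 1)))
  }, numeric(1))
}

#' Detect R peaks in a filtered ECG
#'
#' Derivative-energy detector: the squared first difference is smoothed with
#' a 150 ms moving window, regions exceeding an adaptive threshold become QRS
#' candidates, a 200 ms refractory period suppresses double firing, and each
#' candidate is refined to the local maximum of the filtered signal within
#' +/- 25 ms.
#'
#' @param x filtered ECG signal.
#' @param fs sampling frequency in Hz (>= 100).
#' @return strictly increasing 1-based sample indices; empty integer vector
#'   when no QRS energy is present.
#' @export
detect_r_peaks <- function(x, fs) {
  if (fs < 100) stop("detect_r_peaks: fs must be >= 100 Hz")
  if (length(x) < 2 * fs) stop("detect_r_peaks: signal shorter than 2 s")
  d <- diff(x)
  e <- d * d
  w <- max(3L, round(0.15 * fs))
  cs <- cumsum(c(0, e))
  ei <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
  # align the smoothed energy with the signal (centre of the window)
  pad <- floor(w / 2)
  ei <- c(rep(ei[1], pad), ei, rep(ei[length(ei)], length(x) - length(ei) - pad))
  thr <- 0.2 * stats::quantile(ei, 0.995, names = FALSE)
  if (thr <= 0) return(integer(0))
  above <- ei > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  cand <- apply(regions, 1, function(reg) {
    reg[1] + which.max(ei[reg[1]:reg[2]]) - 1L
  })
  # refine to the local maximum of the signal within +/- 25 ms
  hw <- round(0.025 * fs)
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - hw); hi <- min(length(x), i + hw)
    lo + which.max(x[lo:hi]) - 1L
  }, numeric(1))
  ref <- sort(unique(as.integer(ref)))
  # refractory: drop any peak within 200 ms of the previously kept one,
  # keeping the larger-amplitude of the pair
  refr <- round(0.2 * fs)
  keep <- integer(0)
  for (i in ref) {
    if (length(keep) && i - keep[length(keep)] < refr) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  keep
}

#' Segment a filtered ECG into fixed-length cardiac cycles
#'
#' Each R peak yields one 600-sample cycle: 200 samples before the peak and
#' 400 after (the peak itself is sample 201 of the cycle, i.e. offset 200).
#' Peaks too close to either record boundary to supply the full window are
#' silently dropped.
#'
#' @param x filtered ECG signal.
#' @param r_peaks 1-based R-peak sample indices.
#' @param source_id identifier stored on each cycle.
#' @return list of `cardiac_cycle` objects (fields `samples`, `r_index`,
#'   `source_id`, `source_peak`).
#' @export
segment_cycles <- function(x, r_peaks, source_id = NA_character_) {
  if (any(r_peaks < 1 | r_peaks > length(x)))
    stop("segment_cycles: r_peaks outside the signal")
  ok <- r_peaks >= 201 & r_peaks + 399 <= length(x)
  lapply(r_peaks[ok], function(r) {
    structure(list(samples = x[(r - 200):(r + 399)], r_index = 201L,
                   source_id = source_id, source_peak = as.integer(r)),
              class = "cardiac_cycle")
  })
}

cycle_samples <- function(cycle) {
  if (inherits(cycle, "cardiac_cycle")) cycle$samples else as.numeric(cycle)
}

#' Min-max normalize a cardiac cycle to [0, 1]
#'
#' @param cycle a `cardiac_cycle` or numeric vector.
#' @return same type as the input, rescaled so min = 0 and max = 1. A
#'   constant (degenerate) cycle is an error; callers drop such cycles.
#' @export
minmax_normalize <- function(cycle) {
  x <- cycle_samples(cycle)
  rng <- range(x)
  if (rng[2] <= rng[1])
    stop("minmax_normalize: constant cycle (max == min), cannot rescale")
  y <- (x - rng[1]) / (rng[2] - rng[1])
  if (inherits(cycle, "cardiac_cycle")) { cycle$samples <- y; cycle } else y
}

#' Keep the k cycles most similar to each other (segment elimination)
#'
#' Outlier-removal: computes the full pairwise Euclidean distance matrix over
#' the cycles, scores each cycle by the sum of its distances to all others,
#' and keeps the k lowest-scoring cycles. Ties break toward the earlier
#' cycle; the selection is returned in temporal order.
#'
#' @param cycles list of `cardiac_cycle` (or numeric vectors of equal length).
#' @param k number of cycles to keep (1 <= k <= length(cycles)).
#' @param subject_id,session_id,normalized metadata stored on the set.
#' @return object of class `cycle_set` with fields `subject_id`,
#'   `session_id`, `k`, `cycles`, `normalized`.
#' @export
select_most_similar <- function(cycles, k, subject_id = NA_character_,
                                session_id = NA_integer_, normalized = FALSE) {
  n <- length(cycles)
  if (k < 1) stop("select_most_similar: k must be >= 1")
  if (n < k)
    stop(sprintf("select_most_similar: subject %s session %s has %d cycles, fewer than k = %d",
                 subject_id, session_id, n, k))
  X <- do.call(rbind, lapply(cycles, cycle_samples))
  score <- rowSums(as.matrix(stats::dist(X)))
  sel <- sort(order(score, seq_len(n))[seq_len(k)])
  structure(list(subject_id = subject_id, session_id = as.integer(session_id),
                 k = as.integer(k), cycles = cycles[sel],
                 normalized = isTRUE(normalized)),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("Cycle template set: subject %s session %s, k = %d (%s)\n",
              x$subject_id, x$session_id, x$k,
              if (x$normalized) "normalized" else "not normalized"))
  invisible(x)
}

#' Matrix view of a cycle set
#'
#' @param x a `cycle_set`.
#' @param ... unused.
#' @return k x 600 numeric matrix, one cycle per row, in temporal order.
#' @export
as.matrix.cycle_set <- function(x, ...) {
  do.call(rbind, lapply(x$cycles, cycle_samples))
}

#' Full per-record template extraction
#'
#' Filter, detect R peaks, segment into 600-sample cycles, optionally
#' min-max normalize each cycle (degenerate constant cycles are dropped with
#' a warning), and apply segment elimination down to the k most mutually
#' similar cycles. Elimination runs on the cycles in their current
#' normalization state, so the normalized arm eliminates on normalized
#' waveforms and the raw arm on raw ones.
#'
#' @param record an `ecg_record`.
#' @param k number of cycles to keep (20 for Set 1, 60 for Set 2).
#' @param normalize logical; min-max normalize cycles before elimination.
#' @param fspec a [filter_spec()].
#' @param use_true_peaks use the record's simulated ground-truth R peaks
#'   instead of running the detector (for controlled experiments only).
#' @return a `cycle_set`.
#' @export
extract_cycle_templates <- function(record, k, normalize = TRUE,
                                    fspec = filter_spec(),
                                    use_true_peaks = FALSE) {
  y <- bandpass_filter(record$signal, record$fs, fspec)
  peaks <- if (use_true_peaks) record$true_r_peaks else detect_r_peaks(y, record$fs)
  cycles <- segment_cycles(y, peaks, source_id = record$subject_id)
  if (normalize) {
    ok <- vapply(cycles, function(cc) diff(range(cc$samples)) > 0, logical(1))
    if (!all(ok))
      warning(sprintf("dropping %d constant cycle(s) from %s session %d",
                      sum(!ok), record$subject_id, record$session_id))
    cycles <- lapply(cycles[ok], minmax_normalize)
  }
  select_most_similar(cycles, k, subject_id = record$subject_id,
                      session_id = record$session_id, normalized = normalize)
}
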