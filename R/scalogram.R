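#' Generalized Morse wavelet parameters
#'
#' The analytic generalized Morse wavelet is defined in the frequency domain
#' as \eqn{\Psi(\omega) \propto \omega^\beta e^{-\omega^\gamma}} for
#' \eqn{\omega > 0}, with \eqn{\beta = P^2/\gamma}. The defaults
#' (gamma = 3, P2 = 60, hence beta = 20) give a symmetric, nearly Gaussian
#' envelope well suited to transient cardiac waveforms. Scales are laid out
#' geometrically with `voices` voices per octave over `freq_range`
#' (1-40 Hz by default, covering the filtered ECG band), stored
#' highest-frequency first.
#'
#' @param gamma Morse symmetry parameter (> 0).
#' @param P2 time-bandwidth product (> 0).
#' @param voices voices per octave.
#' @param freq_range analyzed frequency range in Hz, c(low, high).
#' @return object of class `morse_params` (includes the derived `beta` and
#'   peak radian frequency `omega_peak`).
#' @export
morse_params <- function(gamma = 3, P2 = 60, voices = 12,
                         freq_range = c(1, 40)) {
  if (gamma <= 0 || P2 <= 0) stop("morse_params: gamma and P2 must be > 0")
  if (any(freq_range <= 0) || freq_range[1] >= freq_range[2])
    stop("morse_params: freq_range must be positive and increasing")
  beta <- P2 / gamma
  structure(list(gamma = gamma, P2 = P2, beta = beta, voices = voices,
                 freq_range = freq_range,
                 omega_peak = (beta / gamma)^(1 / gamma)),
            class = "morse_params")
}

#' Center frequencies of the scalogram scales
#'
#' @param params a [morse_params()].
#' @return numeric vector of wavelet peak frequencies in Hz, decreasing
#'   (highest-frequency scale first).
#' @export
morse_frequencies <- function(params = morse_params()) {
  fr <- params$freq_range
  n <- floor(log2(fr[2] / fr[1]) * params$voices) + 1L
  fr[2] * 2^(-(seq_len(n) - 1) / params$voices)
}

#' Continuous wavelet transform scalogram of a cardiac cycle
#'
#' Computes |CWT| with the generalized Morse wavelet, evaluated per scale by
#' frequency-domain multiplication (the wavelet is analytic: negative
#' frequencies are zeroed). Each scale's wavelet is unit-peak normalized in
#' the frequency domain, so a unit-amplitude sinusoid at a scale's peak
#' frequency produces magnitude ~0.5 at that scale.
#'
#' @param cycle a `cardiac_cycle` or numeric vector.
#' @param fs sampling frequency in Hz.
#' @param params a [morse_params()].
#' @return scales x time magnitude matrix (highest frequency in row 1), with
#'   the scale center frequencies attached as attribute `frequencies`.
#' @export
compute_scalogram <- function(cycle, fs, params = morse_params()) {
  x <- cycle_samples(cycle)
  N <- length(x)
  freqs <- morse_frequencies(params)
  X <- stats::fft(x)
  w <- 2 * pi * (seq_len(N) - 1) / N          # radian frequency per sample
  pos <- w <= pi & w > 0                      # analytic: positive band only
  beta <- params$beta; gam <- params$gamma
  lpk <- beta * log(params$omega_peak) - params$omega_peak^gam
  # filter bank: one unit-peak Morse filter per scale
  P <- matrix(0, N, length(freqs))
  for (j in seq_along(freqs)) {
    s <- params$omega_peak * fs / (2 * pi * freqs[j])
    sw <- s * w[pos]
    P[pos, j] <- exp(beta * log(sw) - sw^gam - lpk)
  }
  C <- stats::mvfft(P * X, inverse = TRUE) / N
  mag <- t(Mod(C))
  attr(mag, "frequencies") <- freqs
  mag
}

#' Blue-to-red scalogram colormap
#'
#' Fixed five-anchor piecewise-linear map (blue, cyan, green, yellow, red at
#' positions 0, 0.25, 0.5, 0.75, 1) from normalized magnitude to RGB, cold
#' colors for weak intensity and hot for strong.
#'
#' @param u numeric values in [0, 1].
#' @return length(u) x 3 matrix of RGB values in [0, 1].
#' @export
scalogram_colormap <- function(u) {
  anchors <- c(0, 0.25, 0.5, 0.75, 1)
  cols <- rbind(c(0, 0, 1), c(0, 1, 1), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))
  u <- pmin(pmax(u, 0), 1)
  out <- matrix(0, length(u), 3)
  for (ch in 1:3)
    out[, ch] <- stats::approx(anchors, cols[, ch], xout = u)$y
  out
}

#' Bilinear resize of a matrix
#'
#' Half-pixel-centre convention: destination pixel (r, c) samples the source
#' at ((r - 0.5) * H/h, (c - 0.5) * W/w), clamped to the source grid.
#'
#' @param m numeric matrix.
#' @param h,w output dimensions.
#' @return h x w matrix.
#' @export
resize_bilinear <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  sy <- pmin(pmax((seq_len(h) - 0.5) * H / h + 0.5, 1), H)
  sx <- pmin(pmax((seq_len(w) - 0.5) * W / w + 0.5, 1), W)
  y0 <- pmin(floor(sy), H - 1L); x0 <- pmin(floor(sx), W - 1L)
  if (H == 1L) y0 <- rep(1L, h)
  if (W == 1L) x0 <- rep(1L, w)
  fy <- sy - y0; fx <- sx - x0
  y1 <- pmin(y0 + 1L, H); x1 <- pmin(x0 + 1L, W)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  cc <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX + cc * FY * (1 - FX) + d * FY * FX
}

#' Render a scalogram magnitude matrix as a square RGB template
#'
#' Min-max normalizes the magnitude per scalogram to [0, 1], maps it through
#' the fixed blue-to-red colormap, and bilinearly resizes each channel to
#' size x size. A constant magnitude matrix (no dynamic range) maps to the
#' colormap midpoint everywhere.
#'
#' @param magnitude scales x time magnitude matrix.
#' @param size output side length in pixels (56 or 224 in the standard
#'   configurations; any positive size is accepted).
#' @param source_id identifier carried on the template.
#' @return object of class `scalogram_template`: size x size x 3 array with
#'   values in [0, 1].
#' @export
to_rgb_image <- function(magnitude, size = 56, source_id = NA_character_) {
  if (length(magnitude) == 0) stop("to_rgb_image: empty magnitude matrix")
  rng <- range(magnitude)
  u <- if (rng[2] > rng[1]) (magnitude - rng[1]) / (rng[2] - rng[1])
       else matrix(0.5, nrow(magnitude), ncol(magnitude))
  rgb_flat <- scalogram_colormap(as.vector(u))
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    mch <- matrix(rgb_flat[, ch], nrow(magnitude), ncol(magnitude))
    out[, , ch] <- resize_bilinear(mch, size, size)
  }
  structure(out, class = c("scalogram_template", class(out)),
            size = as.integer(size), source_id = source_id)
}

#' Scalogram templates for a whole cycle set
#'
#' @param cset a `cycle_set`.
#' @param fs sampling frequency in Hz.
#' @param size output image side length.
#' @param params a [morse_params()].
#' @return list of `scalogram_template`, one per cycle, temporal order.
#' @export
scalogram_templates <- function(cset, fs, size = 56, params = morse_params()) {
  lapply(cset$cycles, function(cc)
    to_rgb_image(compute_scalogram(cc, fs, params), size,
                 source_id = cset$subject_id))
}
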