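test_that("bandpass removes DC and matches the frequency-response oracle", {
  fs <- 1000
  y <- bandpass_filter(rep(5, 6000), fs)
  expect_lt(max(abs(y)), 1e-6 * 5)

  t <- seq(0, 10, by = 1 / fs)
  mid <- 3000:7000
  # zero-phase gain is the squared single-pass magnitude response
  g10_oracle <- filter_response(10, fs)^2
  y10 <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  g10 <- max(abs(y10[mid]))
  expect_gt(g10, 0.95); expect_lt(g10, 1.05)
  expect_equal(g10, g10_oracle, tolerance = 0.01)

  g50_oracle <- filter_response(50, fs)^2
  y50 <- bandpass_filter(sin(2 * pi * 50 * t), fs)
  g50 <- max(abs(y50[mid]))
  expect_gte(-20 * log10(g50), 20)          # >= 20 dB attenuation
  # deep-stopband peak measurement carries residual leakage; the oracle
  # bound is one-sided and the agreement loose
  expect_equal(g50, g50_oracle, tolerance = 0.2)

  expect_error(bandpass_filter(rnorm(100), fs, filter_spec(high = 600)),
               "cut-offs")
})

test_that("zero-phase filtering leaves fiducial latencies unshifted", {
  rec <- synthesize_ecg(default_morphology(), noise_free_spec(duration_s = 15),
                        seed = 4)
  y <- bandpass_filter(rec$signal, rec$fs)
  cc <- stats::ccf(y, rec$signal, lag.max = 30, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("R-peak detection recovers the ground truth", {
  # noise-free: every true peak within 10 ms, no extras
  rec <- synthesize_ecg(default_morphology(), noise_free_spec(duration_s = 30),
                        seed = 6)
  y <- bandpass_filter(rec$signal, rec$fs)
  det <- detect_r_peaks(y, rec$fs)
  expect_length(det, length(rec$true_r_peaks))
  expect_true(all(abs(det - rec$true_r_peaks) <= 10))

  # default noise: sensitivity and positive predictivity >= 0.95 (50 ms match)
  coh <- small_cohort()
  sens <- ppv <- numeric(0)
  for (rec in coh$records[1:4]) {
    y <- bandpass_filter(rec$signal, rec$fs)
    det <- detect_r_peaks(y, rec$fs)
    dmat <- abs(outer(det, rec$true_r_peaks, "-"))
    sens <- c(sens, mean(apply(dmat, 2, min) <= 50))
    ppv <- c(ppv, mean(apply(dmat, 1, min) <= 50))
  }
  expect_true(all(sens >= 0.95))
  expect_true(all(ppv >= 0.95))
})

test_that("R-peak detection contracts hold on degenerate input", {
  expect_identical(detect_r_peaks(numeric(5000), 1000), integer(0))
  expect_error(detect_r_peaks(rnorm(1500), 1000), "2 s")
  expect_error(detect_r_peaks(rnorm(5000), 50), "fs")
  rec <- small_cohort()$records[[1]]
  det <- detect_r_peaks(bandpass_filter(rec$signal, rec$fs), rec$fs)
  expect_true(all(diff(det) >= 0.2 * rec$fs))   # refractory period
})

test_that("segmentation yields 600-sample cycles with full margins", {
  x <- rnorm(5000)
  peaks <- c(150L, 300L, 1000L, 2000L, 4500L, 4700L)
  cycles <- segment_cycles(x, peaks)
  # 150 lacks the pre-R margin, 4700 lacks the post-R margin
  expect_length(cycles, 4L)
  for (cc in cycles) {
    expect_length(cc$samples, 600L)
    expect_identical(cc$r_index, 201L)
  }
  expect_identical(cycles[[1]]$samples, x[100:699])   # peak 300: 200 before
  # count conservation: one cycle per margin-satisfying peak
  ok <- sum(peaks >= 201 & peaks + 399 <= length(x))
  expect_length(cycles, ok)
  expect_error(segment_cycles(x, c(0L, 300L)), "outside")
})

test_that("min-max normalization is exact and affine-invariant", {
  ramp <- as.numeric(0:599)
  expect_equal(minmax_normalize(ramp), ramp / 599)
  u <- runif(600)
  v <- minmax_normalize(u)
  expect_equal(min(v), 0); expect_equal(max(v), 1)
  expect_equal(minmax_normalize(v), v)                  # idempotent
  expect_equal(minmax_normalize(3.7 * u - 2.2), v)      # affine invariance
  expect_error(minmax_normalize(rep(1, 600)), "constant")
})

test_that("segment elimination equals the brute-force ranking", {
  # planted outliers: 4 copies of A (tiny jitter), 2 copies of distant B
  set.seed(11)
  A <- sin(seq(0, 2 * pi, length.out = 600))
  B <- A + 10
  cycles <- c(lapply(1:4, function(i) A + rnorm(600, 0, 1e-3)),
              lapply(1:2, function(i) B + rnorm(600, 0, 1e-3)))
  sel <- select_most_similar(cycles, 3)
  X <- as.matrix(sel)
  expect_true(all(abs(X - matrix(A, 3, 600, byrow = TRUE)) < 0.01))

  # brute-force oracle on random instances with <= 10 cycles
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1); k <- sample(2:(n - 1), 1)
    cyc <- lapply(seq_len(n), function(i) rnorm(600))
    score <- sapply(seq_len(n), function(i)
      sum(sapply(seq_len(n), function(j)
        sqrt(sum((cyc[[i]] - cyc[[j]])^2)))))
    expected <- sort(order(score)[seq_len(k)])
    got <- select_most_similar(cyc, k)
    expect_identical(as.matrix(got),
                     do.call(rbind, cyc[expected]))
  }
})

test_that("elimination is order-free and rejects planted outliers", {
  set.seed(21)
  base <- sin(seq(0, 2 * pi, length.out = 600))
  n <- 12; m <- 3
  good <- lapply(seq_len(n - m), function(i) base + rnorm(600, 0, 0.01))
  bad <- lapply(seq_len(m), function(i) base + 50 + rnorm(600, 0, 0.01))
  sel <- select_most_similar(c(good, bad), k = n - m)
  expect_true(max(as.matrix(sel)) < 10)   # no outlier selected

  perm <- sample(n)
  sel_perm <- select_most_similar(c(good, bad)[perm], k = n - m)
  s1 <- as.matrix(sel); s2 <- as.matrix(sel_perm)
  expect_equal(s1[order(s1[, 1]), ], s2[order(s2[, 1]), ])  # same multiset

  expect_identical(as.matrix(select_most_similar(good, length(good))),
                   do.call(rbind, good))                    # k == n: keep all
  expect_error(select_most_similar(good, 50), "fewer than k")
})

test_that("full template extraction produces valid normalized sets", {
  rec <- small_cohort()$records[[1]]
  cset <- extract_cycle_templates(rec, k = 20, normalize = TRUE)
  expect_s3_class(cset, "cycle_set")
  expect_length(cset$cycles, 20L)
  X <- as.matrix(cset)
  expect_equal(dim(X), c(20L, 600L))
  expect_true(all(abs(apply(X, 1, min)) < 1e-9))
  expect_true(all(abs(apply(X, 1, max) - 1) < 1e-9))
  # temporal order preserved
  peaks <- vapply(cset$cycles, function(cc) cc$source_peak, integer(1))
  expect_true(all(diff(peaks) > 0))
})
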