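test_that("Manhattan distance matrix matches hand arithmetic", {
  tr <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  te <- matrix(c(0, 1), 1, 2, dimnames = list("a", NULL))
  D <- manhattan_distance_matrix(tr, te)
  expect_equal(as.numeric(D$values), c(1, 1))

  set.seed(2)
  X <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
  D0 <- manhattan_distance_matrix(X, X)
  expect_equal(diag(D0$values), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(D0$values >= 0))

  # homogeneity: scaling features scales distances
  Da <- manhattan_distance_matrix(2.5 * X, 2.5 * X)
  expect_equal(Da$values, 2.5 * D0$values)
  expect_error(manhattan_distance_matrix(X, X[, 1:2]), "mismatch")
})

test_that("thresholds implement T = mu - sigma with the population sd", {
  # pool {1, 2, 3}: mu = 2, population sigma = 0.8165, T = 1.1835
  tr <- matrix(c(0, 3, 4), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  te <- matrix(1, 1, 1, dimnames = list("a", NULL))
  D <- manhattan_distance_matrix(tr, te)
  expect_equal(sort(as.numeric(D$values)), c(1, 2, 3))
  thr <- compute_thresholds(D)
  expect_equal(thr$mu[1], 2)
  expect_equal(thr$sigma[1], sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(thr$threshold[1], 2 - sqrt(2 / 3), tolerance = 1e-12)
  # the sample-sd convention is switchable and gives T = 1 here
  expect_equal(compute_thresholds(D, sd = "sample")$threshold[1], 1)

  # all pool distances equal c: sigma = 0, T = c
  tre <- matrix(c(0, 8, 0), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  De <- manhattan_distance_matrix(tre, matrix(4, 1, 1,
                                              dimnames = list("a", NULL)))
  expect_equal(compute_thresholds(De)$threshold[1], 4)
})

test_that("Eq.-style thresholds agree with an independent mean/sd oracle", {
  set.seed(5)
  tr <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(letters[1:8], NULL))
  te <- tr + matrix(rnorm(40, 0, 0.3), 8, 5)
  rownames(te) <- rownames(tr)
  D <- manhattan_distance_matrix(tr, te)
  thr <- compute_thresholds(D)
  for (i in 1:8) {
    pool <- D$values[, i]
    mu <- sum(pool) / length(pool)
    sg <- sqrt(sum((pool - mu)^2) / length(pool))
    expect_equal(thr$threshold[i], mu - sg, tolerance = 1e-12)
  }
  # linearity: scaling all distances scales the threshold
  D2 <- manhattan_distance_matrix(3 * tr, 3 * te)
  expect_equal(compute_thresholds(D2)$threshold, 3 * thr$threshold,
               tolerance = 1e-12)
})

test_that("authentication decisions follow the threshold rule", {
  mk_D <- function(vals, ids) {
    structure(list(values = vals, train_ids = ids, test_ids = ids,
                   multiplicity = 1L), class = "dist_matrix")
  }
  ids <- c("a", "b", "c")
  vals <- matrix(10, 3, 3, dimnames = list(ids, ids))
  diag(vals) <- c(1, 5, 2)
  thr <- data.frame(subject = ids, mu = NA, sigma = NA, threshold = c(2, 2, 2))
  rep <- authenticate_subjects(mk_D(vals, ids), thr, "1/1")
  expect_equal(rep$accuracy, 2 / 3)
  expect_equal(rep$decisions$authenticated, c(TRUE, FALSE, TRUE))

  # boundary: equality authenticates ("does not exceed")
  thr2 <- data.frame(subject = ids, mu = NA, sigma = NA, threshold = c(1, 5, 2))
  expect_equal(authenticate_subjects(mk_D(vals, ids), thr2, "1/1")$accuracy, 1)

  # zero self-distance with positive thresholds: everyone authenticated
  vals0 <- vals; diag(vals0) <- 0
  expect_equal(authenticate_subjects(mk_D(vals0, ids), thr, "1/1")$accuracy, 1)

  # monotone in T: raising thresholds never de-authenticates
  set.seed(6)
  v <- matrix(runif(9, 0, 10), 3, 3, dimnames = list(ids, ids))
  base <- data.frame(subject = ids, mu = NA, sigma = NA,
                     threshold = runif(3, 0, 10))
  up <- base; up$threshold <- base$threshold + 2
  a1 <- authenticate_subjects(mk_D(v, ids), base, "1/1")$decisions$authenticated
  a2 <- authenticate_subjects(mk_D(v, ids), up, "1/1")$decisions$authenticated
  expect_true(all(a2[a1]))

  # 1/3: at least two of three self-distances must pass
  arr <- array(10, c(3, 3, 3), dimnames = list(ids, ids, NULL))
  arr[1, 1, ] <- c(1, 1, 9); arr[2, 2, ] <- c(9, 9, 1); arr[3, 3, ] <- c(1, 9, 9)
  D3 <- structure(list(values = arr, train_ids = ids, test_ids = ids,
                       multiplicity = 3L), class = "dist_matrix")
  rep3 <- authenticate_subjects(D3, thr, "1/3")
  expect_equal(rep3$decisions$authenticated, c(TRUE, FALSE, FALSE))
  expect_error(authenticate_subjects(mk_D(vals, ids), thr, "1/3"),
               "multiplicity")
})

test_that("leave-one-out impostor evaluation excludes self and flags twins", {
  # widely separated orthogonal templates: no impostors at all
  ids <- sprintf("s%d", 1:6)
  tr <- diag(100, 6); rownames(tr) <- ids
  rep <- loo_impostor_evaluation(tr, tr, "1/1")
  expect_equal(rep$impostor_score, 0)
  expect_true(all(rep$per_subject$impostor_count == 0))

  # planted near-duplicate subjects flag each other
  set.seed(9)
  X <- matrix(runif(6 * 20, 0, 50), 6, 20, dimnames = list(ids, NULL))
  X[2, ] <- X[5, ] + runif(20, 0, 0.01)
  rep2 <- loo_impostor_evaluation(X, X, "1/1")
  expect_true("s5" %in% rep2$impostors$s2)
  expect_true("s2" %in% rep2$impostors$s5)
  # a subject is never an impostor of themselves
  for (id in ids) expect_false(id %in% rep2$impostors[[id]])
  expect_error(loo_impostor_evaluation(X[1:2, ], X[1:2, ], "1/1"), "3 subjects")
})

test_that("a stricter threshold rule trades impostors against accuracy", {
  coh <- small_cohort()
  tr <- concatenate_subject_templates(session_sets(coh, 1, 10, FALSE))
  te <- concatenate_subject_templates(session_sets(coh, 2, 10, FALSE))
  D <- manhattan_distance_matrix(tr, te)
  acc <- function(mult) {
    thr <- compute_thresholds(D, sigma_mult = mult)
    authenticate_subjects(D, thr, "1/1")$accuracy
  }
  imp <- function(mult)
    loo_impostor_evaluation(tr, te, "1/1", sigma_mult = mult)$impostor_score
  expect_lte(acc(2), acc(1))
  expect_lte(imp(2), imp(1))
})

test_that("the full authentication wrapper combines both evaluations", {
  coh <- small_cohort()
  tr <- concatenate_subject_templates(session_sets(coh, 1, 10, FALSE))
  te <- concatenate_subject_templates(session_sets(coh, 2, 10, FALSE))
  rep <- authenticate(tr, te, "1/1")
  expect_s3_class(rep, "auth_report")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_true(rep$impostor_score >= 0 && rep$impostor_score <= 100)
  expect_equal(nrow(rep$decisions), nrow(tr))

  # 1/3 route via three blocks of session-2 templates
  sets2 <- session_sets(coh, 2, 30, FALSE)
  blocks <- lapply(0:2, function(b)
    concatenate_subject_templates(lapply(sets2, function(s) {
      s$cycles <- s$cycles[(b * 10 + 1):(b * 10 + 10)]; s
    })))
  rep13 <- authenticate(tr, blocks, "1/3")
  expect_equal(rep13$configuration, "1/3")
  expect_true(rep13$accuracy >= 0 && rep13$accuracy <= 1)
})
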