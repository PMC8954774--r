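manhattan_cross <- function(A, B) {
  # full n_train x n_test Manhattan cross-distance matrix
  n <- nrow(A); m <- nrow(B)
  D <- matrix(0, n, m, dimnames = list(rownames(A), rownames(B)))
  tA <- t(A)
  for (j in seq_len(m)) D[, j] <- colSums(abs(tA - B[j, ]))
  D
}

#' Manhattan distance matrix between enrollment and presentation templates
#'
#' @param train `subject_features` matrix, one enrollment row per subject.
#' @param test aligned matrix (multiplicity 1), or list of three aligned
#'   matrices (multiplicity 3: three presentation templates per subject).
#' @return object of class `dist_matrix`: list with `values` (n_train x
#'   n_test matrix, or n x n x 3 array), `train_ids`, `test_ids`,
#'   `multiplicity`.
#' @export
manhattan_distance_matrix <- function(train, test) {
  train <- as.matrix(train)
  tests <- if (is.list(test) && !is.data.frame(test)) test else list(test)
  tests <- lapply(tests, as.matrix)
  for (M in tests)
    if (ncol(M) != ncol(train))
      stop("manhattan_distance_matrix: feature length mismatch between train and test")
  mult <- length(tests)
  vals <- if (mult == 1) manhattan_cross(train, tests[[1]]) else {
    a <- array(0, c(nrow(train), nrow(tests[[1]]), mult))
    for (m in seq_len(mult)) a[, , m] <- manhattan_cross(train, tests[[m]])
    a
  }
  structure(list(values = vals, train_ids = rownames(train),
                 test_ids = rownames(tests[[1]]),
                 multiplicity = as.integer(mult)),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Manhattan distance matrix: %d train x %d test (multiplicity %d)\n",
              length(x$train_ids), length(x$test_ids), x$multiplicity))
  invisible(x)
}

pool_for_subject <- function(D, i) {
  # all distances between subject i's presentation template(s) and every
  # enrollment template (self included)
  if (D$multiplicity == 1) D$values[, i] else as.vector(D$values[, i, ])
}

#' Per-subject authentication thresholds (T = mu - sigma)
#'
#' For each subject the distance pool is the set of distances between that
#' subject's presentation template(s) and the enrollment templates of all
#' subjects (self included). The threshold is the pool mean minus its
#' standard deviation; the population standard deviation (divide by n) is
#' the default, the sample convention is switchable.
#'
#' @param D a `dist_matrix`.
#' @param sd "population" (default) or "sample".
#' @param include_self keep the self-distance in the pool (default TRUE).
#' @param sigma_mult multiplier on sigma in T = mu - sigma_mult * sigma;
#'   the standard rule is 1, larger values make authentication stricter.
#' @return object of class `auth_thresholds`: data frame with columns
#'   `subject`, `mu`, `sigma`, `threshold`.
#' @export
compute_thresholds <- function(D, sd = c("population", "sample"),
                               include_self = TRUE, sigma_mult = 1) {
  sd <- match.arg(sd)
  n <- length(D$train_ids)
  if (n < 2) stop("compute_thresholds: need at least 2 enrollment templates")
  rows <- lapply(seq_along(D$test_ids), function(i) {
    pool <- pool_for_subject(D, i)
    if (!include_self) {
      self <- match(D$test_ids[i], D$train_ids)
      drop_idx <- self + (seq_len(D$multiplicity) - 1) * n
      pool <- pool[-drop_idx]
    }
    mu <- mean(pool)
    sg <- if (sd == "population") sqrt(mean((pool - mu)^2)) else stats::sd(pool)
    data.frame(subject = D$test_ids[i], mu = mu, sigma = sg,
               threshold = mu - sigma_mult * sg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("auth_thresholds", class(out))
  out
}

#' Authenticate enrolled subjects against their own thresholds
#'
#' Configuration "1/1": subject i is authenticated when their self-distance
#' does not exceed their threshold (ties accept). Configuration "1/3": at
#' least two of the three self-distances must not exceed it.
#'
#' @param D a `dist_matrix` (square: same subjects enrolled and presented).
#' @param thresholds an `auth_thresholds` aligned with `D`.
#' @param config "1/1" or "1/3" (the latter requires multiplicity 3).
#' @return object of class `auth_report` with per-subject decisions and
#'   `accuracy` (fraction of subjects authenticated).
#' @export
authenticate_subjects <- function(D, thresholds, config = c("1/1", "1/3")) {
  config <- match.arg(config)
  if (config == "1/3" && D$multiplicity != 3)
    stop("authenticate_subjects: configuration 1/3 needs a multiplicity-3 distance matrix")
  ids <- D$test_ids
  thr <- thresholds$threshold[match(ids, thresholds$subject)]
  self_idx <- match(ids, D$train_ids)
  auth <- vapply(seq_along(ids), function(i) {
    if (D$multiplicity == 1) {
      D$values[self_idx[i], i] <= thr[i]
    } else {
      sum(D$values[self_idx[i], i, ] <= thr[i]) >= 2
    }
  }, logical(1))
  structure(list(configuration = config,
                 decisions = data.frame(subject = ids, threshold = thr,
                                        authenticated = auth,
                                        row.names = NULL),
                 accuracy = mean(auth)),
            class = "auth_report")
}

#' Leave-one-out impostor evaluation
#'
#' Holds out each subject in turn: the held-out subject's threshold is
#' derived (T = mu - sigma) from the distances between their presentation
#' template(s) and the n - 1 remaining enrollment templates. Any other
#' subject whose enrollment template falls strictly below that threshold is
#' counted as an impostor of the held-out subject (configuration "1/3": at
#' least two of the three distances below). A subject is never an impostor
#' of themselves. The impostor score is the mean over subjects of the
#' impostor count as a percentage of the n - 1 possible impostors.
#'
#' @param train,test `subject_features` matrices (test: list of three for
#'   "1/3"), same subject universe.
#' @param config "1/1" or "1/3".
#' @param sd standard-deviation convention for the threshold pool.
#' @param sigma_mult multiplier on sigma in the threshold rule (default 1).
#' @return object of class `auth_report` with per-subject impostor counts,
#'   impostor lists and `impostor_score` (percent).
#' @export
loo_impostor_evaluation <- function(train, test, config = c("1/1", "1/3"),
                                    sd = c("population", "sample"),
                                    sigma_mult = 1) {
  config <- match.arg(config)
  sd <- match.arg(sd)
  D <- manhattan_distance_matrix(train, test)
  if (config == "1/3" && D$multiplicity != 3)
    stop("loo_impostor_evaluation: configuration 1/3 needs three test matrices")
  ids <- D$train_ids
  n <- length(ids)
  if (n < 3) stop("loo_impostor_evaluation: need at least 3 subjects")
  counts <- integer(n)
  impostors <- vector("list", n)
  thr_out <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    pool <- if (D$multiplicity == 1) D$values[others, i]
            else as.vector(D$values[others, i, ])
    mu <- mean(pool)
    sg <- if (sd == "population") sqrt(mean((pool - mu)^2)) else stats::sd(pool)
    thr <- mu - sigma_mult * sg
    thr_out[i] <- thr
    is_imp <- vapply(others, function(j) {
      if (D$multiplicity == 1) D$values[j, i] < thr
      else sum(D$values[j, i, ] < thr) >= 2
    }, logical(1))
    counts[i] <- sum(is_imp)
    impostors[[i]] <- ids[others][is_imp]
  }
  structure(list(configuration = config,
                 per_subject = data.frame(subject = ids, threshold = thr_out,
                                          impostor_count = counts,
                                          row.names = NULL),
                 impostors = stats::setNames(impostors, ids),
                 impostor_score = 100 * mean(counts / (n - 1))),
            class = "auth_report")
}

#' Full authentication evaluation (accuracy + impostor score)
#'
#' Convenience wrapper: builds the Manhattan distance matrix, derives the
#' per-subject thresholds, authenticates every enrolled subject, and runs
#' the leave-one-out impostor evaluation.
#'
#' @param train `subject_features` matrix of enrollment templates.
#' @param test aligned presentation matrix, or list of three for "1/3".
#' @param config "1/1" or "1/3".
#' @param sd standard-deviation convention for the threshold pools.
#' @return an `auth_report` with `accuracy`, `impostor_score`, per-subject
#'   decisions and impostor lists, plus the distance matrix.
#' @export
authenticate <- function(train, test, config = c("1/1", "1/3"),
                         sd = c("population", "sample")) {
  config <- match.arg(config)
  sd <- match.arg(sd)
  D <- manhattan_distance_matrix(train, test)
  thr <- compute_thresholds(D, sd = sd)
  acc <- authenticate_subjects(D, thr, config = config)
  imp <- loo_impostor_evaluation(train, test, config = config, sd = sd)
  structure(list(configuration = config, distance_matrix = D,
                 thresholds = thr, decisions = acc$decisions,
                 accuracy = acc$accuracy,
                 per_subject = imp$per_subject, impostors = imp$impostors,
                 impostor_score = imp$impostor_score),
            class = "auth_report")
}

#' @export
print.auth_report <- function(x, ...) {
  cat("Authentication report (configuration", x$configuration, ")\n")
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy: %.2f%% of subjects authenticated\n",
                100 * x$accuracy))
  if (!is.null(x$impostor_score))
    cat(sprintf("  impostor score: %.2f%% of possible impostors accepted (LOO)\n",
                x$impostor_score))
  invisible(x)
}
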