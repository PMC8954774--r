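#' Identification metrics from a confusion matrix
#'
#' Accuracy plus support-weighted one-vs-rest precision, recall and F1.
#' Rows are true identities, columns predicted. Classes with an undefined
#' ratio (zero denominator) contribute 0, with a warning.
#'
#' @param confusion square non-negative matrix, rows = true, cols = predicted.
#' @return object of class `ident_report` (without per-subject detail).
#' @export
compute_ident_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("compute_ident_metrics: confusion matrix must be square")
  if (any(cm < 0)) stop("compute_ident_metrics: negative counts")
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  if (any(predicted == 0) || any(support == 0))
    warning("compute_ident_metrics: zero-division in per-class metrics, reported as 0")
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wt <- support / sum(support)
  structure(list(accuracy = sum(tp) / sum(cm),
                 precision = sum(wt * prec), recall = sum(wt * rec),
                 f1 = sum(wt * f1), confusion = cm),
            class = "ident_report")
}

#' @export
print.ident_report <- function(x, ...) {
  cat("Identification report\n")
  if (!is.null(x$method)) cat(sprintf("  method: %s\n", x$method))
  if (!is.null(x$configuration)) cat(sprintf("  configuration: %s\n", x$configuration))
  cat(sprintf("  accuracy %.4f | weighted precision %.4f | recall %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

cycle_set_matrix_list <- function(sets) {
  if (is.null(names(sets)))
    names(sets) <- vapply(sets, function(s) s$subject_id, character(1))
  sets
}

# stack per-subject cycle sets into (samples x 600) matrix + label factor
stack_cycles <- function(sets) {
  sets <- cycle_set_matrix_list(sets)
  Xs <- lapply(sets, as.matrix)
  X <- do.call(rbind, Xs)
  y <- factor(rep(names(sets), vapply(Xs, nrow, integer(1))),
              levels = names(sets))
  list(X = X, y = y)
}

# majority vote with documented tie-break: most votes, then highest summed
# confidence across the subject's cycles, then lexicographically first id
majority_vote <- function(pred, conf = NULL) {
  tab <- table(pred)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1 && !is.null(conf)) {
    sums <- vapply(top, function(lbl) sum(conf[pred == lbl]), numeric(1))
    top <- top[sums == max(sums)]
  }
  sort(top)[1]
}

#' Closed-set identification with a classical classifier
#'
#' Each individual 600-sample cycle is one training/testing sample labelled
#' with its subject; the classifier is fitted on session-1 cycles only and
#' every session-2 cycle is classified. A subject's predicted identity is
#' the majority vote over their test cycles (ties break toward the higher
#' summed classifier confidence, then the lexicographically first id), and
#' all metrics are computed at subject level.
#'
#' Classifiers (hyperparameters are the package defaults; the choice of
#' classifier family is the experiment's variable): `lda` (with a PCA
#' projection to the feasible rank when features outnumber the within-class
#' degrees of freedom), `knn` (k = 3, Euclidean), `dt` (CART, Gini, default
#' depth), `svm` (RBF kernel, C = 1, gamma = 1 / (p * var)).
#'
#' @param train_sets,test_sets named lists of `cycle_set` (session 1 / 2),
#'   same subjects, k matching the configuration (20 or 60).
#' @param classifier one of "lda", "knn", "dt", "svm".
#' @param knn_k neighbourhood size for kNN.
#' @param seed integer seed (tree and SVM fitting).
#' @return an `ident_report` with per-subject predictions attached.
#' @export
identify_with_classifier <- function(train_sets, test_sets,
                                     classifier = c("lda", "knn", "dt", "svm"),
                                     knn_k = 3, seed = 1) {
  classifier <- match.arg(classifier)
  train_sets <- cycle_set_matrix_list(train_sets)
  test_sets <- cycle_set_matrix_list(test_sets)
  if (!setequal(names(train_sets), names(test_sets)))
    stop("identify_with_classifier: train and test subject sets differ")
  test_sets <- test_sets[names(train_sets)]
  tr <- stack_cycles(train_sets)
  te <- stack_cycles(test_sets)
  set.seed(as.integer(seed))

  pred <- conf <- NULL
  if (classifier == "lda") {
    # project onto the PCA subspace of the training cycles first: smooth
    # 600-sample waveforms are highly collinear, and when p exceeds the
    # within-class dof the pooled covariance would be singular outright
    rank_cap <- max(1L, nrow(tr$X) - nlevels(tr$y) - 1L)
    pc <- stats::prcomp(tr$X, center = TRUE, scale. = FALSE)
    keep <- which(pc$sdev > max(pc$sdev) * 1e-4)
    keep <- keep[seq_len(min(length(keep), rank_cap))]
    Xtr <- pc$x[, keep, drop = FALSE]
    Xte <- scale(te$X, center = pc$center, scale = FALSE) %*%
      pc$rotation[, keep, drop = FALSE]
    fit <- MASS::lda(Xtr, grouping = tr$y, tol = 1e-10)
    pr <- stats::predict(fit, Xte)
    pred <- as.character(pr$class)
    conf <- apply(pr$posterior, 1, max)
  } else if (classifier == "knn") {
    pr <- class::knn(tr$X, te$X, cl = tr$y, k = knn_k, prob = TRUE)
    pred <- as.character(pr)
    conf <- attr(pr, "prob")
  } else if (classifier == "dt") {
    df <- as.data.frame(tr$X)
    df$.y <- tr$y
    fit <- rpart::rpart(.y ~ ., data = df, method = "class")
    post <- stats::predict(fit, as.data.frame(te$X), type = "prob")
    pred <- colnames(post)[max.col(post, ties.method = "first")]
    conf <- apply(post, 1, max)
  } else {
    gam <- 1 / (ncol(tr$X) * stats::var(as.vector(tr$X)))
    fit <- e1071::svm(tr$X, tr$y, kernel = "radial", cost = 1, gamma = gam)
    pred <- as.character(stats::predict(fit, te$X))
    conf <- rep(1, length(pred))
  }

  ids <- names(train_sets)
  subject_pred <- vapply(ids, function(id) {
    sel <- te$y == id
    majority_vote(pred[sel], conf[sel])
  }, character(1))
  cm <- table(factor(ids, levels = ids),
              factor(subject_pred, levels = ids))
  rep <- compute_ident_metrics(unclass(cm))
  rep$method <- paste0("classifier/", classifier)
  rep$configuration <- sprintf("%d/%d", train_sets[[1]]$k, test_sets[[1]]$k)
  rep$per_subject <- data.frame(subject = ids, predicted = subject_pred,
                                correct = subject_pred == ids,
                                row.names = NULL)
  rep
}

#' Closed-set identification by Manhattan 1-NN template matching
#'
#' Configuration "1/1": subject i is correctly identified when the training
#' row nearest (Manhattan) to their single test row is their own.
#' Configuration "1/3": three test rows per subject; correct when at least
#' two of the three nearest-neighbour decisions point to the subject. For
#' the confusion matrix, a 1/3 subject's predicted label is the 2-of-3
#' majority when one exists; with three distinct predictions the subject has
#' failed and the smallest-distance non-self prediction is recorded, keeping
#' report accuracy equal to the 2-of-3 rule.
#'
#' @param train reduced `subject_features` matrix (one row per subject).
#' @param test matrix aligned with `train` ("1/1"), or a list of three such
#'   matrices ("1/3").
#' @param config "1/1" or "1/3".
#' @return an `ident_report`.
#' @export
identify_with_distance <- function(train, test, config = c("1/1", "1/3")) {
  config <- match.arg(config)
  train <- as.matrix(train)
  ids <- rownames(train)
  tests <- if (config == "1/1") list(as.matrix(test)) else test
  if (config == "1/3" && length(tests) != 3)
    stop("identify_with_distance: configuration 1/3 requires three test matrices")
  D <- lapply(tests, function(M) manhattan_cross(train, as.matrix(M)))
  n <- length(ids)
  preds <- sapply(D, function(Dm) ids[apply(Dm, 2, which.min)])
  preds <- matrix(preds, nrow = n)
  if (config == "1/1") {
    subject_pred <- preds[, 1]
    correct <- subject_pred == ids
  } else {
    subject_pred <- character(n); correct <- logical(n)
    for (i in seq_len(n)) {
      votes <- table(preds[i, ])
      correct[i] <- !is.na(votes[ids[i]]) && votes[ids[i]] >= 2
      if (max(votes) >= 2) {
        subject_pred[i] <- names(votes)[which.max(votes)]
      } else {
        dmins <- vapply(seq_len(3), function(m) min(D[[m]][, i]), numeric(1))
        ord <- order(dmins)
        cand <- preds[i, ord]
        cand <- cand[cand != ids[i]]
        subject_pred[i] <- cand[1]
      }
    }
  }
  cm <- table(factor(ids, levels = ids), factor(subject_pred, levels = ids))
  rep <- compute_ident_metrics(unclass(cm))
  rep$method <- "distance/manhattan-1nn"
  rep$configuration <- config
  rep$per_subject <- data.frame(subject = ids, predicted = subject_pred,
                                correct = correct, row.names = NULL)
  rep$accuracy <- mean(correct)
  rep
}

#' Identification with a convolutional network (optional component)
#'
#' A pluggable surface for image-based identification of scalogram
#' templates. No deep-learning backend ships with this package; callers must
#' supply one as a function `backend(train_images, train_labels,
#' test_images, seed)` returning predicted labels, otherwise a clear
#' "component unavailable" error is raised. This route is exploratory and
#' carries no accuracy contract.
#'
#' @param train_images,test_images named lists (per subject) of
#'   `scalogram_template` lists.
#' @param backend optional classifier backend function.
#' @param seed integer seed passed to the backend.
#' @return an `ident_report` built from the backend's per-image predictions.
#' @export
identify_with_cnn <- function(train_images, test_images, backend = NULL,
                              seed = 1) {
  if (is.null(backend))
    stop(paste("identify_with_cnn: component unavailable - no convolutional",
               "backend is installed; supply one via the `backend` argument"))
  ids <- names(train_images)
  flat <- function(imgs) lapply(imgs, function(per) lapply(per, identity))
  tr_lab <- rep(ids, vapply(train_images, length, integer(1)))
  te_lab <- rep(ids, vapply(test_images, length, integer(1)))
  pred <- backend(unlist(flat(train_images), recursive = FALSE), tr_lab,
                  unlist(flat(test_images), recursive = FALSE), seed)
  subject_pred <- vapply(ids, function(id) majority_vote(pred[te_lab == id]),
                         character(1))
  cm <- table(factor(ids, levels = ids), factor(subject_pred, levels = ids))
  rep <- compute_ident_metrics(unclass(cm))
  rep$method <- "cnn"
  rep
}
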