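#' Flatten one template to a feature vector
#'
#' Flattening convention (fixed and documented so rows can be unflattened):
#' template-major across a subject's templates in temporal order; within an
#' RGB image template, row-major with channel last (channel varies fastest,
#' then image column, then image row); numeric-vector templates (cardiac
#' cycles) are used as is.
#'
#' @param tpl a `cardiac_cycle`, numeric vector, matrix or H x W x 3 array.
#' @return numeric vector.
#' @export
flatten_template <- function(tpl) {
  if (inherits(tpl, "cardiac_cycle")) return(tpl$samples)
  if (is.array(tpl) && length(dim(tpl)) == 3)
    return(as.vector(aperm(unclass(tpl), c(3, 2, 1))))
  if (is.matrix(tpl)) return(as.vector(t(tpl)))
  as.numeric(tpl)
}

#' Invert the flattening of an RGB image template
#'
#' @param v numeric vector of length prod(dim).
#' @param dim the original c(H, W, 3) dimensions.
#' @return H x W x 3 array.
#' @export
unflatten_template <- function(v, dim) {
  aperm(array(v, rev(dim)), c(3, 2, 1))
}

#' Concatenate per-subject templates into a feature matrix
#'
#' Builds the subjects-by-features matrix used for distance matching: row i
#' is the concatenation of subject i's templates in temporal order (see
#' [flatten_template()] for the within-template convention). With k cycles of
#' 600 samples the feature length is 600 k; with k RGB scalograms of side s
#' it is 3 s^2 k.
#'
#' @param templates named list: one entry per subject, each a `cycle_set` or
#'   a list of templates of identical shape and count.
#' @param subject_ids subject ordering; defaults to `names(templates)`.
#' @return object of class `subject_features`: numeric matrix with subject
#'   ids as row names and a `provenance` attribute.
#' @export
concatenate_subject_templates <- function(templates,
                                          subject_ids = names(templates)) {
  if (is.null(subject_ids)) stop("concatenate_subject_templates: subjects must be named")
  tlist <- lapply(templates[subject_ids], function(tp) {
    if (inherits(tp, "cycle_set")) tp$cycles else tp
  })
  counts <- vapply(tlist, length, integer(1))
  if (length(unique(counts)) != 1)
    stop(sprintf("ragged template counts for subjects: %s",
                 paste(subject_ids[counts != max(counts)], collapse = ", ")))
  rows <- lapply(tlist, function(tp)
    unlist(lapply(tp, flatten_template), use.names = FALSE))
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1)
    stop(sprintf("inconsistent feature lengths for subjects: %s",
                 paste(subject_ids[lens != max(lens)], collapse = ", ")))
  X <- do.call(rbind, rows)
  rownames(X) <- subject_ids
  structure(X, class = c("subject_features", class(X)),
            provenance = list(n_templates = counts[[1]],
                              feature_length = lens[[1]]))
}

#' @export
print.subject_features <- function(x, ...) {
  cat(sprintf("Subject feature matrix: %d subjects x %d features\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Fit FastICA on a training feature matrix
#'
#' FastICA with the deflation scheme and the logcosh (tanh) contrast.
#' Subject rows are treated as observed mixtures over the feature axis: each
#' row is centred on its own mean and the rows are whitened by PCA of the
#' row-by-row covariance. This arrangement keeps an n-subject matrix at
#' numerical rank n, so up to n independent components can be extracted
#' (e.g. 63 components from 63 subjects). The model stores the source matrix
#' (components x features) and the projector used to map any template row
#' into component space.
#'
#' @param X a `subject_features` matrix (training rows only).
#' @param n_components number of independent components
#'   (<= number of subjects; default all).
#' @param seed integer seed for the random initial unmixing directions.
#' @param tol convergence tolerance on the unmixing directions.
#' @param max_iter maximum iterations per component; non-convergence is a
#'   warning, not an error.
#' @return object of class `ica_model`.
#' @export
fit_ica <- function(X, n_components = nrow(X), seed = 1, tol = 1e-4,
                    max_iter = 500) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  d <- as.integer(n_components)
  if (d < 1 || d > n)
    stop("fit_ica: n_components must lie in [1, number of subjects]")
  Xc <- X - rowMeans(X)
  Cv <- tcrossprod(Xc) / (p - 1)
  eg <- eigen(Cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  if (d > rank)
    stop(sprintf("fit_ica: n_components = %d exceeds the rank (%d) of the row-centred training matrix; reduce n_components", d, rank))
  K <- t(eg$vectors[, seq_len(d), drop = FALSE]) / sqrt(eg$values[seq_len(d)])
  Z <- K %*% Xc                               # d x p, whitened rows
  set.seed(as.integer(seed))
  W <- matrix(0, d, d)
  converged <- logical(d)
  for (i in seq_len(d)) {
    w <- stats::rnorm(d)
    if (i > 1) w <- w - t(W[seq_len(i - 1), , drop = FALSE]) %*%
        (W[seq_len(i - 1), , drop = FALSE] %*% w)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(crossprod(w, Z))
      g <- tanh(wx)
      w1 <- drop(Z %*% g) / p - mean(1 - g^2) * w
      if (i > 1) w1 <- w1 - t(W[seq_len(i - 1), , drop = FALSE]) %*%
          (W[seq_len(i - 1), , drop = FALSE] %*% w1)
      w1 <- w1 / sqrt(sum(w1^2))
      delta <- abs(abs(sum(w1 * w)) - 1)
      w <- drop(w1)
      if (delta < tol) { converged[i] <- TRUE; break }
    }
    W[i, ] <- w
  }
  if (!all(converged))
    warning(sprintf("fit_ica: %d of %d components hit max_iter without converging",
                    sum(!converged), d))
  S <- W %*% Z                                # d x p independent sources
  proj <- t(S) %*% solve(tcrossprod(S))       # p x d projector
  structure(list(n_components = d, S = S, proj = proj,
                 unmixing = W %*% K, feature_length = p,
                 seed = as.integer(seed), tol = tol,
                 converged = all(converged)),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("FastICA model: %d components over %d features (%s)\n",
              x$n_components, x$feature_length,
              if (x$converged) "converged" else "not fully converged"))
  invisible(x)
}

#' Project template rows into independent-component space
#'
#' Each row is centred on its own mean and projected onto the fitted source
#' basis, yielding one coordinate per independent component. Transforming
#' the training matrix recovers its mixing coefficients exactly when the
#' component count equals the training rank.
#'
#' @param X a `subject_features` matrix (any rows with the model's feature
#'   length).
#' @param model an `ica_model` from [fit_ica()].
#' @return reduced `subject_features` matrix, one column per component.
#' @export
transform_with_ica <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != model$feature_length)
    stop(sprintf("transform_with_ica: feature length %d does not match the model's %d",
                 ncol(X), model$feature_length))
  R <- (X - rowMeans(X)) %*% model$proj
  rownames(R) <- rownames(X)
  structure(R, class = c("subject_features", class(R)),
            provenance = list(reduced = TRUE, n_components = model$n_components))
}
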