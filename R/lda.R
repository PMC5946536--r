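#' Bayes-decision linear discriminant classifier
#'
#' Fits the shared-covariance Gaussian Bayes classifier used for windowed
#' sEMG pattern recognition: per-class means, a pooled within-class
#' covariance with a small trace-scaled ridge for guaranteed invertibility,
#' and class priors. The decision rule is the linear discriminant
#' \deqn{g_k(x) = \mu_k^T \Sigma^{-1} x - \tfrac12 \mu_k^T \Sigma^{-1} \mu_k
#'   + \log \pi_k,}
#' with prediction by maximal \eqn{g_k} and deterministic ties broken in
#' label order.
#'
#' The pooled covariance is the within-class scatter divided by `N - K`,
#' plus `reg_lambda * (trace / d) * I`. Priors default to empirical class
#' frequencies (uniform under the balanced training protocol).
#'
#' @param x numeric feature matrix, one row per training window.
#' @param y class labels (motion names), length `nrow(x)`.
#' @param priors optional named per-class prior probabilities; must cover
#'   every class and sum to 1.
#' @param reg_lambda ridge weight relative to the mean covariance eigenvalue
#'   (default `1e-6`).
#' @return an object of class `emg_lda` with components `labels`, `means`
#'   (K x d), `cov` (pooled, regularized), `priors`, `reg_lambda`,
#'   `feature_names`, `n_by_class`.
#' @seealso [discriminants()], [predict.emg_lda()], [write_lda()]
#' @export
fit_lda <- function(x, y, priors = NULL, reg_lambda = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  if (nrow(x) != length(y))
    stop("training error: nrow(x) != length(y)")
  if (!all(is.finite(x)))
    stop("data error: non-finite feature values")
  labels <- sort(unique(y))
  if (length(labels) < 2L)
    stop("training error: need at least 2 classes, got ", length(labels))
  counts <- table(factor(y, levels = labels))
  if (any(counts < 2L))
    stop("training error: every class needs >= 2 samples; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  d <- ncol(x)
  K <- length(labels)
  means <- t(vapply(labels, function(l) colMeans(x[y == l, , drop = FALSE]),
                    numeric(d)))
  scatter <- matrix(0, d, d)
  for (l in labels) {
    xc <- sweep(x[y == l, , drop = FALSE], 2L, means[l, ])
    scatter <- scatter + crossprod(xc)
  }
  cov <- scatter / (nrow(x) - K)
  cov <- cov + reg_lambda * (sum(diag(cov)) / d) * diag(d)
  if (is.null(priors)) {
    priors <- as.numeric(counts) / nrow(x)
    names(priors) <- labels
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), labels))
      stop("training error: priors must be named with every class label")
    priors <- priors[labels]
    if (abs(sum(priors) - 1) > 1e-8)
      stop("training error: priors must sum to 1")
  }
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("f", seq_len(d))
  dimnames(cov) <- list(fn, fn)
  colnames(means) <- fn
  structure(list(labels = labels, means = means, cov = cov,
                 priors = priors, reg_lambda = reg_lambda,
                 feature_names = fn,
                 n_by_class = stats::setNames(as.integer(counts), labels)),
            class = "emg_lda")
}

# Shared linear-form pieces: weights W (d x K) and intercepts b (K).
lda_linear_form <- function(m) {
  ch <- chol(m$cov)
  W <- backsolve(ch, forwardsolve(t(ch), t(m$means)))  # Sigma^{-1} mu_k
  b <- -0.5 * colSums(t(m$means) * W) + log(m$priors)
  list(W = W, b = b)
}

#' Per-class discriminant scores
#'
#' Evaluates \eqn{g_k(x)} for every class, in label order.
#'
#' @param m an `emg_lda` model.
#' @param x numeric feature vector, or a matrix with one row per window.
#' @return numeric matrix, rows = inputs, columns = classes (label order).
#' @export
discriminants <- function(m, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(m$means))
    stop("parameter error: feature dimension ", ncol(x),
         " does not match model dimension ", ncol(m$means))
  lf <- lda_linear_form(m)
  g <- x %*% lf$W
  g <- sweep(g, 2L, lf$b, `+`)
  colnames(g) <- m$labels
  g
}

#' Predict motions from feature vectors
#'
#' @param object an `emg_lda` model.
#' @param newdata feature vector or matrix (one row per window).
#' @param type `"class"` (default) for motion labels, `"score"` for the
#'   discriminant matrix, `"posterior"` for class posteriors.
#' @param ... unused.
#' @return character vector of labels, or a numeric matrix for
#'   `type = "score"` / `"posterior"`.
#' @export
predict.emg_lda <- function(object, newdata,
                            type = c("class", "score", "posterior"), ...) {
  type <- match.arg(type)
  g <- discriminants(object, newdata)
  if (type == "score") return(g)
  if (type == "posterior") {
    p <- exp(g - apply(g, 1L, max))
    return(p / rowSums(p))
  }
  # max.col with "first" tie-break = first label in (sorted) label order
  object$labels[max.col(g, ties.method = "first")]
}

#' @export
print.emg_lda <- function(x, ...) {
  cat(sprintf("<emg_lda> %d classes, %d features, reg_lambda = %g\n",
              length(x$labels), ncol(x$means), x$reg_lambda))
  cat("  classes:",
      paste(sprintf("%s (n=%d, pi=%.3g)", x$labels, x$n_by_class, x$priors),
            collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.emg_lda <- function(object, ...) {
  lf <- lda_linear_form(object)
  structure(list(model = object, weights = lf$W, intercepts = lf$b),
            class = "summary.emg_lda")
}

#' @export
print.summary.emg_lda <- function(x, ...) {
  print(x$model)
  cat("\nClass means (first columns):\n")
  print(utils::head(t(x$model$means), 8L))
  cat("\nDiscriminant intercepts:\n")
  print(x$intercepts)
  invisible(x)
}

#' @export
coef.emg_lda <- function(object, ...) {
  lf <- lda_linear_form(object)
  rbind(`(Intercept)` = lf$b, lf$W)
}

#' Serialize / restore a fitted classifier as JSON
#'
#' Stores labels, class means, pooled covariance, priors, the ridge weight
#' and the feature layout, so a model trained offline can drive the
#' classification CLI later.
#'
#' @param m an `emg_lda` model.
#' @param path JSON file path.
#' @export
write_lda <- function(m, path) {
  jsonlite::write_json(
    list(labels = m$labels, means = unclass(m$means), cov = unclass(m$cov),
         priors = as.list(m$priors), reg_lambda = m$reg_lambda,
         feature_names = m$feature_names,
         n_by_class = as.list(m$n_by_class)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda
#' @export
read_lda <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  means <- as.matrix(j$means)
  cov <- as.matrix(j$cov)
  fn <- j$feature_names
  dimnames(cov) <- list(fn, fn)
  rownames(means) <- j$labels
  colnames(means) <- fn
  structure(list(labels = j$labels, means = means, cov = cov,
                 priors = unlist(j$priors)[j$labels],
                 reg_lambda = j$reg_lambda, feature_names = fn,
                 n_by_class = stats::setNames(
                   as.integer(unlist(j$n_by_class)[j$labels]), j$labels)),
            class = "emg_lda")
}
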