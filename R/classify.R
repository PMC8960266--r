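#' Classifier configuration
#'
#' Settings for the single-hidden-layer rectifier network: hidden width 100,
#' L2 strength 2e-4, cross-entropy loss, softmax output, full-batch Adam
#' (adaptive-moment) first-order updates of the form
#' \eqn{W_{i+1} = W_i - \epsilon \nabla Loss(W_i)}, at most 200 iterations.
#'
#' @param hidden Hidden-layer width (>= 1).
#' @param alpha L2 penalty strength (>= 0).
#' @param learning_rate Adam step size \eqn{\epsilon}.
#' @param max_iter Maximum update iterations (>= 1).
#' @param test_fraction Held-out fraction for the stratified split.
#' @param seed Integer seed (weights initialization and split).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(hidden = 100, alpha = 2e-4,
                              learning_rate = 1e-3, max_iter = 200,
                              test_fraction = 0.2, seed = 1L) {
  stopifnot(hidden >= 1, alpha >= 0, max_iter >= 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(hidden = as.integer(hidden), alpha = alpha,
                 learning_rate = learning_rate,
                 max_iter = as.integer(max_iter),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "classifier_config")
}

# range-normalize each spectrum (row) to [0, 1]
range_normalize_rows <- function(X) {
  t(apply(X, 1, function(r) {
    rng <- range(r)
    if (diff(rng) == 0) rep(0, length(r)) else (r - rng[1]) / diff(rng)
  }))
}

# one-hot encode a factor
one_hot <- function(f) {
  Y <- matrix(0, length(f), nlevels(f))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

# ReLU MLP with softmax output trained by full-batch Adam on
# cross-entropy + (alpha/2)||W||^2
mlp_fit <- function(X, f, hidden, alpha, lr, max_iter) {
  n <- nrow(X); m <- ncol(X); k <- nlevels(f)
  Y <- one_hot(f)
  glorot <- function(n_in, n_out)
    matrix(stats::runif(n_in * n_out, -1, 1) * sqrt(6 / (n_in + n_out)),
           n_in, n_out)
  W1 <- glorot(m, hidden); b1 <- numeric(hidden)
  W2 <- glorot(hidden, k); b2 <- numeric(k)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (it in seq_len(max_iter)) {
    H <- pmax(X %*% params$W1 + rep(params$b1, each = n), 0)
    Z <- H %*% params$W2 + rep(params$b2, each = n)
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    dZ <- (P - Y) / n
    grad <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(H, dZ) + alpha * params$W2 / n,
      b2 = colSums(dZ))
    dH <- dZ %*% t(params$W2)
    dH[H <= 0] <- 0
    grad$W1 <- crossprod(X, dH) + alpha * params$W1 / n
    grad$b1 <- colSums(dH)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^it)
      vhat <- vel[[nm]] / (1 - beta2^it)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(params = params, levels = levels(f)), class = "ramanld_mlp")
}

mlp_predict <- function(model, X) {
  p <- model$params
  H <- pmax(X %*% p$W1 + rep(p$b1, each = nrow(X)), 0)
  Z <- H %*% p$W2 + rep(p$b2, each = nrow(X))
  factor(model$levels[max.col(Z, ties.method = "first")],
         levels = model$levels)
}

# stratified train/test split indices
stratified_split <- function(f, test_fraction) {
  test <- integer(0)
  for (lv in levels(f)) {
    idx <- which(f == lv)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

#' Train a spectral classifier and report held-out accuracy
#'
#' Range-normalizes all spectra to a common \[0, 1\] range, splits them into
#' stratified train/held-out sets, trains the rectifier MLP
#' (see [classifier_config()]) and reports held-out accuracy with per-class
#' confusion counts. Deterministic for a fixed config seed.
#'
#' @param set A [spectrum_set()].
#' @param factor_name Metadata column with the target classes (>= 2 levels).
#' @param config A [classifier_config()].
#' @return List of class `spectrum_classifier`: `model`, `accuracy`,
#'   `confusion` (table, truth x predicted), `test_index`, `config`.
#' @export
train_spectrum_classifier <- function(set, factor_name,
                                      config = classifier_config()) {
  stopifnot(inherits(set, "spectrum_set"),
            inherits(config, "classifier_config"))
  f <- set_labels(set, factor_name)
  f <- droplevels(f)
  if (nlevels(f) < 2) stop("need at least 2 classes to classify")
  X <- range_normalize_rows(set$intensity)
  set.seed(config$seed)
  test <- stratified_split(f, config$test_fraction)
  train <- setdiff(seq_along(f), test)
  if (!length(train) || !length(test)) stop("split infeasible at this n")
  model <- mlp_fit(X[train, , drop = FALSE], droplevels(f[train]),
                   config$hidden, config$alpha, config$learning_rate,
                   config$max_iter)
  pred <- mlp_predict(model, X[test, , drop = FALSE])
  truth <- factor(as.character(f[test]), levels = model$levels)
  structure(list(model = model,
                 accuracy = mean(pred == truth),
                 confusion = table(truth = truth, predicted = pred),
                 test_index = test, config = config),
            class = "spectrum_classifier")
}

#' @export
print.spectrum_classifier <- function(x, ...) {
  cat(sprintf("<spectrum_classifier> held-out accuracy %.3f (n_test = %d)\n",
              x$accuracy, length(x$test_index)))
  print(x$confusion)
  invisible(x)
}
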