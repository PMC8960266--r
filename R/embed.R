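#' Embedding configuration
#'
#' Settings for the PCA-to-t-SNE workflow: the top principal components
#' (default 10) are fed to t-distributed stochastic neighbour embedding at
#' perplexity 30 with no early exaggeration (factor 1), the configuration
#' that preserves global structure in the group-separation plots.
#'
#' @param components Number of principal components kept (>= 2).
#' @param perplexity t-SNE perplexity (must be < n samples / 3).
#' @param exaggeration Early-exaggeration factor (1 = none, the default).
#' @param max_iter t-SNE gradient iterations.
#' @param seed Integer seed.
#' @return List of class `embedding_config`.
#' @export
embedding_config <- function(components = 10, perplexity = 30,
                             exaggeration = 1, max_iter = 500, seed = 1L) {
  stopifnot(components >= 2, perplexity > 0, exaggeration >= 1, max_iter >= 50)
  structure(list(components = as.integer(components), perplexity = perplexity,
                 exaggeration = exaggeration, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

# exact t-SNE (O(n^2), adequate for cohort-scale n) with PCA initialization
# for determinism and global-structure preservation
tsne_exact <- function(X, perplexity = 30, exaggeration = 1, max_iter = 500) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  # per-point precision by binary search on perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) p <- rep(1e-12, length(di)) else p <- p / sumP
      H <- -sum(p[p > 0] * log(p[p > 0]))
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) { betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else { betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # PCA initialization, scaled small
  Y <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  Y <- Y / stats::sd(Y[, 1]) * 1e-4
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 200
  stop_exagg <- min(100L, max_iter %/% 4)
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= stop_exagg) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it < 250) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' PCA followed by t-SNE embedding of a spectrum set
#'
#' Projects the spectra onto their top principal components (variance-ranked
#' linear decomposition) and embeds the scores in 2-D by exact t-SNE. The
#' pipeline is deterministic given the config seed.
#'
#' @param set A [spectrum_set()].
#' @param config An [embedding_config()].
#' @param label_factors Metadata columns copied into the output for
#'   plotting (defaults to all).
#' @return List of class `spectrum_embedding`: `coords` (data.frame with
#'   `x`, `y` and label columns), `explained_variance` (fraction per kept
#'   component, non-increasing), `config`.
#' @export
embed_pca_tsne <- function(set, config = embedding_config(),
                           label_factors = NULL) {
  stopifnot(inherits(set, "spectrum_set"),
            inherits(config, "embedding_config"))
  n <- n_spectra(set)
  if (n <= config$components)
    stop("need more spectra than principal components")
  if (config$perplexity >= n / 3)
    stop("perplexity must be below n/3")
  if (any(apply(set$intensity, 2, stats::sd) == 0) &&
      all(apply(set$intensity, 1, stats::sd) == 0))
    stop("degenerate (constant) spectra cannot be embedded")
  set.seed(config$seed)
  pc <- stats::prcomp(set$intensity, center = TRUE, scale. = FALSE)
  k <- min(config$components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  # identical spectra must embed identically: collapse exact duplicates and
  # share their coordinates (duplicates add no information to the map)
  key <- apply(set$intensity, 1, paste, collapse = "\r")
  first <- match(key, key)
  uniq <- which(first == seq_along(key))
  if (config$perplexity >= length(uniq))
    stop("perplexity must be below the number of distinct spectra")
  Yu <- tsne_exact(scores[uniq, , drop = FALSE], config$perplexity,
                   config$exaggeration, config$max_iter)
  Y <- Yu[match(first, uniq), , drop = FALSE]
  if (is.null(label_factors)) label_factors <- names(set$meta)
  coords <- data.frame(x = Y[, 1], y = Y[, 2])
  for (lf in intersect(label_factors, names(set$meta)))
    coords[[lf]] <- set$meta[[lf]]
  structure(list(coords = coords, explained_variance = ev, config = config),
            class = "spectrum_embedding")
}
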