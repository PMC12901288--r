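#' PCA embedding of chunk-sum feature vectors
#'
#' Columns are centred (and optionally unit-scaled); scores and loadings
#' come from the singular value decomposition ([stats::prcomp()]). A
#' deterministic sign convention makes the largest-magnitude loading of
#' each component positive, so embeddings are reproducible across runs.
#'
#' @param features numeric matrix (n_movies x n_features) or list of
#'   `feature_vector`s.
#' @param n_components number of components to keep
#'   (<= min(n_movies - 1, n_features)).
#' @param standardize unit-scale the columns; zero-variance features are
#'   then dropped with a warning.
#' @param labels optional condition label per movie, carried into the
#'   embedding.
#' @return object of class `embedding`: `scores` (n_movies x
#'   n_components), `loadings`, `explained_variance_ratio` (non-negative,
#'   non-increasing, summing to <= 1), `labels`.
#' @export
pca_embed <- function(features, n_components = 2, standardize = FALSE,
                      labels = NULL) {
  if (is.list(features) && !is.data.frame(features) && !is.matrix(features))
    features <- do.call(rbind, lapply(features, function(f) {
      if (inherits(f, "feature_vector")) f$values else as.numeric(f)
    }))
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 movies")
  if (n_components > min(n - 1, ncol(X)))
    stop("n_components must be <= min(n_movies - 1, n_features)")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance feature(s) dropped before scaling")
      X <- X[, sds > 0, drop = FALSE]
      if (ncol(X) == 0) stop("no features left after dropping zero-variance columns")
    }
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = standardize)
  for (i in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, i]))
    if (pr$rotation[j, i] < 0) {
      pr$rotation[, i] <- -pr$rotation[, i]
      pr$x[, i] <- -pr$x[, i]
    }
  }
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  k <- min(n_components, ncol(pr$x))
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 explained_variance_ratio = evr[seq_len(k)],
                 labels = labels, center = pr$center,
                 standardize = standardize),
            class = "embedding")
}

# Mean silhouette coefficient over all points, from a precomputed distance
# matrix. Degenerate points (a = b = 0) contribute 0.
silhouette_from_dist <- function(D, labels) {
  labels <- as.character(labels)
  n <- nrow(D)
  groups <- split(seq_len(n), labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    a <- mean(D[i, setdiff(groups[[own]], i)])
    b <- min(vapply(groups[names(groups) != own],
                    function(idx) mean(D[i, idx]), numeric(1)))
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

#' Separation of labelled groups in an embedding
#'
#' Mean silhouette coefficient of the condition labels on the first two
#' principal-component scores, with a permutation p-value: labels are
#' shuffled `n_permutations` times under a fixed seed and the p-value is
#' the fraction of permutations (plus one) whose silhouette is at least
#' the observed one.
#'
#' @param embedding an `embedding` (or a bare score matrix).
#' @param labels one label per movie; at least two groups with at least
#'   two members each. Defaults to the embedding's labels.
#' @param n_permutations number of label permutations (>= 999 recommended).
#' @param seed permutation seed, recorded in the result.
#' @return object of class `cluster_separation`: `statistic` (mean
#'   silhouette), `p_value`, `n_permutations`, `seed`.
#' @export
cluster_separation <- function(embedding, labels = NULL, n_permutations = 999,
                               seed = 1) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else as.matrix(embedding)
  labels <- labels %||% (if (inherits(embedding, "embedding")) embedding$labels else NULL)
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(scores)) stop("one label per movie required")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two distinct labels")
  if (any(tab < 2)) stop("every label needs at least two members (",
                         paste(names(tab)[tab < 2], collapse = ", "), " has fewer)")
  scores <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
  D <- as.matrix(stats::dist(scores))
  stat <- silhouette_from_dist(D, labels)
  perm <- withr::with_seed(as.integer(seed), vapply(seq_len(n_permutations),
    function(i) silhouette_from_dist(D, sample(labels)), numeric(1)))
  p <- (1 + sum(perm >= stat)) / (n_permutations + 1)
  structure(list(statistic = stat, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "cluster_separation")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d movies x %d components (EVR: %s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.2f", x$explained_variance_ratio), collapse = ", ")))
  invisible(x)
}

#' @export
print.cluster_separation <- function(x, ...) {
  cat(sprintf("cluster_separation: mean silhouette %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
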