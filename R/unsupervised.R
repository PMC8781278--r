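#' Principal component analysis of an autoscaled response matrix
#'
#' PCA on the sample correlation structure: the input must already be
#' autoscaled (see [autoscale()]), so the covariance of the input equals its
#' correlation matrix and the component loadings are the eigenvectors of
#' that matrix ordered by decreasing eigenvalue. Scores are the projections
#' `X %*% loadings`. Each component's sign is fixed so that the variable
#' with the largest absolute loading has a positive loading (first such
#' variable on ties), which makes score plots and downstream regressions
#' deterministic across linear-algebra backends.
#'
#' @param X Autoscaled runs x responses matrix.
#' @param n_components Number of components to keep; `NULL` keeps all
#'   `min(runs - 1, responses)`.
#' @return An object of class `pca_model`: a list with `loadings`
#'   (responses x components, orthonormal columns), `scores`
#'   (runs x components), `explained` (percent of total variance per kept
#'   component) and `cum_explained`. Percentages are always computed over all
#'   components, so truncation does not change them.
#' @examples
#' Xs <- autoscale(matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c"))))
#' run_pca(Xs)$explained
#' @export
run_pca <- function(X, n_components = NULL) {
  X <- as.matrix(X)
  if (!is_autoscaled(X)) {
    stop("input must be autoscaled (zero mean, unit sd per column); ",
         "call autoscale() first", call. = FALSE)
  }
  m <- ncol(X)
  max_comp <- min(nrow(X) - 1L, m)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components < 1 || n_components > max_comp) {
    stop("n_components must lie in [1, ", max_comp, "]", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation[, seq_len(max_comp), drop = FALSE]
  # deterministic sign: largest-|loading| variable positive per component
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  ev <- pc$sdev[seq_len(max_comp)]^2
  explained <- 100 * ev / sum(ev)
  keep <- seq_len(n_components)
  loadings <- loadings[, keep, drop = FALSE]
  structure(
    list(
      loadings = loadings,
      scores = X %*% loadings,
      explained = explained[keep],
      cum_explained = cumsum(explained)[keep]
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d response(s), %d component(s) kept\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat("  explained (%):",
      paste(sprintf("%.2f", utils::head(x$explained, 5)), collapse = ", "),
      if (length(x$explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' Correlation-distance dissimilarity between response variables
#'
#' The default (unsigned) variant is `d(j, l) = 1 - |r_jl|`, so strongly
#' positively and strongly negatively correlated variables are both near —
#' required for modules that mix anti-correlated members, such as a
#' fermentation-length/fermentation-rate pair. The signed variant `1 - r`
#' is available for comparison.
#'
#' @param X Runs x responses numeric matrix.
#' @param variant `"absolute"` (`1 - |r|`, default) or `"signed"` (`1 - r`).
#' @return A `dist` object over the response variables.
#' @export
correlation_distance <- function(X, variant = c("absolute", "signed")) {
  variant <- match.arg(variant)
  r <- correlation_matrix(X)
  d <- if (variant == "absolute") 1 - abs(r) else 1 - r
  # clamp tiny negatives from floating-point |r| slightly above 1
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Agglomerative hierarchical clustering of response variables
#'
#' Clusters the variables (not the runs) of a response matrix under the
#' correlation distance of [correlation_distance()], cutting the dendrogram
#' to exactly `k` clusters. Average linkage (UPGMA) is the default; complete
#' and single linkage are selectable. The assignment is deterministic given
#' the data and `k`.
#'
#' @param X Runs x responses numeric matrix (autoscaling does not change
#'   correlations, so either scaled or raw input works).
#' @param k Target number of clusters, between 1 and the number of responses.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param distance Distance variant passed to [correlation_distance()].
#' @return An object of class `cluster_assignment`: a list with `labels`
#'   (named integer vector, response -> cluster id, ids numbered by first
#'   appearance in column order), `merge_history` (data frame `step`, `left`,
#'   `right`, `height`), `k`, and the underlying `hclust` tree.
#' @examples
#' d <- generate_ccd(seed = 1)
#' sim <- simulate_responses(d, default_truth(noise_sd = 0), seed = 7)
#' ahc_cluster(sim$responses, k = 5)$labels
#' @export
ahc_cluster <- function(X, k, linkage = c("average", "complete", "single"),
                        distance = c("absolute", "signed")) {
  linkage <- match.arg(linkage)
  X <- as.matrix(X)
  m <- ncol(X)
  if (!(is.numeric(k) && length(k) == 1L && k >= 1 && k <= m)) {
    stop("k must lie between 1 and the number of responses (", m, ")",
         call. = FALSE)
  }
  d <- correlation_distance(X, match.arg(distance))
  hc <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(hc, k = as.integer(k))
  # renumber cluster ids by first appearance so labels are column-order stable
  labels <- match(raw, unique(raw))
  names(labels) <- colnames(X)

  node_name <- function(idx) {
    vapply(idx, function(i) {
      if (i < 0) colnames(X)[-i] else paste0("node", i)
    }, character(1))
  }
  merge_history <- data.frame(
    step = seq_len(nrow(hc$merge)),
    left = node_name(hc$merge[, 1]),
    right = node_name(hc$merge[, 2]),
    height = hc$height,
    stringsAsFactors = FALSE
  )
  structure(
    list(labels = labels, merge_history = merge_history, k = as.integer(k),
         tree = hc),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d variables in %d cluster(s)\n",
              length(x$labels), x$k))
  for (cl in unique(x$labels)) {
    cat(sprintf("  %d: %s\n", cl,
                paste(names(x$labels)[x$labels == cl], collapse = ", ")))
  }
  invisible(x)
}

#' Member lists of a cluster assignment
#'
#' @param assignment A `cluster_assignment`.
#' @return A list of character vectors, one per cluster id in order.
#' @export
cluster_members <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  lapply(sort(unique(assignment$labels)), function(cl) {
    names(assignment$labels)[assignment$labels == cl]
  })
}
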