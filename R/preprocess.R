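#' Autoscale a response matrix
#'
#' Z-transforms every response column to zero mean and unit standard
#' deviation (sample sd, `n - 1` denominator), so that downstream principal
#' component analysis and clustering see only the correlation structure. The
#' column means and sds are kept in the `"scaling"` attribute for the inverse
#' transform used at reconstruction time.
#'
#' @param X Runs x responses numeric matrix (no missing values).
#' @return The scaled matrix, with attribute `scaling = list(mean, sd)`.
#' @seealso [unscale()], [reconstruct()]
#' @examples
#' autoscale(cbind(a = c(1, 2, 3)))[, 1]  # -1 0 1
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("response matrix contains missing values", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (constant) column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  means <- colMeans(X)
  out <- scale(X, center = means, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "scaling") <- list(mean = means, sd = sds)
  out
}

#' @rdname autoscale
#' @param X_scaled A matrix produced by [autoscale()].
#' @export
unscale <- function(X_scaled) {
  sc <- attr(X_scaled, "scaling")
  if (is.null(sc)) stop("matrix carries no scaling attribute", call. = FALSE)
  out <- sweep(sweep(unclass(X_scaled), 2, sc$sd, `*`), 2, sc$mean, `+`)
  attr(out, "scaling") <- NULL
  out
}

# TRUE when every column has mean ~0 and sample sd ~1.
is_autoscaled <- function(X, tol = 1e-6) {
  all(abs(colMeans(X)) < tol) && all(abs(apply(X, 2, stats::sd) - 1) < tol)
}

#' Per-factor-level numeric summaries of every response
#'
#' The numeric content behind the classic DOE boxplot panel: for each
#' response, factor and coded level, the group size, mean, quartiles and
#' range of the response values observed at that level.
#'
#' @param design A `ccd_design`.
#' @param X Runs x responses numeric matrix, row-aligned with the design.
#' @return A tidy data frame with columns `response`, `factor`, `level`,
#'   `n`, `mean`, `q1`, `q3`, `min`, `max`.
#' @examples
#' d <- generate_ccd(seed = 1)
#' sim <- simulate_responses(d, seed = 42)
#' head(level_summaries(d, sim$responses))
#' @export
level_summaries <- function(design, X) {
  stopifnot(inherits(design, "ccd_design"))
  X <- as.matrix(X)
  if (nrow(X) != nrow(design$runs)) {
    stop("responses (", nrow(X), " rows) are not aligned with the design (",
         nrow(design$runs), " runs)", call. = FALSE)
  }
  rows <- list()
  for (resp in colnames(X)) {
    for (fac in colnames(design$runs)) {
      for (lev in sort(unique(design$runs[, fac]))) {
        v <- X[design$runs[, fac] == lev, resp]
        q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, factor = fac, level = lev, n = length(v),
          mean = mean(v), q1 = q[1], q3 = q[2], min = min(v), max = max(v),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlation matrix of the responses
#'
#' @param X Runs x responses numeric matrix with at least 3 rows and no
#'   constant columns.
#' @return Symmetric responses x responses correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 runs to estimate correlations",
                        call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (constant) column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(X)
}
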