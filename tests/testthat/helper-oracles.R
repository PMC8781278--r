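# Independent oracles used to cross-check the package implementations.
# These deliberately use different machinery (lm/anova, naive re-scan loops)
# from the code paths they validate.

# Brute-force greedy stepwise with partial F-tests, built on lm(): at each
# iteration try every excluded term via a fresh lm fit, add the smallest-p
# term if p < alpha_enter (first minimum in label order), then re-test every
# included term and drop the largest-p one if p > alpha_remove.
oracle_stepwise <- function(y, Z, labels, alpha_enter = 0.05,
                            alpha_remove = 0.05, max_iter = 50) {
  Z <- scale(Z)  # same standardization contract as the implementation
  dat <- data.frame(y = y, Z, check.names = FALSE)
  rss_of <- function(sel) {
    f <- if (length(sel) == 0) {
      y ~ 1
    } else {
      stats::reformulate(sprintf("`%s`", sel), response = "y")
    }
    sum(stats::resid(stats::lm(f, data = dat))^2)
  }
  n <- length(y)
  included <- character(0)
  actions <- list()
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    rss_cur <- rss_of(included)
    best <- list(p = Inf, term = NA, F = NA)
    for (term in setdiff(labels, included)) {
      p_full <- 1 + length(included) + 1
      if (n - p_full < 2) next
      rss_new <- rss_of(c(included, term))
      Fstat <- max(rss_cur - rss_new, 0) / (rss_new / (n - p_full))
      pval <- stats::pf(Fstat, 1, n - p_full, lower.tail = FALSE)
      if (!is.nan(pval) && pval < best$p) best <- list(p = pval, term = term, F = Fstat)
    }
    if (!is.na(best$term) && best$p < alpha_enter) {
      included <- c(included, best$term)
      actions[[length(actions) + 1]] <- c("add", best$term)
      changed <- TRUE
    }
    if (length(included) > 0) {
      p_full <- 1 + length(included)
      rss_full <- rss_of(included)
      worst <- list(p = -Inf, term = NA)
      for (term in included) {
        rss_red <- rss_of(setdiff(included, term))
        Fstat <- max(rss_red - rss_full, 0) / (rss_full / (n - p_full))
        pval <- stats::pf(Fstat, 1, n - p_full, lower.tail = FALSE)
        if (!is.nan(pval) && pval > worst$p) worst <- list(p = pval, term = term)
      }
      if (worst$p > alpha_remove) {
        included <- setdiff(included, worst$term)
        actions[[length(actions) + 1]] <- c("drop", worst$term)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(selected = included,
       actions = do.call(rbind, actions))
}

# Naive O(m^3) agglomeration by full re-scan of the between-cluster distance
# at every step. Linkage between clusters A and B is the mean (average),
# max (complete) or min (single) over all cross pairs of the original
# distance matrix. Ties broken toward the smallest (i, j) pair in current
# cluster order. Returns merge heights and the k-cluster partition.
oracle_ahc <- function(D, k, linkage = "average") {
  m <- nrow(D)
  clusters <- as.list(seq_len(m))
  heights <- numeric(0)
  link_fun <- switch(linkage, average = mean, complete = max, single = min)
  while (length(clusters) > k) {
    best <- list(h = Inf, i = NA, j = NA)
    nc <- length(clusters)
    for (i in seq_len(nc - 1)) {
      for (j in seq((i + 1), nc)) {
        h <- link_fun(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (h < best$h - 1e-12) best <- list(h = h, i = i, j = j)
      }
    }
    heights <- c(heights, best$h)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  labels <- integer(m)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  list(labels = labels, heights = heights)
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  identical(ta, tb)
}

# Adjusted Rand index between two labelings (Hubert & Arabie form).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
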