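test_that("PCA of a perfectly correlated pair puts 100% on PC1 at 0.7071 each", {
  set.seed(1)
  x <- rnorm(25)
  Xs <- autoscale(cbind(a = x, b = 2 * x + 3))
  pc <- run_pca(Xs)
  expect_equal(pc$explained[1], 100, tolerance = 1e-10)
  expect_equal(unname(abs(pc$loadings[, 1])), c(1, 1) / sqrt(2),
               tolerance = 1e-8)
})

test_that("independent columns share explained variance evenly", {
  set.seed(42)
  m <- 5
  Xs <- autoscale(matrix(rnorm(1e5 * m), ncol = m,
                         dimnames = list(NULL, letters[1:m])))
  pc <- run_pca(Xs)
  expect_lt(max(abs(pc$explained - 100 / m)), 1)
})

test_that("all components reconstruct the data and account for 100% variance", {
  Xs <- autoscale(ferm_sim(seed = 10)$responses)
  pc <- run_pca(Xs)
  expect_lt(max(abs(pc$scores %*% t(pc$loadings) - Xs)), 1e-8)
  expect_equal(sum(pc$explained), 100, tolerance = 1e-6)
  expect_equal(pc$cum_explained[length(pc$cum_explained)], 100,
               tolerance = 1e-6)
  # loadings are orthonormal
  G <- crossprod(pc$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # explained percentages are non-increasing
  expect_true(all(diff(pc$explained) <= 1e-10))
})

test_that("PCA is sign-stable: X and -X give identical explained and |loadings|", {
  Xs <- autoscale(ferm_sim(seed = 11)$responses)
  neg <- -Xs
  attr(neg, "scaling") <- attr(Xs, "scaling")
  p1 <- run_pca(Xs)
  p2 <- run_pca(neg)
  expect_equal(p1$explained, p2$explained, tolerance = 1e-10)
  expect_equal(abs(p1$loadings), abs(p2$loadings), tolerance = 1e-8)
})

test_that("PCA refuses unscaled input and out-of-range component counts", {
  sim <- ferm_sim(seed = 12)
  expect_error(run_pca(sim$responses), "autoscale")
  Xs <- autoscale(sim$responses)
  expect_error(run_pca(Xs, n_components = 0), "n_components")
  expect_error(run_pca(Xs, n_components = 99), "n_components")
})

test_that("correlation distance is bounded and zero iff |r| = 1", {
  set.seed(3)
  x <- rnorm(20)
  X <- cbind(a = x, b = -x, c = rnorm(20), d = 0.5 * x + rnorm(20))
  D <- as.matrix(correlation_distance(X))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D["a", "b"], 0, tolerance = 1e-12)
  expect_gt(D["a", "c"], 0)
  Ds <- as.matrix(correlation_distance(X, variant = "signed"))
  expect_equal(Ds["a", "b"], 2, tolerance = 1e-12)
})

test_that("duplicated and anti-correlated variables cluster together", {
  set.seed(4)
  x <- rnorm(30)
  z <- rnorm(30)
  copies <- cbind(a = x, b = x + rnorm(30, sd = 1e-3), c = z)
  cl <- ahc_cluster(copies, k = 2)
  expect_identical(cl$labels[["a"]], cl$labels[["b"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])

  anti <- cbind(a = x, b = -x + rnorm(30, sd = 1e-3), c = z)
  cl2 <- ahc_cluster(anti, k = 2)
  expect_identical(cl2$labels[["a"]], cl2$labels[["b"]])
  # the signed variant separates the anti-correlated pair instead
  cl3 <- ahc_cluster(anti, k = 2, distance = "signed")
  expect_false(cl3$labels[["a"]] == cl3$labels[["b"]])
})

test_that("clustering the default synthetic study recovers the five modules", {
  sim <- ferm_sim(noise_sd = 0.05, seed = 42)
  cl <- ahc_cluster(autoscale(sim$responses), k = 5)
  expect_equal(ari(cl$labels, truth_labels(sim$truth)[names(cl$labels)]), 1)
})

test_that("degenerate cluster counts give singletons or one cluster", {
  sim <- ferm_sim(seed = 13)
  m <- ncol(sim$responses)
  expect_identical(unname(sort(ahc_cluster(sim$responses, k = m)$labels)),
                   1:m)
  expect_identical(unique(unname(ahc_cluster(sim$responses, k = 1)$labels)),
                   1L)
  expect_error(ahc_cluster(sim$responses, k = 0), "between 1")
  expect_error(ahc_cluster(sim$responses, k = m + 1), "between 1")
})

test_that("merge heights are non-decreasing for average linkage", {
  sim <- ferm_sim(seed = 14)
  cl <- ahc_cluster(sim$responses, k = 5)
  expect_true(all(diff(cl$merge_history$height) >= -1e-12))
  expect_identical(nrow(cl$merge_history), ncol(sim$responses) - 1L)
})

test_that("agglomeration agrees with a naive re-scan oracle on small problems", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- sample(4:8, 1)
    n <- 25
    # latent two-group structure plus noise keeps distances tie-free
    g <- rnorm(n)
    h <- rnorm(n)
    X <- sapply(seq_len(m), function(j) {
      if (j %% 2 == 0) g + rnorm(n, sd = runif(1, 0.3, 2)) else
        h + rnorm(n, sd = runif(1, 0.3, 2))
    })
    colnames(X) <- paste0("v", seq_len(m))
    D <- as.matrix(correlation_distance(X))
    for (linkage in c("average", "complete", "single")) {
      for (k in c(1, 2, m - 1)) {
        mine <- ahc_cluster(X, k = k, linkage = linkage)
        orac <- oracle_ahc(D, k = k, linkage = linkage)
        expect_true(same_partition(unname(mine$labels), orac$labels))
      }
      # full merge-height sequence matches the oracle run to a single cluster
      orac_all <- oracle_ahc(D, k = 1, linkage = linkage)
      mine_all <- ahc_cluster(X, k = 1, linkage = linkage)
      expect_equal(mine_all$merge_history$height, orac_all$heights,
                   tolerance = 1e-10)
    }
  }
})
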