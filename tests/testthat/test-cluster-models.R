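test_that("a single-member cluster degenerates to loading 1 and 100% explained", {
  Xs <- autoscale(ferm_sim(seed = 1)$responses)
  cp <- cluster_pc1(Xs, "Ethyl acetate", cluster_id = 1)
  expect_equal(unname(cp$loadings_pc1), 1)
  expect_equal(cp$explained, 100)
  expect_equal(unname(cp$scores_pc1), unname(Xs[, "Ethyl acetate"]))
})

test_that("two-member clusters always load at 0.7071 in magnitude", {
  Xs <- autoscale(ferm_sim(seed = 2)$responses)
  cp <- cluster_pc1(Xs, c("R100", "MFR"))
  expect_equal(unname(abs(cp$loadings_pc1)), c(1, 1) / sqrt(2),
               tolerance = 1e-10)
  # sign convention: the largest-|loading| member is positive
  expect_gt(max(cp$loadings_pc1), 0)
})

test_that("two-member PC1 explained variance matches the closed form", {
  # eigenvalues of a 2x2 correlation matrix are 1 +/- |r|, so PC1 explains
  # 100 * (1 + |r|) / 2
  set.seed(3)
  for (rho in c(-0.9, -0.3, 0.2, 0.7, 0.95)) {
    n <- 40
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    Xs <- autoscale(cbind(a = x, b = y))
    r <- stats::cor(Xs)[1, 2]
    cp <- cluster_pc1(Xs, c("a", "b"))
    expect_equal(cp$explained[1], 100 * (1 + abs(r)) / 2, tolerance = 1e-8)
  }
})

test_that("cluster_pc1 validates its member list", {
  Xs <- autoscale(ferm_sim(seed = 3)$responses)
  expect_error(cluster_pc1(Xs, character(0)), "nonempty")
  expect_error(cluster_pc1(Xs, c("R100", "nope")), "not present")
})

test_that("the candidate term set has the canonical size and order", {
  ts <- build_terms(ferm_design())
  expect_identical(ts$labels,
                   c("S", "N", "T", "I",
                     "S:N", "S:T", "S:I", "N:T", "N:I", "T:I",
                     "S^2", "N^2", "T^2", "I^2"))
  d2 <- generate_ccd(2, n_center = 1, seed = 1)
  expect_length(build_terms(d2)$labels, 5)

  # interactions are products, quadratics are squares (in {0,1} face-centered)
  d <- ferm_design()
  expect_equal(ts$values[, "N:T"], d$runs[, "N"] * d$runs[, "T"])
  expect_true(all(ts$values[, "S^2"] %in% c(0, 1)))
  expect_equal(ts$values[, "S^2"], d$runs[, "S"]^2)
})

test_that("a noiseless single-term response is selected alone with R^2 = 1", {
  ts <- build_terms(ferm_design())
  std <- scale(ts$values)
  y <- as.numeric(std[, "N:T"]) * 2.5
  fit <- stepwise_fit(y, ts)
  expect_identical(fit$selected, "N:T")
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_identical(fit$trace$action, "add")
})

test_that("pure-noise responses rarely admit terms and the trace stays coherent", {
  ts <- build_terms(ferm_design())
  set.seed(7)
  n_empty <- 0
  for (r in 1:50) {
    fit <- stepwise_fit(rnorm(31), ts)
    if (length(fit$selected) == 0) n_empty <- n_empty + 1
    # every dropped term was previously added
    if (nrow(fit$trace) > 0) {
      for (i in which(fit$trace$action == "drop")) {
        expect_true(fit$trace$term[i] %in%
                      fit$trace$term[seq_len(i - 1)][
                        fit$trace$action[seq_len(i - 1)] == "add"])
      }
    }
    expect_true(all(fit$p_value > 0 & fit$p_value < 1))
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  }
  expect_gt(n_empty, 15)  # pure-noise fits mostly stay empty at alpha 0.05
})

test_that("empty-model rate under the null matches a Monte-Carlo oracle", {
  ts <- small_term_set(n = 12, k = 2, seed = 5)
  run_rate <- function(nrep, fitter) {
    empty <- 0
    for (r in seq_len(nrep)) {
      set.seed(20000 + r)
      y <- rnorm(nrow(ts$values))
      if (length(fitter(y)) == 0) empty <- empty + 1
    }
    empty / nrep
  }
  mine <- run_rate(1000, function(y) stepwise_fit(y, ts)$selected)
  orac <- run_rate(2000, function(y) {
    oracle_stepwise(y, ts$values, ts$labels)$selected
  })
  expect_lt(abs(mine - orac), 0.03)
})

test_that("partial F equals the squared t-statistic of the added term", {
  set.seed(11)
  for (r in 1:40) {
    ts <- small_term_set(n = sample(10:20, 1), k = sample(2:3, 1),
                         seed = 100 + r)
    n <- nrow(ts$values)
    y <- rnorm(n) + ts$values %*% rnorm(ncol(ts$values), sd = 0.5)
    repeat {
      included <- sample(ts$labels, sample(0:2, 1))
      term <- sample(setdiff(ts$labels, included), 1)
      M <- cbind(1, scale(ts$values)[, c(included, term)])
      if (qr(M)$rank == ncol(M)) break
    }
    pf_mine <- partial_f_add(as.numeric(y), ts, included, term)

    Zs <- scale(ts$values)
    dat <- data.frame(y = as.numeric(y), Zs, check.names = FALSE)
    f <- stats::reformulate(sprintf("`%s`", c(included, term)), response = "y")
    coefs <- summary(stats::lm(f, data = dat))$coefficients
    rn <- intersect(c(term, paste0("`", term, "`")), rownames(coefs))
    tstat <- coefs[rn, "t value"]
    expect_lt(abs(pf_mine$F - tstat^2), 1e-8)
  }
})

test_that("the stepwise path matches a brute-force greedy oracle exactly", {
  for (r in 1:25) {
    ts <- small_term_set(n = sample(12:20, 1), k = 2, seed = 200 + r)
    set.seed(300 + r)
    beta <- rnorm(ncol(ts$values)) * rbinom(ncol(ts$values), 1, 0.4)
    y <- as.numeric(ts$values %*% beta + rnorm(nrow(ts$values), sd = 1))
    mine <- stepwise_fit(y, ts)
    orac <- oracle_stepwise(y, ts$values, ts$labels)
    expect_identical(mine$selected, orac$selected)
    steps <- mine$trace[mine$trace$action %in% c("add", "drop"), ]
    if (is.null(orac$actions)) {
      expect_identical(nrow(steps), 0L)
    } else {
      expect_identical(unname(as.matrix(steps[, c("action", "term")])),
                       unname(orac$actions))
    }
  }
})

test_that("R^2 is non-decreasing along the add steps of the trace", {
  ts <- build_terms(ferm_design())
  sim <- ferm_sim(seed = 21)
  Xs <- autoscale(sim$responses)
  cp <- cluster_pc1(Xs, sim$truth[[2]]$members)
  fit <- stepwise_fit(cp$scores_pc1, ts)
  adds <- fit$trace[fit$trace$action == "add", ]
  expect_gt(nrow(adds), 1)
  # refit the prefix models and check R^2 growth
  r2 <- vapply(seq_len(nrow(adds)), function(i) {
    sel <- adds$term[seq_len(i)]
    Zs <- scale(ts$values)
    summary(stats::lm(cp$scores_pc1 ~ Zs[, sel]))$r.squared
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("the degrees-of-freedom guard refuses saturating additions", {
  # 2 factors, 5 candidate terms, but only 8 runs: after a few additions the
  # residual df guard must kick in rather than fit a saturated model
  set.seed(5)
  coded <- matrix(sample(c(-1L, 0L, 1L), 16, replace = TRUE), 8, 2,
                  dimnames = list(NULL, c("A", "B")))
  while (any(apply(build_terms(coded)$values, 2, sd) == 0)) {
    coded <- matrix(sample(c(-1L, 0L, 1L), 16, replace = TRUE), 8, 2,
                    dimnames = list(NULL, c("A", "B")))
  }
  ts <- build_terms(coded)
  y <- rowSums(ts$values) + rnorm(8, sd = 0.01)
  fit <- stepwise_fit(y, ts)
  expect_lte(length(fit$selected), 8 - 1 - 2)  # n - intercept - 2 residual df
})

test_that("reconstruction inverts a rank-1 noiseless cluster exactly", {
  sim <- ferm_sim(noise_sd = 0, seed = 30)
  Xs <- autoscale(sim$responses)
  scaling <- attr(Xs, "scaling")
  members <- sim$truth[[4]]$members
  cp <- cluster_pc1(Xs, members)
  rec <- reconstruct(cp, cp$scores_pc1, scaling)
  expect_lt(max(abs(rec - sim$responses[, members])), 1e-8)
})

test_that("zero scores reconstruct to the member means", {
  sim <- ferm_sim(seed = 31)
  Xs <- autoscale(sim$responses)
  scaling <- attr(Xs, "scaling")
  members <- sim$truth[[5]]$members
  cp <- cluster_pc1(Xs, members)
  rec <- reconstruct(cp, rep(0, nrow(Xs)), scaling)
  for (m in members) {
    expect_equal(unname(rec[, m]), rep(unname(scaling$mean[m]), nrow(Xs)))
  }
})

test_that("reconstruct refuses missing scaling", {
  sim <- ferm_sim(seed = 32)
  Xs <- autoscale(sim$responses)
  cp <- cluster_pc1(Xs, c("R100", "MFR"))
  expect_error(reconstruct(cp, cp$scores_pc1, NULL), "scaling")
  bad <- attr(Xs, "scaling")
  bad$mean <- bad$mean[setdiff(names(bad$mean), "R100")]
  expect_error(reconstruct(cp, cp$scores_pc1, bad), "R100")
})

test_that("model_summary assembles row blocks and round-trips through JSON", {
  res <- run_pipeline(pipeline_config(noise_sd = 0.05, seed = 42))
  ledger <- res$ledger
  expect_length(ledger, 5)
  expect_identical(sum(lengths(lapply(ledger, `[[`, "members"))), 18L)

  df <- as.data.frame(ledger)
  expect_true(all(c("cluster_id", "member", "loading_pc1", "cum_explained",
                    "r_squared", "term", "beta", "std_err", "p_value")
                  %in% names(df)))

  path <- withr::local_tempfile(fileext = ".json")
  write_ledger_json(ledger, path)
  back <- read_ledger_json(path)
  expect_equal(unclass(back), unclass(ledger), tolerance = 0)
})

test_that("a cluster with nothing selected reports R^2 = 0 and no term rows", {
  ts <- build_terms(ferm_design())
  set.seed(8)
  y <- rnorm(31)  # pure noise; retry seeds until the model is empty
  fit <- stepwise_fit(y, ts)
  while (length(fit$selected) > 0) {
    y <- rnorm(31)
    fit <- stepwise_fit(y, ts)
  }
  Xs <- autoscale(ferm_sim(seed = 33)$responses)
  cp <- cluster_pc1(Xs, "Ethyl acetate", cluster_id = 1)
  ledger <- model_summary(list(fit), list(cp))
  expect_equal(ledger[[1]]$r_squared, 0)
  expect_identical(nrow(ledger[[1]]$terms), 0L)
})
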