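#' Cluster-level PC1 surrogate model
#'
#' Restricts PCA to a cluster's member columns of the autoscaled response
#' matrix and keeps the first principal component as a single surrogate for
#' all members. A single-member cluster degenerates to loading 1 with scores
#' equal to the scaled column and 100% explained variance. The sign
#' convention of [run_pca()] applies (largest-|loading| member positive).
#'
#' @param X Autoscaled runs x responses matrix.
#' @param members Character vector of member response names (nonempty, all
#'   present in `X`).
#' @param cluster_id Optional identifier carried into reports.
#' @return An object of class `cluster_pca`: a list with `cluster_id`,
#'   `members`, `loadings_pc1` (unit vector over members), `scores_pc1`
#'   (per-run surrogate values), `explained` and `cum_explained` (percent per
#'   principal component of the member block).
#' @examples
#' d <- generate_ccd(seed = 1)
#' Xs <- autoscale(simulate_responses(d, seed = 42)$responses)
#' cluster_pc1(Xs, c("R100", "MFR"))$loadings_pc1
#' @export
cluster_pc1 <- function(X, members, cluster_id = NA) {
  X <- as.matrix(X)
  if (length(members) < 1L) stop("member list must be nonempty", call. = FALSE)
  missing <- setdiff(members, colnames(X))
  if (length(missing) > 0) {
    stop("member(s) not present in the response matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(members) == 1L) {
    if (!is_autoscaled(X[, members, drop = FALSE])) {
      stop("input must be autoscaled; call autoscale() first", call. = FALSE)
    }
    out <- list(
      cluster_id = cluster_id,
      members = members,
      loadings_pc1 = stats::setNames(1, members),
      scores_pc1 = X[, members],
      explained = 100,
      cum_explained = 100
    )
    return(structure(out, class = "cluster_pca"))
  }
  pc <- run_pca(X[, members, drop = FALSE])
  structure(
    list(
      cluster_id = cluster_id,
      members = members,
      loadings_pc1 = stats::setNames(pc$loadings[, 1], members),
      scores_pc1 = pc$scores[, 1],
      explained = pc$explained,
      cum_explained = pc$cum_explained
    ),
    class = "cluster_pca"
  )
}

#' @export
print.cluster_pca <- function(x, ...) {
  cat(sprintf("<cluster_pca> cluster %s: %d member(s), PC1 explains %.2f%%\n",
              as.character(x$cluster_id), length(x$members), x$explained[1]))
  invisible(x)
}

# OLS on an intercept + selected standardized term columns; returns the
# pieces the stepwise loop and the final report need.
ols_fit <- function(y, Z, selected) {
  n <- length(y)
  M <- cbind(`(Intercept)` = 1, Z[, selected, drop = FALSE])
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) {
    return(list(rss = NA_real_, rank_deficient = TRUE))
  }
  coefs <- qr.coef(qr_, y)
  res <- y - M %*% coefs
  rss <- sum(res^2)
  df_res <- n - ncol(M)
  sigma2 <- if (df_res > 0) rss / df_res else NA_real_
  XtX_inv <- chol2inv(chol(crossprod(M)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  list(
    coef = coefs, se = stats::setNames(se, colnames(M)),
    p = stats::setNames(pval, colnames(M)),
    rss = rss, df_res = df_res, rank_deficient = FALSE
  )
}

#' Forward stepwise selection with partial F-tests
#'
#' Greedy model building for a per-run surrogate response over the candidate
#' term set of [build_terms()]. At every iteration the partial F statistic
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - p_full))` is computed for
#' adding each excluded term on its own; the term with the smallest p-value
#' enters if `p < alpha_enter` (ties broken toward the earlier label in the
#' canonical order: mains, interactions, quadratics). Every included term is
#' then re-tested and the largest-p term is dropped if `p > alpha_remove`.
#' The loop stops when no addition or removal changes the model. Terms are
#' standardized (centered, unit sample sd) before fitting, so coefficients
#' are reported on the standardized predictor scale; no effect-heredity
#' constraint is imposed, and an addition that would leave fewer than 2
#' residual degrees of freedom (or a rank-deficient fit) is ineligible that
#' iteration and recorded in the trace.
#'
#' @param y Numeric response vector (e.g. PC1 surrogate scores), used as-is.
#' @param terms A `term_set` from [build_terms()] (standardized internally).
#' @param alpha_enter,alpha_remove Partial-F significance levels for entry
#'   and removal (both default 0.05).
#' @param cluster_id Optional identifier carried into the report.
#' @return An object of class `stepwise_model`: a list with `cluster_id`,
#'   `selected` (ordered labels), `beta`, `std_err`, `p_value` (per selected
#'   term, intercept fitted but not reported), `r_squared`, `trace` (data
#'   frame `action`, `term`, `partial_F`, `p`), `n`, and the thresholds.
#' @examples
#' d <- generate_ccd(seed = 1)
#' ts <- build_terms(d)
#' y <- ts$values[, "S"] * 2 + rnorm(nrow(ts$values), sd = 0.05)
#' stepwise_fit(y, ts)$selected
#' @export
stepwise_fit <- function(y, terms, alpha_enter = 0.05, alpha_remove = 0.05,
                         cluster_id = NA) {
  stopifnot(inherits(terms, "term_set"))
  stopifnot(alpha_enter > 0, alpha_enter < 1, alpha_remove > 0, alpha_remove < 1)
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(terms$values)) {
    stop("length of y (", n, ") does not match the term matrix (",
         nrow(terms$values), " runs)", call. = FALSE)
  }
  terms <- standardize_terms(terms)
  Z <- unclass(terms$values)
  labels <- terms$labels

  included <- character(0)
  tss <- sum((y - mean(y))^2)
  trace <- list()
  note <- function(action, term, F, p) {
    trace[[length(trace) + 1L]] <<- data.frame(
      action = action, term = term, partial_F = F, p = p,
      stringsAsFactors = FALSE
    )
  }

  for (iter in seq_len(50L)) {
    changed <- FALSE
    fit_cur <- ols_fit(y, Z, included)

    # --- entry scan ---
    # a numerically perfect fit cannot be improved significantly; without
    # this guard the partial-F ratio degenerates to 0/0 on noiseless data
    candidates <- if (fit_cur$rss <= 1e-10 * max(tss, .Machine$double.eps)) {
      character(0)
    } else {
      setdiff(labels, included)
    }
    best_p <- Inf; best_term <- NA_character_; best_F <- NA_real_
    for (term in candidates) {
      p_full <- 1L + length(included) + 1L
      if (n - p_full < 2L) { note("ineligible", term, NA, NA); next }
      fit_new <- ols_fit(y, Z, c(included, term))
      if (fit_new$rank_deficient) { note("ineligible", term, NA, NA); next }
      Fstat <- max(fit_cur$rss - fit_new$rss, 0) / (fit_new$rss / fit_new$df_res)
      pval <- stats::pf(Fstat, 1, fit_new$df_res, lower.tail = FALSE)
      if (!is.nan(pval) && pval < best_p) {
        best_p <- pval; best_term <- term; best_F <- Fstat
      }
    }
    if (!is.na(best_term) && best_p < alpha_enter) {
      included <- c(included, best_term)
      note("add", best_term, best_F, best_p)
      changed <- TRUE
    }

    # --- removal scan ---
    if (length(included) > 0L) {
      fit_full <- ols_fit(y, Z, included)
      worst_p <- -Inf; worst_term <- NA_character_; worst_F <- NA_real_
      for (term in included) {
        fit_red <- ols_fit(y, Z, setdiff(included, term))
        Fstat <- max(fit_red$rss - fit_full$rss, 0) /
          (fit_full$rss / fit_full$df_res)
        pval <- stats::pf(Fstat, 1, fit_full$df_res, lower.tail = FALSE)
        if (!is.nan(pval) && pval > worst_p) {
          worst_p <- pval; worst_term <- term; worst_F <- Fstat
        }
      }
      if (worst_p > alpha_remove) {
        included <- setdiff(included, worst_term)
        note("drop", worst_term, worst_F, worst_p)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- ols_fit(y, Z, included)
  tss <- sum((y - mean(y))^2)
  r_squared <- if (length(included) == 0L || tss == 0) 0 else 1 - fit$rss / tss
  beta <- se <- pv <- stats::setNames(numeric(0), character(0))
  if (length(included) > 0L) {
    beta <- fit$coef[included]
    se <- fit$se[included]
    pv <- fit$p[included]
  }
  structure(
    list(
      cluster_id = cluster_id,
      selected = included,
      beta = beta, std_err = se, p_value = pv,
      r_squared = r_squared,
      trace = if (length(trace) > 0) do.call(rbind, trace) else
        data.frame(action = character(0), term = character(0),
                   partial_F = numeric(0), p = numeric(0)),
      n = n, alpha_enter = alpha_enter, alpha_remove = alpha_remove
    ),
    class = "stepwise_model"
  )
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> cluster %s: R^2 = %.4f, %d term(s)\n",
              as.character(x$cluster_id), x$r_squared, length(x$selected)))
  if (length(x$selected) > 0) {
    tab <- data.frame(term = x$selected, beta = unname(x$beta),
                      std_err = unname(x$std_err), p_value = unname(x$p_value))
    print(tab, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Partial F-test for adding a single term
#'
#' The statistic used by the entry scan of [stepwise_fit()]:
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - p_full))` with 1 and
#' `n - p_full` degrees of freedom, where the reduced model holds the
#' intercept plus `included` and the full model additionally holds `term`.
#' For a single added term, F equals the square of the term's t-statistic in
#' the full model.
#'
#' @param y Numeric response vector.
#' @param terms A `term_set` (standardized internally, as in
#'   [stepwise_fit()]).
#' @param included Character vector of terms already in the model (may be
#'   empty).
#' @param term The candidate term label.
#' @return A list with `F`, `p` and `df_res`.
#' @export
partial_f_add <- function(y, terms, included, term) {
  stopifnot(inherits(terms, "term_set"), term %in% terms$labels,
            !term %in% included)
  terms <- standardize_terms(terms)
  Z <- unclass(terms$values)
  y <- as.numeric(y)
  fit_red <- ols_fit(y, Z, included)
  fit_full <- ols_fit(y, Z, c(included, term))
  if (fit_full$rank_deficient) {
    stop("the augmented model is rank deficient", call. = FALSE)
  }
  Fstat <- max(fit_red$rss - fit_full$rss, 0) /
    (fit_full$rss / fit_full$df_res)
  list(F = Fstat,
       p = stats::pf(Fstat, 1, fit_full$df_res, lower.tail = FALSE),
       df_res = fit_full$df_res)
}

#' Predict surrogate scores from a fitted stepwise model
#'
#' Evaluates the fitted polynomial on (new) coded runs, applying the same
#' term standardization as at fit time.
#'
#' @param object A `stepwise_model`.
#' @param terms The standardized `term_set` used at fit time, or a fresh
#'   [build_terms()] result on the same design.
#' @param y The response used at fit time (needed for the intercept; the
#'   intercept is refitted from the selected terms).
#' @param ... Unused.
#' @return Numeric vector of fitted surrogate scores.
#' @export
predict_scores <- function(object, terms, y, ...) {
  stopifnot(inherits(object, "stepwise_model"), inherits(terms, "term_set"))
  terms <- standardize_terms(terms)
  Z <- unclass(terms$values)
  fit <- ols_fit(as.numeric(y), Z, object$selected)
  M <- cbind(1, Z[, object$selected, drop = FALSE])
  as.numeric(M %*% fit$coef)
}

#' Reconstruct member responses from predicted surrogate scores
#'
#' The outer product of predicted PC1 scores with the cluster's PC1 loading
#' vector gives member predictions on the autoscaled scale; the stored
#' per-member (mean, sd) then maps them back to original units.
#'
#' @param model A `cluster_pca`.
#' @param t_hat Predicted per-run PC1 scores.
#' @param scaling A `list(mean, sd)` of named per-column statistics as stored
#'   by [autoscale()] in the `"scaling"` attribute; must cover every member.
#' @return Runs x members matrix of predicted responses in original units.
#' @examples
#' d <- generate_ccd(seed = 1)
#' Xs <- autoscale(simulate_responses(d, seed = 42)$responses)
#' cp <- cluster_pc1(Xs, c("Ethanol", "Glycerol"))
#' rec <- reconstruct(cp, cp$scores_pc1, attr(Xs, "scaling"))
#' @export
reconstruct <- function(model, t_hat, scaling) {
  stopifnot(inherits(model, "cluster_pca"))
  if (is.null(scaling) || is.null(scaling$mean) || is.null(scaling$sd)) {
    stop("scaling must be a list(mean, sd) of per-member statistics",
         call. = FALSE)
  }
  missing <- setdiff(model$members, intersect(names(scaling$mean),
                                              names(scaling$sd)))
  if (length(missing) > 0) {
    stop("scaling missing for member(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Zhat <- outer(as.numeric(t_hat), model$loadings_pc1)
  colnames(Zhat) <- model$members
  mu <- scaling$mean[model$members]
  sd_ <- scaling$sd[model$members]
  sweep(sweep(Zhat, 2, sd_, `*`), 2, mu, `+`)
}

#' Summary ledger across cluster models
#'
#' Combines the per-cluster PC1 models and stepwise reports into the
#' nine-column summary structure used to report this workflow: cluster id,
#' composition, PC1 loadings, cumulative explained variance, model R^2, and
#' the selected terms with coefficients, standard errors and p-values.
#'
#' @param reports List of `stepwise_model` objects, one per cluster.
#' @param pca_models List of `cluster_pca` objects, aligned with `reports`.
#' @return An object of class `model_ledger`: a list of per-cluster blocks,
#'   each with `cluster_id`, `members`, `loadings_pc1`, `cum_explained`,
#'   `r_squared` and a `terms` data frame (`term`, `beta`, `std_err`,
#'   `p_value`; zero rows when nothing was selected).
#' @seealso [as.data.frame.model_ledger()], [write_ledger_json()]
#' @export
model_summary <- function(reports, pca_models) {
  stopifnot(length(reports) == length(pca_models))
  blocks <- Map(function(rep, pc) {
    stopifnot(inherits(rep, "stepwise_model"), inherits(pc, "cluster_pca"))
    list(
      cluster_id = pc$cluster_id,
      members = pc$members,
      loadings_pc1 = as.numeric(pc$loadings_pc1),
      cum_explained = as.numeric(pc$cum_explained),
      r_squared = rep$r_squared,
      terms = data.frame(
        term = rep$selected,
        beta = as.numeric(rep$beta),
        std_err = as.numeric(rep$std_err),
        p_value = as.numeric(rep$p_value),
        stringsAsFactors = FALSE
      )
    )
  }, reports, pca_models)
  structure(blocks, class = "model_ledger")
}

#' @export
print.model_ledger <- function(x, ...) {
  cat(sprintf("<model_ledger> %d cluster model(s)\n", length(x)))
  for (b in x) {
    cat(sprintf("cluster %s (R^2 = %.4f): %s\n", as.character(b$cluster_id),
                b$r_squared, paste(b$members, collapse = ", ")))
    if (nrow(b$terms) > 0) {
      print(b$terms, row.names = FALSE, digits = 4)
    } else {
      cat("  (no terms selected)\n")
    }
  }
  invisible(x)
}

#' Flatten a model ledger to a data frame
#'
#' One row per (cluster, member-or-term) pairing the composition/loadings
#' columns with the model columns, mimicking the row-block layout of the
#' printed summary table.
#'
#' @param x A `model_ledger`.
#' @param ... Unused.
#' @return A data frame with columns `cluster_id`, `member`, `loading_pc1`,
#'   `cum_explained`, `r_squared`, `term`, `beta`, `std_err`, `p_value`.
#' @export
as.data.frame.model_ledger <- function(x, ...) {
  rows <- lapply(x, function(b) {
    n <- max(length(b$members), nrow(b$terms), 1L)
    pad <- function(v, fill = NA) c(v, rep(fill, n - length(v)))
    data.frame(
      cluster_id = rep(b$cluster_id, n),
      member = pad(b$members, NA_character_),
      loading_pc1 = pad(b$loadings_pc1),
      cum_explained = pad(b$cum_explained),
      r_squared = rep(b$r_squared, n),
      term = pad(b$terms$term, NA_character_),
      beta = pad(b$terms$beta),
      std_err = pad(b$terms$std_err),
      p_value = pad(b$terms$p_value),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Ledger JSON round trip
#'
#' `write_ledger_json()` serializes a `model_ledger` losslessly (full double
#' precision); `read_ledger_json()` restores it.
#'
#' @param ledger A `model_ledger`.
#' @param path File path.
#' @return The path invisibly; `read_ledger_json()` returns a `model_ledger`.
#' @export
write_ledger_json <- function(ledger, path) {
  stopifnot(inherits(ledger, "model_ledger"))
  payload <- lapply(unclass(ledger), function(b) {
    b$terms <- as.list(b$terms)
    b
  })
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ledger_json
#' @export
read_ledger_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  blocks <- lapply(payload, function(b) {
    b$terms <- data.frame(
      term = as.character(b$terms$term %||% character(0)),
      beta = as.numeric(b$terms$beta %||% numeric(0)),
      std_err = as.numeric(b$terms$std_err %||% numeric(0)),
      p_value = as.numeric(b$terms$p_value %||% numeric(0)),
      stringsAsFactors = FALSE
    )
    b$members <- as.character(b$members)
    b$loadings_pc1 <- as.numeric(b$loadings_pc1)
    b$cum_explained <- as.numeric(b$cum_explained)
    b
  })
  structure(blocks, class = "model_ledger")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
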