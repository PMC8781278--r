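#' Pipeline configuration
#'
#' Assembles and checks the configuration of an end-to-end run. Configs can
#' be round-tripped through YAML with [read_config()] / [write_config()].
#'
#' @param mode `"synthetic"` (simulate the responses) or `"files"` (load
#'   `design_csv` and `responses_csv`).
#' @param factors Named list of [factor_spec()] objects.
#' @param n_center Center replicates for the generated design.
#' @param design_seed Seed for the run-order randomization.
#' @param noise_sd Generator noise level (synthetic mode).
#' @param sim_seed Generator seed (synthetic mode).
#' @param k_clusters Number of variable clusters to cut.
#' @param linkage,distance Clustering options, see [ahc_cluster()].
#' @param alpha_enter,alpha_remove Stepwise thresholds, see [stepwise_fit()].
#' @param design_csv,responses_csv Input files for `mode = "files"`.
#' @param seed Global seed; stage seeds not given explicitly are derived from
#'   it by a fixed fan-out rule, so adding a stage never perturbs earlier
#'   stages' randomness.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            factors = fermentation_factors(),
                            n_center = 7,
                            design_seed = NULL,
                            noise_sd = 0.05,
                            sim_seed = NULL,
                            k_clusters = 5,
                            linkage = "average",
                            distance = "absolute",
                            alpha_enter = 0.05,
                            alpha_remove = 0.05,
                            design_csv = NULL,
                            responses_csv = NULL,
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(alpha_enter > 0, alpha_enter < 1, alpha_remove > 0, alpha_remove < 1,
            k_clusters >= 1)
  child <- derive_seeds(seed)
  cfg <- list(
    mode = mode, factors = factors, n_center = n_center,
    design_seed = if (is.null(design_seed)) child[["design"]] else design_seed,
    noise_sd = noise_sd,
    sim_seed = if (is.null(sim_seed)) child[["simulate"]] else sim_seed,
    k_clusters = as.integer(k_clusters),
    linkage = linkage, distance = distance,
    alpha_enter = alpha_enter, alpha_remove = alpha_remove,
    design_csv = design_csv, responses_csv = responses_csv,
    seed = as.integer(seed)
  )
  if (mode == "files") {
    for (f in c("design_csv", "responses_csv")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        stop("mode = 'files' requires an existing ", f, call. = FALSE)
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

# Fixed fan-out from the global seed to per-stage child seeds: stage i gets
# the i-th draw of a seeded stream, so appending stages preserves earlier
# seeds. Values stay below 2^31.
derive_seeds <- function(seed) {
  stages <- c("design", "simulate", "cluster", "model")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> mode = %s, k_clusters = %d, seed = %d\n",
              x$mode, x$k_clusters, x$seed))
  invisible(x)
}

#' Read and write pipeline configs as YAML
#'
#' The flat YAML layout stores each factor as a `name/low/mid/high/units`
#' block; the round trip `read_config(write_config(cfg))` is lossless.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- unclass(config)
  flat$factors <- lapply(config$factors, function(f) {
    list(name = f$name, low = f$low, mid = f$mid, high = f$high,
         units = f$units)
  })
  flat <- flat[!vapply(flat, is.null, TRUE)]
  yaml::write_yaml(flat, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  factors <- lapply(raw$factors, function(f) {
    factor_spec(f$name, f$low, f$mid, f$high, units = f$units %||% "")
  })
  names(factors) <- vapply(factors, `[[`, "", "name")
  pipeline_config(
    mode = raw$mode %||% "synthetic",
    factors = factors,
    n_center = raw$n_center %||% 7,
    design_seed = raw$design_seed,
    noise_sd = raw$noise_sd %||% 0.05,
    sim_seed = raw$sim_seed,
    k_clusters = raw$k_clusters %||% 5,
    linkage = raw$linkage %||% "average",
    distance = raw$distance %||% "absolute",
    alpha_enter = raw$alpha_enter %||% 0.05,
    alpha_remove = raw$alpha_remove %||% 0.05,
    design_csv = raw$design_csv,
    responses_csv = raw$responses_csv,
    seed = raw$seed %||% 1
  )
}

#' Run the full three-stage analysis
#'
#' Executes design acquisition (generate or load), response acquisition
#' (simulate or load), Stage 1 (autoscaling, per-level summaries, pairwise
#' correlations), Stage 2 (global PCA and variable clustering) and Stage 3
#' (per-cluster PC1 surrogates, stepwise polynomial models, reconstruction,
#' summary ledger). When `out_dir` is given, every artifact is written there
#' along with a manifest (config echo, seeds, package version) and a plain
#' text log; identical configs produce identical analysis artifacts.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @return A list of class `pipeline_result` with elements `design`,
#'   `responses`, `scaled`, `summaries`, `correlation`, `pca`, `clusters`,
#'   `cluster_pcas`, `models`, `ledger`, `reconstructed`, `truth` (synthetic
#'   mode only) and `config`.
#' @examples
#' res <- run_pipeline(pipeline_config(noise_sd = 0, seed = 42))
#' length(res$ledger)  # 5 cluster models
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(stage, event, ...) {
    msg <- sprintf("[%s] %s %s", stage, event, paste(..., collapse = " "))
    log_lines <<- c(log_lines, msg)
  }

  # --- inputs ---
  truth <- NULL
  if (config$mode == "synthetic") {
    design <- generate_ccd(config$factors, n_center = config$n_center,
                           seed = config$design_seed)
    sim <- simulate_responses(design, default_truth(config$noise_sd),
                              seed = config$sim_seed)
    responses <- sim$responses
    truth <- sim$truth
    say("input", "simulated", ncol(responses), "responses over",
        nrow(responses), "runs")
  } else {
    design <- read_design(config$design_csv, config$factors)
    responses <- read_responses(config$responses_csv)
    if (nrow(responses) != nrow(design$runs)) {
      stop("responses (", nrow(responses), " rows) are not aligned with the ",
           "design (", nrow(design$runs), " runs)", call. = FALSE)
    }
    say("input", "loaded", config$design_csv, "and", config$responses_csv)
  }
  if (config$k_clusters > ncol(responses)) {
    stop("k_clusters (", config$k_clusters, ") exceeds the number of responses (",
         ncol(responses), ")", call. = FALSE)
  }

  # --- stage 1 ---
  scaled <- autoscale(responses)
  summaries <- level_summaries(design, responses)
  corr <- correlation_matrix(responses)
  say("stage1", "autoscaled;", nrow(summaries), "summary rows")

  # --- stage 2 ---
  pca <- run_pca(scaled)
  clusters <- ahc_cluster(scaled, k = config$k_clusters,
                          linkage = config$linkage,
                          distance = config$distance)
  sizes <- table(clusters$labels)
  say("stage2", "PC1 explains", sprintf("%.1f%%;", pca$explained[1]),
      "cluster sizes", paste(as.integer(sizes), collapse = "/"))

  # --- stage 3 ---
  terms <- build_terms(design)
  scaling <- attr(scaled, "scaling")
  members <- cluster_members(clusters)
  cluster_pcas <- vector("list", length(members))
  models <- vector("list", length(members))
  recon <- matrix(NA_real_, nrow(responses), ncol(responses),
                  dimnames = dimnames(responses))
  for (ci in seq_along(members)) {
    cp <- cluster_pc1(scaled, members[[ci]], cluster_id = ci)
    fit <- stepwise_fit(cp$scores_pc1, terms,
                        alpha_enter = config$alpha_enter,
                        alpha_remove = config$alpha_remove,
                        cluster_id = ci)
    t_hat <- predict_scores(fit, terms, cp$scores_pc1)
    recon[, cp$members] <- reconstruct(cp, t_hat, scaling)
    cluster_pcas[[ci]] <- cp
    models[[ci]] <- fit
    say("stage3", sprintf("cluster %d: R^2 = %.4f, terms = {%s}", ci,
                          fit$r_squared, paste(fit$selected, collapse = ", ")))
  }
  ledger <- model_summary(models, cluster_pcas)

  result <- structure(
    list(design = design, responses = responses, scaled = scaled,
         summaries = summaries, correlation = corr, pca = pca,
         clusters = clusters, cluster_pcas = cluster_pcas, models = models,
         ledger = ledger, reconstructed = recon, truth = truth,
         config = config, log = log_lines),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d runs x %d responses, %d cluster model(s)\n",
              nrow(x$responses), ncol(x$responses), length(x$ledger)))
  invisible(x)
}

# Write the full artifact set of a run. Analysis artifacts are
# timestamp-free so identical configs give identical files; the log carries
# wall-clock context.
write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_design(result$design, p("design.csv"))
  write_responses(result$responses, p("responses.csv"))
  utils::write.csv(result$summaries, p("level_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(response = rownames(result$correlation),
                              result$correlation, check.names = FALSE),
                   p("correlation.csv"), row.names = FALSE)
  utils::write.csv(data.frame(run_id = seq_len(nrow(result$pca$scores)),
                              result$pca$scores, check.names = FALSE),
                   p("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(response = rownames(result$pca$loadings),
                              result$pca$loadings, check.names = FALSE),
                   p("pca_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(result$pca$explained),
                              explained = result$pca$explained,
                              cum_explained = result$pca$cum_explained),
                   p("pca_explained.csv"), row.names = FALSE)
  utils::write.csv(data.frame(response = names(result$clusters$labels),
                              cluster_id = as.integer(result$clusters$labels)),
                   p("cluster_labels.csv"), row.names = FALSE)
  utils::write.csv(result$clusters$merge_history, p("merge_history.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$ledger), p("ledger.csv"),
                   row.names = FALSE)
  write_ledger_json(result$ledger, p("ledger.json"))
  traces <- do.call(rbind, lapply(result$models, function(m) {
    if (nrow(m$trace) == 0) return(NULL)
    cbind(cluster_id = m$cluster_id, m$trace)
  }))
  if (is.null(traces)) {
    traces <- data.frame(cluster_id = integer(0), action = character(0),
                         term = character(0), partial_F = numeric(0),
                         p = numeric(0))
  }
  utils::write.csv(traces, p("trace.csv"), row.names = FALSE)
  utils::write.csv(data.frame(run_id = seq_len(nrow(result$reconstructed)),
                              result$reconstructed, check.names = FALSE),
                   p("reconstructed.csv"), row.names = FALSE)
  cfg <- result$config
  manifest <- list(
    package = "fermrsm",
    version = as.character(utils::packageVersion("fermrsm")),
    mode = cfg$mode,
    seed = cfg$seed,
    design_seed = cfg$design_seed,
    sim_seed = cfg$sim_seed,
    k_clusters = cfg$k_clusters,
    linkage = cfg$linkage,
    distance = cfg$distance,
    alpha_enter = cfg$alpha_enter,
    alpha_remove = cfg$alpha_remove,
    noise_sd = cfg$noise_sd
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(format(Sys.time(), "# run at %Y-%m-%d %H:%M:%S"), result$log),
             p("run.log"))
  invisible(out_dir)
}
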