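#' Specify one latent response module for the synthetic generator
#'
#' A module is a block of correlated responses driven by a single latent
#' score. For run `i` with coded factor vector `x_i`, the module score is
#' `s(x_i) = sum_t beta_t * g_t(x_i)` where `g_t` is a coded main effect,
#' pairwise product or square (see [build_terms()]). Member `j` then takes
#' the value `mu_j + lambda_j * (p_j * s(x_i) + eps_ij)` with
#' `eps_ij ~ N(0, noise_sd^2)` independent across runs and members. The
#' loading vector `p` is renormalized to unit Euclidean norm, so printed
#' (rounded) loadings can be passed as-is; any rescaling applied is recorded
#' in the `provenance` element.
#'
#' @param id Module identifier (integer or string).
#' @param members Character vector of response names (nonempty).
#' @param loadings Numeric loading per member; renormalized to unit norm.
#' @param betas Named numeric vector of latent effect sizes; names are term
#'   labels understood by [build_terms()] (e.g. `"S"`, `"N:T"`, `"S^2"`).
#' @param noise_sd Residual standard deviation on the standardized scale
#'   (default 0.05).
#' @param member_means,member_scales Per-member location `mu` and physical
#'   scale `lambda` (defaults 0 and 1: standardized units).
#' @return An object of class `module_spec`.
#' @examples
#' module_spec(1, c("A", "B"), c(0.7071, -0.7071), c(S = 1))
#' @export
module_spec <- function(id, members, loadings, betas, noise_sd = 0.05,
                        member_means = 0, member_scales = 1) {
  stopifnot(is.character(members), length(members) >= 1L,
            length(loadings) == length(members),
            is.numeric(betas), !is.null(names(betas)), all(nzchar(names(betas))),
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  nrm <- sqrt(sum(loadings^2))
  if (nrm == 0) stop("loadings must not all be zero", call. = FALSE)
  member_means <- rep_len(member_means, length(members))
  member_scales <- rep_len(member_scales, length(members))
  structure(
    list(
      id = id,
      members = members,
      loadings = loadings / nrm,
      betas = betas,
      noise_sd = noise_sd,
      member_means = stats::setNames(member_means, members),
      member_scales = stats::setNames(member_scales, members),
      provenance = list(loading_renorm = nrm)
    ),
    class = "module_spec"
  )
}

#' @export
print.module_spec <- function(x, ...) {
  cat(sprintf("<module_spec> %s: %d member(s), noise_sd = %g\n",
              as.character(x$id), length(x$members), x$noise_sd))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  cat("  betas:  ", paste(sprintf("%s = %g", names(x$betas), x$betas),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Default ground-truth modules of the emulated fermentation study
#'
#' Five response modules covering the 18 fermentation responses (sizes
#' 1/2/7/3/5): ethyl acetate alone; the fermentation-kinetics pair (time to
#' dryness R100 and maximum fermentation rate MFR, anti-correlated); the
#' ethyl esters, isoamyl acetate and 1-propanol; the primary fermentation
#' products ethanol, acetic acid and glycerol; and the higher alcohols with
#' 2-phenylethyl acetate. Loadings and latent effect sizes are the reported
#' cluster-specific PC1 loadings and standardized regression coefficients of
#' the reference study; loading vectors are renormalized to unit norm where
#' the printed 4-decimal values round-trip imperfectly.
#'
#' @param noise_sd Residual standard deviation shared by all modules
#'   (default 0.05 on the standardized scale).
#' @return A list of five [module_spec()] objects.
#' @examples
#' sum(lengths(lapply(default_truth(), `[[`, "members")))  # 18
#' @export
default_truth <- function(noise_sd = 0.05) {
  list(
    module_spec(
      1, "Ethyl acetate", 1,
      c("I" = 0.7592, "N:I" = -0.2088),
      noise_sd = noise_sd
    ),
    module_spec(
      2, c("R100", "MFR"), c(-0.7071, 0.7071),
      c("S" = -0.6569, "N" = 0.4962, "T" = 0.8519, "I" = -0.1458,
        "N:T" = 0.1663, "S^2" = -0.2045, "N^2" = -0.2727),
      noise_sd = noise_sd
    ),
    module_spec(
      3,
      c("Ethyl hexanoate", "Ethyl dodecanoate", "Isoamyl acetate",
        "Ethyl octanoate", "Ethyl decanoate", "1-propanol", "Ethyl butanoate"),
      c(0.3857, 0.3494, 0.4000, 0.4157, 0.4122, 0.3231, 0.3492),
      c("N" = 0.8544, "S^2" = -1.9078),
      noise_sd = noise_sd
    ),
    module_spec(
      4, c("Ethanol", "Acetic acid", "Glycerol"),
      c(0.5446, 0.6202, 0.5646),
      c("S" = 1.3519, "I" = -0.2347, "N:T" = -0.2327, "S^2" = 0.3637),
      noise_sd = noise_sd
    ),
    module_spec(
      5,
      c("2-Phenylethanol", "Phenylethyl acetate", "1-butanol",
        "Amyl alcohol", "Isoamyl alcohol"),
      c(0.3658, 0.3737, 0.4725, 0.5063, 0.4969),
      c("N" = -1.0532, "T" = 0.6838, "S:I" = 0.4231),
      noise_sd = noise_sd
    )
  )
}

#' Ground-truth module labels as a named vector
#'
#' @param modules A list of [module_spec()] objects.
#' @return Named integer-ish vector mapping each response name to its module
#'   id, in member order.
#' @export
truth_labels <- function(modules) {
  unlist(lapply(modules, function(m) {
    stats::setNames(rep(m$id, length(m$members)), m$members)
  }))
}

#' Simulate multivariate responses with known modular structure
#'
#' Runs the latent generating model of [module_spec()] over a coded design:
#' each module's polynomial latent score is evaluated on the coded factor
#' levels and broadcast to its members through the loading vector, with
#' independent Gaussian noise added on the standardized scale before the
#' per-member location/scale decoration. This is the reconstruction step of
#' the analysis run in reverse, so the analysis pipeline can be validated
#' against known ground truth.
#'
#' @param design A `ccd_design`.
#' @param modules List of [module_spec()] objects with disjoint member names.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `synthetic_dataset`: a list with `design`,
#'   `responses` (runs x responses numeric matrix with run ids as rownames),
#'   `truth` (the module list), `latent` (runs x modules matrix of noiseless
#'   latent scores) and `seed`.
#' @examples
#' d <- generate_ccd(seed = 1)
#' sim <- simulate_responses(d, default_truth(), seed = 42)
#' dim(sim$responses)  # 31 x 18
#' @export
simulate_responses <- function(design, modules = default_truth(), seed = 1) {
  stopifnot(inherits(design, "ccd_design"))
  stopifnot(all(vapply(modules, inherits, TRUE, "module_spec")))
  members_all <- unlist(lapply(modules, `[[`, "members"))
  if (anyDuplicated(members_all)) {
    stop("module member names must be disjoint across modules", call. = FALSE)
  }
  coded <- design$runs
  n <- nrow(coded)
  Y <- matrix(NA_real_, n, length(members_all),
              dimnames = list(paste0("run", seq_len(n)), members_all))
  latent <- matrix(NA_real_, n, length(modules),
                   dimnames = list(rownames(Y),
                                   vapply(modules, function(m) as.character(m$id), "")))

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  for (ci in seq_along(modules)) {
    m <- modules[[ci]]
    s <- rep(0, n)
    for (t in names(m$betas)) s <- s + m$betas[[t]] * eval_term(t, coded)
    latent[, ci] <- s
    eps <- matrix(stats::rnorm(n * length(m$members), sd = m$noise_sd),
                  n, length(m$members))
    Z <- outer(s, m$loadings) + eps
    Y[, m$members] <- sweep(sweep(Z, 2, m$member_scales, `*`),
                            2, m$member_means, `+`)
  }

  structure(
    list(design = design, responses = Y, truth = modules,
         latent = latent, seed = as.integer(seed)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d runs x %d responses, %d modules, seed %d\n",
              nrow(x$responses), ncol(x$responses), length(x$truth), x$seed))
  invisible(x)
}

#' Write and read synthetic-run files
#'
#' `write_responses()` writes a runs x responses matrix as CSV with a
#' `run_id` column, row-aligned with the design CSV; `read_responses()` reads
#' it back, refusing missing entries. `write_truth_json()` serializes the
#' ground-truth modules (members, loadings, betas, noise_sd, seed) as JSON.
#'
#' @param responses Runs x responses numeric matrix.
#' @param path File path.
#' @param dataset A `synthetic_dataset` (for `write_truth_json`).
#' @return The path, invisibly, for writers; a numeric matrix for
#'   `read_responses()`.
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(run_id = seq_len(nrow(responses)), responses,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"run_id" %in% names(df)) stop("responses file lacks a run_id column",
                                     call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "run_id"), drop = FALSE])
  if (anyNA(m)) stop("responses contain missing values; a complete table is required",
                     call. = FALSE)
  rownames(m) <- paste0("run", df$run_id)
  m
}

#' @rdname write_responses
#' @export
write_truth_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  modules <- lapply(dataset$truth, function(m) {
    list(id = m$id, members = m$members, loadings = m$loadings,
         betas = as.list(m$betas), noise_sd = m$noise_sd)
  })
  jsonlite::write_json(list(seed = dataset$seed, modules = modules), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
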