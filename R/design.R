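#' Define an experimental factor with three physical levels
#'
#' A factor in a face-centered central composite design takes three coded
#' levels (-1, 0, +1) that map linearly onto three physical values
#' (low, mid, high). The linear coded/physical map `mid + coded * (high - mid)`
#' is only the inverse of encoding when `mid` is the midpoint of `low` and
#' `high`, so that condition is enforced here.
#'
#' @param name Short factor label, e.g. `"S"` for sugar.
#' @param low,mid,high Physical values at coded -1, 0 and +1. Must be strictly
#'   increasing with `mid = (low + high) / 2` (relative tolerance `1e-8`).
#' @param units Free-text units, e.g. `"g/L"`.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("T", 10, 20, 30, units = "degC")
#' @export
factor_spec <- function(name, low, mid, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vals <- c(low = low, mid = mid, high = high)
  if (!all(is.finite(vals))) {
    stop("factor '", name, "': low/mid/high must be finite numbers", call. = FALSE)
  }
  if (!(low < mid && mid < high)) {
    stop("factor '", name, "': levels must satisfy low < mid < high", call. = FALSE)
  }
  span <- high - low
  if (abs(mid - (low + high) / 2) > 1e-8 * span) {
    stop("factor '", name, "': mid must equal (low + high)/2 for linear coding",
         call. = FALSE)
  }
  structure(
    list(name = name, low = low, mid = mid, high = high, units = units),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: -1 = %g, 0 = %g, +1 = %g %s\n",
              x$name, x$low, x$mid, x$high, x$units))
  invisible(x)
}

#' The four fermentation factors of the reference study
#'
#' Sugar content `S` (150/225/300 g/L), yeast assimilable nitrogen `N`
#' (100/300/500 mg/L), fermentation temperature `T` (10/20/30 degC) and the
#' co-inoculation level `I` of the non-Saccharomyces adjunct yeast
#' (0 / 5e5 / 1e6 CFU/mL). Coded -1 on `I` means no co-inoculation but is
#' treated numerically like any other level.
#'
#' @return A named list of four [factor_spec()] objects.
#' @examples
#' fermentation_factors()
#' @export
fermentation_factors <- function() {
  list(
    S = factor_spec("S", 150, 225, 300, units = "g/L"),
    N = factor_spec("N", 100, 300, 500, units = "mg/L"),
    T = factor_spec("T", 10, 20, 30, units = "degC"),
    I = factor_spec("I", 0, 5e5, 1e6, units = "CFU/mL")
  )
}

#' Generate a face-centered central composite design
#'
#' Builds the standard single-block CCD run list for `k` factors: the
#' `2^k` full-factorial corners at coded +/-1, `2k` axial (star) points with a
#' single coordinate at +/-alpha, and `n_center` replicated all-zero center
#' points. Only the face-centered case `alpha = 1` is supported, because the
#' factor specification defines exactly three physical levels per factor.
#' The execution order is a seeded uniform permutation of the rows.
#'
#' @param factors A list of [factor_spec()] objects (default the four
#'   fermentation factors), or an integer `k >= 2`, in which case `k` generic
#'   factors coded on `[-1, 1]` are created.
#' @param n_center Number of center replicates (default 7, giving 31 runs for
#'   four factors).
#' @param alpha Star-point distance in coded units; must be 1.
#' @param seed Integer seed for the run-order randomization; `NULL` leaves the
#'   standard construction order.
#' @return An object of class `ccd_design`: a list with elements `factors`,
#'   `runs` (integer matrix of coded levels, one row per run in standard
#'   order), `run_order` (execution position of each row) and `center_mask`.
#' @examples
#' d <- generate_ccd(n_center = 7, seed = 1)
#' nrow(d$runs)  # 31
#' @export
generate_ccd <- function(factors = fermentation_factors(), n_center = 7,
                         alpha = 1, seed = NULL) {
  if (is.numeric(factors) && length(factors) == 1L) {
    k <- as.integer(factors)
    if (k < 2L) stop("a central composite design needs k >= 2 factors", call. = FALSE)
    factors <- lapply(paste0("X", seq_len(k)), factor_spec,
                      low = -1, mid = 0, high = 1)
    names(factors) <- vapply(factors, `[[`, "", "name")
  }
  stopifnot(is.list(factors), all(vapply(factors, inherits, TRUE, "factor_spec")))
  k <- length(factors)
  if (k < 2L) stop("a central composite design needs k >= 2 factors", call. = FALSE)
  if (!isTRUE(all.equal(alpha, 1))) {
    stop("only the face-centered design (alpha = 1) is supported", call. = FALSE)
  }
  if (!(is.numeric(n_center) && length(n_center) == 1L && n_center >= 1)) {
    stop("n_center must be a single integer >= 1", call. = FALSE)
  }
  n_center <- as.integer(n_center)

  fnames <- vapply(factors, `[[`, "", "name")
  names(factors) <- fnames
  factorial <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))
  axial <- matrix(0L, nrow = 2L * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -1L
    axial[2L * j, j] <- 1L
  }
  center <- matrix(0L, nrow = n_center, ncol = k)
  runs <- rbind(factorial, axial, center)
  dimnames(runs) <- list(NULL, fnames)
  storage.mode(runs) <- "integer"
  n <- nrow(runs)

  run_order <- seq_len(n)
  if (!is.null(seed)) {
    run_order <- with_preserved_rng(seed, sample.int(n))
  }

  structure(
    list(
      factors = factors,
      runs = runs,
      run_order = run_order,
      center_mask = rowSums(runs != 0L) == 0L
    ),
    class = "ccd_design"
  )
}

#' @export
print.ccd_design <- function(x, ...) {
  k <- length(x$factors)
  cat(sprintf(
    "<ccd_design> %d factors (%s), %d runs (%d factorial + %d axial + %d center)\n",
    k, paste(names(x$factors), collapse = ", "), nrow(x$runs),
    2^k, 2 * k, sum(x$center_mask)
  ))
  invisible(x)
}

#' Map coded levels to physical values and back
#'
#' `decode_level()` applies the linear map `mid + coded * (high - mid)` for one
#' factor; `encode_level()` is its inverse `(value - mid) / (high - mid)`.
#' `decode_design()` converts a whole design's coded run matrix to physical
#' units.
#'
#' @param design A `ccd_design`.
#' @param factor Factor name (must exist in the design).
#' @param coded Numeric vector of coded levels in `[-1, 1]`.
#' @param value Numeric vector of physical values.
#' @return Numeric vector (`decode_level`, `encode_level`) or a data frame of
#'   physical values with a `run_id` column (`decode_design`).
#' @examples
#' d <- generate_ccd()
#' decode_level(d, "S", 0)    # 225
#' encode_level(d, "T", 30)   # 1
#' @export
decode_level <- function(design, factor, coded) {
  f <- design$factors[[factor]]
  if (is.null(f)) stop("unknown factor: '", factor, "'", call. = FALSE)
  if (any(coded < -1 - 1e-9 | coded > 1 + 1e-9)) {
    stop("coded levels must lie in [-1, 1]", call. = FALSE)
  }
  f$mid + coded * (f$high - f$mid)
}

#' @rdname decode_level
#' @export
encode_level <- function(design, factor, value) {
  f <- design$factors[[factor]]
  if (is.null(f)) stop("unknown factor: '", factor, "'", call. = FALSE)
  (value - f$mid) / (f$high - f$mid)
}

#' @rdname decode_level
#' @export
decode_design <- function(design) {
  stopifnot(inherits(design, "ccd_design"))
  out <- as.data.frame(lapply(names(design$factors), function(nm) {
    decode_level(design, nm, design$runs[, nm])
  }))
  names(out) <- names(design$factors)
  cbind(run_id = seq_len(nrow(out)), out)
}

#' Validate the structure of a central composite design
#'
#' Checks the coded run matrix against the face-centered CCD template:
#' every entry in \{-1, 0, +1\}, the factorial/axial/center decomposition with
#' the expected counts, and duplicated non-center rows. The result is a
#' report; the caller decides what severity to attach to each finding.
#'
#' @param design A `ccd_design`, or a bare coded matrix.
#' @return An object of class `ccd_validation`: a list with the row-count
#'   decomposition (`n_factorial`, `n_axial`, `n_center`, and the expected
#'   counts), `out_of_range` row/column indices of non-\{-1,0,1\} entries,
#'   `duplicate_rows` among non-center runs, and a logical `valid`.
#' @examples
#' validate_design(generate_ccd())$valid  # TRUE
#' @export
validate_design <- function(design) {
  runs <- if (inherits(design, "ccd_design")) design$runs else as.matrix(design)
  k <- ncol(runs)
  ok_level <- runs %in% c(-1, 0, 1)
  out_of_range <- which(matrix(!ok_level, nrow(runs), k), arr.ind = TRUE)

  n_nonzero <- rowSums(runs != 0)
  center <- n_nonzero == 0
  axial <- n_nonzero == 1
  factorial <- n_nonzero == k & apply(abs(runs) == 1, 1, all)
  other <- !(center | axial | factorial)

  noncenter <- runs[!center, , drop = FALSE]
  dup <- which(duplicated(noncenter) | duplicated(noncenter, fromLast = TRUE))

  decomposition_ok <- sum(factorial) == 2^k && sum(axial) == 2 * k &&
    sum(other) == 0 && sum(center) >= 1
  structure(
    list(
      n_runs = nrow(runs),
      n_factorial = sum(factorial), expected_factorial = 2^k,
      n_axial = sum(axial), expected_axial = 2L * k,
      n_center = sum(center),
      n_unclassified = sum(other),
      out_of_range = out_of_range,
      duplicate_rows = dup,
      valid = nrow(out_of_range) == 0 && decomposition_ok && length(dup) == 0
    ),
    class = "ccd_validation"
  )
}

#' @export
print.ccd_validation <- function(x, ...) {
  cat(sprintf(
    "<ccd_validation> %s: %d runs = %d/%d factorial + %d/%d axial + %d center",
    if (x$valid) "valid" else "INVALID",
    x$n_runs, x$n_factorial, x$expected_factorial,
    x$n_axial, x$expected_axial, x$n_center
  ))
  if (x$n_unclassified > 0) cat(sprintf(" (+%d unclassified)", x$n_unclassified))
  cat("\n")
  if (nrow(x$out_of_range) > 0) {
    cat("  out-of-range entries at rows:",
        paste(unique(x$out_of_range[, 1]), collapse = ", "), "\n")
  }
  if (length(x$duplicate_rows) > 0) {
    cat("  duplicated non-center rows present\n")
  }
  invisible(x)
}

#' Read and write design tables as CSV
#'
#' The coded CSV layout has columns `run_id`, `run_order`, then one integer
#' column of coded levels per factor. `write_design()` can also emit physical
#' units via [decode_design()]. `read_design()` re-encodes a physical-units
#' CSV (such as a published design table) through a factor specification,
#' rounding the coded values to the nearest of \{-1, 0, 1\} when they are
#' within `1e-6`.
#'
#' @param design A `ccd_design`.
#' @param path File path.
#' @param units `"coded"` or `"physical"`.
#' @param factors Named list of [factor_spec()] used to (re-)encode.
#' @return `read_design()` returns a `ccd_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path, units = c("coded", "physical")) {
  units <- match.arg(units)
  stopifnot(inherits(design, "ccd_design"))
  tab <- if (units == "coded") {
    as.data.frame(design$runs)
  } else {
    decode_design(design)[, names(design$factors), drop = FALSE]
  }
  out <- cbind(run_id = seq_len(nrow(tab)), run_order = design$run_order, tab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, factors = fermentation_factors()) {
  tab <- utils::read.csv(path, check.names = FALSE)
  fnames <- vapply(factors, `[[`, "", "name")
  names(factors) <- fnames
  missing <- setdiff(fnames, names(tab))
  if (length(missing) > 0) {
    stop("design file lacks factor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  coded <- matrix(0L, nrow(tab), length(fnames), dimnames = list(NULL, fnames))
  design_stub <- list(factors = factors)
  for (nm in fnames) {
    x <- tab[[nm]]
    # accept either coded or physical columns: physical if outside [-1, 1]
    if (any(abs(x) > 1 + 1e-6)) {
      x <- encode_level(design_stub, nm, x)
    }
    snapped <- round(x)
    if (any(abs(x - snapped) > 1e-6) || any(abs(snapped) > 1)) {
      stop("column '", nm, "' does not re-encode to coded levels {-1, 0, 1}",
           call. = FALSE)
    }
    coded[, nm] <- as.integer(snapped)
  }
  run_order <- if ("run_order" %in% names(tab)) {
    as.integer(tab$run_order)
  } else {
    seq_len(nrow(coded))
  }
  structure(
    list(
      factors = factors,
      runs = coded,
      run_order = run_order,
      center_mask = rowSums(coded != 0L) == 0L
    ),
    class = "ccd_design"
  )
}

# encode_level() also accepts a bare list(factors = ...) stub, used internally
# when re-encoding files before a full ccd_design exists.

# Evaluate expr under a temporary seed, restoring the caller's RNG state so
# seeded helpers never perturb the global stream.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
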