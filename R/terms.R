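#' Candidate polynomial terms for a coded design
#'
#' Expands the coded run matrix of a design into the full second-order
#' candidate set: the `k` main effects, the `k(k-1)/2` pairwise interactions
#' (elementwise products of coded columns) and the `k` quadratics
#' (elementwise squares). Labels use `:` for interactions and `^2` for
#' quadratics, in the canonical order mains, then interactions in
#' lexicographic factor-pair order, then quadratics: for the four fermentation
#' factors this is `S, N, T, I, S:N, S:T, S:I, N:T, N:I, T:I, S^2, N^2, T^2,
#' I^2` (14 terms). In a face-centered design the quadratic columns take
#' values in \{0, 1\}.
#'
#' @param design A `ccd_design`, or a bare coded matrix with factor column
#'   names.
#' @return An object of class `term_set`: a list with `labels`, `values`
#'   (runs x terms numeric matrix, unstandardized) and `factors` (the factor
#'   names).
#' @examples
#' ts <- build_terms(generate_ccd())
#' ts$labels
#' @export
build_terms <- function(design) {
  coded <- if (inherits(design, "ccd_design")) design$runs else as.matrix(design)
  fnames <- colnames(coded)
  if (is.null(fnames)) stop("coded design matrix must have factor column names",
                            call. = FALSE)
  k <- length(fnames)
  labels <- c(
    unname(fnames),
    if (k >= 2) {
      pairs <- utils::combn(fnames, 2)
      paste(pairs[1, ], pairs[2, ], sep = ":")
    },
    paste0(fnames, "^2")
  )
  values <- matrix(NA_real_, nrow(coded), length(labels),
                   dimnames = list(NULL, labels))
  for (lab in labels) values[, lab] <- eval_term(lab, coded)
  structure(
    list(labels = labels, values = values, factors = fnames),
    class = "term_set"
  )
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set> %d candidate terms over factors %s\n",
              length(x$labels), paste(x$factors, collapse = ", ")))
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# Evaluate one term label ("S", "N:T", "S^2") on a coded run matrix.
eval_term <- function(label, coded) {
  fnames <- colnames(coded)
  if (label %in% fnames) return(coded[, label])
  if (grepl("\\^2$", label)) {
    f <- sub("\\^2$", "", label)
    if (f %in% fnames) return(coded[, f]^2)
  }
  if (grepl(":", label, fixed = TRUE)) {
    parts <- strsplit(label, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2 && all(parts %in% fnames)) {
      return(coded[, parts[1]] * coded[, parts[2]])
    }
  }
  stop("unknown term label: '", label, "' (expected a factor name, 'A:B' or 'A^2')",
       call. = FALSE)
}

# Center and scale term columns to unit sample sd; keeps the scaling so that
# coefficients are reported on the standardized predictor scale.
standardize_terms <- function(terms) {
  stopifnot(inherits(terms, "term_set"))
  sds <- apply(terms$values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant term column(s): ",
         paste(terms$labels[sds == 0], collapse = ", "),
         "; the design does not vary these terms", call. = FALSE)
  }
  means <- colMeans(terms$values)
  terms$values <- scale(terms$values, center = means, scale = sds)
  terms$scaling <- list(mean = means, sd = sds)
  terms
}
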