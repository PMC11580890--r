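#' Contact map container
#'
#' A square, symmetric matrix of log-scaled observed/expected contact values
#' over the `n_bins` output bins of a prediction, with a per-bin validity
#' mask and a number of near-diagonal bands excluded from comparisons (as in
#' the training maps of the predictors this package targets, where the first
#' two diagonals are undefined).
#'
#' @param values `n_bins x n_bins` numeric matrix; entries within
#'   `diagonal_offset` of the diagonal may be `NA`.
#' @param geometry A [predictor_geometry()].
#' @param mask Logical vector of length `n_bins`; `TRUE` marks a valid bin.
#' @param diagonal_offset Number of bands around the diagonal excluded from
#'   all comparisons (`|i - j| < diagonal_offset`).
#' @return An object of class `ContactMap`.
#' @export
contact_map <- function(values, geometry, mask = NULL, diagonal_offset = 2L) {
  n <- geometry$n_bins
  if (!is.matrix(values) || nrow(values) != n || ncol(values) != n)
    stop("values must be an ", n, " x ", n, " matrix")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("mask length must equal n_bins")
  structure(
    list(values = values, geometry = geometry, mask = mask,
         diagonal_offset = as.integer(diagonal_offset)),
    class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %d x %d bins (%d bp), %d masked bins\n",
              x$geometry$n_bins, x$geometry$n_bins, x$geometry$bin_bp,
              sum(!x$mask)))
  invisible(x)
}

# --- predictor registry ------------------------------------------------------

.predictors <- new.env(parent = emptyenv())

#' Register a contact-map predictor
#'
#' A predictor is a function `f(sequence, geometry, ...)` returning a
#' [contact_map()]. The registry is the seam where an external trained model
#' can be plugged in; the built-in `"surrogate"` predictor
#' ([surrogate_motif_predictor()]) is registered at load time.
#'
#' @param name Predictor name.
#' @param fun Predictor function.
#' @export
register_predictor <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .predictors)
  invisible(name)
}

#' Look up a registered predictor by name
#' @param name Predictor name (e.g. `"surrogate"`).
#' @return The predictor function.
#' @export
get_predictor <- function(name) {
  if (!exists(name, envir = .predictors, inherits = FALSE))
    stop("unknown predictor '", name, "'; registered: ",
         paste(ls(.predictors), collapse = ", "))
  get(name, envir = .predictors, inherits = FALSE)
}

#' Predict a contact map from sequence
#'
#' Validates the predictor contract (sequence length and alphabet) and
#' dispatches to a registered predictor. Deterministic for identical input.
#'
#' @param sequence Nucleotide string (A/C/G/T/N) of exactly
#'   `geometry$input_span_bp` characters, or a [Biostrings::DNAString].
#' @param geometry A [predictor_geometry()].
#' @param predictor Predictor name or function.
#' @param ... Passed to the predictor (e.g. `params` for the surrogate).
#' @return A [contact_map()].
#' @export
predict_contact_map <- function(sequence, geometry = predictor_geometry(),
                                predictor = "surrogate", ...) {
  if (is.character(predictor)) predictor <- get_predictor(predictor)
  sequence <- as.character(sequence)
  if (nchar(sequence) != geometry$input_span_bp)
    stop("sequence length mismatch: expected ", geometry$input_span_bp,
         ", got ", nchar(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  predictor(sequence, geometry, ...)
}

# --- surrogate predictor -----------------------------------------------------

#' Frozen parameters of the surrogate predictor
#'
#' The surrogate emulates the qualitative structure of real contact maps: a
#' distance-decay baseline with block insulation at occurrences of a fixed
#' boundary motif (a CTCF-like 19-mer). Parameters are frozen so downstream
#' expected values are stable.
#'
#' @param motif Boundary motif (19-mer by default); hits on both strands
#'   insulate.
#' @param sigma Insulation strength subtracted per intervening motif.
#' @param alpha Distance-decay exponent of the log baseline.
#' @return Named list of parameters.
#' @export
surrogate_params <- function(motif = "CCACCAGGGGGCGCTAGTC", sigma = 0.6,
                             alpha = 1.0) {
  list(motif = toupper(motif), sigma = sigma, alpha = alpha)
}

# distance-decay baseline matrices are geometry-dependent; cache per n_bins
.surrogate_cache <- new.env(parent = emptyenv())

surrogate_baseline <- function(n_bins, alpha, diagonal_offset) {
  key <- paste(n_bins, alpha, diagonal_offset, sep = "_")
  if (!is.null(.surrogate_cache[[key]])) return(.surrogate_cache[[key]])
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  base <- -alpha * log(d + 1)
  base[d < diagonal_offset] <- NA_real_
  .surrogate_cache[[key]] <- base
  base
}

#' Deterministic motif-based surrogate contact-map predictor
#'
#' Produces `value(i, j) = -alpha * log(|i - j| + 1) - sigma * m(i, j)` where
#' `m(i, j)` counts boundary-motif occurrences (either strand) whose midpoint
#' lies strictly between the centers of bins `i` and `j` of the cropped
#' output region. This yields TAD-like blocks separated at motif hits, decays
#' with genomic distance, is exactly symmetric, and is equivariant under
#' reverse complement (the map of the reverse-complemented sequence is the
#' original map flipped on both axes) -- the property that makes
#' reverse-complement augmentation averaging meaningful.
#'
#' @inheritParams predict_contact_map
#' @param params See [surrogate_params()].
#' @param diagonal_offset Near-diagonal bands set to `NA`.
#' @return A [contact_map()].
#' @export
surrogate_motif_predictor <- function(sequence, geometry = predictor_geometry(),
                                      params = surrogate_params(),
                                      diagonal_offset = 2L) {
  seq <- Biostrings::DNAString(sequence)
  motif <- Biostrings::DNAString(params$motif)
  hits_fwd <- Biostrings::start(Biostrings::matchPattern(motif, seq))
  hits_rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(motif), seq))
  starts <- c(hits_fwd, hits_rev)                  # 1-based within the input
  mlen <- length(motif)
  n <- geometry$n_bins
  base <- surrogate_baseline(n, params$alpha, diagonal_offset)
  if (length(starts) > 0L) {
    # motif midpoint in bin units of the cropped output region (0-based bins)
    centers0 <- (starts - 1) + mlen / 2             # 0-based bp midpoint
    t <- (centers0 - crop_bp(geometry)) / geometry$bin_bp
    # s[k] = number of motif midpoints left of the center of 0-based bin k-1
    k_half <- seq_len(n) - 0.5                      # centers of bins 0..n-1
    s <- vapply(k_half, function(h) sum(t < h), numeric(1))
    values <- base - params$sigma * abs(outer(s, s, "-"))
  } else {
    values <- base
  }
  contact_map(values, geometry, diagonal_offset = diagonal_offset)
}
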