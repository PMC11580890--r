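#' @importFrom GenomicRanges GRanges start end width
NULL

# structured error conditions so exclusion filtering can classify failures
off_contig_error <- function(msg)
  stop(errorCondition(msg, class = c("svdisrupt_off_contig", "error",
                                     "condition")))
too_long_error <- function(msg)
  stop(errorCondition(msg, class = c("svdisrupt_too_long", "error",
                                     "condition")))

sv_midpoint0 <- function(variant)
  ((start(variant) - 1L) + end(variant)) %/% 2L

#' Build a prediction window around a variant
#'
#' The default window (`shift_bp = 0`) is centered on the variant midpoint
#' and spans exactly `geometry$input_span_bp`. Positive shifts move the
#' window downstream. Windows that would protrude past a contig end are
#' clamped inside it with the clamp amount recorded (clamped windows are
#' flagged downstream and excluded from augmentation averaging rather than
#' silently biased).
#'
#' @param variant Length-1 `GRanges` SV record.
#' @param geometry A [predictor_geometry()].
#' @param shift_bp Signed window shift in bp; `|shift_bp|` must be below half
#'   the input span.
#' @param chrom_length Length of the variant's chromosome in bp.
#' @return An object of class `PredictionWindow`: `chrom`, `start`, `end`
#'   (1-based closed), `shift_bp`, `clamp_bp` (signed bp the window was moved
#'   to stay on the contig; 0 if untouched) and the `variant`.
#' @export
build_prediction_window <- function(variant, geometry, shift_bp = 0L,
                                    chrom_length) {
  span <- geometry$input_span_bp
  if (abs(shift_bp) >= span / 2)
    stop("|shift_bp| must be < input_span_bp / 2")
  if (chrom_length < span)
    off_contig_error(sprintf(
      "chromosome of %s (%d bp) shorter than input span %d bp",
      as.character(seqnames(variant)), chrom_length, span))
  mid0 <- sv_midpoint0(variant)
  w0 <- mid0 - span %/% 2L + as.integer(shift_bp)
  clamp <- 0L
  if (w0 < 0L) { clamp <- -w0; w0 <- 0L }
  if (w0 + span > chrom_length) {
    clamp <- chrom_length - (w0 + span)
    w0 <- chrom_length - span
  }
  structure(list(chrom = as.character(seqnames(variant)),
                 start = w0 + 1L, end = w0 + span,
                 shift_bp = as.integer(shift_bp), clamp_bp = as.integer(clamp),
                 variant = variant),
            class = "PredictionWindow")
}

#' @export
print.PredictionWindow <- function(x, ...) {
  cat(sprintf("PredictionWindow %s:%d-%d (shift %+d, clamp %+d) for %s\n",
              x$chrom, x$start, x$end, x$shift_bp, x$clamp_bp,
              x$variant$id))
  invisible(x)
}

new_sequence_pair <- function(ref_seq, alt_seq, variant_offset, ref_len,
                              alt_len, pad_left, pad_right, window,
                              augmentation = "identity") {
  structure(list(ref_seq = ref_seq, alt_seq = alt_seq,
                 variant_offset = as.integer(variant_offset),
                 ref_len = as.integer(ref_len), alt_len = as.integer(alt_len),
                 length_delta = as.integer(alt_len - ref_len),
                 pad_left = as.integer(pad_left),
                 pad_right = as.integer(pad_right),
                 window = window, augmentation = augmentation),
            class = "SequencePair")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Construct reference/alternate allele sequences for a window
#'
#' All SV types reduce to a span substitution on the reference window:
#' deletions substitute the empty string, duplications substitute two copies
#' of the duplicated span (an extra copy inserted immediately 5' of the
#' original), inversions substitute the reverse complement (no length
#' change), and complex variants substitute the user-supplied alternate
#' sequence. To keep both alleles exactly `input_span_bp` long, the length
#' difference is compensated at the two window edges, split evenly: for a
#' net deletion the flanks are extended into the chromosome; for a net
#' insertion the flanks are trimmed (shifted onto the shorter flank when the
#' even split does not fit).
#'
#' @param window A [build_prediction_window()] result.
#' @param genome `DNAStringSet` genome.
#' @return A `SequencePair` with `ref_seq`, `alt_seq` (both
#'   `input_span_bp` long), `variant_offset` (0-based position of the
#'   variant start within `ref_seq`), `ref_len`/`alt_len`/`length_delta`,
#'   and the signed flank paddings used.
#' @export
construct_allele_sequences <- function(window, genome) {
  v <- window$variant
  geometry_span <- window$end - window$start + 1L
  chrom <- window$chrom
  chrom_len <- length(genome[[chrom]])
  w0 <- window$start - 1L                      # 0-based window start
  w1 <- window$end                             # 0-based half-open window end
  vs0 <- start(v) - 1L; ve0 <- end(v)
  if (vs0 < w0 || ve0 > w1)
    too_long_error("variant does not fit inside the prediction window")
  svtype <- v$svtype
  if (!svtype %in% SV_TYPES)
    stop("cannot construct alleles for svtype ", svtype)
  svlen <- ve0 - vs0
  if (svlen > (2 / 3) * geometry_span)
    too_long_error(sprintf("variant length %d exceeds 2/3 of input span",
                           svlen))
  ref_seq <- get_sequence(genome, chrom, w0 + 1L, w1)
  variant_offset <- vs0 - w0
  span_seq <- substr(ref_seq, variant_offset + 1L, variant_offset + svlen)
  repl <- switch(svtype,
    DEL = "",
    INV = revcomp_chr(span_seq),
    DUP = paste0(span_seq, span_seq),
    CPX = toupper(v$alt_sequence))
  alt_len <- nchar(repl)
  dl <- alt_len - svlen
  left_flank <- substr(ref_seq, 1L, variant_offset)
  right_flank <- substr(ref_seq, variant_offset + svlen + 1L,
                        geometry_span)
  if (dl == 0L) {
    alt_seq <- paste0(left_flank, repl, right_flank)
    pad_left <- 0L; pad_right <- 0L
  } else if (dl < 0L) {
    # net deletion: extend both flanks into the chromosome, split evenly
    pad_left <- (-dl) %/% 2L
    pad_right <- (-dl) - pad_left
    if (w0 - pad_left < 0L || w1 + pad_right > chrom_len)
      off_contig_error(sprintf(
        "allele construction for %s needs sequence beyond %s ends", v$id,
        chrom))
    alt_seq <- paste0(get_sequence(genome, chrom, w0 - pad_left + 1L, vs0),
                      repl,
                      get_sequence(genome, chrom, ve0 + 1L, w1 + pad_right))
    pad_right <- pad_right
  } else {
    # net insertion: trim the window edges, split evenly (shift the split
    # when one flank is too short)
    pad_left <- dl %/% 2L
    pad_right <- dl - pad_left
    lf <- nchar(left_flank); rf <- nchar(right_flank)
    if (lf + rf < dl)
      too_long_error(sprintf(
        "alternate allele of %s too long to fit the window", v$id))
    if (pad_left > lf) { pad_left <- lf; pad_right <- dl - pad_left }
    if (pad_right > rf) { pad_right <- rf; pad_left <- dl - pad_right }
    alt_seq <- paste0(substr(left_flank, pad_left + 1L, lf), repl,
                      substr(right_flank, 1L, rf - pad_right))
    pad_left <- -pad_left; pad_right <- -pad_right
  }
  if (nchar(alt_seq) != geometry_span)
    stop("internal error: alt length ", nchar(alt_seq), " != ", geometry_span)
  new_sequence_pair(ref_seq, alt_seq, variant_offset, svlen, alt_len,
                    pad_left, pad_right, window)
}

#' Generate the four augmentation sequence pairs
#'
#' Returns the identity pair, pairs rebuilt from the window shifted by +1
#' and -1 bp, and the reverse complement of both sequences. Averaging scores
#' over these four is the package's augmentation scheme. At a contig edge
#' where a 1 bp shift is impossible, that augmentation is replaced by the
#' identity pair and flagged via its `augmentation` label.
#'
#' @param pair Identity `SequencePair`.
#' @param window The window `pair` was built from.
#' @param genome `DNAStringSet` genome.
#' @return List of 4 `SequencePair`s labelled `identity`, `shift_plus1`,
#'   `shift_minus1`, `revcomp` (fallbacks labelled
#'   `<label>_unavailable_identity`).
#' @export
make_augmentations <- function(pair, window, genome) {
  chrom_len <- length(genome[[window$chrom]])
  shifted <- function(delta, label) {
    w0 <- window$start - 1L + delta
    if (w0 < 0L || w0 + (window$end - window$start + 1L) > chrom_len) {
      p <- pair; p$augmentation <- paste0(label, "_unavailable_identity")
      return(p)
    }
    wnew <- window
    wnew$start <- window$start + delta
    wnew$end <- window$end + delta
    wnew$shift_bp <- window$shift_bp + delta
    p <- tryCatch(construct_allele_sequences(wnew, genome),
                  error = function(e) {
                    p <- pair
                    p$augmentation <- paste0(label, "_unavailable_identity")
                    p
                  })
    if (inherits(p, "SequencePair") &&
        !grepl("unavailable", p$augmentation)) p$augmentation <- label
    p
  }
  rc <- pair
  L <- nchar(pair$ref_seq)
  rc$ref_seq <- revcomp_chr(pair$ref_seq)
  rc$alt_seq <- revcomp_chr(pair$alt_seq)
  rc$variant_offset <- L - (pair$variant_offset + pair$ref_len)
  rc$pad_left <- pair$pad_right
  rc$pad_right <- pair$pad_left
  rc$augmentation <- "revcomp"
  list(pair,
       shifted(+1L, "shift_plus1"),
       shifted(-1L, "shift_minus1"),
       rc)
}

#' Apply the variant exclusion filters
#'
#' Classifies each variant as scorable or excluded, with exactly one
#' exclusion code per excluded variant (the first failing check wins):
#' `UNKNOWN_ALT` (unsupported SV type -- insertion classes and
#' translocations, whose alternate sequence is unknown), `TOO_LONG_ABS`
#' (longer than `max_abs_len`, default 700 kb), `TOO_LONG_REL` (longer than
#' `max_rel_len` of the input span, default 2/3, or otherwise unable to fit
#' the window), `OFF_CONTIG` (window or allele construction runs off the
#' chromosome), `N_CONTENT` (reference window has more than `max_n_frac`
#' unknown sequence, default 5%).
#'
#' @param variants `GRanges` of SV records.
#' @param genome `DNAStringSet` genome.
#' @param geometry A [predictor_geometry()].
#' @param max_abs_len,max_rel_len,max_n_frac Filter thresholds.
#' @param min_len Minimum variant length (default 1 bp, i.e. no lower
#'   filter); shorter variants get code `TOO_SHORT`.
#' @return List with `kept` (`GRanges`) and `excluded` (data.frame
#'   `id`, `code`, `detail`). Every input variant appears in exactly one.
#' @export
apply_exclusion_filters <- function(variants, genome, geometry,
                                    max_abs_len = 700000L,
                                    max_rel_len = 2 / 3,
                                    max_n_frac = 0.05,
                                    min_len = 1L) {
  codes <- character(length(variants))
  details <- character(length(variants))
  for (i in seq_along(variants)) {
    v <- variants[i]
    res <- exclusion_code_one(v, genome, geometry, max_abs_len, max_rel_len,
                              max_n_frac, min_len)
    codes[i] <- res$code
    details[i] <- res$detail
  }
  keep <- codes == ""
  list(kept = variants[keep],
       excluded = data.frame(id = variants$id[!keep], code = codes[!keep],
                             detail = details[!keep],
                             stringsAsFactors = FALSE))
}

exclusion_code_one <- function(v, genome, geometry, max_abs_len, max_rel_len,
                               max_n_frac, min_len) {
  len <- width(v)
  if (v$svtype == "UNSUPPORTED")
    return(list(code = "UNKNOWN_ALT",
                detail = "alternate allele sequence not known for this SV type"))
  if (len > max_abs_len)
    return(list(code = "TOO_LONG_ABS",
                detail = sprintf("length %d > %d bp", len, max_abs_len)))
  if (len > max_rel_len * geometry$input_span_bp)
    return(list(code = "TOO_LONG_REL",
                detail = sprintf("length %d > %.3g of input span", len,
                                 max_rel_len)))
  chrom <- as.character(seqnames(v))
  if (!chrom %in% names(genome))
    return(list(code = "OFF_CONTIG",
                detail = paste("chromosome not in genome:", chrom)))
  built <- tryCatch({
    w <- build_prediction_window(v, geometry, 0L,
                                 length(genome[[chrom]]))
    construct_allele_sequences(w, genome)
  },
  svdisrupt_off_contig = function(e) list(code = "OFF_CONTIG",
                                          detail = conditionMessage(e)),
  svdisrupt_too_long = function(e) list(code = "TOO_LONG_REL",
                                        detail = conditionMessage(e)))
  if (!inherits(built, "SequencePair")) return(built)
  n_frac <- n_fraction(built$ref_seq)
  if (n_frac > max_n_frac)
    return(list(code = "N_CONTENT",
                detail = sprintf("N fraction %.3f > %.3f", n_frac,
                                 max_n_frac)))
  if (len < min_len)
    return(list(code = "TOO_SHORT",
                detail = sprintf("length %d < %d bp", len, min_len)))
  list(code = "", detail = "")
}

n_fraction <- function(seq) {
  L <- nchar(seq)
  if (L == 0L) return(0)
  lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE))) / L
}
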