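#' Predictor map geometry
#'
#' Describes the fixed geometry every sequence-to-contact-map predictor in
#' this package adheres to: an input sequence of `input_span_bp` is mapped to
#' a square contact map of `n_bins` bins of `bin_bp` each, after cropping
#' `crop_bins_per_side` bins from each side of the input. The defaults
#' correspond to the published convolutional predictor this package was
#' designed around: 448 bins x 2,048 bp = 917,504 bp of output from a
#' 1,048,576 bp input.
#'
#' @param input_span_bp Length of the input sequence in bp.
#' @param bin_bp Bin width in bp.
#' @param n_bins Number of output bins per map side.
#' @param crop_bins_per_side Bins cropped from each side of the input when
#'   producing the output map.
#' @return An object of class `PredictorGeometry` (a named list with the four
#'   fields plus the derived `output_span_bp`).
#' @examples
#' geom <- predictor_geometry()
#' geom$output_span_bp  # 917504
#' @export
predictor_geometry <- function(input_span_bp = 1048576L, bin_bp = 2048L,
                               n_bins = 448L, crop_bins_per_side = 32L) {
  input_span_bp <- as.integer(input_span_bp)
  bin_bp <- as.integer(bin_bp)
  n_bins <- as.integer(n_bins)
  crop_bins_per_side <- as.integer(crop_bins_per_side)
  if (bin_bp <= 0L || n_bins <= 0L || crop_bins_per_side < 0L)
    stop("geometry fields must be positive (crop may be zero)")
  if ((n_bins + 2L * crop_bins_per_side) * bin_bp != input_span_bp)
    stop("inconsistent geometry: (n_bins + 2*crop_bins_per_side) * bin_bp = ",
         (n_bins + 2L * crop_bins_per_side) * bin_bp,
         " but input_span_bp = ", input_span_bp)
  structure(
    list(input_span_bp = input_span_bp, bin_bp = bin_bp, n_bins = n_bins,
         crop_bins_per_side = crop_bins_per_side,
         output_span_bp = n_bins * bin_bp),
    class = "PredictorGeometry")
}

#' @export
print.PredictorGeometry <- function(x, ...) {
  cat(sprintf(
    "PredictorGeometry: input %d bp -> %d x %d bp bins (%d bp output, crop %d bins/side)\n",
    x$input_span_bp, x$n_bins, x$bin_bp, x$output_span_bp,
    x$crop_bins_per_side))
  invisible(x)
}

# bp offset of the output (cropped) region start relative to the input start
crop_bp <- function(geometry) geometry$crop_bins_per_side * geometry$bin_bp
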