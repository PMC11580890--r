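#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name (the first
#'   whitespace-delimited token of each FASTA header).
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# 1-based closed slice of a chromosome; errors past contig ends
get_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (start < 1L || end > length(genome[[chrom]]))
    stop("requested ", chrom, ":", start, "-", end,
         " exceeds contig length ", length(genome[[chrom]]))
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Read a gene expression table
#'
#' @param path TSV with columns `gene_id` and `tpm` (TPM >= 0).
#' @return data.frame with `gene_id`, `tpm`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tpm") %in% names(df)))
    stop("expression table needs columns gene_id, tpm: ", path)
  df$tpm <- as.numeric(df$tpm)
  if (anyNA(df$tpm) || any(df$tpm < 0))
    stop("tpm values must be non-negative numbers: ", path)
  df[, c("gene_id", "tpm")]
}

#' Read the annotation bundle used for ROI construction and prioritization
#'
#' Loads BED interval sets (via `rtracklayer`) and the expression table, and
#' derives a transcription start site (TSS) set from the gene BED: the TSS is
#' the first base of a `+`-strand gene and the last base of a `-`-strand
#' gene.
#'
#' @param bed_paths Named list/vector of BED file paths. Required keys:
#'   `ctcf_peaks`, `h3k27ac`, `h3k4me1`, `h3k27me3`, `asd_gene_exons`,
#'   `genes` (BED6 with gene id in the name column and strand).
#' @param expression_path Expression TSV (`gene_id`, `tpm`).
#' @return A list with one `GRanges` per peak key, `genes`, `gene_tss`
#'   (1 bp `GRanges` named by gene), and `expression` (data.frame).
#' @export
read_annotation_inputs <- function(bed_paths, expression_path) {
  required <- c("ctcf_peaks", "h3k27ac", "h3k4me1", "h3k27me3",
                "asd_gene_exons", "genes")
  missing <- setdiff(required, names(bed_paths))
  if (length(missing) > 0L)
    stop("missing required annotation key(s): ",
         paste(missing, collapse = ", "))
  read_bed <- function(p) {
    if (file.size(p) == 0L) return(GenomicRanges::GRanges())
    rtracklayer::import(p, format = "BED")
  }
  out <- lapply(bed_paths[required], read_bed)
  genes <- out$genes
  if (length(genes) > 0L && is.null(genes$name))
    stop("gene BED must carry gene ids in the name column")
  out$gene_tss <- gene_tss(genes)
  out$expression <- read_expression_table(expression_path)
  out
}

#' Derive TSS positions from a stranded gene set
#'
#' @param genes `GRanges` with strand and `name` metadata.
#' @return 1 bp `GRanges`, one per gene, named by gene id.
#' @export
gene_tss <- function(genes) {
  if (length(genes) == 0L) return(GenomicRanges::GRanges())
  tss <- GenomicRanges::resize(genes, width = 1L, fix = "start")
  names(tss) <- genes$name
  tss
}

#' Read a pre-binned contact matrix from tab-delimited text
#'
#' The format is a one-line header `chrom start end bin_bp` (0-based
#' half-open region) followed by either a dense square matrix (one row of
#' whitespace-separated values per bin) or COO triplets `i j value` (0-based
#' bin indices; symmetrized on read). Values are taken as already log-scaled
#' and balanced; no normalization is performed here.
#'
#' @param path File path.
#' @return A list of class `DenseContactMatrix`: `region` (`GRanges`),
#'   `bin_bp`, `values` (square symmetric matrix), `mask` (per-bin validity:
#'   bins with any finite value).
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) != 4L)
    stop("contact matrix header must be 'chrom start end bin_bp': ", path)
  start0 <- as.integer(hdr[2]); end0 <- as.integer(hdr[3])
  bin_bp <- as.integer(hdr[4])
  n <- as.integer(ceiling((end0 - start0) / bin_bp))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "[ \t]+")
  ncols <- lengths(fields)
  dense <- length(body) == n && all(ncols == n)
  if (!dense) {
    if (!all(ncols == 3L))
      stop("contact matrix body is neither a dense ", n, "-column matrix ",
           "nor COO triplets: ", path)
    # COO triplets
    i <- as.integer(vapply(fields, `[`, "", 1)) + 1L
    j <- as.integer(vapply(fields, `[`, "", 2)) + 1L
    v <- as.numeric(vapply(fields, `[`, "", 3))
    values <- matrix(NA_real_, n, n)
    values[cbind(i, j)] <- v
    values[cbind(j, i)] <- v
  } else {
    if (length(body) != n)
      stop("dense matrix has ", length(body), " rows, expected ", n)
    values <- do.call(rbind, lapply(fields, as.numeric))
  }
  region <- GenomicRanges::GRanges(hdr[1], IRanges::IRanges(start0 + 1L, end0))
  mask <- apply(values, 1, function(r) any(is.finite(r)))
  structure(list(region = region, bin_bp = bin_bp, values = values,
                 mask = mask),
            class = "DenseContactMatrix")
}

#' Write a contact matrix in the dense tab-delimited text format
#'
#' @param mat A `DenseContactMatrix` (see [read_contact_matrix()]) or a list
#'   with `region`, `bin_bp`, `values`.
#' @param path Output path.
#' @export
write_contact_matrix <- function(mat, path) {
  hdr <- sprintf("%s %d %d %d", as.character(seqnames(mat$region)),
                 start(mat$region) - 1L, end(mat$region), mat$bin_bp)
  rows <- apply(mat$values, 1, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
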