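#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "CPX")
UNSUPPORTED_SVTYPES <- c("ALU", "LINE1", "SVA", "INS", "CTX")
COHORTS <- c("proband", "sibling")

new_sv_records <- function(id, chrom, start, end, svtype, subject_id, cohort,
                           alt_sequence = NA_character_) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  mcols(gr)$id <- as.character(id)
  mcols(gr)$svtype <- as.character(svtype)
  mcols(gr)$subject_id <- as.character(subject_id)
  mcols(gr)$cohort <- as.character(cohort)
  mcols(gr)$alt_sequence <- as.character(alt_sequence)
  validate_sv_records(gr)
}

validate_sv_records <- function(gr) {
  m <- mcols(gr)
  bad <- !(m$svtype %in% c(SV_TYPES, "UNSUPPORTED"))
  if (any(bad))
    stop("unknown svtype(s): ", paste(unique(m$svtype[bad]), collapse = ", "))
  bad <- !(m$cohort %in% COHORTS)
  if (any(bad))
    stop("unknown cohort label(s): ",
         paste(unique(m$cohort[bad]), collapse = ", "),
         " (expected proband/sibling)")
  cpx_no_alt <- m$svtype == "CPX" & (is.na(m$alt_sequence) | m$alt_sequence == "")
  if (any(cpx_no_alt))
    stop("CPX record(s) without alt_sequence: ",
         paste(m$id[cpx_no_alt], collapse = ", "))
  if (any(IRanges::width(gr) < 1L))
    stop("SV records must have positive length")
  gr
}

#' Read structural variant calls
#'
#' Reads SVs from either a minimal symbolic-allele VCF (INFO fields `SVTYPE`
#' and `END` or `SVLEN`) or a tab-delimited table with header
#' `chrom,start,end,svtype,subject,cohort[,alt_sequence]` (0-based half-open
#' coordinates on disk). Insertion-like and translocation SV types (ALU,
#' LINE1, SVA, INS, CTX), whose alternate allele sequence is unknown, are
#' retained but flagged `UNSUPPORTED` so exclusion accounting can report
#' them. Coordinates are converted to the in-memory 1-based `GRanges`
#' convention; a VCF `POS..END` span of 1001..2000 is a 1,000 bp variant.
#'
#' @param path File path.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return A `GRanges` with metadata columns `id`, `svtype`, `subject_id`,
#'   `cohort`, `alt_sequence`.
#' @export
read_sv_records <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") read_sv_tsv(path) else read_sv_vcf(path)
}

read_sv_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("chrom", "start", "end", "svtype", "subject", "cohort")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("SV TSV missing column(s): ", paste(missing, collapse = ", "))
  start0 <- suppressWarnings(as.integer(df$start))
  end0 <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0)
  if (length(bad) > 0L)
    stop("malformed SV row at line ", bad[1] + 1L, " of ", path)
  svtype <- toupper(df$svtype)
  svtype[svtype %in% UNSUPPORTED_SVTYPES] <- "UNSUPPORTED"
  alt <- if ("alt_sequence" %in% names(df)) {
    a <- toupper(df$alt_sequence); a[a == ""] <- NA_character_; a
  } else rep(NA_character_, nrow(df))
  id <- if ("id" %in% names(df)) df$id else sprintf("sv%04d", seq_len(nrow(df)))
  new_sv_records(id, df$chrom, start0 + 1L, end0, svtype, df$subject,
                 df$cohort, alt)
}

read_sv_vcf <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0L)
    return(new_sv_records(character(), character(), integer(), integer(),
                          character(), character(), character()))
  parse_info <- function(info) {
    kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
    names(vals) <- vapply(kv, `[`, "", 1)
    vals
  }
  info_get <- function(info, key, default = NA_character_) {
    if (key %in% names(info)) info[[key]] else default
  }
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed VCF row at line ", i, " of ", path,
           ": expected >= 8 fields")
    info <- parse_info(f[8])
    svtype <- toupper(info_get(info, "SVTYPE", ""))
    if (svtype == "")
      stop("malformed VCF row at line ", i, " of ", path, ": missing SVTYPE")
    pos <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(info_get(info, "END")))
    svlen <- suppressWarnings(as.integer(info_get(info, "SVLEN")))
    if (is.na(end) && !is.na(svlen)) end <- pos + abs(svlen) - 1L
    if (is.na(pos) || is.na(end) || end < pos)
      stop("malformed VCF row at line ", i, " of ", path,
           ": need valid POS and END (or SVLEN)")
    subject <- info_get(info, "SUBJECT", "unknown")
    cohort <- info_get(info, "COHORT", "proband")
    altseq <- info_get(info, "ALTSEQ")
    list(id = if (f[3] == ".") sprintf("sv_line%d", i) else f[3],
         chrom = f[1], pos = pos, end = end, svtype = svtype,
         subject = subject, cohort = cohort, altseq = altseq)
  })
  svtype <- vapply(rows, `[[`, "", "svtype")
  svtype[svtype %in% UNSUPPORTED_SVTYPES] <- "UNSUPPORTED"
  new_sv_records(vapply(rows, `[[`, "", "id"),
                 vapply(rows, `[[`, "", "chrom"),
                 vapply(rows, function(r) r$pos, integer(1)),
                 vapply(rows, function(r) r$end, integer(1)),
                 svtype,
                 vapply(rows, `[[`, "", "subject"),
                 vapply(rows, `[[`, "", "cohort"),
                 vapply(rows, function(r) as.character(r$altseq), ""))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write structural variant records
#'
#' Writes SV records in either the TSV dialect (0-based half-open on disk) or
#' the minimal symbolic-allele VCF dialect read by [read_sv_records()].
#' Writing then re-reading yields identical records.
#'
#' @param sv `GRanges` of SV records.
#' @param path Output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @export
write_sv_records <- function(sv, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  m <- mcols(sv)
  if (dialect == "tsv") {
    df <- data.frame(chrom = as.character(seqnames(sv)),
                     start = start(sv) - 1L, end = end(sv),
                     svtype = m$svtype, subject = m$subject_id,
                     cohort = m$cohort, id = m$id,
                     alt_sequence = ifelse(is.na(m$alt_sequence), "",
                                           m$alt_sequence))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
             "##INFO=<ID=SUBJECT,Number=1,Type=String,Description=\"Subject id\">",
             "##INFO=<ID=COHORT,Number=1,Type=String,Description=\"Cohort\">",
             "##INFO=<ID=ALTSEQ,Number=1,Type=String,Description=\"Alternate allele sequence\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- sprintf("SVTYPE=%s;END=%d;SUBJECT=%s;COHORT=%s%s",
                    m$svtype, end(sv), m$subject_id, m$cohort,
                    ifelse(is.na(m$alt_sequence), "",
                           paste0(";ALTSEQ=", m$alt_sequence)))
    body <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\t.\t%s",
                    as.character(seqnames(sv)), start(sv), m$id,
                    ifelse(m$svtype == "UNSUPPORTED", "INS", m$svtype), info)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
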