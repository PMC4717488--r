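#' Load aligned ribosome footprints
#'
#' Consumes the product of upstream read mapping: either BAM/SAM or a
#' BED-like tab-separated table. Every record becomes one aligned read with
#' its biological 5' end resolved: on the plus strand the lowest genomic
#' coordinate of the alignment, on the minus strand the highest.
#'
#' For BAM/SAM input, mismatch counts are taken from the `NM` tag (a hard
#' error if absent) and uniqueness follows the convention "mapping quality
#' >= `min_mapq` and not flagged secondary". The BED-like dialect must
#' carry explicit columns: chrom, start0 (0-based), end0, strand,
#' mismatches, unique (0/1 or TRUE/FALSE), and optionally read_id.
#'
#' @param path Alignment file.
#' @param format "auto" (by extension), "bam", "sam" or "bed".
#' @param min_mapq Mapping-quality floor of the uniqueness convention
#'   (BAM/SAM only).
#' @return data.frame with columns read_id, chrom, strand, five_prime_pos
#'   (1-based), length, mismatches, is_unique.
#' @export
load_alignments <- function(path, format = c("auto", "bam", "sam", "bed"),
                            min_mapq = 10L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bam = "bam", sam = "sam",
      bed = "bed", tsv = "bed", txt = "bed",
      stop("cannot guess alignment format from extension '", ext,
           "'; pass format=")
    )
  }
  if (format == "bed") {
    return(load_alignments_bed(path))
  }
  bam_path <- path
  if (format == "sam") {
    bam_path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                 indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "mapq"),
    tag = "NM"
  )
  b <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  n <- length(b$pos)
  if (n == 0L) {
    return(empty_reads())
  }
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  if (anyNA(nm)) {
    bad <- b$qname[which(is.na(nm))[1]]
    stop("missing mismatch (NM) information, e.g. record '", bad, "'")
  }
  strand <- as.character(b$strand)
  if (anyNA(b$pos) || any(!strand %in% c("+", "-"))) {
    stop("unmapped or unstranded records present; filter them upstream")
  }
  secondary <- bitwAnd(b$flag, 256L) != 0L
  data.frame(
    read_id = b$qname,
    chrom = as.character(b$rname),
    strand = strand,
    five_prime_pos = ifelse(strand == "+", b$pos, b$pos + b$qwidth - 1L),
    length = b$qwidth,
    mismatches = as.integer(nm),
    is_unique = !secondary & !is.na(b$mapq) & b$mapq >= min_mapq,
    stringsAsFactors = FALSE
  )
}

empty_reads <- function() {
  data.frame(
    read_id = character(0), chrom = character(0), strand = character(0),
    five_prime_pos = integer(0), length = integer(0),
    mismatches = integer(0), is_unique = logical(0),
    stringsAsFactors = FALSE
  )
}

load_alignments_bed <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1))
  need <- c("chrom", "start0", "end0", "strand", "mismatches", "unique")
  if (!all(need %in% names(dt))) {
    # also accept headerless six/seven-column tables
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6L) {
      stop("BED-like table needs >= 6 columns: ",
           paste(need, collapse = ", "))
    }
    names(dt)[1:6] <- need
    if (ncol(dt) >= 7L) names(dt)[7] <- "read_id"
  }
  if (nrow(dt) == 0L) return(empty_reads())
  if (anyNA(dt$mismatches)) {
    stop("missing mismatch information in BED-like record(s): row ",
         which(is.na(dt$mismatches))[1])
  }
  if (anyNA(dt$unique)) {
    stop("missing uniqueness information in BED-like record(s): row ",
         which(is.na(dt$unique))[1])
  }
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(dt$end0 <= dt$start0)) stop("zero- or negative-length alignment")
  data.frame(
    read_id = if ("read_id" %in% names(dt)) as.character(dt$read_id) else
      sprintf("r%07d", seq_len(nrow(dt))),
    chrom = as.character(dt$chrom),
    strand = dt$strand,
    five_prime_pos = as.integer(ifelse(dt$strand == "+",
                                       dt$start0 + 1L, dt$end0)),
    length = as.integer(dt$end0 - dt$start0),
    mismatches = as.integer(dt$mismatches),
    is_unique = as.logical(dt$unique),
    stringsAsFactors = FALSE
  )
}

#' Write aligned reads to disk
#'
#' Writes reads (e.g. from [simulate_footprints()]) either as the BED-like
#' tab-separated dialect or as SAM, both round-trippable through
#' [load_alignments()]. In SAM output uniqueness is encoded in the mapping
#' quality (42 for unique, 3 otherwise) and mismatches in the `NM` tag.
#'
#' @param reads data.frame as returned by [load_alignments()] /
#'   [simulate_footprints()].
#' @param path Output path.
#' @param format "bed" or "sam".
#' @param genome `DNAStringSet`; required for the SAM header.
#' @param truth Optional truth table to write as TSV next to `path`
#'   (suffix `.truth.tsv`).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, format = c("bed", "sam"),
                             genome = NULL, truth = NULL) {
  format <- match.arg(format)
  start0 <- ifelse(reads$strand == "+",
                   reads$five_prime_pos - 1L,
                   reads$five_prime_pos - reads$length)
  end0 <- start0 + reads$length
  if (format == "bed") {
    dt <- data.table::data.table(
      chrom = reads$chrom, start0 = start0, end0 = end0,
      strand = reads$strand, mismatches = reads$mismatches,
      unique = as.integer(reads$is_unique),
      read_id = if (!is.null(reads$read_id)) reads$read_id else
        sprintf("r%07d", seq_len(nrow(reads)))
    )
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    if (is.null(genome)) stop("SAM output needs the genome for @SQ lines")
    header <- c(
      "@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome))
    )
    lines <- header
    if (nrow(reads) > 0L) {
      recs <- sprintf(
        "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
        if (!is.null(reads$read_id)) reads$read_id else
          sprintf("r%07d", seq_len(nrow(reads))),
        ifelse(reads$strand == "-", 16L, 0L),
        reads$chrom,
        start0 + 1L,
        ifelse(reads$is_unique, 42L, 3L),
        reads$length,
        reads$mismatches
      )
      lines <- c(lines, recs)
    }
    writeLines(lines, path)
  }
  if (!is.null(truth)) {
    data.table::fwrite(truth, paste0(path, ".truth.tsv"), sep = "\t")
  }
  invisible(path)
}
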