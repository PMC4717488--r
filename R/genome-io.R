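#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into a `DNAStringSet`, one record per
#' chromosome/contig. Sequence names are truncated at the first whitespace
#' and sequences are upper-cased. The alphabet is restricted to A, C, G, T
#' and N.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome id.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed or empty FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) {
    stop("duplicate chrom_id in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("zero-length sequence in FASTA")
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- Biostrings::letterFrequency(seqs, letters = "ACGTN")
  if (any(rowSums(bad) != Biostrings::width(seqs))) {
    stop("sequence alphabet must be restricted to A/C/G/T/N")
  }
  seqs
}

new_orf_catalog <- function(df, exons) {
  stopifnot(is.data.frame(df), is.data.frame(exons))
  rownames(df) <- NULL
  structure(df, exons = exons, class = c("orf_catalog", "data.frame"))
}

#' Exon table of an ORF catalog
#' @param orfs An `orf_catalog`.
#' @return data.frame with columns orf_id, exon_rank, start, end
#'   (1-based closed genomic coordinates, exon_rank in transcription order).
#' @export
orf_exons <- function(orfs) attr(orfs, "exons")

#' @export
print.orf_catalog <- function(x, ...) {
  cat("ORF catalog:", nrow(x), "ORFs on",
      length(unique(x$chrom)), "sequence(s)\n")
  print.data.frame(utils::head(x[, setdiff(names(x), "spliced_cds")], 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Load an ORF annotation from GFF3
#'
#' Reads CDS features, groups them by parent transcript, and assembles the
#' spliced coding sequence in transcription order (minus-strand features
#' are reverse-complemented). Coordinates are kept 1-based closed as in
#' GFF3; `cds_start`/`cds_end` are the genomic span of the CDS.
#'
#' ORFs whose spliced length is not divisible by 3 are flagged
#' `truncated` (with a warning); ORFs not beginning with ATG are flagged
#' `noncanonical_start`; ORFs with an internal in-frame stop or without a
#' terminal stop are flagged as well. Flags never drop an ORF.
#'
#' @param path Path to a GFF3 file with CDS features.
#' @param genome A `DNAStringSet` from [load_genome()].
#' @return An `orf_catalog`: a data.frame with columns orf_id, chrom,
#'   strand, cds_start, cds_end, n_exons, length_nt, spliced_cds and the
#'   flag columns, plus an exon table available via [orf_exons()].
#' @export
load_annotation <- function(path, genome) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0L) stop("no CDS features in ", path)

  parent <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0)) {
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else NA_character_
  ids <- ifelse(!is.na(parent), parent,
                if (!is.null(gr$ID)) gr$ID else NA_character_)
  if (anyNA(ids)) stop("CDS features must carry a Parent or ID attribute")

  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(BiocGenerics::strand(gr))
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)

  missing_chrom <- setdiff(unique(chroms), names(genome))
  if (length(missing_chrom)) {
    stop("annotation references unknown sequence(s): ",
         paste(missing_chrom, collapse = ", "))
  }
  too_far <- ends > Biostrings::width(genome)[match(chroms, names(genome))]
  if (any(too_far)) {
    stop("CDS feature beyond chromosome end for ORF(s): ",
         paste(unique(ids[too_far]), collapse = ", "))
  }

  ord <- order(ids, starts)
  ids <- ids[ord]; chroms <- chroms[ord]; strands <- strands[ord]
  starts <- starts[ord]; ends <- ends[ord]

  uid <- unique(ids)
  rows <- vector("list", length(uid))
  exon_rows <- vector("list", length(uid))
  n_trunc <- 0L
  for (i in seq_along(uid)) {
    sel <- which(ids == uid[i])
    chrom <- unique(chroms[sel])
    strand <- unique(strands[sel])
    if (length(chrom) != 1L || length(strand) != 1L) {
      stop("ORF ", uid[i], " mixes chromosomes or strands")
    }
    if (!strand %in% c("+", "-")) {
      stop("ORF ", uid[i], " has no usable strand")
    }
    ex_start <- starts[sel]
    ex_end <- ends[sel]
    # transcription order: ascending for +, descending for -
    o <- if (strand == "+") order(ex_start) else order(-ex_start)
    ex_start <- ex_start[o]; ex_end <- ex_end[o]
    pieces <- vapply(seq_along(ex_start), function(j) {
      as.character(Biostrings::subseq(genome[[chrom]], ex_start[j], ex_end[j]))
    }, character(1))
    spliced <- paste(pieces, collapse = "")
    if (strand == "-") spliced <- revcomp_chr(spliced)
    len <- nchar(spliced)
    truncated <- (len %% 3L) != 0L
    if (truncated) n_trunc <- n_trunc + 1L
    ncod <- len %/% 3L
    first <- substr(spliced, 1L, 3L)
    last <- if (!truncated && ncod >= 1L) {
      substr(spliced, len - 2L, len)
    } else NA_character_
    cods <- substring(spliced, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
    internal_stop <- any(cods[-length(cods)] %in% STOP_CODONS)
    rows[[i]] <- data.frame(
      orf_id = uid[i], chrom = chrom, strand = strand,
      cds_start = min(ex_start), cds_end = max(ex_end),
      n_exons = length(ex_start), length_nt = len,
      spliced_cds = spliced,
      noncanonical_start = first != "ATG",
      truncated = truncated,
      missing_stop = is.na(last) || !(last %in% STOP_CODONS),
      internal_stop = internal_stop,
      stringsAsFactors = FALSE
    )
    exon_rows[[i]] <- data.frame(
      orf_id = uid[i], exon_rank = seq_along(ex_start),
      start = ex_start, end = ex_end, stringsAsFactors = FALSE
    )
  }
  if (n_trunc > 0L) {
    warning(n_trunc, " ORF(s) have CDS length not divisible by 3; ",
            "flagged 'truncated'")
  }
  new_orf_catalog(do.call(rbind, rows), do.call(rbind, exon_rows))
}

#' Write an ORF catalog back to GFF3
#'
#' Emits one CDS feature per exon, grouped by a shared Parent id, so that
#' [load_annotation()] on the output reproduces the catalog.
#'
#' @param orfs An `orf_catalog`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(orfs, path) {
  ex <- orf_exons(orfs)
  meta <- orfs[match(ex$orf_id, orfs$orf_id), ]
  gr <- GenomicRanges::GRanges(
    seqnames = meta$chrom,
    ranges = IRanges::IRanges(start = ex$start, end = ex$end),
    strand = meta$strand
  )
  gr$type <- "CDS"
  gr$ID <- paste0(ex$orf_id, ".cds", ex$exon_rank)
  gr$Parent <- ex$orf_id
  # GFF3 phase: codon offset at each exon start, from cumulative exon
  # lengths in transcription order
  widths <- ex$end - ex$start + 1L
  before <- unlist(lapply(split(widths, ex$orf_id), function(w) {
    cumsum(c(0L, utils::head(w, -1L)))
  }), use.names = FALSE)[order(order(ex$orf_id, ex$exon_rank))]
  gr$phase <- (3L - before %% 3L) %% 3L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ORF-local (spliced, 1-based) coordinates of genomic positions.
# Positions in introns or outside the CDS span return NA. Vectorized over
# gpos; orf_row is a single catalog row, ex its exon table rows in
# transcription order.
orf_local_position <- function(orf_row, ex, gpos) {
  widths <- ex$end - ex$start + 1L
  before <- cumsum(c(0L, widths))[seq_along(widths)]
  local <- rep(NA_integer_, length(gpos))
  for (j in seq_len(nrow(ex))) {
    inside <- gpos >= ex$start[j] & gpos <= ex$end[j]
    if (!any(inside)) next
    off <- if (orf_row$strand == "+") {
      gpos[inside] - ex$start[j]
    } else {
      ex$end[j] - gpos[inside]
    }
    local[inside] <- before[j] + off + 1L
  }
  local
}

# inverse mapping for single-exon ORFs, allowing upstream (local <= -1)
# coordinates; local 0 does not exist
local_to_genomic <- function(orf_row, local) {
  up <- local <= -1L
  if (orf_row$strand == "+") {
    ifelse(up, orf_row$cds_start + local, orf_row$cds_start + local - 1L)
  } else {
    ifelse(up, orf_row$cds_end - local, orf_row$cds_end - local + 1L)
  }
}
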