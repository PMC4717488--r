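#' Enumerate upstream near-cognate initiation candidates
#'
#' Scans the 5' leader of each ORF for in-frame occurrences of the
#' configured near-cognate start codons within `max_upstream_nt`
#' (inclusive) of the annotated AUG, rejecting any candidate separated
#' from the AUG by an in-frame stop codon. Scanning walks codon by codon
#' away from the AUG and stops at the first in-frame stop or at the contig
#' edge.
#'
#' Offsets are reported in codon units relative to the AUG (the nearest
#' upstream in-frame codon is -1) and in nucleotides (`offset_nt = 3 *
#' offset_codons`).
#'
#' @param orfs An `orf_catalog`.
#' @param genome `DNAStringSet`.
#' @param codon_set Near-cognate codons to consider; DNA or RNA alphabet
#'   (default UUG, ACG, GUG -- GUC may be added).
#' @param max_upstream_nt Maximal distance of the candidate codon's first
#'   nucleotide from the AUG, inclusive (default 100).
#' @return data.frame: orf_id, codon (RNA display form), offset_codons,
#'   offset_nt, supporting_reads (NA until scored), reported (NA until
#'   scored).
#' @export
enumerate_candidates <- function(orfs, genome,
                                 codon_set = c("TTG", "ACG", "GTG"),
                                 max_upstream_nt = 100L) {
  codon_set <- rna_to_dna(codon_set)
  bad <- codon_set[nchar(codon_set) != 3L]
  if (length(bad)) stop("invalid codon(s): ", paste(bad, collapse = ", "))
  k_max <- max_upstream_nt %/% 3L
  rows <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    row <- orfs[i, ]
    chrom_len <- Biostrings::width(genome)[match(row$chrom, names(genome))]
    if (is.na(chrom_len)) stop("unknown chromosome: ", row$chrom)
    found <- list()
    for (k in seq_len(k_max)) {
      if (row$strand == "+") {
        lo <- row$cds_start - 3L * k
        hi <- lo + 2L
        if (lo < 1L) break
        cod <- as.character(Biostrings::subseq(genome[[row$chrom]], lo, hi))
      } else {
        hi <- row$cds_end + 3L * k
        lo <- hi - 2L
        if (hi > chrom_len) break
        cod <- revcomp_chr(as.character(
          Biostrings::subseq(genome[[row$chrom]], lo, hi)))
      }
      if (cod %in% STOP_CODONS) break
      if (cod %in% codon_set) {
        found[[length(found) + 1L]] <- data.frame(
          orf_id = row$orf_id, codon = dna_to_rna(cod),
          offset_codons = -k, offset_nt = -3L * k,
          supporting_reads = NA_integer_, reported = NA,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(found)) rows[[i]] <- do.call(rbind, found)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(orf_id = character(0), codon = character(0),
                      offset_codons = integer(0), offset_nt = integer(0),
                      supporting_reads = integer(0), reported = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score candidates by extension-region read support
#'
#' A candidate's support is the number of P-sites falling in its leader
#' extension, i.e. between the candidate codon's first nucleotide and the
#' nucleotide immediately 5' of the annotated AUG (strand-aware). Reads
#' there cannot derive from AUG-initiated ribosomes, making the count
#' specific to upstream initiation. A candidate is reported when support
#' reaches `min_reads`.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param track A `psite_track`.
#' @param orfs The `orf_catalog` the candidates refer to.
#' @param min_reads Reporting threshold (default 128).
#' @return `candidates` with supporting_reads and reported filled in.
#' @export
score_candidates <- function(candidates, track, orfs, min_reads = 128L) {
  if (nrow(candidates) == 0L) return(candidates)
  dt <- data.table::as.data.table(track)
  data.table::setkey(dt, chrom, strand, pos)
  support <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    row <- orfs[orfs$orf_id == candidates$orf_id[i], , drop = FALSE]
    if (nrow(row) != 1L) stop("candidate for unknown ORF: ",
                              candidates$orf_id[i])
    k <- -candidates$offset_codons[i]
    if (row$strand == "+") {
      lo <- row$cds_start - 3L * k
      hi <- row$cds_start - 1L
    } else {
      lo <- row$cds_end + 1L
      hi <- row$cds_end + 3L * k
    }
    sub <- dt[.(row$chrom, row$strand)][pos >= lo & pos <= hi]
    support[i] <- if (nrow(sub) == 0L || anyNA(sub$pos)) 0L else
      sum(sub$count)
  }
  candidates$supporting_reads <- support
  candidates$reported <- support >= min_reads
  candidates
}

#' Compare reported non-AUG starts between two samples
#'
#' @param calls_a,calls_b Scored candidate tables (see
#'   [score_candidates()]) for the two samples over the same annotation.
#' @return data.frame with one row per codon: reported counts in each
#'   sample and their ratio (b over a; 0 when both are empty, Inf when
#'   only a is empty).
#' @export
compare_start_counts <- function(calls_a, calls_b) {
  codons <- sort(unique(c(calls_a$codon, calls_b$codon)))
  na <- vapply(codons, function(cc)
    sum(calls_a$reported[calls_a$codon == cc], na.rm = TRUE), integer(1))
  nb <- vapply(codons, function(cc)
    sum(calls_b$reported[calls_b$codon == cc], na.rm = TRUE), integer(1))
  ratio <- ifelse(nb == 0L, 0, ifelse(na == 0L, Inf, nb / na))
  data.frame(codon = codons, reported_a = na, reported_b = nb,
             ratio = ratio, row.names = NULL, stringsAsFactors = FALSE)
}
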