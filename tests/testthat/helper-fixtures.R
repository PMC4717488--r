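# Shared fixture builders and brute-force oracles. Everything is built in
# code at test time; no binary fixtures.

# single-chromosome genome from a plain string
toy_genome <- function(seq, name = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# hand-built single-exon ORF catalog; seqs looked up from the genome
toy_orfs <- function(genome, start, end, strand = "+",
                     orf_id = sprintf("orf%02d", seq_along(start)),
                     chrom = names(genome)[1]) {
  strand <- rep_len(strand, length(start))
  spliced <- vapply(seq_along(start), function(i) {
    s <- as.character(Biostrings::subseq(genome[[chrom]], start[i], end[i]))
    if (strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  strand <- rep_len(strand, length(start))
  df <- data.frame(
    orf_id = orf_id, chrom = chrom, strand = strand,
    cds_start = start, cds_end = end, n_exons = 1L,
    length_nt = end - start + 1L, spliced_cds = spliced,
    noncanonical_start = FALSE, truncated = FALSE,
    missing_stop = FALSE, internal_stop = FALSE,
    stringsAsFactors = FALSE
  )
  exons <- data.frame(orf_id = orf_id, exon_rank = 1L,
                      start = start, end = end, stringsAsFactors = FALSE)
  structure(df, exons = exons, class = c("orf_catalog", "data.frame"))
}

# reads data.frame from explicit fields (defaults: clean unique 28-mers)
toy_reads <- function(chrom, five_prime_pos, strand = "+", length = 28L,
                      mismatches = 0L, is_unique = TRUE) {
  n <- length(five_prime_pos)
  data.frame(
    read_id = sprintf("t%04d", seq_len(n)),
    chrom = rep_len(chrom, n), strand = rep_len(strand, n),
    five_prime_pos = five_prime_pos, length = rep_len(length, n),
    mismatches = rep_len(mismatches, n),
    is_unique = rep_len(is_unique, n),
    stringsAsFactors = FALSE
  )
}

# a P-site track directly from genomic positions (counts of 1 unless given)
toy_track <- function(chrom, pos, strand = "+", count = 1L) {
  df <- data.frame(chrom = rep_len(chrom, length(pos)),
                   strand = rep_len(strand, length(pos)),
                   pos = pos, count = rep_len(count, length(pos)),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(structure(df, total_psites = 0L,
                     class = c("psite_track", "data.frame")))
  }
  agg <- stats::aggregate(count ~ chrom + strand + pos, df, sum)
  agg <- agg[order(agg$chrom, agg$strand, agg$pos), ]
  rownames(agg) <- NULL
  structure(agg, total_psites = sum(agg$count),
            class = c("psite_track", "data.frame"))
}

# random in-frame coding sequence: ATG + sense codons + TAA
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  body <- sample(sense_codons(), n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

# --- brute-force oracles ---------------------------------------------------

# per-read loop over windows and frames
oracle_frame_profile <- function(track, orfs) {
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    win <- window_orf(o$length_nt)
    tally <- matrix(0L, nrow = nrow(win), ncol = 3)
    for (r in seq_len(nrow(track))) {
      if (track$chrom[r] != o$chrom || track$strand[r] != o$strand) next
      p <- track$pos[r]
      if (p < o$cds_start || p > o$cds_end) next
      local <- if (o$strand == "+") p - o$cds_start + 1L else
        o$cds_end - p + 1L
      fr <- (local - 1L) %% 3L
      w <- which(local >= win$start_nt & local <= win$end_nt)
      tally[w, fr + 1L] <- tally[w, fr + 1L] + track$count[r]
    }
    rows[[i]] <- data.frame(orf_id = o$orf_id,
                            window_index = win$window_index,
                            start_nt = win$start_nt, end_nt = win$end_nt,
                            n0 = tally[, 1], n1 = tally[, 2], n2 = tally[, 3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$orf_id, out$window_index), ]
}

# per-read loop over E/P/A site codons (single-exon, plus- or minus-strand)
oracle_site_counts <- function(track, orfs, trim_codons = 5L) {
  sense <- sense_codons()
  res <- expand.grid(site = c("A", "E", "P"), codon = sense,
                     stringsAsFactors = FALSE)
  res$count <- 0L
  bump <- function(site, codon, n) {
    if (!codon %in% sense) return(invisible())
    k <- which(res$site == site & res$codon == codon)
    res$count[k] <<- res$count[k] + n
  }
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    n_sense <- o$length_nt %/% 3L - 1L
    for (r in seq_len(nrow(track))) {
      if (track$chrom[r] != o$chrom || track$strand[r] != o$strand) next
      p <- track$pos[r]
      if (p < o$cds_start || p > o$cds_end) next
      local <- if (o$strand == "+") p - o$cds_start + 1L else
        o$cds_end - p + 1L
      if ((local - 1L) %% 3L != 0L) next
      ci <- (local - 1L) %/% 3L + 1L
      if (ci < trim_codons + 1L || ci > n_sense - trim_codons) next
      cod <- function(j) substr(o$spliced_cds, 3 * j - 2, 3 * j)
      bump("P", cod(ci), track$count[r])
      if (ci + 1L <= n_sense) bump("A", cod(ci + 1L), track$count[r])
      if (ci - 1L >= 1L) bump("E", cod(ci - 1L), track$count[r])
    }
  }
  res[order(res$site, res$codon), ]
}

# regex-free scan of an upstream window for in-frame near-cognates
oracle_enumerate <- function(upstream_seq, codon_set = c("TTG", "ACG", "GTG"),
                             max_upstream_nt = 100L) {
  n <- nchar(upstream_seq)
  hits <- integer(0)
  k <- 1L
  repeat {
    lo <- n - 3L * k + 1L
    if (lo < 1L || 3L * k > max_upstream_nt) break
    cod <- substr(upstream_seq, lo, lo + 2L)
    if (cod %in% c("TAA", "TAG", "TGA")) break
    if (cod %in% codon_set) hits <- c(hits, -k)
    k <- k + 1L
  }
  sort(hits)
}
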