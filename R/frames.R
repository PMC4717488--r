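#' Filter footprints to the frame-informative set
#'
#' Retains reads of exactly the stated length that aligned uniquely and
#' carry no mismatches -- the strict criterion under which a footprint's
#' P-site frame is trustworthy. Reports how many reads each criterion
#' rejects (a read failing several criteria is counted under each).
#'
#' @param reads data.frame from [load_alignments()].
#' @param read_length Required footprint length in nt (default 28, the
#'   dominant protected-fragment length in yeast).
#' @return list with `reads` (the retained subset) and `report` (named
#'   counts: input, retained, dropped_length, dropped_mismatch,
#'   dropped_multimap).
#' @export
filter_reads <- function(reads, read_length = 28L) {
  ok_len <- reads$length == read_length
  ok_mm <- reads$mismatches == 0L
  ok_uni <- reads$is_unique
  keep <- ok_len & ok_mm & ok_uni
  list(
    reads = reads[keep, , drop = FALSE],
    report = c(
      input = nrow(reads),
      retained = sum(keep),
      dropped_length = sum(!ok_len),
      dropped_mismatch = sum(!ok_mm),
      dropped_multimap = sum(!ok_uni)
    )
  )
}

#' Infer P-site positions from filtered footprints
#'
#' The ribosomal P-site is taken as the nucleotide a fixed offset
#' downstream of the read's biological 5' end: `five_prime_pos + offset`
#' on the plus strand, `five_prime_pos - offset` on the minus strand.
#' Counts are accumulated per (chrom, strand, position).
#'
#' @param reads Filtered reads (see [filter_reads()]).
#' @param offset 5'-to-P-site offset in nt (default 12).
#' @param genome Optional `DNAStringSet`; when given, P-sites falling
#'   outside chromosome bounds are dropped with a warning.
#' @return A `psite_track`: data.frame (chrom, strand, pos, count) with
#'   attribute `total_psites`.
#' @export
assign_psites <- function(reads, offset = 12L, genome = NULL) {
  pos <- ifelse(reads$strand == "+",
                reads$five_prime_pos + offset,
                reads$five_prime_pos - offset)
  dt <- data.table::data.table(chrom = reads$chrom, strand = reads$strand,
                               pos = as.integer(pos))
  if (!is.null(genome)) {
    lim <- Biostrings::width(genome)[match(dt$chrom, names(genome))]
    bad <- dt$pos < 1L | dt$pos > lim | is.na(lim)
    if (any(bad)) {
      warning(sum(bad), " P-site(s) outside chromosome bounds dropped")
      dt <- dt[!bad]
    }
  }
  track <- dt[, .(count = .N), by = .(chrom, strand, pos)]
  data.table::setkey(track, chrom, strand, pos)
  track <- as.data.frame(track)
  structure(track, total_psites = sum(track$count),
            class = c("psite_track", "data.frame"))
}

#' @export
print.psite_track <- function(x, ...) {
  cat("P-site track:", attr(x, "total_psites"), "P-sites at",
      nrow(x), "positions\n")
  print.data.frame(utils::head(x, 10), ...)
  invisible(x)
}

#' Reading frame of a P-site within an ORF
#'
#' Frame 0 is the annotated frame; frames +1/+2 are one and two
#' nucleotides downstream of it. Positions outside the (spliced) CDS give
#' `NA`.
#'
#' @param psite Genomic position(s), 1-based.
#' @param orf A single-row subset of an `orf_catalog`.
#' @param exons Exon table for that ORF; defaults to single-exon geometry
#'   from the catalog row.
#' @return Integer vector over {0, 1, 2} or NA.
#' @export
frame_of <- function(psite, orf, exons = NULL) {
  if (is.null(exons)) {
    exons <- data.frame(start = orf$cds_start, end = orf$cds_end)
  }
  local <- orf_local_position(orf, exons, psite)
  ifelse(is.na(local) | local < 1L | local > orf$length_nt,
         NA_integer_, (local - 1L) %% 3L)
}

#' Tile an ORF into frame-analysis windows
#'
#' An ORF is split into `k = clamp(round(length/300), 3, 9)` codon-aligned
#' windows of near-equal size: the remainder of the codon count divided by
#' `k` is spread over the leftmost windows, so window lengths differ by at
#' most 3 nt. A trailing partial codon (truncated ORFs) is absorbed by the
#' last window.
#'
#' @param orf_length ORF length in nt (>= 9).
#' @param target_nt Target window size in nt (default 300).
#' @param min_windows,max_windows Clamp bounds (defaults 3 and 9).
#' @return data.frame with window_index, start_nt, end_nt (ORF-local,
#'   1-based closed).
#' @export
window_orf <- function(orf_length, target_nt = 300L, min_windows = 3L,
                       max_windows = 9L) {
  if (orf_length < 9L) stop("ORF too short to window: ", orf_length, " nt")
  k <- max(min_windows, min(max_windows, round(orf_length / target_nt)))
  n_codons <- orf_length %/% 3L
  k <- min(k, n_codons)
  base <- n_codons %/% k
  rem <- n_codons %% k
  sizes <- 3L * (base + as.integer(seq_len(k) <= rem))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  ends[k] <- orf_length  # absorb any partial trailing codon
  data.frame(window_index = seq_len(k), start_nt = starts, end_nt = ends)
}

# internal: per-ORF local P-site table. Returns data.table with
# orf_id, local, frame, count for all in-CDS P-sites.
local_psites <- function(track, orfs) {
  dt <- data.table::as.data.table(track)
  data.table::setkey(dt, chrom, strand, pos)
  exons_all <- orf_exons(orfs)
  out <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    row <- orfs[i, ]
    sub <- dt[.(row$chrom, row$strand)][pos >= row$cds_start &
                                        pos <= row$cds_end]
    if (nrow(sub) == 0L || anyNA(sub$pos)) next
    ex <- exons_all[exons_all$orf_id == row$orf_id, , drop = FALSE]
    local <- orf_local_position(row, ex, sub$pos)
    keep <- !is.na(local)
    if (!any(keep)) next
    out[[i]] <- data.table::data.table(
      orf_id = row$orf_id, local = local[keep],
      frame = (local[keep] - 1L) %% 3L, count = sub$count[keep]
    )
  }
  found <- !vapply(out, is.null, logical(1))
  if (!any(found)) {
    return(data.table::data.table(orf_id = character(0), local = integer(0),
                                  frame = integer(0), count = integer(0)))
  }
  data.table::rbindlist(out[found])
}

#' Windowed frame profiles per ORF
#'
#' Assigns every in-CDS P-site to the window containing it and tallies
#' counts per frame. ORFs shorter than 9 nt are skipped with a warning.
#'
#' @param track A `psite_track`.
#' @param orfs An `orf_catalog` over the same genome.
#' @return A `window_frame_profile` data.frame: orf_id, window_index,
#'   start_nt, end_nt, n0, n1, n2 (complete grid, zero-filled).
#' @export
frame_profile <- function(track, orfs) {
  short <- orfs$length_nt < 9L
  if (any(short)) {
    warning(sum(short), " ORF(s) shorter than 9 nt skipped")
    orfs <- orfs[!short, , drop = FALSE]
  }
  win_all <- do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
    w <- window_orf(orfs$length_nt[i])
    w$orf_id <- orfs$orf_id[i]
    w
  }))
  lp <- local_psites(track, orfs)
  grid <- data.table::as.data.table(
    win_all[, c("orf_id", "window_index", "start_nt", "end_nt")]
  )
  if (nrow(lp) > 0L) {
    lp <- merge(lp, grid, by = "orf_id", allow.cartesian = TRUE)
    lp <- lp[local >= start_nt & local <= end_nt]
    agg <- lp[, .(
      n0 = sum(count[frame == 0L]),
      n1 = sum(count[frame == 1L]),
      n2 = sum(count[frame == 2L])
    ), by = .(orf_id, window_index)]
    out <- merge(grid, agg, by = c("orf_id", "window_index"), all.x = TRUE)
  } else {
    out <- grid
    out[, c("n0", "n1", "n2")] <- 0L
  }
  out <- as.data.frame(out)
  for (cn in c("n0", "n1", "n2")) {
    out[[cn]][is.na(out[[cn]])] <- 0L
    out[[cn]] <- as.integer(out[[cn]])
  }
  out <- out[order(out$orf_id, out$window_index), ]
  rownames(out) <- NULL
  structure(out, class = c("window_frame_profile", "data.frame"))
}

#' Call per-ORF translational ambiguities
#'
#' An ORF is flagged ambiguous when at least one of its windows has
#' sufficient coverage and an off-frame (frames +1/+2 combined) read
#' fraction at or above the threshold. The dominant off-frame is the one
#' with more reads summed over offending windows.
#'
#' @param profiles A `window_frame_profile`.
#' @param min_window_reads Minimum reads in a window for it to be
#'   informative (default 32).
#' @param offframe_fraction Off-frame fraction at or above which a window
#'   is offending (default 0.5).
#' @return data.frame: orf_id, ambiguous, n_offending, offending_windows
#'   (comma-joined indices), dominant_offframe ("+1"/"+2" or NA).
#' @export
call_ambiguities <- function(profiles, min_window_reads = 32L,
                             offframe_fraction = 0.5) {
  dt <- data.table::as.data.table(profiles)
  dt[, total := n0 + n1 + n2]
  dt[, off := ifelse(total > 0L, (n1 + n2) / total, 0)]
  dt[, offending := total >= min_window_reads & off >= offframe_fraction]
  calls <- dt[, {
    offw <- window_index[offending]
    s1 <- sum(n1[offending]); s2 <- sum(n2[offending])
    list(
      ambiguous = length(offw) > 0L,
      n_offending = length(offw),
      offending_windows = paste(offw, collapse = ","),
      dominant_offframe = if (length(offw) == 0L) NA_character_ else
        if (s1 >= s2) "+1" else "+2"
    )
  }, by = orf_id]
  as.data.frame(calls)
}

#' Localize a frame transition inside an ambiguous ORF
#'
#' Treats each in-CDS P-site in frame 0 or in the dominant off-frame as a
#' Bernoulli observation ordered along the ORF and finds the change-point
#' maximizing the two-segment binomial likelihood. Intended for ORFs with
#' a single dominant off-frame (e.g. a programmed +1 frameshift).
#'
#' @param track A `psite_track`.
#' @param orfs An `orf_catalog`.
#' @param orf_id The ORF to analyze.
#' @param dominant_frame 1 or 2; the off-frame to model against frame 0.
#' @return ORF-local 1-based transition nucleotide, or NA if the ORF has
#'   no off-frame (or no frame-0) P-sites to delimit a transition.
#' @export
locate_transition <- function(track, orfs, orf_id, dominant_frame = 1L) {
  stopifnot(dominant_frame %in% c(1L, 2L))
  row <- orfs[orfs$orf_id == orf_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown orf_id: ", orf_id)
  lp <- local_psites(track, row)
  lp <- lp[frame %in% c(0L, dominant_frame)]
  if (nrow(lp) == 0L) return(NA_integer_)
  lp <- lp[order(local)]
  x <- rep(lp$local, lp$count)
  y <- rep(as.integer(lp$frame == dominant_frame), lp$count)
  m <- length(y)
  if (sum(y) == 0L) return(NA_integer_)
  if (sum(y) == m) return(max(1L, x[1] - 1L))
  bin_ll <- function(k, n) {
    p <- k / n
    t1 <- ifelse(k > 0, k * log(p), 0)
    t2 <- ifelse(n - k > 0, (n - k) * log(1 - p), 0)
    t1 + t2
  }
  s <- cumsum(y)
  i <- seq_len(m - 1L)
  ll <- bin_ll(s[i], i) + bin_ll(s[m] - s[i], m - i)
  best <- which.max(ll)
  as.integer(floor((x[best] + x[best + 1L]) / 2))
}

#' Global frame-fidelity summary and between-sample test
#'
#' Sums in-CDS P-sites over all ORFs to per-sample frame fractions
#' (f0, f1, f2), then compares per-ORF frame-0 fractions between the two
#' samples with an unpaired two-sample t-test, restricted to ORFs with at
#' least `min_orf_reads` P-sites in both samples.
#'
#' @param track_a,track_b `psite_track`s for the two samples.
#' @param orfs Shared `orf_catalog`.
#' @param min_orf_reads Per-ORF coverage floor for the test (default 32).
#' @param sample_names Length-2 labels.
#' @return list of class `frame_summary`: `fractions` (per-sample f0, f1,
#'   f2 and totals), `n_orfs_tested`, `statistic`, `df`, `p.value`.
#' @export
global_frame_summary <- function(track_a, track_b, orfs,
                                 min_orf_reads = 32L,
                                 sample_names = c("A", "B")) {
  per_orf <- function(track) {
    lp <- local_psites(track, orfs)
    if (nrow(lp) == 0L) {
      return(data.table::data.table(orf_id = character(0), n0 = integer(0),
                                    n1 = integer(0), n2 = integer(0)))
    }
    lp[, .(n0 = sum(count[frame == 0L]), n1 = sum(count[frame == 1L]),
           n2 = sum(count[frame == 2L])), by = orf_id]
  }
  pa <- per_orf(track_a)
  pb <- per_orf(track_b)
  frac <- function(p) {
    tot <- sum(p$n0) + sum(p$n1) + sum(p$n2)
    if (tot == 0L) stop("no in-CDS P-sites in one sample")
    c(f0 = sum(p$n0) / tot, f1 = sum(p$n1) / tot, f2 = sum(p$n2) / tot,
      total = tot)
  }
  fr <- rbind(frac(pa), frac(pb))
  fractions <- data.frame(sample = sample_names, fr,
                          stringsAsFactors = FALSE)
  merged <- merge(pa, pb, by = "orf_id", suffixes = c("_a", "_b"))
  merged[, tot_a := n0_a + n1_a + n2_a]
  merged[, tot_b := n0_b + n1_b + n2_b]
  merged <- merged[tot_a >= min_orf_reads & tot_b >= min_orf_reads]
  if (nrow(merged) < 3L) {
    stop("fewer than 3 ORFs meet the per-ORF coverage floor in both samples")
  }
  x <- merged$n0_a / merged$tot_a
  y <- merged$n0_b / merged$tot_b
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stat <- 0; dof <- NA_real_
    pv <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    stat <- unname(tt$statistic); dof <- unname(tt$parameter)
    pv <- tt$p.value
  }
  structure(
    list(fractions = fractions, n_orfs_tested = nrow(merged),
         statistic = stat, df = dof, p.value = pv),
    class = "frame_summary"
  )
}

#' @export
print.frame_summary <- function(x, ...) {
  cat("Global frame summary (", x$n_orfs_tested, " ORFs tested)\n", sep = "")
  print(x$fractions, ...)
  cat(sprintf("t = %.3f, df = %.1f, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}
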