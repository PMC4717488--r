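#' Specify a footprint simulation
#'
#' Bundles and validates every knob of the synthetic genome and footprint
#' generator. Defaults describe a small yeast-like experiment: 50
#' intron-less ORFs of 0.3-1.8 kb separated by >= 200 nt of intergenic
#' sequence, 28-nt footprints, clean reads, and no programmed events.
#'
#' @param orf_lengths Integer vector of ORF lengths in nt (each a multiple
#'   of 3, including start and stop codons). `NULL` draws 50 lengths
#'   uniformly from 300-1800 nt at genome construction.
#' @param codon_weights Named non-negative weights over sense codons used
#'   to draw the coding sequence composition; missing codons get weight 1.
#'   Stop codons are never drawn inside an ORF.
#' @param dwell_weights Named positive multipliers of per-codon ribosome
#'   dwell, keyed on the A-site codon; missing codons get 1.
#' @param events `NULL` or a data.frame with columns kind ("frameshift" or
#'   "upstream_init"), orf_id, position (codon index inside the ORF for
#'   frameshifts; codon-unit distance upstream of the AUG, as a positive
#'   number, for upstream starts), shift (+1/-1, frameshifts only), codon
#'   (near-cognate planted at the upstream position, default "TTG") and
#'   penetrance (fraction of ribosomes affected, in (0, 1]).
#' @param depth Mean reads per codon position.
#' @param read_lengths Named probability vector over read lengths in nt.
#' @param mismatch_rate Probability that a read carries one mismatch.
#' @param multimap_rate Probability that a read is flagged non-unique.
#' @param background_offframe Probability that a read's P-site is displaced
#'   +1 or +2 nt out of its ribosome's frame, emulating residual frame
#'   noise unrelated to any programmed event.
#' @param minus_strand_fraction Fraction of ORFs placed on the minus
#'   strand.
#' @param intergenic_nt Intergenic spacer length (>= 200).
#' @param seed Integer seed; the whole pipeline is reproducible from it.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(orf_lengths = NULL,
                            codon_weights = NULL,
                            dwell_weights = NULL,
                            events = NULL,
                            depth = 10,
                            read_lengths = c("28" = 1),
                            mismatch_rate = 0,
                            multimap_rate = 0,
                            background_offframe = 0,
                            minus_strand_fraction = 0,
                            intergenic_nt = 250L,
                            seed = 1L) {
  if (!is.null(orf_lengths)) {
    stopifnot(all(orf_lengths >= 9), all(orf_lengths %% 3 == 0))
  }
  stopifnot(depth > 0)
  probs <- c(mismatch_rate, multimap_rate, background_offframe,
             minus_strand_fraction, read_lengths)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(read_lengths) - 1) > 1e-9) {
    stop("read_lengths must sum to 1")
  }
  if (intergenic_nt < 200L) stop("intergenic spacers must be >= 200 nt")
  if (!is.null(dwell_weights)) {
    if (any(dwell_weights <= 0)) stop("dwell weights must be positive")
    unknown <- setdiff(rna_to_dna(names(dwell_weights)), sense_codons())
    if (length(unknown)) stop("dwell weight on non-sense codon: ",
                              paste(unknown, collapse = ", "))
  }
  if (!is.null(codon_weights)) {
    cw <- codon_weights[rna_to_dna(names(codon_weights)) %in% sense_codons()]
    if (any(codon_weights < 0)) stop("codon weights must be non-negative")
    if (length(cw) == 0 || all(cw == 0)) {
      stop("codon composition leaves no sense codon available: ",
           "a stop-free ORF is impossible")
    }
  }
  if (!is.null(events)) {
    events <- as.data.frame(events)
    need <- c("kind", "orf_id", "position", "penetrance")
    if (!all(need %in% names(events))) {
      stop("events need columns: ", paste(need, collapse = ", "))
    }
    if (!all(events$kind %in% c("frameshift", "upstream_init"))) {
      stop("event kind must be frameshift or upstream_init")
    }
    if (any(events$penetrance <= 0 | events$penetrance > 1)) {
      stop("penetrance must lie in (0, 1]")
    }
    if (is.null(events$shift)) events$shift <- NA_integer_
    if (is.null(events$codon)) events$codon <- NA_character_
    fs <- events$kind == "frameshift"
    if (any(fs & !(events$shift %in% c(1L, -1L)))) {
      stop("frameshift events need shift +1 or -1")
    }
    events$codon[events$kind == "upstream_init" & is.na(events$codon)] <- "TTG"
    events$codon <- rna_to_dna(events$codon)
    if (any(events$position < 1)) stop("event positions are 1-based codon units")
  }
  structure(
    list(orf_lengths = orf_lengths, codon_weights = codon_weights,
         dwell_weights = dwell_weights, events = events, depth = depth,
         read_lengths = read_lengths, mismatch_rate = mismatch_rate,
         multimap_rate = multimap_rate,
         background_offframe = background_offframe,
         minus_strand_fraction = minus_strand_fraction,
         intergenic_nt = as.integer(intergenic_nt), seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

# codons that may appear in a planted 5' leader without creating a second
# candidate, an upstream AUG, or an intervening in-frame stop
leader_filler_codons <- function() {
  setdiff(sense_codons(), c("ATG", "TTG", "ACG", "GTG", "GTC"))
}

#' Build a synthetic genome and ORF catalog
#'
#' Constructs one chromosome carrying single-exon ORFs separated by
#' intergenic spacers. Each ORF begins with ATG, ends with a stop codon,
#' and contains no internal in-frame stop. For every `upstream_init` event
#' in the simulation spec, the 5' leader is written in-frame: the stated near-cognate
#' codon at the stated codon-unit distance, benign filler codons between it
#' and the AUG, and a stop codon immediately 5' of the planted region so
#' the candidate set is exactly the planted one.
#'
#' @param spec A [simulation_spec()].
#' @return list with elements `genome` (`DNAStringSet`) and `orfs`
#'   (`orf_catalog`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, make_genome_impl(spec))
}

make_genome_impl <- function(spec) {
  lengths <- spec$orf_lengths
  if (is.null(lengths)) {
    lengths <- 3L * sample(100:600, 50, replace = TRUE)
  }
  n_orf <- length(lengths)
  orf_ids <- sprintf("ORF%04d", seq_len(n_orf))

  sense <- sense_codons()
  w <- rep(1, length(sense))
  names(w) <- sense
  if (!is.null(spec$codon_weights)) {
    cw <- spec$codon_weights
    names(cw) <- rna_to_dna(names(cw))
    w[names(cw)] <- cw
  }
  if (all(w == 0)) stop("codon composition leaves no sense codon available")

  strands <- ifelse(runif(n_orf) < spec$minus_strand_fraction, "-", "+")

  ev <- spec$events
  pieces <- character(0)
  cursor <- 0L
  rows <- vector("list", n_orf)
  for (i in seq_len(n_orf)) {
    ncod <- lengths[i] %/% 3L
    body <- sample(sense, ncod - 2L, replace = TRUE, prob = w)
    if (!is.null(ev)) {
      # a programmed frameshift site must support the shifted path: re-draw
      # the codon after the event until the first shifted triplet is not a
      # stop (bounded retries)
      fs_here <- ev[ev$kind == "frameshift" & ev$orf_id == orf_ids[i], ,
                    drop = FALSE]
      for (r in seq_len(nrow(fs_here))) {
        e <- as.integer(fs_here$position[r])
        s <- as.integer(fs_here$shift[r])
        if (e < 1L || e > ncod - 3L) next
        for (try in 1:50) {
          seq_now <- paste(c("ATG", body, "TAA"), collapse = "")
          trip <- substr(seq_now, 3L * e + 1L + s, 3L * e + 3L + s)
          if (!trip %in% STOP_CODONS) break
          body[e] <- sample(sense, 1L, prob = w)
        }
      }
    }
    orf_seq <- paste(c("ATG", body, "TAA"), collapse = "")

    leader <- ""
    if (!is.null(ev)) {
      ui <- ev[ev$kind == "upstream_init" & ev$orf_id == orf_ids[i], ,
               drop = FALSE]
      if (nrow(ui) > 1L) {
        warning("multiple upstream_init events for ", orf_ids[i],
                "; using the first")
        ui <- ui[1, , drop = FALSE]
      }
      if (nrow(ui) == 1L) {
        k <- as.integer(ui$position)
        fill <- sample(leader_filler_codons(), k - 1L, replace = TRUE)
        leader <- paste(c("TAA", ui$codon, fill), collapse = "")
      }
    }

    spacer <- paste(sample(c("A", "C", "G", "T"), spec$intergenic_nt,
                           replace = TRUE), collapse = "")
    locus <- paste0(leader, orf_seq)
    if (strands[i] == "-") locus <- revcomp_chr(locus)
    pieces <- c(pieces, spacer, locus)
    locus_start <- cursor + spec$intergenic_nt + 1L
    if (strands[i] == "+") {
      cds_start <- locus_start + nchar(leader)
      cds_end <- cds_start + lengths[i] - 1L
    } else {
      cds_start <- locus_start
      cds_end <- cds_start + lengths[i] - 1L
    }
    cursor <- cursor + spec$intergenic_nt + nchar(locus)
    rows[[i]] <- data.frame(
      orf_id = orf_ids[i], chrom = "chrSim", strand = strands[i],
      cds_start = cds_start, cds_end = cds_end,
      n_exons = 1L, length_nt = lengths[i], spliced_cds = orf_seq,
      noncanonical_start = FALSE, truncated = FALSE,
      missing_stop = FALSE, internal_stop = FALSE,
      stringsAsFactors = FALSE
    )
  }
  # closing spacer so reads near the last stop codon stay in bounds
  pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), spec$intergenic_nt,
                                   replace = TRUE), collapse = ""))
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- "chrSim"
  df <- do.call(rbind, rows)
  exons <- data.frame(orf_id = df$orf_id, exon_rank = 1L,
                      start = df$cds_start, end = df$cds_end,
                      stringsAsFactors = FALSE)
  list(genome = genome, orfs = new_orf_catalog(df, exons))
}

#' Simulate ribosome footprints with per-read ground truth
#'
#' Places elongating ribosomes along each ORF with P-site probability
#' proportional to the dwell weight of the codon in the A site, then emits
#' one read per placement whose 5' end lies 12 nt upstream of the P-site
#' (mirrored on the minus strand) -- the same offset geometry the analysis
#' assumes. Frameshift events divert the stated fraction of ribosomes into
#' the shifted frame downstream of the event codon; upstream-initiation
#' events start the stated fraction at the planted near-cognate, in frame
#' with the main AUG, emitting reads from the leader extension through the
#' ORF. Mismatch and multimapping flags are assigned independently at the
#' stated rates.
#'
#' @param genome,orfs Output of [make_genome()] (or compatible objects
#'   with single-exon ORFs).
#' @param spec The same [simulation_spec()] used to build the genome.
#' @param offset 5'-to-P-site distance in nt used for read emission.
#' @return list with `reads` (data.frame as in [load_alignments()]) and
#'   `truth` (one row per read: read_id, orf_id, true_frame, event,
#'   psite_local).
#' @export
simulate_footprints <- function(genome, orfs, spec, offset = 12L) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed + 1L,
                   simulate_footprints_impl(genome, orfs, spec, offset))
}

simulate_footprints_impl <- function(genome, orfs, spec, offset) {
  dwell <- rep(1, length(sense_codons()))
  names(dwell) <- sense_codons()
  if (!is.null(spec$dwell_weights)) {
    dw <- spec$dwell_weights
    names(dw) <- rna_to_dna(names(dw))
    dwell[names(dw)] <- dw
  }
  dwell_of <- function(codons) {
    out <- dwell[codons]
    out[is.na(out)] <- 1  # off-frame triplets incl. stops: neutral dwell
    unname(out)
  }
  ev <- spec$events
  if (!is.null(ev)) {
    unknown <- setdiff(ev$orf_id, orfs$orf_id)
    if (length(unknown)) {
      stop("event references unknown ORF(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  read_lens <- as.integer(names(spec$read_lengths))

  out_reads <- vector("list", nrow(orfs))
  out_truth <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    row <- orfs[i, ]
    cds <- row$spliced_cds
    ncod <- nchar(cds) %/% 3L
    n_sense <- ncod - 1L                      # drop the stop codon
    m <- n_sense - 1L                         # P positions with an A site in CDS
    if (m < 1L) next
    cod <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))

    fs <- ui <- NULL
    if (!is.null(ev)) {
      evi <- ev[ev$orf_id == row$orf_id, , drop = FALSE]
      fs <- evi[evi$kind == "frameshift", , drop = FALSE]
      ui <- evi[evi$kind == "upstream_init", , drop = FALSE]
      if (nrow(fs) > 1L) {
        warning("multiple frameshift events for ", row$orf_id,
                "; using the first")
        fs <- fs[1, , drop = FALSE]
      }
      if (nrow(ui) > 1L) ui <- ui[1, , drop = FALSE]
      if (nrow(fs) == 1L && (fs$position < 1L || fs$position > m - 1L)) {
        stop("frameshift position must lie strictly inside ", row$orf_id)
      }
    }

    n_reads <- rpois(1L, spec$depth * m)
    if (n_reads == 0L) next

    p_ui <- if (!is.null(ui) && nrow(ui) == 1L) ui$penetrance else 0
    p_fs <- if (!is.null(fs) && nrow(fs) == 1L) (1 - p_ui) * fs$penetrance else 0
    cls <- sample(c("upstream", "shifted", "normal"), n_reads, replace = TRUE,
                  prob = c(p_ui, p_fs, 1 - p_ui - p_fs))

    loc <- integer(n_reads)          # P-site, ORF-local nt (no 0)
    frm <- integer(n_reads)          # frame of the ribosome at that P-site
    evlab <- rep("none", n_reads)

    n_norm <- sum(cls == "normal")
    if (n_norm > 0L) {
      wpos <- dwell_of(cod[seq_len(m) + 1L])
      j <- sample.int(m, n_norm, replace = TRUE, prob = wpos)
      loc[cls == "normal"] <- 3L * (j - 1L) + 1L
    }
    n_sh <- sum(cls == "shifted")
    if (n_sh > 0L) {
      e <- as.integer(fs$position)
      s <- as.integer(fs$shift)
      psite_nt <- ifelse(seq_len(m) <= e,
                         3L * (seq_len(m) - 1L) + 1L,
                         3L * (seq_len(m) - 1L) + 1L + s)
      a_codon <- substring(cds, psite_nt + 3L, psite_nt + 5L)
      jmax <- m
      first_shift_codon <- substring(cds, 3L * e + 1L + s, 3L * e + 3L + s)
      if (first_shift_codon %in% STOP_CODONS) {
        warning("shifted path of ", row$orf_id,
                " hits an immediate stop; truncating shifted ribosomes")
        jmax <- e
      }
      wpos <- dwell_of(a_codon[seq_len(jmax)])
      j <- sample.int(jmax, n_sh, replace = TRUE, prob = wpos)
      loc[cls == "shifted"] <- psite_nt[j]
      frm[cls == "shifted"] <- ifelse(j > e, s %% 3L, 0L)
      evlab[cls == "shifted"] <- "frameshift"
    }
    n_up <- sum(cls == "upstream")
    if (n_up > 0L) {
      k <- as.integer(ui$position)
      updex <- c(-(k:1), seq_len(m))          # codon indices, no 0
      lead <- leader_codons(genome, row, k)
      path_cod <- c(lead, cod[seq_len(ncod)])  # codons -k..-1, 1..ncod
      a_idx <- match(updex, c(-(k:1), seq_len(ncod))) + 1L
      wpos <- dwell_of(path_cod[a_idx])
      j <- sample.int(length(updex), n_up, replace = TRUE, prob = wpos)
      u <- updex[j]
      loc[cls == "upstream"] <- ifelse(u < 0L, 3L * u, 3L * (u - 1L) + 1L)
      evlab[cls == "upstream"] <- "upstream_init"
    }

    if (spec$background_offframe > 0) {
      hit <- runif(n_reads) < spec$background_offframe
      if (any(hit)) {
        d <- sample(1:2, sum(hit), replace = TRUE)
        loc[hit] <- loc[hit] + d
        frm[hit] <- (frm[hit] + d) %% 3L
      }
    }

    gpos <- local_to_genomic(row, loc)
    fp <- if (row$strand == "+") gpos - offset else gpos + offset
    out_reads[[i]] <- data.table::data.table(
      chrom = row$chrom, strand = row$strand, five_prime_pos = fp,
      length = read_lens[sample.int(length(read_lens), n_reads,
                                    replace = TRUE,
                                    prob = spec$read_lengths)],
      mismatches = rbinom(n_reads, 1L, spec$mismatch_rate),
      is_unique = runif(n_reads) >= spec$multimap_rate
    )
    out_truth[[i]] <- data.table::data.table(
      orf_id = row$orf_id, true_frame = frm, event = evlab,
      psite_local = loc
    )
  }
  reads <- data.table::rbindlist(out_reads)
  truth <- data.table::rbindlist(out_truth)
  if (nrow(reads) == 0L) {
    return(list(reads = empty_reads(),
                truth = data.frame(read_id = character(0),
                                   orf_id = character(0),
                                   true_frame = integer(0),
                                   event = character(0),
                                   psite_local = integer(0))))
  }
  ids <- sprintf("r%07d", seq_len(nrow(reads)))
  reads <- data.frame(read_id = ids, as.data.frame(reads),
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, as.data.frame(truth),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

# codons of the k-codon in-frame leader immediately 5' of the AUG,
# in transcript orientation, indices -k..-1
leader_codons <- function(genome, orf_row, k) {
  lead <- if (orf_row$strand == "+") {
    as.character(Biostrings::subseq(genome[[orf_row$chrom]],
                                    orf_row$cds_start - 3L * k,
                                    orf_row$cds_start - 1L))
  } else {
    revcomp_chr(as.character(Biostrings::subseq(genome[[orf_row$chrom]],
                                                orf_row$cds_end + 1L,
                                                orf_row$cds_end + 3L * k)))
  }
  substring(lead, 3L * seq_len(k) - 2L, 3L * seq_len(k))
}
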