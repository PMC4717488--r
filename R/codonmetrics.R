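#' Load a tRNA gene-copy table
#'
#' The table drives tAI computation and wobble-decoding classification.
#' Expected columns: anticodon (RNA or DNA alphabet, 5'->3'), amino_acid
#' (three-letter or one-letter code; the initiator methionine tRNA must be
#' excluded or labelled "iMet", in which case it is dropped), gene_copies,
#' inosine34 (logical: A34 modified to inosine), t6a37 (logical: position
#' 37 carries t6A).
#'
#' @param path TSV path; default is the bundled budding-yeast table
#'   compiled from genomic tRNA gene-copy numbers.
#' @return data.frame with normalized columns (anticodon in DNA alphabet).
#' @export
load_trna_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "yeast_trna_gene_copies.tsv",
                        package = "ribofidelity", mustWork = TRUE)
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("anticodon", "amino_acid", "gene_copies")
  if (!all(need %in% names(df))) {
    stop("tRNA table needs columns: ", paste(need, collapse = ", "))
  }
  df$anticodon <- rna_to_dna(df$anticodon)
  if (any(nchar(df$anticodon) != 3L)) stop("anticodons must be triplets")
  if (any(df$gene_copies < 0)) stop("gene copies must be >= 0")
  if (is.null(df$inosine34)) df$inosine34 <- FALSE
  if (is.null(df$t6a37)) df$t6a37 <- FALSE
  df <- df[df$amino_acid != "iMet", , drop = FALSE]
  aa_map <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  long <- df$amino_acid %in% names(aa_map)
  df$amino_acid[long] <- aa_map[df$amino_acid[long]]
  rownames(df) <- NULL
  df
}

trna_copies <- function(trna_table, anticodon, aa = NULL) {
  sel <- trna_table$anticodon == anticodon
  if (!is.null(aa)) sel <- sel & trna_table$amino_acid == aa
  if (!any(sel)) 0 else sum(trna_table$gene_copies[sel])
}

#' CAI weights from a reference gene set
#'
#' Classical relative-adaptiveness weights: within each synonymous family
#' the weight of a codon is its count divided by the family maximum, so
#' exactly one codon per family has weight 1. Codons unobserved in the
#' reference set receive a pseudo-count (default 0.5) before the ratio is
#' taken.
#'
#' @param ref_counts Named numeric vector of codon counts over the
#'   reference gene set (see [codon_usage()]).
#' @param pseudo Pseudo-count for unobserved codons.
#' @return Named numeric vector of weights over the 61 sense codons.
#' @export
compute_cai_weights <- function(ref_counts, pseudo = 0.5) {
  sense <- sense_codons()
  counts <- setNames(numeric(length(sense)), sense)
  names(ref_counts) <- rna_to_dna(names(ref_counts))
  common <- intersect(names(ref_counts), sense)
  counts[common] <- ref_counts[common]
  aa <- codon_aa(sense)
  missing_aa <- setdiff(unique(aa), unique(aa[counts > 0]))
  if (length(missing_aa)) {
    stop("amino acid(s) absent from reference set: ",
         paste(missing_aa, collapse = ", "))
  }
  w <- counts
  for (a in unique(aa)) {
    fam <- aa == a
    cc <- counts[fam]
    cc[cc == 0] <- pseudo
    w[fam] <- cc / max(cc)
  }
  w
}

#' Codon usage of a set of ORFs
#'
#' @param orfs An `orf_catalog`.
#' @param gene_ids Optional subset of orf_ids.
#' @return Named numeric vector of codon counts (64 codons; stops come
#'   from terminal stop codons).
#' @export
codon_usage <- function(orfs, gene_ids = NULL) {
  sel <- if (is.null(gene_ids)) orfs else
    orfs[orfs$orf_id %in% gene_ids, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no ORFs selected")
  m <- codon_count_matrix(sel$spliced_cds)
  colSums(m)
}

#' Gene-level CAI
#'
#' Geometric mean of CAI weights over a gene's codons, excluding stop
#' codons and (by default) the single-codon families Met and Trp.
#'
#' @param seqs Character vector of in-frame coding sequences.
#' @param w CAI weights from [compute_cai_weights()].
#' @param exclude Codons excluded from the mean.
#' @return Numeric vector of CAI values in (0, 1].
#' @export
gene_cai <- function(seqs, w, exclude = c("ATG", "TGG")) {
  m <- codon_count_matrix(seqs)
  use <- setdiff(intersect(colnames(m), names(w)), exclude)
  vapply(seq_len(nrow(m)), function(i) {
    n <- m[i, use]
    if (sum(n) == 0) return(NA_real_)
    exp(sum(n * log(w[use])) / sum(n))
  }, numeric(1))
}

# default wobble penalties, classical tAI parameterization
default_s_penalties <- function() {
  c("WC" = 0, "I34:U3" = 0, "G34:U3" = 0.41, "I34:C3" = 0.28,
    "I34:A3" = 0.9999, "U34:G3" = 0.68)
}

#' tRNA adaptation index weights
#'
#' For each sense codon, the absolute adaptiveness W is the sum over
#' anticodons able to decode it of `(1 - s) * gene_copies`, where `s` is
#' the selective penalty of the codon:anticodon pairing type: Watson-Crick
#' and inosine:U pair freely, while G34:U3, I34:C3, I34:A3 and U34:G3
#' wobble pairings are penalized. Wobble contributions are only counted
#' from anticodons of the codon's own amino acid, which keeps e.g.
#' isoleucine tRNAs from inflating the AUG weight. `w_tai = W / max(W)`;
#' codons with W = 0 get the geometric mean of the nonzero weights and are
#' flagged `imputed`.
#'
#' @param trna_table Output of [load_trna_table()].
#' @param s_penalties Named penalties in `[0, 1]` for pairing classes WC,
#'   I34:U3, G34:U3, I34:C3, I34:A3, U34:G3.
#' @return data.frame: codon, aa, W, w_tai, imputed.
#' @export
compute_tai <- function(trna_table, s_penalties = default_s_penalties()) {
  need <- names(default_s_penalties())
  missing <- setdiff(need, names(s_penalties))
  if (length(missing)) {
    stop("missing penalty class(es): ", paste(missing, collapse = ", "))
  }
  if (any(s_penalties < 0 | s_penalties > 1)) {
    stop("penalties must lie in [0, 1]")
  }
  if (sum(trna_table$gene_copies) == 0) stop("all tRNA gene copies are zero")
  sense <- sense_codons()
  aa <- codon_aa(sense)
  W <- numeric(length(sense))
  for (i in seq_along(sense)) {
    cod <- sense[i]
    third <- substr(cod, 3L, 3L)
    wc <- revcomp_chr(cod)            # exact Watson-Crick anticodon
    sib <- function(base34) paste0(base34, substr(wc, 2L, 3L))
    contrib <- switch(third,
      "T" = c(setNames(s_penalties[["I34:U3"]], sib("A")),
              setNames(s_penalties[["G34:U3"]], sib("G"))),
      "C" = c(setNames(s_penalties[["WC"]], sib("G")),
              setNames(s_penalties[["I34:C3"]], sib("A"))),
      "A" = c(setNames(s_penalties[["WC"]], sib("T")),
              setNames(s_penalties[["I34:A3"]], sib("A"))),
      "G" = c(setNames(s_penalties[["WC"]], sib("C")),
              setNames(s_penalties[["U34:G3"]], sib("T")))
    )
    W[i] <- sum(vapply(seq_along(contrib), function(j) {
      (1 - contrib[j]) * trna_copies(trna_table, names(contrib)[j], aa[i])
    }, numeric(1)))
  }
  if (max(W) == 0) stop("no codon is decodable under this table")
  w <- W / max(W)
  imputed <- w == 0
  if (any(imputed)) {
    gm <- exp(mean(log(w[!imputed])))
    w[imputed] <- gm
  }
  data.frame(codon = sense, aa = aa, W = W, w_tai = w, imputed = imputed,
             stringsAsFactors = FALSE)
}

#' Normalized translational efficiency (nTE)
#'
#' Balances tRNA supply against transcriptome-weighted codon demand:
#' `demand(c)` is the abundance-weighted count of codon c over all genes,
#' normalized to frequencies; `nte = w_tai / demand`, rescaled so the
#' maximum is 1. Invariant to uniform scaling of the abundances.
#'
#' @param tai Output of [compute_tai()] (or a named w_tai vector).
#' @param abundance data.frame with columns gene_id and abundance (>= 0,
#'   at least one positive), e.g. mRNA levels.
#' @param orfs An `orf_catalog` providing the coding sequences.
#' @return data.frame: codon, w_tai, demand, nte, defined (FALSE where
#'   demand is zero).
#' @export
compute_nte <- function(tai, abundance, orfs) {
  w <- if (is.data.frame(tai)) setNames(tai$w_tai, tai$codon) else tai
  if (any(abundance$abundance < 0) || all(abundance$abundance == 0)) {
    stop("abundances must be >= 0 with at least one positive value")
  }
  sel <- orfs[match(abundance$gene_id, orfs$orf_id), , drop = FALSE]
  if (anyNA(sel$orf_id)) {
    stop("abundance table references unknown gene(s): ",
         paste(abundance$gene_id[is.na(sel$orf_id)], collapse = ", "))
  }
  m <- codon_count_matrix(sel$spliced_cds)
  demand_raw <- colSums(m * abundance$abundance)
  sense <- sense_codons()
  demand <- demand_raw[sense] / sum(demand_raw[sense])
  defined <- demand > 0
  nte_raw <- ifelse(defined, w[sense] / demand, NA_real_)
  nte <- nte_raw / max(nte_raw, na.rm = TRUE)
  data.frame(codon = sense, w_tai = unname(w[sense]),
             demand = unname(demand), nte = unname(nte),
             defined = unname(defined),
             stringsAsFactors = FALSE)
}

#' Classify how a codon is decoded
#'
#' Determines the primary decoding route of each codon under a tRNA gene
#' table and the classical wobble rules: an exact Watson-Crick anticodon
#' when one exists with gene copies (an A34 anticodon counts as inosine,
#' not Watson-Crick, when flagged), otherwise the wobble route for the
#' codon's third base (G34:U3, I34:U3, I34:C3, I34:A3, or U34:G3 --
#' reported as "other-wobble"). The abundance class sums the gene copies
#' of the primary route: <= `rare_max_copies` is "rare".
#'
#' @param codons Character vector of sense codons (DNA or RNA alphabet).
#' @param trna_table Output of [load_trna_table()].
#' @param rare_max_copies Rare/abundant boundary in gene copies
#'   (default 4).
#' @return data.frame: codon, aa, category, decoder_anticodon (RNA
#'   display), decoder_copies, abundance_class, t6a_dependent.
#' @export
classify_decoding <- function(codons, trna_table, rare_max_copies = 4L) {
  codons <- rna_to_dna(codons)
  bad <- setdiff(codons, sense_codons())
  if (length(bad)) stop("not sense codon(s): ", paste(bad, collapse = ", "))
  rows <- lapply(codons, function(cod) {
    aa <- codon_aa(cod)
    third <- substr(cod, 3L, 3L)
    wc <- revcomp_chr(cod)
    sib <- function(base34) paste0(base34, substr(wc, 2L, 3L))
    has <- function(ac) trna_copies(trna_table, ac, aa) > 0
    ino <- function(ac) {
      sel <- trna_table$anticodon == ac & trna_table$amino_acid == aa
      any(sel) && any(trna_table$inosine34[sel])
    }
    route <- NULL
    if (third %in% c("C", "A", "G") && has(wc) &&
        !(substr(wc, 1, 1) == "A" && ino(wc))) {
      route <- list(cat = "Watson-Crick", ac = wc)
    } else if (third == "T") {
      if (has(sib("A")) && ino(sib("A"))) {
        route <- list(cat = "I34:U3", ac = sib("A"))
      } else if (has(sib("A"))) {
        route <- list(cat = "Watson-Crick", ac = sib("A"))
      } else if (has(sib("G"))) {
        route <- list(cat = "G34:U3", ac = sib("G"))
      }
    } else if (third == "C" && has(sib("A")) && ino(sib("A"))) {
      route <- list(cat = "I34:C3", ac = sib("A"))
    } else if (third == "A" && has(sib("A")) && ino(sib("A"))) {
      route <- list(cat = "I34:A3", ac = sib("A"))
    } else if (third == "G" && has(sib("T"))) {
      route <- list(cat = "other-wobble", ac = sib("T"))
    }
    if (is.null(route)) {
      stop("codon ", dna_to_rna(cod), " is not decodable under this table")
    }
    copies <- trna_copies(trna_table, route$ac, aa)
    sel <- trna_table$anticodon == route$ac & trna_table$amino_acid == aa
    data.frame(
      codon = dna_to_rna(cod), aa = aa, category = route$cat,
      decoder_anticodon = dna_to_rna(route$ac),
      decoder_copies = copies,
      abundance_class = if (copies <= rare_max_copies) "rare" else "abundant",
      t6a_dependent = any(trna_table$t6a37[sel]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank genes by t6A-dependent arginine-codon usage
#'
#' Arginine is split between codons read by t6A-carrying tRNAs (AGA, AGG)
#' and codons read by tRNAs without t6A (CGU, CGC, CGA, CGG). Genes using
#' only the former are maximally exposed to t6A loss.
#'
#' @param orfs An `orf_catalog`.
#' @return data.frame sorted by decreasing t6A-dependent fraction:
#'   gene_id, n_AGA, n_AGG, n_CGN, n_arg, t6a_fraction, exclusive_t6a.
#' @export
rank_arg_usage <- function(orfs) {
  m <- codon_count_matrix(orfs$spliced_cds)
  cgn <- c("CGT", "CGC", "CGA", "CGG")
  out <- data.frame(
    gene_id = orfs$orf_id,
    n_AGA = m[, "AGA"], n_AGG = m[, "AGG"],
    n_CGN = rowSums(m[, cgn, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  out$n_arg <- out$n_AGA + out$n_AGG + out$n_CGN
  out$t6a_fraction <- ifelse(out$n_arg > 0,
                             (out$n_AGA + out$n_AGG) / out$n_arg, NA_real_)
  out$exclusive_t6a <- out$n_arg > 0 & out$n_CGN == 0
  out <- out[order(-out$t6a_fraction, out$gene_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
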