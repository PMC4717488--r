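test_that("CAI weights are family-relative with one maximal codon per family", {
  set.seed(90)
  counts <- setNames(100 + 3 * sample(seq_len(61)), sense_codons())
  counts["AAA"] <- 60
  counts["AAG"] <- 40
  w <- compute_cai_weights(counts)
  expect_equal(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 40 / 60, tolerance = 1e-12)
  expect_equal(unname(w["ATG"]), 1)  # single-codon family
  aa <- codon_aa(sense_codons())
  for (a in unique(aa)) {
    expect_equal(sum(w[aa == a] == 1), 1)
  }
  # an amino acid entirely absent from the reference is an error naming it
  counts2 <- counts
  counts2[codon_aa(sense_codons()) == "W"] <- 0
  expect_error(compute_cai_weights(counts2), "W")
})

test_that("gene CAI is a geometric mean reaching 1 for all-maximal genes", {
  counts <- setNames(rep(10, 61), sense_codons())
  counts["AAA"] <- 60
  w <- compute_cai_weights(counts)
  best <- paste0("ATG", strrep("AAA", 10), "TGG")
  expect_equal(gene_cai(best, w), 1)
  mixed <- paste0("ATG", "AAA", "AAG")
  expect_equal(gene_cai(mixed, w), sqrt(1 * unname(w["AAG"])))
})

test_that("tAI follows the wobble-penalty model", {
  # one exact-match tRNA per codon, equal copies: absolute adaptiveness is
  # the Watson-Crick term plus the penalized same-aa sibling terms.
  # Hand plug-in for the valine box (copies 2, s = 0, 0.41, 0.28,
  # 0.9999, 0.68): GUU gets 2 + 2*(1-0.41), GUC 2 + 2*(1-0.28),
  # GUA 2 + 2*(1-0.9999), GUG 2 + 2*(1-0.68).
  toy <- do.call(rbind, lapply(sense_codons(), function(cod) {
    data.frame(anticodon = ribofidelity:::revcomp_chr(cod),
               amino_acid = codon_aa(cod), gene_copies = 2,
               inosine34 = FALSE, t6a37 = FALSE)
  }))
  toy <- unique(toy)
  tai <- compute_tai(toy)
  W <- setNames(tai$W, tai$codon)
  expect_equal(unname(W["GTT"]), 2 + 2 * 0.59, tolerance = 1e-12)
  expect_equal(unname(W["GTC"]), 2 + 2 * 0.72, tolerance = 1e-12)
  expect_equal(unname(W["GTA"]), 2 + 2 * 1e-4, tolerance = 1e-12)
  expect_equal(unname(W["GTG"]), 2 + 2 * 0.32, tolerance = 1e-12)
  # cross-amino-acid siblings never contribute: AAA (Lys) gains nothing
  # from the Asn anticodon AUU
  expect_equal(unname(W["AAA"]), 2, tolerance = 1e-12)
  expect_true(all(tai$w_tai > 0 & tai$w_tai <= 1))

  # codon decoded only via G34:U3 at s = 0.41 vs a Watson-Crick codon:
  # weight ratio 1 - 0.41
  toy2 <- data.frame(
    anticodon = c("GUU", "GUA"), amino_acid = c("N", "Y"),
    gene_copies = c(2, 2), inosine34 = FALSE, t6a37 = FALSE
  )
  toy2$anticodon <- rna_to_dna(toy2$anticodon)
  tai2 <- compute_tai(toy2)
  w_aat <- tai2$W[tai2$codon == "AAT"]  # GUU reads AAU via G:U
  w_tac <- tai2$W[tai2$codon == "TAC"]  # GUA reads UAC via Watson-Crick
  expect_equal(w_aat / w_tac, 1 - 0.41, tolerance = 1e-12)

  zero <- toy
  zero$gene_copies <- 0
  expect_error(compute_tai(zero), "zero")
  expect_error(compute_tai(load_trna_table(),
                           s_penalties = c("WC" = 0)), "penalty")
})

test_that("absolute tAI adaptiveness is monotone in gene copies", {
  trna <- load_trna_table()
  base <- compute_tai(trna)
  for (i in c(1L, 7L, 15L, 30L)) {
    boosted <- trna
    boosted$gene_copies[i] <- boosted$gene_copies[i] + 5
    after <- compute_tai(boosted)
    expect_true(all(after$W >= base$W - 1e-12))
    # codons whose W rose keep or improve their normalized weight ranking
    rose <- after$W > base$W + 1e-12
    if (any(rose)) {
      expect_true(all(rank(-after$w_tai)[rose] <= rank(-base$w_tai)[rose]))
    }
  }
})

test_that("nTE balances supply against transcriptome demand", {
  set.seed(91)
  spec <- simulation_spec(orf_lengths = rep(300L, 10), seed = 92)
  g <- make_genome(spec)
  tai <- compute_tai(load_trna_table())
  ab <- data.frame(gene_id = g$orfs$orf_id, abundance = runif(10, 1, 5))
  nte <- compute_nte(tai, ab, g$orfs)
  expect_equal(max(nte$nte, na.rm = TRUE), 1)

  # invariant to uniform scaling of abundances
  ab2 <- ab; ab2$abundance <- ab2$abundance * 1000
  nte2 <- compute_nte(tai, ab2, g$orfs)
  expect_equal(nte$nte, nte2$nte, tolerance = 1e-12)

  # raising one gene's abundance raises its codons' share of demand, and
  # so weakly lowers their nte, for codons the gene uses more heavily than
  # the rest of the transcriptome (direct recompute)
  ab3 <- ab; ab3$abundance[1] <- ab3$abundance[1] * 10
  nte3 <- compute_nte(tai, ab3, g$orfs)
  mm <- ribofidelity:::codon_count_matrix(g$orfs$spliced_cds)
  gene_share <- mm[1, sense_codons()] / sum(mm[1, sense_codons()])
  rest <- colSums(mm[-1, sense_codons(), drop = FALSE] *
                    ab$abundance[-1])
  rest_share <- rest / sum(rest)
  over <- nte$codon[gene_share[nte$codon] > rest_share[nte$codon] + 1e-9]
  sel <- nte$codon %in% over
  expect_gt(sum(sel), 0)
  expect_true(all(nte3$demand[sel] >= nte$demand[sel] - 1e-12))
  r_before <- nte$w_tai / nte$demand
  r_after <- nte3$w_tai / nte3$demand
  expect_true(all(r_after[sel] <= r_before[sel] + 1e-9))

  # uniform supply and uniform demand -> all nte equal
  uni_w <- setNames(rep(1, 61), sense_codons())
  one_each <- paste(c("ATG", sense_codons(), "TAA"), collapse = "")
  orfs1 <- data.frame(
    orf_id = "g1", chrom = "c", strand = "+", cds_start = 1,
    cds_end = nchar(one_each), n_exons = 1L, length_nt = nchar(one_each),
    spliced_cds = one_each, noncanonical_start = FALSE, truncated = FALSE,
    missing_stop = FALSE, internal_stop = FALSE
  )
  attr(orfs1, "exons") <- data.frame(orf_id = "g1", exon_rank = 1L,
                                     start = 1, end = nchar(one_each))
  class(orfs1) <- c("orf_catalog", "data.frame")
  nte_u <- compute_nte(uni_w, data.frame(gene_id = "g1", abundance = 2),
                       orfs1)
  # ATG appears twice in that gene; all singly-used codons tie
  single <- nte_u$codon != "ATG"
  expect_equal(length(unique(round(nte_u$nte[single], 12))), 1L)
})

test_that("decoding classification reproduces the canonical wobble examples", {
  trna <- load_trna_table()
  cls <- classify_decoding(c("AAU", "AUC", "AAG", "ACC", "AUA", "ACG",
                             "AGG", "AGU", "GCU", "CGG"), trna)
  get <- function(cod) cls[cls$codon == cod, ]
  expect_equal(get("AAU")$category, "G34:U3")        # tRNA-Asn(GUU)
  expect_equal(get("AUC")$category, "I34:C3")        # tRNA-Ile(IAU)
  expect_equal(get("ACC")$category, "I34:C3")        # tRNA-Thr(IGU)
  expect_equal(get("AAG")$category, "Watson-Crick")  # dedicated CUU
  expect_equal(get("GCU")$category, "I34:U3")
  expect_equal(get("AGU")$category, "G34:U3")
  expect_equal(get("AUA")$abundance_class, "rare")
  expect_equal(get("ACG")$abundance_class, "rare")
  expect_equal(get("AGG")$abundance_class, "rare")
  expect_equal(get("CGG")$abundance_class, "rare")
  expect_equal(get("AAG")$abundance_class, "abundant")
  expect_true(get("AAU")$t6a_dependent)
  expect_false(get("CGG")$t6a_dependent)

  empty <- trna[trna$amino_acid == "ZZZ", ]
  expect_error(classify_decoding("AAA", empty), "not decodable")
})

test_that("arginine-codon usage ranking matches a brute-force tally", {
  g1 <- paste0("ATG", "AGA", "AGA", "AGA", "TAA")
  g2 <- paste0("ATG", "AGA", "AGA", "CGG", "TAA")
  g3 <- paste0("ATG", "AAA", "CCC", "TAA")
  orfs <- data.frame(
    orf_id = c("g1", "g2", "g3"), chrom = "c", strand = "+",
    cds_start = 1, cds_end = 15, n_exons = 1L,
    length_nt = c(15L, 15L, 12L), spliced_cds = c(g1, g2, g3),
    noncanonical_start = FALSE, truncated = FALSE, missing_stop = FALSE,
    internal_stop = FALSE
  )
  attr(orfs, "exons") <- data.frame(orf_id = orfs$orf_id, exon_rank = 1L,
                                    start = 1, end = orfs$cds_end)
  class(orfs) <- c("orf_catalog", "data.frame")
  arg <- rank_arg_usage(orfs)
  expect_true(arg$exclusive_t6a[arg$gene_id == "g1"])
  expect_false(arg$exclusive_t6a[arg$gene_id == "g2"])
  expect_false(arg$exclusive_t6a[arg$gene_id == "g3"])
  expect_equal(arg$n_AGA[arg$gene_id == "g1"], 3)
  expect_equal(arg$n_CGN[arg$gene_id == "g2"], 1)

  # 20-gene toy genome: per-gene counts sum to the genome-wide tally
  spec <- simulation_spec(orf_lengths = rep(300L, 20), seed = 93)
  gg <- make_genome(spec)
  arg2 <- rank_arg_usage(gg$orfs)
  all_cods <- unlist(lapply(gg$orfs$spliced_cds, function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }))
  expect_equal(sum(arg2$n_AGA), sum(all_cods == "AGA"))
  expect_equal(sum(arg2$n_AGG), sum(all_cods == "AGG"))
  expect_equal(sum(arg2$n_CGN),
               sum(all_cods %in% c("CGT", "CGC", "CGA", "CGG")))
})
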