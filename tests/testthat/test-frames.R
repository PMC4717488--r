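test_that("filter_reads applies the three strict criteria and reports drops", {
  reads <- rbind(
    toy_reads("chr1", 100L, length = 27L),                 # short
    toy_reads("chr1", 100L, length = 28L, mismatches = 1L), # mismatch
    toy_reads("chr1", 100L, length = 28L, is_unique = FALSE), # multimap
    toy_reads("chr1", 100L, length = 29L),                 # long
    toy_reads("chr1", 100L, length = 28L)                  # clean
  )
  fl <- filter_reads(reads)
  expect_equal(nrow(fl$reads), 1L)
  expect_equal(unname(fl$report["dropped_length"]), 2L)
  expect_equal(unname(fl$report["dropped_mismatch"]), 1L)
  expect_equal(unname(fl$report["dropped_multimap"]), 1L)

  clean <- toy_reads("chr1", 1:50 + 100L)
  expect_equal(filter_reads(clean)$reads, clean)

  long_clean <- toy_reads("chr1", 1:10 + 100L, length = 30L)
  expect_equal(nrow(filter_reads(long_clean, read_length = 30L)$reads), 10L)
})

test_that("P-site assignment applies the +12 offset strand-symmetrically", {
  reads <- toy_reads("chr1", c(1000L, 1027L), strand = c("+", "-"))
  tr <- assign_psites(reads)
  expect_equal(tr$pos[tr$strand == "+"], 1012L)
  expect_equal(tr$pos[tr$strand == "-"], 1015L)
  expect_equal(attr(tr, "total_psites"), 2L)

  tr0 <- assign_psites(reads, offset = 0L)
  expect_setequal(tr0$pos, c(1000L, 1027L))

  g <- toy_genome(strrep("A", 1013))
  expect_warning(trb <- assign_psites(reads, genome = g), "outside")
  expect_equal(nrow(trb), 1L)
})

test_that("frame_of returns ORF-relative frames and NA outside the CDS", {
  g <- toy_genome(paste0(strrep("C", 10), "ATGAAACCCTAA", strrep("C", 10)))
  orfs <- toy_orfs(g, start = 11L, end = 22L)
  o <- orfs[1, ]
  expect_equal(frame_of(11L, o), 0L)   # first nt of start codon
  expect_equal(frame_of(12L, o), 1L)   # second nt of a codon
  expect_equal(frame_of(16L, o), 2L)
  expect_true(is.na(frame_of(10L, o))) # 1 nt upstream
  expect_true(is.na(frame_of(23L, o)))
})

test_that("windowing clamps to 3-9 near-equal codon-aligned windows", {
  expect_equal(nrow(window_orf(600L)), 3L)
  expect_equal(nrow(window_orf(6000L)), 9L)
  w <- window_orf(2700L)
  expect_equal(nrow(w), 9L)
  expect_true(all(w$end_nt - w$start_nt + 1L == 300L))
  # tiling without overlap, codon-aligned starts, sizes within 3 nt
  for (len in c(333L, 601L, 999L, 1502L, 2000L, 5000L, 12000L)) {
    len3 <- len - (len %% 3L)
    w <- window_orf(len3)
    expect_gte(nrow(w), 3L)
    expect_lte(nrow(w), 9L)
    expect_equal(w$start_nt[1], 1L)
    expect_equal(w$end_nt[nrow(w)], len3)
    expect_equal(w$start_nt[-1], head(w$end_nt, -1) + 1L)
    expect_true(all(w$start_nt %% 3L == 1L))
    sizes <- w$end_nt - w$start_nt + 1L
    expect_lte(max(sizes) - min(sizes), 3L)
  }
})

test_that("frame_profile matches a brute-force per-read loop and conserves counts", {
  set.seed(31)
  cds1 <- random_cds(60)   # 180 nt
  cds2 <- random_cds(80)   # 240 nt
  g <- toy_genome(paste0(
    strrep("A", 50), cds1, strrep("A", 50),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds2))),
    strrep("A", 50)
  ))
  orfs <- toy_orfs(g, start = c(51L, 281L), end = c(230L, 520L),
                   strand = c("+", "-"))
  pos <- sample(1:570, 50, replace = TRUE)
  strand <- sample(c("+", "-"), 50, replace = TRUE)
  track <- toy_track("chr1", pos, strand)
  prof <- frame_profile(track, orfs)
  oracle <- oracle_frame_profile(track, orfs)
  expect_equal(as.data.frame(prof), oracle, ignore_attr = TRUE)

  # conservation: window sums equal in-CDS P-site totals per ORF
  for (i in 1:2) {
    o <- orfs[i, ]
    in_cds <- track$strand == o$strand & track$pos >= o$cds_start &
      track$pos <= o$cds_end
    expect_equal(
      sum(prof[prof$orf_id == o$orf_id, c("n0", "n1", "n2")]),
      sum(track$count[in_cds])
    )
  }

  # all frame-0 reads -> all counts in n0; empty track -> all zero
  psites <- 51L + 3L * (0:59)
  tr0 <- toy_track("chr1", psites)
  p0 <- frame_profile(tr0, orfs[1, ])
  expect_true(all(p0$n1 == 0L & p0$n2 == 0L))
  expect_equal(sum(p0$n0), 60L)
  pe <- frame_profile(toy_track("chr1", integer(0)), orfs)
  expect_true(all(pe[, c("n0", "n1", "n2")] == 0L))
})

test_that("ambiguity calling flags off-frame windows at the thresholds", {
  prof <- data.frame(
    orf_id = rep(c("clean", "shifty", "edge"), each = 3),
    window_index = rep(1:3, 3),
    start_nt = 1L, end_nt = 100L,
    n0 = c(50L, 50L, 50L,   60L, 5L, 2L,   50L, 49L, 50L),
    n1 = c(0L, 0L, 0L,      0L, 55L, 58L,  0L, 47L, 0L),
    n2 = c(0L, 0L, 0L,      0L, 0L, 0L,    0L, 0L, 0L)
  )
  calls <- call_ambiguities(prof)
  expect_false(calls$ambiguous[calls$orf_id == "clean"])
  sh <- calls[calls$orf_id == "shifty", ]
  expect_true(sh$ambiguous)
  expect_equal(sh$offending_windows, "2,3")
  expect_equal(sh$dominant_offframe, "+1")
  # off-frame fraction 47/96 = 0.49 < 0.5 -> not ambiguous
  expect_false(calls$ambiguous[calls$orf_id == "edge"])
  # a window below the read floor cannot offend
  few <- data.frame(orf_id = "few", window_index = 1:3, start_nt = 1L,
                    end_nt = 100L, n0 = c(1L, 1L, 1L), n1 = c(20L, 0L, 0L),
                    n2 = 0L)
  expect_false(call_ambiguities(few)$ambiguous)
  expect_true(call_ambiguities(few, min_window_reads = 10L)$ambiguous)
})

test_that("locate_transition recovers programmed shift points", {
  spec <- simulation_spec(
    orf_lengths = 900L, depth = 30,
    events = data.frame(kind = "frameshift", orf_id = "ORF0001",
                        position = 100L, shift = 1L, penetrance = 1),
    seed = 41
  )
  g <- make_genome(spec)
  sim <- simulate_footprints(g$genome, g$orfs, spec)
  tr <- assign_psites(filter_reads(sim$reads)$reads)
  t_nt <- locate_transition(tr, g$orfs, "ORF0001", 1L)
  expect_lte(abs(t_nt - 300L), 3L)

  # degenerate: shift at the first codon
  spec1 <- simulation_spec(
    orf_lengths = 900L, depth = 30,
    events = data.frame(kind = "frameshift", orf_id = "ORF0001",
                        position = 1L, shift = 1L, penetrance = 1),
    seed = 42
  )
  g1 <- make_genome(spec1)
  sim1 <- simulate_footprints(g1$genome, g1$orfs, spec1)
  tr1 <- assign_psites(filter_reads(sim1$reads)$reads)
  expect_lte(locate_transition(tr1, g1$orfs, "ORF0001", 1L), 3L)

  # no off-frame reads -> none
  specc <- simulation_spec(orf_lengths = 900L, depth = 10, seed = 43)
  gc_ <- make_genome(specc)
  simc <- simulate_footprints(gc_$genome, gc_$orfs, specc)
  trc <- assign_psites(filter_reads(simc$reads)$reads)
  expect_true(is.na(locate_transition(trc, gc_$orfs, "ORF0001", 1L)))
})

test_that("global frame summary fractions and t-test behave", {
  spec <- simulation_spec(orf_lengths = rep(450L, 12), depth = 10,
                          background_offframe = 0.2, seed = 51)
  g <- make_genome(spec)
  sim <- simulate_footprints(g$genome, g$orfs, spec)
  tr <- assign_psites(filter_reads(sim$reads)$reads)
  fs <- global_frame_summary(tr, tr, g$orfs, min_orf_reads = 10L)
  expect_equal(sum(fs$fractions[1, c("f0", "f1", "f2")]), 1, tolerance = 1e-9)
  expect_equal(fs$fractions$f0[1], fs$fractions$f0[2])
  expect_equal(fs$statistic, 0)
  expect_equal(fs$p.value, 1)

  # doubled off-frame rate is detected across ORFs
  spec2 <- simulation_spec(orf_lengths = rep(450L, 120), depth = 6,
                           background_offframe = 0.2, seed = 52)
  g2 <- make_genome(spec2)
  simA <- simulate_footprints(g2$genome, g2$orfs, spec2)
  spec3 <- simulation_spec(orf_lengths = rep(450L, 120), depth = 6,
                           background_offframe = 0.4, seed = 53)
  simB <- simulate_footprints(g2$genome, g2$orfs, spec3)
  trA <- assign_psites(filter_reads(simA$reads)$reads)
  trB <- assign_psites(filter_reads(simB$reads)$reads)
  fs2 <- global_frame_summary(trA, trB, g2$orfs, min_orf_reads = 32L)
  expect_lt(fs2$p.value, 0.01)
  expect_gt(fs2$fractions$f0[1], fs2$fractions$f0[2])

  # all frame-0 in both -> f0 = 1 exactly
  psites <- g2$orfs$cds_start[1] + 3L * (0:50)
  tr1 <- toy_track("chrSim", psites)
  expect_error(global_frame_summary(tr1, tr1, g2$orfs), "fewer than 3")
  tr3 <- toy_track("chrSim", c(vapply(1:4, function(i)
    g2$orfs$cds_start[i] + 3L * (0:49), integer(50))))
  fs3 <- global_frame_summary(tr3, tr3, g2$orfs)
  expect_equal(fs3$fractions$f0, c(1, 1))
})
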