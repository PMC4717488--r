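# Per-ORF in-frame P-site codon table used by both dwell metrics.
# Returns data.table: orf_id, cidx (codon index of the P-site), count,
# restricted to the trimmed codon window; plus per-ORF metadata.
inframe_codon_psites <- function(track, orfs, trim_codons) {
  lp <- local_psites(track, orfs)
  lp <- lp[frame == 0L]
  meta <- data.table::data.table(
    orf_id = orfs$orf_id,
    n_sense = orfs$length_nt %/% 3L - 1L   # codons excluding the stop
  )
  lp[, cidx := (local + 2L) %/% 3L]
  lp <- merge(lp, meta, by = "orf_id")
  lp <- lp[cidx >= trim_codons + 1L & cidx <= n_sense - trim_codons]
  lp
}

site_shift <- c(E = -1L, P = 0L, A = 1L)

#' Count codons in the ribosomal E, P and A sites
#'
#' For every in-frame P-site (off-frame P-sites have no well-defined site
#' codons and are excluded), the codon under the P site is tallied
#' together with the codon one triplet downstream (A site, the decoding
#' site) and one upstream (E site). Sites whose codon falls outside the
#' coding sequence or on the stop codon are skipped for that site. The
#' first and last `trim_codons` codons of each ORF are excluded to keep
#' initiation and termination piling out of the dwell estimates.
#'
#' @param track A `psite_track`.
#' @param orfs An `orf_catalog`.
#' @param trim_codons ORF-end exclusion width in codons (default 5).
#' @param sample_id Optional label stored with the result.
#' @return A `site_codon_counts` object: list with `counts` (data.frame
#'   site x 61 sense codons, zero-filled), `orfs_with_reads`,
#'   `trim_codons`, `sample_id`.
#' @export
site_codon_counts <- function(track, orfs, trim_codons = 5L,
                              sample_id = NA_character_) {
  lp <- inframe_codon_psites(track, orfs, trim_codons)
  sense <- sense_codons()
  grid <- data.table::CJ(site = names(site_shift), codon = sense)
  if (nrow(lp) > 0L) {
    cods <- lapply(names(site_shift), function(s) {
      idx <- lp$cidx + site_shift[[s]]
      ok <- idx >= 1L & idx <= lp$n_sense
      if (!any(ok)) return(NULL)
      seqs <- orfs$spliced_cds[match(lp$orf_id[ok], orfs$orf_id)]
      data.table::data.table(
        site = s,
        codon = substring(seqs, 3L * idx[ok] - 2L, 3L * idx[ok]),
        count = lp$count[ok]
      )
    })
    tab <- data.table::rbindlist(cods[!vapply(cods, is.null, logical(1))])
    tab <- tab[codon %in% sense,
               .(count = sum(count)), by = .(site, codon)]
    out <- merge(grid, tab, by = c("site", "codon"), all.x = TRUE)
  } else {
    out <- grid
    out[, count := NA_integer_]
  }
  out <- as.data.frame(out)
  out$count[is.na(out$count)] <- 0L
  out$count <- as.integer(out$count)
  structure(
    list(counts = out,
         orfs_with_reads = sort(unique(lp$orf_id)),
         trim_codons = trim_codons,
         sample_id = sample_id),
    class = "site_codon_counts"
  )
}

#' @export
print.site_codon_counts <- function(x, ...) {
  cat("Site codon counts (", sum(x$counts$count), " in-frame P-sites, ",
      length(x$orfs_with_reads), " ORFs)\n", sep = "")
  invisible(x)
}

# codon frequencies over the trimmed windows of the given ORFs
background_codon_freq <- function(orfs, orf_ids, trim_codons) {
  sel <- orfs[orfs$orf_id %in% orf_ids, , drop = FALSE]
  sense <- sense_codons()
  tot <- setNames(numeric(length(sense)), sense)
  for (i in seq_len(nrow(sel))) {
    n_sense <- sel$length_nt[i] %/% 3L - 1L
    lo <- trim_codons + 1L
    hi <- n_sense - trim_codons
    if (hi < lo) next
    idx <- lo:hi
    cods <- substring(sel$spliced_cds[i], 3L * idx - 2L, 3L * idx)
    tt <- table(cods)
    keep <- intersect(names(tt), sense)
    tot[keep] <- tot[keep] + as.numeric(tt[keep])
  }
  if (sum(tot) == 0) stop("no background codons available")
  tot / sum(tot)
}

#' Codon occupancy (CO) per ribosomal site
#'
#' For each site, a codon's occupancy is its frequency among site codons
#' of the footprint P-sites divided by its background frequency among all
#' CDS codon positions of ORFs with at least one read. Under uniform
#' dwell, CO is 1 for every codon.
#'
#' @param counts A `site_codon_counts` object.
#' @param orfs The `orf_catalog` the counts came from.
#' @return data.frame: site, codon, count, f_site, f_bg, co, defined.
#' @export
codon_occupancy <- function(counts, orfs) {
  stopifnot(inherits(counts, "site_codon_counts"))
  df <- counts$counts
  if (sum(df$count) == 0L) stop("all-zero site codon counts")
  f_bg <- background_codon_freq(orfs, counts$orfs_with_reads,
                                counts$trim_codons)
  out <- do.call(rbind, lapply(split(df, df$site), function(d) {
    d$f_site <- d$count / sum(d$count)
    d
  }))
  out$f_bg <- unname(f_bg[out$codon])
  out$defined <- out$f_bg > 0
  out$co <- ifelse(out$defined, out$f_site / out$f_bg, NA_real_)
  rownames(out) <- NULL
  out[order(out$site, out$codon), ]
}

#' Ribosome residence time (RRT) per ribosomal site
#'
#' For every gene passing a read floor, the in-frame P-site density at
#' positions whose site-s codon is c is averaged and divided by the gene's
#' mean density; the per-codon value is the across-gene average, rescaled
#' to mean 1 over codons at each site. Per-gene normalization removes
#' expression-level confounding, making RRT robust to depth differences
#' between genes.
#'
#' @param track A `psite_track`.
#' @param orfs An `orf_catalog`.
#' @param min_gene_reads Per-gene in-frame P-site floor inside the trimmed
#'   window (default 100).
#' @param trim_codons ORF-end exclusion width in codons (default 5).
#' @return data.frame: site, codon, n_genes, rrt (NA for codons absent
#'   from every qualifying gene).
#' @export
ribosome_residence_time <- function(track, orfs, min_gene_reads = 100L,
                                    trim_codons = 5L) {
  lp <- inframe_codon_psites(track, orfs, trim_codons)
  if (nrow(lp) == 0L) stop("no qualifying genes: no in-frame P-sites")
  totals <- lp[, .(n = sum(count)), by = orf_id]
  qualifying <- totals$orf_id[totals$n >= min_gene_reads]
  if (length(qualifying) == 0L) {
    stop("no genes reach min_gene_reads = ", min_gene_reads)
  }
  if (length(qualifying) < 10L) {
    warning("only ", length(qualifying),
            " gene(s) reach min_gene_reads; RRT will be noisy")
  }
  sense <- sense_codons()
  acc <- list()
  for (g in qualifying) {
    row <- orfs[orfs$orf_id == g, ]
    n_sense <- row$length_nt %/% 3L - 1L
    lo <- trim_codons + 1L
    hi <- n_sense - trim_codons
    if (hi < lo) next
    idx <- lo:hi
    dens <- setNames(numeric(length(idx)), idx)
    sub <- lp[orf_id == g]
    dens[as.character(sub$cidx)] <- sub$count
    gene_mean <- mean(dens)
    cods <- substring(row$spliced_cds, 3L * (1:n_sense) - 2L,
                      3L * (1:n_sense))
    for (s in names(site_shift)) {
      site_idx <- idx + site_shift[[s]]
      ok <- site_idx >= 1L & site_idx <= n_sense
      d <- data.table::data.table(codon = cods[site_idx[ok]],
                                  density = dens[ok])
      r <- d[, .(val = mean(density) / gene_mean), by = codon]
      r[, site := s]
      acc[[length(acc) + 1L]] <- r
    }
  }
  all_r <- data.table::rbindlist(acc)
  all_r <- all_r[codon %in% sense]
  agg <- all_r[, .(n_genes = .N, rrt = mean(val)), by = .(site, codon)]
  grid <- data.table::CJ(site = names(site_shift), codon = sense)
  out <- merge(grid, agg, by = c("site", "codon"), all.x = TRUE)
  out[is.na(n_genes), n_genes := 0L]
  # mean-1 rescale per site over codons with defined values
  out[, rrt := rrt / mean(rrt, na.rm = TRUE), by = site]
  as.data.frame(out[order(site, codon)])
}

#' Full per-site per-codon dwell table for one sample
#'
#' Convenience wrapper combining raw counts, background frequencies,
#' codon occupancy and ribosome residence time.
#'
#' @inheritParams ribosome_residence_time
#' @param sample_id Label stored in the table.
#' @return data.frame: sample_id, site, codon, count, f_bg, co, rrt.
#' @export
site_codon_table <- function(track, orfs, min_gene_reads = 100L,
                             trim_codons = 5L, sample_id = "sample") {
  sc <- site_codon_counts(track, orfs, trim_codons, sample_id)
  co <- codon_occupancy(sc, orfs)
  rrt <- ribosome_residence_time(track, orfs, min_gene_reads, trim_codons)
  out <- merge(co[, c("site", "codon", "count", "f_bg", "co")],
               rrt[, c("site", "codon", "rrt")],
               by = c("site", "codon"))
  out <- data.frame(sample_id = sample_id, out, stringsAsFactors = FALSE)
  out[order(out$site, out$codon), ]
}

#' Compare dwell metrics between two samples
#'
#' Per-site, per-codon log2 fold-changes of codon occupancy and ribosome
#' residence time (second sample over first), optionally annotated with
#' the wobble-decoding category of each codon.
#'
#' @param table_ref,table_alt Outputs of [site_codon_table()] (e.g. wild
#'   type and mutant).
#' @param trna_table Optional tRNA gene table for decoding annotation
#'   (see [classify_decoding()]).
#' @return data.frame: site, codon, count_ref, count_alt, co_ref, co_alt,
#'   rrt_ref, rrt_alt, l2fc_co, l2fc_rrt, defined (both inputs positive),
#'   and, when `trna_table` is given, category and abundance_class.
#' @export
compare_site_tables <- function(table_ref, table_alt, trna_table = NULL) {
  m <- merge(table_ref, table_alt, by = c("site", "codon"),
             suffixes = c("_ref", "_alt"))
  out <- data.frame(
    site = m$site, codon = m$codon,
    count_ref = m$count_ref, count_alt = m$count_alt,
    co_ref = m$co_ref, co_alt = m$co_alt,
    rrt_ref = m$rrt_ref, rrt_alt = m$rrt_alt,
    stringsAsFactors = FALSE
  )
  ok_co <- !is.na(out$co_ref) & !is.na(out$co_alt) &
    out$co_ref > 0 & out$co_alt > 0
  ok_rrt <- !is.na(out$rrt_ref) & !is.na(out$rrt_alt) &
    out$rrt_ref > 0 & out$rrt_alt > 0
  out$l2fc_co <- ifelse(ok_co, log2(out$co_alt / out$co_ref), NA_real_)
  out$l2fc_rrt <- ifelse(ok_rrt, log2(out$rrt_alt / out$rrt_ref), NA_real_)
  out$defined <- ok_co & ok_rrt
  if (!is.null(trna_table)) {
    cls <- classify_decoding(unique(out$codon), trna_table)
    out$category <- cls$category[match(out$codon, cls$codon)]
    out$abundance_class <- cls$abundance_class[match(out$codon, cls$codon)]
  }
  out[order(out$site, out$codon), ]
}
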