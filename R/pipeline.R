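#' Combine CLR, FST and pi-ratio scans into one window table
#'
#' Runs the CLR scan (per population, 10-kb non-overlapping windows by
#' default) and windowed FST / per-population pi with the pi ratio
#' (wild over domesticated orientation is the caller's choice of pop1 /
#' pop2) on 50-kb sliding windows, and flags top-percentile candidates
#' for each statistic.
#'
#' @param x a `site_matrix` with populations pop1 (e.g., domesticated)
#'   and pop2 (e.g., wild).
#' @param layout a `genome_layout`.
#' @param pop1,pop2 population labels; the pi ratio is
#'   `pi(pop2) / pi(pop1)` so high values flag diversity loss in pop1.
#' @param clr_window CLR window size (default 10 kb, non-overlapping).
#' @param fstpi_window FST/pi window size (default 50 kb).
#' @param step FST/pi window step (default 10 kb).
#' @param top_fraction candidate quantile (default 0.01).
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @param min_snps minimum SNPs per FST window (default 10).
#' @param config a `sweep_config`.
#' @return list(clr = per-window CLR tables per population, fstpi =
#'   FST/pi window table, candidates = named list of candidate
#'   `interval_set`s).
#' @export
scan_sweeps <- function(x, layout, pop1 = "pop1", pop2 = "pop2",
                        clr_window = 10000, fstpi_window = 50000,
                        step = 10000, top_fraction = 0.01, maf_min = 0.05,
                        min_snps = 10, config = sweep_config()) {
  x <- filter_maf(x, maf_min)
  wins_clr <- make_windows(layout, clr_window, clr_window)
  wins_fp <- make_windows(layout, fstpi_window, step)
  clr1 <- clr_scan(x, pop1, wins_clr, config = config)
  clr2 <- clr_scan(x, pop2, wins_clr, config = config)
  fst <- windowed_fst(x, pop1, pop2, wins_fp, min_snps = min_snps)
  pi1 <- windowed_pi(x, pop1, wins_fp)
  pi2 <- windowed_pi(x, pop2, wins_fp)
  fstpi <- data.frame(chrom = wins_fp$chrom, start = wins_fp$start,
                      end = wins_fp$end, n_snps = fst$n_snps,
                      fst = fst$fst, pi_pop1 = pi1, pi_pop2 = pi2,
                      pi_ratio = ifelse(pi1 > 0, pi2 / pi1, NA_real_),
                      stringsAsFactors = FALSE)
  suppressWarnings({
    cand <- list(
      clr_pop1 = select_top_windows(wins_clr, clr1$clr, top_fraction),
      clr_pop2 = select_top_windows(wins_clr, clr2$clr, top_fraction),
      fst = select_top_windows(wins_fp, fstpi$fst, top_fraction),
      pi_ratio = select_top_windows(wins_fp, fstpi$pi_ratio, top_fraction))
  })
  list(clr = list(pop1 = clr1, pop2 = clr2), fstpi = fstpi,
       candidates = cand)
}

#' Drop candidate windows shared with a matched scan
#'
#' Removes candidate windows of `primary` that overlap any candidate
#' window of `matched` by at least 1 bp (used to clean the domesticated
#' top-CLR set against the wild scan).
#'
#' @param primary,matched `interval_set`s of candidate windows.
#' @return A filtered `interval_set`.
#' @export
remove_shared_candidates <- function(primary, matched) {
  if (nrow(primary) == 0 || nrow(matched) == 0) return(primary)
  drop <- IRanges::overlapsAny(as_granges(primary), as_granges(matched))
  interval_set(primary$chrom[!drop], primary$start[!drop],
               primary$end[!drop], layout_of(primary),
               score = primary$score[!drop])
}

#' End-to-end synthetic multiomics analysis
#'
#' Generates one seeded synthetic dataset (two-population genotypes with
#' sweeps, two-breed expression trajectories with time-shifted genes, and
#' bisulfite tracks whose differential regions are injected inside the
#' detected sweep windows), runs the sweep scan, DPG calling and DMR
#' calling, and computes the DMR-vs-sweep interval permutation
#' enrichment. Results are written under `out_dir`: candidate windows
#' (BED), DPG table (TSV), DMR table (TSV) and enrichment (JSON).
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed.
#' @param chrom_length chromosome length of the synthetic genome.
#' @param n_genes genes in the expression layer.
#' @param n_dmr injected DMR tiles.
#' @param n_perm permutations for the enrichment test.
#' @return list with the scan, DPG table, DMR table and
#'   `enrichment_result`, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1, chrom_length = 1e6,
                         n_genes = 100, n_dmr = 10, n_perm = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- genome_layout("chr1", chrom_length)
  sweep_spec <- data.frame(chrom = "chr1", center = chrom_length / 2,
                           alpha = 1e-5, pop = "pop1",
                           stringsAsFactors = FALSE)
  gg <- gen_genotypes(layout, n_per_pop = 20, snp_density = 0.002,
                      sweep_spec = sweep_spec, seed = seed)
  scan <- scan_sweeps(gg$genotypes, layout)
  cand <- scan$candidates$clr_pop1
  write_intervals(cand, file.path(out_dir, "sweep_candidates.bed"))
  # broaden the sweep region for DMR injection: candidate windows plus
  # 20 kb flanks, so injected DMRs sit inside the swept neighborhood
  flank_gr <- GenomicRanges::reduce(GenomicRanges::resize(
    as_granges(cand), IRanges::width(as_granges(cand)) + 40000,
    fix = "center"))
  GenomicRanges::start(flank_gr) <- pmax(GenomicRanges::start(flank_gr), 1)
  GenomicRanges::end(flank_gr) <- pmin(GenomicRanges::end(flank_gr),
                                       chrom_length)
  sweep_region <- granges_to_intervals(flank_gr, layout)
  ge <- gen_expression(n_genes = n_genes, phase = "prenatal",
                       dpg_fraction = 0.1, seed = seed + 1)
  dpgs <- call_dpgs(ge$query, ge$reference, n_boot = 50, seed = seed + 2)
  utils::write.table(dpgs, file.path(out_dir, "dpg_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- gen_methylome(layout, cpg_density = 0.01, reps = 3, n_dmr = n_dmr,
                      delta = 0.4, coverage_mean = 30,
                      dmr_regions = sweep_region, seed = seed + 3)
  dmrs <- call_dmr(gm$group1, gm$group2)
  utils::write.table(dmrs, file.path(out_dir, "dmr_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- dmrs[dmrs$significant, , drop = FALSE]
  enr <- NULL
  if (nrow(sig) > 0) {
    sig_iv <- interval_set(sig$chrom, sig$start, sig$end, layout)
    enr <- interval_permutation_test(sig_iv, sweep_region,
                                     statistic = "count_overlap",
                                     n_perm = n_perm, seed = seed + 4)
    jsonlite::write_json(unclass(enr),
                         file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(scan = scan, dpgs = dpgs, dmrs = dmrs, enrichment = enr,
                 truth = list(genotypes = gg$truth, expression = ge$truth,
                              methylome = gm$truth)))
}
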