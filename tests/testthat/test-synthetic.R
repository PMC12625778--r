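test_that("generators are pure functions of (config, seed)", {
  ly <- genome_layout("chr1", 50000)
  g1 <- gen_genotypes(ly, n_per_pop = 4, snp_density = 0.002, seed = 9)
  g2 <- gen_genotypes(ly, n_per_pop = 4, snp_density = 0.002, seed = 9)
  expect_identical(g1$genotypes$dosage, g2$genotypes$dosage)
  e1 <- gen_expression(n_genes = 10, seed = 5)
  e2 <- gen_expression(n_genes = 10, seed = 5)
  expect_identical(e1$query$values, e2$query$values)
  expect_identical(e1$truth, e2$truth)
  m1 <- gen_methylome(ly, seed = 4)
  m2 <- gen_methylome(ly, seed = 4)
  expect_identical(m1$group1[[1]], m2$group1[[1]])
  a1 <- gen_annotation(ly, n_genes = 3, seed = 2)
  a2 <- gen_annotation(ly, n_genes = 3, seed = 2)
  expect_identical(a1$sequences, a2$sequences)
})

test_that("sweep injection pushes derived-allele mass toward fixation near the center", {
  ly <- genome_layout("chr1", 400000)
  sw <- data.frame(chrom = "chr1", center = 2e5, alpha = 1e-5,
                   pop = "pop1", stringsAsFactors = FALSE)
  g <- gen_genotypes(ly, n_per_pop = 10, snp_density = 0.003,
                     sweep_spec = sw, seed = 21)
  af <- allele_freq(g$genotypes, "pop1")
  d <- abs(g$genotypes$pos - 2e5)
  near <- af[d <= 5000]
  far <- af[d > 100000]
  expect_gt(mean(near), mean(far))
  # neutral configuration: no systematic frequency difference
  g0 <- gen_genotypes(ly, n_per_pop = 10, snp_density = 0.003, seed = 21)
  daf <- abs(allele_freq(g0$genotypes, "pop1") -
               allele_freq(g0$genotypes, "pop2"))
  # independent Watterson draws per population give typical |dAF| well
  # below fixation, with essentially no fully fixed differences
  expect_lt(mean(daf), 0.35)
  expect_lt(mean(daf == 1), 0.01)
  expect_equal(nrow(g0$truth$fixed_diff_sites), 0)
  expect_error(gen_genotypes(ly, sweep_spec = data.frame(
    chrom = "chr1", center = 5e5, alpha = 1e-5, pop = "pop1")), "outside")
})

test_that("expression generator nulls, shifts and containers behave", {
  e0 <- gen_expression(n_genes = 20, dpg_fraction = 0, noise_sd = 0.1,
                       seed = 3)
  expect_equal(nrow(e0$truth), 0)
  # with no shift the two breeds differ only by noise
  mu_diff <- apply(e0$query$values, c(1, 2), mean) -
    apply(e0$reference$values, c(1, 2), mean)
  expect_lt(max(abs(mu_diff)), 0.5)
  expect_error(expression_time_course("b", "prenatal", "g", c(1, 2),
                                      array(0, c(1, 2, 1))), "3 stages")
  expect_equal(length(stage_times("prenatal")), 15)
  expect_equal(length(stage_times("postnatal")), 12)
  # positive shift makes the query (breed A) advanced: PAS > 0 noise-free
  e <- gen_expression(n_genes = 30, dpg_fraction = 0.3, noise_sd = 0,
                      reps = 2, delta_range = c(0.2, 0.2), seed = 8)
  d <- call_dpgs(e$query, e$reference, n_boot = 0)
  m <- merge(d, e$truth)
  expect_true(all(sign(m$pas) == sign(m$delta)))
})

test_that("methylome generator respects binomial support and injects recoverable shifts", {
  ly <- genome_layout("chr1", 100000)
  gm <- gen_methylome(ly, cpg_density = 0.01, reps = 3, n_dmr = 5,
                      delta = 0.4, coverage_mean = 30, seed = 6)
  for (s in c(gm$group1, gm$group2)) {
    expect_true(all(s$meth <= s$total))
    expect_true(all(s$meth >= 0))
  }
  # truth regions separate the group means by close to the full shift
  al <- sweepomics:::align_cpg_tables(c(gm$group1, gm$group2))
  diffs <- vapply(seq_len(nrow(gm$truth)), function(i) {
    sel <- al$chrom == gm$truth$chrom[i] & al$pos >= gm$truth$start[i] &
      al$pos < gm$truth$end[i]
    l1 <- rowMeans((al$meth / al$total)[sel, 1:3, drop = FALSE])
    l2 <- rowMeans((al$meth / al$total)[sel, 4:6, drop = FALSE])
    mean(l1 - l2)
  }, 0)
  expect_true(mean(abs(diffs) >= 0.3) >= 0.9)
  expect_equal(sign(diffs), sign(gm$truth$score))
})

test_that("synthetic annotation yields consistent gene structures and coding sequence", {
  ly <- genome_layout(c("chr1", "chr2"), c(60000, 40000))
  an <- gen_annotation(ly, n_genes = 5, seed = 12)
  expect_equal(length(an$universe), 5)
  for (g in seq_len(nrow(an$models))) {
    m <- sweepomics:::parse_gene_model(an$models[g, ])
    # exons within the transcript, sorted, non-overlapping
    expect_true(all(diff(m$exon_starts) > 0))
    expect_true(all(m$exon_ends > m$exon_starts))
    expect_equal(min(m$exon_starts), m$tx_start)
    expect_equal(max(m$exon_ends), m$tx_end)
    # exon union + intron union tile the gene span exactly
    ex_bp <- sum(m$exon_ends - m$exon_starts)
    intr_bp <- if (length(m$exon_starts) > 1)
      sum(utils::tail(m$exon_starts, -1) - utils::head(m$exon_ends, -1))
      else 0
    expect_equal(ex_bp + intr_bp, m$tx_end - m$tx_start)
    # CDS translates ATG...stop with no internal stop
    cds <- paste(vapply(seq_along(m$cds_starts), function(k)
      substr(an$sequences[[m$chrom]], m$cds_starts[k] + 1, m$cds_ends[k]),
      ""), collapse = "")
    if (m$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    expect_equal(nchar(cds) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  # trait classes only contain universe genes
  expect_true(all(unlist(an$traits) %in% an$universe))
})

test_that("format writers round-trip expression, CpG and gene-model tables", {
  e <- gen_expression(n_genes = 5, reps = 2, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(e$query, f)
  back <- read_expression(f)
  expect_equal(back$breed, e$query$breed)
  expect_equal(back$times, e$query$times)
  expect_equal(back$values, e$query$values, tolerance = 1e-12)
  ly <- genome_layout("chr1", 50000)
  gm <- gen_methylome(ly, seed = 1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cpg_table(gm$group1[[1]], f2)
  expect_equal(read_cpg_table(f2), gm$group1[[1]])
  an <- gen_annotation(ly, n_genes = 2, seed = 3)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(an$models, f3)
  expect_equal(read_gene_models(f3), an$models)
})
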