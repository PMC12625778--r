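test_that("admixture filter removes samples over the 20% threshold only", {
  anc <- data.frame(sample = c("w1", "w2", "w3", "e1", "e2"),
                    comp1 = c(0.95, 0.75, 0.80, 0.05, 0.10),
                    comp2 = c(0.05, 0.25, 0.20, 0.95, 0.90))
  assign <- c(w1 = "west", w2 = "west", w3 = "west",
              e1 = "east", e2 = "east")
  kept <- filter_admixed(anc, assign, threshold = 0.2)
  expect_false("w2" %in% kept)          # 0.25 opposite ancestry: removed
  expect_true("w3" %in% kept)           # exactly 0.20: retained
  expect_true(all(c("w1", "e1", "e2") %in% kept))
  expect_error(filter_admixed(anc, assign[-1]), "missing from assignment")
})

test_that("MAF filter removes sites strictly below the cutoff", {
  pops <- stats::setNames(rep(c("pop1", "pop2"), each = 5),
                          paste0("s", 1:10))
  # 10 diploids = 20 alleles: alt counts 1 (MAF .05), 0 (monomorphic),
  # 2 (MAF .1), 20 (MAF 0)
  dos <- matrix(0L, 4, 10, dimnames = list(NULL, names(pops)))
  dos[1, 1] <- 1L
  dos[3, 1] <- 2L
  dos[4, ] <- 2L
  m <- site_matrix(rep("chr1", 4), c(10, 20, 30, 40), rep("A", 4),
                   rep("G", 4), dos, pops)
  kept <- filter_maf(m, 0.05)
  expect_equal(kept$pos, c(10, 30))     # MAF .05 kept, 0s removed
  expect_equal(n_sites(filter_maf(m, 0)), 4)
})

test_that("background SFS counting, folding and projection", {
  pops <- c(a = "p", b = "p")
  # 2 diploids = 4 alleles; derived counts {1, 1, 3}
  dos <- matrix(c(1L, 0L, 1L, 0L, 1L, 2L), 3, 2,
                dimnames = list(NULL, names(pops)))
  m <- site_matrix(rep("chr1", 3), c(1, 2, 3), rep("A", 3), rep("G", 3),
                   dos, pops)
  s <- compute_background_sfs(m, "p", folded = FALSE, n0 = 4)
  expect_equal(s$probs, c(2 / 3, 0, 1 / 3))
  sf <- compute_background_sfs(m, "p", folded = TRUE, n0 = 4)
  expect_equal(sf$probs, c(1, 0))       # 1 and 3 fold to minor class 1
  # hypergeometric projection of one site J=2 of n=4 down to n0=2
  expect_equal(sweepomics:::project_site(2, 4, 2), c(1 / 6, 2 / 3, 1 / 6))
})

test_that("sweep class distribution is normalized, neutral in the limit, and matches enumeration", {
  cfg <- sweep_config()
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    b <- as.numeric(rgamma(n - 1, 1)); b <- b / sum(b)
    bg <- sfs(b, n)
    d <- runif(1, 10, 1e5)
    alpha <- 10^runif(1, -7, -2)
    p <- sweep_site_distribution(d, alpha, bg, cfg)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    # full-escape limit recovers the background
    p_neutral <- sweep_site_distribution(d, 30 / d, bg, cfg)
    expect_equal(p_neutral, bg$probs, tolerance = 1e-6)
  }
  # exact agreement with the independent triple enumeration
  bg <- sfs(c(2 / 3, 0, 1 / 3), 4)
  for (d in c(100, 1000, 2e4)) for (alpha in c(1e-5, 1e-4, 1e-3)) {
    expect_equal(sweep_site_distribution(d, alpha, bg, cfg),
                 oracle_sweep_dist(d, alpha, bg$probs, 4),
                 tolerance = 1e-12)
    expect_equal(sweep_site_probability(2, d, alpha, bg, cfg),
                 oracle_sweep_dist(d, alpha, bg$probs, 4)[2],
                 tolerance = 1e-12)
  }
  expect_error(sweep_site_probability(4, 100, 1e-4, bg, cfg),
               "out of range")
})

test_that("clr_scan equals brute-force recomputation on a tiny instance", {
  # 10-kb chromosome and alphas small enough that the neutral shortcut
  # never fires, so the oracle needs no shortcut logic
  ly <- genome_layout("chr1", 10000)
  pops <- c(a = "p", b = "p")
  pos <- c(500, 2100, 4800, 7300, 9100)
  dos <- matrix(c(1L, 0L, 2L, 1L, 0L, 1L, 1L, 1L, 2L, 1L), 5, 2,
                dimnames = list(NULL, names(pops)))
  m <- site_matrix(rep("chr1", 5), pos, rep("A", 5), rep("G", 5), dos, pops)
  bg <- compute_background_sfs(m, "p", folded = FALSE, n0 = 4)
  cfg <- sweep_config(alpha_grid = c(1e-6, 1e-5, 1e-4))
  w <- make_windows(ly, 2000, 2000)
  sc <- clr_scan(m, "p", w, bg, cfg)
  j <- rowSums(dos)
  for (wi in seq_len(nrow(w))) {
    center <- (w$start[wi] + w$end[wi]) / 2
    o <- oracle_clr(pos, j, center, cfg$alpha_grid, bg$probs, 4)
    expect_equal(sc$clr[wi], o$clr, tolerance = 1e-9)
    expect_equal(sc$alpha_hat[wi], o$alpha_hat)
  }
})

test_that("windowed pi matches single-site formulas and pairwise brute force", {
  ly <- genome_layout("chr1", 1000)
  pops <- c(a = "p")
  # one site, 1 derived of 2 alleles, 10-bp window -> pi = 1/10
  m1 <- site_matrix("chr1", 5, "A", "G",
                    matrix(1L, 1, 1, dimnames = list(NULL, "a")), pops)
  w <- interval_set("chr1", 0, 10, ly)
  expect_equal(windowed_pi(m1, "p", w), 1 / 10)
  # monomorphic window
  m0 <- site_matrix("chr1", 5, "A", "G",
                    matrix(0L, 1, 1, dimnames = list(NULL, "a")), pops)
  expect_equal(windowed_pi(m0, "p", w), 0)
  # 4 haplotypes, counts {2,1} in 100-bp window -> (4/6 + 3/6)/100
  pops2 <- c(a = "p", b = "p")
  hap <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 0))
  m2 <- matrix_from_haplotypes(hap, "chr1", c(10, 20), pops2)
  w2 <- interval_set("chr1", 0, 100, ly)
  expect_equal(windowed_pi(m2, "p", w2), 7 / 600)
  expect_equal(windowed_pi(m2, "p", w2), oracle_pi(hap, c(10, 20), 0, 100))
  # random haplotype property: pi == mean pairwise differences / length
  set.seed(11)
  for (i in 1:10) {
    S <- sample(3:12, 1)
    hap <- matrix(rbinom(8 * S, 1, runif(1, 0.2, 0.8)), 8, S)
    pos <- sort(sample(0:999, S))
    mm <- matrix_from_haplotypes(hap, "chr1",  pos,
                                 stats::setNames(rep("p", 4),
                                                 paste0("s", 1:4)))
    expect_equal(windowed_pi(mm, "p", w2), oracle_pi(hap, pos, 0, 100),
                 tolerance = 1e-12)
  }
})

test_that("windowed FST transcribes Weir-Cockerham and hits 1 on fixed differences", {
  ly <- genome_layout("chr1", 1000)
  pops <- stats::setNames(rep(c("p1", "p2"), each = 10),
                          paste0("s", 1:20))
  # all fixed differences: p1 = 1, p2 = 0 at every site
  dos <- cbind(matrix(2L, 12, 10), matrix(0L, 12, 10))
  colnames(dos) <- names(pops)
  m <- site_matrix(rep("chr1", 12), seq(10, 120, by = 10), rep("A", 12),
                   rep("G", 12), dos, pops)
  w <- interval_set("chr1", 0, 200, ly)
  expect_equal(windowed_fst(m, "p1", "p2", w)$fst, 1)
  # fewer SNPs than min_snps -> missing
  expect_true(is.na(windowed_fst(m, "p1", "p2", w, min_snps = 13)$fst))
  # random genotypes: ratio-of-sums of the directly transcribed a,b,c
  set.seed(5)
  dos2 <- matrix(sample(0:2, 12 * 20, replace = TRUE), 12, 20,
                 dimnames = list(NULL, names(pops)))
  m2 <- site_matrix(rep("chr1", 12), seq(10, 120, by = 10), rep("A", 12),
                    rep("G", 12), dos2, pops)
  comp <- sapply(seq_len(12), function(i) {
    g1 <- dos2[i, 1:10]; g2 <- dos2[i, 11:20]
    jt <- sum(g1) + sum(g2)
    if (jt == 0 || jt == 40) return(c(a = 0, b = 0, c = 0))
    oracle_wc_site(10, mean(g1) / 2, mean(g1 == 1), 10, mean(g2) / 2,
                   mean(g2 == 1))
  })
  expect_equal(windowed_fst(m2, "p1", "p2", w)$fst,
               sum(comp["a", ]) / sum(comp), tolerance = 1e-12)
})

test_that("top-window selection keeps ties and respects direction", {
  ly <- genome_layout("chr1", 100 * 1000)
  w <- make_windows(ly, 1000, 1000)
  scores <- as.numeric(1:100)
  top <- select_top_windows(w, scores, 0.01)
  expect_equal(nrow(top), 1)
  expect_equal(top$score, 100)
  scores2 <- c(rep(1, 97), 5, 5, 5)
  top2 <- select_top_windows(w, scores2, 0.01)
  expect_equal(nrow(top2), 3)           # ties at the threshold included
  expect_equal(nrow(select_top_windows(w, scores, 1.0)), 100)
  low <- select_top_windows(w, scores, 0.01, direction = "low")
  expect_equal(low$score, 1)
  expect_error(select_top_windows(w, rep(NA_real_, 100), 0.01), "missing")
})

test_that("delta-AF filter keeps near-fixed SNPs inside swept genes only", {
  ly <- genome_layout("chr1", 10000)
  pops <- stats::setNames(rep(c("p1", "p2"), c(6, 6)), paste0("s", 1:12))
  # site 1: af1 = 11/12 (~0.917), af2 = 0/12; inside gene
  # site 2: af1 = af2 = 0.5; inside gene
  # site 3: af1 = 1, af2 = 0; outside gene
  dos <- rbind(c(2L, 2L, 2L, 2L, 2L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
               c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
               c(2L, 2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L))
  colnames(dos) <- names(pops)
  m <- site_matrix(rep("chr1", 3), c(100, 200, 5000), rep("A", 3),
                   rep("G", 3), dos, pops)
  genes <- interval_set("chr1", 50, 300, ly)
  rec <- delta_af_filter(m, "p1", "p2", genes, delta_min = 0.7)
  expect_equal(rec$pos, 100)
  expect_equal(rec$delta_af, 11 / 12)
  # fixed differences have delta AF exactly 1
  g <- gen_genotypes(genome_layout("chr1", 50000), n_per_pop = 5,
                     snp_density = 0.002, fixed_diff_fraction = 0.3,
                     seed = 3)
  fd <- g$truth$fixed_diff_sites
  daf <- abs(allele_freq(g$genotypes, "pop1") -
               allele_freq(g$genotypes, "pop2"))
  expect_true(all(daf[g$genotypes$pos %in% fd$pos] == 1))
})
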