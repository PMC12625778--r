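cpg <- function(pos, meth, total, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = "+", meth = meth,
             total = total, stringsAsFactors = FALSE)
}

test_that("DMC coverage filter and group test behave", {
  g1 <- list(cpg(c(10, 20), c(27, 5), c(30, 30)),
             cpg(c(10, 20), c(28, 6), c(30, 9)),    # site 20 cov 9
             cpg(c(10, 20), c(25, 5), c(30, 30)))
  g2 <- list(cpg(c(10, 20), c(3, 5), c(30, 30)),
             cpg(c(10, 20), c(2, 5), c(30, 30)),
             cpg(c(10, 20), c(4, 5), c(30, 30)))
  res <- call_dmc(g1, g2, min_cov = 10)
  expect_equal(res$start, 10)               # site 20 excluded (coverage 9)
  expect_equal(res$meth_diff, 100 * (mean(c(27, 28, 25) / 30) -
                                       mean(c(3, 2, 4) / 30)))
  expect_true(res$significant)
  expect_equal(res$direction, "hyper")
  # independent likelihood-ratio oracle: closed-form binomial MLEs
  m1 <- c(27, 28, 25); m2 <- c(3, 2, 4); t1 <- t2 <- rep(30, 3)
  ll <- function(m, t, p) sum(dbinom(m, t, p, log = TRUE))
  p1 <- sum(m1) / sum(t1); p2 <- sum(m2) / sum(t2)
  p0 <- sum(m1 + m2) / sum(t1 + t2)
  lrt <- 2 * (ll(m1, t1, p1) + ll(m2, t2, p2) - ll(c(m1, m2), c(t1, t2), p0))
  expect_equal(res$p, pchisq(lrt, 1, lower.tail = FALSE), tolerance = 1e-6)
  # identical groups: zero difference, not significant
  same <- call_dmc(g1[c(1, 3)], g1[c(1, 3)], min_cov = 10)
  expect_equal(same$meth_diff, rep(0, nrow(same)))
  expect_false(any(same$significant))
  expect_warning(call_dmc(list(cpg(1, 1, 5)), list(cpg(1, 1, 5))),
                 "coverage")
})

test_that("GLM p-values agree with the closed-form LRT oracle on random tables", {
  set.seed(14)
  for (i in 1:20) {
    t1 <- rpois(3, 40) + 5; t2 <- rpois(3, 40) + 5
    m1 <- rbinom(3, t1, runif(1)); m2 <- rbinom(3, t2, runif(1))
    p_pkg <- sweepomics:::group_meth_test(m1, t1, m2, t2)
    ll <- function(m, t, p) sum(dbinom(m, t, pmin(pmax(p, 1e-12), 1 - 1e-12),
                                       log = TRUE))
    p1 <- sum(m1) / sum(t1); p2 <- sum(m2) / sum(t2)
    p0 <- sum(m1 + m2) / sum(t1 + t2)
    lrt <- 2 * (ll(m1, t1, p1) + ll(m2, t2, p2) -
                  ll(c(m1, m2), c(t1, t2), p0))
    expect_equal(p_pkg, pchisq(lrt, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("DMR tiling skips thin tiles and pools counts invariantly", {
  # tile 0: 3 CpGs, strong difference; tile 1: only 2 CpGs -> skipped
  g1 <- lapply(1:3, function(r) cpg(c(100, 300, 700, 1200, 1500),
                                    c(27, 26, 28, 5, 6), rep(30, 5)))
  g2 <- lapply(1:3, function(r) cpg(c(100, 300, 700, 1200, 1500),
                                    c(3, 4, 2, 5, 6), rep(30, 5)))
  res <- call_dmr(g1, g2, window = 1000)
  expect_equal(res$start, 0)
  expect_true(res$significant)
  expect_equal(res$n_cpg, 3L)
  expect_gt(res$meth_diff, 30)
  # splitting one sample's counts across duplicate rows leaves pooled
  # levels unchanged
  split1 <- lapply(g1, function(t)
    rbind(transform(t, meth = floor(meth / 2), total = floor(total / 2)),
          transform(t, meth = meth - floor(meth / 2),
                    total = total - floor(total / 2))))
  lev <- function(tabs) {
    al <- sweepomics:::align_cpg_tables(tabs)
    colSums(al$meth) / colSums(al$total)
  }
  expect_equal(lev(split1), lev(g1))
  expect_error(call_dmr(g1, g2, window = 1000, step = 500), "step")
})

test_that("feature methylation pools counts and respects strand", {
  models <- data.frame(
    gene = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
    tx_start = c(5000, 20000), tx_end = c(8000, 23000),
    exon_starts = c("5000", "20000"), exon_ends = c("8000", "23000"),
    cds_starts = c("5100", "20100"), cds_ends = c("7900", "22900"),
    stringsAsFactors = FALSE)
  # promoter of gp = [3000, 7000); CpGs at 3500 (5/10) and 4000 (10/10)
  samples <- list(cpg(c(3500, 4000, 21500), c(5, 10, 4), c(10, 10, 10)))
  fm <- feature_methylation(samples, models, promoter_flank = 2000)
  expect_equal(fm$promoter[fm$gene == "gp"], 0.75)
  expect_equal(fm$gene_body[fm$gene == "gm"], 0.4)
  expect_true(is.na(fm$gene_body[fm$gene == "gp"]))
  # minus-strand promoter sits around the rightmost coordinate:
  # [TSS - 2000, TSS + 2000) = [21000, 25000) for gm
  expect_equal(fm$promoter[fm$gene == "gm"], 0.4)
  samples2 <- list(cpg(c(22950, 24500), c(10, 0), c(10, 10)))
  fm2 <- feature_methylation(samples2, models, promoter_flank = 2000)
  expect_equal(fm2$promoter[fm2$gene == "gm"], 0.5)
  expect_true(is.na(fm2$gene_body[fm2$gene == "gp"]))
})

test_that("methylation-expression correlation filters expression range", {
  lv <- c(a = 0.9, b = 0.7, c = 0.5, d = 0.3, e = 0.1)
  ex <- c(a = 1, b = 3, c = 5, d = 7, e = 9)
  r <- methylation_expression_correlation(lv, ex)
  expect_equal(r$r, -1)
  expect_equal(r$n, 5)
  ex2 <- ex; ex2["a"] <- 25                  # above the [0, 20] band
  r2 <- methylation_expression_correlation(lv, ex2)
  expect_equal(r2$n, 4)
  # hand-computed Pearson on 5 listed pairs
  lv3 <- c(a = 0.2, b = 0.8, c = 0.4, d = 0.9, e = 0.1)
  ex3 <- c(a = 2, b = 11, c = 6, d = 13, e = 1)
  expect_equal(methylation_expression_correlation(lv3, ex3)$r,
               cov(lv3, ex3) / (sd(lv3) * sd(ex3)))
  expect_error(methylation_expression_correlation(lv[1:2], ex[1:2]),
               "fewer than 3")
})

test_that("persistence grouping bins significant stage counts", {
  mk <- function(start, sig, dir) {
    data.frame(chrom = "chr1", start = start, end = start + 1000,
               n_cpg = 3L, meth_diff = ifelse(dir == "hypo", -40, 40),
               p = 1e-9, q = 1e-6, direction = dir, significant = sig,
               stage = NA_character_, stringsAsFactors = FALSE)
  }
  # tile 0: significant in 12/15 prenatal stages (hypo); tile 1000: 3
  # stages (hyper); tile 2000: never significant
  stages <- lapply(1:15, function(s) {
    rbind(mk(0, s <= 12, "hypo"), mk(1000, s <= 3, "hyper"),
          mk(2000, FALSE, "hyper"))
  })
  pg <- persistence_groups(stages, "prenatal")
  t0 <- pg$tiles[pg$tiles$tile == "chr1:0", ]
  expect_equal(as.character(t0$group), "high")
  expect_equal(t0$n_significant, 12L)
  t1 <- pg$tiles[pg$tiles$tile == "chr1:1000", ]
  expect_equal(as.character(t1$group), "low")
  expect_false("chr1:2000" %in% pg$tiles$tile)
  expect_equal(pg$groups$hypo_fraction[pg$groups$group == "high"], 1)
  expect_equal(pg$groups$hypo_fraction[pg$groups$group == "low"], 0)
  bad <- stages
  bad[[1]]$end <- bad[[1]]$start + 500
  expect_error(persistence_groups(bad, "prenatal"), "mixed tilings")
})
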