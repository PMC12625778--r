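# Independent oracle implementations used across the suite. These follow
# the definitions directly (full enumeration, no shortcuts, no shared
# code with the package internals).

# Hitchhiking class distribution by direct triple enumeration over
# (escaped e, pre-sweep draw j', ancestor state). b: unfolded background
# over j = 1..n-1.
oracle_sweep_dist <- function(d, alpha, b, n, d_min = 1) {
  p_e <- 1 - exp(-alpha * max(d, d_min))
  tot <- numeric(n + 1)                       # final counts f = 0..n
  for (e in 0:n) {
    we <- dbinom(e, n, p_e)
    if (e == n) {
      tot[2:n] <- tot[2:n] + we * b
      next
    }
    m <- e + 1
    for (jsrc in seq_len(n - 1)) {
      if (b[jsrc] == 0) next
      for (jp in 0:m) {
        w <- b[jsrc] * dhyper(jp, jsrc, n - jsrc, m)
        if (w == 0) next
        if (jp > 0)                            # ancestor carries derived
          tot[(n - e + jp - 1) + 1] <- tot[(n - e + jp - 1) + 1] +
            we * w * jp / m
        tot[jp + 1] <- tot[jp + 1] + we * w * (1 - jp / m)
      }
    }
  }
  tot[2:n] / sum(tot[2:n])
}

# Brute-force CLR for one window center: direct sum over SNPs and grid
# maximization, P_sweep by oracle_sweep_dist (no neutral shortcut; use
# grids/distances where the shortcut never fires).
oracle_clr <- function(pos, j, center, alphas, b, n, d_min = 1) {
  lls <- vapply(alphas, function(a) {
    sum(vapply(seq_along(pos), function(i) {
      p <- oracle_sweep_dist(abs(pos[i] - center), a, b, n, d_min)
      log(p[j[i]]) - log(b[j[i]])
    }, 0))
  }, 0)
  list(clr = 2 * max(lls), alpha_hat = alphas[which.min(-lls)])
}

# Exhaustive DTW: minimal cost over all monotone paths with steps
# {(1,0),(0,1),(1,1)}, anchored endpoints.
oracle_dtw_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(cost[1, 1])
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    best + cost[i, j]
  }
  rec(n, m)
}

# Weir & Cockerham (1984) per-site components, transcribed directly from
# the published formulas for r populations (here r = 2), using diploid
# sample sizes n_i, allele frequencies p_i and het frequencies h_i.
oracle_wc_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# Upper-tail hypergeometric by direct summation of binomial coefficients.
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Build a site_matrix from a haplotype matrix (n_hap rows x S sites,
# 0/1; consecutive row pairs form one diploid), keeping the haplotypes
# available for pairwise-difference oracles.
matrix_from_haplotypes <- function(hap, chrom, pos, populations,
                                   layout = NULL) {
  n_dip <- nrow(hap) / 2
  S <- ncol(hap)
  dosage <- matrix(0L, S, n_dip)
  for (i in seq_len(n_dip))
    dosage[, i] <- as.integer(hap[2 * i - 1, ] + hap[2 * i, ])
  colnames(dosage) <- names(populations)
  site_matrix(chrom = rep(chrom, S), pos = pos,
              ref = rep("A", S), alt = rep("G", S),
              dosage = dosage, populations = populations, layout = layout)
}

# Mean pairwise difference count between haplotypes in a window / length.
oracle_pi <- function(hap, pos, start, end) {
  sel <- which(pos >= start & pos < end)
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hap[i, sel] != hap[j, sel])
  tot / choose(n, 2) / (end - start)
}
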