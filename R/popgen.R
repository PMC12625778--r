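#' Site frequency spectrum
#'
#' Normalized masses over allele-count classes for a fixed haploid sample
#' size: derived-count classes j = 1..n-1 (unfolded) or minor-count classes
#' m = 1..floor(n/2) (folded). The background SFS is the neutral reference
#' of the composite-likelihood sweep test.
#'
#' @param probs numeric vector of class masses (normalized internally).
#' @param n haploid sample size.
#' @param folded logical.
#' @return An object of class `sfs`.
#' @export
sfs <- function(probs, n, folded = FALSE) {
  n <- as.integer(n)
  nclass <- if (folded) n %/% 2 else n - 1L
  if (length(probs) != nclass)
    stop("probs must have length ", nclass, " for n = ", n,
         if (folded) " (folded)" else " (unfolded)")
  if (any(probs < 0)) stop("SFS masses must be non-negative")
  s <- sum(probs)
  if (s <= 0) stop("SFS has zero total mass")
  structure(list(probs = probs / s, n = n, folded = folded), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s SFS, n = %d haploids, %d classes\n",
              if (x$folded) "folded" else "unfolded", x$n, length(x$probs)))
  invisible(x)
}

# Hypergeometric projection of one site with j derived of n called alleles
# down to n0 alleles; returns masses over classes 0..n0.
project_site <- function(j, n, n0) {
  stats::dhyper(0:n0, j, n - j, n0)
}

# Per-site derived (alt) count and called-allele count for one population.
site_counts <- function(x, population) {
  idx <- pop_samples(x, population)
  if (length(idx) == 0) stop("no samples in population ", population)
  d <- x$dosage[, idx, drop = FALSE]
  list(j = rowSums(d, na.rm = TRUE), n = 2 * rowSums(!is.na(d)))
}

#' Alternate-allele frequency per site for one population
#'
#' @param x a `site_matrix`.
#' @param population population label.
#' @return numeric vector of frequencies (NA where no allele called).
#' @export
allele_freq <- function(x, population) {
  sc <- site_counts(x, population)
  ifelse(sc$n > 0, sc$j / sc$n, NA_real_)
}

#' Background site frequency spectrum of a population
#'
#' Every segregating site is hypergeometrically projected to `n0` called
#' alleles (sites with fewer called alleles are dropped; projection mass on
#' the monomorphic classes is discarded); class masses are accumulated and
#' normalized. Folding merges classes j and n0 - j.
#'
#' @param x a `site_matrix`.
#' @param population population label.
#' @param folded logical; fold to minor-allele classes (default TRUE: no
#'   ancestral polarization is assumed).
#' @param n0 projection size (haploid); default the 20th percentile of the
#'   per-site called-allele counts.
#' @return An `sfs`; `n0` used is in the `n` field.
#' @export
compute_background_sfs <- function(x, population, folded = TRUE, n0 = NULL) {
  sc <- site_counts(x, population)
  if (is.null(n0))
    n0 <- as.integer(stats::quantile(sc$n[sc$n >= 2], 0.2, type = 1))
  n0 <- as.integer(n0)
  if (n0 < 2) stop("projection size n0 must be >= 2")
  keep <- sc$n >= n0 & sc$j > 0 & sc$j < sc$n
  if (!any(keep)) stop("no usable segregating sites for population ", population)
  counts <- numeric(n0 + 1)
  jj <- sc$j[keep]; nn <- sc$n[keep]
  for (i in seq_along(jj))
    counts <- counts + project_site(jj[i], nn[i], n0)
  poly <- counts[2:n0]           # classes 1..n0-1
  if (sum(poly) <= 0) stop("projected spectrum has no polymorphic mass")
  if (folded) {
    m_max <- n0 %/% 2
    fp <- vapply(seq_len(m_max), function(m)
      if (m == n0 - m) poly[m] else poly[m] + poly[n0 - m], 0)
    sfs(fp, n0, folded = TRUE)
  } else {
    sfs(poly, n0, folded = FALSE)
  }
}

#' Sweep model configuration
#'
#' @param alpha_grid per-bp sweep intensities, strictly increasing; default
#'   50 log-spaced values in `[1e-7, 1e-1]`.
#' @param d_min_clamp minimum distance (bp) used in the escape probability.
#' @param neutral_shortcut_tol sites with escape probability above
#'   `1 - neutral_shortcut_tol` contribute a zero log-ratio without being
#'   evaluated.
#' @param polymorphic_mass_floor below this polymorphic mass the sweep
#'   distribution falls back to the background.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(alpha_grid = 10^seq(-7, -1, length.out = 50),
                         d_min_clamp = 1,
                         neutral_shortcut_tol = 1e-6,
                         polymorphic_mass_floor = 1e-12) {
  if (any(diff(alpha_grid) <= 0) || any(alpha_grid <= 0))
    stop("alpha_grid must be strictly increasing and positive")
  structure(list(alpha_grid = alpha_grid, d_min_clamp = d_min_clamp,
                 neutral_shortcut_tol = neutral_shortcut_tol,
                 polymorphic_mass_floor = polymorphic_mass_floor),
            class = "sweep_config")
}

# Unfolded background vector over j = 1..n-1 from an sfs, symmetrizing a
# folded spectrum (mass split equally between j and n-j).
unfold_background <- function(background) {
  n <- background$n
  if (!background$folded) return(background$probs)
  b <- numeric(n - 1)
  for (m in seq_along(background$probs)) {
    if (m == n - m) b[m] <- background$probs[m]
    else {
      b[m] <- background$probs[m] / 2
      b[n - m] <- background$probs[m] / 2
    }
  }
  b
}

# Star-genealogy hitchhiking transition matrix. Row e (0..n escaped
# lineages), column f (0..n final derived count): distribution of the
# post-sweep derived count given e. The e escapees plus the one sweeping
# ancestor are e+1 exchangeable draws from the pre-sweep population
# (background projected to m = e+1, monomorphic outcomes included); the
# ancestor carries the derived allele with probability j'/m, in which case
# the n-e hitchhiking lineages all inherit it.
sweep_transition <- function(background) {
  n <- background$n
  b <- unfold_background(background)
  T <- matrix(0, n + 1, n + 1)
  for (e in 0:(n - 1)) {
    m <- e + 1
    pm <- numeric(m + 1)
    for (j in seq_len(n - 1))
      if (b[j] > 0) pm <- pm + b[j] * stats::dhyper(0:m, j, n - j, m)
    for (jp in 0:m) {
      if (pm[jp + 1] == 0) next
      pder <- jp / m
      if (pder > 0) {
        f_der <- n - e + jp - 1
        T[e + 1, f_der + 1] <- T[e + 1, f_der + 1] + pm[jp + 1] * pder
      }
      T[e + 1, jp + 1] <- T[e + 1, jp + 1] + pm[jp + 1] * (1 - pder)
    }
  }
  T[n + 1, 2:n] <- b
  T
}

# Class-indexed columns of the transition matrix: unfolded class j maps to
# column j+1; folded class m sums columns m+1 and n-m+1.
class_columns <- function(T, background) {
  n <- background$n
  if (!background$folded) {
    T[, 2:n, drop = FALSE]
  } else {
    m_max <- n %/% 2
    sapply(seq_len(m_max), function(m)
      if (m == n - m) T[, m + 1] else T[, m + 1] + T[, n - m + 1])
  }
}

#' Post-sweep class distribution at one locus
#'
#' Full distribution of the observed allele-count class at distance `d`
#' from a sweep of per-bp intensity `alpha`, under the star-genealogy
#' hitchhiking approximation: each lineage escapes the sweep with
#' probability `p_e = 1 - exp(-alpha * max(d, d_min_clamp))`; conditional
#' on e ~ Binomial(n, p_e) escapees, the escapees plus one sweeping
#' ancestor are exchangeable draws from the background. Mass is
#' renormalized over polymorphic outcomes; if the polymorphic mass falls
#' below the configured floor the background itself is returned.
#'
#' @param d distance in bp (>= 0).
#' @param alpha per-bp sweep intensity.
#' @param background an `sfs`.
#' @param config a `sweep_config`.
#' @param transition optional precomputed [sweep_transition()] matrix.
#' @return numeric vector of class probabilities (length = number of SFS
#'   classes), summing to 1.
#' @export
sweep_site_distribution <- function(d, alpha, background,
                                    config = sweep_config(),
                                    transition = NULL) {
  n <- background$n
  if (d < 0) stop("d must be >= 0")
  if (is.null(transition)) transition <- sweep_transition(background)
  p <- 1 - exp(-alpha * max(d, config$d_min_clamp))
  w <- stats::dbinom(0:n, n, p)
  M <- as.vector(w %*% transition)
  Z <- sum(M[2:n])
  if (Z < config$polymorphic_mass_floor) return(background$probs)
  if (background$folded) {
    m_max <- n %/% 2
    vapply(seq_len(m_max), function(m)
      if (m == n - m) M[m + 1] / Z else (M[m + 1] + M[n - m + 1]) / Z, 0)
  } else {
    M[2:n] / Z
  }
}

#' Probability of one allele-count class under the sweep model
#'
#' @param j class index: derived count (unfolded) or minor count (folded).
#' @param d distance in bp.
#' @param alpha per-bp sweep intensity.
#' @param background an `sfs`.
#' @param config a `sweep_config`.
#' @param transition optional precomputed transition matrix.
#' @return scalar probability.
#' @export
sweep_site_probability <- function(j, d, alpha, background,
                                   config = sweep_config(),
                                   transition = NULL) {
  nclass <- length(background$probs)
  if (any(j < 1) || any(j > nclass))
    stop("class index j out of range 1..", nclass)
  p <- sweep_site_distribution(d, alpha, background, config, transition)
  p[j]
}

# Map per-site (j, n_s) to a class index at projection size n0; 0 = drop.
site_class_index <- function(j, ns, background) {
  n0 <- background$n
  j0 <- ifelse(ns == n0, j, round(j * n0 / pmax(ns, 1)))
  j0[ns < n0] <- 0
  j0[j0 <= 0 | j0 >= n0] <- 0
  if (background$folded) {
    m <- pmin(j0, n0 - j0)
    m[j0 == 0] <- 0
    m
  } else j0
}

#' Composite-likelihood-ratio sweep scan
#'
#' For each window center x, `CLR(x) = 2 * max_alpha sum_i [log
#' P_sweep(j_i | |s_i - x|, alpha) - log b_{j_i}]` over the segregating
#' sites of the chromosome, maximized over the intensity grid. `alpha_hat`
#' is the argmax (first grid point on ties). Windows on chromosomes with
#' no usable site get NA.
#'
#' @param x a `site_matrix`.
#' @param population population label scanned for sweeps.
#' @param windows an `interval_set` of scan windows.
#' @param background an `sfs` for the same population (computed with
#'   [compute_background_sfs()] if omitted).
#' @param config a `sweep_config`.
#' @return data.frame: chrom, start, end, snp_count, clr, alpha_hat.
#' @export
clr_scan <- function(x, population, windows, background = NULL,
                     config = sweep_config()) {
  if (is.null(background))
    background <- compute_background_sfs(x, population)
  n0 <- background$n
  T <- sweep_transition(background)
  Tpoly <- rowSums(T[, 2:n0, drop = FALSE])
  Tclass <- class_columns(T, background)
  bclass <- background$probs
  sc <- site_counts(x, population)
  cls <- site_class_index(sc$j, sc$n, background)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, snp_count = NA_integer_,
                    clr = NA_real_, alpha_hat = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    ssel <- which(x$chrom == ch & cls > 0)
    if (length(ssel) == 0) next
    pos <- x$pos[ssel]
    centers <- (windows$start[wsel] + windows$end[wsel]) / 2
    res <- clr_scan_cpp(T, Tpoly, Tclass, bclass, pos, cls[ssel],
                        centers, config$alpha_grid, config$d_min_clamp,
                        config$neutral_shortcut_tol,
                        config$polymorphic_mass_floor)
    out$clr[wsel] <- res$clr
    out$alpha_hat[wsel] <- config$alpha_grid[res$alpha_idx]
    out$snp_count[wsel] <- vapply(wsel, function(w)
      sum(pos >= windows$start[w] & pos < windows$end[w]), 0L)
  }
  out
}

#' Windowed nucleotide diversity
#'
#' Per-site unbiased heterozygosity `2 * j * (n_s - j) / (n_s * (n_s - 1))`
#' summed over sites in the window and divided by the window length in bp
#' (sites with fewer than 2 called alleles are skipped).
#'
#' @param x a `site_matrix`.
#' @param population population label.
#' @param windows an `interval_set`.
#' @return numeric vector of per-bp pi, one per window.
#' @export
windowed_pi <- function(x, population, windows) {
  sc <- site_counts(x, population)
  ok <- sc$n >= 2
  h <- ifelse(ok, 2 * sc$j * (sc$n - sc$j) / (sc$n * (sc$n - 1)), 0)
  window_sums(x$chrom, x$pos, h, windows) / (windows$end - windows$start)
}

# Sum per-site values over windows using per-chromosome prefix sums
# (positions are sorted within chromosome by construction).
window_sums <- function(chrom, pos, val, windows, counts = FALSE) {
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    ssel <- which(chrom == ch)
    if (length(ssel) == 0) next
    p <- pos[ssel]
    cs <- c(0, cumsum(val[ssel]))
    lo <- findInterval(windows$start[wsel] - 0.5, p)
    hi <- findInterval(windows$end[wsel] - 0.5, p)
    out[wsel] <- cs[hi + 1] - cs[lo + 1]
  }
  out
}

# Weir & Cockerham (1984) per-site variance components for two populations.
wc_components <- function(j1, n1, j2, n2, h1, h2) {
  r <- 2
  nn1 <- n1 / 2; nn2 <- n2 / 2            # diploid counts
  p1 <- ifelse(n1 > 0, j1 / n1, NA); p2 <- ifelse(n2 > 0, j2 / n2, NA)
  nbar <- (nn1 + nn2) / r
  nc <- (r * nbar - (nn1^2 + nn2^2) / (r * nbar)) / (r - 1)
  pbar <- (nn1 * p1 + nn2 * p2) / (r * nbar)
  s2 <- (nn1 * (p1 - pbar)^2 + nn2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nn1 * h1 + nn2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST
#'
#' Weighted ratio-of-sums estimator: per-site variance components a, b, c
#' are summed over the sites of each window that segregate in the pooled
#' sample, and FST = sum(a) / sum(a + b + c). Windows with fewer
#' contributing sites than `min_snps` are set to NA.
#'
#' @param x a `site_matrix`.
#' @param pop1,pop2 population labels.
#' @param windows an `interval_set` (may be sliding).
#' @param min_snps minimum contributing SNPs per window (default 10).
#' @return data.frame: chrom, start, end, n_snps, fst.
#' @export
windowed_fst <- function(x, pop1, pop2, windows, min_snps = 10) {
  s1 <- pop_samples(x, pop1); s2 <- pop_samples(x, pop2)
  d1 <- x$dosage[, s1, drop = FALSE]; d2 <- x$dosage[, s2, drop = FALSE]
  j1 <- rowSums(d1, na.rm = TRUE); n1 <- 2 * rowSums(!is.na(d1))
  j2 <- rowSums(d2, na.rm = TRUE); n2 <- 2 * rowSums(!is.na(d2))
  h1 <- rowSums(d1 == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(d1)), 1)
  h2 <- rowSums(d2 == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(d2)), 1)
  jt <- j1 + j2; nt <- n1 + n2
  use <- n1 >= 2 & n2 >= 2 & jt > 0 & jt < nt
  comp <- wc_components(j1, n1, j2, n2, h1, h2)
  av <- ifelse(use, comp$a, 0)
  tv <- ifelse(use, comp$a + comp$b + comp$c, 0)
  num <- window_sums(x$chrom, x$pos, av, windows)
  den <- window_sums(x$chrom, x$pos, tv, windows)
  cnt <- window_sums(x$chrom, x$pos, as.numeric(use), windows)
  fst <- ifelse(cnt >= min_snps & den != 0, num / den, NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = as.integer(cnt), fst = fst,
             stringsAsFactors = FALSE)
}

#' Top-percentile candidate windows
#'
#' Flags windows whose score reaches the `1 - top_fraction` quantile of
#' the non-missing scores (ties at the threshold included).
#'
#' @param windows an `interval_set`.
#' @param scores numeric vector, one per window (NA = missing).
#' @param top_fraction fraction flagged (default 0.01, the top 1 percent).
#' @param direction "high" flags the upper tail, "low" the lower.
#' @return An `interval_set` of candidate windows with a `score` column.
#' @export
select_top_windows <- function(windows, scores, top_fraction = 0.01,
                               direction = c("high", "low")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores)
  if (!any(ok)) stop("all scores are missing")
  if (sum(ok) < 100)
    warning("fewer than 100 non-missing windows; the ", top_fraction,
            " quantile cut is coarse")
  if (direction == "high") {
    thr <- stats::quantile(scores[ok], 1 - top_fraction, names = FALSE)
    sel <- ok & scores >= thr
  } else {
    thr <- stats::quantile(scores[ok], top_fraction, names = FALSE)
    sel <- ok & scores <= thr
  }
  interval_set(windows$chrom[sel], windows$start[sel], windows$end[sel],
               layout_of(windows), score = scores[sel])
}

#' Near-fixed differences inside swept genes
#'
#' Retains SNPs that lie inside a swept-gene span and whose absolute
#' allele-frequency difference between the two populations exceeds
#' `delta_min` (strictly).
#'
#' @param x a `site_matrix`.
#' @param pop1,pop2 population labels.
#' @param swept_genes an `interval_set` of gene spans.
#' @param delta_min threshold (default 0.7); sites with delta AF <= this
#'   are removed.
#' @return data.frame: chrom, pos, af_pop1, af_pop2, delta_af.
#' @export
delta_af_filter <- function(x, pop1, pop2, swept_genes, delta_min = 0.7) {
  af1 <- allele_freq(x, pop1); af2 <- allele_freq(x, pop2)
  daf <- abs(af1 - af2)
  snp_gr <- GenomicRanges::GRanges(x$chrom,
                                   IRanges::IRanges(x$pos + 1, x$pos + 1))
  inside <- IRanges::overlapsAny(snp_gr, as_granges(swept_genes))
  keep <- which(inside & !is.na(daf) & daf > delta_min)
  data.frame(chrom = x$chrom[keep], pos = x$pos[keep],
             ref = x$ref[keep], alt = x$alt[keep],
             af_pop1 = af1[keep], af_pop2 = af2[keep],
             delta_af = daf[keep], stringsAsFactors = FALSE)
}

#' Remove admixed samples
#'
#' With K = 2 ancestry components, a sample is removed when its
#' coefficient on the opposite group's component exceeds `threshold`
#' (strictly; exactly 20 percent is retained). Components are matched to
#' populations by their mean coefficient within each population.
#'
#' @param ancestry data.frame with columns sample, comp1, comp2 (rows sum
#'   to 1), or a 2-column matrix with sample rownames.
#' @param assignment named character vector sample -> population (exactly
#'   two populations).
#' @param threshold admixture proportion above which a sample is dropped.
#' @return character vector of retained sample names.
#' @export
filter_admixed <- function(ancestry, assignment, threshold = 0.2) {
  if (is.data.frame(ancestry)) {
    samples <- as.character(ancestry$sample)
    Q <- as.matrix(ancestry[, setdiff(names(ancestry), "sample")])
  } else {
    samples <- rownames(ancestry)
    Q <- as.matrix(ancestry)
  }
  if (ncol(Q) != 2) stop("ancestry must have exactly K = 2 components")
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop("ancestry coefficients must sum to 1 per sample")
  miss <- setdiff(samples, names(assignment))
  if (length(miss) > 0)
    stop("sample(s) missing from assignment: ", paste(miss, collapse = ", "))
  pops <- unique(assignment[samples])
  if (length(pops) != 2) stop("assignment must contain exactly two populations")
  pop <- assignment[samples]
  # component that dominates in population 1
  comp_pop1 <- which.max(colMeans(Q[pop == pops[1], , drop = FALSE]))
  own_comp <- ifelse(pop == pops[1], comp_pop1, 3 - comp_pop1)
  opp <- Q[cbind(seq_along(samples), 3 - own_comp)]
  samples[opp <= threshold]
}

#' Remove low-minor-allele-frequency sites
#'
#' Pooled minor allele frequency over all samples; sites with MAF strictly
#' below `maf_min` are removed (MAF exactly at the threshold is kept).
#'
#' @param x a `site_matrix`.
#' @param maf_min threshold (default 0.05).
#' @return A filtered `site_matrix`.
#' @export
filter_maf <- function(x, maf_min = 0.05) {
  if (n_sites(x) == 0) stop("empty site matrix")
  j <- rowSums(x$dosage, na.rm = TRUE)
  n <- 2 * rowSums(!is.na(x$dosage))
  af <- ifelse(n > 0, j / n, 0)
  maf <- pmin(af, 1 - af)
  subset_sites(x, maf >= maf_min)
}
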