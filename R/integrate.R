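# Cross-layer statistics: interval Jaccard and permutation enrichment,
# gene-set overlap permutation, DMR-SNP proximity, hypergeometric trait
# enrichment.

#' Jaccard index of two interval sets
#'
#' Base-pair intersection over union after merging each set internally.
#'
#' @param a,b `interval_set`s on the same layout.
#' @return scalar in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0)
    stop("Jaccard index undefined for two empty sets")
  ga <- GenomicRanges::reduce(as_granges(a))
  gb <- GenomicRanges::reduce(as_granges(b))
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}

# Merge possibly overlapping half-open intervals (single chromosome).
merge_spans <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (length(s) > 1) {
    run_end <- cummax(e)
    grp <- cumsum(c(TRUE, s[-1] > run_end[-length(e)]))
  } else grp <- rep(1, length(s))
  list(s = as.numeric(tapply(s, grp, min)),
       e = as.numeric(tapply(e, grp, max)))
}

# Per-chromosome coverage index of a merged interval set: supports O(log)
# queries of covered bp below a coordinate via prefix sums.
coverage_index <- function(b) {
  idx <- list()
  for (ch in unique(b$chrom)) {
    sel <- b$chrom == ch
    m <- merge_spans(b$start[sel], b$end[sel])
    idx[[ch]] <- list(s = m$s, e = m$e,
                      cum = cumsum(c(0, m$e - m$s)))
  }
  idx
}

# Covered bp in (-Inf, x) for a coverage index entry.
covered_below <- function(ix, x) {
  k <- findInterval(x, ix$s)
  out <- numeric(length(x))
  pos <- k > 0
  out[pos] <- ix$cum[k[pos]] +
    pmax(0, pmin(ix$e[k[pos]], x[pos]) - ix$s[k[pos]])
  out
}

# Overlap statistic of intervals (chrom, s, e) against a coverage index.
# Intervals of the query may overlap each other; bp statistics merge the
# query first, the count statistic does not.
interval_statistic <- function(chrom, s, e, bidx, b_total, statistic) {
  total_inter <- 0; n_hit <- 0; a_len <- 0
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ix <- bidx[[ch]]
    if (statistic == "count_overlap") {
      if (!is.null(ix))
        n_hit <- n_hit +
          sum(covered_below(ix, e[sel]) - covered_below(ix, s[sel]) > 0)
      next
    }
    m <- merge_spans(s[sel], e[sel])
    a_len <- a_len + sum(m$e - m$s)
    if (!is.null(ix))
      total_inter <- total_inter +
        sum(covered_below(ix, m$e) - covered_below(ix, m$s))
  }
  switch(statistic,
         count_overlap = n_hit,
         bp_overlap = total_inter,
         jaccard = total_inter / (a_len + b_total - total_inter))
}

#' Interval overlap permutation test
#'
#' The null relocates each interval of `a` uniformly at random within its
#' chromosome (length and chromosome preserved; relocated intervals may
#' overlap each other), holding `b` fixed. Enrichment p is
#' `(1 + #{null >= observed}) / (n_perm + 1)`; the depletion p is the
#' lower tail. Fold change is observed/expected: `(obs + 1) /
#' (median(null) + 1)` for count and bp statistics, `obs / median(null)`
#' for the Jaccard statistic.
#'
#' @param a query `interval_set` (relocated under the null; nonempty).
#' @param b fixed `interval_set`.
#' @param statistic "jaccard", "count_overlap" or "bp_overlap".
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list of class `enrichment_result`: observed, null_median,
#'   fold, p, p_depletion, n_perm, seed, statistic.
#' @export
interval_permutation_test <- function(a, b,
                                      statistic = c("count_overlap",
                                                    "jaccard", "bp_overlap"),
                                      n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  if (nrow(a) == 0) stop("query set must be nonempty")
  layout <- layout_of(a)
  lens <- a$end - a$start
  chr_len <- unclass(layout)[a$chrom]
  if (any(lens > chr_len))
    stop("interval longer than its chromosome cannot be relocated")
  bidx <- coverage_index(b)
  b_total <- sum(vapply(bidx, function(ix) sum(ix$e - ix$s), 0))
  observed <- interval_statistic(a$chrom, a$start, a$end, bidx, b_total,
                                 statistic)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      ns <- floor(stats::runif(nrow(a)) * (chr_len - lens + 1))
      interval_statistic(a$chrom, ns, ns + lens, bidx, b_total, statistic)
    }, 0)
  })
  med <- stats::median(null)
  fold <- if (statistic == "jaccard") {
    if (med == 0) stop("null median Jaccard is 0; fold change undefined")
    observed / med
  } else (observed + 1) / (med + 1)
  structure(list(observed = observed, null_median = med, fold = fold,
                 p = (1 + sum(null >= observed)) / (n_perm + 1),
                 p_depletion = (1 + sum(null <= observed)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, statistic = statistic),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment (%s): observed %.4g, null median %.4g, fold %.3g, p = %.4g (%d perms, seed %d)\n",
    x$statistic, x$observed, x$null_median, x$fold, x$p, x$n_perm, x$seed))
  invisible(x)
}

#' Gene-set overlap permutation test
#'
#' Observed statistic is `|a intersect b|`; the null redraws `|a|` genes
#' uniformly without replacement from the universe. p and fold follow the
#' count conventions of [interval_permutation_test()].
#'
#' @param set_a,set_b character vectors of gene ids (subsets of
#'   `universe`).
#' @param universe character vector of all genes.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return An `enrichment_result`.
#' @export
geneset_overlap_test <- function(set_a, set_b, universe, n_perm = 1000,
                                 seed = 1) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("gene sets must be subsets of the universe")
  if (length(set_a) > length(universe))
    stop("query set larger than universe")
  b_mask <- universe %in% set_b
  observed <- sum(set_a %in% set_b)
  na <- length(set_a); N <- length(universe)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k)
      sum(b_mask[sample.int(N, na)]), 0)
  })
  med <- stats::median(null)
  structure(list(observed = observed, null_median = med,
                 fold = (observed + 1) / (med + 1),
                 p = (1 + sum(null >= observed)) / (n_perm + 1),
                 p_depletion = (1 + sum(null <= observed)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, statistic = "gene_overlap"),
            class = "enrichment_result")
}

#' Distance from each region to the nearest SNP
#'
#' Distance is 0 when a SNP lies inside the region, otherwise the bp gap
#' `max(0, start - p, p - (end - 1))` to the nearest SNP. Fractions of
#' regions within each cutoff are reported (over regions on chromosomes
#' with at least one SNP).
#'
#' @param regions an `interval_set` (e.g., DMRs).
#' @param snps data.frame with columns chrom, pos (0-based), sorted or
#'   not.
#' @param cutoffs distances in bp (default 5 kb and 50 kb).
#' @return list(distances = per-region data.frame, fractions = named
#'   numeric vector over cutoffs).
#' @export
nearest_snp_distance <- function(regions, snps, cutoffs = c(5000, 50000)) {
  d <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    rsel <- which(regions$chrom == ch)
    p <- sort(snps$pos[snps$chrom == ch])
    if (length(p) == 0) next
    for (i in rsel) {
      s <- regions$start[i]; e <- regions$end[i]
      k <- findInterval(e - 1, p)
      cand <- p[pmax(1, k):pmin(length(p), k + 1)]
      d[i] <- min(pmax(0, pmax(s - cand, cand - (e - 1))))
    }
  }
  fr <- vapply(cutoffs, function(cu) mean(d[!is.na(d)] <= cu), 0)
  names(fr) <- paste0("within_", cutoffs)
  list(distances = data.frame(chrom = regions$chrom, start = regions$start,
                              end = regions$end, distance = d),
       fractions = fr)
}

#' Hypergeometric trait/QTL enrichment
#'
#' Per trait class, upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query genes and the class genes in
#' the annotated universe; adjusted across classes.
#'
#' @param swept_genes character vector of query gene ids (subset of
#'   `universe`).
#' @param traits named list: trait class -> gene ids.
#' @param universe character vector of all annotated genes.
#' @param correction "BH" (default) or "bonferroni".
#' @return data.frame: trait, k (overlap), K (class size), n (query
#'   size), N (universe size), p, p_adjusted.
#' @export
hypergeom_trait_enrichment <- function(swept_genes, traits, universe,
                                       correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(universe) == 0) stop("empty universe")
  swept_genes <- unique(swept_genes)
  if (!all(swept_genes %in% universe))
    stop("query genes must be in the universe")
  N <- length(universe); n <- length(swept_genes)
  rows <- lapply(names(traits), function(cl) {
    tg <- intersect(unique(traits[[cl]]), universe)
    K <- length(tg)
    k <- length(intersect(swept_genes, tg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(trait = cl, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method =
                                      if (correction == "BH") "BH"
                                      else "bonferroni")
  out
}
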