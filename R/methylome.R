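# DMC/DMR calling from replicated bisulfite counts: per-site or per-tile
# binomial logistic regression with likelihood-ratio tests, Bonferroni
# correction, and the coverage / CpG-count / effect-size filters.

# Align a set of per-sample CpG tables on the union of sites.
# Returns meth and total matrices (sites x samples; absent site = 0
# coverage) plus site coordinates.
align_cpg_tables <- function(tables) {
  keys <- unique(unlist(lapply(tables, function(t)
    paste(t$chrom, t$pos, t$strand, sep = ":"))))
  keys <- sort(keys)
  M <- matrix(0, length(keys), length(tables))
  T_ <- matrix(0, length(keys), length(tables))
  for (s in seq_along(tables)) {
    t <- tables[[s]]
    k <- paste(t$chrom, t$pos, t$strand, sep = ":")
    # duplicate rows for one site are accumulated, so pooled levels are
    # invariant to splitting a sample's counts across rows
    msum <- rowsum(t$meth, k)
    tsum <- rowsum(t$total, k)
    idx <- match(rownames(msum), keys)
    M[idx, s] <- msum[, 1]
    T_[idx, s] <- tsum[, 1]
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1)
  pos <- as.numeric(vapply(parts, `[[`, "", 2))
  strand <- vapply(parts, `[[`, "", 3)
  o <- order(chrom, pos)
  list(chrom = chrom[o], pos = pos[o], strand = strand[o],
       meth = M[o, , drop = FALSE], total = T_[o, , drop = FALSE])
}

# Binomial logistic-regression LRT of methylation on group; Fisher's
# exact test on pooled counts when either group has a single sample.
group_meth_test <- function(m1, t1, m2, t2) {
  if (length(m1) == 1 || length(m2) == 1) {
    tab <- matrix(c(sum(m1), sum(t1) - sum(m1),
                    sum(m2), sum(t2) - sum(m2)), nrow = 2)
    return(stats::fisher.test(tab)$p.value)
  }
  y <- cbind(c(m1, m2), c(t1 - m1, t2 - m2))
  g <- factor(rep(c("g1", "g2"), c(length(m1), length(m2))))
  fit <- stats::glm(y ~ g, family = stats::binomial())
  stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                lower.tail = FALSE)
}

meth_direction <- function(meth_diff) ifelse(meth_diff < 0, "hypo", "hyper")

#' Call differentially methylated cytosines
#'
#' Tests every CpG site at which all samples of both groups have coverage
#' `>= min_cov`, using a binomial logistic regression of methylated /
#' unmethylated counts on the group indicator (likelihood-ratio p;
#' Fisher's exact test on pooled counts when a group has one sample).
#' Bonferroni correction is applied over the tested sites; a site is
#' significant when `q < q_max` and `|meth_diff| > diff_min` (percentage
#' points, group1 - group2).
#'
#' @param group1,group2 lists of per-sample CpG data.frames (chrom, pos,
#'   strand, meth, total).
#' @param min_cov minimum per-sample coverage (default 10).
#' @param diff_min minimum absolute methylation difference in percentage
#'   points (default 30).
#' @param q_max Bonferroni-corrected significance cutoff (default 0.05).
#' @param stage optional stage label carried into the output.
#' @return data.frame: chrom, start, end (1-bp region), n_cpg, meth_diff,
#'   p, q, direction, significant, stage.
#' @export
call_dmc <- function(group1, group2, min_cov = 10, diff_min = 30,
                     q_max = 0.05, stage = NA_character_) {
  al <- align_cpg_tables(c(group1, group2))
  i1 <- seq_along(group1)
  i2 <- length(group1) + seq_along(group2)
  pass <- rowSums(al$total >= min_cov) == ncol(al$total)
  if (!any(pass)) {
    warning("no site passes the coverage filter")
    return(empty_dm_frame())
  }
  idx <- which(pass)
  p <- vapply(idx, function(i)
    group_meth_test(al$meth[i, i1], al$total[i, i1],
                    al$meth[i, i2], al$total[i, i2]), 0)
  lev1 <- rowMeans(al$meth[idx, i1, drop = FALSE] /
                     al$total[idx, i1, drop = FALSE])
  lev2 <- rowMeans(al$meth[idx, i2, drop = FALSE] /
                     al$total[idx, i2, drop = FALSE])
  md <- 100 * (lev1 - lev2)
  q <- pmin(1, p * length(idx))
  data.frame(chrom = al$chrom[idx], start = al$pos[idx],
             end = al$pos[idx] + 1, n_cpg = 1L, meth_diff = md,
             p = p, q = q, direction = meth_direction(md),
             significant = q < q_max & abs(md) > diff_min,
             stage = stage, stringsAsFactors = FALSE)
}

empty_dm_frame <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             n_cpg = integer(), meth_diff = numeric(), p = numeric(),
             q = numeric(), direction = character(), significant = logical(),
             stage = character(), stringsAsFactors = FALSE)
}

#' Call differentially methylated regions
#'
#' Tiles the genome in `window`-bp non-overlapping tiles (window and step
#' equal). Within a tile, CpGs with coverage `>= min_cov` in every sample
#' are retained and the per-sample counts summed; tiles with fewer than
#' `min_cpg` retained CpGs are skipped. Each tested tile gets the same
#' group test as [call_dmc()]; Bonferroni correction runs over the tested
#' tiles of this comparison. Direction is hypo when group1 is less
#' methylated.
#'
#' @inheritParams call_dmc
#' @param window tile size in bp (default 1000).
#' @param step tile step; must equal `window` (sliding tiles with
#'   step < window are not supported).
#' @param min_cov minimum per-sample CpG coverage (default 5).
#' @param min_cpg minimum retained CpGs per tile (default 3).
#' @return data.frame as in [call_dmc()] with one row per tested tile.
#' @export
call_dmr <- function(group1, group2, window = 1000, step = window,
                     min_cov = 5, min_cpg = 3, diff_min = 30, q_max = 0.05,
                     stage = NA_character_) {
  if (step != window) stop("only step == window tiling is supported")
  al <- align_cpg_tables(c(group1, group2))
  i1 <- seq_along(group1)
  i2 <- length(group1) + seq_along(group2)
  keep <- rowSums(al$total >= min_cov) == ncol(al$total)
  if (!any(keep)) {
    warning("no CpG passes the coverage filter")
    return(empty_dm_frame())
  }
  tile <- paste0(al$chrom, ":", floor(al$pos / window))
  keys <- unique(tile[keep])
  rows <- lapply(keys, function(k) {
    i <- which(tile == k & keep)
    if (length(unique(al$pos[i])) < min_cpg) return(NULL)
    m1 <- colSums(al$meth[i, i1, drop = FALSE])
    t1 <- colSums(al$total[i, i1, drop = FALSE])
    m2 <- colSums(al$meth[i, i2, drop = FALSE])
    t2 <- colSums(al$total[i, i2, drop = FALSE])
    md <- 100 * (mean(m1 / t1) - mean(m2 / t2))
    p <- group_meth_test(m1, t1, m2, t2)
    ch <- sub(":[^:]*$", "", k)
    ts <- as.numeric(sub(".*:", "", k)) * window
    data.frame(chrom = ch, start = ts, end = ts + window,
               n_cpg = length(unique(al$pos[i])), meth_diff = md, p = p,
               q = NA_real_, direction = meth_direction(md),
               significant = NA, stage = stage, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty_dm_frame())
  rows$q <- pmin(1, rows$p * nrow(rows))
  rows$significant <- rows$q < q_max & abs(rows$meth_diff) > diff_min
  rows[order(rows$chrom, rows$start), ]
}

#' Feature-level methylation per gene
#'
#' Pooled methylation level (sum of methylated counts over sum of
#' coverage) per sample over the CpGs of each feature, averaged across
#' samples. Features: promoter = TSS +- `promoter_flank` (strand-aware;
#' for a minus-strand gene the TSS is the transcript's rightmost
#' coordinate) and gene body = TSS to TES.
#'
#' @param samples list of per-sample CpG data.frames.
#' @param models gene-model data.frame.
#' @param promoter_flank bp either side of the TSS (default 2000).
#' @return data.frame: gene, promoter, gene_body (NA where a feature has
#'   no covered CpG).
#' @export
feature_methylation <- function(samples, models, promoter_flank = 2000) {
  al <- align_cpg_tables(samples)
  level_in <- function(ch, s, e) {
    i <- which(al$chrom == ch & al$pos >= s & al$pos < e &
                 rowSums(al$total) > 0)
    if (length(i) == 0) return(NA_real_)
    m <- colSums(al$meth[i, , drop = FALSE])
    t <- colSums(al$total[i, , drop = FALSE])
    mean(ifelse(t > 0, m / t, NA), na.rm = TRUE)
  }
  rows <- lapply(seq_len(nrow(models)), function(g) {
    m <- models[g, ]
    tss <- if (m$strand == "+") m$tx_start else m$tx_end
    data.frame(gene = m$gene,
               promoter = level_in(m$chrom, max(0, tss - promoter_flank),
                                   tss + promoter_flank),
               gene_body = level_in(m$chrom, m$tx_start, m$tx_end),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Methylation-expression correlation
#'
#' Pearson correlation between per-gene methylation levels and normalized
#' expression, after removing genes with expression outside
#' `[expr_lo, expr_hi]` or missing methylation.
#'
#' @param levels named numeric vector: gene -> methylation level.
#' @param expression named numeric vector: gene -> normalized expression.
#' @param expr_lo,expr_hi expression filter bounds (defaults 0 and 20).
#' @return list(r = Pearson r, n = genes used).
#' @export
methylation_expression_correlation <- function(levels, expression,
                                               expr_lo = 0, expr_hi = 20) {
  genes <- intersect(names(levels), names(expression))
  lv <- levels[genes]; ex <- expression[genes]
  keep <- !is.na(lv) & !is.na(ex) & ex >= expr_lo & ex <= expr_hi
  if (sum(keep) < 3) stop("fewer than 3 genes after filtering")
  list(r = stats::cor(lv[keep], ex[keep]), n = sum(keep))
}

#' Persistence grouping of DMR tiles across stages
#'
#' Counts, per tile, the stages at which it is a significant DMR and bins
#' tiles into low/mid/high persistence groups (prenatal bins 1-5 / 6-10 /
#' 11-15 significant stages; postnatal 1-4 / 5-8 / 9-12). Per group,
#' reports the fraction of tiles whose majority direction is hypo.
#'
#' @param dmr_list list of [call_dmr()] outputs, one per stage, on the
#'   same tiling.
#' @param phase "prenatal" or "postnatal".
#' @return list(tiles = per-tile data.frame with n_significant, group and
#'   majority direction; groups = per-group tile count and hypo fraction).
#' @export
persistence_groups <- function(dmr_list, phase = c("prenatal", "postnatal")) {
  phase <- match.arg(phase)
  widths <- unique(unlist(lapply(dmr_list, function(d) d$end - d$start)))
  if (length(widths) > 1) stop("stage DMR lists use mixed tilings")
  bins <- if (phase == "prenatal") c(0, 5, 10, 15) else c(0, 4, 8, 12)
  sig <- lapply(dmr_list, function(d) d[d$significant, , drop = FALSE])
  keys <- unlist(lapply(sig, function(d)
    if (nrow(d) > 0) paste0(d$chrom, ":", d$start) else character(0)))
  dirs <- unlist(lapply(sig, function(d) d$direction))
  if (length(keys) == 0)
    return(list(tiles = data.frame(), groups = data.frame()))
  n_sig <- table(keys)
  hypo_n <- tapply(dirs == "hypo", keys, sum)
  tiles <- data.frame(
    tile = names(n_sig),
    n_significant = as.integer(n_sig),
    majority_direction = ifelse(hypo_n[names(n_sig)] * 2 >
                                  as.integer(n_sig), "hypo",
                                ifelse(hypo_n[names(n_sig)] * 2 <
                                         as.integer(n_sig), "hyper", "tie")),
    stringsAsFactors = FALSE)
  tiles$group <- cut(tiles$n_significant, bins,
                     labels = c("low", "mid", "high"))
  groups <- do.call(rbind, lapply(levels(tiles$group), function(g) {
    sel <- tiles[tiles$group == g, , drop = FALSE]
    data.frame(group = g, n_tiles = nrow(sel),
               hypo_fraction = if (nrow(sel) == 0) NA_real_
               else mean(sel$majority_direction == "hypo"),
               stringsAsFactors = FALSE)
  }))
  list(tiles = tiles, groups = groups)
}
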