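# Developmental heterochrony detection: dynamic time warping of two
# breeds' expression trajectories, progression-advanced scores (PAS) and
# differentially progressing gene (DPG) calling.

#' Interpolate a replicated trajectory onto a uniform grid
#'
#' Replicates are averaged per stage, interpolated with a monotone cubic
#' spline onto `grid_size` evenly spaced points spanning the stage range,
#' then min-max scaled to `[0, 1]`. Range scaling (rather than
#' z-normalization) keeps the resting levels of two time-shifted copies
#' of the same trajectory numerically equal, which the warping step needs
#' to recover the shift; a z-score would move the plateau levels apart
#' whenever the shift changes how much of each plateau falls inside the
#' observed window. Constant trajectories return all-zeros with
#' attribute `constant = TRUE`.
#'
#' @param times stage times, strictly increasing (>= 3 stages).
#' @param values numeric vector (one per stage) or stage x replicate
#'   matrix.
#' @param grid_size number of grid points (default 100).
#' @return numeric vector of length `grid_size`.
#' @export
interpolate_trajectory <- function(times, values, grid_size = 100) {
  if (length(times) < 3) stop("need at least 3 stages")
  if (is.matrix(values)) values <- rowMeans(values)
  if (length(values) != length(times))
    stop("values must have one entry (or row) per stage")
  if (any(!is.finite(values)) || any(!is.finite(times)))
    stop("non-finite input")
  grid <- seq(times[1], times[length(times)], length.out = grid_size)
  s <- stats::splinefun(times, values, method = "monoH.FC")
  y <- s(grid)
  rng <- diff(range(y))
  if (rng < 1e-12 || diff(range(values)) < 1e-12) {
    out <- rep(0, grid_size)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (y - min(y)) / rng
  attr(out, "constant") <- FALSE
  out
}

#' Dynamic time warping alignment of two series
#'
#' Minimal-cost monotone alignment under squared-difference local cost
#' with steps (1,0), (0,1), (1,1) and anchored endpoints. The aligned
#' correlation is the Pearson r of the value pairs along the path.
#'
#' @param query,reference numeric vectors (equal length for PAS use;
#'   unequal lengths are allowed for stage correspondence).
#' @return list of class `warp_alignment`: grid sizes, `path` (data.frame
#'   of 0-based indices a = query, b = reference), `dtw_cost`,
#'   `aligned_correlation`.
#' @export
dtw_align <- function(query, reference) {
  if (length(query) < 2 || length(reference) < 2)
    stop("series must have length >= 2")
  cost <- outer(query, reference, function(x, y) (x - y)^2)
  r <- dtw_cost_path(cost)
  a <- r$index_a - 1L; b <- r$index_b - 1L
  qa <- query[a + 1]; rb <- reference[b + 1]
  ac <- if (stats::sd(qa) < 1e-12 || stats::sd(rb) < 1e-12) NA_real_
        else stats::cor(qa, rb)
  structure(list(n_query = length(query), n_reference = length(reference),
                 path = data.frame(a = a, b = b), dtw_cost = r$cost,
                 aligned_correlation = ac),
            class = "warp_alignment")
}

#' Progression-advanced score of a warp alignment
#'
#' `PAS = mean over the path of (b_k - a_k) / (T - 1)` with a the query
#' and b the reference index. Positive PAS means the query reaches
#' matched expression states at earlier grid positions: the query breed
#' is developmentally advanced. Exactly antisymmetric under query /
#' reference exchange.
#'
#' @param alignment a `warp_alignment` on equal-length grids.
#' @return scalar in (-1, 1).
#' @export
progression_advanced_score <- function(alignment) {
  if (alignment$n_query != alignment$n_reference)
    stop("PAS requires equal grid sizes")
  T <- alignment$n_query
  mean(alignment$path$b - alignment$path$a) / (T - 1)
}

# Stage means for one gene, optionally with replicates resampled within
# each stage (bootstrap draw).
gene_stage_means <- function(tc, gi, rep_idx = NULL) {
  v <- tc$values[gi, , , drop = FALSE]
  ns <- dim(v)[2]; nr <- dim(v)[3]
  if (is.null(rep_idx)) return(apply(v, 2, mean))
  vapply(seq_len(ns), function(s) mean(v[1, s, rep_idx[[s]]]), 0)
}

#' Call differentially progressing genes
#'
#' Per gene: interpolate both breeds' stage means onto a common grid,
#' align with DTW, compute PAS and the aligned correlation; a bootstrap
#' over replicates (resampled with replacement within each stage and
#' breed) gives a two-sided p for PAS != 0. A gene is classified when
#' `|PAS| >= pas_min`, aligned correlation `>= r_min` and `p < p_max`.
#'
#' @param query,reference `expression_time_course` objects with matching
#'   genes and phase; positive PAS = query advanced.
#' @param pas_min minimum absolute PAS (default 0.1).
#' @param r_min minimum aligned correlation (default 0.5).
#' @param n_boot bootstrap draws (default 100; requires >= 2 replicates).
#' @param p_max significance cutoff (default 0.05).
#' @param grid_size interpolation grid (default 100).
#' @param seed integer seed for the bootstrap.
#' @return data.frame: gene, pas, aligned_correlation, p, class
#'   (query_accelerated / reference_accelerated / none), constant flag.
#' @export
call_dpgs <- function(query, reference, pas_min = 0.1, r_min = 0.5,
                      n_boot = 100, p_max = 0.05, grid_size = 100,
                      seed = 1) {
  if (!identical(query$genes, reference$genes))
    stop("query and reference must have matching gene ids")
  if (!identical(query$phase, reference$phase))
    stop("query and reference must be the same phase")
  nrep_q <- dim(query$values)[3]; nrep_r <- dim(reference$values)[3]
  if (n_boot > 0 && (nrep_q < 2 || nrep_r < 2))
    stop("bootstrap requires >= 2 replicates per breed")
  ns_q <- length(query$times); ns_r <- length(reference$times)
  with_seed(seed, {
    rows <- lapply(seq_along(query$genes), function(gi) {
      xq <- interpolate_trajectory(query$times, gene_stage_means(query, gi),
                                   grid_size)
      xr <- interpolate_trajectory(reference$times,
                                   gene_stage_means(reference, gi),
                                   grid_size)
      if (isTRUE(attr(xq, "constant")) || isTRUE(attr(xr, "constant")))
        return(data.frame(gene = query$genes[gi], pas = NA_real_,
                          aligned_correlation = NA_real_, p = NA_real_,
                          class = "none", constant = TRUE,
                          stringsAsFactors = FALSE))
      al <- dtw_align(xq, xr)
      pas <- progression_advanced_score(al)
      p <- NA_real_
      if (n_boot > 0) {
        pas_b <- vapply(seq_len(n_boot), function(b) {
          ridx_q <- lapply(seq_len(ns_q), function(s)
            sample.int(nrep_q, nrep_q, replace = TRUE))
          ridx_r <- lapply(seq_len(ns_r), function(s)
            sample.int(nrep_r, nrep_r, replace = TRUE))
          bq <- interpolate_trajectory(query$times,
                                       gene_stage_means(query, gi, ridx_q),
                                       grid_size)
          br <- interpolate_trajectory(reference$times,
                                       gene_stage_means(reference, gi, ridx_r),
                                       grid_size)
          if (isTRUE(attr(bq, "constant")) || isTRUE(attr(br, "constant")))
            return(0)
          progression_advanced_score(dtw_align(bq, br))
        }, 0)
        p_lo <- (1 + sum(pas_b <= 0)) / (n_boot + 1)
        p_hi <- (1 + sum(pas_b >= 0)) / (n_boot + 1)
        p <- min(1, 2 * min(p_lo, p_hi))
      }
      cls <- "none"
      if (!is.na(al$aligned_correlation) && abs(pas) >= pas_min &&
          al$aligned_correlation >= r_min &&
          (n_boot == 0 || (!is.na(p) && p < p_max)))
        cls <- if (pas > 0) "query_accelerated" else "reference_accelerated"
      data.frame(gene = query$genes[gi], pas = pas,
                 aligned_correlation = al$aligned_correlation, p = p,
                 class = cls, constant = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Cross-breed developmental stage correspondence
#'
#' DTW over actual stages (no interpolation) with local cost 1 - Pearson
#' correlation between whole-transcriptome stage profiles; returns the
#' warping path over stage indices.
#'
#' @param mat_a,mat_b stage x gene matrices (column names are gene ids;
#'   the intersection of gene universes is used).
#' @return data.frame: stage_a, stage_b (1-based indices), plus the
#'   stage-pair correlation.
#' @export
stage_correspondence <- function(mat_a, mat_b) {
  shared <- intersect(colnames(mat_a), colnames(mat_b))
  if (length(shared) < 2) stop("fewer than 2 shared genes")
  A <- mat_a[, shared, drop = FALSE]; B <- mat_b[, shared, drop = FALSE]
  C <- stats::cor(t(A), t(B))
  r <- dtw_cost_path(1 - C)
  data.frame(stage_a = r$index_a, stage_b = r$index_b,
             correlation = C[cbind(r$index_a, r$index_b)])
}
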