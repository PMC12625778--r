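# Synthetic multiomics generators. Each generator is a pure function of
# (config, seed): the caller's RNG state is saved and restored, and the
# same seed always reproduces the same dataset. Each returns a ground
# truth manifest sufficient to score every downstream caller.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Neutral (Watterson) site frequency spectrum
#'
#' Class masses proportional to 1/j over derived counts j = 1..n-1, the
#' expected spectrum of segregating sites under the standard neutral model.
#'
#' @param n haploid sample size.
#' @param folded logical.
#' @return An `sfs`.
#' @export
watterson_sfs <- function(n, folded = FALSE) {
  b <- 1 / seq_len(n - 1)
  s <- sfs(b / sum(b), n, folded = FALSE)
  if (!folded) return(s)
  m_max <- n %/% 2
  fp <- vapply(seq_len(m_max), function(m)
    if (m == n - m) s$probs[m] else s$probs[m] + s$probs[n - m], 0)
  sfs(fp, n, folded = TRUE)
}

# Turn a derived-allele count among 2N haploids into N diploid dosages by
# random pairing of haplotypes.
count_to_dosages <- function(count, n_dip) {
  hap <- sample(c(rep(1L, count), rep(0L, 2 * n_dip - count)))
  hap[seq_len(n_dip) * 2 - 1] + hap[seq_len(n_dip) * 2]
}

#' Simulate two-population genotypes with localized sweeps
#'
#' Neutral sites draw their derived counts independently per population
#' from the Watterson spectrum; sites near a sweep center in the swept
#' population draw from the star-genealogy hitchhiking distribution at
#' their distance (same model as the scan). A configurable fraction of
#' sites are converted to fixed differences (delta AF = 1).
#'
#' @param layout a `genome_layout`.
#' @param n_per_pop diploid individuals per population (two populations,
#'   labelled `pop1` and `pop2`).
#' @param snp_density expected SNPs per bp.
#' @param sweep_spec data.frame with columns chrom, center (bp),
#'   alpha (per-bp intensity), pop ("pop1"/"pop2"); NULL for all-neutral.
#' @param fixed_diff_fraction fraction of sites replaced by fixed
#'   differences.
#' @param seed integer seed.
#' @return list(genotypes = `site_matrix`, truth = list with sweep_centers
#'   and fixed_diff positions).
#' @export
gen_genotypes <- function(layout, n_per_pop = 20, snp_density = 0.002,
                          sweep_spec = NULL, fixed_diff_fraction = 0,
                          seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), n_per_pop >= 2,
            snp_density > 0)
  if (!is.null(sweep_spec) && nrow(sweep_spec) > 0) {
    if (!all(sweep_spec$chrom %in% names(layout)))
      stop("sweep center chromosome not in layout")
    if (any(sweep_spec$center < 0) ||
        any(sweep_spec$center > unclass(layout)[sweep_spec$chrom]))
      stop("sweep center outside layout")
  }
  n_hap <- 2L * n_per_pop
  bg <- watterson_sfs(n_hap, folded = FALSE)
  cfg <- sweep_config()
  trans <- sweep_transition(bg)
  with_seed(seed, {
    chroms <- c(); poss <- c()
    for (ch in names(layout)) {
      L <- unclass(layout)[[ch]]
      ns <- stats::rpois(1, snp_density * L)
      p <- sort(sample.int(L, min(ns, L)) - 1)
      chroms <- c(chroms, rep(ch, length(p)))
      poss <- c(poss, p)
    }
    S <- length(poss)
    samples <- c(sprintf("p1_%03d", seq_len(n_per_pop)),
                 sprintf("p2_%03d", seq_len(n_per_pop)))
    pops <- stats::setNames(rep(c("pop1", "pop2"), each = n_per_pop), samples)
    dos <- matrix(0L, S, 2 * n_per_pop, dimnames = list(NULL, samples))
    shortcut_d <- -log(cfg$neutral_shortcut_tol)
    for (pop_i in 1:2) {
      pop_lab <- paste0("pop", pop_i)
      cols <- which(pops == pop_lab)
      counts <- sample(seq_len(n_hap - 1), S, replace = TRUE, prob = bg$probs)
      if (!is.null(sweep_spec) && nrow(sweep_spec) > 0) {
        sw <- sweep_spec[sweep_spec$pop == pop_lab, , drop = FALSE]
        for (k in seq_len(nrow(sw))) {
          on_chr <- which(chroms == sw$chrom[k])
          d <- abs(poss[on_chr] - sw$center[k])
          hit <- on_chr[sw$alpha[k] * pmax(d, 1) < shortcut_d]
          for (i in hit) {
            pr <- sweep_site_distribution(abs(poss[i] - sw$center[k]),
                                          sw$alpha[k], bg, cfg, trans)
            counts[i] <- sample(seq_len(n_hap - 1), 1, prob = pr)
          }
        }
      }
      for (i in seq_len(S))
        dos[i, cols] <- count_to_dosages(counts[i], n_per_pop)
    }
    fixed_idx <- integer(0)
    if (fixed_diff_fraction > 0) {
      fixed_idx <- sort(sample.int(S, round(fixed_diff_fraction * S)))
      for (i in fixed_idx) {
        derived_pop <- sample(1:2, 1)
        dos[i, pops == paste0("pop", derived_pop)] <- 2L
        dos[i, pops == paste0("pop", 3 - derived_pop)] <- 0L
      }
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, S, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    m <- site_matrix(chroms, poss, ref, alt, dos, pops, layout)
    truth <- list(
      sweep_centers = if (is.null(sweep_spec)) {
        data.frame(chrom = character(), center = numeric(),
                   alpha = numeric(), pop = character())
      } else sweep_spec,
      fixed_diff_sites = data.frame(chrom = chroms[fixed_idx],
                                    pos = poss[fixed_idx]))
    list(genotypes = m, truth = truth)
  })
}

#' Expression time course container
#'
#' @param breed breed label.
#' @param phase "prenatal" or "postnatal".
#' @param genes gene ids.
#' @param times stage times in days, strictly increasing.
#' @param values numeric array gene x stage x replicate of normalized log
#'   expression.
#' @return An object of class `expression_time_course`.
#' @export
expression_time_course <- function(breed, phase, genes, times, values) {
  values <- as.array(values)
  if (length(dim(values)) != 3)
    stop("values must be a gene x stage x replicate array")
  if (length(times) < 3) stop("need at least 3 stages per phase")
  if (any(diff(times) <= 0)) stop("stage times must be strictly increasing")
  stopifnot(dim(values)[1] == length(genes), dim(values)[2] == length(times))
  structure(list(breed = breed, phase = phase, genes = genes,
                 times = times, values = values),
            class = "expression_time_course")
}

#' @export
print.expression_time_course <- function(x, ...) {
  cat(sprintf("expression_time_course: breed %s, %s, %d genes x %d stages x %d reps\n",
              x$breed, x$phase, length(x$genes), length(x$times),
              dim(x$values)[3]))
  invisible(x)
}

#' Default developmental stage times
#'
#' Prenatal: 15 stages spanning embryonic days E33-E105, expressed as days
#' relative to birth (E - 114, gestation length); postnatal: 12 stages
#' spanning day 0 to day 180.
#'
#' @param phase "prenatal" or "postnatal".
#' @return numeric vector of stage times (days).
#' @export
stage_times <- function(phase = c("prenatal", "postnatal")) {
  phase <- match.arg(phase)
  if (phase == "prenatal") seq(33, 105, length.out = 15) - 114
  else seq(0, 180, length.out = 12)
}

#' Simulate two-breed developmental expression trajectories
#'
#' Each gene follows a smooth template (logistic rise/fall or Gaussian
#' bump in time) on the normalized log-expression scale. A fraction of
#' genes are differentially progressing: breed B's trajectory is the
#' template evaluated at `t - delta * span`, so positive `delta` makes
#' breed A reach matched expression states earlier (breed A advanced).
#' Replicate noise is additive Gaussian.
#'
#' @param n_genes number of genes.
#' @param phase "prenatal" (15 stages) or "postnatal" (12 stages).
#' @param reps replicates per stage (>= 2 for bootstrap significance).
#' @param dpg_fraction fraction of genes time-shifted.
#' @param delta_range absolute shift range as a fraction of the phase span.
#' @param noise_sd replicate noise sd on the log scale.
#' @param seed integer seed.
#' @return list(query = breed A `expression_time_course`, reference =
#'   breed B, truth = data.frame(gene, delta) for shifted genes).
#' @export
gen_expression <- function(n_genes = 200, phase = c("prenatal", "postnatal"),
                           reps = 3, dpg_fraction = 0.1,
                           delta_range = c(0.1, 0.3), noise_sd = 0.25,
                           seed = 1) {
  phase <- match.arg(phase)
  stopifnot(reps >= 1, dpg_fraction >= 0, dpg_fraction <= 1)
  times <- stage_times(phase)
  span <- diff(range(times))
  genes <- sprintf("g%04d", seq_len(n_genes))
  with_seed(seed, {
    # Templates keep their dynamic feature (logistic transition or bump)
    # well inside the observed window even after the largest shift: a
    # time shift of a trajectory that is linear over the window is
    # invisible after z-normalization, so truth DPGs built from such
    # templates could never be recovered by any method.
    # and the feature spans a sizable fraction of the window, as
    # stage-regulated developmental programs do: long flat plateaus on
    # both sides leave the warping path unconstrained there.
    kind <- sample(c("logistic", "bump"), n_genes, replace = TRUE)
    t0 <- stats::runif(n_genes, min(times) + 0.3 * span,
                       max(times) - 0.3 * span)
    rate <- stats::runif(n_genes, 6 / span, 15 / span)
    width <- stats::runif(n_genes, 0.1 * span, 0.2 * span)
    amp <- stats::runif(n_genes, 2, 6) * sample(c(-1, 1), n_genes, replace = TRUE)
    base <- stats::runif(n_genes, 2, 8)
    template <- function(g, t) {
      if (kind[g] == "logistic") base[g] + amp[g] / (1 + exp(-rate[g] * (t - t0[g])))
      else base[g] + amp[g] * exp(-(t - t0[g])^2 / (2 * width[g]^2))
    }
    n_dpg <- round(dpg_fraction * n_genes)
    dpg_idx <- sort(sample.int(n_genes, n_dpg))
    delta <- numeric(n_genes)
    if (n_dpg > 0)
      delta[dpg_idx] <- stats::runif(n_dpg, delta_range[1], delta_range[2]) *
        sample(c(-1, 1), n_dpg, replace = TRUE)
    vA <- array(0, c(n_genes, length(times), reps))
    vB <- array(0, c(n_genes, length(times), reps))
    for (g in seq_len(n_genes)) {
      muA <- template(g, times)
      muB <- template(g, times - delta[g] * span)
      for (r in seq_len(reps)) {
        vA[g, , r] <- muA + stats::rnorm(length(times), 0, noise_sd)
        vB[g, , r] <- muB + stats::rnorm(length(times), 0, noise_sd)
      }
    }
    list(query = expression_time_course("breedA", phase, genes, times, vA),
         reference = expression_time_course("breedB", phase, genes, times, vB),
         truth = data.frame(gene = genes[dpg_idx], delta = delta[dpg_idx],
                            stringsAsFactors = FALSE))
  })
}

#' Simulate replicated bisulfite count tracks with injected DMRs
#'
#' CpG sites are scattered at `cpg_density`; each 1-kb tile has a baseline
#' methylation level drawn from Beta(2, 2). In truth DMR tiles, group 1's
#' level is shifted by +-`delta` (clamped to `[0, 1]`). Per CpG and
#' sample, coverage ~ Poisson(`coverage_mean`) and the methylated count is
#' Binomial(coverage, level).
#'
#' @param layout a `genome_layout`.
#' @param cpg_density expected CpGs per bp.
#' @param reps samples per group.
#' @param n_dmr number of truth DMR tiles.
#' @param delta methylation-level shift (proportion, 0 <= delta <= 1; 0 gives null data).
#' @param coverage_mean mean per-CpG coverage.
#' @param dmr_regions optional `interval_set`; when given, truth DMR
#'   tiles are drawn from the 1-kb tiles overlapping these regions
#'   (instead of uniformly), up to `n_dmr`.
#' @param seed integer seed.
#' @return list(group1, group2 = lists of CpG data.frames (chrom, pos,
#'   strand, meth, total); truth = `interval_set` of DMR tiles with the
#'   signed shift in `score`).
#' @export
gen_methylome <- function(layout, cpg_density = 0.01, reps = 3, n_dmr = 10,
                          delta = 0.4, coverage_mean = 30,
                          dmr_regions = NULL, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), reps >= 1,
            delta >= 0, delta <= 1)
  tile <- 1000
  with_seed(seed, {
    chroms <- c(); poss <- c()
    for (ch in names(layout)) {
      L <- unclass(layout)[[ch]]
      ns <- stats::rpois(1, cpg_density * L)
      p <- sort(sample.int(L, min(ns, L)) - 1)
      chroms <- c(chroms, rep(ch, length(p)))
      poss <- c(poss, p)
    }
    tile_id <- paste0(chroms, ":", floor(poss / tile))
    utiles <- unique(tile_id)
    base_level <- stats::setNames(stats::rbeta(length(utiles), 2, 2), utiles)
    candidates <- utiles
    if (!is.null(dmr_regions)) {
      tch <- sub(":.*", "", utiles)
      tstartv <- as.numeric(sub(".*:", "", utiles)) * tile
      tl_gr <- GenomicRanges::GRanges(tch, IRanges::IRanges(tstartv + 1,
                                                            tstartv + tile))
      candidates <- utiles[IRanges::overlapsAny(tl_gr,
                                                as_granges(dmr_regions))]
      n_dmr <- min(n_dmr, length(candidates))
    }
    if (n_dmr > length(candidates))
      stop("fewer tiles with CpGs than requested DMRs")
    dmr_tiles <- sample(candidates, n_dmr)
    shift <- stats::setNames(rep(0, length(utiles)), utiles)
    # shift away from the nearer boundary so the injected effect size is
    # the full delta whenever delta <= 0.5 (clamping would silently
    # shrink the truth effect)
    shift[dmr_tiles] <- delta * ifelse(base_level[dmr_tiles] <= 0.5, 1, -1)
    lev1 <- pmin(pmax(base_level + shift, 0), 1)
    lev2 <- base_level
    n_clamped <- sum((base_level + shift) != lev1)
    if (n_clamped > 0)
      message(n_clamped, " shifted tile level(s) clamped to [0,1]")
    make_group <- function(levels) {
      lapply(seq_len(reps), function(r) {
        lv <- levels[tile_id]
        cov <- stats::rpois(length(poss), coverage_mean)
        meth <- stats::rbinom(length(poss), cov, lv)
        data.frame(chrom = chroms, pos = poss, strand = "+",
                   meth = meth, total = cov, stringsAsFactors = FALSE)
      })
    }
    g1 <- make_group(lev1)
    g2 <- make_group(lev2)
    tchrom <- sub(":.*", "", dmr_tiles)
    tstart <- as.numeric(sub(".*:", "", dmr_tiles)) * tile
    truth <- interval_set(tchrom, tstart,
                          pmin(tstart + tile, unclass(layout)[tchrom]),
                          layout, score = shift[dmr_tiles])
    list(group1 = g1, group2 = g2, truth = truth)
  })
}

#' Simulate gene models, genomic features and a trait map
#'
#' Places non-overlapping protein-coding gene models (1-3 exons, CDS
#' starting ATG and ending at a stop codon, length divisible by 3, UTRs on
#' both ends) on a random genome, writes each coding sequence into the
#' reference, and derives the feature classes used downstream: promoter
#' (2 kb upstream of the TSS), exon, intron, intergenic (complement of
#' gene spans), and TE (random intervals covering about `te_fraction` of
#' the genome). Genes are assigned to trait classes independently at
#' `trait_rate`.
#'
#' @param layout a `genome_layout`.
#' @param n_genes number of genes.
#' @param te_fraction fraction of the genome covered by TE intervals.
#' @param trait_classes character vector of trait class names.
#' @param trait_rate per-class membership probability.
#' @param seed integer seed.
#' @return list(models = gene-model data.frame, sequences = named
#'   character vector of chromosome sequences, features = named list of
#'   `interval_set`s, traits = named list of gene-id vectors,
#'   universe = all gene ids).
#' @export
gen_annotation <- function(layout, n_genes = 10, te_fraction = 0.1,
                           trait_classes = c("growth", "meat_quality",
                                             "reproduction", "health"),
                           trait_rate = 0.15, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  with_seed(seed, {
    seqs <- lapply(names(layout), function(ch)
      sample(bases, unclass(layout)[[ch]], replace = TRUE))
    names(seqs) <- names(layout)
    models <- list(); placed <- list()
    for (ch in names(layout)) placed[[ch]] <- interval_set(
      character(), numeric(), numeric(), layout)
    for (g in seq_len(n_genes)) {
      ok <- FALSE
      for (try in 1:200) {
        ch <- sample(names(layout), 1,
                     prob = unclass(layout) / sum(unclass(layout)))
        L <- unclass(layout)[[ch]]
        n_cod <- sample(20:60, 1)
        cds_len <- 3 * (n_cod + 2)          # ATG + codons + stop
        u5 <- sample(30:120, 1); u3 <- sample(30:120, 1)
        tx_len <- u5 + cds_len + u3
        n_ex <- sample(1:3, 1)
        if (n_ex == 1) ex_len <- tx_len
        else {
          cuts <- sort(sample(seq(30, tx_len - 30, by = 1), n_ex - 1))
          ex_len <- diff(c(0, cuts, tx_len))
          if (any(ex_len < 20)) next
        }
        in_len <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE)
                  else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (L < span + 6000) next
        gstart <- sample.int(L - span - 6000, 1) + 3000
        cand <- c(gstart, gstart + span)
        prior <- placed[[ch]]
        clash <- nrow(prior) > 0 &&
          any(pmax(prior$start, cand[1]) < pmin(prior$end, cand[2]))
        if (clash) next
        strand <- sample(c("+", "-"), 1)
        ex_starts <- gstart + cumsum(c(0, utils::head(ex_len, -1) +
                                            in_len))
        ex_ends <- ex_starts + ex_len
        # transcript coordinate -> genomic position map (5'->3' on + strand
        # genomic order; for - strand transcript reads right to left)
        tx2gen <- unlist(lapply(seq_len(n_ex), function(e)
          seq(ex_starts[e], ex_ends[e] - 1)))
        if (strand == "-") tx2gen <- rev(tx2gen)
        coding <- c("ATG", sample(sense, n_cod, replace = TRUE),
                    sample(stops, 1))
        cds_chars <- strsplit(paste(coding, collapse = ""), "")[[1]]
        cds_tx <- seq(u5 + 1, u5 + cds_len)
        cds_gen <- tx2gen[cds_tx]
        # write the coding sequence into the reference (reverse-complement
        # for - strand genes, whose transcript reads right to left)
        seqs[[ch]][cds_gen + 1] <-
          if (strand == "+") cds_chars else chartr("ACGT", "TGCA", cds_chars)
        cds_iv <- runs_to_intervals(sort(cds_gen))
        models[[g]] <- data.frame(
          gene = sprintf("gene%03d", g), chrom = ch, strand = strand,
          tx_start = gstart, tx_end = gstart + span,
          exon_starts = paste(ex_starts, collapse = ","),
          exon_ends = paste(ex_ends, collapse = ","),
          cds_starts = paste(cds_iv$start, collapse = ","),
          cds_ends = paste(cds_iv$end, collapse = ","),
          stringsAsFactors = FALSE)
        placed[[ch]] <- interval_set(
          c(placed[[ch]]$chrom, ch), c(placed[[ch]]$start, gstart),
          c(placed[[ch]]$end, gstart + span), layout)
        ok <- TRUE
        break
      }
      if (!ok) stop("genome too small to place ", n_genes, " genes")
    }
    models <- do.call(rbind, models)
    sequences <- vapply(seqs, paste, "", collapse = "")
    features <- annotation_features(models, layout, te_fraction)
    universe <- models$gene
    traits <- lapply(stats::setNames(trait_classes, trait_classes),
                     function(cl)
                       universe[stats::runif(length(universe)) < trait_rate])
    list(models = models, sequences = sequences, features = features,
         traits = traits, universe = universe)
  })
}

# Collapse a sorted vector of positions into half-open intervals.
runs_to_intervals <- function(pos) {
  br <- which(diff(pos) > 1)
  start <- pos[c(1, br + 1)]
  end <- pos[c(br, length(pos))] + 1
  data.frame(start = start, end = end)
}

# Derive promoter/exon/intron/intergenic/TE interval sets from gene models.
annotation_features <- function(models, layout, te_fraction = 0.1) {
  ex <- list(); intr <- list(); prom <- list()
  for (g in seq_len(nrow(models))) {
    m <- parse_gene_model(models[g, ])
    ex[[g]] <- data.frame(chrom = m$chrom, start = m$exon_starts,
                          end = m$exon_ends)
    if (length(m$exon_starts) > 1)
      intr[[g]] <- data.frame(chrom = m$chrom,
                              start = utils::head(m$exon_ends, -1),
                              end = utils::tail(m$exon_starts, -1))
    tss <- if (m$strand == "+") m$tx_start else m$tx_end
    ps <- max(0, if (m$strand == "+") tss - 2000 else tss)
    pe <- min(unclass(layout)[[m$chrom]],
              if (m$strand == "+") tss else tss + 2000)
    if (ps < pe)
      prom[[g]] <- data.frame(chrom = m$chrom, start = ps, end = pe)
  }
  bindiv <- function(lst) {
    df <- do.call(rbind, lst)
    if (is.null(df)) interval_set(character(), numeric(), numeric(), layout)
    else interval_set(df$chrom, df$start, df$end, layout)
  }
  exons <- bindiv(ex); introns <- bindiv(intr); promoters <- bindiv(prom)
  genes_iv <- interval_set(models$chrom, models$tx_start, models$tx_end,
                           layout)
  gaps_gr <- GenomicRanges::gaps(GenomicRanges::reduce(as_granges(genes_iv)))
  gaps_gr <- gaps_gr[as.character(GenomicRanges::strand(gaps_gr)) == "*"]
  intergenic <- granges_to_intervals(gaps_gr, layout)
  # TE intervals: random 200-2000 bp pieces until te_fraction is covered
  te <- list(); covered <- 0; total <- sum(unclass(layout)); k <- 0
  while (covered < te_fraction * total && k < 10000) {
    k <- k + 1
    ch <- sample(names(layout), 1, prob = unclass(layout) / total)
    L <- unclass(layout)[[ch]]
    len <- sample(200:2000, 1)
    if (L <= len) next
    s <- sample.int(L - len, 1)
    te[[length(te) + 1]] <- data.frame(chrom = ch, start = s, end = s + len)
    covered <- covered + len
  }
  tes <- bindiv(te)
  list(promoter = promoters, exon = exons, intron = introns,
       intergenic = intergenic, TE = tes, gene = genes_iv)
}

#' Write / read gene models as TSV
#'
#' Columns: gene, chrom, strand, tx_start, tx_end, exon_starts, exon_ends,
#' cds_starts, cds_ends (comma-joined, 0-based half-open).
#'
#' @param models gene-model data.frame.
#' @param path file path.
#' @return `path` / the data.frame.
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(models, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(exon_starts = "character",
                                   exon_ends = "character",
                                   cds_starts = "character",
                                   cds_ends = "character"))
}

#' Write / read per-CpG bisulfite counts as TSV
#'
#' Columns: chrom, pos (0-based), strand, meth, total.
#'
#' @param x CpG data.frame.
#' @param path file path.
#' @return `path` / the data.frame.
#' @export
write_cpg_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cpg_table
#' @export
read_cpg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (any(df$meth > df$total)) stop("meth count exceeds coverage in ", path)
  df
}

#' Write / read an expression time course as long-format TSV
#'
#' Columns: gene, stage_time, replicate, value; breed and phase are kept
#' in header comment lines.
#'
#' @param x an `expression_time_course`.
#' @param path file path.
#' @return `path` / an `expression_time_course`.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# breed=", x$breed), paste0("# phase=", x$phase)), con)
  d <- dim(x$values)
  df <- data.frame(
    gene = rep(x$genes, times = d[2] * d[3]),
    stage_time = rep(rep(x$times, each = d[1]), times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$values))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  hdr <- readLines(path, n = 2)
  breed <- sub("# breed=", "", hdr[1], fixed = TRUE)
  phase <- sub("# phase=", "", hdr[2], fixed = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  genes <- unique(df$gene)
  times <- sort(unique(df$stage_time))
  reps <- sort(unique(df$replicate))
  v <- array(NA_real_, c(length(genes), length(times), length(reps)))
  gi <- match(df$gene, genes); ti <- match(df$stage_time, times)
  ri <- match(df$replicate, reps)
  v[cbind(gi, ti, ri)] <- df$value
  expression_time_course(breed, phase, genes, times, v)
}

#' Write a ground-truth manifest as JSON
#'
#' @param truth a list (as returned by the generators).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  to_plain <- function(x) {
    if (inherits(x, "interval_set")) as.data.frame(x)
    else if (is.list(x) && !is.data.frame(x)) lapply(x, to_plain)
    else x
  }
  jsonlite::write_json(to_plain(truth), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
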