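---
title: "Methods: sweep scanning, developmental heterochrony and differential methylation in sweepomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning, developmental heterochrony and differential methylation in sweepomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sweepomics implements the statistical core of an integrative domestication
genomics analysis: where in the genome has selection reshaped allele
frequencies, which genes run on a shifted developmental clock between a
domesticated and a local breed, which genomic tiles are differentially
methylated between them, and whether these three layers coincide more than
chance allows. Every component is exercised end to end against synthetic data
with known ground truth; this vignette records the models, the tunable
parameters, and the design choices that were genuinely open.

## Coordinates and containers

All intervals are 0-based half-open (BED convention). VCF positions are
converted on read (`pos - 1`) and write (`pos + 1`). Windows tile each
chromosome from 0 and trailing partial windows are dropped, so a chromosome of
length $L$ yields $\lfloor (L - w)/s \rfloor + 1$ windows of size $w$ at step
$s$; fixed-size windows keep per-window statistics comparable without length
normalization. Genotypes live in a `site_matrix` of alternate-allele dosages
(0/1/2, `NA` for missing); per-site haploid sample sizes count called alleles
only, so no imputation is ever needed.

## The hitchhiking CLR scan

The sweep scan compares, window by window, a composite likelihood of the
observed site frequency spectrum (SFS) under a selective sweep against the
genome-wide background. The background $b_j$ is the normalized frequency of
derived-count classes $j = 1..n-1$ (or minor-count classes when folded, the
default — no outgroup polarization is assumed), with every site
hypergeometrically projected to a common haploid size $n_0$ (the 20th
percentile of per-site called-allele counts; lower-coverage sites are
dropped). Sites whose called-allele count exceeds $n_0$ have their observed
count rescaled deterministically (`round(j * n0 / n_s)`), keeping the scan a
pure function of its inputs; with complete data this is the identity.

The sweep model is the star-genealogy approximation of the
SweepFinder/SweeD family. A lineage at distance $d$ bp from a sweep of
per-bp intensity $\alpha$ escapes the sweep with probability
$p_e = 1 - e^{-\alpha \max(d, d_{\min})}$ (clamp $d_{\min} = 1$ bp). With
$e \sim \mathrm{Binomial}(n, p_e)$ escapees, the escapees plus the single
sweeping ancestor are $e + 1$ exchangeable draws from the pre-sweep
population — the background projected to $m = e + 1$ alleles, monomorphic
outcomes included. The ancestor carries the derived allele with probability
$j'/m$, in which case all $n - e$ hitchhiking lineages inherit it, giving a
final derived count $(n - e) + (j' - 1)$; otherwise the count is $j'$. Mass
is renormalized over polymorphic outcomes $1..n-1$; if the polymorphic mass
falls below $10^{-12}$ the background itself is returned. Folded spectra are
handled by symmetrizing the background and summing the model's symmetric
classes.

For a window centered at $x$,
$$\mathrm{CLR}(x) = 2 \max_{\alpha}
  \sum_i \left[ \log P_{\text{sweep}}(j_i \mid |s_i - x|, \alpha)
              - \log b_{j_i} \right],$$
maximized over a grid of 50 log-spaced intensities in
$[10^{-7}, 10^{-1}]$ per bp (spanning $\alpha d \ll 1$ to $\gg 1$ for loci up
to megabase scale); `alpha_hat` is the argmax, first grid point on ties.
Where $p_e > 1 - 10^{-6}$ the site's log-ratio is exactly negligible and is
skipped (the "neutral shortcut"); the compiled scan restricts each window's
inner loop to the sites within the shortcut radius, which is why the factor
2 and the tolerance appear in the reported statistic but not in its cost.
The reported CLR is $2\times$ the log composite-likelihood ratio — monotone
in the conventional ratio, so top-percentile calling is unaffected. Note
that the scan can report values a few parts in $10^{3}$ below zero when the
grid's largest intensity is not yet neutral at the distance clamp; a grid
containing $\alpha d_{\min} \ge 25$ restores $\mathrm{CLR} \ge 0$ to
numerical tolerance.

Windowed diversity and differentiation follow the named tools' conventions:
$\pi$ sums the per-site unbiased heterozygosity $2j(n_s-j)/(n_s(n_s-1))$ and
divides by window length (not callable sites); FST is the Weir–Cockerham
(1984) weighted ratio-of-sums over sites segregating in the pooled sample,
with windows under 10 contributing SNPs set missing. The $\pi$ ratio is
oriented wild/domesticated, so its high tail flags diversity loss in the
domesticated group. Candidate windows are the top 1% of each statistic, ties
at the threshold included; domesticated top-CLR windows overlapping any
wild candidate window by $\ge 1$ bp can be dropped with
`remove_shared_candidates()` (the overlap rule is an interpretation — the
source procedure is stated only as removal of overlapped windows). Samples
with more than 20% ancestry on the opposite group's component (ADMIXTURE-style
$K = 2$ coefficients) are excluded, exactly 20% is retained; sites with pooled
minor-allele frequency strictly below 5% are removed. Near-fixed differences
are SNPs inside swept-gene spans with $|\Delta AF| > 0.7$ strictly.

## Variant consequences

`classify_variant()` assigns one category per site against single-transcript
gene models by fixed priority: splice (intronic, within 2 bp of a junction) >
coding > UTR > intron > upstream/downstream (within 1 kb of TSS/TES,
strand-aware) > intergenic; with overlapping genes the most severe call wins
(stop-gain before stop-loss before start-loss before missense before
synonymous). Coding calls translate the affected codon on the coding strand
with the standard nuclear code. INDELs and multi-transcript resolution are out
of scope. The test suite validates every possible CDS substitution on a
synthetic genome against independent re-translation of the mutated CDS, and
checks reverse-strand genes against their mirrored plus-strand models.

## Developmental heterochrony (DTW / PAS / DPGs)

Expression trajectories (normalized log scale; one per breed, phase analyzed
separately — prenatal and postnatal stages are biologically distinct programs)
are compared per gene:

1. Replicates are averaged per stage and interpolated with a monotone cubic
   spline (Fritsch–Carlson; no overshoot) onto a $T = 100$ uniform grid.
2. Each curve is min-max scaled to $[0, 1]$. Range scaling, rather than a
   z-score, was a deliberate choice: for a truncated sigmoid trajectory a
   time shift changes how much of each plateau is observed, so z-scores move
   the two breeds' plateau levels apart and the warping step then matches
   the wrong segments — flipping the score's sign even without noise. Range
   scaling pins both plateaus and preserves the intended sign semantics.
   Constant trajectories are flagged and excluded from calling.
3. Unconstrained symmetric dynamic time warping with squared-difference
   local cost, steps $\{(1,0),(0,1),(1,1)\}$ and anchored endpoints yields
   the globally minimal-cost monotone path (computed by dynamic programming
   in compiled code; ties in backtracking prefer the diagonal).
4. The progression-advanced score is the mean path offset
   $\mathrm{PAS} = \overline{(b_k - a_k)}/(T-1)$ ($a$ = query index, $b$ =
   reference index): positive means the query breed reaches matched
   expression states earlier (query accelerated). PAS is exactly
   antisymmetric under query/reference exchange. Because the path is
   anchored at both ends, PAS is attenuated relative to the injected shift
   (a shift of 0.2 of the span typically scores about 0.15).
5. Significance comes from a replicate bootstrap (resampling replicates with
   replacement within each stage and breed, 100 draws), two-sided with the
   +1 correction. A gene is a differentially progressing gene (DPG) when
   $|\mathrm{PAS}| \ge 0.1$, aligned-path Pearson correlation $\ge 0.5$ and
   $p < 0.05$; all three are configuration, not constants.

Whole-transcriptome stage correspondence runs the same DTW over actual
stages with local cost $1 - r$ between stage profiles, no interpolation.

## DMC/DMR calling

Per-sample CpG counts are aligned on the union of sites (duplicate rows are
accumulated, so pooled levels are invariant to row splitting; strands are
kept distinct — no strand merging). DMCs test single sites where every
sample has coverage $\ge 10$; DMRs tile the genome in 1-kb non-overlapping
tiles (window = step = 1000 bp), keep CpGs with coverage $\ge 5$ in every
sample, require $\ge 3$ retained CpGs per tile and sum counts per sample
within the tile. The test is a binomial logistic regression of
methylated/unmethylated counts on the group indicator with a
likelihood-ratio p (with a single sample per group, Fisher's exact test on
pooled counts). Correction is Bonferroni over the tiles tested within one
stage comparison — the smallest family consistent with per-stage reporting;
significance requires $q < 0.05$ and $|\text{meth.diff}| > 30$ percentage
points, where meth.diff is $100\times$(mean group-1 level − mean group-2
level) and hypo means group 1 lower. Feature-level methylation pools counts
(promoter = TSS ± 2 kb, strand-aware; gene body = TSS→TES), and
methylation–expression correlation is Pearson's $r$ after removing genes
with normalized expression outside $[0, 20]$. Persistence grouping bins
tiles by the number of stages at which they are significant (prenatal 1–5 /
6–10 / 11–15; postnatal 1–4 / 5–8 / 9–12) and reports each group's
hypomethylated fraction.

## Enrichment statistics

The interval permutation null relocates each query interval uniformly within
its chromosome (length and chromosome preserved, overlaps among relocated
intervals permitted), holding the other set fixed — the simplest null
consistent with an unconditional permutation test; spacing-preserving nulls
are not implemented. Statistics: bp-level Jaccard (sets merged first),
overlap count, or overlapping bp. $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(n_{\text{perm}} + 1)$, never 0; the depletion tail is the
mirror. Fold change is reported as observed/expected — $(obs + 1)/(median +
1)$ for counts, $obs/median$ for Jaccard — i.e. enrichment $> 1$; note that
when the observed statistic is already maximal every permutation ties it and
the enrichment $p$ is 1 by construction. Gene-set overlap uses the same
conventions with the null redrawing the query set uniformly from the
universe, whose distribution is exactly hypergeometric — the suite verifies
the permutation p against the closed-form tail. Trait/QTL enrichment is the
upper-tail hypergeometric test per trait class, BH-adjusted by default
(Bonferroni available). DMR–SNP proximity reports, per region, the bp gap to
the nearest SNP (0 if one lies inside) and the fractions within 5 kb and
50 kb.

## The synthetic-data generators

The generators emulate the statistical structure the analysis assumes — not
the raw data modalities (no reads, no alignment, no linkage):

* **Genotypes**: two populations of 20 diploids (40 haplotypes each) by
  default; SNPs at $2 \times 10^{-3}$/bp with neutral derived counts drawn
  independently per population from the Watterson spectrum
  ($b_j \propto 1/j$), and sites near a sweep center drawn from the same
  hitchhiking distribution the scan fits (at the study-scale intensity
  $\alpha = 10^{-5}$/bp in the recovery experiments). Site-wise generation
  rather than coalescent simulation is deliberate: it makes the generator an
  exact self-consistency oracle for the CLR model and keeps desk-scale
  runtime; no in-scope statistic uses linkage. A configurable fraction of
  sites become fixed differences ($\Delta AF = 1$).
* **Expression**: 15 prenatal stages mapped to days −81..−9 (embryonic day −
  114) and 12 postnatal stages at days 0..180. Each gene follows a logistic
  or Gaussian-bump template with amplitude 2–6 log units over a baseline of
  2–8; shifted genes evaluate breed B at $t - \delta \cdot \text{span}$, so
  positive $\delta$ makes breed A advanced. Template features are constrained
  to lie well inside the observed window with transitions spanning a sizable
  fraction of it: a trajectory that is linear (or flat) across the window
  carries no recoverable time shift after normalization, and truth that is
  unrecoverable in principle would break the recall contract of the
  manifests. Replicate noise is additive Gaussian (default sd 0.25).
* **Methylome**: CpGs at $10^{-2}$/bp, per-1-kb-tile baseline levels from
  Beta(2,2), coverage Poisson(30), methylated counts Binomial(coverage,
  level); truth tiles shift one group's level by $\Delta$ away from the
  nearer boundary (so the injected effect is exactly $\Delta$ for
  $\Delta \le 0.5$; random signs would silently clamp some truth effects).
* **Annotation**: non-overlapping 1–3-exon protein-coding genes with UTRs,
  CDS beginning ATG, ending a stop, divisible by 3, written into a random
  reference; promoters (2 kb upstream), exons, introns, intergenic
  complement, and random TE intervals; a trait map assigns genes to classes
  independently at rate 0.15.

All generators restore the caller's RNG state and are pure functions of
(configuration, seed).

What passing on these data does and does not show: the generators have no
linkage disequilibrium, no demographic structure, no batch effects, no
read-level noise, and their trajectory shapes are smooth two-parameter
families. Recovery rates measured here are therefore upper bounds on what
identical settings would achieve on real data; conversely the exact oracles
(CLR enumeration, pairwise-difference $\pi$, Weir–Cockerham transcription,
DTW path enumeration, hypergeometric tails, GLM likelihood ratios) validate
the implementations themselves, independent of data realism.

## Numerical choices and degenerate inputs

Binomial mixture weights are computed by a stable two-sided recurrence
(anchored at $(1-p)^n$ or $p^n$, whichever does not underflow). Quantile
thresholds for top-window calling include ties. Windows without usable SNPs
report missing CLR; tiles with fewer than 3 retained CpGs are skipped;
features without CpGs report missing methylation; constant expression
trajectories are flagged and never called. Empty interval sets refuse the
Jaccard index (undefined) and the permutation test refuses intervals longer
than their chromosome.

## Problem sizes used by the suite

The test and acceptance runs use desk-scale versions of the study design,
stated here as the package's own experiment sizes: sweep recovery on a 1-Mb
chromosome over 100 seeds (50 for the intensity estimate in the acceptance
script), DPG recovery with 500 genes (10% shifted at $|\delta| = 0.2$, noise
0.25, 3 replicates) plus 10 null seeds of 60 genes, DMR calibration over 50
null seeds and recovery over 5 seeds of 10 truth tiles each, 20,000
permutations for the gene-set law check and 100 independent runs for
permutation calibration.

## Known limitations

PAS values are attenuated, path-dependent summaries — comparable in sign and
ordering, not calibrated in units of developmental time; no numeric
equivalence with any external tool's scores is claimed. The DMR family-wise
correction is per stage comparison; a genome-and-stages family would be more
conservative. The admixture filter infers which ancestry component belongs
to which population from mean coefficients, which requires the two groups to
be the dominant components. The consequence caller handles one transcript
per gene and SNVs only.
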