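# Variant consequence classification against single-transcript gene
# models. Categories: synonymous, missense, stop_gain, stop_loss,
# start_loss, splice, utr, intron, upstream, downstream, intergenic.

CONSEQUENCE_SEVERITY <- c("splice", "stop_gain", "stop_loss", "start_loss",
                          "missense", "synonymous", "utr", "intron",
                          "upstream", "downstream", "intergenic")

# Parse one gene-model row (comma-joined coordinate lists) into vectors.
parse_gene_model <- function(row) {
  nums <- function(s) as.numeric(strsplit(as.character(s), ",")[[1]])
  list(gene = row$gene, chrom = row$chrom, strand = row$strand,
       tx_start = row$tx_start, tx_end = row$tx_end,
       exon_starts = nums(row$exon_starts), exon_ends = nums(row$exon_ends),
       cds_starts = nums(row$cds_starts), cds_ends = nums(row$cds_ends))
}

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Read / write a reference genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}

#' @rdname read_reference_fasta
#' @param sequences named character vector.
#' @export
write_reference_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

# Classify one variant against one gene model; returns NULL when the
# variant is out of the gene's reach (beyond the flank).
classify_against_gene <- function(pos, ref, alt, m, sequences,
                                  flank, splice_window) {
  if (m$strand != "+" && m$strand != "-")
    stop("strand must be + or - for gene ", m$gene)
  res <- list(gene = m$gene, category = NA_character_,
              codon_change = NA_character_, aa_change = NA_character_)
  inside <- pos >= m$tx_start && pos < m$tx_end
  if (!inside) {
    # upstream within flank of the TSS, downstream within flank of the TES
    if (m$strand == "+") {
      if (pos < m$tx_start && m$tx_start - pos <= flank) res$category <- "upstream"
      else if (pos >= m$tx_end && pos - m$tx_end + 1 <= flank) res$category <- "downstream"
    } else {
      if (pos >= m$tx_end && pos - m$tx_end + 1 <= flank) res$category <- "upstream"
      else if (pos < m$tx_start && m$tx_start - pos <= flank) res$category <- "downstream"
    }
    if (is.na(res$category)) return(NULL)
    return(res)
  }
  in_exon <- any(pos >= m$exon_starts & pos < m$exon_ends)
  if (!in_exon) {
    # intron; splice when within splice_window bp of a junction
    n_ex <- length(m$exon_starts)
    for (k in seq_len(n_ex - 1)) {
      i_start <- m$exon_ends[k]; i_end <- m$exon_starts[k + 1]
      if (pos >= i_start && pos < i_end) {
        near <- (pos - i_start < splice_window) ||
          (i_end - 1 - pos < splice_window)
        res$category <- if (near) "splice" else "intron"
        return(res)
      }
    }
    res$category <- "intron"
    return(res)
  }
  # exonic: CDS or UTR
  cds_pos <- unlist(lapply(seq_along(m$cds_starts), function(k)
    seq(m$cds_starts[k], m$cds_ends[k] - 1)))
  cds_pos <- sort(cds_pos)
  hit <- match(pos, cds_pos)
  if (is.na(hit)) {
    res$category <- "utr"
    return(res)
  }
  Lc <- length(cds_pos)
  if (Lc %% 3 != 0) {
    warning("CDS length of ", m$gene, " not divisible by 3; skipped")
    return(NULL)
  }
  idx <- if (m$strand == "+") hit else Lc - hit + 1   # 1-based CDS offset
  codon_no <- (idx - 1) %/% 3 + 1
  within <- (idx - 1) %% 3 + 1
  cds_oriented <- if (m$strand == "+") cds_pos else rev(cds_pos)
  codon_gen <- cds_oriented[(codon_no - 1) * 3 + 1:3]
  base_at <- function(p) substr(sequences[[m$chrom]], p + 1, p + 1)
  ref_codon_plus <- vapply(sort(codon_gen), base_at, "")
  ref_codon <- if (m$strand == "+") paste(ref_codon_plus, collapse = "")
               else revcomp(paste(ref_codon_plus, collapse = ""))
  if (base_at(pos) != ref)
    stop("ref allele mismatch at ", m$chrom, ":", pos + 1,
         " (expected ", base_at(pos), ", got ", ref, ")")
  alt_or <- if (m$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_or
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  res$codon_change <- paste0(ref_codon, ">", alt_codon)
  res$aa_change <- paste0(ref_aa, codon_no, alt_aa)
  res$category <-
    if (codon_no == 1 && ref_codon == "ATG" && alt_codon != "ATG") "start_loss"
    else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
    else if (ref_aa != "*" && alt_aa == "*") "stop_gain"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  res
}

#' Classify a SNP into a functional category
#'
#' Assigns the functional category against single-transcript
#' gene models by fixed priority: splice > coding > UTR > intron >
#' upstream/downstream > intergenic. Coding calls translate the affected
#' codon on the coding strand with the standard nuclear code. When a site
#' hits several genes, the most severe category wins.
#'
#' @param chrom,pos site (pos 0-based).
#' @param ref,alt single-base alleles (as on the + strand).
#' @param models gene-model data.frame (see [write_gene_models()]).
#' @param sequences named character vector of chromosome sequences.
#' @param flank upstream/downstream reach from TSS/TES in bp.
#' @param splice_window intronic bp around a junction called splice.
#' @return one-row data.frame: chrom, pos, ref, alt, gene, category,
#'   codon_change, aa_change.
#' @export
classify_variant <- function(chrom, pos, ref, alt, models, sequences,
                             flank = 1000, splice_window = 2) {
  cand <- models[models$chrom == chrom, , drop = FALSE]
  calls <- list()
  for (g in seq_len(nrow(cand))) {
    m <- parse_gene_model(cand[g, ])
    r <- classify_against_gene(pos, ref, alt, m, sequences,
                               flank, splice_window)
    if (!is.null(r)) calls[[length(calls) + 1]] <- r
  }
  if (length(calls) == 0) {
    best <- list(gene = NA_character_, category = "intergenic",
                 codon_change = NA_character_, aa_change = NA_character_)
  } else {
    sev <- vapply(calls, function(r)
      match(r$category, CONSEQUENCE_SEVERITY), 0L)
    best <- calls[[which.min(sev)]]
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = best$gene, category = best$category,
             codon_change = best$codon_change, aa_change = best$aa_change,
             stringsAsFactors = FALSE)
}

#' Classify many SNPs
#'
#' @param sites data.frame with columns chrom, pos, ref, alt.
#' @inheritParams classify_variant
#' @return data.frame of consequence calls, one row per site.
#' @export
classify_variants <- function(sites, models, sequences, flank = 1000,
                              splice_window = 2) {
  do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    classify_variant(sites$chrom[i], sites$pos[i], sites$ref[i],
                     sites$alt[i], models, sequences, flank, splice_window)))
}

#' Tally consequence categories
#'
#' @param calls data.frame of consequence calls.
#' @return named integer vector over all categories (zeros included);
#'   the values sum to `nrow(calls)`.
#' @export
summarize_consequences <- function(calls) {
  counts <- stats::setNames(integer(length(CONSEQUENCE_SEVERITY)),
                            CONSEQUENCE_SEVERITY)
  if (nrow(calls) > 0) {
    tb <- table(calls$category)
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}
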