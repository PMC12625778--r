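#' Genome layout
#'
#' Ordered chromosome names and lengths used by all interval containers.
#' All coordinates in the package are 0-based half-open (BED convention);
#' VCF positions are converted on read (pos - 1) and on write (pos + 1).
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths numeric vector of chromosome lengths in bp (> 0).
#' @return An object of class `genome_layout`: a named numeric vector of
#'   lengths, ordered as given.
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be finite and > 0")
  structure(stats::setNames(chrom_lengths, chrom_names), class = "genome_layout")
}

#' Interval set
#'
#' A set of genomic intervals (0-based half-open) tied to a [genome_layout()].
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors; 0 <= start < end <= chromosome length.
#' @param layout a `genome_layout`.
#' @param label optional character vector of interval labels.
#' @param score optional numeric vector carried through to BED column 5.
#' @return A data.frame of class `interval_set` with columns chrom, start,
#'   end (and label/score when given) and the layout stored as an attribute.
#' @export
interval_set <- function(chrom, start, end, layout, label = NULL, score = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  bad <- !(chrom %in% names(layout))
  if (any(bad))
    stop("chromosome(s) not in layout: ", paste(unique(chrom[bad]), collapse = ", "))
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end (empty interval)")
  if (any(end > unclass(layout)[chrom]))
    stop("interval end exceeds chromosome length")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.character(label)
  if (!is.null(score)) df$score <- as.numeric(score)
  attr(df, "layout") <- layout
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @export
as.data.frame.interval_set <- function(x, ...) {
  attr(x, "layout") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d intervals on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

layout_of <- function(x) {
  ly <- attr(x, "layout")
  if (is.null(ly)) stop("interval_set has no layout attribute")
  ly
}

# GRanges view of an interval_set (1-based closed internally to GRanges).
as_granges <- function(x) {
  ly <- layout_of(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    seqlengths = stats::setNames(as.integer(unclass(ly)), names(ly))
  )
}

granges_to_intervals <- function(gr, layout) {
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr),
               layout)
}

#' Read genomic intervals from BED or TSV
#'
#' BED: columns chrom/start/end (0-based half-open), optional name and score.
#' TSV: a header line with at least chrom/start/end columns.
#'
#' @param path file path.
#' @param layout a `genome_layout`; when NULL, a layout is inferred with each
#'   chromosome as long as its rightmost interval end.
#' @param format "BED" or "TSV".
#' @return An `interval_set`.
#' @export
read_intervals <- function(path, layout = NULL, format = c("BED", "TSV")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "BED") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                     !startsWith(lines, "track") & !startsWith(lines, "browser")]
    if (length(lines) == 0) stop("no intervals in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
      stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
    chrom <- vapply(fields, `[[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
    if (anyNA(start) || anyNA(end))
      stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
           ": non-numeric coordinates")
    if (any(start >= end))
      stop("empty interval at line ", which(start >= end)[1],
           " (start >= end)")
    label <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4) else NULL
    score <- if (all(nf >= 5))
      suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5))) else NULL
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("TSV must have columns chrom, start, end")
    chrom <- df$chrom; start <- df$start; end <- df$end
    label <- df$label; score <- df$score
    if (any(start >= end)) stop("empty interval (start >= end) in ", path)
  }
  if (is.null(layout)) {
    mx <- tapply(end, chrom, max)
    layout <- genome_layout(names(mx), as.numeric(mx))
  }
  interval_set(chrom, start, end, layout, label = label, score = score)
}

#' Write an interval set as BED
#'
#' @param x an `interval_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$label)) {
    cols <- c(cols, list(x$label))
    if (!is.null(x$score)) cols <- c(cols, list(as.character(x$score)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Tile a genome with fixed-size windows
#'
#' Windows tile each chromosome from position 0. Trailing partial windows
#' are dropped, so a chromosome of length L yields
#' `floor((L - size) / step) + 1` windows when L >= size, else 0.
#'
#' @param layout a `genome_layout`.
#' @param size window size in bp.
#' @param step step in bp; `step == size` gives non-overlapping windows.
#' @return An `interval_set` of windows.
#' @export
make_windows <- function(layout, size, step = size) {
  stopifnot(inherits(layout, "genome_layout"))
  if (size <= 0) stop("size must be > 0")
  if (step <= 0) stop("step must be > 0")
  if (step > size) stop("step must be <= size")
  res <- lapply(names(layout), function(ch) {
    L <- unclass(layout)[[ch]]
    if (L < size) return(NULL)
    n <- floor((L - size) / step) + 1
    starts <- (seq_len(n) - 1) * step
    data.frame(chrom = ch, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(interval_set(character(), numeric(), numeric(), layout))
  interval_set(res$chrom, res$start, res$end, layout)
}

#' Biallelic genotype dosage matrix
#'
#' Container for per-site alternate-allele dosages of labelled populations;
#' the substrate of all population-genetic statistics in the package.
#'
#' @param chrom,pos site coordinates (pos 0-based), strictly increasing
#'   within chromosome.
#' @param ref,alt single-base alleles per site.
#' @param dosage integer matrix, sites x samples, values 0/1/2/NA.
#' @param populations named character vector: sample -> population label.
#' @param layout optional `genome_layout`.
#' @return An object of class `site_matrix`.
#' @export
site_matrix <- function(chrom, pos, ref, alt, dosage, populations,
                        layout = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(length(chrom) == nrow(dosage), length(pos) == nrow(dosage))
  if (is.null(colnames(dosage))) stop("dosage must have sample column names")
  if (!all(colnames(dosage) %in% names(populations)))
    stop("sample(s) absent from population table: ",
         paste(setdiff(colnames(dosage), names(populations)), collapse = ", "))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  o <- order(chrom, pos)
  structure(list(
    chrom = as.character(chrom)[o], pos = as.numeric(pos)[o],
    ref = as.character(ref)[o], alt = as.character(alt)[o],
    dosage = dosage[o, , drop = FALSE],
    populations = populations[colnames(dosage)],
    layout = layout
  ), class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("site_matrix: %d sites x %d samples (%s)\n",
              length(x$pos), ncol(x$dosage),
              paste(sprintf("%s: %d", names(table(x$populations)),
                            table(x$populations)), collapse = ", ")))
  invisible(x)
}

n_sites <- function(x) length(x$pos)

subset_sites <- function(x, keep) {
  x$chrom <- x$chrom[keep]; x$pos <- x$pos[keep]
  x$ref <- x$ref[keep]; x$alt <- x$alt[keep]
  x$dosage <- x$dosage[keep, , drop = FALSE]
  x
}

pop_samples <- function(x, population) {
  names(x$populations)[x$populations == population]
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Keeps biallelic SNP records only; multi-allelic and non-SNP records are
#' skipped and counted. Genotypes are taken from the GT field: "0/0" -> 0,
#' "0/1" or "1/0" -> 1, "1/1" -> 2, missing -> NA. Positions are converted
#' to 0-based.
#'
#' @param path VCF file (plain or gzipped).
#' @param populations named character vector: sample -> population, or a
#'   data.frame with columns `sample` and `population`.
#' @param layout optional `genome_layout`.
#' @return A `site_matrix`; the number of skipped records is attached as
#'   attribute `n_skipped`.
#' @export
read_genotypes <- function(path, populations, layout = NULL) {
  if (is.data.frame(populations))
    populations <- stats::setNames(as.character(populations$population),
                                   populations$sample)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (!any(is_snp)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, names(populations))
  if (length(missing_samples) > 0)
    stop("sample(s) in VCF absent from population table: ",
         paste(missing_samples, collapse = ", "))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt_clean %in% c("0/0")] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean %in% c("1/1")] <- 2L
  m <- site_matrix(chrom = fix[is_snp, "CHROM"],
                   pos = as.numeric(fix[is_snp, "POS"]) - 1,
                   ref = ref[is_snp], alt = alt[is_snp],
                   dosage = dos, populations = populations, layout = layout)
  attr(m, "n_skipped") <- n_skipped
  m
}

#' Write a site matrix as a minimal VCF
#'
#' @param x a `site_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  samples <- colnames(x$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(x$layout))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(x$layout),
                       as.integer(unclass(x$layout))), con)
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt <- matrix("./.", n_sites(x), length(samples))
  gt[!is.na(x$dosage) & x$dosage == 0L] <- "0/0"
  gt[!is.na(x$dosage) & x$dosage == 1L] <- "0/1"
  gt[!is.na(x$dosage) & x$dosage == 2L] <- "1/1"
  body <- paste(x$chrom, format(x$pos + 1, scientific = FALSE, trim = TRUE),
                ".", x$ref, x$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Validate a BED/TSV/VCF file
#'
#' Light-weight validation entry point: parses the file with the package
#' readers and reports record counts or the first error.
#'
#' @param path file path.
#' @param format one of "BED", "TSV", "VCF".
#' @param populations required for VCF.
#' @return TRUE invisibly on success; stops with a message otherwise.
#' @export
validate_file <- function(path, format = c("BED", "TSV", "VCF"),
                          populations = NULL) {
  format <- match.arg(format)
  if (format == "VCF") {
    x <- read_genotypes(path, populations)
    message(sprintf("OK: %d biallelic SNPs, %d samples, %d records skipped",
                    n_sites(x), ncol(x$dosage), attr(x, "n_skipped")))
  } else {
    x <- read_intervals(path, format = format)
    message(sprintf("OK: %d intervals", nrow(x)))
  }
  invisible(TRUE)
}
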