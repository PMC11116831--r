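# File-format boundary: variant tables (TSV dialect and minimal VCF),
# BED interval files, and position blacklists. Variant positions are 1-based
# (VCF convention); interval coordinates are 0-based half-open (BED
# convention); conversion happens here and in .regions_to_granges only.

#' Read a mutation table (TSV dialect)
#'
#' Expects a header with columns \code{sample, chrom, pos, ref, alt} and
#' optionally \code{vaf} (positions 1-based). Non-SBS rows (multi-base ref or
#' alt) are skipped with a count.
#'
#' @param path TSV file.
#' @return Mutation data.frame; attribute \code{n_skipped_non_sbs} counts
#'   skipped indel/MNV rows.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  df <- .check_mutation_df(df, add_vaf = TRUE)
  sbs <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    toupper(df$ref) %in% .DNA_BASES & toupper(df$alt) %in% .DNA_BASES
  out <- df[sbs, , drop = FALSE]
  attr(out, "n_skipped_non_sbs") <- sum(!sbs)
  out
}

#' Write a mutation table (TSV dialect)
#'
#' @param mutations Mutation data.frame.
#' @param path Output file.
#' @export
write_variants_tsv <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read somatic variants from a VCF file
#'
#' Keeps single-base substitutions only (indels and MNVs are skipped with a
#' count). The VAF is taken, in order of preference, from an AF-style INFO or
#' FORMAT field, else computed from FORMAT allelic depths (AD), else left
#' missing.
#'
#' @param path VCF file (plain or gzipped).
#' @param sample_id Sample id to stamp on the records; defaults to the first
#'   genotype column name, or the file stem for site-only VCFs.
#' @return Mutation data.frame with attribute \code{n_skipped_non_sbs}.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_samples <- if (ncol(v@gt) > 1L) colnames(v@gt)[-1L] else character(0)
  if (is.null(sample_id)) {
    sample_id <- if (length(gt_samples)) gt_samples[1L]
                 else sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vaf <- rep(NA_real_, nrow(fix))
  info_af <- suppressWarnings(vcfR::extract.info(v, element = "AF",
                                                 as.numeric = TRUE))
  if (!is.null(info_af)) vaf <- as.numeric(info_af)
  if (all(is.na(vaf)) && length(gt_samples)) {
    af_fmt <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)),
      error = function(e) NULL)
    if (!is.null(af_fmt)) vaf <- as.numeric(af_fmt[, 1L])
    if (all(is.na(vaf))) {
      ad <- tryCatch(suppressWarnings(vcfR::extract.gt(v, element = "AD")),
                     error = function(e) NULL)
      if (!is.null(ad)) {
        parts <- strsplit(as.character(ad[, 1L]), ",", fixed = TRUE)
        vaf <- vapply(parts, function(p) {
          d <- suppressWarnings(as.numeric(p))
          if (length(d) >= 2L && sum(d, na.rm = TRUE) > 0) {
            d[2L] / sum(d[1:2], na.rm = TRUE)
          } else NA_real_
        }, numeric(1))
      }
    }
  }
  df <- data.frame(sample = sample_id, chrom = fix$CHROM,
                   pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                   vaf = vaf, stringsAsFactors = FALSE)
  sbs <- !is.na(df$ref) & !is.na(df$alt) &
    nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    toupper(df$ref) %in% .DNA_BASES & toupper(df$alt) %in% .DNA_BASES
  out <- df[sbs, , drop = FALSE]
  attr(out, "n_skipped_non_sbs") <- sum(!sbs)
  out
}

#' Write mutations as a minimal VCF
#'
#' One file per call; the VAF is carried in the INFO AF field. Intended for
#' round-tripping simulated cohorts through VCF-consuming steps.
#'
#' @param mutations Mutation data.frame (a single sample's records).
#' @param path Output VCF path.
#' @param sample_id Sample name for the header; defaults to the records'.
#' @export
write_vcf <- function(mutations, path, sample_id = NULL) {
  mutations <- .check_mutation_df(mutations, add_vaf = TRUE)
  if (is.null(sample_id)) sample_id <- unique(mutations$sample)[1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    sprintf("##SAMPLE=<ID=%s>", sample_id),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(mutations)) {
    info <- ifelse(is.na(mutations$vaf), ".",
                   sprintf("AF=%.6g", mutations$vaf))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       mutations$chrom, mutations$pos, mutations$ref,
                       mutations$alt, info), con)
  }
  invisible(path)
}

#' Read a BED interval file
#'
#' BED3 plus a label (name) column; coordinates stay 0-based half-open.
#'
#' @param path BED file.
#' @return data.frame with columns \code{chrom, start, end, label}.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               label = if (!is.null(gr$name)) gr$name else NA_character_,
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:min(4L, ncol(df))] <-
      c("chrom", "start", "end", "label")[1:min(4L, ncol(df))]
    if (!"label" %in% names(df)) df$label <- NA_character_
    df[, c("chrom", "start", "end", "label")]
  }
}

#' Write intervals as BED
#'
#' @param regions data.frame with columns \code{chrom, start, end, label}
#'   (0-based half-open).
#' @param path Output file.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a position blacklist
#'
#' Two-column TSV (chrom, pos), 1-based positions, with or without header.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{chrom, pos}.
#' @export
read_blacklist <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("chrom", "pos")
  df$pos <- as.integer(df$pos)
  df[, c("chrom", "pos")]
}

#' Write a position blacklist
#'
#' @param blacklist data.frame with columns \code{chrom, pos}.
#' @param path Output file.
#' @export
write_blacklist <- function(blacklist, path) {
  utils::write.table(blacklist[, c("chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
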