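# Canonical SBS-96 channel machinery.
#
# Channels follow the COSMIC catalogue convention: six pyrimidine-centred
# substitution blocks (C>A, C>G, C>T, T>A, T>C, T>G), each expanded over the
# 16 flanking dinucleotide contexts with flanks ordered A, C, G, T, giving
# strings such as "A[C>A]A". Purine-reference mutations are mapped to their
# reverse complement before lookup.

.SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.DNA_BASES <- c("A", "C", "G", "T")
.BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

.make_channels <- function() {
  out <- character(96)
  k <- 1L
  for (s in .SBS_SUBS) {
    for (up in .DNA_BASES) {
      for (dn in .DNA_BASES) {
        out[k] <- paste0(up, "[", s, "]", dn)
        k <- k + 1L
      }
    }
  }
  out
}

#' The 96 canonical SBS channel labels
#'
#' Returns the single-base-substitution channel strings (e.g. \code{"A[C>A]A"})
#' in canonical COSMIC order: substitution blocks C>A, C>G, C>T, T>A, T>C,
#' T>G, each crossed with the 16 flanking contexts (flanks ordered A, C, G, T).
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() .SBS96_CHANNELS

.SBS96_CHANNELS <- .make_channels()

#' Classify a single-base substitution into its SBS-96 channel
#'
#' Maps (ref, alt, upstream flank, downstream flank) to the pyrimidine-strand
#' SBS-96 channel index. Purine-reference events (ref A or G) are
#' reverse-complemented before lookup, so the classification is closed under
#' reverse complement by construction.
#'
#' @param ref,alt Reference and alternate base, single characters in A/C/G/T.
#'   Vectors are recycled to a common length.
#' @param upstream,downstream Flanking bases on the reference strand.
#' @return Integer vector of 1-based channel indices in \code{1..96}; the
#'   channel string is \code{sbs96_channels()[index]}.
#' @export
#' @examples
#' classify_sbs("C", "A", "A", "A")            # 1, i.e. "A[C>A]A"
#' classify_sbs("G", "T", "T", "T")            # also 1 (reverse complement)
classify_sbs <- function(ref, alt, upstream, downstream) {
  n <- max(length(ref), length(alt), length(upstream), length(downstream))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  up <- rep_len(toupper(upstream), n)
  dn <- rep_len(toupper(downstream), n)
  all_bases <- c(ref, alt, up, dn)
  if (!all(all_bases %in% .DNA_BASES)) {
    bad <- unique(all_bases[!(all_bases %in% .DNA_BASES)])
    stop("non-ACGT base in SBS classification input: ",
         paste(bad, collapse = ", "))
  }
  if (any(ref == alt)) {
    stop("ref == alt is not a substitution")
  }
  flip <- ref %in% c("A", "G")
  r2 <- ifelse(flip, .BASE_COMP[ref], ref)
  a2 <- ifelse(flip, .BASE_COMP[alt], alt)
  u2 <- ifelse(flip, .BASE_COMP[dn], up)
  d2 <- ifelse(flip, .BASE_COMP[up], dn)
  sub_idx <- match(paste0(r2, ">", a2), .SBS_SUBS)
  up_idx <- match(u2, .DNA_BASES)
  dn_idx <- match(d2, .DNA_BASES)
  as.integer((sub_idx - 1L) * 16L + (up_idx - 1L) * 4L + dn_idx)
}

.check_mutation_df <- function(mutations, add_vaf = FALSE) {
  needed <- c("sample", "chrom", "pos", "ref", "alt")
  missing <- setdiff(needed, names(mutations))
  if (length(missing)) {
    stop("mutation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (add_vaf && !"vaf" %in% names(mutations)) {
    mutations$vaf <- rep(NA_real_, nrow(mutations))
  }
  mutations
}

#' Filter mutations on variant allele fraction
#'
#' Retains records whose VAF is at or above \code{min_vaf} (the threshold is
#' inclusive). Records without a VAF are retained unless \code{strict = TRUE}.
#' Input order is preserved.
#'
#' @param mutations Mutation data.frame with columns
#'   \code{sample, chrom, pos, ref, alt} and optionally \code{vaf}.
#' @param min_vaf Minimum fraction in \[0, 1\]; default 0.10.
#' @param strict Drop records lacking a VAF? Default \code{FALSE}.
#' @return The filtered data.frame.
#' @export
filter_vaf <- function(mutations, min_vaf = 0.10, strict = FALSE) {
  if (!is.numeric(min_vaf) || length(min_vaf) != 1L ||
      is.na(min_vaf) || min_vaf < 0 || min_vaf > 1) {
    stop("min_vaf must be a single number in [0, 1]")
  }
  mutations <- .check_mutation_df(mutations, add_vaf = TRUE)
  keep <- mutations$vaf >= min_vaf
  keep[is.na(keep)] <- !strict
  mutations[keep, , drop = FALSE]
}

#' Remove mutations at blacklisted genomic positions
#'
#' Drops every record whose (chrom, pos) pair appears in the blacklist —
#' typically a "metanormal" list of artefact- or germline-prone sites pooled
#' from healthy donors. Idempotent.
#'
#' @param mutations Mutation data.frame.
#' @param blacklist data.frame with columns \code{chrom} and \code{pos}
#'   (1-based), or NULL/empty for a no-op.
#' @return List with \code{mutations} (retained records) and \code{n_removed}.
#' @export
blacklist_filter <- function(mutations, blacklist) {
  mutations <- .check_mutation_df(mutations)
  if (is.null(blacklist) || nrow(blacklist) == 0L) {
    return(list(mutations = mutations, n_removed = 0L))
  }
  key <- paste(mutations$chrom, mutations$pos, sep = ":")
  bad <- paste(blacklist$chrom, blacklist$pos, sep = ":")
  hit <- key %in% bad
  list(mutations = mutations[!hit, , drop = FALSE],
       n_removed = sum(hit))
}

.regions_to_granges <- function(regions) {
  needed <- c("chrom", "start", "end", "label")
  if (!all(needed %in% names(regions))) {
    stop("region table needs columns chrom, start, end, label")
  }
  if (any(regions$start >= regions$end)) {
    stop("region intervals must satisfy start < end (0-based half-open)")
  }
  # BED-style 0-based half-open -> 1-based closed GRanges
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    label = regions$label
  )
}

#' Assign mutations to genomic compartments
#'
#' Labels every mutation as exonic, intronic or extragenic using interval
#' annotations. A mutation overlapping intervals with several labels takes the
#' highest-precedence one (exonic > intronic > extragenic); positions covered
#' by no interval receive \code{default_label}.
#'
#' @param mutations Mutation data.frame (positions 1-based).
#' @param regions data.frame of intervals with columns
#'   \code{chrom, start, end, label}; coordinates are 0-based half-open (BED).
#' @param default_label Label for uncovered positions; default "extragenic".
#' @return The mutation data.frame with a \code{region} column added/replaced.
#' @export
partition_by_region <- function(mutations, regions,
                                default_label = "extragenic") {
  mutations <- .check_mutation_df(mutations)
  if (nrow(mutations) == 0L) {
    mutations$region <- character(0)
    return(mutations)
  }
  gr_mut <- GenomicRanges::GRanges(
    seqnames = mutations$chrom,
    ranges = IRanges::IRanges(start = mutations$pos, width = 1L)
  )
  gr_reg <- .regions_to_granges(regions)
  precedence <- c(exonic = 1L, intronic = 2L, extragenic = 3L)
  hits <- GenomicRanges::findOverlaps(gr_mut, gr_reg)
  label <- rep(default_label, nrow(mutations))
  if (length(hits)) {
    h_lab <- gr_reg$label[S4Vectors::subjectHits(hits)]
    h_rank <- precedence[h_lab]
    h_rank[is.na(h_rank)] <- 99L  # panel or custom labels rank after compartments
    ord <- order(S4Vectors::queryHits(hits), h_rank)
    first <- !duplicated(S4Vectors::queryHits(hits)[ord])
    label[S4Vectors::queryHits(hits)[ord][first]] <- h_lab[ord][first]
  }
  mutations$region <- label
  mutations
}

#' Restrict mutations to a panel footprint
#'
#' Keeps only mutations whose position falls inside any interval of the panel
#' (e.g. an in-silico targeted-panel extraction from exome data).
#'
#' @param mutations Mutation data.frame.
#' @param panel Interval data.frame (\code{chrom, start, end, label}), BED
#'   0-based half-open coordinates.
#' @return The filtered data.frame.
#' @export
subset_to_panel <- function(mutations, panel) {
  mutations <- .check_mutation_df(mutations)
  if (nrow(mutations) == 0L || is.null(panel) || nrow(panel) == 0L) {
    return(mutations[integer(0), , drop = FALSE])
  }
  gr_mut <- GenomicRanges::GRanges(
    seqnames = mutations$chrom,
    ranges = IRanges::IRanges(start = mutations$pos, width = 1L)
  )
  gr_pan <- .regions_to_granges(panel)
  keep <- IRanges::overlapsAny(gr_mut, gr_pan)
  mutations[keep, , drop = FALSE]
}

.genome_as_strings <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("character genome must be named by chrom")
    toupper(genome)
  } else if (is.list(genome) && !is.null(genome$sequence)) {
    .genome_as_strings(genome$sequence)
  } else {
    stop("genome must be a named character vector, a DNAStringSet, ",
         "or a simulated genome object")
  }
}

#' Build SBS-96 mutation catalogues from a mutation table
#'
#' Extracts the trinucleotide context of every single-base substitution from
#' the reference genome, classifies it into one of the 96 canonical channels
#' and tallies a 96-row count matrix with one column per sample.
#'
#' Records whose flanking context contains a non-ACGT base (or that sit at a
#' sequence boundary) are dropped and counted in the discard tally. Records
#' whose stated reference base disagrees with the genome are dropped with a
#' warning (or raise an error when \code{on_ref_mismatch = "error"}).
#'
#' @param mutations Mutation data.frame with columns
#'   \code{sample, chrom, pos, ref, alt} (pos 1-based).
#' @param genome Named character vector of chromosome sequences, a
#'   \code{Biostrings::DNAStringSet}, or the object returned by
#'   \code{\link{make_genome}}.
#' @param samples Optional character vector fixing the columns (so samples
#'   with zero mutations still appear); defaults to the samples present.
#' @param on_ref_mismatch "warn" (drop with warning, default) or "error".
#' @return An object of class \code{sbs96_catalogue}: a 96 x n_samples integer
#'   matrix with channel rownames, plus attributes \code{n_discarded_context}
#'   and \code{n_discarded_ref}.
#' @export
build_catalogue <- function(mutations, genome, samples = NULL,
                            on_ref_mismatch = c("warn", "error")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  mutations <- .check_mutation_df(mutations)
  seqs <- .genome_as_strings(genome)
  if (is.null(samples)) samples <- unique(mutations$sample)
  mat <- matrix(0L, nrow = 96L, ncol = length(samples),
                dimnames = list(.SBS96_CHANNELS, samples))
  n_ctx_drop <- 0L
  n_ref_drop <- 0L
  if (nrow(mutations)) {
    miss <- setdiff(unique(mutations$chrom), names(seqs))
    if (length(miss)) {
      stop("chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
    }
    chrom_len <- nchar(seqs)[mutations$chrom]
    ok_pos <- mutations$pos >= 2L & mutations$pos <= chrom_len - 1L
    n_ctx_drop <- n_ctx_drop + sum(!ok_pos)
    mutations <- mutations[ok_pos, , drop = FALSE]
    if (nrow(mutations)) {
      ctx <- substr(rep(seqs[mutations$chrom], 1L),
                    mutations$pos - 1L, mutations$pos + 1L)
      ctx <- toupper(ctx)
      up <- substr(ctx, 1L, 1L)
      mid <- substr(ctx, 2L, 2L)
      dn <- substr(ctx, 3L, 3L)
      good_ctx <- up %in% .DNA_BASES & mid %in% .DNA_BASES & dn %in% .DNA_BASES
      n_ctx_drop <- n_ctx_drop + sum(!good_ctx)
      ref_ok <- mid == toupper(mutations$ref)
      bad_ref <- good_ctx & !ref_ok
      if (any(bad_ref)) {
        msg <- sprintf("%d record(s) whose ref base disagrees with the genome",
                       sum(bad_ref))
        if (on_ref_mismatch == "error") stop(msg)
        warning(msg, " were discarded")
        n_ref_drop <- sum(bad_ref)
      }
      keep <- good_ctx & ref_ok
      if (any(keep)) {
        idx <- classify_sbs(mutations$ref[keep], mutations$alt[keep],
                            up[keep], dn[keep])
        samp <- factor(mutations$sample[keep], levels = samples)
        tab <- table(factor(idx, levels = 1:96), samp)
        mat <- mat + matrix(as.integer(tab), nrow = 96L,
                            dimnames = dimnames(mat))
      }
    }
  }
  structure(mat,
            class = c("sbs96_catalogue", "matrix", "array"),
            n_discarded_context = n_ctx_drop,
            n_discarded_ref = n_ref_drop)
}

#' @export
print.sbs96_catalogue <- function(x, ...) {
  cat("SBS-96 mutation catalogue\n")
  cat(sprintf("  samples: %d\n", ncol(x)))
  cat(sprintf("  mutations per sample: %s\n",
              paste(utils::head(colSums(x), 8L), collapse = ", ")))
  nd <- attr(x, "n_discarded_context")
  if (!is.null(nd) && nd > 0) {
    cat(sprintf("  discarded (context/boundary): %d\n", nd))
  }
  invisible(x)
}

#' Write an SBS-96 catalogue as a COSMIC-layout TSV
#'
#' Rows are the 96 canonical context strings (column header "Type"), columns
#' are samples.
#'
#' @param catalogue Matrix from \code{\link{build_catalogue}}.
#' @param path Output file.
#' @export
write_catalogue <- function(catalogue, path) {
  df <- data.frame(Type = rownames(catalogue),
                   as.data.frame(unclass(catalogue), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SBS-96 catalogue TSV
#'
#' @param path TSV written by \code{\link{write_catalogue}} (or any
#'   COSMIC-layout matrix with a context column).
#' @return An \code{sbs96_catalogue} matrix in canonical row order.
#' @export
read_catalogue <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  ctx_col <- names(df)[1L]
  rn <- df[[ctx_col]]
  if (!setequal(rn, .SBS96_CHANNELS) || anyDuplicated(rn)) {
    stop("catalogue file does not contain exactly the 96 canonical contexts")
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- rn
  mat <- mat[.SBS96_CHANNELS, , drop = FALSE]
  storage.mode(mat) <- "double"
  structure(mat, class = c("sbs96_catalogue", "matrix", "array"))
}
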