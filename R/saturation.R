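# Downsampling saturation analysis: how many mutations does a sample need
# before its signature fit becomes reliable? Each sample's mutation list is
# repeatedly subsampled on a fraction grid (default 5%..95% in 5% steps, five
# replicates each), every subset is refitted, and the mutation count at which
# the median reconstruction cosine sustainably clears the reliability
# threshold is reported.

# Deterministic 31-bit seed derived from (seed, sample_id, fraction,
# replicate) via an FNV-style string hash, so replicates are independent yet
# bit-reproducible across runs. All arithmetic stays below 2^31 via modular
# reduction in double precision.
derive_seed <- function(seed, sample_id, fraction, replicate) {
  key <- paste(seed, sample_id, format(fraction, digits = 10), replicate,
               sep = "\x1f")
  h <- 216613626
  for (cc in utf8ToInt(key)) {
    h <- (h * 131 + cc) %% 2147483647   # stays within exact double range
  }
  as.integer(h)
}

#' Subsample a mutation list without replacement
#'
#' Draws a uniform random subset of size \code{floor(fraction * n)},
#' deterministically for a given seed.
#'
#' @param mutations Mutation data.frame.
#' @param fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return The subsampled data.frame (possibly zero rows, with a warning).
#' @export
subsample_mutations <- function(mutations, fraction, seed) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(mutations)
  if (n < 1L) stop("need at least one mutation")
  k <- floor(fraction * n)
  if (k == 0L) {
    warning("subset size 0 at fraction ", fraction, "; point skipped")
    return(mutations[integer(0), , drop = FALSE])
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mutations[sort(sample.int(n, k)), , drop = FALSE]
}

#' Saturation analysis for one or more samples
#'
#' For every (fraction, replicate) cell of the grid, the sample's mutations
#' are subsampled, the subset's SBS-96 profile rebuilt, the reference
#' refitted, and the cosine similarity between the subset's own profile and
#' its reconstruction recorded. At the defaults (19 fractions x 5 replicates)
#' each sample yields 95 points.
#'
#' @param mutations Mutation data.frame (one or several samples).
#' @param genome Genome as accepted by \code{\link{build_catalogue}}.
#' @param reference A \code{\link{signature_reference}}.
#' @param fractions Subsampling grid; default \code{seq(0.05, 0.95, 0.05)}.
#' @param replicates Replicates per fraction; default 5.
#' @param seed Master seed; per-point seeds are derived from
#'   (seed, sample, fraction, replicate).
#' @param method Fitting backend; default "nnls".
#' @param against "subset" (default) scores each subset fit against the
#'   subset's own profile; "full" scores it against the sample's full
#'   profile (sensitivity analysis).
#' @return A data.frame of class \code{saturation_curve} with columns
#'   \code{sample, fraction, replicate, n_mutations, cosine}.
#' @export
saturation_analysis <- function(mutations, genome, reference,
                                fractions = seq(0.05, 0.95, by = 0.05),
                                replicates = 5L, seed = 1L,
                                method = "nnls",
                                against = c("subset", "full")) {
  against <- match.arg(against)
  mutations <- .check_mutation_df(mutations)
  samples <- unique(mutations$sample)
  rows <- vector("list", 0L)
  for (s in samples) {
    mu <- mutations[mutations$sample == s, , drop = FALSE]
    if (nrow(mu) < 20L) {
      warning("sample ", s, " has fewer than 20 mutations; ",
              "small fractions collapse to degenerate subset sizes")
    }
    full_profile <- if (against == "full") {
      build_catalogue(mu, genome, samples = s)[, 1L]
    }
    for (f in fractions) {
      for (r in seq_len(replicates)) {
        sd_pt <- derive_seed(seed, s, f, r)
        sub <- suppressWarnings(subsample_mutations(mu, f, sd_pt))
        if (nrow(sub) == 0L) next
        prof <- build_catalogue(sub, genome, samples = s)
        if (sum(prof) == 0) next
        cosv <- tryCatch({
          fit <- fit_signatures(prof, reference, method = method)
          if (against == "subset") unname(fit$cosine)
          else cosine_similarity(full_profile, fit$reconstructed[, 1L])
        }, error = function(e) NA_real_)
        if (is.na(cosv)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, fraction = f, replicate = r,
          n_mutations = nrow(sub), cosine = cosv,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(), fraction = numeric(),
                      replicate = integer(), n_mutations = integer(),
                      cosine = numeric())
  }
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Minimum mutation count for reliable signature assignment
#'
#' Pools all saturation points as (mutation count, cosine) pairs, computes the
#' median cosine within consecutive equal-width mutation-count bins (default:
#' ten bins spanning the pooled count range), and reports the lower edge of
#' the smallest bin from which the median — and every higher bin's median —
#' stays at or above the reliability threshold (sustained-crossing rule).
#' Raising the threshold can only raise the reported minimum.
#'
#' @param curves A \code{saturation_curve} data.frame (or anything with
#'   columns \code{n_mutations} and \code{cosine}, plus \code{sample} for the
#'   per-sample diagnostics).
#' @param threshold Reliability threshold; default 0.9.
#' @param n_bins Number of equal-width bins over the pooled count range;
#'   default 10 (decile width).
#' @return List with \code{minimum_n} (bin lower edge, or NA when the
#'   threshold is never sustained), \code{reached}, \code{max_median},
#'   \code{bins} (per-bin diagnostic table) and \code{per_sample} (smallest
#'   sustained crossing count per sample).
#' @export
minimum_mutations <- function(curves, threshold = 0.9, n_bins = 10L) {
  if (!nrow(curves)) stop("need at least one saturation point")
  n <- curves$n_mutations
  cosv <- curves$cosine
  rng <- range(n)
  if (rng[1] == rng[2]) {
    edges <- c(rng[1], rng[1] + 1)
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  bin <- findInterval(n, edges, rightmost.closed = TRUE)
  med <- tapply(cosv, factor(bin, levels = seq_len(length(edges) - 1L)),
                stats::median)
  bins <- data.frame(bin = seq_along(med),
                     lower = edges[-length(edges)],
                     upper = edges[-1L],
                     n_points = as.integer(table(factor(bin,
                       levels = seq_along(med)))),
                     median_cosine = as.numeric(med))
  occupied <- !is.na(bins$median_cosine)
  # tolerance guards medians that equal the threshold up to floating error
  # (e.g. the mean of an even bin's central pair)
  ok <- bins$median_cosine >= threshold - 1e-9
  ok[!occupied] <- NA
  # sustained crossing: all occupied bins from here up clear the threshold
  sustained <- rev(cumprod(rev(ifelse(is.na(ok), TRUE, ok)))) == 1
  sustained[!occupied] <- FALSE
  reached <- any(sustained)
  minimum_n <- if (reached) bins$lower[which(sustained)[1L]] else NA_real_
  per_sample <- NULL
  if ("sample" %in% names(curves)) {
    per_sample <- do.call(rbind, lapply(split(curves, curves$sample),
      function(cu) {
        agg <- stats::aggregate(cosine ~ n_mutations, data = cu,
                                FUN = stats::median)
        agg <- agg[order(agg$n_mutations), ]
        sus <- rev(cumprod(rev(agg$cosine >= threshold - 1e-9))) == 1
        data.frame(sample = cu$sample[1L],
                   crossing_n = if (any(sus)) agg$n_mutations[which(sus)[1L]]
                                else NA_real_)
      }))
    rownames(per_sample) <- NULL
  }
  list(minimum_n = minimum_n, reached = reached,
       max_median = max(bins$median_cosine, na.rm = TRUE),
       threshold = threshold, bins = bins, per_sample = per_sample)
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("Saturation curve: %d points, %d sample(s), %d fraction(s)\n",
              nrow(x), length(unique(x$sample)), length(unique(x$fraction))))
  NextMethod()
}

#' Plot saturation curves
#'
#' Median cosine similarity against subset mutation count, one line per
#' sample, with the reliability threshold marked.
#'
#' @param x A \code{saturation_curve}.
#' @param threshold Threshold line; default 0.9.
#' @param ... Passed to \code{plot}.
#' @export
plot.saturation_curve <- function(x, threshold = 0.9, ...) {
  graphics::plot(x$n_mutations, x$cosine, col = "grey70", pch = 16,
                 cex = 0.5, xlab = "mutations in subset",
                 ylab = "cosine similarity", ...)
  for (s in unique(x$sample)) {
    cu <- x[x$sample == s, ]
    agg <- stats::aggregate(cosine ~ n_mutations, data = cu,
                            FUN = stats::median)
    graphics::lines(agg$n_mutations[order(agg$n_mutations)],
                    agg$cosine[order(agg$n_mutations)], col = "steelblue")
  }
  graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}
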