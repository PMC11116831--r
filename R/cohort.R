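# Cohort-level readouts: not-assigned rates, median set-contribution deltas
# between annotated sample groups, and Wilcoxon rank-sum significance.

#' Significance code for a p-value
#'
#' The conventional footnote mapping: \code{****} p < 0.0001, \code{***}
#' p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05, otherwise \code{ns}.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 5e-2) "*"
    else "ns"
  }, character(1))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Wraps \code{stats::wilcox.test}: the exact null distribution is used when
#' the combined sample size is at most 12 and the data are tie-free; otherwise
#' the normal approximation with continuity and tie correction applies.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @param alternative Passed to \code{wilcox.test}; default "two.sided".
#' @return List with \code{p_value}, \code{statistic} (the rank-sum W of
#'   group A), \code{code} (significance footnote) and \code{exact}.
#' @export
ranksum_test <- function(values_a, values_b, alternative = "two.sided") {
  if (!length(values_a) || !length(values_b)) {
    stop("both groups must be non-empty")
  }
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (length(values_a) + length(values_b) <= 12L) && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  list(p_value = wt$p.value,
       statistic = unname(wt$statistic),
       code = significance_code(wt$p.value),
       exact = exact)
}

#' Median set-contribution difference between two sample groups
#'
#' The discrimination statistic: the difference between the median signature
#' set contribution of two annotated groups, oriented so that group A is the
#' signature-bearing group (e.g. MSI-MMRd against MSS-MMRp for the
#' mismatch-repair set, or POLE-mutated against POLE wild-type). A positive
#' delta therefore means discrimination in the expected direction. The
#' difference is tested with a Wilcoxon rank-sum test.
#'
#' @param contributions Named numeric vector: per-sample set contribution
#'   (e.g. from \code{\link{set_contribution}}).
#' @param annotation data.frame with columns \code{sample} and \code{label}.
#' @param group_a,group_b Labels of the signature-bearing and reference group.
#' @param set_label Optional tag recorded in the result.
#' @return A one-row data.frame (class \code{delta_result}) with
#'   \code{set_label, group_a, group_b, median_a, median_b, delta, p_value,
#'   code, n_a, n_b}.
#' @export
delta_stat <- function(contributions, annotation, group_a, group_b,
                       set_label = NA_character_) {
  if (!all(c("sample", "label") %in% names(annotation))) {
    stop("annotation needs columns sample, label")
  }
  samp <- names(contributions)
  if (is.null(samp)) stop("contributions must be named by sample")
  lab <- annotation$label[match(samp, annotation$sample)]
  unlabelled <- is.na(lab)
  if (any(unlabelled)) {
    warning(sum(unlabelled), " sample(s) without annotation excluded",
            call. = FALSE)
  }
  va <- contributions[!unlabelled & lab == group_a]
  vb <- contributions[!unlabelled & lab == group_b]
  if (!length(va)) stop("no samples with label '", group_a, "'")
  if (!length(vb)) stop("no samples with label '", group_b, "'")
  med_a <- stats::median(va)
  med_b <- stats::median(vb)
  rs <- ranksum_test(va, vb)
  out <- data.frame(set_label = set_label,
                    group_a = group_a, group_b = group_b,
                    median_a = med_a, median_b = med_b,
                    delta = med_a - med_b,
                    p_value = rs$p_value, code = rs$code,
                    n_a = length(va), n_b = length(vb),
                    stringsAsFactors = FALSE)
  class(out) <- c("delta_result", "data.frame")
  out
}

#' Not-assigned rate of a cohort fit
#'
#' Fraction of samples whose reconstruction cosine similarity falls below the
#' reliability threshold.
#'
#' @param fits A \code{signature_fit} or a list of them (e.g. one per
#'   backend); the breakdown is then reported per element.
#' @return List with \code{rate}, \code{n_not_assigned}, \code{n_total} and,
#'   for a list input, \code{per_fit}.
#' @export
not_assigned_rate <- function(fits) {
  if (inherits(fits, "signature_fit")) fits <- list(fits)
  if (!length(fits)) stop("need at least one fit")
  per <- lapply(fits, function(f) {
    stopifnot(inherits(f, "signature_fit"))
    n <- length(f$assigned)
    data.frame(backend = f$method, reference = f$reference$name,
               n_not_assigned = sum(!f$assigned), n_total = n,
               rate = sum(!f$assigned) / n)
  })
  per <- do.call(rbind, per)
  list(rate = sum(per$n_not_assigned) / sum(per$n_total),
       n_not_assigned = sum(per$n_not_assigned),
       n_total = sum(per$n_total),
       per_fit = per)
}

#' Comparative fit matrix across backends, references and regions
#'
#' Runs the full refitting pipeline over the Cartesian product of fitting
#' backends, reference catalogues and (optionally) genomic compartments, and
#' returns the cohort readouts of every configuration in one long table:
#' median cosine similarity, not-assigned rate, and the median
#' set-contribution delta with rank-sum p-value for every declared signature
#' set and group pair.
#'
#' @param mutations Mutation data.frame (after any VAF/blacklist filtering).
#' @param genome Genome as accepted by \code{\link{build_catalogue}}.
#' @param references List of \code{\link{signature_reference}} objects.
#' @param annotation data.frame with columns \code{sample, label}.
#' @param group_pairs List of length-2 character vectors
#'   \code{c(group_a, group_b)} with group A the signature-bearing group.
#' @param backends Character subset of \code{c("nnls", "sparse")}.
#' @param regions Optional region table (\code{chrom, start, end, label});
#'   when given, every configuration is additionally stratified by
#'   compartment.
#' @param sets Optional named list of signature-id sets overriding each
#'   reference's own sets.
#' @param assigned_only Compute deltas on assigned samples only? Default
#'   FALSE (all fitted samples enter the medians).
#' @param p_adjust Optional p-value adjustment method for the delta tests
#'   across the whole table (e.g. "BH"); default "none".
#' @param cosine_threshold Reliability threshold; default 0.9.
#' @return A data.frame with one row per (backend, reference, region, set,
#'   group pair): \code{backend, reference, region, set_label, group_a,
#'   group_b, median_a, median_b, delta, p_value, code, median_cosine,
#'   not_assigned_rate, n_assigned, n_total}. Rows are ordered
#'   deterministically by (backend, reference, region, set).
#' @export
compare_cohort <- function(mutations, genome, references, annotation,
                           group_pairs, backends = c("nnls", "sparse"),
                           regions = NULL, sets = NULL,
                           assigned_only = FALSE, p_adjust = "none",
                           cosine_threshold = 0.9) {
  stopifnot(length(backends) >= 1L, length(references) >= 1L)
  if (is.null(names(references))) {
    names(references) <- make.unique(
      vapply(references, `[[`, character(1), "name"))
  }
  region_labels <- "all"
  mut_by_region <- list(all = mutations)
  if (!is.null(regions)) {
    part <- partition_by_region(mutations, regions)
    region_labels <- c("all", sort(unique(part$region)))
    for (rl in setdiff(region_labels, "all")) {
      mut_by_region[[rl]] <- part[part$region == rl, , drop = FALSE]
    }
  }
  samples <- unique(mutations$sample)
  rows <- list()
  for (bk in backends) {
    for (rf in names(references)) {
      ref <- references[[rf]]
      use_sets <- if (is.null(sets)) ref$sets else sets
      for (rl in region_labels) {
        mu <- mut_by_region[[rl]]
        cat_rl <- build_catalogue(mu, genome, samples = samples)
        nonzero <- colSums(cat_rl) > 0
        fit <- fit_signatures(cat_rl[, nonzero, drop = FALSE], ref,
                              method = bk,
                              cosine_threshold = cosine_threshold)
        na_rate <- not_assigned_rate(fit)
        for (sl in names(use_sets)) {
          contrib <- set_contribution(fit, use_sets[[sl]])
          if (assigned_only) contrib <- contrib[fit$assigned]
          for (gp in group_pairs) {
            d <- tryCatch(
              delta_stat(contrib, annotation, gp[1], gp[2], set_label = sl),
              error = function(e) {
                stop("comparative cell (", bk, ", ", rf, ", ", rl, ", ", sl,
                     "): ", conditionMessage(e), call. = FALSE)
              })
            rows[[length(rows) + 1L]] <- data.frame(
              backend = bk, reference = rf, region = rl,
              d[, c("set_label", "group_a", "group_b", "median_a",
                    "median_b", "delta", "p_value", "code")],
              median_cosine = stats::median(fit$cosine),
              not_assigned_rate = na_rate$rate,
              n_assigned = sum(fit$assigned),
              n_total = length(fit$assigned),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}
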