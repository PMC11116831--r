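# Reference signature catalogues: loading, validation, subsetting, and the
# aetiology-based signature sets used for cohort stratification.

#' Default aetiology-based signature sets
#'
#' The signature groupings used for cohort stratification when fitting against
#' a COSMIC-style reference:
#' \itemize{
#'   \item \code{MMRd}: SBS6, SBS15, SBS20, SBS21, SBS25, SBS26, SBS44 —
#'     signatures associated with defective DNA mismatch repair. Note SBS25 is
#'     included here for stratification although COSMIC ascribes it a
#'     different (chemotherapy-related) aetiology.
#'   \item \code{POLE}: SBS10a, SBS10b — polymerase-epsilon
#'     exonuclease-domain hypermutation.
#'   \item \code{FLAT}: SBS3, SBS5, SBS8, SBS40, SBS89 — "flat" signatures
#'     whose mass is spread nearly evenly over the 96 channels.
#' }
#' Set members absent from a loaded reference are dropped (with a warning) at
#' intersection time.
#'
#' @return Named list of character vectors of COSMIC signature ids.
#' @export
default_signature_sets <- function() {
  list(
    MMRd = c("SBS6", "SBS15", "SBS20", "SBS21", "SBS25", "SBS26", "SBS44"),
    POLE = c("SBS10a", "SBS10b"),
    FLAT = c("SBS3", "SBS5", "SBS8", "SBS40", "SBS89")
  )
}

.new_signature_reference <- function(matrix, name, sets = list()) {
  structure(list(name = name, matrix = matrix,
                 signature_ids = colnames(matrix), sets = sets),
            class = "signature_reference")
}

.validate_reference_matrix <- function(mat, name = "reference") {
  if (!setequal(rownames(mat), .SBS96_CHANNELS)) {
    missing <- setdiff(.SBS96_CHANNELS, rownames(mat))
    extra <- setdiff(rownames(mat), .SBS96_CHANNELS)
    stop(name, ": context rows invalid",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unrecognized: ",
                                   paste(utils::head(extra, 5), collapse = ", ")))
  }
  if (anyDuplicated(rownames(mat))) stop(name, ": duplicated context rows")
  if (anyDuplicated(colnames(mat))) stop(name, ": duplicated signature ids")
  if (any(mat < 0)) {
    bad <- colnames(mat)[colSums(mat < 0) > 0][1L]
    stop(name, ": negative entries in signature ", bad)
  }
  cs <- colSums(mat)
  if (any(cs == 0)) {
    stop(name, ": all-zero signature column ", colnames(mat)[cs == 0][1L])
  }
  mat <- mat[.SBS96_CHANNELS, , drop = FALSE]
  sweep(mat, 2L, colSums(mat), "/")
}

#' Construct a signature reference from a matrix
#'
#' @param matrix Numeric 96 x K matrix; rownames must be the canonical SBS-96
#'   context strings (any order), colnames the signature ids. Columns are
#'   renormalized to sum to 1.
#' @param name Short reference label (e.g. "C3").
#' @param sets Named list of signature-id vectors (aetiology sets); members
#'   absent from the matrix are dropped with a warning.
#' @return A \code{signature_reference} object.
#' @export
signature_reference <- function(matrix, name = "reference",
                                sets = default_signature_sets()) {
  mat <- .validate_reference_matrix(as.matrix(matrix), name)
  ref <- .new_signature_reference(mat, name)
  ref$sets <- .intersect_sets(sets, colnames(mat))
  ref
}

.intersect_sets <- function(sets, ids) {
  out <- lapply(names(sets), function(lb) {
    members <- sets[[lb]]
    present <- intersect(members, ids)
    dropped <- setdiff(members, ids)
    if (length(dropped) && length(present)) {
      warning("set '", lb, "': dropping absent signature(s) ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    present
  })
  names(out) <- names(sets)
  out[lengths(out) > 0]
}

#' Load a signature reference from a COSMIC-style TSV
#'
#' The file must have a first column of the 96 canonical context strings
#' (conventionally headed "Type"; any row order) and one column per signature.
#' Rows are reordered to canonical channel order and columns renormalized to
#' sum to 1.
#'
#' @param path TSV file.
#' @param name Reference label; defaults to the file stem.
#' @param sets Aetiology sets to attach (see
#'   \code{\link{default_signature_sets}}).
#' @return A \code{signature_reference}.
#' @export
load_reference <- function(path, name = NULL,
                           sets = default_signature_sets()) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(name, ": reference needs >= 1 signature column")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop(name, ": non-numeric signature values")
  rownames(mat) <- df[[1L]]
  signature_reference(mat, name = name, sets = sets)
}

#' Write a signature reference as TSV
#'
#' Inverse of \code{\link{load_reference}}: column 1 is "Type" with the
#' canonical context strings, remaining columns the signature values.
#'
#' @param ref A \code{signature_reference}.
#' @param path Output file.
#' @export
write_reference <- function(ref, path) {
  df <- data.frame(Type = rownames(ref$matrix),
                   as.data.frame(ref$matrix, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a reference to selected signatures
#'
#' @param ref A \code{signature_reference}.
#' @param signature_ids Ids to keep; absent ids are dropped with a warning.
#' @return A \code{signature_reference} with the column subset and the
#'   aetiology sets intersected accordingly.
#' @export
subset_reference <- function(ref, signature_ids) {
  present <- intersect(signature_ids, ref$signature_ids)
  absent <- setdiff(signature_ids, ref$signature_ids)
  if (length(absent)) {
    warning("dropping signature id(s) absent from '", ref$name, "': ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!length(present)) {
    stop("subset of '", ref$name, "' would be empty")
  }
  out <- .new_signature_reference(ref$matrix[, present, drop = FALSE],
                                  ref$name)
  out$sets <- suppressWarnings(.intersect_sets(ref$sets, present))
  out
}

#' Test whether a signature is "flat"
#'
#' A flat signature spreads its mass nearly evenly over the 96 channels, so no
#' single trinucleotide context dominates. The criterion used here is that the
#' maximum channel probability is strictly below \code{threshold} (default
#' 0.05, i.e. no context carries 5\% or more of the signature). For scale: the
#' uniform signature puts 1/96 (about 1.04\%) on every channel.
#'
#' @param signature Numeric 96-vector summing to 1 (tolerance 1e-6).
#' @param threshold Flatness cutoff, default 0.05.
#' @return List with \code{flat} (logical) and \code{max_channel} (the largest
#'   channel probability).
#' @export
is_flat <- function(signature, threshold = 0.05) {
  signature <- as.numeric(signature)
  if (length(signature) != 96L) stop("signature must have 96 channels")
  if (abs(sum(signature) - 1) > 1e-6) {
    stop("signature vector must sum to 1 (got ", format(sum(signature)), ")")
  }
  m <- max(signature)
  list(flat = m < threshold, max_channel = m)
}

#' @export
print.signature_reference <- function(x, ...) {
  cat(sprintf("Signature reference '%s': %d signatures x 96 channels\n",
              x$name, ncol(x$matrix)))
  if (length(x$sets)) {
    for (lb in names(x$sets)) {
      cat(sprintf("  set %-8s %s\n", lb,
                  paste(x$sets[[lb]], collapse = ", ")))
    }
  }
  invisible(x)
}
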