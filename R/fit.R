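# Signature refitting by non-negative least squares.
#
# The estimator solves, per sample, min ||y - S e||_2 subject to e >= 0 where
# y is the 96-channel mutation count vector and S the 96 x K reference matrix.
# Reconstruction quality is scored as the cosine similarity between y and the
# reconstruction S e; samples below the reliability threshold (default 0.9)
# are flagged "not assigned".

#' Non-negative least squares (Lawson--Hanson active set)
#'
#' Solves \eqn{\min_x \|Ax - b\|_2} subject to \eqn{x \ge 0} by the classic
#' active-set algorithm: coordinates enter the passive (free) set by largest
#' positive gradient of the dual, an unconstrained least-squares problem is
#' solved on the passive set, and infeasible coordinates are stepped back to
#' the boundary. At termination no coordinate's partial derivative permits
#' descent while respecting non-negativity (Karush--Kuhn--Tucker conditions).
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @return List with \code{x} (the solution), \code{residual} (b - Ax) and
#'   \code{rnorm} (the residual 2-norm).
#' @export
nnls <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m) stop("length(b) must equal nrow(A)")
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, n)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b)          # gradient of -0.5*||Ax-b||^2 at x = 0
  iter <- 0L
  max_iter <- 3L * n + 30L
  repeat {
    iter <- iter + 1L
    w_free <- w
    w_free[passive] <- -Inf
    if (all(passive) || max(w_free) <= tol || iter > max_iter) break
    j <- which.max(w_free)
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      if (!length(P)) { x <- numeric(n); break }
      # least squares on the passive set via QR
      z <- numeric(n)
      fit <- qr.coef(qr(A[, P, drop = FALSE]), b)
      fit[is.na(fit)] <- 0
      z[P] <- fit
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  r <- b - as.numeric(A %*% x)
  list(x = as.numeric(x), residual = r, rnorm = sqrt(sum(r^2)))
}

#' Cosine similarity between two profiles
#'
#' \eqn{a \cdot b / (\|a\| \|b\|)}; for non-negative vectors the value lies in
#' \[0, 1\]. A zero vector yields 0 with a warning (degenerate case).
#'
#' @param a,b Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity of a zero vector is defined as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Assignment status from reconstruction cosine
#'
#' A sample is "assigned" when its reconstruction cosine similarity reaches
#' the reliability threshold; strictly below the threshold it is "not
#' assigned". Default threshold 0.9.
#'
#' @param cosine Numeric vector of cosine similarities in \[0, 1\].
#' @param threshold Reliability threshold; default 0.9.
#' @return Logical vector.
#' @export
assign_status <- function(cosine, threshold = 0.9) {
  cosine >= threshold
}

.fit_one_nnls <- function(y, S) {
  sol <- nnls(S, y)
  e <- sol$x
  recon <- as.numeric(S %*% e)
  cosv <- if (sum(recon) == 0) 0 else cosine_similarity(y, recon)
  list(exposures = e, reconstructed = recon, cosine = cosv)
}

.fit_one_sparse <- function(y, S, drop_tolerance = 0.01) {
  full <- .fit_one_nnls(y, S)
  support <- which(full$exposures > 0)
  current <- full
  cur_cos <- current$cosine
  while (length(support) > 1L) {
    # candidate cosine after removing each surviving signature
    cand <- lapply(seq_along(support), function(i) {
      keep <- support[-i]
      .fit_one_nnls(y, S[, keep, drop = FALSE])
    })
    cand_cos <- vapply(cand, `[[`, numeric(1), "cosine")
    best <- which.max(cand_cos)
    if (cur_cos - cand_cos[best] < drop_tolerance) {
      support <- support[-best]
      sub <- cand[[best]]
      e <- numeric(ncol(S))
      e[support] <- sub$exposures
      current <- list(exposures = e, reconstructed = sub$reconstructed,
                      cosine = sub$cosine)
      cur_cos <- sub$cosine
      support <- which(current$exposures > 0)
    } else break
  }
  current
}

#' Fit reference signatures to SBS-96 mutation catalogues
#'
#' The central estimator: per-sample signature exposures are obtained by
#' refitting the observed 96-channel count profile against a reference
#' catalogue under non-negativity, the profile is reconstructed from the
#' fitted exposures, and the cosine similarity between observed and
#' reconstructed profile decides whether the sample's signature assignment is
#' considered reliable.
#'
#' Two backends are available: \code{"nnls"} (plain non-negative least
#' squares) and \code{"sparse"}, which starts from the NNLS solution and
#' greedily removes signatures while the cosine degradation per removal stays
#' below \code{drop_tolerance}, emulating strict-fitting tools.
#'
#' Exposures are reported raw (mutation-count scale) and normalized to sum
#' 1 over fitted signatures; the unexplained residual fraction
#' \eqn{1 - \sum_k e_k / n} is reported separately.
#'
#' @param catalogue A 96 x n_samples matrix (e.g. from
#'   \code{\link{build_catalogue}}) or a 96-vector for a single sample.
#'   Rownames, when present, must be the canonical channel strings.
#' @param reference A \code{\link{signature_reference}}.
#' @param method "nnls" (default) or "sparse".
#' @param cosine_threshold Reliability threshold for the assigned flag;
#'   default 0.9.
#' @param drop_tolerance Sparse-backend removal tolerance in cosine units;
#'   default 0.01.
#' @return An object of class \code{signature_fit} with components
#'   \code{exposures} (K x S raw), \code{exposures_norm} (K x S fractions),
#'   \code{reconstructed} (96 x S), \code{cosine}, \code{assigned},
#'   \code{residual_fraction}, \code{catalogue}, \code{reference},
#'   \code{method}.
#' @seealso \code{\link{coef.signature_fit}},
#'   \code{\link{set_contribution}}, \code{\link{saturation_analysis}}
#' @export
#' @examples
#' ref <- make_reference(n_spiky = 3, n_flat = 1, seed = 7)
#' truth <- c(0.5, 0.3, 0.2, 0)
#' y <- round(5000 * as.numeric(ref$matrix %*% truth))
#' fit <- fit_signatures(y, ref)
#' coef(fit)
fit_signatures <- function(catalogue, reference,
                           method = c("nnls", "sparse"),
                           cosine_threshold = 0.9,
                           drop_tolerance = 0.01) {
  method <- match.arg(method)
  if (is.null(dim(catalogue))) {
    catalogue <- matrix(as.numeric(catalogue), ncol = 1L,
                        dimnames = list(names(catalogue), "sample1"))
  }
  Y <- unclass(as.matrix(catalogue))
  if (nrow(Y) != 96L) stop("catalogue must have 96 channel rows")
  if (!is.null(rownames(Y))) {
    if (!setequal(rownames(Y), .SBS96_CHANNELS)) {
      stop("catalogue rownames are not the canonical SBS-96 channels")
    }
    Y <- Y[.SBS96_CHANNELS, , drop = FALSE]
  } else {
    rownames(Y) <- .SBS96_CHANNELS
  }
  if (any(Y < 0)) stop("catalogue contains negative counts")
  zero <- colSums(Y) == 0
  if (any(zero)) {
    stop("cannot fit all-zero profile(s): ",
         paste(colnames(Y)[zero], collapse = ", "))
  }
  S <- reference$matrix
  K <- ncol(S); ns <- ncol(Y)
  E <- matrix(0, K, ns, dimnames = list(colnames(S), colnames(Y)))
  R <- matrix(0, 96L, ns, dimnames = list(.SBS96_CHANNELS, colnames(Y)))
  cosv <- numeric(ns)
  for (j in seq_len(ns)) {
    one <- if (method == "nnls") .fit_one_nnls(Y[, j], S)
           else .fit_one_sparse(Y[, j], S, drop_tolerance)
    E[, j] <- one$exposures
    R[, j] <- one$reconstructed
    cosv[j] <- one$cosine
  }
  tot <- colSums(E)
  En <- sweep(E, 2L, ifelse(tot > 0, tot, 1), "/")
  En[, tot == 0] <- 0
  names(cosv) <- colnames(Y)
  structure(list(
    exposures = E,
    exposures_norm = En,
    reconstructed = R,
    cosine = cosv,
    assigned = assign_status(cosv, cosine_threshold) & tot > 0,
    residual_fraction = 1 - tot / colSums(Y),
    catalogue = Y,
    reference = reference,
    method = method,
    cosine_threshold = cosine_threshold,
    call = match.call()
  ), class = "signature_fit")
}

#' Summed contribution of a signature set
#'
#' Sums the normalized exposures of the signatures in an aetiology set (for
#' instance the mismatch-repair-deficiency set) for every sample; the result
#' is the fraction of fitted mutations attributed to that set, in \[0, 1\].
#'
#' @param fit A \code{signature_fit}.
#' @param set Either a set label present in the fit's reference (e.g.
#'   \code{"MMRd"}) or a character vector of signature ids.
#' @return Named numeric vector (one fraction per sample).
#' @export
set_contribution <- function(fit, set) {
  stopifnot(inherits(fit, "signature_fit"))
  ids <- if (length(set) == 1L && set %in% names(fit$reference$sets)) {
    fit$reference$sets[[set]]
  } else as.character(set)
  ids <- intersect(ids, rownames(fit$exposures_norm))
  if (!length(ids)) {
    return(stats::setNames(numeric(ncol(fit$exposures_norm)),
                           colnames(fit$exposures_norm)))
  }
  colSums(fit$exposures_norm[ids, , drop = FALSE])
}

# ---- standard model methods ------------------------------------------------

#' Extract fitted exposures
#'
#' @param object A \code{signature_fit}.
#' @param type "norm" for normalized contributions (default) or "raw" for
#'   mutation-count-scale exposures.
#' @param ... Unused.
#' @return K x n_samples matrix.
#' @export
coef.signature_fit <- function(object, type = c("norm", "raw"), ...) {
  type <- match.arg(type)
  if (type == "norm") object$exposures_norm else object$exposures
}

#' @export
fitted.signature_fit <- function(object, ...) object$reconstructed

#' @export
residuals.signature_fit <- function(object, ...) {
  object$catalogue - object$reconstructed
}

#' Predict reconstructed profiles
#'
#' Returns the reconstruction for the fitted samples, or refits the model's
#' reference to new profiles when \code{newdata} is supplied.
#'
#' @param object A \code{signature_fit}.
#' @param newdata Optional 96 x S matrix of new profiles.
#' @param ... Unused.
#' @export
predict.signature_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$reconstructed)
  fit_signatures(newdata, object$reference, method = object$method,
                 cosine_threshold = object$cosine_threshold)$reconstructed
}

#' Simulate catalogues from a fitted model
#'
#' Draws multinomial mutation catalogues from each sample's reconstructed
#' profile, at the sample's fitted mutation total.
#'
#' @param object A \code{signature_fit}.
#' @param nsim Number of simulated catalogues.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of 96 x n_samples count matrices.
#' @export
simulate.signature_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- sweep(object$reconstructed, 2L, colSums(object$reconstructed), "/")
  n <- round(colSums(object$catalogue))
  lapply(seq_len(nsim), function(i) {
    out <- vapply(seq_len(ncol(P)), function(j) {
      as.numeric(stats::rmultinom(1, n[j], P[, j]))
    }, numeric(96L))
    dimnames(out) <- dimnames(object$reconstructed)
    out
  })
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("Signature fit (%s backend) against reference '%s'\n",
              x$method, x$reference$name))
  cat(sprintf("  samples: %d  signatures: %d\n",
              ncol(x$exposures), nrow(x$exposures)))
  cat(sprintf("  cosine similarity: median %.4f (range %.4f-%.4f)\n",
              stats::median(x$cosine), min(x$cosine), max(x$cosine)))
  cat(sprintf("  assigned (cosine >= %.2f): %d / %d\n",
              x$cosine_threshold, sum(x$assigned), length(x$assigned)))
  invisible(x)
}

#' Summarize a signature fit
#'
#' @param object A \code{signature_fit}.
#' @param ... Unused.
#' @return A data.frame with one row per sample: mutation total, cosine,
#'   assigned flag, residual fraction and the top signature with its
#'   contribution.
#' @export
summary.signature_fit <- function(object, ...) {
  top <- apply(object$exposures_norm, 2L, function(e) {
    if (all(e == 0)) NA_integer_ else which.max(e)
  })
  df <- data.frame(
    sample = colnames(object$catalogue),
    n_mutations = unname(colSums(object$catalogue)),
    cosine = as.numeric(object$cosine),
    assigned = as.logical(object$assigned),
    residual_fraction = as.numeric(object$residual_fraction),
    top_signature = rownames(object$exposures_norm)[top],
    top_contribution = vapply(seq_along(top), function(j) {
      if (is.na(top[j])) NA_real_ else object$exposures_norm[top[j], j]
    }, numeric(1)),
    row.names = NULL
  )
  class(df) <- c("summary.signature_fit", "data.frame")
  df
}

#' Plot a signature fit
#'
#' Stacked normalized contributions per sample, with reconstruction cosine
#' similarity overlaid against the reliability threshold.
#'
#' @param x A \code{signature_fit}.
#' @param ... Passed to \code{barplot}.
#' @export
plot.signature_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  K <- nrow(x$exposures_norm)
  cols <- grDevices::hcl.colors(max(K, 2L), "Dark 3")[seq_len(K)]
  graphics::barplot(x$exposures_norm, col = cols, border = NA,
                    las = 2, ylab = "contribution",
                    main = sprintf("Signature contributions (%s, ref %s)",
                                   x$method, x$reference$name), ...)
  graphics::legend("topright", legend = rownames(x$exposures_norm),
                   fill = cols, cex = 0.6, bg = "white")
  graphics::plot(seq_along(x$cosine), x$cosine, pch = 19,
                 ylim = c(min(0.5, min(x$cosine)), 1),
                 xlab = "sample", ylab = "cosine similarity",
                 main = "Reconstruction quality")
  graphics::abline(h = x$cosine_threshold, lty = 2, col = "red")
  invisible(x)
}

#' Export a fit as a long-format table
#'
#' One row per sample with exposure columns, cosine, assigned flag and
#' residual fraction — the tabular companion of \code{\link{fit_signatures}}.
#'
#' @param fit A \code{signature_fit}.
#' @param type "norm" or "raw" exposures.
#' @return A data.frame.
#' @export
fit_table <- function(fit, type = c("norm", "raw")) {
  type <- match.arg(type)
  E <- t(coef(fit, type = type))
  data.frame(
    sample = colnames(fit$catalogue),
    backend = fit$method,
    reference = fit$reference$name,
    as.data.frame(E, check.names = FALSE),
    cosine = as.numeric(fit$cosine),
    assigned = as.logical(fit$assigned),
    residual_fraction = as.numeric(fit$residual_fraction),
    row.names = NULL, check.names = FALSE
  )
}
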