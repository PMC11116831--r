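# Synthetic-data generation: a random genome with compartment annotations,
# signature references with designed spiky/flat properties, and seeded
# cohorts whose catalogues are multinomial draws from known signature
# mixtures — realized as concrete variant records whose trinucleotide
# contexts round-trip exactly through the catalogue builder.

.revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Generate a random genome with compartment annotations
#'
#' A uniform-random ACGT sequence on a single synthetic chromosome, overlaid
#' with alternating exonic / intronic / extragenic blocks that partition the
#' whole sequence. Deterministic for a given seed.
#'
#' @param length Sequence length in bp; at least 1000. Default 100000 — small
#'   enough for seconds-scale simulation, large enough that all 96 channels'
#'   contexts occur in every compartment with near-certainty.
#' @param seed Integer seed.
#' @param block Compartment block size in bp; default 1000.
#' @param chrom Chromosome name; default "chrS".
#' @return A list of class \code{sim_genome}: \code{sequence} (named
#'   character vector) and \code{regions} (BED-style 0-based half-open
#'   data.frame with labels cycling exonic, intronic, extragenic).
#' @export
make_genome <- function(length = 100000L, seed = 1L, block = 1000L,
                        chrom = "chrS") {
  if (length < 1000L) stop("genome length must be >= 1000")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  seq <- paste(sample(.DNA_BASES, length, replace = TRUE), collapse = "")
  length <- as.integer(length)
  starts <- as.integer(seq(0L, length - 1L, by = block))
  ends <- as.integer(pmin(starts + block, length))
  labels <- rep(c("exonic", "intronic", "extragenic"),
                length.out = length(starts))
  structure(list(
    sequence = stats::setNames(seq, chrom),
    regions = data.frame(chrom = chrom, start = starts, end = ends,
                         label = labels, stringsAsFactors = FALSE)
  ), class = "sim_genome")
}

#' Write a genome to FASTA (with index)
#'
#' @param genome A \code{sim_genome} or named character vector.
#' @param path Output FASTA path; a samtools-style \code{.fai} index is
#'   written alongside when Rsamtools is available.
#' @export
write_genome <- function(genome, path) {
  seqs <- .genome_as_strings(genome)
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  if (requireNamespace("Rsamtools", quietly = TRUE)) {
    Rsamtools::indexFa(path)
  }
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  stats::setNames(toupper(as.character(dss)), names(dss))
}

#' Generate a synthetic signature reference
#'
#' Spiky signatures concentrate at least 50\% of their mass on at most three
#' channels (default 75\% on three); flat signatures are drawn near-uniform
#' so every channel stays below the 5\% flatness cutoff. Spiky signatures are
#' rejection-sampled until all pairwise cosine similarities fall below 0.5,
#' keeping them well separated for identifiability.
#'
#' @param n_spiky,n_flat Number of spiky and flat signatures (sum >= 1).
#' @param seed Integer seed.
#' @param spike_mass Total mass on the three spike channels; default 0.75.
#' @param name Reference label; default "synthetic".
#' @return A \code{\link{signature_reference}} named "synthetic" with ids
#'   \code{SIMS1..} (spiky) and \code{SIMF1..} (flat), and sets
#'   \code{SPIKY} / \code{FLAT}.
#' @export
make_reference <- function(n_spiky = 4L, n_flat = 2L, seed = 1L,
                           spike_mass = 0.75, name = "synthetic") {
  if (n_spiky + n_flat < 1L) stop("need at least one signature")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  make_spiky <- function() {
    ch <- sample.int(96L, 3L)
    v <- rep((1 - spike_mass) / 93, 96)
    v[ch] <- spike_mass * c(0.6, 0.25, 0.15)
    v / sum(v)
  }
  spiky <- list()
  tries <- 0L
  while (length(spiky) < n_spiky) {
    cand <- make_spiky()
    ok <- all(vapply(spiky, function(s) cosine_similarity(s, cand) < 0.5,
                     logical(1)))
    if (ok) spiky[[length(spiky) + 1L]] <- cand
    tries <- tries + 1L
    if (tries > 1000L) stop("could not generate well-separated signatures")
  }
  flat <- lapply(seq_len(n_flat), function(i) {
    v <- stats::rgamma(96, shape = 500)
    v <- v / sum(v)
    while (max(v) >= 0.05) {       # essentially never at shape 500
      v <- stats::rgamma(96, shape = 500)
      v <- v / sum(v)
    }
    v
  })
  mat <- do.call(cbind, c(spiky, flat))
  ids <- c(if (n_spiky) paste0("SIMS", seq_len(n_spiky)),
           if (n_flat) paste0("SIMF", seq_len(n_flat)))
  dimnames(mat) <- list(.SBS96_CHANNELS, ids)
  sets <- list()
  if (n_spiky) sets$SPIKY <- ids[seq_len(n_spiky)]
  if (n_flat) sets$FLAT <- ids[n_spiky + seq_len(n_flat)]
  signature_reference(mat, name = name, sets = sets)
}

#' Draw a multinomial SBS-96 catalogue from known exposures
#'
#' The probabilistic core of the simulator: channel counts are a single
#' multinomial draw of size \code{n_mutations} from the mixture profile
#' \code{reference$matrix \%*\% exposures}.
#'
#' @param reference A \code{\link{signature_reference}}.
#' @param exposures Mixing weights over the reference signatures (normalized
#'   internally).
#' @param n_mutations Number of mutations to draw.
#' @return Named integer 96-vector in canonical channel order.
#' @export
simulate_catalogue <- function(reference, exposures, n_mutations) {
  e <- as.numeric(exposures)
  if (length(e) != ncol(reference$matrix)) {
    stop("exposures must have one weight per reference signature")
  }
  if (any(e < 0) || sum(e) <= 0) stop("exposures must be non-negative")
  p <- as.numeric(reference$matrix %*% (e / sum(e)))
  stats::setNames(as.integer(stats::rmultinom(1, n_mutations, p)),
                  .SBS96_CHANNELS)
}

# channel -> (pyrimidine context key "uRd", alt base on pyrimidine strand)
.channel_context <- function(ch) {
  sub <- .SBS_SUBS[(ch - 1L) %/% 16L + 1L]
  up <- .DNA_BASES[((ch - 1L) %% 16L) %/% 4L + 1L]
  dn <- .DNA_BASES[(ch - 1L) %% 4L + 1L]
  list(key = paste0(up, substr(sub, 1L, 1L), dn), alt = substr(sub, 3L, 3L))
}

# Index every interior genome position by its pyrimidine-normalized
# trinucleotide context; positions on the purine strand are flagged so the
# emitted record can carry the genome-strand alleles.
.context_index <- function(genome) {
  seqs <- .genome_as_strings(genome)
  regions <- if (is.list(genome) && !is.null(genome$regions)) genome$regions
  out <- list()
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    L <- nchar(s)
    pos <- 2:(L - 1L)
    ctx <- substring(s, pos - 1L, pos + 1L)
    mid <- substr(ctx, 2L, 2L)
    flip <- mid %in% c("A", "G")
    key <- ctx
    key[flip] <- .revcomp_chr(ctx[flip])
    label <- rep("unknown", length(pos))
    if (!is.null(regions)) {
      ri <- regions[regions$chrom == chrom, , drop = FALSE]
      idx <- findInterval(pos - 1L, ri$start)  # 0-based pos into sorted starts
      inside <- idx >= 1 & (pos - 1L) < ri$end[pmax(idx, 1L)]
      label[inside] <- ri$label[idx[inside]]
    }
    out[[chrom]] <- data.frame(pos = pos, key = key, flip = flip,
                               label = label, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, Map(function(chrom, d) {
    d$chrom <- chrom
    d
  }, names(out), out))
  rownames(df) <- NULL
  df
}

#' Declare a synthetic cohort
#'
#' @param groups List of groups, each a list with \code{label},
#'   \code{n_samples} and \code{exposures} (mixing weights over the reference
#'   signatures, summing to 1).
#' @param mutations_per_sample Mutations per sample.
#' @param region_mixture Optional named list mapping region labels (exonic,
#'   intronic, extragenic) to exposure vectors that override the group
#'   exposures inside that compartment.
#' @param artefact_rate Expected fraction of each sample's records placed at
#'   dedicated blacklist positions, with channels drawn from
#'   \code{artefact_signature}; in \[0, 1). Default 0.
#' @param artefact_signature Signature id supplying artefact channels
#'   (required when \code{artefact_rate > 0}).
#' @param blacklist_share Fraction of each context's genome positions
#'   reserved as the blacklist pool; default 0.2. Raise it (or lengthen the
#'   genome) for high artefact loads on spiky artefact signatures.
#' @param vaf_range VAF sampling range; default uniform on \[0.1, 1\].
#' @param subthreshold_rate Fraction of records given a VAF below 0.1 to
#'   exercise the VAF filter; default 0.
#' @param seed Integer seed.
#' @return A list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(groups, mutations_per_sample,
                        region_mixture = NULL,
                        artefact_rate = 0, artefact_signature = NULL,
                        blacklist_share = 0.2,
                        vaf_range = c(0.1, 1), subthreshold_rate = 0,
                        seed = 1L) {
  for (g in groups) {
    stopifnot(!is.null(g$label), g$n_samples >= 1,
              abs(sum(g$exposures) - 1) < 1e-6)
  }
  stopifnot(artefact_rate >= 0, artefact_rate < 1,
            blacklist_share > 0, blacklist_share < 1)
  if (artefact_rate > 0 && is.null(artefact_signature)) {
    stop("artefact_rate > 0 requires an artefact_signature id")
  }
  structure(list(groups = groups,
                 mutations_per_sample = mutations_per_sample,
                 region_mixture = region_mixture,
                 artefact_rate = artefact_rate,
                 artefact_signature = artefact_signature,
                 blacklist_share = blacklist_share,
                 vaf_range = vaf_range,
                 subthreshold_rate = subthreshold_rate,
                 seed = seed),
            class = "cohort_spec")
}

.draw_positions <- function(pool, counts_by_channel, used) {
  # pool: context-index rows available; counts_by_channel: named int vector
  # (channel index -> count). Returns realized record rows; collisions with
  # `used` (chrom:pos keys) are redrawn.
  picked <- list()
  for (ch in as.integer(names(counts_by_channel))) {
    cnt <- counts_by_channel[[as.character(ch)]]
    if (cnt == 0L) next
    cc <- .channel_context(ch)
    cand <- pool[pool$key == cc$key, , drop = FALSE]
    if (nrow(cand) < 1L) {
      stop("context ", cc$key, " absent from the genome compartment; ",
           "use a longer genome")
    }
    take <- if (cnt <= nrow(cand)) {
      cand[sample.int(nrow(cand), cnt), , drop = FALSE]
    } else {
      stop("not enough distinct positions for context ", cc$key,
           " (need ", cnt, ", have ", nrow(cand), "); use a longer genome")
    }
    ref_pyr <- substr(cc$key, 2L, 2L)
    take$ref <- ifelse(take$flip, .BASE_COMP[ref_pyr], ref_pyr)
    take$alt <- ifelse(take$flip, .BASE_COMP[cc$alt], cc$alt)
    take$channel <- ch
    picked[[length(picked) + 1L]] <- take
  }
  if (!length(picked)) return(NULL)
  rec <- do.call(rbind, picked)
  # resolve residual collisions (same position drawn for two channels)
  key <- paste(rec$chrom, rec$pos, sep = ":")
  clash <- duplicated(key) | key %in% used
  attempts <- 0L
  while (any(clash) && attempts < 50L) {
    attempts <- attempts + 1L
    for (i in which(clash)) {
      ch <- rec$channel[i]
      cc <- .channel_context(ch)
      cand <- pool[pool$key == cc$key, , drop = FALSE]
      j <- sample.int(nrow(cand), 1L)
      rec$pos[i] <- cand$pos[j]
      rec$chrom[i] <- cand$chrom[j]
      rec$flip[i] <- cand$flip[j]
      rec$label[i] <- cand$label[j]
      ref_pyr <- substr(cc$key, 2L, 2L)
      rec$ref[i] <- if (cand$flip[j]) .BASE_COMP[[ref_pyr]] else ref_pyr
      rec$alt[i] <- if (cand$flip[j]) .BASE_COMP[[cc$alt]] else cc$alt
    }
    key <- paste(rec$chrom, rec$pos, sep = ":")
    clash <- duplicated(key) | key %in% used
  }
  if (any(clash)) {
    stop("could not place all mutations at distinct positions; ",
         "use a longer genome")
  }
  rec
}

#' Simulate a cohort of somatic mutation records
#'
#' Each sample's channel counts are drawn multinomially from its group's
#' signature mixture (optionally per genomic compartment), and every drawn
#' channel is realized as a concrete variant record at a genome position
#' whose trinucleotide context matches — so rebuilding the catalogue from the
#' emitted records reproduces the drawn counts exactly. A configurable
#' fraction of records is instead drawn from a designated artefact signature
#' and placed at dedicated blacklist positions, emulating recurrent
#' artefact/germline sites removable by metanormal filtering.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param reference A \code{\link{signature_reference}}.
#' @param genome A \code{\link{make_genome}} result.
#' @return List with \code{mutations} (data.frame: sample, chrom, pos, ref,
#'   alt, vaf, region), \code{annotation} (sample, label), \code{blacklist}
#'   (chrom, pos), and \code{truth} (true exposures per sample, realized
#'   channel counts, artefact counts).
#' @export
simulate_cohort <- function(spec, reference, genome) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- ncol(reference$matrix)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  idx <- .context_index(genome)
  # reserve a slice of positions per context as the blacklist pool
  reserved <- rep(FALSE, nrow(idx))
  if (spec$artefact_rate > 0) {
    for (k in unique(idx$key)) {
      rows <- which(idx$key == k)
      n_res <- max(1L, floor(spec$blacklist_share * length(rows)))
      reserved[sample(rows, n_res)] <- TRUE
    }
  }
  pool_normal <- idx[!reserved, , drop = FALSE]
  pool_black <- idx[reserved, , drop = FALSE]
  blacklist <- if (nrow(pool_black)) {
    data.frame(chrom = pool_black$chrom, pos = pool_black$pos,
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), pos = integer())

  rm_lbl <- names(spec$region_mixture)
  region_share <- NULL
  if (!is.null(rm_lbl)) {
    region_share <- vapply(rm_lbl, function(l) sum(pool_normal$label == l),
                           numeric(1))
    if (any(region_share == 0)) {
      stop("region label(s) absent from genome: ",
           paste(rm_lbl[region_share == 0], collapse = ", "))
    }
  }

  all_rec <- list()
  ann <- list()
  truth_expo <- list()
  truth_counts <- list()
  n_art_per_sample <- integer()
  art_col <- if (!is.null(spec$artefact_signature)) {
    match(spec$artefact_signature, colnames(reference$matrix))
  }
  if (!is.null(art_col) && is.na(art_col)) {
    stop("artefact signature '", spec$artefact_signature,
         "' not in the reference")
  }
  si <- 0L
  for (g in spec$groups) {
    e <- as.numeric(g$exposures)
    if (length(e) != K) stop("group '", g$label, "': exposures length != K")
    for (r in seq_len(g$n_samples)) {
      si <- si + 1L
      sample_id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", g$label), r)
      n <- spec$mutations_per_sample
      n_art <- if (spec$artefact_rate > 0) {
        stats::rbinom(1L, n, spec$artefact_rate)
      } else 0L
      n_sig <- n - n_art
      used <- character(0)
      recs <- list()
      draw_block <- function(n_draw, expo, pool) {
        p <- as.numeric(reference$matrix %*% (expo / sum(expo)))
        counts <- as.integer(stats::rmultinom(1L, n_draw, p))
        nz <- which(counts > 0L)
        .draw_positions(pool, stats::setNames(counts[nz], nz), used)
      }
      if (is.null(spec$region_mixture)) {
        rec <- draw_block(n_sig, e, pool_normal)
        if (!is.null(rec)) {
          used <- c(used, paste(rec$chrom, rec$pos, sep = ":"))
          recs[[length(recs) + 1L]] <- rec
        }
      } else {
        n_by_region <- as.integer(
          stats::rmultinom(1L, n_sig, region_share / sum(region_share)))
        for (ri in seq_along(rm_lbl)) {
          if (n_by_region[ri] == 0L) next
          expo_r <- as.numeric(spec$region_mixture[[ri]])
          rec <- draw_block(n_by_region[ri], expo_r,
                            pool_normal[pool_normal$label == rm_lbl[ri], ,
                                        drop = FALSE])
          if (!is.null(rec)) {
            used <- c(used, paste(rec$chrom, rec$pos, sep = ":"))
            recs[[length(recs) + 1L]] <- rec
          }
        }
      }
      if (n_art > 0L) {
        expo_a <- numeric(K); expo_a[art_col] <- 1
        rec <- draw_block(n_art, expo_a, pool_black)
        if (!is.null(rec)) {
          used <- c(used, paste(rec$chrom, rec$pos, sep = ":"))
          recs[[length(recs) + 1L]] <- rec
        }
      }
      rec <- do.call(rbind, recs)
      m <- nrow(rec)
      vaf <- stats::runif(m, spec$vaf_range[1], spec$vaf_range[2])
      if (spec$subthreshold_rate > 0) {
        low <- stats::runif(m) < spec$subthreshold_rate
        vaf[low] <- stats::runif(sum(low), 0, 0.0999)
      }
      all_rec[[si]] <- data.frame(
        sample = sample_id, chrom = rec$chrom, pos = rec$pos,
        ref = unname(rec$ref), alt = unname(rec$alt), vaf = vaf,
        region = rec$label, stringsAsFactors = FALSE)
      ann[[si]] <- data.frame(sample = sample_id, label = g$label,
                              stringsAsFactors = FALSE)
      truth_expo[[sample_id]] <- e
      truth_counts[[sample_id]] <- tabulate(rec$channel, nbins = 96L)
      n_art_per_sample[sample_id] <- n_art
    }
  }
  mutations <- do.call(rbind, all_rec)
  rownames(mutations) <- NULL
  expo_mat <- do.call(cbind, truth_expo)
  rownames(expo_mat) <- colnames(reference$matrix)
  counts_mat <- do.call(cbind, truth_counts)
  rownames(counts_mat) <- .SBS96_CHANNELS
  list(mutations = mutations,
       annotation = do.call(rbind, ann),
       blacklist = blacklist,
       truth = list(exposures = expo_mat,
                    channel_counts = counts_mat,
                    n_artefact = n_art_per_sample,
                    seed = spec$seed))
}
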