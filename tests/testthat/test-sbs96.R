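test_that("channel labels follow the canonical COSMIC ordering", {
  ch <- sbs96_channels()
  expect_length(ch, 96L)
  expect_false(anyDuplicated(ch) > 0)
  expect_identical(ch[1], "A[C>A]A")
  expect_identical(ch[2], "A[C>A]C")
  expect_identical(ch[17], "A[C>G]A")
  expect_identical(ch[96], "T[T>G]T")
})

test_that("classification maps pyrimidine- and purine-strand events alike", {
  expect_identical(classify_sbs("C", "A", "A", "A"), 1L)
  expect_identical(classify_sbs("G", "T", "T", "T"), 1L)
  idx <- classify_sbs("T", "G", "A", "C")
  expect_identical(sbs96_channels()[idx], "A[T>G]C")
})

test_that("classification is closed under reverse complement", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  hit <- logical(96)
  n_quads <- 0L
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (up in bases) for (dn in bases) {
      n_quads <- n_quads + 1L
      k1 <- classify_sbs(ref, alt, up, dn)
      k2 <- classify_sbs(comp[ref], comp[alt], comp[dn], comp[up])
      expect_identical(k1, k2)
      expect_true(k1 >= 1L && k1 <= 96L)
      hit[k1] <- TRUE
    }
  }
  expect_identical(n_quads, 192L)
  expect_true(all(hit))  # every channel reachable
})

test_that("invalid classification inputs error", {
  expect_error(classify_sbs("C", "C", "A", "A"), "ref == alt")
  expect_error(classify_sbs("N", "A", "A", "A"), "non-ACGT")
})

test_that("catalogue builder matches an independent per-mutation tally", {
  gen <- small_genome()
  seqs <- gen$sequence
  set.seed(101)
  pos <- sample(2:(nchar(seqs[[1]]) - 1L), 60)
  ref <- substr(rep(seqs[[1]], 60), pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                character(1), USE.NAMES = FALSE)
  muts <- data.frame(sample = rep(c("s1", "s2"), 30), chrom = "chrS",
                     pos = pos, ref = ref, alt = alt, vaf = 0.5)
  catal <- build_catalogue(muts, gen)
  # oracle: independent per-record tally using string ops only
  expected <- matrix(0L, 96, 2, dimnames = list(sbs96_channels(), c("s1","s2")))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp3 <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  for (i in seq_len(nrow(muts))) {
    tri <- substr(seqs[[1]], muts$pos[i] - 1, muts$pos[i] + 1)
    r <- muts$ref[i]; a <- muts$alt[i]
    if (r %in% c("A", "G")) {
      tri <- revcomp3(tri); r <- comp[[r]]; a <- comp[[a]]
    }
    lab <- paste0(substr(tri,1,1), "[", r, ">", a, "]", substr(tri,3,3))
    expected[lab, muts$sample[i]] <- expected[lab, muts$sample[i]] + 1L
  }
  expect_equal(unclass(catal), expected, ignore_attr = TRUE)
  expect_identical(sum(catal), 60L)
})

test_that("catalogue builder handles empty input, boundaries and mismatches", {
  gen <- toy_genome()
  empty <- build_catalogue(
    data.frame(sample = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character()),
    gen, samples = "s1")
  expect_identical(sum(empty), 0L)
  expect_identical(ncol(empty), 1L)

  # 3 identical C>A at a known ACA context (pos 3 of toy genome is A? find one)
  s <- gen[["chrT"]]
  p <- which(vapply(2:(nchar(s)-1),
                    function(i) substr(s, i-1, i+1) == "ACA", logical(1)))[1] + 1L
  muts <- data.frame(sample = "s1", chrom = "chrT", pos = rep(p, 3),
                     ref = "C", alt = "A")
  catal <- build_catalogue(muts, gen)
  expect_identical(unname(catal["A[C>A]A", "s1"]), 3L)
  expect_identical(sum(catal), 3L)

  # boundary position dropped with tally; count conservation holds
  muts2 <- rbind(muts, data.frame(sample = "s1", chrom = "chrT", pos = 1L,
                                  ref = substr(s, 1, 1), alt = "G"))
  catal2 <- build_catalogue(muts2, gen)
  expect_identical(sum(catal2) + attr(catal2, "n_discarded_context"), 4L)

  # ref mismatch warns and discards
  bad <- data.frame(sample = "s1", chrom = "chrT", pos = p,
                    ref = setdiff(c("A","G","T"), substr(s, p, p))[1], alt = "C")
  expect_warning(catal3 <- build_catalogue(bad, gen), "disagrees")
  expect_identical(sum(catal3), 0L)
  expect_error(build_catalogue(bad, gen, on_ref_mismatch = "error"),
               "disagrees")
  # absent chromosome errors
  expect_error(build_catalogue(transform(muts, chrom = "chrX"), gen),
               "absent")
})

test_that("VAF filter is inclusive at the threshold and keeps missing VAFs", {
  muts <- data.frame(sample = "s", chrom = "c", pos = 1:4,
                     ref = "C", alt = "A", vaf = c(0.05, 0.10, 0.50, NA))
  expect_identical(nrow(filter_vaf(muts, 0.10)), 3L)          # 0.10 retained
  expect_identical(filter_vaf(muts, 0.10)$pos, c(2L, 3L, 4L)) # order kept
  expect_identical(nrow(filter_vaf(muts, 0.10, strict = TRUE)), 2L)
  expect_identical(nrow(filter_vaf(muts, 0)), 4L)             # identity
  expect_identical(nrow(filter_vaf(muts[1:3, ], 0.9)), 0L)
  expect_error(filter_vaf(muts, 1.5), "min_vaf")
})

test_that("region partition follows precedence and matches brute force", {
  regions <- data.frame(
    chrom = "c1",
    start = c(100, 150, 300, 0),
    end = c(200, 250, 400, 1000),
    label = c("exonic", "intronic", "intronic", "extragenic"))
  m <- data.frame(sample = "s", chrom = "c1",
                  pos = c(150, 180, 220, 350, 500, 50),
                  ref = "C", alt = "T")
  out <- partition_by_region(m, regions)
  # pos 180 overlaps exon [100,200) and intron [150,250): exonic wins
  expect_identical(out$region,
                   c("exonic", "exonic", "intronic", "intronic",
                     "extragenic", "extragenic"))

  # property: disjoint partition matching a per-mutation interval scan
  set.seed(5)
  gen <- small_genome()
  m2 <- data.frame(sample = "s", chrom = "chrS",
                   pos = sample(1:30000, 100), ref = "C", alt = "T")
  out2 <- partition_by_region(m2, gen$regions)
  prec <- c(exonic = 1, intronic = 2, extragenic = 3)
  oracle <- vapply(m2$pos, function(p) {
    hits <- gen$regions$label[gen$regions$start < p & p <= gen$regions$end]
    if (!length(hits)) "extragenic" else hits[which.min(prec[hits])]
  }, character(1))
  expect_identical(out2$region, oracle)
  expect_identical(nrow(out2), nrow(m2))
})

test_that("panel subsetting keeps exactly the covered mutations", {
  m <- data.frame(sample = "s", chrom = "c1", pos = c(5, 15, 25, 35),
                  ref = "C", alt = "T")
  panel <- data.frame(chrom = "c1", start = c(10, 30), end = c(20, 40),
                      label = "panel")
  expect_identical(subset_to_panel(m, panel)$pos, c(15, 35))
  expect_identical(nrow(subset_to_panel(m, panel[0, ])), 0L)
  whole <- data.frame(chrom = "c1", start = 0, end = 100, label = "panel")
  expect_identical(subset_to_panel(m, whole), m)
  # brute-force overlap oracle on random intervals
  set.seed(9)
  pan2 <- data.frame(chrom = "c1", start = s <- sort(sample(0:90, 5)),
                     end = s + sample(3:10, 5, replace = TRUE), label = "p")
  m2 <- data.frame(sample = "s", chrom = "c1", pos = 1:100, ref = "C", alt = "T")
  inside <- vapply(m2$pos, function(p) any(pan2$start < p & p <= pan2$end),
                   logical(1))
  expect_identical(subset_to_panel(m2, pan2)$pos, m2$pos[inside])
})

test_that("blacklist filtering removes listed positions and is idempotent", {
  m <- data.frame(sample = "s", chrom = c("c1", "c1", "c2"),
                  pos = c(10, 20, 10), ref = "C", alt = "T")
  bl <- data.frame(chrom = "c1", pos = 10)
  out <- blacklist_filter(m, bl)
  expect_identical(out$n_removed, 1L)
  expect_identical(out$mutations$pos, c(20, 10))
  again <- blacklist_filter(out$mutations, bl)
  expect_identical(again$n_removed, 0L)
  expect_identical(again$mutations, out$mutations)
  expect_identical(blacklist_filter(m, NULL)$mutations, m)
  all_bl <- m[, c("chrom", "pos")]
  expect_identical(nrow(blacklist_filter(m, all_bl)$mutations), 0L)
})

test_that("catalogue TSV round-trips through write/read", {
  gen <- small_genome()
  set.seed(3)
  pos <- sample(2:29999, 40)
  s <- gen$sequence[[1]]
  ref <- substr(rep(s, 40), pos, pos)
  alt <- vapply(ref, function(b) setdiff(c("A","C","G","T"), b)[1],
                character(1), USE.NAMES = FALSE)
  muts <- data.frame(sample = "sx", chrom = "chrS", pos = pos,
                     ref = ref, alt = alt)
  catal <- build_catalogue(muts, gen)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue(catal, tf)
  back <- read_catalogue(tf)
  expect_identical(rownames(back), sbs96_channels())
  expect_equal(unclass(back), unclass(catal) + 0, ignore_attr = TRUE)
})
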