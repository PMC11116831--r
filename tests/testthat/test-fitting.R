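test_that("orthogonal one-hot mixtures are fitted exactly", {
  ref <- onehot_reference()
  y <- numeric(96); y[1] <- 30; y[2] <- 70
  fit <- fit_signatures(y, ref)
  expect_equal(unname(coef(fit, "raw")[, 1]), c(30, 70), tolerance = 1e-9)
  expect_equal(unname(coef(fit)[, 1]), c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(unname(fit$cosine), 1, tolerance = 1e-12)
  expect_true(fit$assigned)
  expect_equal(unname(fit$residual_fraction), 0, tolerance = 1e-12)
})

test_that("profiles outside the reference span give zero exposure, cosine 0", {
  ref <- onehot_reference()
  y <- numeric(96); y[50] <- 10   # unreachable channel
  fit <- suppressWarnings(fit_signatures(y, ref))
  expect_equal(unname(coef(fit, "raw")[, 1]), c(0, 0))
  expect_equal(unname(fit$cosine), 0)
  expect_false(fit$assigned)
  expect_true(all(coef(fit)[, 1] == 0))
})

test_that("zero profiles are rejected", {
  ref <- onehot_reference()
  expect_error(fit_signatures(numeric(96), ref), "all-zero")
})

test_that("noise-free mixtures are recovered to 1e-6 with cosine 1", {
  ref <- small_reference(3, 1)
  truth <- c(0.5, 0.3, 0.2, 0)
  y <- 10000 * as.numeric(ref$matrix %*% truth)
  fit <- fit_signatures(y, ref)
  expect_equal(unname(coef(fit)[, 1]), truth, tolerance = 1e-6)
  expect_equal(unname(fit$cosine), 1, tolerance = 1e-9)
})

test_that("fitted exposures agree with a simplex grid-search oracle", {
  # 10 random 3-signature instances; the NNLS residual norm must not exceed
  # the best residual on a step-1e-3 grid (and must come within 1e-4 of it)
  for (i in 1:10) {
    ref <- make_reference(3, 0, seed = 100 + i)
    set.seed(200 + i)
    w <- as.numeric(stats::rmultinom(1, 50, rep(1, 3))) / 50
    y <- as.numeric(stats::rmultinom(1, 2000, ref$matrix %*% w)) / 2000
    fit <- fit_signatures(y, ref)
    rn_fit <- sqrt(sum(residuals(fit)[, 1]^2))
    rn_grid <- grid_search_rnorm(ref$matrix, y, step = 1e-3)
    expect_lte(rn_fit, rn_grid + 1e-4)
    expect_lt(abs(rn_fit - rn_grid), 1e-4)
  }
})

test_that("the NNLS solution matches an independent solver", {
  skip_if_not_installed("pracma")
  for (i in 1:20) {
    set.seed(300 + i)
    A <- matrix(stats::runif(96 * 6), 96, 6)
    b <- stats::runif(96)
    mine <- nnls(A, b)
    theirs <- pracma::lsqnonneg(A, b)
    expect_equal(mine$x, as.numeric(theirs$x), tolerance = 1e-8)
  }
})

test_that("NNLS satisfies the KKT no-descent property", {
  eps <- 1e-6
  for (i in 1:10) {
    set.seed(400 + i)
    A <- matrix(stats::runif(96 * 5), 96, 5)
    b <- stats::runif(96) * 10
    sol <- nnls(A, b)
    f0 <- sum((b - A %*% sol$x)^2)
    for (j in 1:5) {
      for (d in c(-eps, eps)) {
        x2 <- sol$x
        x2[j] <- max(0, x2[j] + d)
        expect_gte(sum((b - A %*% x2)^2), f0 - 1e-10)
      }
    }
  }
})

test_that("fits are scale-equivariant", {
  ref <- small_reference()
  set.seed(21)
  y <- as.numeric(stats::rmultinom(1, 3000, ref$matrix %*% c(.4, .3, .2, .1)))
  f1 <- fit_signatures(y, ref)
  f2 <- fit_signatures(y * 7.5, ref)
  expect_equal(coef(f2, "raw"), coef(f1, "raw") * 7.5, tolerance = 1e-8)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-9)
  expect_equal(f2$cosine, f1$cosine, tolerance = 1e-12)
})

test_that("exposure RMSE shrinks as catalogues grow", {
  ref <- small_reference()
  truth <- c(0.45, 0.3, 0.15, 0.1)
  sizes <- c(100, 300, 1000, 10000)
  set.seed(77)
  med_rmse <- vapply(sizes, function(n) {
    rmse <- replicate(15, {
      y <- simulate_catalogue(ref, truth, n)
      e <- coef(fit_signatures(y, ref))[, 1]
      sqrt(mean((e - truth)^2))
    })
    stats::median(rmse)
  }, numeric(1))
  expect_true(all(diff(med_rmse) < 0))
  expect_lt(med_rmse[4], 0.02)
})

test_that("sparse backend strips decoys from a one-signature profile", {
  ref <- small_reference(4, 1)
  set.seed(31)
  y <- simulate_catalogue(ref, c(1, 0, 0, 0, 0), 5000)
  fit <- fit_signatures(y, ref, method = "sparse")
  support <- which(coef(fit, "raw")[, 1] > 0)
  expect_identical(unname(support), 1L)
  expect_gt(fit$cosine, 0.99)
})

test_that("sparse backend with zero tolerance keeps the NNLS support", {
  ref <- small_reference()
  set.seed(32)
  y <- simulate_catalogue(ref, c(0.4, 0.3, 0.2, 0.1), 4000)
  f_nnls <- fit_signatures(y, ref)
  f_sparse <- fit_signatures(y, ref, method = "sparse", drop_tolerance = 0)
  expect_identical(coef(f_sparse, "raw")[, 1] > 0,
                   coef(f_nnls, "raw")[, 1] > 0)
})

test_that("sparse backend recovers the true pair among decoys", {
  # 2 true signatures + 8 decoys, large catalogues: the surviving support
  # should be exactly the true pair in nearly all replicates
  ref <- make_reference(10, 0, seed = 55)
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    set.seed(500 + i)
    y <- simulate_catalogue(ref, c(0.6, 0.4, rep(0, 8)), 10000)
    fit <- fit_signatures(y, ref, method = "sparse")
    support <- sort(which(coef(fit, "raw")[, 1] > 0))
    if (identical(unname(support), c(1L, 2L))) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("cosine similarity obeys its closed forms and degenerate case", {
  a <- c(1, 1, rep(0, 94)); b <- c(1, rep(0, 95))
  expect_equal(cosine_similarity(a, b), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(cosine_similarity(b, b), 1)
  expect_equal(cosine_similarity(a, c(0, 0, 1, rep(0, 93))), 0)
  expect_warning(z <- cosine_similarity(numeric(96), b), "zero")
  expect_identical(z, 0)
})

test_that("assignment threshold is inclusive at 0.9", {
  expect_true(assign_status(0.95))
  expect_true(assign_status(0.90))
  expect_false(assign_status(0.89))
})

test_that("set contributions sum normalized exposures over the set", {
  ref <- small_reference()
  set.seed(61)
  y <- simulate_catalogue(ref, c(0.4, 0.3, 0.2, 0.1), 5000)
  fit <- fit_signatures(y, ref)
  expect_equal(unname(set_contribution(fit, ref$signature_ids)), 1,
               tolerance = 1e-9)
  expect_identical(unname(set_contribution(fit, character(0))), 0)
  expect_equal(set_contribution(fit, "SPIKY") + set_contribution(fit, "FLAT"),
               stats::setNames(1, colnames(fit$catalogue)), tolerance = 1e-9)
})

test_that("planted set contributions are recovered from multinomial draws", {
  ref <- small_reference(3, 1)
  # 60% of mutations from the first two (set) signatures
  truth <- c(0.35, 0.25, 0.25, 0.15)
  set.seed(71)
  errs <- replicate(20, {
    y <- simulate_catalogue(ref, truth, 20000)
    fit <- fit_signatures(y, ref)
    set_contribution(fit, c("SIMS1", "SIMS2")) - 0.6
  })
  expect_true(all(abs(errs) < 0.03))
})

test_that("model methods are coherent", {
  ref <- small_reference()
  set.seed(81)
  y <- cbind(simulate_catalogue(ref, c(.4, .3, .2, .1), 2000),
             simulate_catalogue(ref, c(.1, .2, .3, .4), 2000))
  colnames(y) <- c("a", "b")
  fit <- fit_signatures(y, ref)
  expect_s3_class(fit, "signature_fit")
  expect_equal(fitted(fit) + residuals(fit), fit$catalogue,
               ignore_attr = TRUE, tolerance = 1e-9)
  sm <- summary(fit)
  expect_identical(sm$sample, c("a", "b"))
  expect_identical(sm$n_mutations, c(2000, 2000))
  expect_identical(sm$top_signature[1], "SIMS1")
  ft <- fit_table(fit)
  expect_identical(nrow(ft), 2L)
  expect_equal(ft$cosine, unname(fit$cosine))
  # predict on new data refits; simulate draws catalogues of the same size
  expect_equal(predict(fit), fit$reconstructed)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(colSums(sims[[1]]), c(a = 2000, b = 2000))
  expect_silent(grDevices::pdf(NULL))
  expect_silent({plot(fit); grDevices::dev.off()})
})
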