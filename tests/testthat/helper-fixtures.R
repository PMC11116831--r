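# Shared fixtures, built in code at test time.

# a deterministic toy genome (single chromosome, known sequence)
toy_genome <- function() {
  c(chrT = "ACATGCTTGACCAGTACGTACCATTGCAGGTCAACTGGAAACATGCTTGA")
}

# a small random genome with compartments, fixed seed
small_genome <- function(length = 30000L, seed = 42L) {
  make_genome(length = length, seed = seed)
}

small_reference <- function(n_spiky = 3L, n_flat = 1L, seed = 7L) {
  make_reference(n_spiky = n_spiky, n_flat = n_flat, seed = seed)
}

# two one-hot signatures on channels 1 and 2 (orthogonal reference)
onehot_reference <- function() {
  m <- matrix(0, 96, 2, dimnames = list(sbs96_channels(), c("ONE", "TWO")))
  m[1, 1] <- 1
  m[2, 2] <- 1
  signature_reference(m, name = "onehot", sets = list())
}

# independent rank-sum enumeration oracle: exact two-sided p by enumerating
# all assignments of the pooled values to group A
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combos <- utils::combn(n, length(a))
  w_all <- apply(combos, 2, function(i) sum(r[i]))
  mu <- length(a) * (n + 1) / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  min(1, p)
}

# brute-force simplex grid oracle for 3-signature NNLS: every grid point is a
# mixture weight w on the 2-simplex; the optimal non-negative scale s for each
# w has a closed form, and the residual norm follows from the Gram matrix so
# no 96 x G intermediate is ever materialized
simplex_grid <- function(step = 1e-3) {
  a <- seq(0, 1, by = step)
  grid <- expand.grid(w1 = a, w2 = a)
  grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
  rbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
}

grid_search_rnorm <- function(S, y, step = 1e-3, W = NULL) {
  if (is.null(W)) W <- simplex_grid(step)
  G <- crossprod(S)                  # 3 x 3 Gram matrix
  b <- as.numeric(crossprod(S, y))
  uy <- colSums(W * b)               # u . y for every grid mixture u = S w
  uu <- colSums(W * (G %*% W))       # |u|^2
  s <- pmax(0, uy / uu)
  r2 <- sum(y^2) - 2 * s * uy + s^2 * uu
  sqrt(max(0, min(r2)))
}
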