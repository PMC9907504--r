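# internal helpers shared across modules

`%||%` <- rlang::`%||%`

# scalar checks ---------------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

assert_prob <- function(x, name) assert_scalar_number(x, name, 0, 1)

# upper triangle of a square matrix as a vector (row < col order)
upper_tri_vec <- function(m) m[upper.tri(m)]

# validate a symmetric zero-diagonal dissimilarity matrix with labels
check_dissimilarity <- function(d, name = "d", tol = 1e-12) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort(sprintf("`%s` must be a square matrix", name))
  }
  if (max(abs(d - t(d))) > tol * max(1, max(abs(d)))) {
    abort(sprintf("`%s` must be symmetric", name))
  }
  if (any(abs(diag(d)) > tol)) {
    abort(sprintf("`%s` must have a zero diagonal", name))
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}

# Gower-centered matrix G = -1/2 * J (D o D) J used by PCoA and PERMANOVA
gower_center <- function(d) {
  a <- -0.5 * d * d
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# accept either a genomes-by-items binary matrix or a wide tibble whose first
# column holds the genome/site label
as_binary_matrix <- function(pa, name = "pa") {
  if (is.data.frame(pa)) {
    lab <- as.character(pa[[1]])
    m <- as.matrix(pa[, -1, drop = FALSE])
    rownames(m) <- lab
    pa <- m
  }
  if (!is.matrix(pa)) abort(sprintf("`%s` must be a matrix or wide data frame", name))
  storage.mode(pa) <- "double"
  if (any(is.na(pa)) || any(pa != 0 & pa != 1)) {
    abort(sprintf("`%s` must be binary (0/1)", name))
  }
  if (is.null(rownames(pa))) rownames(pa) <- paste0("g", seq_len(nrow(pa)))
  pa
}

# deterministic tiny parameters from an integer seed without touching the
# session RNG (linear congruential steps, folded to (0,1))
hash_unit <- function(seed, n) {
  x <- as.double(seed %% 2147483647L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (x * 48271) %% 2147483647
    out[i] <- x / 2147483647
  }
  out
}
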