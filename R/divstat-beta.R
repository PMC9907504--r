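#' Pairwise Sorensen beta-diversity partition
#'
#' Partitions pairwise Sorensen dissimilarity into its turnover (Simpson)
#' and nestedness-resultant components. With a = |A intersect B|,
#' b = |A \ B|, c = |B \ A|:
#' beta_sor = (b + c) / (2a + b + c), beta_sim = min(b, c) / (a + min(b, c)),
#' beta_sne = beta_sor - beta_sim.
#'
#' @param site_a,site_b Character (or other atomic) vectors of items
#'   present at each site; at least one must be non-empty.
#' @return One-row tibble: beta_sor, beta_sim, beta_sne, scope =
#'   "pairwise".
#' @export
beta_pairwise <- function(site_a, site_b) {
  site_a <- unique(site_a); site_b <- unique(site_b)
  if (length(site_a) == 0 && length(site_b) == 0) {
    abort("both sites are empty")
  }
  a <- length(intersect(site_a, site_b))
  b <- length(setdiff(site_a, site_b))
  c <- length(setdiff(site_b, site_a))
  sor <- if (2 * a + b + c == 0) 0 else (b + c) / (2 * a + b + c)
  m <- min(b, c)
  sim <- if (a + m == 0) 0 else m / (a + m)
  tibble(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim,
         scope = "pairwise")
}

#' Multiple-site Sorensen beta-diversity partition
#'
#' Multiple-site generalization over a sites-by-items binary matrix. With
#' b_ij the number of items in site i but not j, S_i the per-site richness
#' and S_T the pooled richness:
#' beta_SIM = sum min(b_ij, b_ji) / (sum S_i - S_T + sum min(b_ij, b_ji));
#' beta_SOR = (sum min + sum max) / (2 (sum S_i - S_T) + sum min + sum max);
#' beta_SNE = beta_SOR - beta_SIM. At two sites this reduces exactly to
#' [beta_pairwise()].
#'
#' @param pa Sites-by-items binary matrix (or wide tibble, first column the
#'   site label).
#' @return One-row tibble: beta_sor, beta_sim, beta_sne, scope =
#'   "multisite".
#' @export
beta_multisite <- function(pa) {
  m <- as_binary_matrix(pa)
  if (nrow(m) < 2) abort("need at least 2 sites")
  if (sum(m) == 0) abort("all-zero matrix")
  shared <- m %*% t(m)                   # a_ij
  s_i <- rowSums(m)
  b <- outer(s_i, rep(1, nrow(m))) - shared  # b_ij = S_i - a_ij
  ut <- upper.tri(b)
  bmin <- pmin(b, t(b))[ut]
  bmax <- pmax(b, t(b))[ut]
  s_t <- sum(colSums(m) > 0)
  core <- sum(s_i) - s_t
  sim <- sum(bmin) / (core + sum(bmin))
  sor <- (sum(bmin) + sum(bmax)) / (2 * core + sum(bmin) + sum(bmax))
  tibble(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim,
         scope = "multisite")
}

#' Jaccard dissimilarity matrix of presence-absence profiles
#'
#' d(i, j) = 1 - |A_i intersect A_j| / |A_i union A_j| over the item sets
#' of each row. Two empty rows get d = 0 with a warning.
#'
#' @param pa Binary matrix or wide tibble (first column = label).
#' @return Symmetric, zero-diagonal matrix with dimnames.
#' @export
jaccard_matrix <- function(pa) {
  m <- as_binary_matrix(pa)
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    warn("pairs of empty rows: distance set to 0")
    d[uni == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
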