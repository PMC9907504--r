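#' Simulate a species tree and a presence-absence matrix evolved along it
#'
#' Grows a Yule (pure-birth) tree with `n_tips` tips, then evolves each
#' family as an independent two-state Markov process (absent -> present at
#' `gain_rate`, present -> absent at `loss_rate`, per unit branch length)
#' from a root state drawn from the stationary distribution. Fast rates wash
#' out phylogenetic signal; slow rates preserve it, so the output calibrates
#' Mantel/PERMANOVA behaviour against a known generating process.
#'
#' @param params [evolution_params()]; `n_tips`, `gain_rate`, `loss_rate`
#'   and `seed` are used.
#' @param n_families Number of presence-absence columns.
#' @return List with `tree` (an `ape::phylo`), `pa` (tips x families 0/1
#'   matrix) and `root_states` (0/1 vector, the truth at the root).
#' @export
simulate_tree_pa <- function(params, n_families = 100) {
  if (params$n_tips < 3) abort("n_tips must be >= 3")
  set.seed(params$seed)
  tree <- ape::rphylo(params$n_tips, birth = 1, death = 0)
  g <- params$gain_rate; l <- params$loss_rate
  n_node <- ape::Nnode(tree) + ape::Ntip(tree)
  root <- ape::Ntip(tree) + 1L
  if (g + l > 0) {
    root_states <- rbinom(n_families, 1, g / (g + l))
  } else {
    root_states <- rep(0L, n_families)
  }
  states <- matrix(NA_integer_, n_node, n_families)
  states[root, ] <- root_states
  # cladewise order visits parents before children
  tr2 <- ape::reorder.phylo(tree, "cladewise")
  ord <- tr2$edge
  lens <- tr2$edge.length
  for (e in seq_len(nrow(ord))) {
    par <- ord[e, 1]; child <- ord[e, 2]; t <- lens[e]
    s <- states[par, ]
    if (g + l == 0) {
      states[child, ] <- s
    } else {
      p01 <- g / (g + l) * (1 - exp(-(g + l) * t))  # absent -> present
      p10 <- l / (g + l) * (1 - exp(-(g + l) * t))  # present -> absent
      u <- runif(n_families)
      states[child, ] <- ifelse(s == 1L, as.integer(u >= p10),
                                as.integer(u < p01))
    }
  }
  pa <- states[seq_len(ape::Ntip(tree)), , drop = FALSE]
  rownames(pa) <- tree$tip.label
  colnames(pa) <- sprintf("fam%03d", seq_len(n_families))
  zero <- colSums(pa) == 0
  if (g + l == 0 && any(root_states == 0)) {
    warn("gain and loss rates are both 0 with absent root states: all-zero columns kept")
  } else if (any(zero)) {
    warn(sprintf("%d all-zero family columns in simulated matrix", sum(zero)))
  }
  list(tree = tree, pa = pa, root_states = root_states)
}
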