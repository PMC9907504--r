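#' Principal coordinates analysis
#'
#' Double-centers the squared dissimilarities (G = -1/2 J D*D J), takes the
#' eigendecomposition, and scales eigenvectors of positive eigenvalues by
#' sqrt(lambda). Negative eigenvalues (non-Euclidean input) are reported,
#' not corrected. Axes are ordered by decreasing eigenvalue; each axis is
#' signed so its first non-zero loading is positive.
#'
#' @param d Symmetric zero-diagonal dissimilarity matrix (labels in
#'   dimnames) or `dist` object.
#' @param eig_tol Eigenvalues within `eig_tol * max(|lambda|)` of zero are
#'   treated as zero.
#' @return Object of class `lichen_pcoa`: list with `points` (tibble:
#'   label, Axis1..k), `eigenvalues` (all, descending) and `var_explained`
#'   (fractions over positive eigenvalues).
#' @export
pcoa <- function(d, eig_tol = 1e-8) {
  d <- check_dissimilarity(d, "d")
  g <- gower_center(d)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- eig_tol * max(abs(lam), 1e-300)
  pos <- which(lam > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]),
                                                    length(pos))
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
  }
  pts <- tibble(label = rownames(d))
  if (ncol(coords) > 0) {
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
    pts <- dplyr::bind_cols(pts, as_tibble(coords))
  }
  structure(list(points = pts, eigenvalues = lam,
                 var_explained = lam[pos] / sum(lam[pos])),
            class = "lichen_pcoa")
}

#' @export
print.lichen_pcoa <- function(x, ...) {
  cat(sprintf("<lichen_pcoa> %d points, %d positive axes\n",
              nrow(x$points), ncol(x$points) - 1))
  if (length(x$var_explained)) {
    cat(sprintf("  Axis1 %.1f%%, Axis2 %.1f%% of positive inertia\n",
                100 * x$var_explained[1],
                if (length(x$var_explained) > 1) 100 * x$var_explained[2]
                else NA))
  }
  invisible(x)
}

#' Cophenetic (patristic) distances of a tree
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree An `ape::phylo` object, a newick string, or a path to a
#'   newick file.
#' @return Symmetric zero-diagonal matrix over tip labels.
#' @export
cophenetic_distances <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) abort("tree must be a phylo or newick")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    abort(sprintf("missing branch length on edge %d (%d -> %d)",
                  bad, tree$edge[bad, 1], tree$edge[bad, 2]))
  }
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

#' Principal components of phylogenetic distances
#'
#' Treats the rows of the distance matrix as observations (each taxon
#' described by its distances to all taxa), column-centers, and takes the
#' SVD. `k` is the smallest number of components whose cumulative variance
#' fraction reaches `var_threshold`. Set `center = "double"` to operate on
#' the Gower-centered matrix instead (PCoA-equivalent); the default follows
#' the raw-rows description.
#'
#' @param d_phylo Symmetric distance matrix over taxa.
#' @param var_threshold Cumulative variance target (default 0.8).
#' @param center `"columns"` (raw rows as features, default) or
#'   `"double"`.
#' @return List: `scores` (tibble label, PC1..), `var_frac`, `k`.
#' @export
phylo_pcs <- function(d_phylo, var_threshold = 0.8,
                      center = c("columns", "double")) {
  center <- match.arg(center)
  d_phylo <- check_dissimilarity(d_phylo, "d_phylo")
  x <- if (center == "double") gower_center(d_phylo)
       else scale(d_phylo, center = TRUE, scale = FALSE)
  sv <- svd(x)
  var_frac <- sv$d^2 / sum(sv$d^2)
  k <- if (var_threshold <= 0) 1L else
    max(1L, which(cumsum(var_frac) >= var_threshold)[1])
  scores <- x %*% sv$v
  pts <- as_tibble(scores, .name_repair = ~ paste0("PC", seq_along(.x)))
  list(scores = dplyr::bind_cols(tibble(label = rownames(d_phylo)), pts),
       var_frac = var_frac, k = k)
}
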