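# composite BGC distance: domain-content Jaccard (J), domain sequence
# similarity (DSS) and adjacency index (AI), combined as
# d = 1 - (wJ*J + wDSS*DSS + wAI*AI)

default_weights <- c(J = 0.2, DSS = 0.7, AI = 0.1)

check_weights <- function(weights) {
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be 3 non-negative numbers summing to 1")
  }
  weights
}

# accepts a one-row clusters tibble, a list with $genes, or a genes tibble
cluster_genes <- function(x) {
  if (is.data.frame(x) && "genes" %in% names(x) && is.list(x$genes)) {
    return(x$genes[[1]])
  }
  if (is.list(x) && !is.data.frame(x) && !is.null(x$genes)) return(x$genes)
  if (is.data.frame(x) && "domains" %in% names(x)) return(x)
  abort("cannot extract genes from cluster object")
}

# domains linearized in gene order
linear_domains <- function(genes) unlist(genes$domains, use.names = FALSE)

# vectorized identity of sequence pairs via the compiled global-alignment
# kernel; identity = matches / alignment columns
batch_identity <- function(seq_a, seq_b) {
  stopifnot(length(seq_a) == length(seq_b))
  if (length(seq_a) == 0) return(numeric(0))
  # canonical order so identity(a, b) == identity(b, a) exactly
  swap <- seq_a > seq_b
  tmp <- seq_a[swap]; seq_a[swap] <- seq_b[swap]; seq_b[swap] <- tmp
  .nw_identity_batch(seq_a, seq_b)$identity
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a linear
#' gap penalty of -2 per gap position; identity is the fraction of alignment
#' columns that match. Symmetric in its arguments.
#'
#' @param seq_a,seq_b Non-empty residue strings.
#' @return Identity in [0, 1].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("empty sequence")
  batch_identity(seq_a, seq_b)
}

#' Domain-content Jaccard similarity of two clusters
#'
#' Jaccard index of the sets of domain labels pooled across each cluster's
#' genes. If both clusters have no domains at all, returns 1 with a warning.
#'
#' @param a,b Cluster records (one-row tibble with nested `genes`, or a
#'   genes tibble).
#' @return J in [0, 1].
#' @export
domain_jaccard <- function(a, b) {
  sa <- unique(linear_domains(cluster_genes(a)))
  sb <- unique(linear_domains(cluster_genes(b)))
  if (length(sa) == 0 && length(sb) == 0) {
    warn("both clusters have no domains: J = 1")
    return(1)
  }
  length(intersect(sa, sb)) / length(union(sa, sb))
}

#' Adjacency index of two clusters
#'
#' Linearizes each cluster's domains in gene order, forms the set of
#' unordered adjacent pairs, and returns the larger Jaccard of the pair sets
#' between A and B as given or B reversed (so the index is strand-flip
#' invariant). Clusters with fewer than two domains score 0.
#'
#' @inheritParams domain_jaccard
#' @return AI in [0, 1].
#' @export
adjacency_index <- function(a, b) {
  da <- linear_domains(cluster_genes(a))
  db <- linear_domains(cluster_genes(b))
  if (length(da) < 2 || length(db) < 2) return(0)
  pair_set <- function(d) {
    unique(vapply(seq_len(length(d) - 1), function(i) {
      paste(sort(c(d[i], d[i + 1])), collapse = "|")
    }, ""))
  }
  pa <- pair_set(da)
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  max(jac(pa, pair_set(db)), jac(pa, pair_set(rev(db))))
}

#' Domain sequence similarity of two clusters
#'
#' For every domain label shared by the two clusters, copies are paired
#' greedily by descending global-alignment identity of their parent-gene
#' sequences. DSS is twice the summed paired identity divided by the total
#' domain copy count of both clusters, so identical clusters score 1 and
#' clusters with no shared labels score 0; unpaired copies (extra copy
#' number or unshared labels) dilute the score.
#'
#' @inheritParams domain_jaccard
#' @return DSS in [0, 1].
#' @export
domain_sequence_similarity <- function(a, b) {
  ca <- domain_copies(cluster_genes(a))
  cb <- domain_copies(cluster_genes(b))
  dss_from_copies(ca, cb, batch_identity)
}

# (label, parent sequence) for every domain copy of a cluster
domain_copies <- function(g) {
  tibble(label = unlist(g$domains, use.names = FALSE),
         sequence = rep(g$sequence, lengths(g$domains)))
}

# greedy per-label pairing by descending identity; idfun(seq_a, seq_b) is
# vectorized and may be a precomputed lookup
dss_from_copies <- function(ca, cb, idfun) {
  total <- nrow(ca) + nrow(cb)
  if (total == 0) return(0)
  shared <- intersect(ca$label, cb$label)
  if (length(shared) == 0) return(0)
  paired_sum <- 0
  for (lab in shared) {
    xa <- ca$sequence[ca$label == lab]
    xb <- cb$sequence[cb$label == lab]
    grid <- expand.grid(i = seq_along(xa), j = seq_along(xb))
    ids <- matrix(idfun(xa[grid$i], xb[grid$j]), nrow = length(xa))
    for (k in seq_len(min(length(xa), length(xb)))) {
      best <- arrayInd(which.max(ids), dim(ids))
      paired_sum <- paired_sum + ids[best]
      ids[best[1], ] <- -Inf
      ids[, best[2]] <- -Inf
    }
  }
  2 * paired_sum / total
}

#' Composite distance between two clusters
#'
#' @inheritParams domain_jaccard
#' @param weights Named or positional weights (J, DSS, AI); non-negative,
#'   summing to 1. Default c(0.2, 0.7, 0.1).
#' @return One-row tibble: J, DSS, AI, d with d = 1 - (wJ J + wDSS DSS +
#'   wAI AI).
#' @export
bgc_distance <- function(a, b, weights = default_weights) {
  check_weights(weights)
  j <- domain_jaccard(a, b)
  dss <- domain_sequence_similarity(a, b)
  ai <- adjacency_index(a, b)
  tibble(J = j, DSS = dss, AI = ai,
         d = 1 - (weights[[1]] * j + weights[[2]] * dss + weights[[3]] * ai))
}

#' All within-class pairwise distances of a cluster panel
#'
#' Pairs are formed only within the same BGC class (RiPP and saccharide
#' classes, if present, are excluded).
#'
#' @param clusters Clusters tibble (cluster_id, genome_id, class, nested
#'   `genes`, ...).
#' @param weights See [bgc_distance()].
#' @return Tibble: a_id, b_id, class, J, DSS, AI, d (one row per unordered
#'   pair).
#' @export
bgc_distance_matrix <- function(clusters, weights = default_weights) {
  check_weights(weights)
  clusters <- clusters[!clusters$class %in% c("RiPPs", "RiPP", "Saccharide",
                                              "saccharide"), , drop = FALSE]
  # per-cluster precomputation: domain set, adjacency pair set, copies
  pre <- lapply(seq_len(nrow(clusters)), function(i) {
    g <- cluster_genes(clusters[i, ])
    lin <- linear_domains(g)
    pairs <- if (length(lin) >= 2) {
      unique(vapply(seq_len(length(lin) - 1), function(k) {
        paste(sort(c(lin[k], lin[k + 1])), collapse = "|")
      }, ""))
    } else character()
    list(set = unique(lin), adj = pairs, copies = domain_copies(g))
  })
  empty <- tibble(a_id = character(), b_id = character(),
                  class = character(), J = double(), DSS = double(),
                  AI = double(), d = double())
  out <- list(empty)
  for (cls in unique(clusters$class)) {
    sub_idx <- which(clusters$class == cls)
    n <- length(sub_idx)
    if (n < 2) next
    idx <- combn(n, 2)
    # identities of every same-label sequence pair in this class, computed
    # in one alignment batch and held in a dense matrix over unique
    # sequences
    all_copies <- bind_rows(lapply(sub_idx, function(i) pre[[i]]$copies))
    useqs <- unique(all_copies$sequence)
    nseq <- length(useqs)
    idmat <- matrix(NA_real_, nseq, nseq)
    diag(idmat) <- 1
    cseq <- match(all_copies$sequence, useqs)
    need <- integer(0)
    for (lab in unique(all_copies$label)) {
      ids <- sort(unique(cseq[all_copies$label == lab]))
      if (length(ids) >= 2) {
        cmb <- combn(ids, 2)
        need <- c(need, cmb[1, ] + nseq * (cmb[2, ] - 1L))
      }
    }
    need <- unique(need)
    if (length(need)) {
      ia <- ((need - 1L) %% nseq) + 1L
      ib <- ((need - 1L) %/% nseq) + 1L
      vals <- batch_identity(useqs[ia], useqs[ib])
      idmat[cbind(ia, ib)] <- vals
      idmat[cbind(ib, ia)] <- vals
    }
    idfun <- function(sa, sb) {
      idmat[cbind(match(sa, useqs), match(sb, useqs))]
    }
    jac <- function(x, y) {
      u <- length(union(x, y))
      if (u == 0) NA_real_ else length(intersect(x, y)) / u
    }
    rows <- lapply(seq_len(ncol(idx)), function(p) {
      i <- sub_idx[idx[1, p]]; j <- sub_idx[idx[2, p]]
      jv <- jac(pre[[i]]$set, pre[[j]]$set)
      if (is.na(jv)) jv <- 1  # both domainless
      ai <- if (length(pre[[i]]$adj) && length(pre[[j]]$adj)) {
        jac(pre[[i]]$adj, pre[[j]]$adj)
      } else 0
      dss <- dss_from_copies(pre[[i]]$copies, pre[[j]]$copies, idfun)
      tibble(a_id = clusters$cluster_id[i], b_id = clusters$cluster_id[j],
             class = cls, J = jv, DSS = dss, AI = ai,
             d = 1 - (weights[[1]] * jv + weights[[2]] * dss +
                        weights[[3]] * ai))
    })
    out[[cls]] <- bind_rows(rows)
  }
  bind_rows(out) |> select("a_id", "b_id", "class", "J", "DSS", "AI", "d")
}
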