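#' Network and family-assignment configuration
#'
#' @param cutoff Distance cutoff for linking two clusters (edge iff
#'   d <= cutoff); default 0.46.
#' @param cutoff_grid Grid searched by [select_cutoff()]; default 0.30-1.00
#'   in steps of 0.01.
#' @param preference Affinity-propagation exemplar preference on the
#'   similarity scale (default 0.5). A value below typical within-family
#'   similarities keeps coherent families whole while still splitting
#'   components that mix families.
#' @param damping Affinity-propagation damping factor (default 0.9).
#' @param max_iter Iteration cap (default 1000); components whose
#'   propagation does not converge collapse to a single family.
#' @param seed Integer seed (tie-breaking noise).
#' @return A list of class `network_config`.
#' @export
network_config <- function(cutoff = 0.46,
                           cutoff_grid = seq(0.30, 1.00, by = 0.01),
                           preference = 0.5, damping = 0.9,
                           max_iter = 1000, seed = 1L) {
  assert_prob(cutoff, "cutoff")
  structure(list(cutoff = cutoff, cutoff_grid = cutoff_grid,
                 preference = preference, damping = damping,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "network_config")
}

#' Build the similarity network
#'
#' Links every within-class pair whose composite distance is at or below
#' the cutoff. Pairs at the maximum distance (d = 1, no shared signal) are
#' never linked, whatever the cutoff.
#'
#' @param pairs Pairwise distance tibble from [bgc_distance_matrix()].
#' @param cutoff Distance cutoff (inclusive).
#' @return Edge tibble (subset of `pairs`).
#' @export
build_network <- function(pairs, cutoff = 0.46) {
  pairs |> filter(.data$d <= cutoff, .data$d < 1)
}

# affinity propagation on a similarity matrix; returns integer labels or
# NULL on non-convergence
ap_cluster <- function(s, preference = 0.5, damping = 0.9, max_iter = 1000,
                       conv_iter = 50, seed = 1L) {
  n <- nrow(s)
  diag(s) <- preference
  # seeded tie-breaking noise, small relative to the similarity scale
  set.seed(seed)
  s <- s + matrix(runif(n * n), n, n) * 1e-9
  r <- matrix(0, n, n); a <- matrix(0, n, n)
  exemplar_hist <- rep(-1L, n)
  stable <- 0L
  for (it in seq_len(max_iter)) {
    as_mat <- a + s
    max1 <- apply(as_mat, 1, max)
    which1 <- max.col(as_mat, ties.method = "first")
    max2 <- vapply(seq_len(n), function(i) {
      max(as_mat[i, -which1[i]])
    }, 0)
    rn <- s - max1
    for (i in seq_len(n)) rn[i, which1[i]] <- s[i, which1[i]] - max2[i]
    r <- damping * r + (1 - damping) * rn
    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    colsum <- colSums(rp)
    an <- matrix(rep(colsum, each = n), n, n) - rp
    da <- diag(an)
    an <- pmin(an, 0)
    diag(an) <- da
    a <- damping * a + (1 - damping) * an
    ex <- which(diag(a + r) > 0)
    key <- if (length(ex)) as.integer(ex) else -1L
    if (identical(key, exemplar_hist)) stable <- stable + 1L else stable <- 0L
    exemplar_hist <- key
    if (stable >= conv_iter && length(ex) > 0) {
      labels <- ex[max.col(s[, ex, drop = FALSE], ties.method = "first")]
      labels[ex] <- ex
      return(as.integer(labels))
    }
  }
  NULL
}

#' Assign clusters to families
#'
#' Computes connected components of the cutoff network; components of size
#' >= 3 are partitioned by affinity propagation on similarity s = 1 - d
#' (non-convergent components stay one family); singletons and pairs keep
#' their component identity. Every cluster lands in exactly one family
#' (hybrids-off), and family ids are canonicalized to the lexicographically
#' smallest member cluster_id, so the partition is invariant to input
#' order.
#'
#' @param clusters Clusters tibble.
#' @param pairs Pairwise distances from [bgc_distance_matrix()]; computed
#'   if `NULL`.
#' @param cutoff Distance cutoff (default `config$cutoff`).
#' @param config [network_config()].
#' @param weights Distance weights, used only when `pairs` is `NULL`.
#' @return An object of class `bgc_families`: tibble (cluster_id,
#'   genome_id, family_id, is_reference, compound) with the edge list and
#'   config as attributes.
#' @export
assign_families <- function(clusters, pairs = NULL, cutoff = NULL,
                            config = network_config(),
                            weights = default_weights) {
  if (is.null(pairs)) pairs <- bgc_distance_matrix(clusters, weights)
  cutoff <- cutoff %||% config$cutoff
  edges <- build_network(pairs, cutoff)
  ids <- sort(clusters$cluster_id)
  g <- igraph::graph_from_data_frame(
    edges |> select("a_id", "b_id"), directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  family <- setNames(rep(NA_character_, length(ids)), ids)
  d_lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    d_lookup[[paste(pairs$a_id[i], pairs$b_id[i], sep = "\r")]] <- pairs$d[i]
  }
  get_d <- function(x, y) {
    v <- d_lookup[[paste(x, y, sep = "\r")]] %||%
      d_lookup[[paste(y, x, sep = "\r")]]
    v %||% 1
  }
  for (cid in unique(comp)) {
    members <- sort(names(comp)[comp == cid])
    if (length(members) <= 2) {
      family[members] <- members[1]
      next
    }
    n <- length(members)
    s <- matrix(0, n, n, dimnames = list(members, members))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s[i, j] <- s[j, i] <- 1 - get_d(members[i], members[j])
      }
    }
    labels <- ap_cluster(s, preference = config$preference,
                         damping = config$damping,
                         max_iter = config$max_iter, seed = config$seed)
    if (is.null(labels)) {
      family[members] <- members[1]
    } else {
      for (lab in unique(labels)) {
        sub <- members[labels == lab]
        family[sub] <- sort(sub)[1]
      }
    }
  }
  out <- clusters
  if (!"is_reference" %in% names(out)) out$is_reference <- FALSE
  if (!"compound" %in% names(out)) out$compound <- NA_character_
  out <- out |>
    select(dplyr::any_of(c("cluster_id", "genome_id", "class",
                           "is_reference", "compound"))) |>
    mutate(family_id = paste0("F_", unname(family[.data$cluster_id])))
  structure(out, class = c("bgc_families", class(out)),
            edges = edges, cutoff = cutoff)
}

#' @export
print.bgc_families <- function(x, ...) {
  cat(sprintf("<bgc_families> %d clusters in %d families (cutoff %.2f)\n",
              nrow(x), dplyr::n_distinct(x$family_id), attr(x, "cutoff")))
  NextMethod()
}

#' Summaries of a family assignment
#'
#' `tidy()` returns one row per family (size, genomes, reference members,
#' compounds); `glance()` one row of panel-level counts.
#'
#' @param x A `bgc_families` object.
#' @param ... Unused.
#' @method tidy bgc_families
#' @export
tidy.bgc_families <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$family_id) |>
    summarise(
      n_clusters = n(),
      n_genomes = dplyr::n_distinct(.data$genome_id[!.data$is_reference]),
      n_references = sum(.data$is_reference),
      compounds = paste(sort(unique(.data$compound[!is.na(.data$compound)])),
                        collapse = ";"),
      .groups = "drop"
    )
}

#' @rdname tidy.bgc_families
#' @method glance bgc_families
#' @export
glance.bgc_families <- function(x, ...) {
  tibble(
    n_clusters = nrow(x),
    n_families = dplyr::n_distinct(x$family_id),
    n_singletons = sum(table(x$family_id) == 1),
    cutoff = attr(x, "cutoff")
  )
}

#' Choose the distance cutoff from a reference pair
#'
#' Returns the smallest grid value at which the two reference clusters land
#' in the same family, additionally verifying co-clustering at the next
#' grid step (so a knife-edge value is not selected).
#'
#' @param clusters Clusters tibble containing both reference ids.
#' @param reference_pair Character vector of two cluster_ids.
#' @param grid Cutoff grid (default 0.30-1.00 by 0.01).
#' @param config,weights See [assign_families()].
#' @return The selected cutoff (numeric scalar).
#' @export
select_cutoff <- function(clusters, reference_pair,
                          grid = seq(0.30, 1.00, by = 0.01),
                          config = network_config(),
                          weights = default_weights) {
  stopifnot(length(reference_pair) == 2)
  if (!all(reference_pair %in% clusters$cluster_id)) {
    abort("both reference clusters must be present")
  }
  pairs <- bgc_distance_matrix(clusters, weights)
  grid <- sort(grid)
  co <- function(cutoff) {
    fam <- assign_families(clusters, pairs = pairs, cutoff = cutoff,
                           config = config)
    f <- fam$family_id[match(reference_pair, fam$cluster_id)]
    f[1] == f[2]
  }
  for (i in seq_along(grid)) {
    if (co(grid[i])) {
      if (i == length(grid) || co(grid[i + 1])) return(grid[i])
    }
  }
  abort(sprintf("reference pair never co-clustered on grid (max %.2f)",
                max(grid)))
}

#' Genome-by-family presence-absence matrix
#'
#' A cell is 1 iff the genome has at least one member cluster in the
#' family. Reference clusters do not form genome rows, and families whose
#' only members are references are dropped.
#'
#' @param assignment A `bgc_families` object (or tibble with cluster_id,
#'   genome_id, family_id, is_reference).
#' @return Wide tibble: first column `genome_id`, then one 0/1 column per
#'   family.
#' @export
presence_absence <- function(assignment) {
  df <- as_tibble(assignment) |> filter(!.data$is_reference)
  if (nrow(df) == 0) abort("no non-reference clusters")
  wide <- df |>
    distinct(.data$genome_id, .data$family_id) |>
    mutate(present = 1) |>
    tidyr::pivot_wider(names_from = "family_id", values_from = "present",
                       values_fill = 0)
  wide |> arrange(.data$genome_id)
}
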