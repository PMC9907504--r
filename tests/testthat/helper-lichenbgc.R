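# shared fixture builders (everything generated in code)

# toy cluster: one row with nested genes; domains is a list of character
# vectors (one per gene), seqs a character vector
make_cluster <- function(id, domains, seqs, class = "PKSI", genome = "g1",
                         is_reference = FALSE, compound = NA_character_,
                         roles = NULL) {
  stopifnot(length(domains) == length(seqs))
  tibble::tibble(
    cluster_id = id, genome_id = genome, class = class,
    is_reference = is_reference, compound = compound,
    genes = list(tibble::tibble(
      gene_id = paste0(id, "_g", seq_along(seqs)),
      order_index = seq_along(seqs),
      strand = "+",
      role_annotation = roles %||% rep(NA_character_, length(seqs)),
      domains = domains,
      sequence = seqs
    ))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# reverse a cluster (strand flip): gene order reversed, per-gene domain
# order kept (protein N->C order is strand-independent)
reverse_cluster <- function(cl) {
  g <- cl$genes[[1]]
  g <- g[rev(seq_len(nrow(g))), ]
  g$order_index <- seq_len(nrow(g))
  g$strand <- ifelse(g$strand == "+", "-", "+")
  cl$genes <- list(g)
  cl
}

# deterministic random amino-acid string
raa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, TRUE), collapse = "")
}

# the five variant fixtures of the conserved four-gene anthraquinone
# architecture (ABC-transporter, MbL-TE, NR-PKS, EthD) plus its named
# exceptions
aq_variant_fixtures <- function() {
  pks <- c("SAT", "KS", "AT", "PT", "ACP")
  list(
    COMPLETE = make_cluster(
      "fx_complete",
      list("ABC_transporter", "MBL_TE", pks, "EthD"),
      c(raa(40, 1), raa(40, 2), raa(60, 3), raa(30, 4))),
    MISSING_ETHD = make_cluster(          # Seirophora villosa pattern
      "fx_no_ethd",
      list("ABC_transporter", "MBL_TE", pks),
      c(raa(40, 5), raa(40, 6), raa(60, 7))),
    MISSING_ABC = make_cluster(           # Xanthoria sp. 1 pattern
      "fx_no_abc",
      list("MBL_TE", pks, "EthD"),
      c(raa(40, 8), raa(60, 9), raa(30, 10))),
    PKS_ONLY = make_cluster(              # Caloplaca aegaea pattern
      "fx_pks_only",
      list(pks),
      raa(60, 11)),
    ETHD_IN_PKS = make_cluster(           # Usnochroma carphinea pattern
      "fx_ethd_in_pks",
      list("ABC_transporter", "MBL_TE", c(pks, "EthD")),
      c(raa(40, 12), raa(40, 13), raa(60, 14)))
  )
}

# independently coded brute-force multiple-site Sorensen partition
# (Baselga formulas written as explicit double loops, no shared code with
# the implementation)
brute_beta_multisite <- function(m) {
  n <- nrow(m)
  sum_min <- 0; sum_max <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      b_ij <- sum(m[i, ] == 1 & m[j, ] == 0)
      b_ji <- sum(m[j, ] == 1 & m[i, ] == 0)
      sum_min <- sum_min + min(b_ij, b_ji)
      sum_max <- sum_max + max(b_ij, b_ji)
    }
  }
  s_total <- sum(apply(m, 2, max))
  core <- sum(rowSums(m)) - s_total
  sim <- sum_min / (core + sum_min)
  sor <- (sum_min + sum_max) / (2 * core + sum_min + sum_max)
  c(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim)
}

# binary matrix with no all-zero rows
random_pa <- function(n_sites, n_items, p = 0.4) {
  m <- matrix(rbinom(n_sites * n_items, 1, p), n_sites, n_items)
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  rownames(m) <- sprintf("s%02d", seq_len(n_sites))
  m
}

# mycobiont F1 / tail recall of a binning result against simulator truth
binning_scores <- function(res, truth) {
  myco <- truth$contig_id[truth$role %in% c("mycobiont_core",
                                            "mycobiont_at_tail")]
  got <- res$retained$contig_id
  tp <- length(intersect(got, myco))
  prec <- tp / length(got)
  rec <- tp / length(myco)
  tail_ids <- truth$contig_id[truth$role == "mycobiont_at_tail"]
  c(f1 = 2 * prec * rec / (prec + rec),
    precision = prec, recall = rec,
    tail_recall = if (length(tail_ids)) {
      length(intersect(got, tail_ids)) / length(tail_ids)
    } else NA_real_)
}
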