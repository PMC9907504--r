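#' Default role lexicon for the anthraquinone architecture screen
#'
#' Maps domain labels and role annotations to the four conserved roles of
#' Teloschistales anthraquinone clusters: the ABC-transporter efflux pump,
#' the standalone metallo-beta-lactamase-type thioesterase (MbL-TE), the
#' TE-less non-reducing PKS, and the EthD-domain gene. Labels not listed
#' map to OTHER; a gene qualifies as NR_PKS when it carries both KS and AT
#' domains (so degraded annotations still screen).
#'
#' @return Tibble: label, role.
#' @export
default_role_lexicon <- function() {
  tibble(
    label = c("ABC_transporter", "ABC", "abc_transporter",
              "MBL_TE", "MbL-TE", "metallo-beta-lactamase_TE",
              "EthD", "ETHD", "EthylD"),
    role = c(rep("ABC_TRANSPORTER", 3), rep("MBL_TE", 3), rep("ETHD", 3))
  )
}

#' Reference compounds indicating anthraquinone families
#'
#' Anthraquinones and structurally related polyketides with experimentally
#' characterized reference clusters; endocrocin and clavorubin are listed
#' separately although they share one reference cluster.
#'
#' @return Character vector.
#' @export
default_aq_compounds <- function() {
  c("emodin", "asperthecin", "endocrocin", "clavorubin", "alternariol",
    "TAN-1612")
}

PKS_DOMAINS <- c("SAT", "KS", "AT", "PT", "ACP", "TE")

lookup_role <- function(labels, lexicon) {
  roles <- lexicon$role[match(labels, lexicon$label)]
  roles[is.na(roles)] <- "OTHER"
  roles
}

# role of one gene: lexicon match on domains + annotation; NR_PKS on KS+AT
gene_role <- function(domains, role_annotation, lexicon) {
  if (all(c("KS", "AT") %in% domains)) return("NR_PKS")
  cand <- lookup_role(c(domains, role_annotation), lexicon)
  hit <- setdiff(unique(cand), "OTHER")
  if (length(hit)) hit[1] else "OTHER"
}

#' Check the PKS domain architecture of one gene
#'
#' `pks_domain_order_ok` is TRUE when SAT, KS, AT, ACP occur as an
#' order-preserving subsequence of the gene's domains (other domains may
#' intervene; the PT domain is optional since it often evades annotation).
#' `pks_te_less` flags the absence of a TE domain (anthraquinone PKSs
#' release via a standalone MbL-TE instead). `ethd_in_pks` flags an
#' EthD-mapped domain inside the gene.
#'
#' @param domains Character vector of the gene's ordered domain labels.
#' @param lexicon Role lexicon ([default_role_lexicon()]).
#' @return One-row tibble: pks_domain_order_ok, pks_te_less, ethd_in_pks.
#' @export
check_pks_domain_order <- function(domains, lexicon = default_role_lexicon()) {
  want <- c("SAT", "KS", "AT", "ACP")
  pos <- 1L
  for (d in domains) {
    if (pos <= length(want) && d == want[pos]) pos <- pos + 1L
  }
  tibble(
    pks_domain_order_ok = pos > length(want),
    pks_te_less = !"TE" %in% domains,
    ethd_in_pks = any(lookup_role(domains, lexicon) == "ETHD")
  )
}

#' Classify one cluster against the four-gene anthraquinone architecture
#'
#' Assigns each gene a role via the lexicon (NR_PKS on KS+AT
#' co-occurrence), then applies the variant decision table:
#' all four roles present with gene order ABC, MbL-TE, PKS, EthD (or its
#' reversal; intervening genes tolerated) -> COMPLETE; PKS + ABC + MbL-TE
#' without an EthD gene -> MISSING_ETHD, or ETHD_IN_PKS when the EthD
#' domain sits inside the PKS gene; PKS + MbL-TE + EthD without ABC ->
#' MISSING_ABC; PKS alone of the four -> PKS_ONLY; no PKS ->
#' NOT_CANDIDATE; anything else -> OTHER_PARTIAL.
#'
#' @param cluster One-row clusters tibble (nested `genes`) or a genes
#'   tibble.
#' @param lexicon Role lexicon.
#' @return One-row tibble: cluster_id, genome_id, roles_present,
#'   pks_domain_order_ok, pks_te_less, ethd_in_pks, order_matched,
#'   variant, extra_genes.
#' @export
classify_architecture <- function(cluster, lexicon = default_role_lexicon()) {
  genes <- cluster_genes(cluster)
  if (nrow(genes) == 0) abort("empty cluster")
  cid <- if (is.data.frame(cluster) && "cluster_id" %in% names(cluster)) {
    cluster$cluster_id[1]
  } else NA_character_
  gid <- if (is.data.frame(cluster) && "genome_id" %in% names(cluster)) {
    cluster$genome_id[1]
  } else NA_character_
  annot <- if ("role_annotation" %in% names(genes)) genes$role_annotation
           else rep(NA_character_, nrow(genes))
  roles <- vapply(seq_len(nrow(genes)), function(i) {
    gene_role(genes$domains[[i]], annot[i], lexicon)
  }, "")
  pks_idx <- which(roles == "NR_PKS")
  pks_flags <- if (length(pks_idx)) {
    check_pks_domain_order(genes$domains[[pks_idx[1]]], lexicon)
  } else {
    tibble(pks_domain_order_ok = FALSE, pks_te_less = FALSE,
           ethd_in_pks = FALSE)
  }
  present <- intersect(c("ABC_TRANSPORTER", "MBL_TE", "NR_PKS", "ETHD"),
                       unique(roles))
  core_order <- roles[roles %in% c("ABC_TRANSPORTER", "MBL_TE", "NR_PKS",
                                   "ETHD")]
  canonical <- c("ABC_TRANSPORTER", "MBL_TE", "NR_PKS", "ETHD")
  subseq_match <- function(x, ref) {
    # x restricted to the four roles must follow ref's relative order
    identical(x, ref[ref %in% x])
  }
  order_matched <- subseq_match(core_order, canonical) ||
    subseq_match(core_order, rev(canonical))
  has <- function(r) r %in% present
  variant <-
    if (!has("NR_PKS")) "NOT_CANDIDATE"
    else if (all(canonical %in% present) && order_matched) "COMPLETE"
    else if (has("ABC_TRANSPORTER") && has("MBL_TE") && !has("ETHD")) {
      if (pks_flags$ethd_in_pks) "ETHD_IN_PKS" else "MISSING_ETHD"
    }
    else if (has("MBL_TE") && has("ETHD") && !has("ABC_TRANSPORTER")) {
      "MISSING_ABC"
    }
    else if (identical(present, "NR_PKS")) "PKS_ONLY"
    else "OTHER_PARTIAL"
  tibble(
    cluster_id = cid, genome_id = gid,
    roles_present = list(present),
    pks_domain_order_ok = pks_flags$pks_domain_order_ok,
    pks_te_less = pks_flags$pks_te_less,
    ethd_in_pks = pks_flags$ethd_in_pks,
    order_matched = order_matched,
    variant = variant,
    extra_genes = list(genes$gene_id[roles == "OTHER"] %||% character())
  )
}

#' @rdname classify_architecture
#' @param clusters Clusters tibble (one report row per cluster).
#' @export
classify_architectures <- function(clusters,
                                   lexicon = default_role_lexicon()) {
  bind_rows(lapply(seq_len(nrow(clusters)), function(i) {
    classify_architecture(clusters[i, ], lexicon)
  }))
}

#' Flag families anchored by anthraquinone reference clusters
#'
#' A family is flagged iff it contains at least one reference cluster whose
#' compound is in `compound_set`; all member clusters of flagged families
#' are returned as anthraquinone candidates.
#'
#' @param assignment A `bgc_families` object.
#' @param compound_set Compounds of interest ([default_aq_compounds()]).
#' @return List: `families` (flagged ids), `candidates` (assignment rows
#'   in flagged families).
#' @export
find_reference_families <- function(assignment,
                                    compound_set = default_aq_compounds()) {
  df <- as_tibble(assignment)
  if (!any(df$is_reference)) abort("assignment contains no reference clusters")
  flagged <- df |>
    filter(.data$is_reference, .data$compound %in% compound_set) |>
    pull("family_id") |>
    unique()
  list(families = flagged,
       candidates = df |> filter(.data$family_id %in% flagged))
}

#' Screen genomes for the four-gene anthraquinone architecture
#'
#' Flags candidate families via reference compounds, classifies every
#' candidate cluster against the architecture template, and summarises
#' per-clade role incidence with exclusivity assertions (a role is
#' exclusive to a clade when it is observed in candidates of that clade
#' and no other).
#'
#' @param assignment A `bgc_families` object.
#' @param clusters The clusters tibble the assignment was built from.
#' @param clade_map Tibble `genome_id`, `clade` covering all genomes.
#' @param lexicon Role lexicon.
#' @param compound_set Reference compounds.
#' @return List of class `aq_screen`: `reports` (per-candidate
#'   classifications), `clade_incidence` (clade x role counts),
#'   `exclusive_roles` (role, clade) and `families` (flagged ids).
#' @export
screen_genomes <- function(assignment, clusters, clade_map,
                           lexicon = default_role_lexicon(),
                           compound_set = default_aq_compounds()) {
  genomes <- unique(as_tibble(assignment) |>
                      filter(!.data$is_reference) |> pull("genome_id"))
  if (!all(genomes %in% clade_map$genome_id)) {
    abort("clade_map must cover all genomes")
  }
  ref <- find_reference_families(assignment, compound_set)
  cand <- ref$candidates |> filter(!.data$is_reference)
  if (nrow(cand) == 0) {
    return(structure(list(reports = tibble(), clade_incidence = tibble(),
                          exclusive_roles = tibble(),
                          families = ref$families),
                     class = "aq_screen"))
  }
  reports <- classify_architectures(
    clusters[match(cand$cluster_id, clusters$cluster_id), , drop = FALSE],
    lexicon)
  reports <- reports |>
    left_join(clade_map, by = "genome_id")
  incidence <- reports |>
    select("clade", "roles_present") |>
    tidyr::unnest_longer(col = "roles_present", values_to = "role") |>
    count(.data$clade, .data$role, name = "n_clusters")
  exclusive <- incidence |>
    group_by(.data$role) |>
    filter(dplyr::n_distinct(.data$clade) == 1) |>
    ungroup() |>
    select("role", "clade")
  structure(list(reports = reports, clade_incidence = incidence,
                 exclusive_roles = exclusive, families = ref$families),
            class = "aq_screen")
}

#' @export
print.aq_screen <- function(x, ...) {
  cat(sprintf("<aq_screen> %d candidate clusters in %d flagged families\n",
              nrow(x$reports), length(x$families)))
  if (nrow(x$reports)) {
    print(table(x$reports$variant))
    if (nrow(x$exclusive_roles)) {
      cat("exclusive roles:\n")
      print(as.data.frame(x$exclusive_roles), row.names = FALSE)
    }
  }
  invisible(x)
}
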