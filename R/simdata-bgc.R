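AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y")

BGC_CLASSES <- c("PKSI", "NRPS", "PKS-NRP Hybrid", "PKS other", "Terpene",
                 "Others")

rand_aa <- function(len) paste(sample(AA_ALPHABET, len, TRUE), collapse = "")

#' Define a BGC family archetype
#'
#' An archetype is the ancestral form of a gene-cluster family: an ordered
#' set of genes, each with an ordered domain list and a representative
#' protein sequence. Genome-specific instances are derived from it by gene
#' loss, domain shuffling and residue substitution
#' ([simulate_bgc_panel()]). Reference archetypes (`is_reference = TRUE`)
#' emulate database clusters with experimentally known compounds and are
#' emitted unmutated.
#'
#' @param family_id Family label (truth label for derived instances).
#' @param class BGC class, one of PKSI, NRPS, PKS-NRP Hybrid, PKS other, Terpene, Others.
#' @param genes Tibble with columns `role` (character), `domains` (list of
#'   character vectors) and `sequence` (character).
#' @param is_reference Reference (database) cluster flag.
#' @param compound Optional compound annotation for references.
#' @param clades Optional character vector; if given, only genomes in these
#'   clades carry the archetype.
#' @return A one-row tibble (nested `genes`, `clades` list-columns).
#' @export
archetype_spec <- function(family_id, class, genes, is_reference = FALSE,
                           compound = NA_character_, clades = NULL) {
  class <- match.arg(class, BGC_CLASSES)
  stopifnot(is.data.frame(genes), nrow(genes) >= 1,
            all(c("role", "domains", "sequence") %in% names(genes)))
  tibble(family_id = family_id, class = class,
         genes = list(as_tibble(genes)),
         is_reference = is_reference, compound = compound,
         clades = list(clades))
}

#' Random archetype panel
#'
#' Generates `n` family archetypes with distinct domain repertoires drawn
#' from a shared lexicon, 3-6 genes of 1-3 domains each and random protein
#' sequences, mimicking the heterogeneity of a real cluster inventory.
#'
#' @param n Number of families.
#' @param seed Integer seed.
#' @param classes Classes to sample from.
#' @param seq_length Protein sequence length per gene.
#' @return Tibble of archetypes (one row per family).
#' @export
random_archetypes <- function(n = 20, seed = 1L,
                              classes = c("PKSI", "NRPS", "Terpene"),
                              seq_length = 60) {
  set.seed(as.integer(seed))
  lexicon <- sprintf("DOM%02d", 1:40)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    n_genes <- sample(3:6, 1)
    pool <- sample(lexicon, 8)
    genes <- tibble(
      role = sprintf("orf%d", seq_len(n_genes)),
      domains = lapply(seq_len(n_genes),
                       function(j) sample(pool, sample(1:3, 1), TRUE)),
      sequence = vapply(seq_len(n_genes), function(j) rand_aa(seq_length), "")
    )
    out[[i]] <- archetype_spec(sprintf("FAM%02d", i),
                               sample(classes, 1), genes)
  }
  bind_rows(out)
}

# four-gene anthraquinone architecture: ABC-transporter, MbL-TE, TE-less
# non-reducing PKS (SAT-KS-AT-PT-ACP), EthD
aq_genes <- function(seq_length = 60, with_abc = TRUE, with_ethd = TRUE,
                     with_mbl = TRUE, ethd_in_pks = FALSE) {
  pks_domains <- c("SAT", "KS", "AT", "PT", "ACP")
  if (ethd_in_pks) pks_domains <- c(pks_domains, "EthD")
  g <- list()
  if (with_abc) g <- c(g, list(tibble(role = "ABC_transporter",
                                      domains = list("ABC_transporter"),
                                      sequence = rand_aa(seq_length))))
  if (with_mbl) g <- c(g, list(tibble(role = "MBL_TE",
                                      domains = list("MBL_TE"),
                                      sequence = rand_aa(seq_length))))
  g <- c(g, list(tibble(role = "PKS", domains = list(pks_domains),
                        sequence = rand_aa(seq_length))))
  if (with_ethd && !ethd_in_pks) {
    g <- c(g, list(tibble(role = "EthD", domains = list("EthD"),
                          sequence = rand_aa(seq_length))))
  }
  bind_rows(g)
}

#' Anthraquinone-like archetypes with MIBiG-style references
#'
#' Builds one lineage-restricted anthraquinone archetype carrying the
#' conserved four-gene architecture (ABC-transporter, MbL-TE, TE-less
#' NR-PKS, EthD) plus reference archetypes annotated with anthraquinone (or
#' structurally related) compounds, including the highly similar
#' asperthecin / TAN-1612 pair used for cutoff selection, and one unrelated
#' melanin reference as a negative control.
#'
#' @param seed Integer seed.
#' @param aq_clades Clades whose genomes carry the anthraquinone archetype.
#' @return Tibble of archetypes.
#' @export
anthraquinone_archetypes <- function(seed = 1L, aq_clades = "Teloschistales") {
  set.seed(as.integer(seed))
  aq_g <- aq_genes()
  aq <- archetype_spec("AQ", "PKSI", aq_g, clades = aq_clades)
  diverge <- function(genes, p) {
    genes$sequence <- vapply(genes$sequence, substitute_residues, p = p, "",
                             USE.NAMES = FALSE)
    genes
  }
  # references are homologous to the lichen archetype (diverged copies
  # without the lineage-specific ABC-transporter), so lichen instances
  # co-cluster with them below a moderate cutoff; TAN-1612 is a close
  # relative of asperthecin, the pair used for cutoff selection
  asper_genes <- diverge(aq_g[aq_g$role != "ABC_transporter", ], 0.12)
  tan_genes <- diverge(asper_genes, 0.10)
  refs <- bind_rows(
    archetype_spec("REF_asperthecin", "PKSI", asper_genes,
                   is_reference = TRUE, compound = "asperthecin"),
    archetype_spec("REF_tan1612", "PKSI", tan_genes,
                   is_reference = TRUE, compound = "TAN-1612"),
    archetype_spec("REF_emodin", "PKSI",
                   diverge(aq_g[aq_g$role != "ABC_transporter", ], 0.15),
                   is_reference = TRUE, compound = "emodin"),
    archetype_spec("REF_melanin", "PKSI",
                   tibble(role = c("PKS", "laccase"),
                          domains = list(c("SAT", "KS", "AT", "ACP", "TE"),
                                         "laccase"),
                          sequence = c(rand_aa(60), rand_aa(60))),
                   is_reference = TRUE, compound = "melanin")
  )
  bind_rows(aq, refs)
}

substitute_residues <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < p
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(a) sample(setdiff(AA_ALPHABET, a), 1), "")
  }
  paste(ch, collapse = "")
}

swap_adjacent_domains <- function(domains, p) {
  n <- length(domains)
  if (n < 2) return(domains)
  for (i in seq_len(n - 1)) {
    if (runif(1) < p) domains[c(i, i + 1)] <- domains[c(i + 1, i)]
  }
  domains
}

#' Evolution parameters for BGC panels and presence-absence matrices
#'
#' @param gene_loss_prob Per-gene loss probability when deriving an instance
#'   from its archetype.
#' @param domain_swap_prob Per-domain probability of swapping position with
#'   its right neighbour (domain shuffling).
#' @param residue_sub_prob Per-residue substitution probability.
#' @param gain_rate,loss_rate Per-unit-branch-length gain/loss rates of the
#'   two-state presence-absence process along a tree.
#' @param n_tips Number of tree tips (>= 3).
#' @param seed Integer seed.
#' @return A validated list of parameters.
#' @export
evolution_params <- function(gene_loss_prob = 0.1, domain_swap_prob = 0.1,
                             residue_sub_prob = 0.1, gain_rate = 1,
                             loss_rate = 1, n_tips = 10, seed = 1L) {
  assert_prob(gene_loss_prob, "gene_loss_prob")
  assert_prob(domain_swap_prob, "domain_swap_prob")
  assert_prob(residue_sub_prob, "residue_sub_prob")
  assert_scalar_number(gain_rate, "gain_rate", 0)
  assert_scalar_number(loss_rate, "loss_rate", 0)
  if (n_tips < 3) abort("n_tips must be >= 3")
  list(gene_loss_prob = gene_loss_prob, domain_swap_prob = domain_swap_prob,
       residue_sub_prob = residue_sub_prob, gain_rate = gain_rate,
       loss_rate = loss_rate, n_tips = as.integer(n_tips),
       seed = as.integer(seed))
}

#' Simulate a panel of gene clusters from family archetypes
#'
#' Each genome carries, for every archetype whose clade restriction it
#' satisfies, a derived instance: genes are dropped with
#' `params$gene_loss_prob`, domains shuffled with `params$domain_swap_prob`,
#' and residues substituted with `params$residue_sub_prob`. Reference
#' archetypes are emitted once, unmutated, with their compound annotation.
#' Instances that lose every gene are suppressed and recorded in the truth
#' table with status `"lost"`.
#'
#' @param archetypes Tibble of archetypes ([archetype_spec()]).
#' @param genome_clade_map Tibble with columns `genome_id`, `clade`.
#' @param params [evolution_params()].
#' @param seed Integer seed (defaults to `params$seed`).
#' @return List with `clusters` (tibble: cluster_id, genome_id, class,
#'   is_reference, compound, nested `genes`) and `truth` (cluster_id,
#'   genome_id, family_id, status).
#' @export
simulate_bgc_panel <- function(archetypes, genome_clade_map, params,
                               seed = params$seed) {
  if (!is.data.frame(archetypes) || nrow(archetypes) == 0) {
    abort("archetypes must be a non-empty tibble")
  }
  if (!all(c("genome_id", "clade") %in% names(genome_clade_map))) {
    abort("genome_clade_map needs columns genome_id, clade")
  }
  if (anyDuplicated(genome_clade_map$genome_id)) {
    abort("duplicate genome in clade map")
  }
  set.seed(as.integer(seed))
  clusters <- list(); truth <- list()
  for (gi in seq_len(nrow(genome_clade_map))) {
    g <- genome_clade_map$genome_id[gi]
    clade <- genome_clade_map$clade[gi]
    for (ai in seq_len(nrow(archetypes))) {
      a <- archetypes[ai, ]
      if (a$is_reference) next
      restr <- a$clades[[1]]
      if (!is.null(restr) && !clade %in% restr) next
      genes <- a$genes[[1]]
      keep <- runif(nrow(genes)) >= params$gene_loss_prob
      cid <- sprintf("%s__%s", g, a$family_id)
      if (!any(keep)) {
        truth[[length(truth) + 1]] <- tibble(
          cluster_id = NA_character_, genome_id = g,
          family_id = a$family_id, status = "lost")
        next
      }
      genes <- genes[keep, , drop = FALSE]
      genes$domains <- lapply(genes$domains, swap_adjacent_domains,
                              p = params$domain_swap_prob)
      genes$sequence <- vapply(genes$sequence, substitute_residues,
                               p = params$residue_sub_prob, "",
                               USE.NAMES = FALSE)
      clusters[[length(clusters) + 1]] <- tibble(
        cluster_id = cid, genome_id = g, class = a$class,
        is_reference = FALSE, compound = NA_character_,
        genes = list(tibble(
          gene_id = sprintf("%s_g%d", cid, seq_len(nrow(genes))),
          order_index = seq_len(nrow(genes)), strand = "+",
          role_annotation = genes$role, domains = genes$domains,
          sequence = genes$sequence)))
      truth[[length(truth) + 1]] <- tibble(
        cluster_id = cid, genome_id = g, family_id = a$family_id,
        status = "present")
    }
  }
  refs <- archetypes[archetypes$is_reference, , drop = FALSE]
  for (ai in seq_len(nrow(refs))) {
    a <- refs[ai, ]
    genes <- a$genes[[1]]
    cid <- sprintf("MIBiG__%s", a$family_id)
    clusters[[length(clusters) + 1]] <- tibble(
      cluster_id = cid, genome_id = sprintf("MIBiG_%s", a$family_id),
      class = a$class, is_reference = TRUE, compound = a$compound,
      genes = list(tibble(
        gene_id = sprintf("%s_g%d", cid, seq_len(nrow(genes))),
        order_index = seq_len(nrow(genes)), strand = "+",
        role_annotation = genes$role, domains = genes$domains,
        sequence = genes$sequence)))
    truth[[length(truth) + 1]] <- tibble(
      cluster_id = cid, genome_id = sprintf("MIBiG_%s", a$family_id),
      family_id = a$family_id, status = "reference")
  }
  list(clusters = bind_rows(clusters), truth = bind_rows(truth))
}
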