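#' Binning configuration
#'
#' Thresholds of the mycobiont-isolation pipeline. The tail-merge thresholds
#' (`coverage_ratio_tol`, `gc_slack`, `contaminant_bp_frac`) automate the
#' manual merging of low-GC "tail" bins into the anchor bin; they are
#' engineering choices surfaced in the run report, not literature values.
#'
#' @param fragment_size Contigs are cut into windows of this many bases
#'   before clustering (default 10000).
#' @param max_bins Model-selection ceiling on the number of mixture
#'   components (default 8).
#' @param coverage_ratio_tol Maximum fold-difference between a bin's median
#'   coverage and the anchor's for merging (default 2.0).
#' @param gc_slack A bin merges only if its median GC is at most the
#'   anchor's plus this slack (default 0.02); lower-GC tails always satisfy
#'   it.
#' @param contaminant_bp_frac Maximum fraction of bin bases carrying a
#'   taxon call other than the target taxon or NO_HIT (default 0.2).
#' @param seed Integer seed for the mixture fit.
#' @param pc_var Fraction of variance the PCA projection must retain
#'   (default 0.9).
#' @param max_pcs Cap on retained principal components (default 20).
#' @return A list of class `binning_config`.
#' @export
binning_config <- function(fragment_size = 10000, max_bins = 8,
                           coverage_ratio_tol = 2.0, gc_slack = 0.02,
                           contaminant_bp_frac = 0.2, seed = 1L,
                           pc_var = 0.9, max_pcs = 20) {
  assert_scalar_number(fragment_size, "fragment_size", 1000)
  assert_scalar_number(coverage_ratio_tol, "coverage_ratio_tol", 1)
  assert_prob(gc_slack, "gc_slack")
  assert_prob(contaminant_bp_frac, "contaminant_bp_frac")
  structure(list(fragment_size = fragment_size, max_bins = as.integer(max_bins),
                 coverage_ratio_tol = coverage_ratio_tol, gc_slack = gc_slack,
                 contaminant_bp_frac = contaminant_bp_frac,
                 seed = as.integer(seed), pc_var = pc_var,
                 max_pcs = as.integer(max_pcs)),
            class = "binning_config")
}

#' Cluster contig fragments by composition and coverage
#'
#' Features per fragment are its canonical tetranucleotide profile plus the
#' parent contig's standardized log10(coverage + 1). The concatenated
#' features are projected by PCA (retaining at least `pc_var` of the
#' variance, capped at `max_pcs` components) and fit with Gaussian mixtures
#' for k = 1..`max_bins`; k is chosen by BIC. Each contig is then assigned
#' to the bin owning the largest summed fragment length (ties to the lower
#' bin id).
#'
#' @param fragments Tibble from [fragment_contigs()].
#' @param coverage Tibble with `contig_id`, `mean_depth`.
#' @param config [binning_config()].
#' @return List with `contig_bins` (contig_id, bin), `fragment_bins`
#'   (fragment_id, contig_id, bin) and `k` (selected number of bins).
#' @export
cluster_fragments <- function(fragments, coverage, config = binning_config()) {
  n <- nrow(fragments)
  if (n < 2) {
    warn("fewer than 2 fragments: assigning a single bin")
    fb <- fragments |> select("fragment_id", "contig_id") |> mutate(bin = 1L)
    return(list(contig_bins = distinct(fb, .data$contig_id) |> mutate(bin = 1L),
                fragment_bins = fb, k = 1L))
  }
  prof <- kmer_profiles(fragments$sequence)
  cov <- coverage$mean_depth[match(fragments$contig_id, coverage$contig_id)]
  logcov <- log10(cov + 1)
  feats <- cbind(prof, logcov = as.numeric(scale(logcov)))
  if (any(!is.finite(feats[, ncol(feats)]))) feats[, ncol(feats)] <- 0
  pc <- prcomp(feats, center = TRUE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k_pc <- min(which(varfrac >= config$pc_var)[1], config$max_pcs, ncol(pc$x))
  k_pc <- max(k_pc, min(3L, ncol(pc$x)))  # keep some composition signal
  scores <- pc$x[, seq_len(k_pc), drop = FALSE]
  set.seed(config$seed)
  models <- if (k_pc == 1) c("E", "V") else c("EII", "VII", "EEI", "VVI",
                                              "VVV")
  fit <- Mclust(scores, G = seq_len(min(config$max_bins, n)),
                modelNames = models, verbose = FALSE)
  if (is.null(fit)) abort("mixture model failed to fit")
  fb <- fragments |>
    select("fragment_id", "contig_id", "start", "end") |>
    mutate(bin = as.integer(fit$classification),
           frag_len = .data$end - .data$start)
  contig_bins <- fb |>
    group_by(.data$contig_id, .data$bin) |>
    summarise(bp = sum(.data$frag_len), .groups = "drop") |>
    group_by(.data$contig_id) |>
    arrange(dplyr::desc(.data$bp), .data$bin, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("contig_id", "bin")
  list(contig_bins = contig_bins,
       fragment_bins = fb |> select("fragment_id", "contig_id", "bin"),
       k = fit$G)
}

# per-bin summaries used by anchor selection and tail merging
summarise_bins <- function(contig_bins, features, calls,
                           target_taxon = "Ascomycota") {
  df <- contig_bins |>
    left_join(features |> select("contig_id", "length", "gc", "coverage"),
              by = "contig_id") |>
    left_join(calls, by = "contig_id") |>
    mutate(taxon_call = dplyr::coalesce(.data$taxon_call, "NO_HIT"))
  df |>
    group_by(.data$bin) |>
    summarise(
      n_contigs = n(),
      total_bp = sum(.data$length),
      median_gc = median(.data$gc),
      median_coverage = median(.data$coverage),
      target_bp = sum(.data$length[.data$taxon_call == target_taxon]),
      contaminant_bp_frac = sum(.data$length[!.data$taxon_call %in%
                                               c(target_taxon, "NO_HIT")]) /
        sum(.data$length),
      .groups = "drop"
    )
}

#' Select the anchor bin
#'
#' The anchor is the bin holding the most bases of contigs called as the
#' target taxon (the large ~50% GC mycobiont bin); ties break by larger
#' total bp, then lower bin id.
#'
#' @param bin_summary Output of the internal bin summariser (exposed via
#'   [run_binning()]'s report) or any tibble with `bin`, `target_bp`,
#'   `total_bp`.
#' @return The anchor bin id (integer).
#' @export
select_anchor_bin <- function(bin_summary) {
  if (nrow(bin_summary) == 0) abort("no bins")
  if (all(bin_summary$target_bp == 0)) abort("no anchor evidence")
  bin_summary |>
    arrange(dplyr::desc(.data$target_bp), dplyr::desc(.data$total_bp),
            .data$bin) |>
    slice(1) |>
    pull("bin")
}

#' Merge tail bins into the anchor
#'
#' A non-anchor bin merges into the anchor iff (i) its median coverage is
#' within `coverage_ratio_tol`-fold of the anchor's, (ii) its median GC does
#' not exceed the anchor's by more than `gc_slack` (AT-rich tails always
#' pass), and (iii) at most `contaminant_bp_frac` of its bases carry a taxon
#' call other than the target or NO_HIT. Bins are evaluated independently
#' against the anchor (no chaining).
#'
#' @param bin_summary Per-bin summary tibble (see [select_anchor_bin()]).
#' @param anchor Anchor bin id.
#' @param config [binning_config()].
#' @return Tibble of merge decisions: bin, cov_ratio_ok, gc_ok,
#'   contaminant_ok, merged.
#' @export
merge_tail_bins <- function(bin_summary, anchor, config = binning_config()) {
  a <- bin_summary[bin_summary$bin == anchor, ]
  if (nrow(a) != 1) abort("anchor bin not found in summary")
  bin_summary |>
    mutate(
      cov_log2_ratio = log2(.data$median_coverage / a$median_coverage),
      cov_ratio_ok = abs(.data$cov_log2_ratio) <=
        log2(config$coverage_ratio_tol),
      gc_ok = .data$median_gc <= a$median_gc + config$gc_slack,
      contaminant_ok = .data$contaminant_bp_frac <= config$contaminant_bp_frac,
      merged = .data$bin == anchor |
        (.data$cov_ratio_ok & .data$gc_ok & .data$contaminant_ok)
    ) |>
    select("bin", "cov_log2_ratio", "cov_ratio_ok", "gc_ok",
           "contaminant_ok", "merged")
}

#' Remove contaminant contigs from the merged mycobiont set
#'
#' Retains a contig iff its taxon call is the target taxon or NO_HIT.
#'
#' @param contig_ids Character vector of merged-set contig ids.
#' @param calls Tibble `contig_id`, `taxon_call`.
#' @param target_taxon Target taxon (default "Ascomycota").
#' @return Character vector of retained contig ids (a subset of the input).
#' @export
filter_contaminants <- function(contig_ids, calls,
                                target_taxon = "Ascomycota") {
  if (length(contig_ids) == 0) abort("merged set is empty")
  call <- calls$taxon_call[match(contig_ids, calls$contig_id)]
  call[is.na(call)] <- "NO_HIT"
  keep <- contig_ids[call %in% c(target_taxon, "NO_HIT")]
  if (length(keep) == 0) abort("mycobiont set empty after filtering")
  keep
}

#' Isolate the mycobiont contig set from a metagenome
#'
#' Runs the full pipeline: feature computation, taxonomy calls,
#' 10-kbp fragmentation, composition/coverage mixture clustering, anchor-bin
#' selection by target-taxon bases, tail-bin merging, and the final
#' contaminant filter (keep target-taxon and no-hit contigs only).
#'
#' @param contigs Tibble with `contig_id`, `sequence`.
#' @param coverage Tibble with `contig_id`, `mean_depth`.
#' @param hits Taxonomy hit tibble (see [assign_taxonomy()]).
#' @param config [binning_config()].
#' @param tax_config [taxonomy_config()].
#' @return An object of class `binning_result`: list with `retained`
#'   (tibble of contig ids), and `report` (bin summary with merge
#'   decisions, anchor id, selected k, removed contaminant ids).
#' @export
run_binning <- function(contigs, coverage, hits,
                        config = binning_config(),
                        tax_config = taxonomy_config()) {
  features <- compute_contig_features(contigs, coverage)
  calls <- assign_taxonomy(hits, contig_ids = contigs$contig_id,
                           config = tax_config)
  fragments <- fragment_contigs(contigs, config$fragment_size)
  cl <- cluster_fragments(fragments, coverage, config)
  bins <- summarise_bins(cl$contig_bins, features, calls,
                         tax_config$target_taxon)
  anchor <- select_anchor_bin(bins)
  merges <- merge_tail_bins(bins, anchor, config)
  merged_bins <- merges$bin[merges$merged]
  merged_ids <- cl$contig_bins$contig_id[cl$contig_bins$bin %in% merged_bins]
  retained <- filter_contaminants(merged_ids, calls, tax_config$target_taxon)
  structure(list(
    retained = tibble(contig_id = retained),
    report = list(
      k = cl$k,
      anchor = anchor,
      bins = left_join(bins, merges, by = "bin"),
      contig_bins = cl$contig_bins,
      taxon_calls = calls,
      removed = setdiff(merged_ids, retained)
    )
  ), class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  cat("<binning_result>\n")
  cat(sprintf("  bins: %d (anchor: bin %d)\n", nrow(x$report$bins),
              x$report$anchor))
  cat(sprintf("  merged bins: %s\n",
              paste(x$report$bins$bin[x$report$bins$merged], collapse = ", ")))
  cat(sprintf("  retained contigs: %d (removed as contaminants: %d)\n",
              nrow(x$retained), length(x$report$removed)))
  invisible(x)
}
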