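# canonical tetranucleotide machinery -----------------------------------------

# n x 136 normalized canonical 4-mer frequencies with +1 pseudocount; each
# k-mer is folded onto the lexicographic minimum of itself and its reverse
# complement (136 = (256 + 16) / 2 classes)
kmer_profiles <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(x, width = 4)
  kmers <- colnames(counts)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  folded <- t(rowsum(t(counts), group = factor(canon, levels = sort(unique(canon))))) + 1
  folded / rowSums(folded)
}

gc_fraction <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  gc <- Biostrings::letterFrequency(x, letters = c("G", "C"))
  acgt <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  rowSums(gc) / rowSums(acgt)
}

#' Per-contig sequence features
#'
#' Computes GC fraction ((G+C)/(A+C+G+T), ambiguity codes ignored) and the
#' normalized canonical tetranucleotide profile (136 k-mers, +1 pseudocount)
#' for every contig, joined with its read coverage.
#'
#' @param contigs Tibble with `contig_id` and `sequence` (e.g. from
#'   [read_contig_fasta()] or [simulate_metagenome()]).
#' @param coverage Tibble with `contig_id` and `mean_depth`; every contig
#'   must have a row.
#' @return Tibble: contig_id, length, gc, coverage, kmer_profile
#'   (list-column of named numeric vectors summing to 1).
#' @export
compute_contig_features <- function(contigs, coverage) {
  if (any(nchar(contigs$sequence) == 0)) abort("empty sequence")
  missing <- setdiff(contigs$contig_id, coverage$contig_id)
  if (length(missing)) {
    abort(paste0("contigs without coverage row: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  prof <- kmer_profiles(contigs$sequence)
  tibble(
    contig_id = contigs$contig_id,
    length = nchar(contigs$sequence),
    gc = gc_fraction(contigs$sequence),
    kmer_profile = lapply(seq_len(nrow(prof)), function(i) prof[i, ])
  ) |>
    left_join(coverage |> select("contig_id", coverage = "mean_depth"),
              by = "contig_id")
}

#' Taxonomy aggregation configuration
#'
#' @param evalue_cutoff Hits with e-value above this are discarded
#'   (default 1e-25).
#' @param rank Taxonomic rank of the calls (informational; default
#'   "phylum").
#' @param target_taxon Taxon whose contigs anchor the mycobiont bin
#'   (default "Ascomycota").
#' @return A list of class `taxonomy_config`.
#' @export
taxonomy_config <- function(evalue_cutoff = 1e-25, rank = "phylum",
                            target_taxon = "Ascomycota") {
  if (evalue_cutoff <= 0) abort("evalue_cutoff must be > 0")
  structure(list(evalue_cutoff = evalue_cutoff, rank = rank,
                 target_taxon = target_taxon), class = "taxonomy_config")
}

#' Best-sum taxonomy calls per contig
#'
#' Discards hit rows with e-value above the cutoff, sums bitscores per taxon
#' across both hit tiers (protein and nucleotide), and calls the taxon with
#' the largest summed bitscore; ties break lexicographically. Contigs with
#' no surviving row are called `"NO_HIT"`.
#'
#' @param hits Tibble with `contig_id`, `taxon`, `bitscore`, `evalue` (and
#'   optionally `tier`).
#' @param contig_ids Optional character vector of all contigs; those without
#'   hits are emitted as NO_HIT rows.
#' @param config [taxonomy_config()].
#' @return Tibble: contig_id, taxon_call.
#' @export
assign_taxonomy <- function(hits, contig_ids = NULL,
                            config = taxonomy_config()) {
  if (nrow(hits) > 0 && any(hits$bitscore < 0)) abort("negative bitscore")
  calls <- hits |>
    filter(.data$evalue <= config$evalue_cutoff) |>
    group_by(.data$contig_id, .data$taxon) |>
    summarise(score = sum(.data$bitscore), .groups = "drop") |>
    group_by(.data$contig_id) |>
    arrange(dplyr::desc(.data$score), .data$taxon, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("contig_id", taxon_call = "taxon")
  if (!is.null(contig_ids)) {
    calls <- tibble(contig_id = contig_ids) |>
      left_join(calls, by = "contig_id") |>
      mutate(taxon_call = dplyr::coalesce(.data$taxon_call, "NO_HIT"))
  }
  calls
}

#' Cut contigs into fixed-size fragments
#'
#' Consecutive non-overlapping windows in 0-based half-open coordinates. A
#' terminal remainder shorter than `fragment_size` is appended to the
#' preceding fragment (so no fragment is shorter than `fragment_size` except
#' for contigs that are themselves shorter, which form a single fragment).
#'
#' @param contigs Tibble with `contig_id` and `sequence`.
#' @param fragment_size Window size in bases (default 10000).
#' @return Tibble: fragment_id, contig_id, start, end, sequence.
#' @export
fragment_contigs <- function(contigs, fragment_size = 10000) {
  assert_scalar_number(fragment_size, "fragment_size", 1000)
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    len <- nchar(contigs$sequence[i])
    n_full <- len %/% fragment_size
    if (n_full <= 1) {
      starts <- 0; ends <- len
    } else {
      starts <- (seq_len(n_full) - 1) * fragment_size
      ends <- c(starts[-1], len)  # remainder appended to final window
    }
    tibble(contig_id = contigs$contig_id[i],
           start = starts, end = ends,
           sequence = substring(contigs$sequence[i], starts + 1, ends))
  })
  bind_rows(out) |>
    mutate(fragment_id = sprintf("%s:%d-%d", .data$contig_id, .data$start,
                                 .data$end)) |>
    select("fragment_id", "contig_id", "start", "end", "sequence")
}
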