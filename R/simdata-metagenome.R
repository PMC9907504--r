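#' Describe one organism of a simulated lichen metagenome
#'
#' An organism spec fixes the compositional and coverage distribution from
#' which that organism's contigs are drawn. The `role` separates the fungal
#' symbiont's main genome (`mycobiont_core`), its AT-rich repeat-derived tail
#' (`mycobiont_at_tail`), the photosynthetic partner (`photobiont`) and
#' bacterial community members (`bacterium`).
#'
#' @param name Organism name (unique within a community).
#' @param role One of `"mycobiont_core"`, `"mycobiont_at_tail"`,
#'   `"photobiont"`, `"bacterium"`.
#' @param genome_size Total bases emitted for the organism.
#' @param gc_mean,gc_sd Mean and standard deviation of the per-contig GC
#'   fraction; `gc_mean +/- 3 * gc_sd` must stay inside (0, 1).
#' @param coverage_mean Mean read depth (x). Per-contig depth is lognormal
#'   around this mean with log-scale sd `coverage_sd_log`.
#' @param coverage_sd_log Lognormal sd of per-contig depth (dimensionless).
#' @param taxon_label Phylum-level taxon reported by the simulated hit table.
#' @param label_miss_prob Probability a contig is absent from the taxonomy
#'   table (a "no-hit"), emulating database blind spots such as AT-rich
#'   repeat regions.
#' @param markov_seed Integer fixing the organism's compositional signature
#'   (the order-2 Markov parameters of its sequence model).
#'
#' @return A one-row tibble; bind rows of these to form a community.
#' @seealso [default_community()], [simulate_metagenome()]
#' @export
organism_spec <- function(name, role, genome_size, gc_mean, gc_sd,
                          coverage_mean, coverage_sd_log, taxon_label,
                          label_miss_prob = 0, markov_seed = 1L) {
  role <- match.arg(role, c("mycobiont_core", "mycobiont_at_tail",
                            "photobiont", "bacterium"))
  assert_prob(gc_mean, "gc_mean")
  assert_scalar_number(gc_sd, "gc_sd", 0, 0.5)
  if (gc_mean - 3 * gc_sd <= 0 || gc_mean + 3 * gc_sd >= 1) {
    abort("gc_mean +/- 3*gc_sd must lie inside (0, 1)")
  }
  assert_scalar_number(genome_size, "genome_size", 1)
  assert_scalar_number(coverage_mean, "coverage_mean")
  if (coverage_mean <= 0) abort("coverage_mean must be > 0")
  assert_scalar_number(coverage_sd_log, "coverage_sd_log", 0)
  assert_prob(label_miss_prob, "label_miss_prob")
  tibble(
    name = as.character(name), role = role,
    genome_size = as.numeric(genome_size),
    gc_mean = gc_mean, gc_sd = gc_sd,
    coverage_mean = coverage_mean, coverage_sd_log = coverage_sd_log,
    taxon_label = as.character(taxon_label),
    label_miss_prob = label_miss_prob,
    markov_seed = as.integer(markov_seed)
  )
}

#' Default simulated lichen community
#'
#' The study conditions for the binning stage: a mycobiont whose core forms a
#' ~50% GC cloud at consistent coverage plus an AT-rich tail (20% of
#' mycobiont bases at GC 0.33) whose contigs mostly lack database hits, a
#' green-algal photobiont at higher GC and lower coverage, and two bacteria
#' at distinct GC/coverage combinations.
#'
#' @param scale Multiplier on all genome sizes (1 = full desk-scale
#'   community, ~13 Mbp total). Tests use smaller scales.
#' @param tail_miss_prob No-hit probability of the AT-rich tail (default 0.8).
#' @return A tibble of organism specs.
#' @export
default_community <- function(scale = 1, tail_miss_prob = 0.8) {
  bind_rows(
    organism_spec("mycobiont", "mycobiont_core", 5e6 * scale, 0.50, 0.02,
                  60, 0.15, "Ascomycota", label_miss_prob = 0.10,
                  markov_seed = 101L),
    organism_spec("mycobiont_tail", "mycobiont_at_tail", 1.25e6 * scale, 0.33,
                  0.02, 60, 0.15, "Ascomycota",
                  label_miss_prob = tail_miss_prob, markov_seed = 101L),
    organism_spec("alga", "photobiont", 3e6 * scale, 0.60, 0.02, 15, 0.15,
                  "Chlorophyta", label_miss_prob = 0.10, markov_seed = 202L),
    organism_spec("bact1", "bacterium", 2e6 * scale, 0.45, 0.015, 240, 0.15,
                  "Proteobacteria", label_miss_prob = 0.05,
                  markov_seed = 303L),
    organism_spec("bact2", "bacterium", 2e6 * scale, 0.65, 0.015, 7, 0.15,
                  "Actinobacteria", label_miss_prob = 0.05,
                  markov_seed = 404L)
  )
}

# organism compositional signature: probabilities of G-vs-C and A-vs-T given
# the strong/weak classes of the two preceding bases (4 contexts each)
organism_signature <- function(markov_seed) {
  u <- hash_unit(markov_seed, 8)
  list(p_g = 0.2 + 0.6 * u[1:4], p_a = 0.2 + 0.6 * u[5:8])
}

# one contig sequence: strong/weak states iid Bernoulli(gc) so realized GC is
# exactly targeted in expectation; the letter within each class follows the
# organism's order-2 context signature
sim_sequence <- function(len, gc, sig) {
  sw <- runif(len) < gc
  ctx <- 1L + 2L * c(0L, as.integer(sw[-len])) +
    c(0L, 0L, as.integer(sw[-c(len - 1L, len)]))
  u <- runif(len)
  out <- character(len)
  s <- sw
  out[s] <- ifelse(u[s] < sig$p_g[ctx[s]], "G", "C")
  out[!s] <- ifelse(u[!s] < sig$p_a[ctx[!s]], "A", "T")
  paste(out, collapse = "")
}

# geometric contig lengths with given mean, floored at min, trimmed to total
sim_contig_lengths <- function(total, mean_len, min_len) {
  lens <- numeric(0)
  while (sum(lens) < total) {
    k <- max(8L, ceiling((total - sum(lens)) / mean_len) + 4L)
    lens <- c(lens, min_len + rgeom(k, 1 / max(1, mean_len - min_len)))
    lens <- lens[cumsum(lens) <= total + mean_len]
  }
  keep <- cumsum(lens) < total
  lens <- lens[keep]
  rem <- total - sum(lens)
  if (rem >= min_len) lens <- c(lens, rem) else if (length(lens)) {
    lens[length(lens)] <- lens[length(lens)] + rem
  } else lens <- max(rem, min_len)
  lens
}

#' Simulate a lichen metagenome assembly with known ground truth
#'
#' Emits contigs for every organism in `specs`. Per-contig GC targets are
#' drawn from the organism's GC distribution; sequences follow a per-organism
#' order-2 Markov chain constrained to the target GC, so composition-based
#' binning has signal beyond GC alone. Per-contig depth is lognormal around
#' the organism mean. The taxonomy table reports the organism's phylum with
#' probability `1 - label_miss_prob` (two hit tiers, protein and nucleotide);
#' otherwise the contig is absent from the table (a "no-hit").
#'
#' @param specs Tibble of organism specs ([organism_spec()]); at least one
#'   row must have role `mycobiont_core`.
#' @param contig_mean_length,contig_min_length Geometric contig-length model
#'   (mean, floor), in bases.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with tibbles `contigs` (contig_id, organism, role, length,
#'   gc_target, coverage, sequence), `coverage` (contig_id, mean_depth),
#'   `taxonomy` (contig_id, taxon, rank, bitscore, evalue, tier) and `truth`
#'   (one row per emitted contig).
#' @export
simulate_metagenome <- function(specs, contig_mean_length = 20000,
                                contig_min_length = 1000, seed = 1L) {
  if (!is.data.frame(specs) || nrow(specs) == 0) abort("no organisms")
  if (!any(specs$role == "mycobiont_core")) {
    abort("at least one spec must have role 'mycobiont_core'")
  }
  if (any(specs$gc_mean <= 0 | specs$gc_mean >= 1)) {
    abort("gc_mean must lie inside (0, 1)")
  }
  set.seed(as.integer(seed))
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    sig <- organism_signature(sp$markov_seed)
    lens <- sim_contig_lengths(sp$genome_size, contig_mean_length,
                               contig_min_length)
    gc_t <- pmin(0.99, pmax(0.01, rnorm(length(lens), sp$gc_mean, sp$gc_sd)))
    cov <- rlnorm(length(lens), log(sp$coverage_mean), sp$coverage_sd_log)
    seqs <- vapply(seq_along(lens),
                   function(j) sim_sequence(lens[j], gc_t[j], sig), "")
    out[[i]] <- tibble(
      contig_id = sprintf("%s_c%04d", sp$name, seq_along(lens)),
      organism = sp$name, role = sp$role,
      length = lens, gc_target = gc_t, coverage = cov, sequence = seqs,
      taxon_label = sp$taxon_label, label_miss_prob = sp$label_miss_prob
    )
  }
  contigs <- bind_rows(out)
  hit <- runif(nrow(contigs)) >= contigs$label_miss_prob
  hits <- contigs[hit, c("contig_id", "taxon_label")]
  taxonomy <- bind_rows(
    tibble(contig_id = hits$contig_id, taxon = hits$taxon_label,
           rank = "phylum", bitscore = round(runif(nrow(hits), 100, 300), 1),
           evalue = 10^runif(nrow(hits), -80, -30), tier = "protein"),
    tibble(contig_id = hits$contig_id, taxon = hits$taxon_label,
           rank = "phylum", bitscore = round(runif(nrow(hits), 80, 250), 1),
           evalue = 10^runif(nrow(hits), -60, -26), tier = "nucleotide")
  ) |> arrange(.data$contig_id, .data$tier)
  truth <- contigs |>
    select("contig_id", "organism", "role", gc = "gc_target", "coverage")
  list(
    contigs = contigs |>
      select("contig_id", "organism", "role", "length", "gc_target",
             "coverage", "sequence"),
    coverage = contigs |> select("contig_id", mean_depth = "coverage"),
    taxonomy = taxonomy,
    truth = truth
  )
}

#' Write a simulated metagenome to FASTA/TSV files
#'
#' @param sim Result of [simulate_metagenome()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (fasta, coverage, taxonomy, truth).
#' @export
write_metagenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "contigs.fasta"),
             coverage = file.path(dir, "coverage.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.tsv"))
  seqs <- Biostrings::DNAStringSet(setNames(sim$contigs$sequence,
                                            sim$contigs$contig_id))
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])
  readr::write_tsv(sim$coverage, paths[["coverage"]])
  readr::write_tsv(sim$taxonomy, paths[["taxonomy"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Read contigs, coverage and taxonomy tables from files
#'
#' @param fasta Path to a contig FASTA file.
#' @return `read_contig_fasta()`: tibble with `contig_id` and `sequence`.
#' @export
read_contig_fasta <- function(fasta) {
  x <- Biostrings::readDNAStringSet(fasta)
  tibble(contig_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

#' @rdname read_contig_fasta
#' @param path Path to a TSV file.
#' @return `read_coverage_tsv()`: tibble `contig_id`, `mean_depth`;
#'   `read_taxonomy_tsv()`: tibble `contig_id`, `taxon`, `rank`, `bitscore`,
#'   `evalue`, `tier`.
#' @export
read_coverage_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_contig_fasta
#' @export
read_taxonomy_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
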