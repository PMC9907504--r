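test_that("pairwise identity follows the global-alignment contract", {
  expect_equal(pairwise_identity("MKV", "MKV"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("MKVL", "MKL"), 0.75)
  expect_error(pairwise_identity("", "MK"), "empty sequence")
  # symmetry
  set.seed(31)
  for (i in 1:10) {
    a <- raa(sample(10:40, 1)); b <- raa(sample(10:40, 1))
    expect_identical(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("identity agrees with an independent aligner", {
  # Biostrings with the same scoring scheme as the compiled kernel
  alph <- LETTERS
  mat <- matrix(-1, 26, 26, dimnames = list(alph, alph)); diag(mat) <- 1
  set.seed(17)
  for (i in 1:25) {
    a <- raa(sample(15:50, 1)); b <- raa(sample(15:50, 1))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::BString(a), Biostrings::BString(b),
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
      type = "global")
    ours <- pairwise_identity(a, b)
    ref <- Biostrings::nmatch(al) /
      Biostrings::nchar(Biostrings::alignedPattern(al))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("similarity components follow their set arithmetic", {
  A <- make_cluster("A", list(c("KS", "AT", "ACP")), "MKVLMKVL")
  B <- make_cluster("B", list(c("KS", "AT", "TE")), "MKVLMKVL")
  expect_equal(domain_jaccard(A, A), 1)
  expect_equal(domain_jaccard(A, B), 0.5)   # {KS,AT} / {KS,AT,ACP,TE}
  C <- make_cluster("C", list("XX"), "MMMM")
  expect_equal(domain_jaccard(A, C), 0)
  E <- make_cluster("E", list(character(0)), "MMMM")
  expect_warning(j <- domain_jaccard(E, E), "no domains")
  expect_equal(j, 1)

  expect_equal(adjacency_index(A, A), 1)
  expect_equal(adjacency_index(A, B), 1 / 3)  # {KS-AT} of {KS-AT,AT-ACP,AT-TE}
  expect_equal(adjacency_index(C, A), 0)      # single-domain cluster

  expect_equal(domain_sequence_similarity(A, A), 1)
  expect_equal(domain_sequence_similarity(A, C), 0)
  # one paired label at identity 1, one unpaired copy each side -> 2/4
  X <- make_cluster("X", list("KS", "AT"), c("MKVL", "AAAA"))
  Y <- make_cluster("Y", list("KS", "TE"), c("MKVL", "CCCC"))
  expect_equal(domain_sequence_similarity(X, Y), 0.5)
})

test_that("composite distance is a weighted complement of the components", {
  A <- make_cluster("A", list(c("KS", "AT", "ACP")), "MKVLMKVL")
  B <- make_cluster("B", list(c("KS", "AT", "TE")), "MKVLMKVL")
  C <- make_cluster("C", list("XX"), "WWWW")
  expect_equal(bgc_distance(A, A)$d, 0)
  expect_equal(bgc_distance(A, C)$d, 1)  # fully disjoint
  d <- bgc_distance(A, B)
  expect_equal(d$d, 1 - (0.2 * d$J + 0.7 * d$DSS + 0.1 * d$AI))
  expect_true(all(c(d$J, d$DSS, d$AI, d$d) >= 0 &
                    c(d$J, d$DSS, d$AI, d$d) <= 1))
  expect_error(bgc_distance(A, B, weights = c(0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("distance matrix route equals the single-pair route", {
  set.seed(23)
  panel <- simulate_bgc_panel(
    random_archetypes(4, seed = 3),
    tibble::tibble(genome_id = c("gA", "gB", "gC"), clade = "X"),
    evolution_params(), seed = 3)
  pairs <- bgc_distance_matrix(panel$clusters)
  expect_true(all(pairs$d >= 0 & pairs$d <= 1))
  for (p in sample(nrow(pairs), 5)) {
    i <- match(pairs$a_id[p], panel$clusters$cluster_id)
    j <- match(pairs$b_id[p], panel$clusters$cluster_id)
    d1 <- bgc_distance(panel$clusters[i, ], panel$clusters[j, ])
    expect_equal(pairs$d[p], d1$d, tolerance = 1e-12)
    expect_equal(pairs$DSS[p], d1$DSS, tolerance = 1e-12)
  }
  # only within-class comparisons
  cls <- panel$clusters$class[match(pairs$a_id, panel$clusters$cluster_id)]
  clsb <- panel$clusters$class[match(pairs$b_id, panel$clusters$cluster_id)]
  expect_true(all(cls == clsb))
})

test_that("network edges respect the cutoff and class boundaries", {
  A <- make_cluster("A1", list(c("KS", "AT", "ACP")), "MKVLWT")
  A2 <- make_cluster("A2", list(c("KS", "AT", "ACP")), "MKVLWT")
  N <- make_cluster("N1", list(c("KS", "AT", "ACP")), "MKVLWT",
                    class = "NRPS")
  D <- make_cluster("D1", list("ZZ"), "PPPP")
  pairs <- bgc_distance_matrix(dplyr::bind_rows(A, A2, N, D))
  edges <- build_network(pairs, 0.46)
  expect_equal(nrow(edges), 1)  # only the identical same-class pair
  expect_setequal(c(edges$a_id, edges$b_id), c("A1", "A2"))
})

test_that("family assignment is a stable, order-invariant partition", {
  set.seed(4)
  trio <- dplyr::bind_rows(lapply(c("t1", "t2", "t3"), function(id) {
    make_cluster(id, list(c("KS", "AT", "ACP")), "MKVLWTAR")
  }))
  fam <- assign_families(trio, cutoff = 0.46)
  expect_equal(dplyr::n_distinct(fam$family_id), 1)
  # two unbridged groups stay two families
  far <- dplyr::bind_rows(trio,
                          make_cluster("u1", list("QQ"), "WWWWWW"),
                          make_cluster("u2", list("QQ"), "WWWWWW"))
  fam2 <- assign_families(far, cutoff = 0.46)
  expect_equal(dplyr::n_distinct(fam2$family_id), 2)
  # every cluster in exactly one family
  expect_setequal(fam2$cluster_id, far$cluster_id)
  # input order does not change the partition or the ids
  fam3 <- assign_families(far[rev(seq_len(nrow(far))), ], cutoff = 0.46)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(fam2), cluster_id)$family_id,
    dplyr::arrange(tibble::as_tibble(fam3), cluster_id)$family_id)
})

test_that("raising the cutoff never increases the family count", {
  panel <- simulate_bgc_panel(
    random_archetypes(6, seed = 9),
    tibble::tibble(genome_id = sprintf("g%d", 1:5), clade = "X"),
    evolution_params(residue_sub_prob = 0.25), seed = 9)
  pairs <- bgc_distance_matrix(panel$clusters)
  counts <- vapply(c(0.3, 0.46, 0.7, 1.0), function(cut) {
    dplyr::n_distinct(assign_families(panel$clusters, pairs = pairs,
                                      cutoff = cut)$family_id)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("cutoff selection returns the minimal co-clustering grid value", {
  ident <- dplyr::bind_rows(
    make_cluster("r1", list(c("KS", "AT", "ACP")), "MKVLWTAR",
                 is_reference = TRUE, compound = "asperthecin"),
    make_cluster("r2", list(c("KS", "AT", "ACP")), "MKVLWTAR",
                 is_reference = TRUE, compound = "TAN-1612"))
  expect_equal(select_cutoff(ident, c("r1", "r2")), 0.30)
  # a pair at distance 1 never co-clusters
  apart <- dplyr::bind_rows(
    make_cluster("r1", list("AA"), "MMMM", is_reference = TRUE),
    make_cluster("r2", list("BB"), "WWWW", is_reference = TRUE))
  expect_error(select_cutoff(apart, c("r1", "r2")), "never co-clustered")
  expect_error(select_cutoff(ident, c("r1", "zz")), "must be present")
})

test_that("selected cutoff is at least the pair distance minus one step", {
  set.seed(12)
  a_seq <- raa(60); b_seq <- paste0(substr(a_seq, 1, 35), raa(25))
  pair <- dplyr::bind_rows(
    make_cluster("p1", list(c("KS", "AT", "ACP")), a_seq,
                 is_reference = TRUE, compound = "asperthecin"),
    make_cluster("p2", list(c("KS", "AT", "ACP")), b_seq,
                 is_reference = TRUE, compound = "TAN-1612"))
  d <- bgc_distance_matrix(pair)$d
  cut <- select_cutoff(pair, c("p1", "p2"))
  expect_gte(cut, d - 0.01)
  expect_lte(cut, max(0.30, d + 0.01))
})

test_that("presence-absence matrix reflects assignments without references", {
  one <- assign_families(
    make_cluster("c1", list("KS"), "MMMM", genome = "G1"), cutoff = 0.46)
  pa <- presence_absence(one)
  expect_equal(dim(pa), c(1L, 2L))
  expect_equal(pa[[2]], 1)
  # two clusters of one genome in the same family -> still 1
  two <- assign_families(dplyr::bind_rows(
    make_cluster("c1", list(c("KS", "AT")), "MMMM", genome = "G1"),
    make_cluster("c2", list(c("KS", "AT")), "MMMM", genome = "G1"),
    make_cluster("ref", list(c("ZZ", "QQ")), "WWWW", genome = "MIBiG_x",
                 is_reference = TRUE, compound = "melanin")),
    cutoff = 0.46)
  pa2 <- presence_absence(two)
  expect_equal(nrow(pa2), 1)
  expect_equal(ncol(pa2), 2)  # genome_id + the single non-reference family
  expect_true(all(pa2[, -1] == 1))
})

test_that("simulated panel families are recovered against truth", {
  panel <- simulate_bgc_panel(
    random_archetypes(8, seed = 5),
    tibble::tibble(genome_id = sprintf("G%02d", 1:6), clade = "X"),
    evolution_params(), seed = 7)
  fam <- assign_families(panel$clusters, cutoff = 0.46)
  truth <- panel$truth[panel$truth$status == "present", ]
  pred <- fam$family_id[match(truth$cluster_id, fam$cluster_id)]
  # smoke-scale panel; the full study-condition panel is asserted at >= 0.9
  # in the acceptance suite
  expect_gte(mclust::adjustedRandIndex(pred, truth$family_id), 0.8)
  # row sums of the presence-absence matrix match per-genome truth counts
  pa <- presence_absence(fam)
  fam_of <- fam$family_id[match(truth$cluster_id, fam$cluster_id)]
  truth_counts <- tapply(fam_of, truth$genome_id,
                         function(x) length(unique(x)))
  got <- rowSums(pa[, -1])
  expect_equal(unname(got[match(names(truth_counts), pa$genome_id)]),
               unname(as.vector(truth_counts)))
})
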