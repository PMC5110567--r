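test_that("pairwise comparison counts sites, transitions and transversions", {
  cmp <- compare_pair("ACGT", "ACGT")
  expect_equal(cmp[c("n_compared", "P", "Q")],
               list(n_compared = 4L, P = 0, Q = 0))

  cmp2 <- compare_pair("AAAA", "GAAA")
  expect_equal(cmp2$n_transitions, 1L)
  expect_equal(cmp2$n_transversions, 0L)
  expect_equal(cmp2$P, 0.25)

  cmp3 <- compare_pair("AC-T", "ACAT")  # pairwise deletion
  expect_equal(cmp3$n_compared, 3L)
  expect_equal(cmp3$n_transitions + cmp3$n_transversions, 0L)

  cmp4 <- compare_pair("AATT", "CCGG")  # all transversions
  expect_equal(cmp4$Q, 1)

  none <- compare_pair("--NN", "AAAA")
  expect_equal(none$n_compared, 0L)
  expect_true(is.na(none$P))
})

test_that("p-distance is the proportion of differing compared sites", {
  expect_equal(p_distance(compare_pair("ACGT", "ACGT")), 0)
  expect_equal(p_distance(compare_pair("AAAA", "AAAT")), 0.25)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  expect_equal(p_distance(compare_pair(a, b)), 0.10)
  expect_true(is.na(p_distance(compare_pair("--", "AA"))))
})

test_that("K2P distance matches its closed form", {
  expect_equal(k2p_distance(compare_pair("ACGT", "ACGT")), 0)
  # frozen closed-form values: -ln(1-2P-Q)/2 - ln(1-2Q)/4
  expect_equal(k2p_distance(list(P = 0.1, Q = 0.05, n_compared = 100)),
               -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-15)
  expect_equal(k2p_distance(list(P = 0.1, Q = 0.05, n_compared = 100)),
               0.17018117, tolerance = 1e-7)
  expect_equal(k2p_distance(list(P = 0.25, Q = 0, n_compared = 100)),
               0.34657359, tolerance = 1e-7)
  # saturation is undefined, not clamped
  expect_true(is.na(k2p_distance(list(P = 0.5, Q = 0.1, n_compared = 10))))
  expect_true(is.na(k2p_distance(list(P = 0, Q = 0.5, n_compared = 10))))
})

test_that("K2P dominates p entrywise and equals it only at zero", {
  set.seed(71)
  for (rep in 1:200) {
    n <- sample(50:400, 1)
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    mut <- runif(n) < runif(1, 0, 0.2)
    b[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    cmp <- compare_pair(a, b)
    dp <- p_distance(cmp)
    dk <- k2p_distance(cmp)
    expect_gte(dk, dp)
    if (dp == 0) expect_equal(dk, 0)
    if (dp > 0) expect_gt(dk, dp)
  }
})

test_that("distance matrices agree with an independent implementation", {
  tr <- simulate_species_tree(8, 0.3, seed = 5)
  aln <- evolve_alignment(tr, 300, kappa = 2, seed = 6)
  m <- unclass(aln)
  set.seed(7)
  m[sample(length(m), 60)] <- "-"   # scattered gaps exercise pairwise deletion
  m[sample(length(m), 20)] <- "N"
  aln <- aligned_matrix(m, "sim")
  bin <- ape::as.DNAbin(unclass(aln))
  ours_k <- build_distance_matrix(aln, "k2p")
  ref_k <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(unname(ours_k[rownames(ref_k), colnames(ref_k)]),
               unname(ref_k), tolerance = 1e-12)

  ours_p <- build_distance_matrix(aln, "p")
  ref_p <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
  expect_equal(unname(ours_p[rownames(ref_p), colnames(ref_p)]),
               unname(ref_p), tolerance = 1e-12)
})

test_that("distance matrix structure, undefined entries and invariances", {
  ident <- aln_from_strings(c(s1 = "ACGT", s2 = "ACGT"))
  expect_equal(unname(build_distance_matrix(ident, "k2p")),
               matrix(0, 2, 2), ignore_attr = TRUE)

  tr <- simulate_species_tree(7, 0.25, seed = 6)
  aln <- evolve_alignment(tr, 200, kappa = 2, seed = 8, marker_name = "sim")
  dk <- build_distance_matrix(aln, "k2p")
  dp <- build_distance_matrix(aln, "p")
  expect_true(all(dk >= dp))
  expect_equal(dk, t(dk), ignore_attr = TRUE)
  expect_equal(unname(diag(dk)), rep(0, 7))

  # duplicated concatenation leaves P and Q, hence distances, unchanged
  dup <- concatenate_markers(list(aln, aln))
  expect_equal(unname(unclass(build_distance_matrix(dup, "k2p"))),
               unname(unclass(dk)))

  # row permutation only relabels
  perm <- c(3, 1, 2, 6, 5, 7, 4)
  alnp <- aligned_matrix(unclass(aln)[perm, ], "sim")
  dkp <- build_distance_matrix(alnp, "k2p")
  expect_equal(dkp[rownames(dk), colnames(dk)], dk, ignore_attr = TRUE)

  # a pair with no comparable sites is NA with a warning, not zero
  gappy <- aln_from_strings(c(s1 = "AC", s2 = "--", s3 = "AC"))
  expect_warning(dg <- build_distance_matrix(gappy, "p"), "undefined")
  expect_true(is.na(dg["s1", "s2"]))
  expect_equal(dg["s1", "s3"], 0)
  expect_equal(attr(dg, "n_undefined"), 2L)
})

test_that("complete deletion removes every gapped column first", {
  aln <- aln_from_strings(c(s1 = "AC-TAA", s2 = "ACATAA", s3 = "GCATAA"))
  d <- build_distance_matrix(aln, "p", deletion = "complete")
  # column 3 dropped for all: 5 sites compared, s1 vs s3 differ at 1
  expect_equal(d["s1", "s3"], 1 / 5)
  expect_equal(d["s1", "s2"], 0)
})

test_that("partition_distances splits intra and inter pairs", {
  ids <- c("a1", "a2", "b1", "b2")
  md <- toy_metadata(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  part <- make_partition(md, "species")
  d <- dist_from_pairs(ids, function(i, j) {
    if (substr(i, 1, 1) == substr(j, 1, 1)) 0.01 else 0.10
  })
  s <- partition_distances(d, part)
  expect_equal(s$groups$max_intra, c(0.01, 0.01))
  expect_equal(s$groups$min_inter, c(0.10, 0.10))
  expect_equal(s$mean_intra, 0.01)
  expect_equal(s$mean_inter, 0.10)
  expect_equal(s$n_intra_pairs, 2L)
  expect_equal(s$n_inter_pairs, 4L)

  # all identical sequences: means collapse to zero
  z <- dist_from_pairs(ids, function(i, j) 0)
  sz <- partition_distances(z, part)
  expect_equal(sz$mean_intra, 0)
  expect_equal(sz$mean_inter, 0)

  # singleton group: no intraspecific distance, interspecific defined
  md3 <- toy_metadata(c(a1 = "A", a2 = "A", c1 = "C"))
  p3 <- make_partition(md3, "species")
  d3 <- dist_from_pairs(c("a1", "a2", "c1"), function(i, j) 0.05)
  s3 <- partition_distances(d3, p3)
  expect_true(is.na(s3$groups$max_intra[s3$groups$group == "C"]))
  expect_equal(s3$groups$min_inter[s3$groups$group == "C"], 0.05)

  # sample missing from the partition is reported by name
  expect_error(partition_distances(d, p3), "b1")
})

test_that("gap histogram bins intra and inter distances and conserves counts", {
  ids <- c("a1", "a2", "b1", "b2")
  md <- toy_metadata(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  part <- make_partition(md, "species")
  d <- dist_from_pairs(ids, function(i, j) {
    if (i == "a1" && j == "a2") 0.001
    else if (i == "b1" && j == "b2") 0.002
    else 0.055
  })
  h <- gap_histogram(d, part, bin_width = 0.01)
  expect_equal(h$intra_count[1], 2L)          # bin [0, 0.01)
  expect_equal(h$bin_start[6], 0.05)
  expect_equal(h$inter_count[6], 4L)          # bin [0.05, 0.06)
  expect_equal(sum(h$intra_count), 2L)
  expect_equal(sum(h$inter_count), 4L)

  # all-singleton partition: empty intra series, inter intact
  md1 <- toy_metadata(c(a1 = "A", b1 = "B", c1 = "C"))
  p1 <- make_partition(md1, "species")
  d1 <- dist_from_pairs(c("a1", "b1", "c1"), function(i, j) 0.02)
  h1 <- gap_histogram(d1, p1, bin_width = 0.01)
  expect_equal(sum(h1$intra_count), 0L)
  expect_equal(sum(h1$inter_count), 3L)

  # conservation on simulated data
  tr <- simulate_species_tree(10, 0.2, seed = 12)
  aln <- evolve_alignment(tr, 150, kappa = 2, seed = 13)
  md10 <- toy_metadata(setNames(rep(c("A", "B", "C", "D", "E"), each = 2),
                                rownames(aln)))
  p10 <- make_partition(md10, "species")
  dm <- build_distance_matrix(aln, "k2p")
  h10 <- gap_histogram(dm, p10, bin_width = 0.05)
  expect_equal(sum(h10$intra_count) + sum(h10$inter_count),
               choose(10, 2) - attr(h10, "n_dropped"))
  expect_error(gap_histogram(dm, p10, bin_width = 0), "positive")
})
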