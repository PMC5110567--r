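test_that("three-taxon neighbor-joining matches the closed form", {
  d <- dist_from_pairs(c("a", "b", "c"), function(i, j)
    if (all(c(i, j) %in% c("a", "b"))) 2 else 4)
  tr <- nj_construct(d)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 1, c = 3))
})

test_that("a four-taxon additive matrix is recovered exactly", {
  gen <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  D <- ape::cophenetic.phylo(gen)
  D <- D[letters[1:4], letters[1:4]]
  tr <- nj_construct(D)
  expect_equal(bip_set(tr), "c|d")  # ab|cd split, canonical side
  C <- ape::cophenetic.phylo(tr)
  expect_equal(C[rownames(D), colnames(D)], D, tolerance = 1e-12)
  # oracle agreement: exhaustive least-squares picks the same topology
  orc <- oracle_best_topology(D)
  expect_equal(bip_set(orc$tree), bip_set(tr))
})

test_that("random additive matrices are recovered (enumeration oracle)", {
  for (seed in 1:30) {
    n <- 4 + (seed %% 3)
    ra <- random_additive(n, seed = 1000 + seed)
    tr <- nj_construct(ra$D)
    expect_equal(bip_set(tr), bip_set(ra$tree))
    C <- ape::cophenetic.phylo(tr)
    expect_lt(max(abs(C[rownames(ra$D), colnames(ra$D)] - ra$D)), 1e-9)
  }
})

test_that("nj_construct agrees with an independent NJ on random matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 8
    D <- matrix(runif(n * n, 0.05, 1), n, n)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    rownames(D) <- colnames(D) <- letters[1:n]
    expect_equal(phangorn::RF.dist(nj_construct(D), ape::nj(D)), 0)
  }
})

test_that("nj_construct validates its input", {
  D <- dist_from_pairs(c("a", "b"), function(i, j) 1)
  expect_error(nj_construct(D), "at least 3")
  D3 <- dist_from_pairs(c("a", "b", "c"), function(i, j) 1)
  D3["a", "b"] <- NA
  D3["b", "a"] <- NA
  expect_error(nj_construct(D3), "undefined")
})

test_that("bootstrap supports behave like resampling fractions", {
  # every column supports ab|cd: a,b identical; c,d identical; 30% divergent
  L <- 200
  block <- c(rep("A", L))
  div <- replace(block, 1:60, "G")
  aln <- aln_from_strings(c(a = paste(block, collapse = ""),
                            b = paste(block, collapse = ""),
                            c = paste(div, collapse = ""),
                            d = paste(div, collapse = "")))
  tr <- bootstrap_supports(aln, model = "p", B = 50, seed = 2)
  sup <- as.numeric(tr$node.label[nzchar(tr$node.label)])
  expect_equal(sup, 1)
  expect_equal(bip_set(tr), "c|d")

  # with B = 10 every support is a multiple of 0.1
  aln2 <- random_alignment(6, 80, seed = 3)
  tr10 <- bootstrap_supports(aln2, model = "p", B = 10, seed = 9)
  sup10 <- as.numeric(tr10$node.label[nzchar(tr10$node.label)])
  expect_true(all(abs(sup10 * 10 - round(sup10 * 10)) < 1e-9))
  expect_true(all(sup10 >= 0 & sup10 <= 1))

  # the same seed reproduces supports exactly
  tr10b <- bootstrap_supports(aln2, model = "p", B = 10, seed = 9)
  expect_identical(tr10$node.label, tr10b$node.label)
  tr10c <- bootstrap_supports(aln2, model = "p", B = 10, seed = 10)
  expect_identical(class(tr10c), "phylo")  # different seed still valid
})

test_that("monophyly is bipartition membership on the unrooted tree", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_true(is_monophyletic(tr, c("a1", "a2")))
  expect_true(is_monophyletic(tr, c("b1", "b2")))

  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_false(is_monophyletic(tr2, c("a1", "a2")))

  # degenerate cases: full leaf set (by convention) and singleton
  expect_true(is_monophyletic(tr, c("a1", "a2", "b1", "b2")))
  expect_true(is_monophyletic(tr, "a1"))
  expect_error(is_monophyletic(tr, c("a1", "zz")), "zz")

  # unrooted symmetry: a set and its complement are equivalent
  set.seed(14)
  big <- ape::unroot(ape::rtree(8))
  labs <- big$tip.label
  for (k in 2:4) {
    members <- sample(labs, k)
    expect_equal(isTRUE(c(is_monophyletic(big, members))),
                 isTRUE(c(is_monophyletic(big, setdiff(labs, members)))))
  }
})

test_that("tree discrimination requires monophyly and strict support", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  md <- toy_metadata(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  part <- make_partition(md, "species")

  tr$node.label <- c("", "0.87", "0.87")
  dec <- tree_discriminate(tr, part, support_threshold = 0.5)
  expect_true(all(dec$discriminated))
  expect_equal(attr(dec, "rate"), 100)

  # boundary: support exactly at the threshold fails (strict >)
  tr$node.label <- c("", "0.5", "0.5")
  dec2 <- tree_discriminate(tr, part, support_threshold = 0.5)
  expect_false(any(dec2$discriminated))
  expect_true(all(dec2$reason == "low_support"))

  # non-monophyletic group fails regardless of supports
  tr3 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  tr3$node.label <- c("", "1", "1")
  dec3 <- tree_discriminate(tr3, part)
  expect_false(any(dec3$discriminated))
  expect_true(all(dec3$reason == "not_monophyletic"))

  # discrimination is monotone non-increasing in the threshold
  tr$node.label <- c("", "0.9", "0.4")
  r_low <- attr(tree_discriminate(tr, part, 0.3), "rate")
  r_mid <- attr(tree_discriminate(tr, part, 0.5), "rate")
  r_high <- attr(tree_discriminate(tr, part, 0.95), "rate")
  expect_true(r_low >= r_mid && r_mid >= r_high)

  # singletons excluded by default, counted monophyletic under zero_intra
  md5 <- toy_metadata(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C"))
  tr5 <- ape::read.tree(
    text = "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,c1:1);")
  tr5$node.label <- rep("0.9", tr5$Nnode)
  p5 <- make_partition(md5, "species")
  d5 <- tree_discriminate(tr5, p5)
  expect_equal(d5$reason[d5$group == "C"], "singleton_excluded")
  expect_equal(attr(d5, "rate"), 100)
  d5z <- tree_discriminate(tr5, p5, singleton_policy = "zero_intra")
  expect_true(d5z$discriminated[d5z$group == "C"])
})
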