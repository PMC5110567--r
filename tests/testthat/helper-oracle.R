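# Independent oracles for the tree tests. Nothing here calls the package's
# neighbor-joining or distance code paths.

# All labeled unrooted binary topologies on `labels` (n <= 6 in practice),
# built by stepwise insertion of each taxon into every edge.
enumerate_topologies <- function(labels) {
  stopifnot(length(labels) >= 3)
  base <- ape::read.tree(text = sprintf("(%s:1,%s:1,%s:1);",
                                        labels[1], labels[2], labels[3]))
  trees <- list(base)
  for (lab in labels[-(1:3)]) {
    trees <- unlist(lapply(trees, function(t) {
      t$edge.length <- rep(1, nrow(t$edge))  # insertion needs room mid-edge
      lapply(t$edge[, 2], function(w)
        phytools::bind.tip(t, lab, edge.length = 1, where = w,
                           position = 0.5))
    }), recursive = FALSE)
  }
  trees
}

# Pairs x edges path-incidence matrix; pair order = combn(sort(labels), 2).
path_matrix <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(n + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  anc_path <- function(node) {
    e <- integer(0)
    while (node != root) {
      e <- c(e, edge_of[node])
      node <- parent[node]
    }
    e
  }
  tipnum <- match(labs, tree$tip.label)
  pairs <- utils::combn(n, 2)
  X <- matrix(0, ncol(pairs), nrow(tree$edge))
  for (k in seq_len(ncol(pairs))) {
    p1 <- anc_path(tipnum[pairs[1, k]])
    p2 <- anc_path(tipnum[pairs[2, k]])
    X[k, c(setdiff(p1, p2), setdiff(p2, p1))] <- 1
  }
  X
}

# Ordinary least-squares branch-length fit of distance matrix D on a fixed
# topology; negative lengths allowed (as in NJ).
ls_fit <- function(tree, D) {
  labs <- sort(rownames(D))
  X <- path_matrix(tree)
  pairs <- utils::combn(labs, 2)
  y <- D[cbind(pairs[1, ], pairs[2, ])]
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients,
       fitted = fit$fitted.values)
}

# Exhaustive-enumeration oracle: best least-squares topology for D.
oracle_best_topology <- function(D) {
  trees <- enumerate_topologies(sort(rownames(D)))
  fits <- lapply(trees, ls_fit, D = D)
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best <- which.min(rss)
  list(tree = trees[[best]], fit = fits[[best]], all_rss = rss)
}

# Canonical nontrivial bipartition set of an unrooted tree, via
# ape::prop.part (independent of the package's bipartition code).
bip_set <- function(tree) {
  labs <- tree$tip.label
  all <- sort(labs)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (all[1] %in% side) side <- setdiff(all, side)
    if (length(side) < 2 || length(side) > length(all) - 2)
      return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}

# Random unrooted binary tree with positive branch lengths and its exact
# (additive) leaf-to-leaf distance matrix.
random_additive <- function(n, seed) {
  set.seed(seed)
  tree <- ape::unroot(ape::rtree(n, tip.label = letters[seq_len(n)]))
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tree)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tree, D = D)
}
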