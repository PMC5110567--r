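# Neighbor-joining construction, column bootstrap, bipartitions and
# monophyly-based discrimination.

# Full-precision branch length for newick assembly: %.17g round-trips doubles.
.bl <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' branch lengths from the standard split formula. Ties in Q are broken
#' deterministically by the lexicographically smallest (i, j) index pair in
#' the current node ordering (input order; joined nodes are appended at the
#' end). Negative branch lengths are kept as computed, so the algorithm
#' recovers additive matrices exactly.
#'
#' @param dm Symmetric distance matrix with >= 3 rows, zero diagonal, sample
#'   ids as rownames, and no undefined (`NA`) entries.
#' @return An unrooted `phylo` tree.
#' @export
nj_construct <- function(dm) {
  dm <- unclass(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("'dm' must be a square matrix")
  if (nrow(dm) < 3L)
    stop("need at least 3 samples for neighbor-joining")
  if (anyNA(dm))
    stop("distance matrix has undefined entries; impute or drop the ",
         "affected samples upstream")
  ids <- rownames(dm)
  if (is.null(ids)) stop("'dm' must carry sample ids as rownames")
  # safe placeholder tokens; original ids restored on the parsed tree
  labels <- sprintf("bgTIP%06d", seq_along(ids))
  D <- dm
  while (length(labels) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]
    j <- hits[1L, 2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    newlab <- sprintf("(%s:%s,%s:%s)",
                      labels[i], .bl(vi), labels[j], .bl(vj))
    keep <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    labels <- c(labels[keep], newlab)
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 labels[1L], .bl(v1), labels[2L], .bl(v2), labels[3L], .bl(v3))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- ids[as.integer(sub("bgTIP", "", tree$tip.label))]
  tree
}

# Leaf sets below every node (tips included), as lists of tip labels.
.clade_sets <- function(tree) {
  n <- ape::Ntip(tree)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1L]
    ch <- post$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Canonical key of the bipartition induced by a leaf-label set `side`,
# given the full leaf set: the side NOT containing the alphabetically first
# leaf, sorted and pasted. Returns NA for trivial bipartitions when
# nontrivial_only is TRUE.
.bip_key <- function(side, all_labels, nontrivial_only = FALSE) {
  anchor <- min(all_labels)
  if (anchor %in% side) side <- setdiff(all_labels, side)
  k <- length(side)
  if (nontrivial_only && (k < 2L || k > length(all_labels) - 2L))
    return(NA_character_)
  paste(sort(side), collapse = "\r")
}

# Keys of all nontrivial bipartitions of an unrooted tree, named by the
# internal node subtending each (child node of the edge).
.tree_bipartitions <- function(tree) {
  n <- ape::Ntip(tree)
  sets <- .clade_sets(tree)
  labs <- tree$tip.label
  internal <- tree$edge[, 2L][tree$edge[, 2L] > n]
  keys <- vapply(internal,
                 function(nd) .bip_key(sets[[nd]], labs, TRUE),
                 character(1))
  names(keys) <- internal
  keys[!is.na(keys)]
}

#' Bootstrap supports on a neighbor-joining tree
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `B` times (seeded), recomputes the
#' distance matrix and NJ tree, and scores each internal edge of the
#' reference tree by the fraction of replicate trees containing the same
#' bipartition. Replicates whose distance matrix has undefined entries are
#' skipped and tallied in the `"n_skipped"` attribute; supports are
#' fractions of the effective replicate count.
#'
#' @param x An [aligned_matrix()].
#' @param model Distance model, `"k2p"` or `"p"`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @param deletion Site-deletion mode, see [build_distance_matrix()].
#' @return The reference `phylo` tree with supports in `$node.label`
#'   (empty for the root / trivial positions), in `[0, 1]`.
#' @export
bootstrap_supports <- function(x, model = c("k2p", "p"), B = 1000L,
                               seed = 1L,
                               deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (B < 1L) stop("'B' must be >= 1")
  m <- unclass(x)
  ref_dm <- build_distance_matrix(x, model = model, deletion = deletion)
  if (anyNA(ref_dm))
    stop("reference distance matrix has undefined entries")
  ref <- nj_construct(ref_dm)
  ref_bips <- .tree_bipartitions(ref)
  counts <- setNames(numeric(length(ref_bips)), unname(ref_bips))
  L <- ncol(m)
  skipped <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    mb <- aligned_matrix(m[, cols, drop = FALSE], marker_name(x))
    dmb <- suppressWarnings(
      tryCatch(build_distance_matrix(mb, model = model, deletion = deletion),
               error = function(e) NULL))
    if (is.null(dmb) || anyNA(dmb)) {
      skipped <- skipped + 1L
      next
    }
    bips_b <- .tree_bipartitions(nj_construct(dmb))
    hit <- names(counts) %in% bips_b
    counts[hit] <- counts[hit] + 1
  }
  B_eff <- B - skipped
  if (B_eff == 0L)
    stop("all bootstrap replicates were skipped (undefined distances)")
  supports <- counts / B_eff
  node.label <- rep("", ref$Nnode)
  idx <- as.integer(names(ref_bips)) - ape::Ntip(ref)
  node.label[idx] <- format(supports[unname(ref_bips)], digits = 6)
  ref$node.label <- node.label
  attr(ref, "n_skipped") <- skipped
  attr(ref, "B_effective") <- B_eff
  ref
}

#' Test monophyly of a sample set on an unrooted tree
#'
#' True iff some edge of the tree induces a bipartition with one side exactly
#' equal to `members`. A single member is trivially monophyletic (its pendant
#' edge), and by convention the full leaf set is monophyletic with no
#' supporting edge.
#'
#' @param tree A `phylo` object.
#' @param members Character vector of leaf labels.
#' @return Logical; when `TRUE` through an edge, the node subtending that
#'   edge is attached as attribute `"node"`.
#' @export
is_monophyletic <- function(tree, members) {
  labs <- tree$tip.label
  unknown <- setdiff(members, labs)
  if (length(unknown))
    stop("member(s) not leaves of the tree: ", paste(unknown, collapse = ", "))
  members <- unique(members)
  if (length(members) == length(labs))
    return(TRUE)  # degenerate: whole leaf set, no supporting edge
  sets <- .clade_sets(tree)
  comp <- setdiff(labs, members)
  for (k in seq_len(nrow(tree$edge))) {
    side <- sets[[tree$edge[k, 2L]]]
    if (length(side) == length(members) && setequal(side, members)) {
      res <- TRUE
      attr(res, "node") <- tree$edge[k, 2L]
      return(res)
    }
    if (length(side) == length(comp) && setequal(side, comp)) {
      res <- TRUE
      attr(res, "node") <- tree$edge[k, 2L]
      return(res)
    }
  }
  FALSE
}

# Support of the edge subtended by `node` on a tree with node labels;
# pendant edges (node <= Ntip) have support 1 by definition.
.edge_support <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(1)
  lab <- tree$node.label[node - n]
  if (is.null(lab) || !nzchar(lab)) return(NA_real_)
  as.numeric(lab)
}

#' Tree-based species discrimination
#'
#' A group is discriminated when its members form a monophyletic group in the
#' tree and the supporting edge's bootstrap support is strictly greater than
#' `support_threshold`. Singletons are handled per `singleton_policy`
#' (default excluded, keeping denominators identical to the PWG criterion;
#' with `"zero_intra"` they count as trivially monophyletic with full
#' support).
#'
#' @param tree A `phylo` with bootstrap supports in `$node.label`
#'   ([bootstrap_supports()] output).
#' @param part Partition of the tree's leaves.
#' @param support_threshold Fraction in `[0, 1]`; default 0.5.
#' @param singleton_policy `"exclude"` or `"zero_intra"`.
#' @return A data.frame of per-group decisions (group, n_members,
#'   monophyletic, support, discriminated, reason) with the rate (percent)
#'   in the `"rate"` attribute.
#' @export
tree_discriminate <- function(tree, part, support_threshold = 0.5,
                              singleton_policy = c("exclude", "zero_intra")) {
  singleton_policy <- match.arg(singleton_policy)
  if (support_threshold < 0 || support_threshold > 1)
    stop("'support_threshold' must be in [0, 1]")
  labs <- tree$tip.label
  all_members <- unlist(part, use.names = FALSE)
  unknown <- setdiff(all_members, labs)
  if (length(unknown))
    stop("partition sample(s) not in tree: ", paste(unknown, collapse = ", "))
  rows <- lapply(names(part), function(g) {
    members <- part[[g]]
    k <- length(members)
    if (k == 1L && singleton_policy == "exclude")
      return(data.frame(group = g, n_members = k, monophyletic = TRUE,
                        support = NA_real_, discriminated = FALSE,
                        reason = "singleton_excluded",
                        stringsAsFactors = FALSE))
    mono <- is_monophyletic(tree, members)
    if (!isTRUE(c(mono))) {
      return(data.frame(group = g, n_members = k, monophyletic = FALSE,
                        support = NA_real_, discriminated = FALSE,
                        reason = "not_monophyletic",
                        stringsAsFactors = FALSE))
    }
    node <- attr(mono, "node")
    if (is.null(node))
      return(data.frame(group = g, n_members = k, monophyletic = TRUE,
                        support = NA_real_, discriminated = FALSE,
                        reason = "no_supporting_edge",
                        stringsAsFactors = FALSE))
    sup <- .edge_support(tree, node)
    disc <- !is.na(sup) && sup > support_threshold  # strict
    data.frame(group = g, n_members = k, monophyletic = TRUE,
               support = sup, discriminated = disc,
               reason = if (disc) "supported_clade" else "low_support",
               stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, rows)
  attr(decisions, "rate") <- discrimination_rate(decisions)
  decisions
}
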