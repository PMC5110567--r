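# Synthetic barcoding datasets with known ground truth: Yule species trees,
# star-shaped intraspecific structure, and sequence evolution under the
# Kimura two-parameter substitution process.

#' Simulation configuration
#'
#' Defaults emulate a barcoding study of a tree family sampled at 21 species
#' with 2–5 individuals each and four markers whose relative substitution
#' rates follow the classic ladder from a slow coding chloroplast gene (rbcL)
#' to a fast nuclear spacer (ITS); rates are proportional to the mean
#' interspecific divergences observed for such markers (rbcL 0.09, matK 0.18,
#' trnS-trnG 0.57, ITS 1). `interspecific_depth` is the expected root-level
#' between-species divergence and `intraspecific_depth` the expected
#' within-species divergence, both in substitutions/site on the rate-1
#' (ITS-like) scale.
#'
#' @param n_species Number of species (>= 2).
#' @param individuals_per_species Integer range `c(min, max)`; the per-species
#'   count is drawn uniformly from it.
#' @param markers data.frame with columns `name`, `length` (bp) and `rate`
#'   (relative substitution rate).
#' @param interspecific_depth,intraspecific_depth Expected divergences in
#'   expected substitutions/site; within must not exceed between.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param indel_rate Expected number of shared indel events per marker
#'   (0 disables indels).
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 21L,
                              individuals_per_species = c(2L, 5L),
                              markers = data.frame(
                                name = c("rbcL", "matK", "trnS-trnG", "ITS"),
                                length = c(497L, 636L, 366L, 346L),
                                rate = c(0.09, 0.18, 0.57, 1),
                                stringsAsFactors = FALSE),
                              interspecific_depth = 0.05,
                              intraspecific_depth = 0.006,
                              kappa = 2,
                              indel_rate = 0,
                              seed = 1L) {
  if (n_species < 2L) stop("'n_species' must be >= 2")
  if (length(individuals_per_species) != 2L ||
      individuals_per_species[1L] < 1L ||
      individuals_per_species[2L] < individuals_per_species[1L])
    stop("'individuals_per_species' must be an increasing range of counts")
  if (!all(c("name", "length", "rate") %in% names(markers)))
    stop("'markers' needs columns name, length, rate")
  if (any(markers$length < 1L)) stop("marker lengths must be >= 1")
  if (any(markers$rate < 0)) stop("marker rates must be >= 0")
  if (kappa <= 0) stop("'kappa' must be > 0")
  if (intraspecific_depth > interspecific_depth)
    stop("'intraspecific_depth' must not exceed 'interspecific_depth'")
  if (indel_rate < 0) stop("'indel_rate' must be >= 0")
  structure(list(n_species = as.integer(n_species),
                 individuals_per_species = as.integer(individuals_per_species),
                 markers = markers,
                 interspecific_depth = interspecific_depth,
                 intraspecific_depth = intraspecific_depth,
                 kappa = kappa,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology with the branch lengths rescaled so the
#' root-to-tip height equals `interspecific_depth / 2`: the expected
#' between-species divergence for the deepest splits is then
#' `interspecific_depth`. Split heights are then affinely compressed so the
#' most recent speciation lies at least `min_split_frac` of the tree height
#' above the tips. An unconstrained pure-birth process can place a split
#' arbitrarily close to the present, i.e. a pair of species less divergent
#' than the within-species variation — exactly the recently-diverged,
#' introgressing complexes that barcoding studies exclude from their
#' sampling. The floor keeps every simulated species pair at an expected
#' divergence of at least `min_split_frac * interspecific_depth`, so that a
#' configured gap between `intraspecific_depth` and `interspecific_depth`
#' is a real gap for every species pair.
#'
#' @param n_species Number of species (>= 2).
#' @param interspecific_depth Expected root-level divergence.
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @param min_split_frac Minimum split height as a fraction of tree height,
#'   in `[0, 1)`; 0 gives the raw Yule heights.
#' @return An ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_species, interspecific_depth,
                                  seed = NULL, min_split_frac = 0.2) {
  if (n_species < 2L) stop("'n_species' must be >= 2")
  if (min_split_frac < 0 || min_split_frac >= 1)
    stop("'min_split_frac' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tree)[seq_len(n_species)])
  tree$edge.length <- tree$edge.length * (interspecific_depth / 2) / h
  if (min_split_frac > 0) {
    # compress internal node depths toward the root: depth -> (1-f)*depth,
    # tips stay put, so every split height >= f * height
    depth <- ape::node.depth.edgelength(tree)
    new_depth <- depth
    internal <- (n_species + 1L):(n_species + tree$Nnode)
    new_depth[internal] <- (1 - min_split_frac) * depth[internal]
    tree$edge.length <- new_depth[tree$edge[, 2L]] - new_depth[tree$edge[, 1L]]
  }
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

# Kimura two-parameter transition-probability matrix for branch length t
# (expected substitutions/site), state order A, G, C, T. Rates are
# normalized so alpha + 2 beta = 1.
.k2p_pmat <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2    # transition (A<->G, C<->T)
  p_tv <- 0.25 - 0.25 * e1               # each transversion target
  p_same <- 1 - p_ts - 2 * p_tv
  matrix(c(p_same, p_ts, p_tv, p_tv,
           p_ts, p_same, p_tv, p_tv,
           p_tv, p_tv, p_same, p_ts,
           p_tv, p_tv, p_ts, p_same),
         nrow = 4L, byrow = TRUE)
}

# Evolve integer-coded states (1=A,2=G,3=C,4=T) along one branch.
.evolve_branch <- function(states, t, kappa) {
  if (t <= 0) return(states)
  P <- .k2p_pmat(t, kappa)
  out <- integer(length(states))
  for (s in 1:4) {
    idx <- which(states == s)
    if (length(idx))
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Evolve an alignment along a tree
#'
#' The root sequence is uniform over A, C, G, T; each site evolves
#' independently down the tree under the Kimura two-parameter process with
#' transition/transversion rate ratio `kappa`. Branch lengths are expected
#' substitutions/site after multiplication by `rate`.
#'
#' @param tree A `phylo` with branch lengths.
#' @param length Number of sites (>= 1).
#' @param kappa Transition/transversion rate ratio.
#' @param rate Relative rate multiplier applied to every branch.
#' @param marker_name Marker name for the resulting alignment.
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return An [aligned_matrix()] with one row per tip.
#' @export
evolve_alignment <- function(tree, length, kappa = 2, rate = 1,
                             marker_name = "sim", seed = NULL) {
  if (length < 1L) stop("'length' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")  # preorder from the root
  seqs <- vector("list", n + tr$Nnode)
  root <- n + 1L
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]
    ch <- tr$edge[k, 2L]
    seqs[[ch]] <- .evolve_branch(seqs[[p]], tr$edge.length[k] * rate, kappa)
  }
  m <- do.call(rbind, seqs[seq_len(n)])
  m <- matrix(c("A", "G", "C", "T")[m], nrow = n)
  rownames(m) <- tr$tip.label
  aligned_matrix(m, marker_name)
}

# Attach `counts[s]` individuals to each species tip as a star of depth
# intra/2, via newick substitution (labels are unique tokens ending in ":").
.individual_tree <- function(species_tree, counts, intraspecific_depth) {
  nwk <- ape::write.tree(species_tree)
  half <- intraspecific_depth / 2
  for (s in seq_along(species_tree$tip.label)) {
    sp <- species_tree$tip.label[s]
    inds <- sprintf("%s_i%d", sp, seq_len(counts[s]))
    star <- paste0("(", paste0(inds, ":", .bl(half), collapse = ","), ")")
    nwk <- sub(paste0(sp, ":"), paste0(star, ":"), nwk, fixed = TRUE)
  }
  # species sampled with one individual create singleton nodes; merge them
  ape::collapse.singles(ape::read.tree(text = nwk))
}

# Insert `n_events` distinct shared gap spans into an alignment. Each event
# picks a random span (length 1-6) and a random species subset, and blanks
# that span in every individual of those species, so the deduplicated
# indel-event count equals the number of distinct spans actually placed.
.insert_indels <- function(m, species_of_row, n_events) {
  if (n_events == 0L) return(m)
  L <- ncol(m)
  used <- character(0)
  species <- unique(species_of_row)
  placed <- 0L
  tries <- 0L
  while (placed < n_events && tries < 50L * n_events) {
    tries <- tries + 1L
    len <- sample.int(6L, 1L)
    if (len >= L) next
    start <- sample.int(L - len + 1L, 1L)
    key <- paste(start, start + len - 1L, sep = ":")
    if (key %in% used) next
    k <- sample.int(max(1L, length(species) - 1L), 1L)
    carriers <- sample(species, k)
    rows <- which(species_of_row %in% carriers)
    m[rows, start:(start + len - 1L)] <- "-"
    used <- c(used, key)
    placed <- placed + 1L
  }
  m
}

#' Simulate a complete multi-marker barcoding dataset
#'
#' Draws per-species individual counts, a Yule species tree, attaches
#' individuals as stars of depth `intraspecific_depth / 2`, and evolves each
#' marker independently with its relative rate under the Kimura
#' two-parameter process. Optional shared indel spans are inserted after
#' simulation. Species are also organized into higher "sections" by cutting
#' the species tree at 40% of its height, giving monophyletic section
#' ground truth.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional directory; when given, per-marker aligned FASTA
#'   files, the metadata TSV, the true species tree (newick) and a JSON echo
#'   of the configuration are written there.
#' @return A list of class `simulated_dataset`: `alignments` (named list of
#'   [aligned_matrix()]), `metadata` (data.frame), `truth` (species tree,
#'   individual tree, per-marker expected root-level divergence, indel
#'   counts), and `config`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  if (!inherits(cfg, "simulation_config"))
    stop("'cfg' must be a simulation_config")
  set.seed(cfg$seed)
  rng <- cfg$individuals_per_species
  counts <- sample(seq(rng[1L], rng[2L]), cfg$n_species, replace = TRUE)
  sp_tree <- simulate_species_tree(cfg$n_species, cfg$interspecific_depth)
  ind_tree <- .individual_tree(sp_tree, counts, cfg$intraspecific_depth)

  species_of_ind <- sub("_i[0-9]+$", "", ind_tree$tip.label)
  # sections = clades obtained by cutting the species tree at 40% height
  sections <- .cut_sections(sp_tree, frac = 0.4)
  populations <- ifelse(as.integer(sub("^.*_i", "", ind_tree$tip.label)) %% 2L
                        == 1L, "pop1", "pop2")
  metadata <- data.frame(sample_id = ind_tree$tip.label,
                         species = species_of_ind,
                         section = sections[species_of_ind],
                         population = populations,
                         stringsAsFactors = FALSE)

  alignments <- list()
  indel_truth <- integer(nrow(cfg$markers))
  for (k in seq_len(nrow(cfg$markers))) {
    mk <- cfg$markers[k, ]
    aln <- evolve_alignment(ind_tree, mk$length, kappa = cfg$kappa,
                            rate = mk$rate, marker_name = mk$name)
    if (cfg$indel_rate > 0) {
      n_events <- stats::rpois(1L, cfg$indel_rate)
      m <- .insert_indels(unclass(aln), species_of_ind, n_events)
      indel_truth[k] <- length(unique(unlist(apply(m == "-", 1, function(r) {
        rl <- rle(r); e <- cumsum(rl$lengths); s <- e - rl$lengths + 1L
        paste(s[rl$values], e[rl$values], sep = ":")
      }))))
      aln <- aligned_matrix(m, mk$name)
    }
    alignments[[mk$name]] <- aln
  }

  out <- structure(list(
    alignments = alignments,
    metadata = metadata,
    truth = list(species_tree = sp_tree,
                 individual_tree = ind_tree,
                 expected_divergence = setNames(
                   cfg$markers$rate * cfg$interspecific_depth,
                   cfg$markers$name),
                 n_indel_events = setNames(indel_truth, cfg$markers$name)),
    config = cfg
  ), class = "simulated_dataset")
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

# Assign species to monophyletic sections by cutting the ultrametric
# species tree at `frac` of its root-to-tip height.
.cut_sections <- function(sp_tree, frac = 0.4) {
  n <- ape::Ntip(sp_tree)
  depth <- ape::node.depth.edgelength(sp_tree)
  h <- max(depth[seq_len(n)])
  cut <- frac * h
  parent <- integer(n + sp_tree$Nnode)
  parent[sp_tree$edge[, 2L]] <- sp_tree$edge[, 1L]
  sets <- .clade_sets(sp_tree)
  # section roots: nodes strictly below the cut whose parent is at/above it
  roots <- which(vapply(seq_len(n + sp_tree$Nnode), function(nd) {
    nd != n + 1L && depth[nd] > cut && depth[parent[nd]] <= cut
  }, logical(1)))
  section <- character(0)
  for (i in seq_along(roots)) {
    tips <- sets[[roots[i]]]
    section[tips] <- sprintf("sect%02d", i)
  }
  section
}

#' Write a simulated dataset to disk
#'
#' Emits one aligned FASTA per marker, the metadata TSV, the true species
#' tree as newick, and a JSON echo of the configuration — all readable back
#' with [read_alignment()], [read_metadata()] and [read_newick()].
#'
#' @param x A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_dataset <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(x$alignments)) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", nm), ".fasta"))
    write_alignment(x$alignments[[nm]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "metadata.tsv")
  utils::write.table(x$metadata, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tp <- file.path(dir, "species_tree.nwk")
  ape::write.tree(x$truth$species_tree, file = tp)
  cp <- file.path(dir, "config.json")
  cfg <- x$config
  cfg$markers <- as.list(cfg$markers)
  writeLines(.to_json(unclass(cfg)), cp)
  invisible(c(paths, mp, tp, cp))
}

# Minimal JSON serializer for the config echo (atomic vectors and lists).
.to_json <- function(x) {
  if (is.list(x)) {
    items <- vapply(names(x), function(nm)
      sprintf("\"%s\": %s", nm, .to_json(x[[nm]])), character(1))
    paste0("{", paste(items, collapse = ", "), "}")
  } else if (is.character(x)) {
    v <- paste0("\"", gsub("\"", "\\\\\"", x), "\"")
    if (length(v) == 1L) v else paste0("[", paste(v, collapse = ", "), "]")
  } else {
    v <- ifelse(is.na(x), "null", format(x, digits = 15))
    if (length(v) == 1L) v else paste0("[", paste(v, collapse = ", "), "]")
  }
}
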