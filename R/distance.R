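# Pairwise distances (uncorrected p and Kimura 2-parameter), intra/inter
# partitioning and barcoding-gap histograms.

# Encode nucleotides as integers with purines first so that a transition is
# "both codes <= 2 or both >= 3": A=1, G=2, C=3, T=4; everything else
# (gap, N, ambiguity codes) is 0 and excluded by pairwise deletion.
.encode_nt <- function(m) {
  e <- match(m, c("A", "G", "C", "T"))
  e[is.na(e)] <- 0L
  matrix(as.integer(e), nrow = nrow(m), dimnames = dimnames(m))
}

#' Compare one pair of aligned sequences
#'
#' Columns where either sequence carries a gap, N or ambiguity code are
#' excluded (pairwise deletion). Transitions are A<->G and C<->T;
#' transversions all other differing pairs. `P` and `Q` are the transition
#' and transversion proportions of the compared columns.
#'
#' @param a,b Aligned sequences of equal length, as single strings or
#'   character vectors of single characters.
#' @return A list with `n_compared`, `n_transitions`, `n_transversions`,
#'   `P`, `Q`. When no column is comparable, `P` and `Q` are `NA`.
#' @export
compare_pair <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b))
    stop("sequences must have equal aligned length")
  x <- .encode_nt(matrix(toupper(a), nrow = 1L))[1L, ]
  y <- .encode_nt(matrix(toupper(b), nrow = 1L))[1L, ]
  ok <- x > 0L & y > 0L
  n <- sum(ok)
  diff <- ok & x != y
  ts <- sum(diff & ((x <= 2L) == (y <= 2L)))
  tv <- sum(diff) - ts
  list(n_compared = n,
       n_transitions = ts,
       n_transversions = tv,
       P = if (n > 0L) ts / n else NA_real_,
       Q = if (n > 0L) tv / n else NA_real_)
}

#' Uncorrected p-distance from a pairwise comparison
#' @param cmp Result of [compare_pair()].
#' @return The proportion of differing compared sites, or `NA` when no site
#'   is comparable.
#' @export
p_distance <- function(cmp) {
  if (cmp$n_compared == 0L) return(NA_real_)
  (cmp$n_transitions + cmp$n_transversions) / cmp$n_compared
}

#' Kimura 2-parameter distance from a pairwise comparison
#'
#' The standard two-parameter estimator
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)}
#' with transition proportion P and transversion proportion Q. Saturated
#' pairs (either log argument <= 0) are undefined and return `NA`.
#'
#' @param cmp Result of [compare_pair()], or a list with elements `P` and
#'   `Q` (and `n_compared`).
#' @return The K2P distance, or `NA` when undefined.
#' @export
k2p_distance <- function(cmp) {
  if (!is.null(cmp$n_compared) && cmp$n_compared == 0L) return(NA_real_)
  P <- cmp$P
  Q <- cmp$Q
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (is.na(a1) || a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Build a pairwise distance matrix
#'
#' Computes all pairwise distances under the chosen model. With
#' `deletion = "pairwise"` each pair uses the columns where both sequences
#' are unambiguous; with `"complete"` any column containing a gap, N or
#' ambiguity code in any sequence is removed first. Undefined entries
#' (no comparable sites, or K2P saturation) are `NA` — never silently
#' zeroed — and their count is reported in a warning and stored in the
#' `"n_undefined"` attribute.
#'
#' @param x An [aligned_matrix()] with >= 2 rows.
#' @param model `"k2p"` or `"p"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, and attributes `model` and `n_undefined`.
#' @export
build_distance_matrix <- function(x, model = c("k2p", "p"),
                                  deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (nrow(x) < 2L)
    stop("need at least two sequences")
  e <- .encode_nt(unclass(x))
  if (deletion == "complete") {
    keep <- colSums(e == 0L) == 0L
    if (!any(keep))
      stop("complete deletion removed every column")
    e <- e[, keep, drop = FALSE]
  }
  n <- nrow(e)
  d <- matrix(0, n, n, dimnames = list(rownames(e), rownames(e)))
  for (i in seq_len(n - 1L)) {
    xi <- e[i, ]
    others <- (i + 1L):n
    block <- e[others, , drop = FALSE]
    ximat <- matrix(xi, nrow = length(others), ncol = length(xi), byrow = TRUE)
    ok <- ximat > 0L & block > 0L
    nc <- rowSums(ok)
    diff <- ok & ximat != block
    ts <- rowSums(diff & ((ximat <= 2L) == (block <= 2L)))
    nd <- rowSums(diff)
    tv <- nd - ts
    if (model == "p") {
      di <- ifelse(nc > 0L, nd / nc, NA_real_)
    } else {
      P <- ts / nc
      Q <- tv / nc
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      di <- ifelse(nc > 0L & a1 > 0 & a2 > 0,
                   -0.5 * log(pmax(a1, .Machine$double.xmin)) -
                     0.25 * log(pmax(a2, .Machine$double.xmin)),
                   NA_real_)
    }
    d[i, others] <- di
    d[others, i] <- di
  }
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0L)
    warning(n_undef, " pairwise distance(s) undefined (saturation or no ",
            "comparable sites); entries set to NA")
  attr(d, "model") <- model
  attr(d, "n_undefined") <- n_undef
  d
}

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Splits the upper triangle of a distance matrix into within-group
#' (intraspecific) and between-group (interspecific) pairs, computing per
#' group the maximum intraspecific distance (undefined for singletons) and
#' minimum interspecific distance, plus dataset-level means over all defined
#' pairs. Undefined (`NA`) distances are excluded and tallied.
#'
#' @param dm Distance matrix from [build_distance_matrix()].
#' @param part A [make_partition()] result covering every sample in `dm`.
#' @return A list of class `group_distance_summary`: `groups` (data.frame
#'   with group, n_members, max_intra, min_inter), `mean_intra`,
#'   `mean_inter`, pair counts and the number of dropped undefined pairs.
#' @export
partition_distances <- function(dm, part) {
  ids <- rownames(dm)
  membership <- rep(names(part), lengths(part))
  names(membership) <- unlist(part, use.names = FALSE)
  missing_ids <- setdiff(ids, names(membership))
  if (length(missing_ids))
    stop("sample(s) missing from partition: ",
         paste(missing_ids, collapse = ", "))
  grp <- membership[ids]
  ut <- upper.tri(dm)
  same <- outer(grp, grp, "==")
  intra_all <- dm[ut & same]
  inter_all <- dm[ut & !same]
  n_dropped <- sum(is.na(intra_all)) + sum(is.na(inter_all))
  intra <- intra_all[!is.na(intra_all)]
  inter <- inter_all[!is.na(inter_all)]
  groups <- lapply(names(part), function(g) {
    members <- intersect(ids, part[[g]])
    idx <- match(members, ids)
    k <- length(idx)
    if (k >= 2L) {
      w <- dm[idx, idx, drop = FALSE][upper.tri(matrix(0, k, k))]
      w <- w[!is.na(w)]
      max_intra <- if (length(w)) max(w) else NA_real_
    } else max_intra <- NA_real_
    b <- dm[idx, -idx, drop = FALSE]
    b <- b[!is.na(b)]
    min_inter <- if (length(b)) min(b) else NA_real_
    data.frame(group = g, n_members = k, max_intra = max_intra,
               min_inter = min_inter, stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, groups)
  structure(list(
    groups = groups,
    mean_intra = if (length(intra)) mean(intra) else NA_real_,
    mean_inter = if (length(inter)) mean(inter) else NA_real_,
    n_intra_pairs = length(intra),
    n_inter_pairs = length(inter),
    n_dropped = n_dropped,
    level = attr(part, "level")
  ), class = "group_distance_summary")
}

#' @export
print.group_distance_summary <- function(x, ...) {
  cat(sprintf(paste0("group_distance_summary (%s level): %d groups; ",
                     "mean intra %.4f (%d pairs), mean inter %.4f (%d pairs)",
                     "%s\n"),
              x$level, nrow(x$groups), x$mean_intra, x$n_intra_pairs,
              x$mean_inter, x$n_inter_pairs,
              if (x$n_dropped) sprintf("; %d undefined pair(s) dropped",
                                       x$n_dropped) else ""))
  invisible(x)
}

#' Barcoding-gap histogram series
#'
#' Bins intraspecific and interspecific pairwise distances into intervals
#' `[k*w, (k+1)*w)`. Undefined distances are excluded and counted in the
#' `"n_dropped"` attribute.
#'
#' @param dm Distance matrix.
#' @param part Partition of its samples.
#' @param bin_width Positive bin width `w`.
#' @return A data.frame with columns `bin_start`, `intra_count`,
#'   `inter_count`, covering bin 0 up to the last non-empty bin.
#' @export
gap_histogram <- function(dm, part, bin_width = 0.005) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("'bin_width' must be positive")
  ids <- rownames(dm)
  membership <- rep(names(part), lengths(part))
  names(membership) <- unlist(part, use.names = FALSE)
  grp <- membership[ids]
  ut <- upper.tri(dm)
  same <- outer(grp, grp, "==")
  intra <- dm[ut & same]
  inter <- dm[ut & !same]
  n_dropped <- sum(is.na(intra)) + sum(is.na(inter))
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  vals <- c(intra, inter)
  n_bins <- if (length(vals)) max(floor(vals / bin_width)) + 1L else 0L
  bin_start <- (seq_len(n_bins) - 1L) * bin_width
  count_in <- function(v) {
    if (!length(v)) return(integer(n_bins))
    tabulate(floor(v / bin_width) + 1L, nbins = n_bins)
  }
  out <- data.frame(bin_start = bin_start,
                    intra_count = count_in(intra),
                    inter_count = count_in(inter))
  attr(out, "n_dropped") <- n_dropped
  out
}
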