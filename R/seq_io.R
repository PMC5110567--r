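# Input/output for aligned sequence sets, sample metadata and trees.

# IUPAC nucleotide alphabet accepted in alignments (after uppercasing;
# U is mapped to T on construction).
.iupac_alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N", "-", "?")

#' Construct an aligned sequence matrix
#'
#' An `aligned_matrix` is a character matrix with one row per sample and one
#' column per alignment position, carrying the marker name as an attribute.
#' Characters are uppercased and `U` is mapped to `T`; rownames are the
#' sample ids.
#'
#' @param x Character matrix of single characters (rows = samples), with
#'   unique non-empty rownames.
#' @param marker_name Name of the marker (or "+"-joined combination).
#' @return An object of class `aligned_matrix`.
#' @export
aligned_matrix <- function(x, marker_name) {
  if (!is.matrix(x) || !is.character(x))
    stop("'x' must be a character matrix")
  if (ncol(x) < 1L)
    stop("alignment must have at least one column")
  ids <- rownames(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all rows must carry a non-empty sample id")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  bad <- setdiff(unique(as.vector(x)), .iupac_alphabet)
  if (length(bad))
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "))
  structure(x, marker = marker_name, class = c("aligned_matrix", "matrix"))
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("aligned_matrix '%s': %d samples x %d columns\n",
              marker_name(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Marker name of an aligned matrix
#' @param x An `aligned_matrix`.
#' @return The marker name attribute.
#' @export
marker_name <- function(x) attr(x, "marker", exact = TRUE)

#' Read an aligned FASTA file
#'
#' All records must have the same length (the file must already be aligned;
#' this package never aligns). Record ids become sample ids.
#'
#' @param path Path to an aligned FASTA file.
#' @param marker_name Marker name to attach.
#' @return An [aligned_matrix()].
#' @export
read_alignment <- function(path, marker_name) {
  recs <- tryCatch(seqinr::read.fasta(path, seqtype = "DNA",
                                      forceDNAtolower = FALSE,
                                      set.attributes = FALSE),
                   error = function(e) stop("empty or unreadable FASTA ",
                                            "file: ", path))
  if (length(recs) == 0L)
    stop("empty FASTA file: ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("not aligned: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ") in ", path)
  if (anyDuplicated(names(recs)))
    stop("duplicate sequence ids in ", path)
  m <- do.call(rbind, recs)
  rownames(m) <- names(recs)
  aligned_matrix(m, marker_name)
}

#' Write an aligned matrix as FASTA
#' @param x An `aligned_matrix`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(x, path) {
  m <- unclass(x)
  seqinr::write.fasta(lapply(seq_len(nrow(m)), function(i) m[i, ]),
                      names = rownames(m), file.out = path, nbchar = 80)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with a header; columns `sample_id` and `species` are
#' required, `section` and `population` optional (filled with `""` when
#' absent). Fields are whitespace-trimmed.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns sample_id, species, section, population.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  required <- c("sample_id", "species")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("section", "population"))
    if (is.null(df[[col]])) df[[col]] <- ""
  df <- df[, c("sample_id", "species", "section", "population")]
  df[] <- lapply(df, trimws)
  if (any(!nzchar(df$sample_id)))
    stop("empty sample_id in metadata")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!nzchar(df$species)))
    stop("empty species label for sample(s): ",
         paste(df$sample_id[!nzchar(df$species)], collapse = ", "))
  df
}

#' Build a species or section partition
#'
#' Groups sample ids by their species (or section) label. Samples with an
#' empty label at the requested level are dropped with a warning; empty
#' groups are never returned.
#'
#' @param records Metadata data.frame as returned by [read_metadata()].
#' @param level `"species"` or `"section"`.
#' @param restrict_to Optional character vector of sample ids; the partition
#'   is restricted to these. Every id must appear in `records`.
#' @return A named list of character vectors (class `species_partition`),
#'   one element per group, with the level stored as an attribute.
#' @export
make_partition <- function(records, level = c("species", "section"),
                           restrict_to = NULL) {
  level <- match.arg(level)
  ids <- records$sample_id
  if (!is.null(restrict_to)) {
    unknown <- setdiff(restrict_to, ids)
    if (length(unknown))
      stop("sample id(s) absent from metadata: ",
           paste(unknown, collapse = ", "))
    keep <- ids %in% restrict_to
    records <- records[keep, , drop = FALSE]
  }
  lab <- records[[level]]
  empty <- !nzchar(lab)
  if (any(empty)) {
    warning(sum(empty), " sample(s) without a ", level,
            " label dropped from partition")
    records <- records[!empty, , drop = FALSE]
    lab <- lab[!empty]
  }
  groups <- split(records$sample_id, lab)
  structure(groups, level = level, class = c("species_partition", "list"))
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("species_partition (%s level): %d groups, %d samples\n",
              attr(x, "level"), length(x), sum(lengths(x))))
  invisible(x)
}

#' Concatenate marker alignments over shared samples
#'
#' Multi-locus supermatrix by strict intersection: only samples present in
#' every input alignment are kept (no missing-data padding); columns are
#' joined in the given marker order. The resulting marker name joins the
#' input names with `"+"`.
#'
#' @param matrices List of `aligned_matrix` objects (>= 2).
#' @return An [aligned_matrix()] with `sum(n_columns)` columns.
#' @export
concatenate_markers <- function(matrices) {
  if (length(matrices) < 2L)
    stop("need at least two alignments to concatenate")
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (length(shared) == 0L)
    stop("no samples shared by all input alignments")
  # keep the sample order of the first alignment
  shared <- rownames(matrices[[1L]])[rownames(matrices[[1L]]) %in% shared]
  blocks <- lapply(matrices, function(m) unclass(m)[shared, , drop = FALSE])
  combined <- do.call(cbind, blocks)
  name <- paste(vapply(matrices, marker_name, character(1)), collapse = "+")
  aligned_matrix(combined, name)
}

# Quote a label for newick if it contains metacharacters.
.newick_label <- function(x) {
  needs <- grepl("[][(){}:;,'\" \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

# Undo .newick_label: strip surrounding single quotes, unescape doubled ones.
.strip_newick_quotes <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Write a tree to a newick file
#'
#' Branch lengths are kept at full double precision; bootstrap supports, when
#' present as node labels, are written as internal-node labels. Leaf labels
#' containing newick metacharacters are quoted.
#'
#' @param tree An object of class `phylo` (>= 3 leaves).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo"))
    stop("'tree' must be a phylo object")
  if (ape::Ntip(tree) < 3L)
    stop("tree must have at least 3 leaves")
  labels <- tree$tip.label
  # placeholders survive write.tree untouched; quoted originals go in after
  tokens <- sprintf("bgTIP%06d", seq_along(labels))
  tree$tip.label <- tokens
  nwk <- ape::write.tree(tree)
  quoted <- .newick_label(labels)
  for (i in seq_along(tokens))
    nwk <- sub(tokens[i], quoted[i], nwk, fixed = TRUE)
  writeLines(nwk, path)
  invisible(path)
}

#' Read a newick tree
#'
#' Quoted leaf labels are unquoted after parsing.
#'
#' @param path Path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  tree$tip.label <- .strip_newick_quotes(tree$tip.label)
  tree
}
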