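# In-code fixtures shared across test files.

# Aligned matrix from named sequence strings.
aln_from_strings <- function(seqs, marker = "toy") {
  m <- do.call(rbind, strsplit(unname(unlist(seqs)), ""))
  rownames(m) <- names(seqs)
  aligned_matrix(m, marker)
}

# Random clean (gap-free) alignment.
random_alignment <- function(n, L, seed = 1,
                             ids = sprintf("s%02d", seq_len(n)),
                             marker = "rand") {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(m) <- ids
  aligned_matrix(m, marker)
}

# Write named sequences as a FASTA file; returns the path.
write_fasta_text <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(mapply(function(id, s) c(paste0(">", id), s),
                         names(seqs), seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# Metadata data.frame from a sample->species mapping.
toy_metadata <- function(species, section = NULL, population = NULL) {
  data.frame(sample_id = names(species),
             species = unname(unlist(species)),
             section = if (is.null(section)) "" else unname(section),
             population = if (is.null(population)) "" else unname(population),
             stringsAsFactors = FALSE)
}

# Symmetric distance matrix from pair values: ids, and a function or matrix.
dist_from_pairs <- function(ids, value_fun) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- value_fun(ids[i], ids[j])
    d[i, j] <- v
    d[j, i] <- v
  }
  d
}
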