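# Per-marker alignment statistics: variable sites, indel events, summary rows.

#' Count variable (SNP) sites in an alignment
#'
#' A column is variable when at least two distinct unambiguous nucleotides
#' (A, C, G, T) occur in it. Gaps, N and IUPAC ambiguity codes never count
#' toward polymorphism.
#'
#' @param x An [aligned_matrix()] with >= 2 rows.
#' @return Integer count of variable columns.
#' @export
count_variable_sites <- function(x) {
  if (nrow(x) < 2L)
    stop("need at least two sequences to assess variability")
  m <- unclass(x)
  present <- vapply(c("A", "C", "G", "T"),
                    function(b) colSums(m == b) > 0L,
                    logical(ncol(m)))
  if (ncol(m) == 1L) present <- matrix(present, nrow = 1L)
  sum(rowSums(present) >= 2L)
}

#' Count indel events in an alignment
#'
#' An indel event is a maximal run of consecutive gap columns within one row,
#' identified by its (start, end) column span; identical spans occurring in
#' several rows count once (`method = "events"`, the default, matching how
#' population-genetics software reports indel events). With
#' `method = "columns"` the count is instead the number of columns containing
#' at least one gap.
#'
#' @param x An [aligned_matrix()] with >= 2 rows.
#' @param method `"events"` (deduplicated spans) or `"columns"`.
#' @return Integer count (0 when the alignment has no gap character).
#' @export
count_indel_events <- function(x, method = c("events", "columns")) {
  method <- match.arg(method)
  if (nrow(x) < 2L)
    stop("need at least two sequences to assess indels")
  g <- unclass(x) == "-"
  if (method == "columns")
    return(sum(colSums(g) > 0L))
  spans <- character(0)
  for (i in seq_len(nrow(g))) {
    r <- rle(g[i, ])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    spans <- c(spans, paste(starts[r$values], ends[r$values], sep = ":"))
  }
  length(unique(spans))
}

#' Assemble a marker summary row
#'
#' One row of the marker-evaluation table: aligned length, number of variable
#' sites, percent variable sites (2 decimals), indel events, dataset mean
#' inter- and intraspecific distances (4 decimals), and the two
#' discrimination rates.
#'
#' @param x An [aligned_matrix()].
#' @param dist_summary Optional [partition_distances()] result supplying the
#'   dataset means.
#' @param rate_pwg,rate_nj Optional discrimination rates in percent.
#' @return A one-row data.frame.
#' @export
marker_summary <- function(x, dist_summary = NULL,
                           rate_pwg = NA_real_, rate_nj = NA_real_) {
  n_snps <- count_variable_sites(x)
  len <- ncol(x)
  data.frame(
    marker = marker_name(x),
    aligned_length = len,
    n_snps = n_snps,
    pct_snp = round(100 * n_snps / len, 2),
    n_indels = count_indel_events(x),
    mean_inter = if (is.null(dist_summary)) NA_real_ else
      round(dist_summary$mean_inter, 4),
    mean_intra = if (is.null(dist_summary)) NA_real_ else
      round(dist_summary$mean_intra, 4),
    rate_pwg = rate_pwg,
    rate_nj = rate_nj,
    stringsAsFactors = FALSE
  )
}
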