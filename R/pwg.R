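# PWG-distance discrimination criterion and the discrimination-rate statistic.

#' Decide discrimination of one group under the PWG-distance criterion
#'
#' A group is discriminated when the minimum interspecific distance involving
#' it is strictly larger than its maximum intraspecific distance. Ties fail.
#' Singletons have no intraspecific distance; with
#' `singleton_policy = "exclude"` (default) they are flagged
#' `singleton_excluded` and omitted from the rate denominator, with
#' `"zero_intra"` their maximum intraspecific distance is taken as 0.
#'
#' @param summary A list or one-row data.frame with `group` (label),
#'   `n_members`, `max_intra`, `min_inter` — one row of
#'   [partition_distances()]`$groups`.
#' @param singleton_policy `"exclude"` or `"zero_intra"`.
#' @return A one-row data.frame: group, n_members, max_intra, min_inter,
#'   discriminated, reason (`gap_present`, `gap_absent`,
#'   `singleton_excluded` or `undefined_distances`).
#' @export
pwg_decide <- function(summary, singleton_policy = c("exclude", "zero_intra")) {
  singleton_policy <- match.arg(singleton_policy)
  g <- summary$group
  k <- summary$n_members
  max_intra <- summary$max_intra
  min_inter <- summary$min_inter
  if (is.na(min_inter)) {
    warning("group '", g, "': all interspecific distances undefined; excluded")
    return(data.frame(group = g, n_members = k, max_intra = max_intra,
                      min_inter = NA_real_, discriminated = FALSE,
                      reason = "undefined_distances",
                      stringsAsFactors = FALSE))
  }
  if (k == 1L) {
    if (singleton_policy == "exclude")
      return(data.frame(group = g, n_members = k, max_intra = NA_real_,
                        min_inter = min_inter, discriminated = FALSE,
                        reason = "singleton_excluded",
                        stringsAsFactors = FALSE))
    max_intra <- 0
  }
  if (is.na(max_intra)) {
    # >= 2 members but every within-group pair undefined
    warning("group '", g, "': all intraspecific distances undefined; excluded")
    return(data.frame(group = g, n_members = k, max_intra = NA_real_,
                      min_inter = min_inter, discriminated = FALSE,
                      reason = "undefined_distances",
                      stringsAsFactors = FALSE))
  }
  disc <- min_inter > max_intra  # strict: ties are not discriminated
  data.frame(group = g, n_members = k, max_intra = max_intra,
             min_inter = min_inter, discriminated = disc,
             reason = if (disc) "gap_present" else "gap_absent",
             stringsAsFactors = FALSE)
}

#' Apply the PWG criterion to every group of a partition
#'
#' @param dm Distance matrix (the criterion is classically applied to
#'   uncorrected p-distances).
#' @param part Partition of the samples in `dm`.
#' @param singleton_policy See [pwg_decide()].
#' @return A data.frame of per-group decisions with the achieved
#'   discrimination rate (percent) in the `"rate"` attribute.
#' @export
pwg_evaluate <- function(dm, part,
                         singleton_policy = c("exclude", "zero_intra")) {
  singleton_policy <- match.arg(singleton_policy)
  ds <- partition_distances(dm, part)
  rows <- lapply(seq_len(nrow(ds$groups)), function(i)
    pwg_decide(ds$groups[i, ], singleton_policy))
  decisions <- do.call(rbind, rows)
  attr(decisions, "rate") <- discrimination_rate(decisions)
  decisions
}

#' Discrimination rate
#'
#' Percentage of groups passing a discrimination criterion among those that
#' could be tested: groups excluded as singletons or for undefined distances
#' do not enter the denominator.
#'
#' @param decisions A data.frame with logical `discriminated` and character
#'   `reason` columns ([pwg_decide()] / [tree_discriminate()] rows).
#' @return The rate in percent (unrounded).
#' @export
discrimination_rate <- function(decisions) {
  excluded <- decisions$reason %in% c("singleton_excluded",
                                      "undefined_distances")
  n <- sum(!excluded)
  if (n == 0L)
    stop("no groups eligible for the discrimination rate")
  100 * sum(decisions$discriminated[!excluded]) / n
}
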