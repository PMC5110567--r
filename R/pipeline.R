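# Orchestration: evaluate every marker and combination with both
# discrimination criteria at species and section level, and render reports.

#' Evaluation configuration
#'
#' @param markers Named list of [aligned_matrix()] objects, or a named
#'   character vector of aligned-FASTA paths (names are the marker names).
#' @param metadata Metadata data.frame ([read_metadata()] schema) or a TSV
#'   path.
#' @param combinations List of character vectors of marker names to
#'   concatenate (strict sample intersection), e.g.
#'   `list(c("rbcL","matK"))`. Empty for single markers only.
#' @param pwg_model Distance model for the PWG criterion (default
#'   uncorrected `"p"`, per the classic formulation; `"k2p"` available).
#' @param tree_model Distance model for NJ trees and the summary-table
#'   means (default `"k2p"`).
#' @param deletion Site-deletion mode for distances.
#' @param bootstrap Number of bootstrap replicates.
#' @param support_threshold Bootstrap support that a clade must strictly
#'   exceed to count as discriminated.
#' @param singleton_policy Shared singleton handling for both criteria.
#' @param bin_width Barcoding-gap histogram bin width.
#' @param levels Grouping levels to evaluate; `"section"` is skipped when the
#'   metadata has no section labels.
#' @param seed Master seed; each unit derives its bootstrap seed from it.
#' @return A list of class `evaluation_config`.
#' @export
evaluation_config <- function(markers, metadata, combinations = list(),
                              pwg_model = c("p", "k2p"),
                              tree_model = c("k2p", "p"),
                              deletion = c("pairwise", "complete"),
                              bootstrap = 1000L,
                              support_threshold = 0.5,
                              singleton_policy = c("exclude", "zero_intra"),
                              bin_width = 0.005,
                              levels = c("species", "section"),
                              seed = 1L) {
  if (is.character(markers)) {
    if (is.null(names(markers)) || any(!nzchar(names(markers))))
      stop("marker file paths must be named by marker")
    markers <- mapply(read_alignment, markers, names(markers),
                      SIMPLIFY = FALSE)
  }
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    stop("'markers' must be a named list")
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (bootstrap < 1L) stop("'bootstrap' must be >= 1")
  bad <- unlist(lapply(combinations, setdiff, names(markers)))
  if (length(bad))
    stop("combination references undeclared marker(s): ",
         paste(unique(bad), collapse = ", "))
  structure(list(markers = markers, metadata = metadata,
                 combinations = combinations,
                 pwg_model = match.arg(pwg_model),
                 tree_model = match.arg(tree_model),
                 deletion = match.arg(deletion),
                 bootstrap = as.integer(bootstrap),
                 support_threshold = support_threshold,
                 singleton_policy = match.arg(singleton_policy),
                 bin_width = bin_width,
                 levels = match.arg(levels, several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "evaluation_config")
}

# Evaluate one unit (a single marker or concatenation) at every level.
.evaluate_unit <- function(aln, cfg, unit_seed) {
  meta <- cfg$metadata[cfg$metadata$sample_id %in% rownames(aln), ,
                       drop = FALSE]
  unknown <- setdiff(rownames(aln), meta$sample_id)
  if (length(unknown))
    stop("sample(s) without metadata: ", paste(unknown, collapse = ", "))
  dm_tree <- build_distance_matrix(aln, model = cfg$tree_model,
                                   deletion = cfg$deletion)
  dm_pwg <- if (cfg$pwg_model == cfg$tree_model) dm_tree else
    build_distance_matrix(aln, model = cfg$pwg_model,
                          deletion = cfg$deletion)
  tree <- NULL
  tree_error <- NULL
  if (anyNA(dm_tree)) {
    tree_error <- "undefined distances: NJ tree skipped"
  } else {
    tree <- bootstrap_supports(aln, model = cfg$tree_model,
                               B = cfg$bootstrap, seed = unit_seed,
                               deletion = cfg$deletion)
  }
  levels <- cfg$levels
  if ("section" %in% levels && !any(nzchar(meta$section)))
    levels <- setdiff(levels, "section")
  per_level <- list()
  for (lv in levels) {
    part <- suppressWarnings(
      make_partition(meta, lv, restrict_to = rownames(aln)))
    covered <- unlist(part, use.names = FALSE)
    dmp <- dm_pwg[covered, covered, drop = FALSE]
    dmt <- dm_tree[covered, covered, drop = FALSE]
    dist_summary <- partition_distances(dmt, part)
    pwg <- pwg_evaluate(dmp, part, cfg$singleton_policy)
    hist <- gap_histogram(dmt, part, cfg$bin_width)
    tree_dec <- NULL
    if (!is.null(tree) && setequal(covered, tree$tip.label)) {
      tree_dec <- tree_discriminate(tree, part, cfg$support_threshold,
                                    cfg$singleton_policy)
    } else if (!is.null(tree)) {
      sub <- ape::keep.tip(tree, covered)
      tree_dec <- tree_discriminate(sub, part, cfg$support_threshold,
                                    cfg$singleton_policy)
    }
    per_level[[lv]] <- list(partition = part,
                            dist_summary = dist_summary,
                            pwg_decisions = pwg,
                            rate_pwg = attr(pwg, "rate"),
                            tree_decisions = tree_dec,
                            rate_nj = if (is.null(tree_dec)) NA_real_ else
                              attr(tree_dec, "rate"),
                            histogram = hist)
  }
  list(alignment = aln, dm = dm_tree, tree = tree, tree_error = tree_error,
       levels = per_level)
}

#' Run the full marker evaluation
#'
#' For each unit (every single marker plus every requested combination):
#' alignment statistics, K2P/p distance matrices, barcoding-gap histogram,
#' PWG decisions and rate, NJ tree with bootstrap supports, and tree-based
#' decisions and rate — at species level and, when section labels exist, at
#' section level. A unit that fails (e.g. saturated distances) is recorded
#' with its error message rather than silently reported as zero.
#'
#' @param cfg An [evaluation_config()].
#' @return A list of class `discrimination_report` with elements `summary`
#'   (data.frame, one row per unit x level), `units` (detailed results) and
#'   `config`.
#' @export
run_evaluation <- function(cfg) {
  if (!inherits(cfg, "evaluation_config"))
    stop("'cfg' must be an evaluation_config")
  units <- c(as.list(names(cfg$markers)), cfg$combinations)
  unit_names <- vapply(units, paste, character(1), collapse = "+")
  results <- list()
  rows <- list()
  for (u in seq_along(units)) {
    nm <- unit_names[u]
    aln <- if (length(units[[u]]) == 1L) cfg$markers[[units[[u]]]] else
      concatenate_markers(cfg$markers[units[[u]]])
    unit_seed <- (cfg$seed + 101L * u) %% .Machine$integer.max
    res <- tryCatch(.evaluate_unit(aln, cfg, unit_seed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      results[[nm]] <- list(error = conditionMessage(res))
      next
    }
    results[[nm]] <- res
    for (lv in names(res$levels)) {
      l <- res$levels[[lv]]
      row <- marker_summary(aln, l$dist_summary,
                            rate_pwg = round(l$rate_pwg, 2),
                            rate_nj = round(l$rate_nj, 2))
      row <- cbind(data.frame(unit = nm, level = lv,
                              n_samples = nrow(aln),
                              n_groups = length(l$partition),
                              stringsAsFactors = FALSE),
                   row[, -1])
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 units = results,
                 config = cfg),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("discrimination_report:", length(x$units), "unit(s)\n")
  print(x$summary)
  invisible(x)
}

#' Write report files
#'
#' Emits the summary TSV (marker-evaluation-table schema), per-unit decision
#' TSVs for both criteria and both levels, barcoding-gap histogram TSVs,
#' newick trees with bootstrap supports, and a run log recording the
#' configuration, seed, package version and dropped/undefined-pair counts.
#'
#' @param report A [run_evaluation()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
render_reports <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- character(0)
  paths <- c(paths, tsv(report$summary, file.path(outdir, "summary.tsv")))
  log_lines <- c(sprintf("barcodegap %s",
                         as.character(utils::packageVersion("barcodegap"))),
                 sprintf("seed: %d", report$config$seed),
                 sprintf("bootstrap replicates: %d", report$config$bootstrap),
                 sprintf("pwg model: %s; tree model: %s; deletion: %s",
                         report$config$pwg_model, report$config$tree_model,
                         report$config$deletion),
                 sprintf("support threshold: %g; singleton policy: %s",
                         report$config$support_threshold,
                         report$config$singleton_policy))
  for (nm in names(report$units)) {
    res <- report$units[[nm]]
    safe <- gsub("[^A-Za-z0-9._+-]", "_", nm)
    if (!is.null(res$error)) {
      log_lines <- c(log_lines, sprintf("unit %s: FAILED (%s)", nm, res$error))
      next
    }
    if (!is.null(res$tree))
      paths <- c(paths, write_newick(res$tree,
                                     file.path(outdir, paste0(safe, ".nwk"))))
    if (!is.null(res$tree_error))
      log_lines <- c(log_lines, sprintf("unit %s: %s", nm, res$tree_error))
    for (lv in names(res$levels)) {
      l <- res$levels[[lv]]
      paths <- c(paths,
                 tsv(l$pwg_decisions,
                     file.path(outdir, sprintf("%s_pwg_%s.tsv", safe, lv))),
                 tsv(l$histogram,
                     file.path(outdir, sprintf("%s_hist_%s.tsv", safe, lv))))
      if (!is.null(l$tree_decisions))
        paths <- c(paths,
                   tsv(l$tree_decisions,
                       file.path(outdir, sprintf("%s_tree_%s.tsv", safe, lv))))
      log_lines <- c(log_lines,
                     sprintf("unit %s (%s): %d undefined pair(s) dropped",
                             nm, lv, l$dist_summary$n_dropped))
    }
  }
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(c(paths, log_path))
}
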