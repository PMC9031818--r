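#' Compute the functional-load trait table from raw lexicons
#'
#' Full ingestion path: profiles every language's lexicon, applies the
#' inclusion filters (strictly more than `min_instances` domain instances
#' and an attested tonic length contrast), and computes the six FL
#' variables for the retained languages. Excluded languages are reported,
#' not fatal; the exclusion log and the output table partition the input
#' language set.
#'
#' @param lexicons `data.frame` with `language_id` and `form` columns (see
#'   [read_lexicons()]), or a path to a lexicon TSV.
#' @param tables a shared [segment_table()], a named list of tables per
#'   language, or a path to a segment-table CSV.
#' @param min_instances inclusion threshold (kept if `n_instances` exceeds
#'   it).
#' @param segmented whether forms are space-delimited segments (`TRUE`) or
#'   contiguous strings to tokenize.
#' @return List with `fl` (the trait table, see [functional_load_table()]),
#'   `excluded` (`data.frame` with `language_id`, `reason`), and `profiles`
#'   (all per-language [domain_profile()]s, named by language).
#' @export
compute_fl <- function(lexicons, tables, min_instances = 200L,
                       segmented = TRUE) {
  if (is.character(lexicons)) lexicons <- read_lexicons(lexicons)
  if (is.character(tables)) tables <- read_segment_table(tables)
  by_lang <- split(lexicons$form, lexicons$language_id)
  profiles <- lapply(names(by_lang), function(id) {
    domain_profile(by_lang[[id]], table_for(tables, id), language_id = id,
                   segmented = segmented)
  })
  names(profiles) <- names(by_lang)
  reasons <- vapply(profiles, function(p) {
    language_exclusion_reason(p, table_for(tables, p$language_id),
                              min_instances)
  }, character(1L))
  keep <- is.na(reasons)
  excluded <- data.frame(language_id = names(profiles)[!keep],
                         reason = unname(reasons[!keep]),
                         stringsAsFactors = FALSE)
  for (i in which(!keep))
    message("excluding '", names(profiles)[i], "': ", reasons[i])
  fl <- if (any(keep)) functional_load_table(profiles[keep], tables) else NULL
  list(fl = fl, excluded = excluded, profiles = profiles)
}

#' Read a precomputed functional-load trait table
#'
#' Ingestion mode for published per-language FL values (CSV with
#' `language_id` and any of the columns `FLVu`, `FLCu`, `FLPu`, `FLVn`,
#' `FLCn`, `FLPn`): the table passes through unchanged into the statistical
#' studies, so downstream results can be reproduced without raw lexicons.
#'
#' @param path CSV path.
#' @return A trait `data.frame`.
#' @export
read_fl_table <- function(path) {
  fl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"language_id" %in% names(fl))
    stop("FL table needs a 'language_id' column", call. = FALSE)
  if (anyDuplicated(fl$language_id))
    stop("duplicated language_id in FL table", call. = FALSE)
  fl$language_id <- trimws(fl$language_id)
  fl
}

#' Study 1: phylogenetic signal summary over a tree sample
#'
#' Runs [signal_over_sample()] for each requested FL variable and gathers
#' the per-trait mean and standard deviation of Blomberg's K and the
#' maximum permutation p across trees.
#'
#' @param fl_table trait table (see [compute_fl()] or [read_fl_table()]).
#' @param trees `multiPhylo` tree sample.
#' @param traits trait columns to analyse (defaults to all six FL
#'   variables present in the table).
#' @param n_perm permutations per tree.
#' @param seed integer seed.
#' @param out optional directory: writes `study1_summary.csv` and the
#'   per-tree `study1_per_tree.csv`.
#' @return `data.frame` with columns `trait`, `mean_K`, `sd_K`, `max_p`,
#'   `n_perm`, `seed`; per-tree results in attribute `"per_tree"`.
#' @export
run_study1 <- function(fl_table, trees, traits = NULL, n_perm = 999L,
                       seed = NULL, out = NULL) {
  traits <- traits %||%
    intersect(c("FLVu", "FLCu", "FLPu", "FLVn", "FLCn", "FLPn"),
              names(fl_table))
  res <- lapply(traits, function(tr) {
    message("study 1: signal in ", tr)
    signal_over_sample(tr, fl_table, trees, n_perm = n_perm, seed = seed)
  })
  summary <- do.call(rbind, lapply(res, function(r) {
    data.frame(trait = r$trait, mean_K = r$mean_K, sd_K = r$sd_K,
               max_p = r$max_p, n_perm = r$n_perm,
               seed = r$seed %||% NA_integer_, stringsAsFactors = FALSE)
  }))
  per_tree <- do.call(rbind, lapply(res, as.data.frame))
  attr(summary, "per_tree") <- per_tree
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out, "study1_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(per_tree, file.path(out, "study1_per_tree.csv"),
                     row.names = FALSE)
  }
  summary
}

#' Study 2: phylogenetic correlations summary over a tree sample
#'
#' Runs [correlate_over_sample()] for each trait pair and gathers the
#' posterior-mean correlation, its equal-tail 95% interval over trees, and
#' the p value at the posterior mean.
#'
#' @param fl_table trait table.
#' @param trees `multiPhylo` tree sample.
#' @param pairs list of length-2 character vectors; defaults to the four
#'   pairs contrasting vowel-length FL with consonant manner and place FL,
#'   unnormalized and normalized.
#' @param out optional directory: writes `study2_summary.csv` and
#'   `study2_per_tree.csv`.
#' @return `data.frame` with columns `pair`, `r_mean`, `ci_low`, `ci_high`,
#'   `p`, `df`; per-tree correlations in attribute `"per_tree"`.
#' @export
run_study2 <- function(fl_table, trees, pairs = NULL, out = NULL) {
  pairs <- pairs %||% list(c("FLVu", "FLCu"), c("FLVu", "FLPu"),
                           c("FLVn", "FLCn"), c("FLVn", "FLPn"))
  pairs <- Filter(function(p) all(p %in% names(fl_table)), pairs)
  res <- lapply(pairs, function(p) {
    message("study 2: correlation ", p[1L], " ~ ", p[2L])
    correlate_over_sample(p[1L], p[2L], fl_table, trees)
  })
  summary <- do.call(rbind, lapply(res, function(r) {
    data.frame(pair = paste(r$pair, collapse = ":"), r_mean = r$r_mean,
               ci_low = r$ci[1L], ci_high = r$ci[2L], p = r$p, df = r$df,
               stringsAsFactors = FALSE)
  }))
  per_tree <- do.call(rbind, lapply(res, as.data.frame))
  attr(summary, "per_tree") <- per_tree
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out, "study2_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(per_tree, file.path(out, "study2_per_tree.csv"),
                     row.names = FALSE)
  }
  summary
}

#' Read a pipeline run configuration
#'
#' YAML mirror of the [run_all()] arguments. Exactly one of `lexicons`
#' (+ `segment_table`) or `fl_table` must be supplied as the trait source.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  has_lex <- !is.null(cfg$lexicons)
  has_fl <- !is.null(cfg$fl_table)
  if (has_lex == has_fl)
    stop("config must supply exactly one of 'lexicons' or 'fl_table'",
         call. = FALSE)
  if (has_lex && is.null(cfg$segment_table))
    stop("raw-lexicon mode needs 'segment_table'", call. = FALSE)
  if (is.null(cfg$trees)) stop("config needs 'trees'", call. = FALSE)
  cfg$n_perm <- as.integer(cfg$n_perm %||% 999L)
  cfg$min_instances <- as.integer(cfg$min_instances %||% 200L)
  cfg$segmented <- isTRUE(cfg$segmented %||% TRUE)
  cfg
}

#' Run both studies end to end
#'
#' Orchestrates the whole analysis from a configuration (list or YAML
#' path): trait source (raw lexicons or a precomputed FL table), tree
#' sample, Study 1 signal summary, Study 2 correlation summary. Outputs are
#' deterministic given the configuration and seed; the seed is recorded in
#' the written metadata.
#'
#' @param config configuration list or YAML path (see [read_run_config()]).
#' @param seed integer seed (overrides `config$seed`).
#' @param out output directory (overrides `config$out`); created if needed.
#' @return List with `fl`, `excluded`, `study1`, `study2` (invisibly if
#'   `out` is given).
#' @export
run_all <- function(config, seed = NULL, out = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
  else validate_run_config(config)
  seed <- seed %||% cfg$seed
  out <- out %||% cfg$out
  if (!is.null(cfg$fl_table)) {
    fl <- if (is.character(cfg$fl_table)) read_fl_table(cfg$fl_table)
    else cfg$fl_table
    excluded <- data.frame(language_id = character(0), reason = character(0))
  } else {
    res <- compute_fl(cfg$lexicons, cfg$segment_table,
                      min_instances = cfg$min_instances,
                      segmented = cfg$segmented)
    fl <- res$fl
    excluded <- res$excluded
  }
  if (is.null(fl) || nrow(fl) < 3L)
    stop("fewer than 3 languages pass the filters; nothing to analyse",
         call. = FALSE)
  trees <- if (is.character(cfg$trees)) read_tree_sample(cfg$trees)
  else as_tree_sample(cfg$trees)
  study1 <- run_study1(fl, trees, traits = cfg$traits, n_perm = cfg$n_perm,
                       seed = seed, out = out)
  study2 <- run_study2(fl, trees, pairs = cfg$pairs, out = out)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fl, file.path(out, "fl_table.csv"), row.names = FALSE)
    utils::write.csv(excluded, file.path(out, "excluded.csv"),
                     row.names = FALSE)
    yaml::write_yaml(
      list(seed = seed, n_perm = cfg$n_perm, n_trees = length(trees),
           n_languages = nrow(fl)),
      file.path(out, "run_metadata.yaml")
    )
    return(invisible(list(fl = fl, excluded = excluded, study1 = study1,
                          study2 = study2)))
  }
  list(fl = fl, excluded = excluded, study1 = study1, study2 = study2)
}
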