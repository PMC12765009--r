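# Shared config resolution for the run_* entry points. Defaults follow the
# motivating analysis where a value is printed there (niche alpha = 0.99,
# 10,000 Monte-Carlo draws, test alpha = 0.05).
.run_config <- function(seed = 1, hs_variant = "significant_only",
                        hs_estimator = "ss_ratio",
                        ds_priors = "proportional",
                        niche_alpha = 0.99, n_mc = 10000, n_draws = 1000,
                        dims = NULL, test_alpha = 0.05) {
  list(seed = as.integer(seed), hs_variant = hs_variant,
       hs_estimator = hs_estimator, ds_priors = ds_priors,
       niche_alpha = niche_alpha, n_mc = as.integer(n_mc),
       n_draws = as.integer(n_draws), dims = dims,
       test_alpha = test_alpha)
}

.config_meta <- function(config) {
  c(lapply(config, function(x) x %||% "auto"),
    list(package = "vocalid", version = as.character(utils::packageVersion("vocalid"))))
}

# Accept a call_table, a file path, or a (possibly named) list of either;
# returns a named list of call_tables split by group_label.
.resolve_tables <- function(tables) {
  if (inherits(tables, "call_table") || is.character(tables)) {
    tables <- list(tables)
  }
  tabs <- lapply(tables, function(t) {
    if (is.character(t)) read_call_table(t) else t
  })
  out <- list()
  for (t in tabs) {
    for (g in unique(t$group_label)) {
      if (g %in% names(out)) stop("duplicate group label across tables: ", g)
      sub <- t[t$group_label == g, , drop = FALSE]
      out[[g]] <- as_call_table(as.data.frame(sub),
                                provenance = attr(t, "provenance"))
    }
  }
  out
}

#' Simulate a two-condition study and write it to disk
#'
#' Writes one flat-dialect call table per condition, a JSON file with the
#' simulation ground truth, and the resolved run configuration.
#'
#' @param out_dir Output directory (created if missing).
#' @param cfg_dense,cfg_sparse [sim_config()]s for the two conditions.
#' @param seed Seed recorded in the metadata (the tables themselves use the
#'   configs' own seeds).
#' @return Invisibly, the `two_condition_study`.
#' @export
run_simulate <- function(out_dir,
                         cfg_dense = sim_config(group_label = "HIGH", seed = 101),
                         cfg_sparse = sim_config(group_label = "LOW", seed = 102),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_two_condition_study(cfg_dense, cfg_sparse)
  for (side in c("dense", "sparse")) {
    ds <- study[[side]]
    write_call_table(ds$table,
                     file.path(out_dir, paste0("calls_", side, ".tsv")))
  }
  truth <- list(
    seed = seed,
    dense = c(study$dense$truth,
              list(group_label = cfg_dense$group_label)),
    sparse = c(study$sparse$truth,
               list(group_label = cfg_sparse$group_label)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(study)
}

# Sample-wide metrics (HS, DS, IVS) for one group's call table.
.group_metrics <- function(tab, config) {
  pcs <- call_pc_scores(tab)
  hs <- calc_hs(pcs, variant = config$hs_variant,
                estimator = config$hs_estimator)
  ds <- calc_ds(pcs, priors = config$ds_priors)
  counts <- table(tab$individual_id)
  data.frame(group = tab$group_label[1],
             n_individuals = ds$n_individuals,
             mean_calls_per_individual = mean(counts),
             hs_all = hs$hs_all,
             hs_significant = hs$hs_significant,
             n_signatures = hs$n_signatures,
             ds_percent = ds$ds_percent,
             chance_percent = ds$chance_percent,
             ivs = ds$ivs,
             stringsAsFactors = FALSE)
}

#' Sample-wide individuality metrics per group
#'
#' For each group label found in the input table(s): standardize and
#' decorrelate the features, then compute Beecher's statistic (both
#' totals), the implied signature count, the leave-one-out discrimination
#' score, the chance level and the IVS. Writes `metrics.csv` (with the
#' resolved configuration as a metadata header) and `metrics.json` when
#' `out_dir` is given.
#'
#' @param tables A `call_table`, a file path, or a list of either; groups
#'   are split by `group_label`.
#' @param out_dir Optional output directory.
#' @param config Optional list of run options (seed, hs_variant,
#'   hs_estimator, ds_priors, niche_alpha, n_mc, n_draws, dims,
#'   test_alpha); omitted entries take the defaults above.
#' @param ... Overrides passed to the config (e.g. `hs_variant = "all"`).
#' @return Data frame with one row per group.
#' @export
run_metrics <- function(tables, out_dir = NULL, config = NULL, ...) {
  config <- utils::modifyList(.run_config(), c(config %||% list(), list(...)))
  groups <- .resolve_tables(tables)
  out <- do.call(rbind, lapply(groups, .group_metrics, config = config))
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_table_meta(out, file.path(out_dir, "metrics.csv"),
                      .config_meta(config))
    jsonlite::write_json(out, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' Acoustic-niche overlap per group
#'
#' Runs the niche-overlap pipeline within each group and, when `out_dir`
#' is given, writes one overlap matrix per group
#' (`overlap_<group>.csv`, focal rows / other columns, with alpha, draw
#' counts, dimensions and seed in the metadata header) plus the pooled
#' per-individual aggregate table `ano.csv`.
#'
#' @inheritParams run_metrics
#' @return Data frame: `group`, `individual_id`, `ano`, plus the attribute
#'   `results` (named list of `ano_result`).
#' @export
run_ano <- function(tables, out_dir = NULL, config = NULL, ...) {
  config <- utils::modifyList(.run_config(), c(config %||% list(), list(...)))
  groups <- .resolve_tables(tables)
  results <- lapply(names(groups), function(g) {
    acoustic_niche_overlap(call_pc_scores(groups[[g]]),
                           alpha = config$niche_alpha, n_mc = config$n_mc,
                           n_draws = config$n_draws, dims = config$dims,
                           seed = .id_seed(config$seed, "ano", g))
  })
  names(results) <- names(groups)
  out <- do.call(rbind, lapply(names(results), function(g) {
    cbind(group = g, results[[g]]$ano, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in names(results)) {
      m <- results[[g]]$overlap
      df <- cbind(focal = rownames(m), as.data.frame(unclass(m)))
      .write_table_meta(df, file.path(out_dir, paste0("overlap_", g, ".csv")),
                        c(.config_meta(config),
                          list(group = g, dims = results[[g]]$dims)))
    }
    .write_table_meta(out, file.path(out_dir, "ano.csv"),
                      .config_meta(config))
  }
  attr(out, "results") <- results
  out
}

#' Full two-condition comparison report
#'
#' The end-to-end analysis of a two-condition study: per condition, the
#' features are standardized and decorrelated and the per-individual WID,
#' BID and aggregate ANO are computed within that condition's own score
#' space (each population is its own acoustic reference frame); each of
#' the three per-individual metrics is then compared between conditions
#' with a two-sided Wilcoxon rank-sum test and median/IQR summaries.
#' Writes `compare.csv`/`compare.json` and the per-individual values
#' `individual_metrics.csv` when `out_dir` is given.
#'
#' @param tables Input with exactly two group labels (see [run_metrics()]).
#' @param out_dir Optional output directory.
#' @param config,... Run configuration and overrides.
#' @return List of class `study_report`: `report` (3-row data frame),
#'   `comparisons`, `individual_metrics`, `metrics` (sample-wide rows),
#'   `config`.
#' @export
run_compare <- function(tables, out_dir = NULL, config = NULL, ...) {
  config <- utils::modifyList(.run_config(), c(config %||% list(), list(...)))
  groups <- .resolve_tables(tables)
  if (length(groups) != 2L) {
    stop("exactly two group labels required, got: ",
         paste(names(groups), collapse = ", "))
  }
  per_ind <- do.call(rbind, lapply(names(groups), function(g) {
    pcs <- call_pc_scores(groups[[g]])
    wid <- calc_wid(pcs)
    bid <- calc_bid(pcs)
    ano <- acoustic_niche_overlap(pcs, alpha = config$niche_alpha,
                                  n_mc = config$n_mc,
                                  n_draws = config$n_draws,
                                  dims = config$dims,
                                  seed = .id_seed(config$seed, "ano", g))
    df <- merge(merge(wid[c("individual_id", "wid")], bid), ano$ano)
    cbind(group = g, df, stringsAsFactors = FALSE)
  }))
  comparisons <- lapply(c("wid", "bid", "ano"), function(metric) {
    compare_conditions(per_ind[[metric]], per_ind$group,
                       alpha = config$test_alpha, metric = metric)
  })
  names(comparisons) <- c("wid", "bid", "ano")
  report <- do.call(rbind, lapply(comparisons, comparison_row))
  rownames(report) <- NULL
  metrics <- run_metrics(groups, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_table_meta(report, file.path(out_dir, "compare.csv"),
                      .config_meta(config))
    .write_table_meta(per_ind, file.path(out_dir, "individual_metrics.csv"),
                      .config_meta(config))
    jsonlite::write_json(list(config = .config_meta(config),
                              metrics = metrics, comparisons = report),
                         file.path(out_dir, "compare.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  structure(list(report = report, comparisons = comparisons,
                 individual_metrics = per_ind, metrics = metrics,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Sample-wide metrics:\n")
  print(x$metrics, digits = 4)
  cat("\nPer-individual comparisons (Wilcoxon rank sum):\n")
  print(x$report, digits = 4)
  invisible(x)
}
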