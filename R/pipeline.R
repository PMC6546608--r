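## Pipeline orchestration: validate -> effect sizes -> pooling -> bias ->
## moderators, with reports written as TSV plus a machine-readable JSON
## bundle and a manifest that fully determines re-execution.

#' Run the full analysis pipeline and write its reports
#'
#' Validates the dataset (aborting with itemized messages on errors), fits
#' the meta-analysis for all trials and for the active-control subset, the
#' by-control-subtype subgroup table, the publication-bias report and the
#' moderator suites, and writes:
#'
#' * `pooled_all.tsv`, `pooled_active.tsv`, `pooled_by_control.tsv` —
#'   the three pooled-result tables (label, k, effect counts, totals, d,
#'   SE, CI, z, p, Q, I2, tau2, plus a qualitative `interpretation`);
#' * `bias.tsv` — Egger and Begg statistics per label for both suites;
#' * `moderators.tsv` — the meta-regression suite;
#' * `effects.tsv` — measure-level effect sizes;
#' * `funnel/<label>.tsv` — funnel data per pooled label;
#' * `results.json` — every table at full precision;
#' * `manifest.json` — configuration, package and R versions, inputs and
#'   outputs. Timestamps are deliberately omitted so identical inputs give
#'   byte-identical outputs.
#'
#' Input files are never modified.
#'
#' @param dataset a `ppc_dataset`, or `NULL` to read from the three paths.
#' @param studies,arms,measures CSV paths (used when `dataset` is `NULL`).
#' @param out_dir output directory, created if needed.
#' @param cfg an [es_config()].
#' @param seed recorded in the manifest and set before any stage that would
#'   draw random numbers; the analysis itself is deterministic.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with both fits, the subgroup table and the
#'   report paths.
#' @export
run_pipeline <- function(dataset = NULL, studies = NULL, arms = NULL,
                         measures = NULL, out_dir, cfg = es_config(),
                         seed = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(dataset)) {
    if (is.null(studies) || is.null(arms) || is.null(measures))
      stop("either a dataset or all three input paths must be given",
           call. = FALSE)
    say("reading dataset: %s", studies)
    dataset <- read_dataset(studies, arms, measures)
  }
  diag <- validate_dataset(dataset)
  if (length(diag$errors))
    stop("validation failed:\n",
         paste0("  - ", diag$errors, collapse = "\n"), call. = FALSE)
  for (w in diag$warnings) say("warning: %s", w)
  if (!is.null(seed)) set.seed(seed)

  say("computing effect sizes for %d measures across %d studies",
      nrow(dataset$measures), nrow(dataset$studies))
  fit_all <- mbi_meta(dataset, cfg, "all")
  n_active <- sum(comparison_table(dataset)$control_subtype %in%
                    .control_levels("active_only"))
  fit_active <- if (n_active > 0) mbi_meta(dataset, cfg, "active_only")
  say("pooled %d comparisons (%d active-control)",
      nrow(comparison_table(dataset)), n_active)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    path
  }
  decorate <- function(tbl) {
    tbl <- as.data.frame(tbl)
    tbl$interpretation <- as.character(interpret_d(tbl$d))
    tbl
  }
  paths <- c(
    wt(decorate(fit_all$pooled), "pooled_all.tsv"),
    if (!is.null(fit_active))
      wt(decorate(fit_active$pooled), "pooled_active.tsv"),
    wt(decorate(fit_all$subgroups), "pooled_by_control.tsv"),
    wt(rbind(cbind(suite = "all", fit_all$bias),
             if (!is.null(fit_active))
               cbind(suite = "active_only", fit_active$bias)),
       "bias.tsv"),
    wt(rbind(fit_all$moderators,
             if (!is.null(fit_active)) fit_active$moderators),
       "moderators.tsv"),
    wt(fit_all$effects, "effects.tsv"),
    wt(fit_all$rob, "rob_summary.tsv")
  )
  funnel_dir <- file.path(out_dir, "funnel")
  if (!dir.exists(funnel_dir)) dir.create(funnel_dir)
  for (lab in fit_all$pooled$label) {
    cc <- if (lab == "all_measures") fit_all$composites
          else fit_all$composites[fit_all$composites$category == lab, ,
                                  drop = FALSE]
    utils::write.table(funnel_points(cc),
                       file.path(funnel_dir, paste0(lab, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  results <- list(
    pooled_all = fit_all$pooled,
    pooled_active = if (!is.null(fit_active)) fit_active$pooled,
    pooled_by_control = fit_all$subgroups,
    bias_all = fit_all$bias,
    bias_active = if (!is.null(fit_active)) fit_active$bias,
    moderators = rbind(fit_all$moderators,
                       if (!is.null(fit_active)) fit_active$moderators),
    rob_summary = fit_all$rob
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       dataframe = "rows", digits = NA, na = "null",
                       auto_unbox = TRUE)
  manifest <- list(
    tool = "ppcmeta",
    version = as.character(utils::packageVersion("ppcmeta")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(cfg),
    seed = seed,
    inputs = list(studies = studies, arms = arms, measures = measures),
    n_studies = nrow(dataset$studies),
    n_comparisons = nrow(comparison_table(dataset)),
    n_measures = nrow(dataset$measures),
    outputs = basename(paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  say("wrote %d report files to %s", length(paths) + 2L, out_dir)
  invisible(list(all = fit_all, active = fit_active,
                 subgroups = fit_all$subgroups,
                 paths = c(paths, file.path(out_dir, "results.json"),
                           file.path(out_dir, "manifest.json"))))
}
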