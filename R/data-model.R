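## Data model: the three-table long format (studies, arms, measures), its
## readers/writers, and structural validation.  A dataset is a plain list of
## three data.frames with class "ppc_dataset"; all downstream stages consume
## this container.

#' Construct a study-level dataset
#'
#' Bundles the three normalized tables describing a collection of randomized
#' pre/post trials: one row per study (`studies`), one row per arm (`arms`),
#' and one row per outcome measure per MBI-vs-control comparison
#' (`measures`). Multi-arm studies appear as several comparisons sharing an
#' arm.
#'
#' @param studies data.frame with columns `study_id`, `age_mean`,
#'   `total_hours`, `training_weeks`, `mbi_name` and the five risk-of-bias
#'   columns `rob_random_sequencing`, `rob_allocation`, `rob_blinding`,
#'   `rob_incomplete`, `rob_selective` (values `low`/`high`/`unclear`).
#' @param arms data.frame with columns `study_id`, `arm_id`, `role`
#'   (`mbi`/`control`), `control_subtype` (`none` for MBI arms), `n`.
#' @param measures data.frame with one row per measure per comparison; see
#'   [read_dataset()] for the full column list.
#' @param check if `TRUE` (default), structural invariants are enforced and
#'   any violation is an error. Set to `FALSE` to build a dataset for
#'   inspection with [validate_dataset()].
#' @return An object of class `ppc_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [validate_dataset()]
#' @export
ppc_dataset <- function(studies, arms, measures, check = TRUE) {
  studies  <- as.data.frame(studies)
  arms     <- as.data.frame(arms)
  measures <- as.data.frame(measures)
  ds <- structure(list(studies = studies, arms = arms, measures = measures),
                  class = "ppc_dataset")
  if (check) {
    errs <- .check_dataset(ds)
    if (length(errs))
      stop("invalid dataset:\n", paste0("  - ", errs, collapse = "\n"),
           call. = FALSE)
  }
  ds
}

#' @export
print.ppc_dataset <- function(x, ...) {
  cmp <- comparison_table(x)
  cat("Pre/post-controlled trial dataset\n")
  cat(sprintf("  studies:     %d\n", nrow(x$studies)))
  cat(sprintf("  arms:        %d\n", nrow(x$arms)))
  cat(sprintf("  comparisons: %d\n", nrow(cmp)))
  cat(sprintf("  measures:    %d\n", nrow(x$measures)))
  if (nrow(x$measures))
    cat("  categories:  ",
        paste(sort(unique(x$measures$category)), collapse = ", "), "\n")
  invisible(x)
}

## Structural checks shared by the constructor and validate_dataset().
## Returns a character vector of error messages (empty when clean).
.check_dataset <- function(ds) {
  errs <- character()
  add <- function(...) errs <<- c(errs, sprintf(...))

  for (nm in setdiff(.studies_cols, names(ds$studies)))
    add("studies: missing required column '%s'", nm)
  for (nm in setdiff(.arms_cols, names(ds$arms)))
    add("arms: missing required column '%s'", nm)
  for (nm in setdiff(.measures_cols, names(ds$measures)))
    add("measures: missing required column '%s'", nm)
  if (length(errs)) return(errs)  # cannot check content without the columns

  st <- ds$studies; ar <- ds$arms; me <- ds$measures

  if (anyDuplicated(st$study_id))
    add("studies: duplicated study_id: %s",
        paste(unique(st$study_id[duplicated(st$study_id)]), collapse = ", "))
  bad_age <- !is.na(st$age_mean) & (st$age_mean <= 0 | st$age_mean >= 19)
  for (i in which(bad_age))
    add("studies row %d (%s): age_mean %.2f outside (0, 19)",
        i, st$study_id[i], st$age_mean[i])
  for (dc in .rob_columns) {
    bad <- !(st[[dc]] %in% .rob_levels)
    for (i in which(bad))
      add("studies row %d (%s): %s must be one of low/high/unclear, got '%s'",
          i, st$study_id[i], dc, as.character(st[[dc]][i]))
  }

  if (nrow(ar)) {
    orphan <- !(ar$study_id %in% st$study_id)
    for (i in which(orphan))
      add("arms row %d: study_id '%s' not in studies", i, ar$study_id[i])
    bad_role <- !(ar$role %in% c("mbi", "control"))
    for (i in which(bad_role))
      add("arms row %d: role must be mbi or control, got '%s'", i, ar$role[i])
    bad_sub <- ifelse(ar$role == "mbi",
                      ar$control_subtype != "none",
                      !(ar$control_subtype %in% ppc_control_subtypes))
    bad_sub[bad_role] <- FALSE
    for (i in which(bad_sub))
      add("arms row %d (%s/%s): control_subtype '%s' inconsistent with role '%s'",
          i, ar$study_id[i], ar$arm_id[i], ar$control_subtype[i], ar$role[i])
    for (i in which(is.na(ar$n) | ar$n < 1))
      add("arms row %d (%s/%s): n must be >= 1", i, ar$study_id[i], ar$arm_id[i])
    key <- paste(ar$study_id, ar$arm_id)
    if (anyDuplicated(key))
      add("arms: duplicated (study_id, arm_id): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
    n_mbi <- tapply(ar$role == "mbi", ar$study_id, sum)
    for (sid in names(n_mbi)[n_mbi == 0])
      add("study %s has no mbi arm", sid)
    n_arms <- table(ar$study_id)
    for (sid in names(n_arms)[n_arms < 2])
      add("study %s has fewer than 2 arms", sid)
  }

  if (nrow(me)) {
    arm_key <- paste(ar$study_id, ar$arm_id)
    for (i in seq_len(nrow(me))) {
      if (!(me$study_id[i] %in% st$study_id)) {
        add("measures row %d: study_id '%s' not in studies", i, me$study_id[i])
        next
      }
      if (!(paste(me$study_id[i], me$mbi_arm_id[i]) %in% arm_key))
        add("measures row %d: mbi_arm_id '%s' not an arm of study %s",
            i, me$mbi_arm_id[i], me$study_id[i])
      if (!(paste(me$study_id[i], me$control_arm_id[i]) %in% arm_key))
        add("measures row %d: control_arm_id '%s' not an arm of study %s",
            i, me$control_arm_id[i], me$study_id[i])
    }
    for (i in which(!(me$category %in% ppc_categories)))
      add("measures row %d: unknown category '%s'", i, me$category[i])
    for (i in which(!(me$direction %in% c("higher_better", "lower_better"))))
      add("measures row %d: direction must be higher_better or lower_better",
          i)
    for (sdcol in c("mbi_pre_sd", "mbi_post_sd", "ctl_pre_sd", "ctl_post_sd"))
      for (i in which(is.na(me[[sdcol]]) | me[[sdcol]] <= 0))
        add("measures row %d: %s must be > 0", i, sdcol)
  }
  errs
}

#' Read a dataset from its three CSV files
#'
#' Reads the `studies`, `arms` and `measures` tables (UTF-8, header row,
#' decimal point `.`) and assembles a validated [ppc_dataset()]. Per-arm
#' sample sizes in `measures` (`mbi_n`, `ctl_n`) default to the arm-level `n`
#' when left empty. Row order is preserved.
#'
#' @param studies_path,arms_path,measures_path paths to the three CSV files.
#' @return A `ppc_dataset`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' write_dataset(generate_dataset(sim_config(n_studies = 3, seed = 7)), dir)
#' ds <- read_dataset(file.path(dir, "studies.csv"),
#'                    file.path(dir, "arms.csv"),
#'                    file.path(dir, "measures.csv"))
#' ds
#' @export
read_dataset <- function(studies_path, arms_path, measures_path) {
  rd <- function(path, what) {
    if (!file.exists(path)) stop("cannot read ", what, " file: ", path,
                                 call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = NA, encoding = "UTF-8")
  }
  studies  <- rd(studies_path, "studies")
  arms     <- rd(arms_path, "arms")
  measures <- rd(measures_path, "measures")
  for (cc in c("study_id", "arm_id"))
    if (cc %in% names(arms)) arms[[cc]] <- as.character(arms[[cc]])
  if ("study_id" %in% names(studies))
    studies$study_id <- as.character(studies$study_id)
  for (cc in c("study_id", "comparison_id", "mbi_arm_id", "control_arm_id"))
    if (cc %in% names(measures)) measures[[cc]] <- as.character(measures[[cc]])

  # fill per-measure n from the arm table where omitted
  if (all(c("mbi_n", "ctl_n") %in% names(measures)) && nrow(measures)) {
    arm_n <- stats::setNames(arms$n, paste(arms$study_id, arms$arm_id))
    miss <- is.na(measures$mbi_n)
    measures$mbi_n[miss] <-
      arm_n[paste(measures$study_id, measures$mbi_arm_id)][miss]
    miss <- is.na(measures$ctl_n)
    measures$ctl_n[miss] <-
      arm_n[paste(measures$study_id, measures$control_arm_id)][miss]
  }
  ppc_dataset(studies, arms, measures, check = TRUE)
}

#' Write a dataset to three CSV files
#'
#' Inverse of [read_dataset()]; writes `studies.csv`, `arms.csv` and
#' `measures.csv` into `dir`.
#'
#' @param ds a `ppc_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ppc_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("studies.csv", "arms.csv", "measures.csv"))
  utils::write.csv(ds$studies,  paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$arms,     paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$measures, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Diagnose a dataset without raising errors
#'
#' Runs every structural invariant check and a set of analysis-readiness
#' warnings, returning them as data rather than conditions. The dataset is
#' never modified.
#'
#' Errors are invariant violations (non-positive SDs, unresolved ids,
#' duplicated `(study_id, comparison_id, measure_name)` rows, bad enum
#' values). Warnings flag conditions the analysis tolerates but the user
#' should know about: missing moderators and outcome categories contributed
#' to by fewer than two studies.
#'
#' @param ds a `ppc_dataset` (may have been built with `check = FALSE`).
#' @return A list with character vectors `errors` and `warnings`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "ppc_dataset"))
  errors <- .check_dataset(ds)
  warnings <- character()

  me <- ds$measures; st <- ds$studies
  if (nrow(me)) {
    key <- paste(me$study_id, me$comparison_id, me$measure_name, sep = "|")
    dup <- unique(key[duplicated(key)])
    if (length(dup))
      errors <- c(errors, sprintf(
        "measures: duplicated (study_id, comparison_id, measure_name): %s",
        paste(dup, collapse = ", ")))
    k_per_cat <- tapply(me$study_id, me$category,
                        function(x) length(unique(x)))
    for (cat in names(k_per_cat)[k_per_cat < 2])
      warnings <- c(warnings, sprintf(
        "category '%s' has k < 2 studies (k = %d)", cat, k_per_cat[[cat]]))
  }
  st <- ds$studies
  for (mod in c("age_mean", "total_hours", "training_weeks")) {
    nmiss <- sum(is.na(st[[mod]]))
    if (nmiss > 0)
      warnings <- c(warnings, sprintf(
        "moderator '%s' missing for %d of %d studies", mod, nmiss, nrow(st)))
  }
  list(errors = errors, warnings = warnings)
}

#' Comparison table of a dataset
#'
#' Derives the unit-of-analysis table: one row per (MBI arm, control arm)
#' comparison, with the control subtype and arm sizes resolved from the arm
#' table. Comparisons are the pooled units throughout the package; multi-arm
#' studies contribute several comparisons sharing an arm.
#'
#' @param ds a `ppc_dataset`.
#' @return data.frame with columns `study_id`, `comparison_id`,
#'   `mbi_arm_id`, `control_arm_id`, `control_subtype`, `n_mbi`, `n_ctl`.
#' @export
comparison_table <- function(ds) {
  me <- ds$measures
  if (!nrow(me))
    return(data.frame(study_id = character(), comparison_id = character(),
                      mbi_arm_id = character(), control_arm_id = character(),
                      control_subtype = character(),
                      n_mbi = integer(), n_ctl = integer()))
  key <- paste(me$study_id, me$comparison_id, sep = "|")
  idx <- !duplicated(key)
  out <- data.frame(
    study_id = me$study_id[idx],
    comparison_id = me$comparison_id[idx],
    mbi_arm_id = me$mbi_arm_id[idx],
    control_arm_id = me$control_arm_id[idx],
    stringsAsFactors = FALSE
  )
  arm_key <- paste(ds$arms$study_id, ds$arms$arm_id)
  out$control_subtype <-
    ds$arms$control_subtype[match(paste(out$study_id, out$control_arm_id),
                                  arm_key)]
  out$n_mbi <- ds$arms$n[match(paste(out$study_id, out$mbi_arm_id), arm_key)]
  out$n_ctl <- ds$arms$n[match(paste(out$study_id, out$control_arm_id),
                               arm_key)]
  out
}

## Map a control filter keyword to the matching subtypes.
.control_levels <- function(filter) {
  switch(filter,
    all          = ppc_control_subtypes,
    active_only  = c("attention_placebo", "active_intervention"),
    passive_only = c("no_contact", "wait_list"),
    {
      if (!filter %in% ppc_control_subtypes)
        stop("unknown control filter '", filter, "'", call. = FALSE)
      filter
    })
}
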