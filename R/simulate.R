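## Synthetic study-level data generator.  Produces datasets with the exact
## statistical structure the analysis assumes -- per-category true effects,
## between-study heterogeneity, change-score sampling error driven by arm
## sizes and the pre/post correlation, multi-arm studies, a control-type
## mixture, and optional p-dependent selective publication -- so every
## pipeline stage can be validated without external data.

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defines the study-generating process. Effects are simulated on the
#' standardized scale (pretest SD about 1), so the per-category true effects
#' `delta` map directly onto the d's the analysis computes. Each study draws
#' a true effect `theta_sc = delta_c + N(0, tau2)` per covered category;
#' arm-level pre and post sample means are drawn jointly normal with
#' correlation `rho_prepost_true` and variance `1/n`, and sample SDs from
#' their chi-square sampling distribution.
#'
#' @param n_studies number of studies.
#' @param delta per-category true standardized effects: a single number or a
#'   named vector over [ppc_categories].
#' @param tau2 between-study variance of true effects (same for all
#'   categories).
#' @param arm_n_range integer range `(min, max)` of participants per arm.
#' @param category_probs probability each study assesses each category
#'   (scalar or named vector); at least one category is always covered.
#' @param measures_per_category_range integer range of instruments per
#'   covered category.
#' @param rho_prepost_true true within-arm pre/post correlation used when
#'   generating; set away from the analysis assumption to stress-test the
#'   variance model.
#' @param control_type_probs named probabilities over the four control
#'   subtypes (must sum to 1).
#' @param multi_arm_prob probability a study has a second control arm of a
#'   different subtype (two comparisons sharing the MBI arm).
#' @param direction_prob fraction of measures scored lower-is-better.
#' @param selection optional selective-publication rule: a list with
#'   `prob` (suppression probability) and `p_threshold`; a study whose
#'   smallest category p-value exceeds the threshold is suppressed with
#'   probability `prob`. `NULL` disables selection.
#' @param seed integer seed; generation is deterministic given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 40,
                       delta = 0.3,
                       tau2 = 0.05,
                       arm_n_range = c(15, 60),
                       category_probs = 0.6,
                       measures_per_category_range = c(1, 3),
                       rho_prepost_true = 0.5,
                       control_type_probs = c(no_contact = 0.30,
                                              wait_list = 0.20,
                                              attention_placebo = 0.30,
                                              active_intervention = 0.20),
                       multi_arm_prob = 0.10,
                       direction_prob = 0.40,
                       selection = NULL,
                       seed = 1L) {
  if (length(delta) == 1L)
    delta <- stats::setNames(rep(delta, length(ppc_categories)),
                             ppc_categories)
  if (length(category_probs) == 1L)
    category_probs <- stats::setNames(
      rep(category_probs, length(ppc_categories)), ppc_categories)
  stopifnot(setequal(names(delta), ppc_categories),
            setequal(names(category_probs), ppc_categories),
            setequal(names(control_type_probs), ppc_control_subtypes))
  if (any(control_type_probs < 0) ||
      abs(sum(control_type_probs) - 1) > 1e-8)
    stop("control_type_probs must be non-negative and sum to 1",
         call. = FALSE)
  if (any(category_probs < 0 | category_probs > 1) ||
      multi_arm_prob < 0 || multi_arm_prob > 1 ||
      direction_prob < 0 || direction_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (tau2 < 0) stop("tau2 must be non-negative", call. = FALSE)
  if (rho_prepost_true <= -1 || rho_prepost_true >= 1)
    stop("rho_prepost_true must lie in (-1, 1)", call. = FALSE)
  if (!is.null(selection))
    stopifnot(is.list(selection),
              all(c("prob", "p_threshold") %in% names(selection)),
              selection$prob >= 0, selection$prob <= 1)
  structure(list(
    n_studies = as.integer(n_studies),
    delta = delta[ppc_categories],
    tau2 = tau2,
    arm_n_range = as.integer(arm_n_range),
    category_probs = category_probs[ppc_categories],
    measures_per_category_range = as.integer(measures_per_category_range),
    rho_prepost_true = rho_prepost_true,
    control_type_probs = control_type_probs[ppc_control_subtypes],
    multi_arm_prob = multi_arm_prob,
    direction_prob = direction_prob,
    selection = selection,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Review-shaped simulation preset
#'
#' A configuration emulating the shape of the published evidence base of
#' randomized trials of mindfulness-based interventions in youth: 33
#' studies totalling roughly 3,500-4,000 participants, about half with
#' active-type controls, per-category coverage and true effects matching
#' the reported category study counts and pooled estimates, arm sizes
#' spanning the reported 9-179 per arm (capped at 100), and a moderate
#' between-study variance.
#'
#' @param seed integer seed passed through to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_mbi_review <- function(seed = 1L) {
  sim_config(
    n_studies = 33,
    delta = c(mindfulness = 0.24, executive_function = 0.30,
              attention = 0.19, depression = 0.27, anxiety_stress = 0.16,
              negative_behaviour = 0.27, social_behaviour = 0.16),
    tau2 = 0.05,
    arm_n_range = c(9, 100),
    category_probs = c(mindfulness = 11, executive_function = 15,
                       attention = 8, depression = 13, anxiety_stress = 20,
                       negative_behaviour = 11, social_behaviour = 10) / 33,
    measures_per_category_range = c(1, 4),
    rho_prepost_true = 0.5,
    control_type_probs = c(no_contact = 11, wait_list = 8,
                           attention_placebo = 11,
                           active_intervention = 9) / 39,
    multi_arm_prob = 5 / 33,
    direction_prob = 0.40,
    seed = seed
  )
}

## Sample summary statistics for one arm on one measure: sample pre/post
## means (jointly normal, correlation rho, variance 1/n) and sample SDs
## (chi-square sampling distribution), for a population with pretest mean 0,
## SD 1 and true change mu.
.sim_arm_stats <- function(n, mu, rho) {
  pre_mean <- stats::rnorm(1, 0, sqrt(1 / n))
  post_mean <- mu + rho * pre_mean +
    stats::rnorm(1, 0, sqrt((1 - rho^2) / n))
  pre_sd <- sqrt(stats::rchisq(1, n - 1) / (n - 1))
  post_sd <- sqrt(stats::rchisq(1, n - 1) / (n - 1))
  c(pre_mean = pre_mean, pre_sd = pre_sd,
    post_mean = post_mean, post_sd = post_sd)
}

.mbi_names <- c("MBSR-derived", "MBCT-derived", "Breathing Awareness",
                "Learning to Breathe", "School curriculum")

#' Generate a synthetic dataset
#'
#' Draws a complete three-table dataset from a [sim_config()]. Moderators
#' are attached per study (mean age 4-18 years, training dose 1.5-18 hours,
#' 2-24 weeks; risk-of-bias domain ratings drawn with realistic marginal
#' probabilities). If `cfg$selection` is set, the selective-publication rule
#' is applied before returning (see [apply_selection()]). Deterministic
#' given the config, including its seed.
#'
#' @param cfg a `sim_config`.
#' @return A `ppc_dataset`. When selection was applied, the suppression log
#'   is attached as `attr(ds, "selection_log")`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    ds <- .generate_raw(cfg)
    if (!is.null(cfg$selection)) {
      sel <- apply_selection(ds, cfg$selection, seed = NULL)
      ds <- sel$dataset
      attr(ds, "selection_log") <- sel$log
    }
    ds
  })
}

.generate_raw <- function(cfg) {
  studies <- list(); arms <- list(); measures <- list()
  nmin <- cfg$arm_n_range[1]; nmax <- cfg$arm_n_range[2]
  mmin <- cfg$measures_per_category_range[1]
  mmax <- cfg$measures_per_category_range[2]
  rho <- cfg$rho_prepost_true

  for (i in seq_len(cfg$n_studies)) {
    sid <- sprintf("S%03d", i)
    rob <- sample(c("low", "unclear", "high"), 5, replace = TRUE,
                  prob = c(0.36, 0.47, 0.17))
    study <- data.frame(
      study_id = sid,
      age_mean = round(stats::runif(1, 4, 18), 1),
      total_hours = round(stats::runif(1, 1.5, 18), 2),
      training_weeks = sample(2:24, 1),
      mbi_name = sample(.mbi_names, 1),
      stringsAsFactors = FALSE
    )
    study[.rob_columns] <- as.list(rob)
    studies[[i]] <- study

    # arms: one MBI arm, one control, optionally a second control subtype
    subtypes <- sample(ppc_control_subtypes, 1,
                       prob = cfg$control_type_probs)
    if (stats::runif(1) < cfg$multi_arm_prob) {
      rest <- setdiff(ppc_control_subtypes, subtypes)
      pr <- cfg$control_type_probs[rest]
      subtypes <- c(subtypes, sample(rest, 1, prob = pr / sum(pr)))
    }
    arm_df <- data.frame(
      study_id = sid,
      arm_id = c("mbi", paste0("ctl", seq_along(subtypes))),
      role = c("mbi", rep("control", length(subtypes))),
      control_subtype = c("none", subtypes),
      n = sample(nmin:nmax, 1 + length(subtypes), replace = TRUE),
      stringsAsFactors = FALSE
    )
    arms[[i]] <- arm_df

    covered <- ppc_categories[stats::runif(7) < cfg$category_probs]
    if (!length(covered)) covered <- sample(ppc_categories, 1)
    theta <- stats::setNames(
      cfg$delta[covered] + stats::rnorm(length(covered), 0,
                                        sqrt(cfg$tau2)),
      covered)

    for (cat in covered) {
      m <- if (mmin == mmax) mmin else sample(mmin:mmax, 1)
      for (j in seq_len(m)) {
        dir <- if (stats::runif(1) < cfg$direction_prob) "lower_better"
               else "higher_better"
        sign <- if (dir == "lower_better") -1 else 1
        # MBI arm stats are drawn once per measure and shared across the
        # comparisons of a multi-arm study
        mbi_n <- arm_df$n[1]
        mbi <- .sim_arm_stats(mbi_n, sign * theta[[cat]], rho)
        for (a in seq_along(subtypes)) {
          ctl_n <- arm_df$n[1 + a]
          ctl <- .sim_arm_stats(ctl_n, 0, rho)
          measures[[length(measures) + 1L]] <- data.frame(
            study_id = sid,
            comparison_id = paste0("cmp", a),
            mbi_arm_id = "mbi",
            control_arm_id = paste0("ctl", a),
            measure_name = sprintf("%s_%02d", cat, j),
            category = cat,
            direction = dir,
            mbi_pre_mean = mbi[["pre_mean"]], mbi_pre_sd = mbi[["pre_sd"]],
            mbi_post_mean = mbi[["post_mean"]],
            mbi_post_sd = mbi[["post_sd"]], mbi_n = mbi_n,
            ctl_pre_mean = ctl[["pre_mean"]], ctl_pre_sd = ctl[["pre_sd"]],
            ctl_post_mean = ctl[["post_mean"]],
            ctl_post_sd = ctl[["post_sd"]], ctl_n = ctl_n,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  ppc_dataset(do.call(rbind, studies), do.call(rbind, arms),
              do.call(rbind, measures))
}

#' Apply a selective-publication rule
#'
#' Emulates p-dependent publication: for each study, the smallest two-sided
#' p-value over its category composites is computed; studies whose smallest
#' p exceeds `rule$p_threshold` are suppressed independently with
#' probability `rule$prob`. Analyses of the surviving set overstate the
#' true effect, which is what the funnel-based diagnostics are meant to
#' detect.
#'
#' @param ds a `ppc_dataset`.
#' @param rule list with `prob` and `p_threshold`.
#' @param seed optional seed for the suppression draws; `NULL` uses the
#'   current RNG state.
#' @return List with `dataset` (the survivors) and `log` (data.frame with
#'   `study_id`, `min_p`, `suppressed`).
#' @export
apply_selection <- function(ds, rule, seed = NULL) {
  stopifnot(inherits(ds, "ppc_dataset"),
            all(c("prob", "p_threshold") %in% names(rule)))
  run <- function() {
    comps <- aggregate_effects(compute_effect_sizes(ds))
    min_p <- tapply(2 * stats::pnorm(-abs(comps$d / sqrt(comps$variance))),
                    comps$study_id, min)
    log <- data.frame(study_id = ds$studies$study_id,
                      stringsAsFactors = FALSE)
    log$min_p <- as.numeric(min_p[log$study_id])
    eligible <- !is.na(log$min_p) & log$min_p > rule$p_threshold
    log$suppressed <- eligible &
      stats::runif(nrow(log)) < rule$prob
    keep <- log$study_id[!log$suppressed]
    kept <- ppc_dataset(
      ds$studies[ds$studies$study_id %in% keep, , drop = FALSE],
      ds$arms[ds$arms$study_id %in% keep, , drop = FALSE],
      ds$measures[ds$measures$study_id %in% keep, , drop = FALSE],
      check = FALSE
    )
    list(dataset = kept, log = log)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}
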