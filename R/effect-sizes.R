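## Pre-post-controlled standardized mean differences, their sampling
## variances, and per-study outcome-category composites.

#' Analysis configuration
#'
#' Holds the assumed correlations and estimator options the effect-size and
#' pooling stages need. The trials supply only summary statistics, so two
#' correlations must be assumed rather than estimated:
#'
#' * `rho_prepost`: the within-arm correlation between pre and post scores,
#'   entering the sampling variance of the change-score effect size. 0.5 is
#'   the conventional default for psychological outcome measures.
#' * `rho_measures`: the correlation between different measures of the same
#'   category within a study, entering the variance of the per-category
#'   composite. The default 1 is maximally conservative (composite variance
#'   is never shrunk by averaging).
#'
#' @param rho_prepost assumed pre/post correlation, in (-1, 1). Default 0.5.
#' @param rho_measures assumed between-measure correlation within a
#'   category, in \[0, 1\]. Default 1 (conservative).
#' @param hedges_correction apply the small-sample correction factor
#'   `J = 1 - 3 / (4(n1 + n2 - 2) - 1)` to each d? Default `FALSE`
#'   (plain Cohen's d).
#' @param tau2_method between-study variance estimator for pooling and
#'   meta-regression: `"DL"` (DerSimonian-Laird / method of moments,
#'   default) or `"REML"`.
#' @return A list of class `es_config`.
#' @export
es_config <- function(rho_prepost = 0.5, rho_measures = 1,
                      hedges_correction = FALSE,
                      tau2_method = c("DL", "REML")) {
  tau2_method <- match.arg(tau2_method)
  if (!is.numeric(rho_prepost) || rho_prepost <= -1 || rho_prepost >= 1)
    stop("rho_prepost must lie in (-1, 1)", call. = FALSE)
  if (!is.numeric(rho_measures) || rho_measures < 0 || rho_measures > 1)
    stop("rho_measures must lie in [0, 1]", call. = FALSE)
  structure(list(rho_prepost = rho_prepost,
                 rho_measures = rho_measures,
                 hedges_correction = isTRUE(hedges_correction),
                 tau2_method = tau2_method),
            class = "es_config")
}

#' Sampling variance of a pre-post-controlled d
#'
#' Variance of the change-score standardized mean difference under an
#' assumed within-arm pre/post correlation `rho`:
#' `v = 2 (1 - rho) (1/n1 + 1/n2) + d^2 / (2 (n1 + n2))`.
#' As `rho -> 1` with `d = 0` the change-score noise vanishes and so does
#' the variance.
#'
#' @param d effect size(s).
#' @param n1,n2 arm sample sizes (each at least 2).
#' @param rho_prepost assumed pre/post correlation in (-1, 1).
#' @return Sampling variance(s), strictly positive for `rho_prepost < 1`.
#' @examples
#' variance_ppc_d(0, 20, 20, rho_prepost = 0.5)  # 0.10
#' @export
variance_ppc_d <- function(d, n1, n2, rho_prepost = 0.5) {
  if (any(rho_prepost <= -1 | rho_prepost >= 1))
    stop("rho_prepost must lie in (-1, 1)", call. = FALSE)
  if (any(n1 < 2 | n2 < 2))
    stop("both arm sizes must be at least 2", call. = FALSE)
  2 * (1 - rho_prepost) * (1 / n1 + 1 / n2) + d^2 / (2 * (n1 + n2))
}

#' Pre-post-controlled standardized mean difference
#'
#' Computes, for each measure row, the between-group effect size
#' `d = [(post - pre)_mbi - (post - pre)_ctl] / S_pre`, where `S_pre` is the
#' Bessel-weighted pooled *pretest* standard deviation
#' `sqrt(((n1-1) s1_pre^2 + (n2-1) s2_pre^2) / (n1 + n2 - 2))`. Scaling by
#' the pretest SD keeps the denominator untouched by the intervention.
#' For `lower_better` measures (symptom scales) the sign is flipped, so a
#' positive d always favours the MBI arm. With `hedges_correction` the
#' result is multiplied by `J = 1 - 3/(4(n1+n2-2)-1)`.
#'
#' @param measures data.frame of measure rows (schema of
#'   `ppc_dataset$measures`); a single measure may be passed as a one-row
#'   data.frame or a named list.
#' @param cfg an [es_config()].
#' @return data.frame with one row per input measure: `study_id`,
#'   `comparison_id`, `category`, `measure_name`, `d`, `variance`,
#'   `n_total`, `n_measures_averaged` (always 1 at this level).
#' @examples
#' m <- list(study_id = "s1", comparison_id = "c1", measure_name = "scale",
#'           category = "mindfulness", direction = "higher_better",
#'           mbi_pre_mean = 10, mbi_pre_sd = 2, mbi_post_mean = 14,
#'           mbi_post_sd = 2, mbi_n = 20,
#'           ctl_pre_mean = 10, ctl_pre_sd = 2, ctl_post_mean = 11,
#'           ctl_post_sd = 2, ctl_n = 20)
#' compute_ppc_d(m, es_config())$d  # 1.5
#' @export
compute_ppc_d <- function(measures, cfg = es_config()) {
  if (!is.data.frame(measures)) measures <- as.data.frame(measures)
  stopifnot(inherits(cfg, "es_config"))
  m <- measures
  n1 <- m$mbi_n; n2 <- m$ctl_n
  if (any(n1 + n2 < 3))
    stop("degenerate denominator: n1 + n2 must be at least 3",
         call. = FALSE)
  if (any(m$mbi_pre_sd <= 0 | m$ctl_pre_sd <= 0))
    stop("pretest SDs must be positive", call. = FALSE)

  s_pre <- sqrt(((n1 - 1) * m$mbi_pre_sd^2 + (n2 - 1) * m$ctl_pre_sd^2) /
                  (n1 + n2 - 2))
  d <- ((m$mbi_post_mean - m$mbi_pre_mean) -
          (m$ctl_post_mean - m$ctl_pre_mean)) / s_pre
  d <- ifelse(m$direction == "lower_better", -d, d)
  if (cfg$hedges_correction)
    d <- d * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  data.frame(
    study_id = m$study_id,
    comparison_id = m$comparison_id,
    category = m$category,
    measure_name = m$measure_name,
    d = d,
    variance = variance_ppc_d(d, n1, n2, cfg$rho_prepost),
    n_total = n1 + n2,
    n_measures_averaged = 1L,
    stringsAsFactors = FALSE
  )
}

#' Composite effect size for one study-comparison and category
#'
#' When a study assesses one outcome category with several instruments, the
#' category composite is the unweighted mean of the per-measure d's. Its
#' variance treats the measures as correlated at `cfg$rho_measures`:
#' `var = (1/m^2) * sum_ij rho_ij sqrt(v_i v_j)` with `rho_ii = 1`. At the
#' default `rho_measures = 1` this never understates the composite's
#' uncertainty.
#'
#' @param effects data.frame of effect-size rows (as from
#'   [compute_ppc_d()]) sharing one `(study_id, comparison_id, category)`.
#' @param cfg an [es_config()].
#' @return One-row data.frame with the composite `d`, `variance`,
#'   `n_total` and `n_measures_averaged`.
#' @export
aggregate_category <- function(effects, cfg = es_config()) {
  stopifnot(nrow(effects) >= 1)
  if (length(unique(effects$category)) > 1L)
    stop("cannot aggregate effects from mixed categories", call. = FALSE)
  if (length(unique(paste(effects$study_id, effects$comparison_id))) > 1L)
    stop("cannot aggregate effects from different comparisons", call. = FALSE)
  m <- nrow(effects)
  if (m == 1L) {
    out <- effects[, c("study_id", "comparison_id", "category", "d",
                       "variance", "n_total"), drop = FALSE]
    out$n_measures_averaged <- 1L
    rownames(out) <- NULL
    return(out)
  }
  # stable order so the composite is invariant to input row shuffles
  effects <- effects[order(effects$measure_name), , drop = FALSE]
  s <- sqrt(effects$variance)
  cov_sum <- sum(effects$variance) +
    cfg$rho_measures * (sum(s)^2 - sum(s^2))
  data.frame(
    study_id = effects$study_id[1],
    comparison_id = effects$comparison_id[1],
    category = effects$category[1],
    d = mean(effects$d),
    variance = cov_sum / m^2,
    n_total = effects$n_total[1],
    n_measures_averaged = m,
    stringsAsFactors = FALSE
  )
}

#' Measure-level effect sizes for a whole dataset
#'
#' Applies [compute_ppc_d()] to every measure row and annotates each effect
#' with the control subtype of its comparison.
#'
#' @param ds a `ppc_dataset`.
#' @param cfg an [es_config()].
#' @return data.frame of measure-level effect sizes with `se` and
#'   `control_subtype` columns added.
#' @export
compute_effect_sizes <- function(ds, cfg = es_config()) {
  stopifnot(inherits(ds, "ppc_dataset"))
  if (!nrow(ds$measures))
    return(data.frame(study_id = character(), comparison_id = character(),
                      category = character(), measure_name = character(),
                      d = numeric(), variance = numeric(), se = numeric(),
                      n_total = integer(), n_measures_averaged = integer(),
                      control_subtype = character()))
  es <- compute_ppc_d(ds$measures, cfg)
  es$se <- sqrt(es$variance)
  cmp <- comparison_table(ds)
  es$control_subtype <-
    cmp$control_subtype[match(paste(es$study_id, es$comparison_id),
                              paste(cmp$study_id, cmp$comparison_id))]
  es
}

#' Category composites for a whole dataset
#'
#' Groups measure-level effects by `(study_id, comparison_id, category)` and
#' aggregates each group with [aggregate_category()]. Output rows are sorted
#' by study, comparison and category, so results do not depend on input row
#' order.
#'
#' @param effects measure-level effect table from [compute_effect_sizes()].
#' @param cfg an [es_config()].
#' @return data.frame of composite effect sizes (one row per comparison and
#'   category) with `se` and, when present in the input, `control_subtype`.
#' @export
aggregate_effects <- function(effects, cfg = es_config()) {
  if (!nrow(effects)) {
    out <- effects[, intersect(
      c("study_id", "comparison_id", "category", "d", "variance",
        "n_total", "n_measures_averaged"), names(effects)), drop = FALSE]
    out$se <- numeric()
    return(out)
  }
  key <- paste(effects$study_id, effects$comparison_id, effects$category,
               sep = "|")
  groups <- split(seq_len(nrow(effects)), key)
  pieces <- lapply(groups, function(ix)
    aggregate_category(effects[ix, , drop = FALSE], cfg))
  out <- do.call(rbind, pieces)
  if ("control_subtype" %in% names(effects))
    out$control_subtype <- vapply(groups, function(ix)
      effects$control_subtype[ix[1]], character(1))
  out <- out[order(out$study_id, out$comparison_id,
                   match(out$category, ppc_categories)), , drop = FALSE]
  out$se <- sqrt(out$variance)
  rownames(out) <- NULL
  out
}

#' Write an effect-size table as TSV
#'
#' @param effects an effect-size or composite table.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_effects_tsv <- function(effects, path) {
  eff <- effects
  if (!"se" %in% names(eff)) eff$se <- sqrt(eff$variance)
  cols <- intersect(c("study_id", "comparison_id", "category",
                      "measure_name", "d", "variance", "se", "n_total",
                      "n_measures_averaged", "control_subtype"), names(eff))
  utils::write.table(eff[, cols, drop = FALSE], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
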