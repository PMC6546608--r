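## Front-end fitting function: one call runs effect-size computation,
## category pooling, publication-bias diagnostics and the moderator suite
## for a chosen control filter, returning a single classed object.

#' Fit the full meta-analysis to a dataset
#'
#' Computes measure-level pre-post-controlled effect sizes, aggregates them
#' to comparison-level category composites, pools each outcome category
#' (plus an all-measures summary) with a random-effects model, runs the
#' Egger and Begg publication-bias tests per category, and fits the
#' single-moderator meta-regressions (age, training hours, risk-of-bias
#' score). With `control_filter = "all"` the by-control-subtype subgroup
#' table is included as well.
#'
#' @param ds a `ppc_dataset` (see [read_dataset()], [generate_dataset()]).
#' @param cfg an [es_config()].
#' @param control_filter `"all"`, `"active_only"`, `"passive_only"` or a
#'   control subtype name; restricts which comparisons enter the fit.
#' @return Object of class `mbi_meta` with components `pooled`
#'   (`ppc_pool_table`), `bias`, `moderators`, `effects` (measure level),
#'   `composites`, `rob`, `subgroups` (only for `"all"`), `cfg`,
#'   `control_filter`.
#' @examples
#' ds <- generate_dataset(preset_mbi_review(seed = 42))
#' fit <- mbi_meta(ds)
#' fit
#' coef(fit)
#' @export
mbi_meta <- function(ds, cfg = es_config(), control_filter = "all") {
  stopifnot(inherits(ds, "ppc_dataset"))
  diag <- validate_dataset(ds)
  if (length(diag$errors))
    stop("dataset failed validation:\n",
         paste0("  - ", diag$errors, collapse = "\n"), call. = FALSE)
  effects <- compute_effect_sizes(ds, cfg)
  levels <- .control_levels(control_filter)
  composites <- aggregate_effects(
    effects[effects$control_subtype %in% levels, , drop = FALSE], cfg)
  fit <- structure(list(
    pooled = pool_by_category(ds, cfg, control_filter),
    bias = bias_report(ds, cfg, control_filter),
    moderators = run_moderator_suite(ds, cfg, suites = control_filter),
    effects = effects,
    composites = composites,
    rob = rob_summary(ds),
    subgroups = if (identical(control_filter, "all"))
      subgroup_by_control(ds, cfg),
    cfg = cfg,
    control_filter = control_filter,
    warnings = diag$warnings
  ), class = "mbi_meta")
  fit
}

#' @export
print.mbi_meta <- function(x, ...) {
  cat("Meta-analysis of pre/post-controlled randomized trials\n")
  cat(sprintf("  control filter: %s | rho_prepost = %.2f | tau2: %s\n",
              x$control_filter, x$cfg$rho_prepost, x$cfg$tau2_method))
  print(x$pooled)
  invisible(x)
}

#' @export
summary.mbi_meta <- function(object, ...) {
  structure(object, class = c("summary.mbi_meta", class(object)))
}

#' @export
print.summary.mbi_meta <- function(x, ...) {
  print.mbi_meta(x)
  cat("\nPublication bias (comparison-level composites):\n")
  b <- x$bias
  num <- vapply(b, is.numeric, logical(1))
  b[num] <- lapply(b[num], round, 3)
  print(b, row.names = FALSE)
  sig <- x$moderators[!is.na(x$moderators$p) & x$moderators$p < 0.05, ,
                      drop = FALSE]
  cat("\nModerators with p < .05:\n")
  if (nrow(sig)) {
    num <- vapply(sig, is.numeric, logical(1))
    sig[num] <- lapply(sig[num], round, 4)
    print(sig[, c("suite", "category", "moderator", "n_used", "slope",
                  "Q_model", "p")], row.names = FALSE)
  } else cat("  none\n")
  if (length(x$warnings))
    cat("\nData warnings:\n", paste0("  - ", x$warnings, collapse = "\n"),
        "\n", sep = "")
  invisible(x)
}

#' @export
coef.mbi_meta <- function(object, ...) {
  stats::setNames(object$pooled$d, object$pooled$label)
}

#' Funnel plot of comparison-level composites
#'
#' Plots effect size against standard error (inverted axis) for the pooled
#' composites, with the pooled estimate and pseudo 95% confidence funnel.
#'
#' @param x an `mbi_meta` fit.
#' @param category a category label or `"all_measures"` (default).
#' @param ... passed to [plot()].
#' @return Invisibly, the plotted data.frame.
#' @export
plot.mbi_meta <- function(x, category = "all_measures", ...) {
  cc <- if (identical(category, "all_measures")) x$composites
        else x$composites[x$composites$category == category, , drop = FALSE]
  if (!nrow(cc)) stop("no composites for category '", category, "'")
  fp <- funnel_points(cc)
  est <- x$pooled$d[x$pooled$label == category]
  ylim <- rev(range(c(0, fp$se)))
  graphics::plot(fp$d, fp$se, ylim = ylim, xlab = "Effect size (d)",
                 ylab = "Standard error",
                 main = paste("Funnel:", category), ...)
  if (length(est)) {
    graphics::abline(v = est, lty = 2)
    s <- seq(0, max(fp$se), length.out = 50)
    graphics::lines(est - .z_crit * s, s, lty = 3)
    graphics::lines(est + .z_crit * s, s, lty = 3)
  }
  invisible(fp)
}
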