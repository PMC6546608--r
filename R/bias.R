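## Publication-bias diagnostics: Egger regression, Begg rank correlation,
## and the data behind funnel plots.

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `z_i = d_i / se_i` on
#' precision `x_i = 1 / se_i`. Under a symmetric funnel the intercept is
#' zero; a nonzero intercept signals small-study effects consistent with
#' selective publication. The intercept is tested with a two-tailed t on
#' `n - 2` df.
#'
#' @param d effect sizes (length >= 3).
#' @param v their sampling variances.
#' @return Object of class `ppc_egger`: list with `intercept`,
#'   `intercept_se`, `t`, `df`, `p`, `slope`, `n`.
#' @export
egger_test <- function(d, v) {
  n <- length(d)
  if (n < 3) stop("Egger regression requires at least 3 effects",
                  call. = FALSE)
  stopifnot(length(v) == n, all(v > 0))
  se <- sqrt(v)
  x <- 1 / se
  y <- d / se
  if (stats::sd(x) < 1e-12 * mean(x))
    stop("all standard errors equal: precision is collinear with the ",
         "intercept", call. = FALSE)
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  sigma2 <- rss / (n - 2)
  se_int <- sqrt(sigma2 * sum(x^2) / (n * sum((x - mean(x))^2)))
  tval <- if (se_int == 0) {
    if (abs(b[[1]]) < 1e-12) 0 else sign(b[[1]]) * Inf
  } else b[[1]] / se_int
  structure(list(
    intercept = unname(b[1]), intercept_se = se_int,
    t = unname(tval), df = n - 2L,
    p = 2 * stats::pt(-abs(tval), n - 2),
    slope = unname(b[2]), n = n
  ), class = "ppc_egger")
}

#' @export
print.ppc_egger <- function(x, digits = 3, ...) {
  cat(sprintf("Egger regression (n = %d)\n", x$n))
  cat(sprintf("  intercept = %.*f (SE %.*f), t(%d) = %.*f, p = %s\n",
              digits, x$intercept, digits, x$intercept_se, x$df,
              digits, x$t, format.pval(x$p, digits = digits)))
  cat(sprintf("  slope (bias-adjusted effect) = %.*f\n", digits, x$slope))
  invisible(x)
}

#' Begg rank-correlation test
#'
#' Kendall's tau (tau-b, so ties are handled) between the
#' variance-standardized deviates `(d_i - dbar_fixed) / sqrt(v_i - 1/sum(w))`
#' and the sampling variances, with a normal-approximation p-value.
#' Concordance between effect magnitude and imprecision is the rank-based
#' signature of a skewed funnel.
#'
#' @param d effect sizes (length >= 3).
#' @param v their sampling variances.
#' @return Object of class `ppc_begg`: list with `tau`, `p`, `n`.
#' @export
begg_test <- function(d, v) {
  n <- length(d)
  if (n < 3) stop("Begg test requires at least 3 effects", call. = FALSE)
  stopifnot(length(v) == n, all(v > 0))
  w <- 1 / v
  dbar <- sum(w * d) / sum(w)
  vstar <- v - 1 / sum(w)  # >= 0 since 1/sum(w) <= min(v)
  u <- (d - dbar) / sqrt(pmax(vstar, .Machine$double.eps))
  tau <- stats::cor(u, v, method = "kendall")
  p <- suppressWarnings(
    stats::cor.test(u, v, method = "kendall", exact = FALSE)$p.value)
  structure(list(tau = tau, p = p, n = n), class = "ppc_begg")
}

#' @export
print.ppc_begg <- function(x, digits = 3, ...) {
  cat(sprintf("Begg rank correlation (n = %d): tau = %.*f, p = %s\n",
              x$n, digits, x$tau, format.pval(x$p, digits = digits)))
  invisible(x)
}

#' Funnel-plot data
#'
#' Returns the `(d, se)` pairs behind a funnel plot, in input order.
#'
#' @param effects effect table with columns `d` and `variance` (or `se`).
#' @return data.frame with columns `d` and `se`.
#' @export
funnel_points <- function(effects) {
  se <- if ("se" %in% names(effects)) effects$se else sqrt(effects$variance)
  data.frame(d = effects$d, se = se)
}

#' Publication-bias report per analysis label
#'
#' Runs the Egger and Begg tests on comparison-level category composites:
#' one row per outcome category plus an `all_measures` row, under the given
#' control filter. Labels with fewer than three composites, or a degenerate
#' precision design, are reported with `NA` statistics and a note.
#'
#' @inheritParams pool_by_category
#' @return data.frame with columns `label`, `n`, `egger_intercept`,
#'   `egger_t`, `egger_df`, `egger_p`, `begg_tau`, `begg_p`, `note`.
#' @export
bias_report <- function(ds, cfg = es_config(), control_filter = "all") {
  stopifnot(inherits(ds, "ppc_dataset"))
  levels <- .control_levels(control_filter)
  es <- compute_effect_sizes(ds, cfg)
  es <- es[es$control_subtype %in% levels, , drop = FALSE]
  comps <- aggregate_effects(es, cfg)
  one <- function(label, cc) {
    row <- data.frame(label = label, n = nrow(cc),
                      egger_intercept = NA_real_, egger_t = NA_real_,
                      egger_df = NA_integer_, egger_p = NA_real_,
                      begg_tau = NA_real_, begg_p = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    if (nrow(cc) < 3) { row$note <- "fewer than 3 effects"; return(row) }
    eg <- tryCatch(egger_test(cc$d, cc$variance), error = function(e) e)
    if (inherits(eg, "error")) { row$note <- conditionMessage(eg); return(row) }
    bg <- begg_test(cc$d, cc$variance)
    row$egger_intercept <- eg$intercept; row$egger_t <- eg$t
    row$egger_df <- eg$df; row$egger_p <- eg$p
    row$begg_tau <- bg$tau; row$begg_p <- bg$p
    row
  }
  rows <- list(one("all_measures", comps))
  for (cat in intersect(ppc_categories, unique(comps$category)))
    rows[[length(rows) + 1L]] <-
      one(cat, comps[comps$category == cat, , drop = FALSE])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
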