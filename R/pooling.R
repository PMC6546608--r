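## Random-effects pooling and heterogeneity statistics.
##
## The pooled unit of analysis is the study-level comparison composite: each
## comparison contributes one d per outcome category, and degrees of freedom
## follow the comparison count.

#' Cochran's Q heterogeneity statistic
#'
#' With fixed-effect inverse-variance weights `w_i = 1/v_i` and weighted
#' mean `dbar`, `Q = sum w_i (d_i - dbar)^2`, chi-square distributed with
#' `k - 1` df under homogeneity.
#'
#' @param d effect sizes (length >= 2).
#' @param v their sampling variances.
#' @return List with `Q`, `df` and upper-tail `p_Q`.
#' @examples
#' cochran_q(c(0, 1), c(0.1, 0.1))  # Q = 5, df = 1
#' @export
cochran_q <- function(d, v) {
  k <- length(d)
  if (k < 2) stop("Q requires at least 2 effects", call. = FALSE)
  stopifnot(length(v) == k, all(v > 0))
  w <- 1 / v
  dbar <- sum(w * d) / sum(w)
  Q <- sum(w * (d - dbar)^2)
  df <- k - 1L
  list(Q = Q, df = df, p_Q = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared from Q and its degrees of freedom
#'
#' `I2 = 100 * max(0, (Q - df) / Q)`, the percentage of total variability in
#' the effects attributable to between-study heterogeneity rather than
#' sampling error; 0% means none, 25% low, 50% moderate, 75% high. Defined
#' as 0 when `Q = 0`.
#'
#' @param Q Cochran's Q (>= 0).
#' @param df its degrees of freedom (>= 1).
#' @return I-squared in percent, in `[0, 100]`.
#' @examples
#' i_squared(21.00, 10)  # 52.38...
#' i_squared(4.21, 8)    # 0: Q below its expectation is truncated
#' @export
i_squared <- function(Q, df) {
  stopifnot(all(Q >= 0), all(df >= 1))
  ifelse(Q == 0, 0, 100 * pmax(0, (Q - df) / Q))
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator: with `w_i = 1/v_i`,
#' `C = sum(w) - sum(w^2)/sum(w)` and `tau2 = max(0, (Q - df) / C)`.
#'
#' @param d effect sizes (length >= 2).
#' @param v their sampling variances.
#' @return Non-negative `tau2`.
#' @examples
#' dl_tau2(c(0, 1), c(0.1, 0.1))  # 0.4
#' @export
dl_tau2 <- function(d, v) {
  q <- cochran_q(d, v)
  w <- 1 / v
  C <- sum(w) - sum(w^2) / sum(w)
  if (C <= 0) stop("cannot estimate tau2: C = 0", call. = FALSE)
  max(0, (q$Q - q$df) / C)
}

## Restricted maximum-likelihood tau2 for an intercept-only or moderator
## model.  X defaults to a column of ones.
.reml_tau2 <- function(d, v, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(d), 1)
  nll <- function(t2) {
    wi <- 1 / (v + t2)
    W <- diag(wi, length(d))
    XtWX <- crossprod(X, W %*% X)
    b <- solve(XtWX, crossprod(X, wi * d))
    r <- d - X %*% b
    0.5 * (sum(log(v + t2)) + determinant(XtWX)$modulus[1] +
             sum(wi * r^2))
  }
  upper <- max(stats::var(d) * 10, 1e-3)
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-10)
  # boundary refinement: accept 0 if it is at least as good
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' Random-effects pooled estimate
#'
#' Inverse-variance pooling with random-effects weights
#' `w*_i = 1/(v_i + tau2)`: `d_pooled = sum(w* d)/sum(w*)`,
#' `se = sqrt(1/sum(w*))`, 95% CI `d_pooled +/- 1.959964 se`, z test
#' two-tailed against the normal. With `tau2 = 0` this reduces exactly to
#' fixed-effect pooling. When `tau2` is omitted it is estimated from the
#' data (`method`); a single effect is returned as-is with
#' `se = sqrt(v + tau2)`.
#'
#' @param d effect sizes (length >= 1).
#' @param v their sampling variances.
#' @param tau2 between-study variance; `NULL` (default) to estimate.
#' @param method tau2 estimator when estimating: `"DL"` or `"REML"`.
#' @return Object of class `ppc_pool`: a list with `k`, `d`, `se`,
#'   `ci_low`, `ci_high`, `z`, `p`, `Q`, `df`, `p_Q`, `i2`, `tau2`,
#'   `method`.
#' @examples
#' pool_random_effects(c(0, 1), c(0.1, 0.1), tau2 = 0.4)
#' @export
pool_random_effects <- function(d, v, tau2 = NULL,
                                method = c("DL", "REML")) {
  method <- match.arg(method)
  k <- length(d)
  stopifnot(k >= 1, length(v) == k, all(v > 0))
  if (k == 1L) {
    if (is.null(tau2)) tau2 <- NA_real_
    se <- sqrt(v + ifelse(is.na(tau2), 0, tau2))
    est <- d
    q <- list(Q = NA_real_, df = 0L, p_Q = NA_real_)
    i2 <- NA_real_
  } else {
    q <- cochran_q(d, v)
    if (is.null(tau2))
      tau2 <- if (method == "DL") dl_tau2(d, v) else .reml_tau2(d, v)
    w <- 1 / (v + tau2)
    est <- sum(w * d) / sum(w)
    se <- sqrt(1 / sum(w))
    i2 <- i_squared(q$Q, q$df)
  }
  z <- est / se
  structure(list(
    k = k, d = est, se = se,
    ci_low = est - .z_crit * se, ci_high = est + .z_crit * se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    Q = q$Q, df = q$df, p_Q = q$p_Q, i2 = i2, tau2 = tau2,
    method = method
  ), class = "ppc_pool")
}

#' @export
print.ppc_pool <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects pooled estimate (%s), k = %d\n",
              x$method, x$k))
  cat(sprintf("  d = %.*f (SE %.*f), 95%% CI [%.*f, %.*f], z = %.*f, p = %s\n",
              digits, x$d, digits, x$se, digits, x$ci_low, digits,
              x$ci_high, digits, x$z, format.pval(x$p, digits = digits)))
  if (!is.na(x$Q))
    cat(sprintf("  Q = %.*f (df %d, p = %s), I2 = %.1f%%, tau2 = %.*f\n",
                digits, x$Q, x$df, format.pval(x$p_Q, digits = digits),
                x$i2, digits + 1, x$tau2))
  invisible(x)
}

#' @export
coef.ppc_pool <- function(object, ...) c(d = object$d)

#' @export
confint.ppc_pool <- function(object, parm, level = 0.95, ...) {
  zc <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$d - zc * object$se, object$d + zc * object$se), 1, 2,
              dimnames = list("d", sprintf("%.1f %%",
                                           c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100)))
  m
}

## Build one report row from a set of composite effects plus bookkeeping.
## composites: rows of the composite table belonging to the row's label;
## effects_n: count of measure-level effects behind them;
## cmp: comparison table restricted to the same comparisons (for arm-level,
## de-duplicated participant totals); arms: the full arm table.
.pool_row <- function(label, composites, effects_n, cmp, arms, method) {
  ids <- unique(c(paste(cmp$study_id, cmp$mbi_arm_id),
                  paste(cmp$study_id, cmp$control_arm_id)))
  total_n <- sum(arms$n[match(ids, paste(arms$study_id, arms$arm_id))])
  pr <- pool_random_effects(composites$d, composites$variance,
                            method = method)
  data.frame(
    label = label,
    k_studies = length(unique(composites$study_id)),
    n_effects = effects_n,
    n_comparisons = nrow(composites),
    total_n = total_n,
    d = pr$d, se = pr$se, ci_low = pr$ci_low, ci_high = pr$ci_high,
    z = pr$z, p = pr$p,
    Q = pr$Q, df = pr$df, p_Q = pr$p_Q, i2 = pr$i2, tau2 = pr$tau2,
    stringsAsFactors = FALSE
  )
}

#' Pooled results per outcome category
#'
#' Computes measure-level effects, aggregates them to comparison-level
#' category composites, and pools the composites with a random-effects model
#' per category present, preceded by an `all_measures` row that pools every
#' composite across categories. Comparisons can be restricted by control
#' type first. Participant totals de-duplicate arms shared between
#' comparisons of multi-arm studies; categories with a single comparison are
#' reported with `Q`, `p_Q` and `i2` set to `NA` rather than dropped.
#'
#' @param ds a `ppc_dataset`.
#' @param cfg an [es_config()].
#' @param control_filter `"all"`, `"active_only"`, `"passive_only"`, or a
#'   single control subtype name.
#' @return data.frame of class `ppc_pool_table`, one row per label.
#' @export
pool_by_category <- function(ds, cfg = es_config(), control_filter = "all") {
  stopifnot(inherits(ds, "ppc_dataset"))
  levels <- .control_levels(control_filter)
  es <- compute_effect_sizes(ds, cfg)
  es <- es[es$control_subtype %in% levels, , drop = FALSE]
  if (!nrow(es)) {
    warning("no comparisons match control filter '", control_filter, "'")
    return(structure(data.frame(), class = c("ppc_pool_table",
                                             "data.frame")))
  }
  comps <- aggregate_effects(es, cfg)
  cmp <- comparison_table(ds)
  cmp_key <- paste(cmp$study_id, cmp$comparison_id)

  rows <- list(.pool_row("all_measures", comps, nrow(es),
                         cmp[cmp_key %in% paste(comps$study_id,
                                                comps$comparison_id), ,
                             drop = FALSE],
                         ds$arms, cfg$tau2_method))
  for (cat in intersect(ppc_categories, unique(comps$category))) {
    cc <- comps[comps$category == cat, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      .pool_row(cat, cc, sum(es$category == cat),
                cmp[cmp_key %in% paste(cc$study_id, cc$comparison_id), ,
                    drop = FALSE],
                ds$arms, cfg$tau2_method)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "control_filter") <- control_filter
  class(out) <- c("ppc_pool_table", "data.frame")
  out
}

#' Pooled results by control-group subtype
#'
#' Pools all-measure comparison composites separately for each control
#' subtype (no contact, wait list, attention placebo, active intervention).
#' A multi-arm study with two control types contributes its comparisons to
#' both applicable rows, so subgroup study counts can sum to more than the
#' overall k.
#'
#' @inheritParams pool_by_category
#' @return data.frame of class `ppc_pool_table`, one row per subtype
#'   present.
#' @export
subgroup_by_control <- function(ds, cfg = es_config()) {
  stopifnot(inherits(ds, "ppc_dataset"))
  es <- compute_effect_sizes(ds, cfg)
  comps <- aggregate_effects(es, cfg)
  cmp <- comparison_table(ds)
  cmp_key <- paste(cmp$study_id, cmp$comparison_id)
  rows <- list()
  for (sub in intersect(ppc_control_subtypes, unique(comps$control_subtype))) {
    cc <- comps[comps$control_subtype == sub, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      .pool_row(sub, cc, sum(es$control_subtype == sub),
                cmp[cmp_key %in% paste(cc$study_id, cc$comparison_id), ,
                    drop = FALSE],
                ds$arms, cfg$tau2_method)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "control_filter") <- "by_subtype"
  class(out) <- c("ppc_pool_table", "data.frame")
  out
}

#' Pool an already-computed comparison-level effect table
#'
#' For re-analyses starting from transcribed per-comparison effect sizes
#' (columns `d` and `variance` or `se`) rather than raw summary statistics.
#'
#' @param effects data.frame with columns `d` and either `variance` or `se`.
#' @param method tau2 estimator.
#' @return A `ppc_pool` object.
#' @export
pool_effect_table <- function(effects, method = c("DL", "REML")) {
  v <- if ("variance" %in% names(effects)) effects$variance
       else effects$se^2
  pool_random_effects(effects$d, v, method = match.arg(method))
}

#' Qualitative interpretation of an effect size
#'
#' Conventional benchmarks: |d| below 0.2 "negligible", 0.2 "small",
#' 0.5 "moderate", 0.8 "large".
#'
#' @param d numeric vector of effect sizes.
#' @return Character vector of labels.
#' @export
interpret_d <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "moderate", "large"),
      right = FALSE)
}

#' @export
print.ppc_pool_table <- function(x, digits = 2, ...) {
  flt <- attr(x, "control_filter")
  cat("Random-effects pooled results",
      if (!is.null(flt)) sprintf(" (control filter: %s)", flt), "\n",
      sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
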