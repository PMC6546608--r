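## Single-moderator random-effects meta-regression with method-of-moments
## residual heterogeneity (REML optional).

#' Random-effects meta-regression on one moderator
#'
#' Weighted least squares of effect sizes on a single study-level moderator
#' with residual between-study variance. The residual `tau2` is estimated by
#' the method of moments (DerSimonian-Laird analogue): from the
#' fixed-effect fit, `tau2 = max(0, (Q_E - (n - 2)) / tr(P))` with
#' `P = W - W X (X'WX)^{-1} X'W`; the model is then refit with weights
#' `1 / (v_i + tau2)`. The slope is tested with `Q_model = (slope/se)^2`
#' against chi-square on 1 df. Effects with a missing moderator are dropped
#' and counted.
#'
#' With `x = NULL` an intercept-only model is fit, whose estimate equals
#' [pool_random_effects()] with the same `tau2` method.
#'
#' @param d effect sizes.
#' @param v their sampling variances.
#' @param x moderator values (same length; `NA` allowed), or `NULL` for the
#'   intercept-only model.
#' @param method residual-tau2 estimator: `"DL"` (method of moments,
#'   default) or `"REML"`.
#' @return Object of class `ppc_metareg`: list with `intercept`, `slope`,
#'   `slope_se`, `Q_model`, `p`, `tau2_residual`, `n_used`, `n_dropped`,
#'   `method`.
#' @export
meta_regress <- function(d, v, x = NULL, method = c("DL", "REML")) {
  method <- match.arg(method)
  stopifnot(length(v) == length(d), all(v > 0))
  intercept_only <- is.null(x)
  if (intercept_only) x <- rep(0, length(d))
  stopifnot(length(x) == length(d))
  keep <- !is.na(x) & !is.na(d)
  n_dropped <- sum(!keep)
  d <- d[keep]; v <- v[keep]; x <- x[keep]
  n <- length(d)
  if (n < 3) stop("meta-regression requires at least 3 comparisons with a ",
                  "non-missing moderator", call. = FALSE)
  if (!intercept_only && stats::sd(x) == 0)
    stop("no moderator variance", call. = FALSE)

  X <- if (intercept_only) matrix(1, n, 1) else cbind(1, x)
  p <- ncol(X)

  mom_tau2 <- function() {
    w <- 1 / v
    W <- diag(w, n)
    XtWX <- crossprod(X, W %*% X)
    b <- solve(XtWX, crossprod(X, w * d))
    r <- d - X %*% b
    Q_E <- sum(w * r^2)
    # tr(P) with P = W - W X (X'WX)^-1 X'W
    trP <- sum(w) - sum(diag(solve(XtWX, crossprod(X, W %*% W %*% X))))
    max(0, (Q_E - (n - p)) / trP)
  }
  tau2 <- if (method == "DL") mom_tau2() else .reml_tau2(d, v, X)

  wstar <- 1 / (v + tau2)
  XtWX <- unname(crossprod(X, wstar * X))
  b <- solve(XtWX, unname(crossprod(X, wstar * d)))
  vcov_b <- solve(XtWX)

  if (intercept_only) {
    slope <- NA_real_; slope_se <- NA_real_
    Q_model <- NA_real_; pval <- NA_real_
  } else {
    slope <- b[2, 1]
    slope_se <- sqrt(vcov_b[2, 2])
    Q_model <- (slope / slope_se)^2
    pval <- stats::pchisq(Q_model, 1, lower.tail = FALSE)
  }
  structure(list(
    intercept = b[1, 1],
    intercept_se = sqrt(vcov_b[1, 1]),
    slope = slope, slope_se = slope_se,
    Q_model = Q_model, p = pval,
    tau2_residual = tau2,
    n_used = n, n_dropped = n_dropped,
    method = method
  ), class = "ppc_metareg")
}

#' @export
print.ppc_metareg <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects meta-regression (%s), n = %d",
              x$method, x$n_used))
  if (x$n_dropped > 0)
    cat(sprintf(" (%d dropped: missing moderator)", x$n_dropped))
  cat("\n")
  if (is.na(x$slope)) {
    cat(sprintf("  intercept-only: estimate = %.*f (SE %.*f)\n",
                digits, x$intercept, digits, x$intercept_se))
  } else {
    cat(sprintf("  slope = %.*f (SE %.*f), Q_model = %.*f, p = %s\n",
                digits, x$slope, digits, x$slope_se, digits, x$Q_model,
                format.pval(x$p, digits = digits)))
  }
  cat(sprintf("  residual tau2 = %.*f\n", digits, x$tau2_residual))
  invisible(x)
}

#' @export
coef.ppc_metareg <- function(object, ...) {
  if (is.na(object$slope)) c(intercept = object$intercept)
  else c(intercept = object$intercept, slope = object$slope)
}

#' Moderator meta-regression suite
#'
#' For each outcome category and each of the three study-level moderators
#' (`age_mean`, `total_hours`, `rob_score`), fits a single-moderator
#' random-effects meta-regression on the comparison-level category
#' composites. Two suites are run by default, mirroring the main analysis
#' and the active-control subanalysis. Comparisons inherit their study's
#' moderator; categories that cannot be fit (too few comparisons, constant
#' or all-missing moderator) are recorded as skips, not errors. A positive
#' age slope means older samples show larger benefits of the intervention.
#'
#' @param ds a `ppc_dataset`.
#' @param cfg an [es_config()].
#' @param suites control filters to run; default `c("all", "active_only")`.
#' @return data.frame with columns `suite`, `category`, `moderator`,
#'   `n_used`, `n_dropped`, `slope`, `slope_se`, `Q_model`, `p`,
#'   `tau2_residual`, `note` (empty or the skip reason).
#' @export
run_moderator_suite <- function(ds, cfg = es_config(),
                                suites = c("all", "active_only")) {
  stopifnot(inherits(ds, "ppc_dataset"))
  st <- ds$studies
  mods <- data.frame(
    study_id = st$study_id,
    age_mean = st$age_mean,
    total_hours = st$total_hours,
    rob_score = .rob_scores(st),
    stringsAsFactors = FALSE
  )
  es_all <- compute_effect_sizes(ds, cfg)
  rows <- list()
  for (suite in suites) {
    levels <- .control_levels(suite)
    es <- es_all[es_all$control_subtype %in% levels, , drop = FALSE]
    comps <- aggregate_effects(es, cfg)
    for (cat in intersect(ppc_categories, unique(comps$category))) {
      cc <- comps[comps$category == cat, , drop = FALSE]
      xs <- mods[match(cc$study_id, mods$study_id), , drop = FALSE]
      for (mod in c("age_mean", "total_hours", "rob_score")) {
        row <- data.frame(suite = suite, category = cat, moderator = mod,
                          n_used = NA_integer_, n_dropped = NA_integer_,
                          slope = NA_real_, slope_se = NA_real_,
                          Q_model = NA_real_, p = NA_real_,
                          tau2_residual = NA_real_, note = "",
                          stringsAsFactors = FALSE)
        fit <- tryCatch(
          meta_regress(cc$d, cc$variance, xs[[mod]],
                       method = cfg$tau2_method),
          error = function(e) e)
        if (inherits(fit, "error")) {
          row$note <- conditionMessage(fit)
          row$n_used <- sum(!is.na(xs[[mod]]))
        } else {
          row$n_used <- fit$n_used; row$n_dropped <- fit$n_dropped
          row$slope <- fit$slope; row$slope_se <- fit$slope_se
          row$Q_model <- fit$Q_model; row$p <- fit$p
          row$tau2_residual <- fit$tau2_residual
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
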