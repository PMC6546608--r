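## Cochrane-style risk-of-bias composite and per-domain summary.

#' Risk-of-bias composite score
#'
#' Collapses the five Cochrane risk-of-bias domain ratings into a single
#' discrete moderator: each `low` rating contributes +1, each `unclear` 0,
#' and each `high` -1, so the composite ranges from -5 (high risk in every
#' domain) to +5 (low risk in every domain). Lower scores indicate a higher
#' risk of bias.
#'
#' @param ratings character vector of the five domain ratings, each one of
#'   `"low"`, `"high"`, `"unclear"`; or a one-row data.frame / list carrying
#'   the five `rob_*` columns of the studies table.
#' @return Integer composite score in `[-5, 5]`.
#' @examples
#' rob_score(rep("low", 5))                         # 5, the scale maximum
#' rob_score(c("low", "low", "low", "low", "high")) # 3
#' @export
rob_score <- function(ratings) {
  if (is.data.frame(ratings) || is.list(ratings)) {
    if (!all(.rob_columns %in% names(ratings)))
      stop("ratings must carry the five domain columns: ",
           paste(.rob_columns, collapse = ", "), call. = FALSE)
    ratings <- unlist(ratings[.rob_columns], use.names = FALSE)
  }
  ratings <- as.character(ratings)
  if (length(ratings) != 5L || anyNA(ratings))
    stop("all five risk-of-bias domains must be rated", call. = FALSE)
  if (!all(ratings %in% .rob_levels))
    stop("ratings must be 'low', 'high' or 'unclear'", call. = FALSE)
  as.integer(sum(ratings == "low") - sum(ratings == "high"))
}

## Composite score for every study in a dataset (vectorized helper).
.rob_scores <- function(studies) {
  if (!nrow(studies)) return(integer())
  vapply(seq_len(nrow(studies)),
         function(i) rob_score(studies[i, , drop = FALSE]),
         integer(1))
}

#' Per-domain risk-of-bias summary
#'
#' Tallies, over studies, how many were rated low/high/unclear in each of
#' the five domains, with percentages.
#'
#' @param ds a `ppc_dataset`.
#' @return data.frame with one row per domain and columns `domain`,
#'   `n_low`, `n_high`, `n_unclear`, `pct_low`, `pct_high`, `pct_unclear`.
#' @export
rob_summary <- function(ds) {
  stopifnot(inherits(ds, "ppc_dataset"))
  st <- ds$studies
  n <- nrow(st)
  out <- data.frame(domain = ppc_rob_domains, stringsAsFactors = FALSE)
  for (lev in .rob_levels)
    out[[paste0("n_", lev)]] <-
      vapply(.rob_columns, function(cc) sum(st[[cc]] == lev), integer(1))
  for (lev in .rob_levels)
    out[[paste0("pct_", lev)]] <-
      if (n) 100 * out[[paste0("n_", lev)]] / n else NA_real_
  rownames(out) <- NULL
  out
}
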