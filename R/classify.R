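# Supervision-area classification against programme targets and against
# camp-average coverage (LQAS as a homogeneity test).

#' Classify an observed count against a decision rule
#'
#' An SA meets the benchmark when its count of successes reaches the
#' rule's cut-off `d`. An `NA` rule (benchmark outside the table, or no
#' benchmark set) propagates to an `NA` classification.
#'
#' @param count Integer vector of successes.
#' @param rule An [lqas_rule()] object, or `NA`.
#' @return Character vector: `"met"`, `"not_met"`, or `NA`.
#' @examples
#' r <- lqas_rule(19, 0.60, 0.30)
#' classify_count(c(8, 9, 19), r)
#' @export
classify_count <- function(count, rule) {
  if (length(rule) == 1L && !inherits(rule, "lqas_rule") && is.na(rule))
    return(rep(NA_character_, length(count)))
  if (!inherits(rule, "lqas_rule"))
    stop("'rule' must be an 'lqas_rule' object or NA", call. = FALSE)
  if (any(count < 0 | count > rule$n, na.rm = TRUE))
    stop(sprintf("count outside [0, %d]", rule$n), call. = FALSE)
  ifelse(is.na(count), NA_character_,
         ifelse(count >= rule$d, "met", "not_met"))
}

#' Classify every supervision area on every indicator
#'
#' Applies two classifications per (SA, indicator) cell: against the
#' programme target (rule from the target benchmark) and against the
#' camp-average coverage (rule from [band_ceiling()] of the average).
#' The second use is LQAS as a test of homogeneity: it flags outlier SAs
#' sitting well below the camp's own average even when no external
#' target exists or the target is widely missed.
#'
#' @param counts SA count table (see [read_sa_counts()]).
#' @param rules_target Named list (by indicator) of [lqas_rule()] objects
#'   or `NA` where no target is set.
#' @param rules_average Named list of rules for the camp-average
#'   benchmark, `NA` where the average falls outside the rule table.
#' @return Data frame in long format: `sa_id`, `indicator`, `count`,
#'   `prop`, `met_target`, `met_average`.
#' @seealso [lqas()] which builds the rule lists and calls this;
#'   [priority_ranking()].
#' @export
classify_sas <- function(counts, rules_target, rules_average) {
  counts <- validate_sa_counts(counts)
  ind <- setdiff(names(counts), c("sa_id", "n"))
  missing_t <- setdiff(ind, names(rules_target))
  missing_a <- setdiff(ind, names(rules_average))
  if (length(missing_t) || length(missing_a))
    stop("rules missing for indicator(s): ",
         paste(union(missing_t, missing_a), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(ind, function(id) {
    cnt <- counts[[id]]
    bad <- which(cnt < 0 | cnt > counts$n)
    if (length(bad))
      stop(sprintf("count %d out of range for SA '%s', indicator '%s'",
                   cnt[bad[1]], counts$sa_id[bad[1]], id), call. = FALSE)
    data.frame(sa_id = counts$sa_id, indicator = id, count = cnt,
               prop = cnt / counts$n,
               met_target = classify_count(cnt, rules_target[[id]]),
               met_average = classify_count(cnt, rules_average[[id]]))
  }))
  rownames(out) <- NULL
  out
}

#' Rank supervision areas by classification failures
#'
#' Orders SAs from highest to lowest priority for intervention. The
#' primary sort key is the number of failures against the camp-average
#' rule (the homogeneity outliers — the "worst of the worst"), the
#' secondary key the number of failures against programme targets;
#' remaining ties break lexicographically on `sa_id`. The count of dual
#' failures (both rules missed on the same indicator) is reported
#' alongside.
#'
#' @param flags Output of [classify_sas()].
#' @return Data frame, one row per SA in priority order: `sa_id`,
#'   `n_average_failures`, `n_target_failures`, `n_dual_failures`.
#' @export
priority_ranking <- function(flags) {
  need <- c("sa_id", "indicator", "met_target", "met_average")
  if (!all(need %in% names(flags)))
    stop("'flags' must be the output of classify_sas()", call. = FALSE)
  sa <- sort(unique(flags$sa_id))
  tally <- function(s) {
    f <- flags[flags$sa_id == s, ]
    a <- !is.na(f$met_average) & f$met_average == "not_met"
    b <- !is.na(f$met_target) & f$met_target == "not_met"
    c(n_average_failures = sum(a), n_target_failures = sum(b),
      n_dual_failures = sum(a & b))
  }
  out <- data.frame(sa_id = sa, t(vapply(sa, tally, numeric(3))),
                    row.names = NULL)
  out[order(-out$n_average_failures, -out$n_target_failures, out$sa_id), ,
      drop = FALSE]
}

# Internal: validate an SA count table (sa_id, n, indicator columns).
validate_sa_counts <- function(counts) {
  if (!is.data.frame(counts) || !all(c("sa_id", "n") %in% names(counts)))
    stop("'counts' must be a data frame with columns 'sa_id' and 'n'",
         call. = FALSE)
  if (anyDuplicated(counts$sa_id))
    stop("duplicate sa_id in counts: ",
         counts$sa_id[duplicated(counts$sa_id)][1], call. = FALSE)
  ind <- setdiff(names(counts), c("sa_id", "n"))
  if (!length(ind))
    stop("'counts' has no indicator columns", call. = FALSE)
  for (id in ind) {
    v <- counts[[id]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)))
      stop(sprintf("indicator '%s' must hold integer counts", id),
           call. = FALSE)
    bad <- which(v < 0 | v > counts$n)
    if (length(bad))
      stop(sprintf(
        "count %d exceeds sample size %d (SA '%s', indicator '%s')",
        v[bad[1]], counts$n[bad[1]], counts$sa_id[bad[1]], id),
        call. = FALSE)
  }
  counts
}
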