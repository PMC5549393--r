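# Camp-level coverage estimation: crude, population-weighted, and
# survey-design (stratified with finite population correction), plus the
# sensitivity comparison of the three.

#' Camp-level coverage estimate from stratified SA samples
#'
#' Aggregates per-supervision-area samples into a single coverage
#' estimate for the camp, treating the SAs as strata of a stratified
#' random sample. Three estimators are available:
#'
#' * `"crude"`: pooled proportion `p = sum(x) / sum(n)` with
#'   `se = sqrt(p (1 - p) / (N - 1))`, `N = sum(n)`. Ignores stratum
#'   populations.
#' * `"weighted"`: population-weighted mean of stratum proportions,
#'   `p = sum(W_h p_h)` with `W_h = N_h / sum(N_h)` and
#'   `se = sqrt(sum(W_h^2 p_h (1 - p_h) / (n_h - 1)))`.
#' * `"design"`: as `"weighted"` with each stratum variance term
#'   multiplied by the finite population correction `1 - n_h / N_h`.
#'
#' @param x Integer vector of successes per stratum.
#' @param n Integer vector (or scalar) of sample sizes per stratum.
#' @param N Stratum population sizes; required for `"weighted"` and
#'   `"design"`.
#' @param method One of `"crude"`, `"weighted"`, `"design"`.
#' @param z Confidence-interval multiplier (default 1.96 for 95%).
#' @return An object of class `"coverage_estimate"`: a list with `p`,
#'   `se`, `ci_half` (`= z * se`), `ci` (bounds clipped to `[0, 1]`),
#'   `method`, `z`, and the stratum summary.
#' @examples
#' # continuous water availability, Batil camp (six SAs of 19)
#' estimate_coverage(c(16, 9, 8, 9, 14, 8), 19)
#' @export
estimate_coverage <- function(x, n, N = NULL,
                              method = c("crude", "weighted", "design"),
                              z = 1.96) {
  method <- match.arg(method)
  if (length(n) == 1L) n <- rep(n, length(x))
  if (length(x) != length(n))
    stop("'x' and 'n' must have the same length", call. = FALSE)
  if (length(x) < 1L) stop("at least one stratum is required", call. = FALSE)
  if (any(x < 0 | x > n)) stop("successes must lie in [0, n]", call. = FALSE)
  if (!is.numeric(z) || z <= 0) stop("'z' must be positive", call. = FALSE)

  if (method == "crude") {
    Ntot <- sum(n)
    if (Ntot < 2) stop("crude estimate needs total sample size >= 2",
                       call. = FALSE)
    p <- sum(x) / Ntot
    se <- sqrt(p * (1 - p) / (Ntot - 1))
  } else {
    if (is.null(N))
      stop("stratum populations 'N' are required for method = \"", method,
           "\"; use method = \"crude\" when populations are unknown",
           call. = FALSE)
    if (length(N) != length(x) || any(!is.finite(N)) || any(N <= 0))
      stop("'N' must give a positive population for every stratum",
           call. = FALSE)
    if (method == "design" && any(n > N))
      stop("sample size exceeds population in some stratum", call. = FALSE)
    if (any(n < 2))
      stop("per-stratum variance needs n >= 2 in every stratum",
           call. = FALSE)
    W <- N / sum(N)
    ph <- x / n
    fpc <- if (method == "design") 1 - n / N else 1
    p <- sum(W * ph)
    se <- sqrt(sum(W^2 * fpc * ph * (1 - ph) / (n - 1)))
  }
  structure(
    list(p = p, se = se, ci_half = z * se,
         ci = c(lower = max(0, p - z * se), upper = min(1, p + z * se)),
         method = method, z = z,
         strata = data.frame(nh = n, xh = x, ph = x / n,
                             Nh = if (is.null(N)) NA_real_ else N)),
    class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Coverage estimate (%s): %s  SE %s  95%% CI [%s, %s]\n",
              x$method,
              format(round(x$p, digits), nsmall = digits),
              format(round(x$se, digits), nsmall = digits),
              format(round(x$ci[1], digits), nsmall = digits),
              format(round(x$ci[2], digits), nsmall = digits)))
  invisible(x)
}

#' Sensitivity comparison of the three coverage estimators
#'
#' Recomputes every indicator's camp coverage under the crude,
#' population-weighted, and survey-design estimators and tabulates the
#' pairwise differences, following the convention crude minus
#' alternative. Four summary statistics (standard deviation, maximum,
#' mean, median) are reported over indicators for each difference
#' column. When the differences are small the crude estimator is an
#' acceptable field shortcut; the table quantifies exactly how small.
#'
#' @param counts Data frame of SA counts: column `sa_id`, column `n`,
#'   and one integer column per indicator (see [read_sa_counts()]).
#' @param populations Data frame with columns `sa_id` and `population`.
#' @param z Confidence-interval multiplier.
#' @return A list of class `"lqas_sensitivity"` with elements `table`
#'   (per indicator: coverage, se and CI half-width under each method
#'   and the difference columns) and `summary` (the four summary rows).
#' @examples
#' bp <- batil_preset()
#' pops <- data.frame(sa_id = bp$counts$sa_id, population = 6333)
#' sensitivity_table(bp$counts, pops)
#' @export
sensitivity_table <- function(counts, populations, z = 1.96) {
  counts <- validate_sa_counts(counts)
  ind <- setdiff(names(counts), c("sa_id", "n"))
  pop <- populations$population[match(counts$sa_id, populations$sa_id)]
  if (anyNA(pop))
    stop("'populations' must cover every sa_id in 'counts'", call. = FALSE)

  one <- function(id, method) {
    est <- estimate_coverage(counts[[id]], counts$n,
                             N = if (method == "crude") NULL else pop,
                             method = method, z = z)
    c(coverage = est$p, se = est$se, ci = est$ci_half)
  }
  block <- function(method)
    t(vapply(ind, one, numeric(3), method = method))
  crude <- block("crude"); wtd <- block("weighted"); dsg <- block("design")

  tab <- data.frame(indicator = ind,
                    crude = crude, weighted = wtd, design = dsg,
                    crude_minus_weighted = crude - wtd,
                    crude_minus_design = crude - dsg,
                    diff_in_diff = (crude - wtd) - (crude - dsg),
                    row.names = NULL, check.names = TRUE)
  dcols <- grep("crude_minus|diff_in_diff", names(tab), value = TRUE)
  summ <- t(vapply(dcols, function(cl)
    c(sd = stats::sd(tab[[cl]]), max = max(tab[[cl]]),
      mean = mean(tab[[cl]]), median = stats::median(tab[[cl]])),
    numeric(4)))
  structure(list(table = tab, summary = as.data.frame(summ), z = z),
            class = "lqas_sensitivity")
}

#' @export
print.lqas_sensitivity <- function(x, digits = 3, ...) {
  cat("Sensitivity of camp coverage to the estimation method\n")
  cat("(differences are crude minus alternative)\n\n")
  tab <- x$table
  show <- tab[, c("indicator",
                  "crude.coverage", "weighted.coverage", "design.coverage",
                  "crude_minus_weighted.coverage",
                  "crude_minus_design.coverage")]
  names(show) <- c("indicator", "crude", "weighted", "design",
                   "crude-wtd", "crude-design")
  show[-1] <- lapply(show[-1], round, digits)
  print(show, row.names = FALSE)
  cat("\nSummary over indicators (coverage / se / CI half-width):\n")
  print(round(x$summary, digits))
  invisible(x)
}
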