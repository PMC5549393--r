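# Exact-binomial LQAS design mathematics: misclassification errors,
# decision-rule selection, benchmark tables, OC curves.

#' Exact LQAS misclassification errors
#'
#' Computes the two misclassification errors of an LQAS decision rule by
#' exact binomial tail sums (no normal approximation). A supervision area
#' is classified "met" when the number of successes among `n` sampled
#' respondents reaches the decision rule `d`. The alpha error is the
#' probability that an area whose true coverage equals the upper threshold
#' `pU` is nevertheless classified low; the beta error is the probability
#' that an area at the lower threshold `pL` is classified high.
#'
#' @param n Sample size per supervision area (positive integer).
#' @param d Decision rule: minimum successes required to classify "met";
#'   an integer in `0:n`.
#' @param pU Upper coverage threshold, in `[0, 1]`.
#' @param pL Lower coverage threshold, in `[0, pU)`.
#' @return Named numeric vector with elements `alpha` and `beta`, where
#'   `alpha = P(X < d)` for `X ~ Binomial(n, pU)` and
#'   `beta = P(X >= d)` for `X ~ Binomial(n, pL)`.
#' @examples
#' lqas_errors(19, 13, 0.80, 0.50)   # both errors below 0.10
#' lqas_errors(10, 7, 0.80, 0.50)    # alpha ~ 0.12, beta ~ 0.17
#' @seealso [lqas_rule()] to choose `d`, [oc_curve()] for the full
#'   operating characteristic.
#' @export
lqas_errors <- function(n, d, pU, pL) {
  check_count(n, "n", positive = TRUE)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d != round(d))
    stop("'d' must be a single integer", call. = FALSE)
  if (d < 0 || d > n)
    stop(sprintf("decision rule d = %s outside [0, %d]", format(d), n),
         call. = FALSE)
  check_prob(pU, "pU")
  check_prob(pL, "pL")
  if (pL >= pU)
    stop("lower threshold 'pL' must be strictly below 'pU'", call. = FALSE)
  c(alpha = stats::pbinom(d - 1, n, pU),
    beta  = stats::pbinom(d - 1, n, pL, lower.tail = FALSE))
}

#' Select an LQAS decision rule
#'
#' Chooses the cut-off `d` for classifying a supervision area against a
#' coverage benchmark. With a non-degenerate lower threshold the rule is
#' the exhaustive minimax: the `d` in `0:n` minimising the larger of the
#' two exact misclassification errors, ties broken toward the smaller
#' `d`. With `n = 19` and thresholds 30 points apart this reproduces the
#' rules of the standard published LQAS tables (e.g. benchmarks
#' 95/80/75/60 per cent give rules 16/13/12/9) with both errors below
#' 0.10.
#'
#' When the benchmark sits so low that `pL` hits zero the beta error is
#' identically zero for every `d >= 1` and the minimax criterion
#' degenerates. The published hand-tabulation tables still carry rules
#' for these benchmarks; here they are reproduced by taking the largest
#' `d` whose alpha error does not exceed `error_cap` (so a 30 per cent
#' benchmark at `n = 19` yields `d = 3`).
#'
#' @inheritParams lqas_errors
#' @param error_cap Maximum tolerated alpha error used only for the
#'   degenerate (`pL <= 0`) branch. Default 0.10.
#' @return An object of class `"lqas_rule"`: a list with elements `n`,
#'   `pU`, `pL`, `d`, `alpha`, `beta` and `degenerate` (logical; `TRUE`
#'   when the alpha-cap branch was used).
#' @examples
#' lqas_rule(19, 0.95, 0.65)  # d = 16
#' lqas_rule(19, 0.80, 0.50)  # d = 13
#' lqas_rule(10, 0.80, 0.50)  # d = 7, errors 0.12 / 0.17
#' @export
lqas_rule <- function(n, pU, pL, error_cap = 0.10) {
  check_count(n, "n", positive = TRUE)
  check_prob(pU, "pU")
  if (!is.numeric(pL) || length(pL) != 1L || is.na(pL))
    stop("'pL' must be a single number", call. = FALSE)
  if (pL >= pU) stop("'pL' must be strictly below 'pU'", call. = FALSE)
  check_prob(error_cap, "error_cap")

  degenerate <- pL <= .prob_eps
  if (degenerate) {
    pL <- 0
    d <- 1:n
    alpha <- stats::pbinom(d - 1, n, pU)
    ok <- alpha <= error_cap + .prob_eps
    d_star <- if (any(ok)) max(d[ok]) else 1L
  } else {
    if (pL < 0) stop("'pL' must be non-negative", call. = FALSE)
    d <- 0:n
    alpha <- stats::pbinom(d - 1, n, pU)
    beta <- stats::pbinom(d - 1, n, pL, lower.tail = FALSE)
    d_star <- d[which.min(pmax(alpha, beta))]  # which.min takes first tie
  }
  err <- c(alpha = stats::pbinom(d_star - 1, n, pU),
           beta = if (pL <= 0) 0 else
             stats::pbinom(d_star - 1, n, pL, lower.tail = FALSE))
  structure(
    list(n = as.integer(n), pU = pU, pL = pL, d = as.integer(d_star),
         alpha = unname(err["alpha"]), beta = unname(err["beta"]),
         degenerate = degenerate),
    class = "lqas_rule")
}

#' @export
print.lqas_rule <- function(x, digits = 4, ...) {
  cat(sprintf(
    "LQAS decision rule: n = %d, thresholds %s / %s -> d = %d\n",
    x$n, format(x$pU), format(x$pL), x$d))
  cat(sprintf("  alpha = %s, beta = %s%s\n",
              format(round(x$alpha, digits), nsmall = digits),
              format(round(x$beta, digits), nsmall = digits),
              if (x$degenerate) "  (degenerate lower threshold)" else ""))
  invisible(x)
}

#' Decision-rule benchmark table
#'
#' Builds the hand-tabulation table of decision rules across a grid of
#' coverage benchmarks, each paired with a lower threshold `gap` below
#' (floored at zero). The default grid spans 20 to 95 per cent in
#' 5-point steps; at `n = 19`, `gap = 0.30` this is the table a field
#' team carries for classifying areas both against programme targets and
#' against the camp average.
#'
#' @inheritParams lqas_rule
#' @param gap Distance between upper and lower thresholds (default 0.30).
#' @param bands Benchmark grid; proportions in `(0, 1]`.
#' @return A data frame with one row per band: `band`, `pU`, `pL`, `d`,
#'   `alpha`, `beta`.
#' @examples
#' tab <- lqas_rule_table(19)
#' tab[tab$band %in% c(0.60, 0.75, 0.80, 0.95), ]
#' @export
lqas_rule_table <- function(n = 19, gap = 0.30,
                            bands = seq(0.20, 0.95, by = 0.05),
                            error_cap = 0.10) {
  check_count(n, "n", positive = TRUE)
  if (any(bands <= 0 | bands > 1))
    stop("'bands' must lie in (0, 1]", call. = FALSE)
  if (gap <= 0 || gap >= 1) stop("'gap' must be in (0, 1)", call. = FALSE)
  bands <- round(sort(bands), 9)  # guard against seq() representation noise
  rules <- lapply(bands, function(p)
    lqas_rule(n, p, max(p - gap, 0), error_cap = error_cap))
  data.frame(
    band  = bands,
    pU    = bands,
    pL    = vapply(rules, `[[`, numeric(1), "pL"),
    d     = vapply(rules, `[[`, integer(1), "d"),
    alpha = vapply(rules, `[[`, numeric(1), "alpha"),
    beta  = vapply(rules, `[[`, numeric(1), "beta"))
}

#' Round a coverage estimate up to its benchmark band
#'
#' Maps an observed camp-average coverage onto the benchmark grid of the
#' decision-rule table by rounding up to the next multiple of 5 per
#' cent. Averages above the 95 per cent band (where no rule is defined:
#' the lower threshold would exceed 65 per cent and every area passes
#' trivially) and below the 20 per cent band return `NA`.
#'
#' @param coverage Numeric vector of proportions in `[0, 1]`.
#' @return Numeric vector of bands (multiples of 0.05) or `NA`.
#' @examples
#' band_ceiling(c(0.570, 0.452, 0.973))  # 0.60, 0.50, NA
#' @export
band_ceiling <- function(coverage) {
  if (!is.numeric(coverage) || any(coverage < -.prob_eps |
                                   coverage > 1 + .prob_eps, na.rm = TRUE))
    stop("'coverage' must be proportions in [0, 1]", call. = FALSE)
  band <- ceiling(round(coverage / 0.05, 9)) * 0.05
  band <- round(band, 2)
  band[band > 0.95 + .prob_eps | band < 0.20 - .prob_eps] <- NA_real_
  band
}

#' Operating characteristic of an LQAS rule
#'
#' Probability that an area is classified "met" as a function of its
#' true coverage: `P(X >= d)` with `X ~ Binomial(n, p)`.
#'
#' @inheritParams lqas_errors
#' @param p Grid of true coverage proportions.
#' @return Data frame with columns `p` and `prob_met`, non-decreasing in
#'   `p`.
#' @examples
#' oc <- oc_curve(19, 13, seq(0, 1, 0.05))
#' plot(oc, type = "l")
#' @export
oc_curve <- function(n, d, p = seq(0, 1, by = 0.01)) {
  check_count(n, "n", positive = TRUE)
  if (d < 0 || d > n || d != round(d))
    stop("'d' must be an integer in [0, n]", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  data.frame(p = p,
             prob_met = stats::pbinom(d - 1, n, p, lower.tail = FALSE))
}

#' Equivalent cluster-sample size
#'
#' Sample size a cluster survey would need to match the precision of a
#' stratified LQAS sample of size `n`, under an assumed design effect.
#'
#' @param n Stratified sample size.
#' @param deff Assumed design effect, at least 1 (1.5 is the customary
#'   planning value for cluster surveys).
#' @return `ceiling(deff * n)`, an integer.
#' @examples
#' cluster_equivalent_n(114, 1.5)  # 171
#' @export
cluster_equivalent_n <- function(n, deff = 1.5) {
  check_count(n, "n", positive = TRUE)
  if (!is.numeric(deff) || length(deff) != 1L || is.na(deff) || deff < 1)
    stop("'deff' must be a single number >= 1", call. = FALSE)
  as.integer(ceiling(deff * n))
}

# tolerance for floating-point comparisons on probability scales
.prob_eps <- 1e-9

check_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < if (positive) 1 else 0)
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"),
         call. = FALSE)
  invisible(TRUE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(TRUE)
}
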