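# The central model fit: counts in, decision rules, classifications and
# coverage estimates out, with the usual S3 surface.

#' Fit an LQAS camp assessment
#'
#' Takes the supervision-area count table of a completed LQAS survey and
#' performs the full analysis: selects an exact-binomial decision rule
#' for every programme target and for every camp-average benchmark,
#' classifies every (SA, indicator) cell against both, ranks the SAs by
#' priority, and estimates camp-level coverage per indicator (crude
#' always; population-weighted and survey-design with finite population
#' correction when SA populations are supplied).
#'
#' The camp-average benchmark drives the homogeneity analysis: the
#' observed camp coverage is rounded up to the next 5 per cent band
#' ([band_ceiling()]) and the band's decision rule flags SAs sitting
#' well below the camp's own average. The average used is, in order of
#' precedence: the `averages` argument; an `average` column in
#' `indicators` (e.g. published weighted averages when SA populations
#' are not public); otherwise it is computed from the data
#' (population-weighted when `populations` is given, crude otherwise).
#'
#' @param counts Data frame with columns `sa_id`, `n` (sample size per
#'   SA) and one integer column of successes per indicator; see
#'   [read_sa_counts()].
#' @param indicators Optional data frame describing the indicators:
#'   column `id` (matching count columns), optional `group` (respondent
#'   group), `target` (programme target proportion, `NA` for none) and
#'   `average` (camp-average proportion to use for the homogeneity rule,
#'   `NA` to skip it). When omitted, no targets are assumed and averages
#'   are computed from the data.
#' @param populations Optional data frame with columns `sa_id` and
#'   `population`; enables the weighted and design estimators.
#' @param averages Optional named numeric vector overriding the
#'   camp-average coverage per indicator.
#' @param gap Distance between upper and lower classification
#'   thresholds (default 0.30).
#' @param error_cap Maximum tolerated misclassification error used in
#'   degenerate rule selection (default 0.10).
#' @param z Confidence-interval multiplier (default 1.96).
#' @return An object of class `"lqas"`, a list with components `counts`,
#'   `indicators`, `rules_target`, `rules_average`, `averages`, `flags`
#'   (long classification table), `ranking`, `estimates` (one data frame
#'   per estimation method) and the design settings. Methods: `print`,
#'   `summary`, `coef`, `confint`, `fitted`, `residuals`, `simulate`,
#'   `plot`.
#' @examples
#' bp <- batil_preset()
#' fit <- lqas(bp$counts, bp$indicators)
#' fit
#' summary(fit)
#' coef(fit)
#' @export
lqas <- function(counts, indicators = NULL, populations = NULL,
                 averages = NULL, gap = 0.30, error_cap = 0.10, z = 1.96) {
  counts <- validate_sa_counts(counts)
  ind_ids <- setdiff(names(counts), c("sa_id", "n"))
  n <- counts$n
  if (length(unique(n)) != 1L)
    stop("per-SA sample sizes must be equal for rule selection",
         call. = FALSE)
  n1 <- unique(n)

  if (is.null(indicators)) {
    indicators <- data.frame(id = ind_ids, group = "head_of_household",
                             target = NA_real_)
  }
  if (!all(c("id", "target") %in% names(indicators)))
    stop("'indicators' needs columns 'id' and 'target'", call. = FALSE)
  if (!all(ind_ids %in% indicators$id))
    stop("indicators table missing: ",
         paste(setdiff(ind_ids, indicators$id), collapse = ", "),
         call. = FALSE)
  indicators <- indicators[match(ind_ids, indicators$id), , drop = FALSE]

  pop <- NULL
  if (!is.null(populations)) {
    pop <- populations$population[match(counts$sa_id, populations$sa_id)]
    if (anyNA(pop))
      stop("'populations' must cover every sa_id", call. = FALSE)
  }

  # camp-level estimates per indicator
  methods <- c("crude", if (!is.null(pop)) c("weighted", "design"))
  estimates <- lapply(methods, function(m) {
    rows <- lapply(ind_ids, function(id) {
      e <- estimate_coverage(counts[[id]], n,
                             N = if (m == "crude") NULL else pop,
                             method = m, z = z)
      data.frame(indicator = id, p = e$p, se = e$se, ci_half = e$ci_half,
                 ci_lower = e$ci[1], ci_upper = e$ci[2])
    })
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  })
  names(estimates) <- methods

  # camp averages feeding the homogeneity rule
  if (is.null(averages)) {
    if ("average" %in% names(indicators)) {
      averages <- stats::setNames(indicators$average, indicators$id)
    } else {
      src <- if (!is.null(pop)) "weighted" else "crude"
      averages <- stats::setNames(estimates[[src]]$p,
                                  estimates[[src]]$indicator)
    }
  }
  averages <- averages[ind_ids]
  names(averages) <- ind_ids

  make_rule <- function(p) {
    if (is.na(p)) return(NA)
    lqas_rule(n1, p, max(p - gap, 0), error_cap = error_cap)
  }
  rules_target <- lapply(stats::setNames(indicators$target, ind_ids),
                         make_rule)
  rules_average <- lapply(band_ceiling(averages), make_rule)
  names(rules_average) <- ind_ids

  flags <- classify_sas(counts, rules_target, rules_average)
  structure(
    list(counts = counts, indicators = indicators,
         rules_target = rules_target, rules_average = rules_average,
         averages = averages, flags = flags,
         ranking = priority_ranking(flags),
         estimates = estimates, populations = populations,
         n = n1, gap = gap, error_cap = error_cap, z = z,
         call = match.call()),
    class = "lqas")
}

#' @export
print.lqas <- function(x, ...) {
  cat(sprintf(
    "LQAS camp assessment: %d supervision areas x %d indicators (n = %d per SA)\n\n",
    nrow(x$counts), length(x$rules_target), x$n))
  print(lqas_table(x), row.names = FALSE, right = FALSE)
  cat("\nFlags: a = below camp-average decision rule,",
      "b = below programme-target decision rule\n")
  invisible(x)
}

#' Render an assessment as a classification table
#'
#' Lays the fitted assessment out in the familiar field-report shape:
#' one row per indicator, one column per SA with flag superscripts
#' (`a` = failed the camp-average rule, `b` = failed the target rule),
#' then the camp average with its decision rule in parentheses, the 95%
#' confidence half-width, and the programme target with its rule.
#'
#' @param x An [lqas()] fit.
#' @return A data frame of formatted character columns.
#' @export
lqas_table <- function(x) {
  stopifnot(inherits(x, "lqas"))
  ind <- names(x$rules_target)
  sas <- x$counts$sa_id
  cell <- function(id, s) {
    f <- x$flags[x$flags$indicator == id & x$flags$sa_id == s, ]
    marks <- paste0(
      if (!is.na(f$met_average) && f$met_average == "not_met") "a" else "",
      if (!is.na(f$met_target) && f$met_target == "not_met") "b" else "")
    paste0(f$count, if (nzchar(marks)) paste0("*", marks) else "")
  }
  body <- sapply(sas, function(s) vapply(ind, cell, "", s = s))
  est <- x$estimates[[length(x$estimates)]]  # design > weighted > crude
  fmt_rule <- function(r) if (inherits(r, "lqas_rule")) r$d else NA
  avg <- vapply(ind, function(id) {
    a <- x$averages[[id]]
    if (is.na(a)) return("")
    sprintf("%.1f%% (%s)", 100 * a,
            ifelse(is.na(fmt_rule(x$rules_average[[id]])), "NA",
                   fmt_rule(x$rules_average[[id]])))
  }, "")
  ci <- vapply(ind, function(id) {
    e <- est[est$indicator == id, ]
    sprintf("±%.1f%%", 100 * e$ci_half)
  }, "")
  target <- vapply(ind, function(id) {
    tg <- x$indicators$target[x$indicators$id == id]
    if (is.na(tg)) return("")
    sprintf("%.0f%% (%d)", 100 * tg, fmt_rule(x$rules_target[[id]]))
  }, "")
  out <- data.frame(indicator = ind, body, avg_dr = avg, ci95 = ci,
                    target_dr = target, check.names = FALSE)
  names(out)[2:(1 + length(sas))] <- sas
  rownames(out) <- NULL
  out
}

#' @export
summary.lqas <- function(object, ...) {
  fl <- object$flags
  structure(
    list(ranking = object$ranking,
         n_target_failures = sum(fl$met_target == "not_met", na.rm = TRUE),
         n_average_failures = sum(fl$met_average == "not_met", na.rm = TRUE),
         estimates = object$estimates,
         n = object$n, n_sas = nrow(object$counts)),
    class = "summary.lqas")
}

#' @export
print.summary.lqas <- function(x, digits = 3, ...) {
  cat(sprintf("LQAS assessment: %d SAs, n = %d per SA per respondent group\n",
              x$n_sas, x$n))
  cat(sprintf("Cells below target rule: %d; below camp-average rule: %d\n\n",
              x$n_target_failures, x$n_average_failures))
  cat("Supervision areas by priority (worst first):\n")
  print(x$ranking, row.names = FALSE)
  cat("\nCamp coverage estimates:\n")
  for (m in names(x$estimates)) {
    cat(sprintf("  [%s]\n", m))
    e <- x$estimates[[m]]
    e[-1] <- lapply(e[-1], round, digits)
    print(e, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.lqas <- function(object, method = NULL, ...) {
  method <- method %||% utils::tail(names(object$estimates), 1)
  e <- object$estimates[[match.arg(method, names(object$estimates))]]
  stats::setNames(e$p, e$indicator)
}

#' @export
confint.lqas <- function(object, parm, level = 0.95, method = NULL, ...) {
  method <- method %||% utils::tail(names(object$estimates), 1)
  e <- object$estimates[[match.arg(method, names(object$estimates))]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(pmax(0, e$p - z * e$se), pmin(1, e$p + z * e$se))
  dimnames(ci) <- list(e$indicator,
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.lqas <- function(object, ...) {
  ind <- names(object$rules_target)
  m <- as.matrix(object$counts[, ind, drop = FALSE]) / object$n
  rownames(m) <- object$counts$sa_id
  m
}

#' @export
residuals.lqas <- function(object, ...) {
  f <- fitted(object)
  camp <- coef(object)[colnames(f)]
  sweep(f, 2, camp)
}

#' Simulate replicate count tables from a fitted assessment
#'
#' Draws new SA count tables with each cell `Binomial(n, p_hat)` at the
#' fitted per-SA proportions — the parametric bootstrap under the
#' binomial classification model.
#'
#' @param object An [lqas()] fit.
#' @param nsim Number of replicate tables.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` count data frames shaped like
#'   `object$counts`.
#' @export
simulate.lqas <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ph <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    out <- object$counts
    for (id in colnames(ph))
      out[[id]] <- stats::rbinom(nrow(ph), object$n, ph[, id])
    out
  })
}

#' Plot a fitted LQAS assessment
#'
#' Dot plot of per-SA observed proportions by indicator, with the camp
#' average (`|`) and the programme target (`x`) marked, making the
#' outlier SAs flagged by the homogeneity rule visible at a glance.
#'
#' @param x An [lqas()] fit.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.lqas <- function(x, ...) {
  f <- fitted(x)
  k <- ncol(f)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0.5, k + 0.5),
                 yaxt = "n", xlab = "coverage proportion", ylab = "",
                 main = "SA coverage by indicator", ...)
  graphics::axis(2, at = k:1, labels = colnames(f), las = 2, cex.axis = 0.7)
  for (j in seq_len(k)) {
    y <- k - j + 1
    graphics::points(f[, j], rep(y, nrow(f)), pch = 1)
    a <- x$averages[[colnames(f)[j]]]
    if (!is.na(a)) graphics::points(a, y, pch = "|", col = "blue", cex = 1.4)
    tg <- x$indicators$target[x$indicators$id == colnames(f)[j]]
    if (!is.na(tg)) graphics::points(tg, y, pch = 4, col = "red")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
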