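# Synthetic refugee-camp generator with known ground truth, and the
# recovery experiment that validates the whole pipeline against it.

#' Default WASH indicator panel for synthetic camps
#'
#' The indicator set of the Batil assessment with baseline (camp-centre)
#' coverages `p0` and distance-gradient strengths `gamma` chosen to
#' emulate its qualitative structure: water and hygiene coverage decline
#' with distance from the central amenities, sanitation is uniformly
#' high everywhere, and diarrhoea prevalence is reported by caregivers
#' rather than heads of household.
#'
#' @return Data frame with columns `id`, `group`, `target`, `p0`,
#'   `gamma`.
#' @export
default_indicators <- function() {
  data.frame(
    id = c("improved_water", "continuous_water", "ibrik", "soap",
           "handwash_area", "health_promoter", "four_moments",
           "handwash_adjacent", "improved_sanitation",
           "no_open_defecation", "diarrhoea"),
    group = c(rep("head_of_household", 10), "caregiver"),
    target = c(0.95, 0.80, 0.60, 0.75, 0.60, 0.95, 0.75, 0.60,
               NA, NA, NA),
    p0    = c(0.99, 0.85, 0.80, 0.90, 0.70, 0.99, 0.80, 0.55,
              0.97, 0.97, 0.25),
    gamma = c(0.4, 0.5, 0.6, 0.7, 0.9, 0.3, 0.9, 0.5, 0, 0, 0))
}

#' Configuration of the synthetic camp generator
#'
#' @param n_sas Number of supervision areas (default 6).
#' @param villages_per_sa Integer range (length 2) of Sheik villages per
#'   SA, inclusive (default 8 to 12).
#' @param total_population Camp population (default 38,000).
#' @param mean_household_size Residents per household (default 6).
#' @param caregiver_fraction Probability a household holds a caregiver
#'   of a child 0-59 months (default 0.6).
#' @param head_present Probability the head of household is at home
#'   (default 0.9).
#' @param indicators Indicator panel with columns `id`, `group`,
#'   `target`, `p0` (coverage at the camp centre) and `gamma`
#'   (logit-scale decline per unit of amenity distance; 0 for uniform
#'   services).
#' @param seed Optional RNG seed stored in the config and applied by
#'   [generate_camp()].
#' @return A list of class `"camp_config"`.
#' @export
camp_config <- function(n_sas = 6L, villages_per_sa = c(8L, 12L),
                        total_population = 38000,
                        mean_household_size = 6,
                        caregiver_fraction = 0.6, head_present = 0.9,
                        indicators = default_indicators(), seed = NULL) {
  check_count(n_sas, "n_sas", positive = TRUE)
  if (length(villages_per_sa) != 2L || any(villages_per_sa < 1) ||
      villages_per_sa[1] > villages_per_sa[2])
    stop("'villages_per_sa' must be an increasing range of two positive ",
         "integers", call. = FALSE)
  if (total_population < n_sas)
    stop("'total_population' too small", call. = FALSE)
  check_prob(caregiver_fraction, "caregiver_fraction")
  check_prob(head_present, "head_present")
  if (!all(c("id", "group", "p0", "gamma") %in% names(indicators)))
    stop("'indicators' needs columns id, group, p0, gamma", call. = FALSE)
  if (any(indicators$p0 <= 0 | indicators$p0 >= 1))
    stop("baseline coverages 'p0' must lie in (0, 1)", call. = FALSE)
  structure(list(n_sas = as.integer(n_sas),
                 villages_per_sa = as.integer(villages_per_sa),
                 total_population = total_population,
                 mean_household_size = mean_household_size,
                 caregiver_fraction = caregiver_fraction,
                 head_present = head_present,
                 indicators = indicators, seed = seed),
            class = "camp_config")
}

#' Generate a synthetic camp with known ground truth
#'
#' Builds a Batil-like hierarchical sampling frame: `n_sas` supervision
#' areas at equally spaced amenity distances (0, 1, 2, ...), each
#' holding a uniform 8-12 Sheik villages whose populations are drawn
#' lognormal and rescaled so the camp totals `total_population` exactly;
#' households are population over mean household size, at least one.
#' True per-SA indicator coverage follows a logit-linear distance
#' gradient, `logit(p_s) = logit(p0) - gamma * distance_s`, the minimal
#' model producing the "periphery is worse served" pattern while keeping
#' every truth inside (0, 1); `gamma = 0` gives spatially uniform
#' services.
#'
#' @param config A [camp_config()].
#' @return A list of class `"lqas_camp"` with elements `sas` (data frame
#'   `sa_id`, `amenity_distance`), `villages` (`sa_id`, `village_id`,
#'   `population`, `households`), `truth` (SA-by-indicator matrix of
#'   true coverages), `indicators`, `caregiver_fraction`,
#'   `head_present`.
#' @examples
#' camp <- generate_camp(camp_config(seed = 1))
#' camp$sas
#' @export
generate_camp <- function(config = camp_config()) {
  stopifnot(inherits(config, "camp_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sa_id <- sprintf("SA%d", seq_len(config$n_sas))
  dist <- seq_len(config$n_sas) - 1
  nv <- sample(seq(config$villages_per_sa[1], config$villages_per_sa[2]),
               config$n_sas, replace = TRUE)
  tp <- as.integer(config$total_population)
  raw <- stats::rlnorm(sum(nv), meanlog = 0, sdlog = 0.5)
  pop <- pmax(1L, as.integer(round(raw / sum(raw) * tp)))
  pop[which.max(pop)] <- pop[which.max(pop)] + (tp - sum(pop))  # exact total
  villages <- data.frame(
    sa_id = rep(sa_id, nv),
    village_id = unlist(lapply(seq_along(nv), function(i)
      sprintf("%s-V%02d", sa_id[i], seq_len(nv[i])))),
    population = pop,
    households = pmax(1L, as.integer(round(
      pop / config$mean_household_size))))
  ind <- config$indicators
  truth <- outer(dist, seq_len(nrow(ind)), function(d, j)
    stats::plogis(stats::qlogis(ind$p0[j]) - ind$gamma[j] * d))
  dimnames(truth) <- list(sa_id, ind$id)
  structure(list(sas = data.frame(sa_id = sa_id, amenity_distance = dist),
                 villages = villages, truth = truth,
                 indicators = ind,
                 caregiver_fraction = config$caregiver_fraction,
                 head_present = config$head_present,
                 config = config),
            class = "lqas_camp")
}

#' @export
print.lqas_camp <- function(x, ...) {
  cat(sprintf(
    "Synthetic camp: %d SAs, %d Sheik villages, population %d\n",
    nrow(x$sas), nrow(x$villages), sum(x$villages$population)))
  cat(sprintf("Indicators: %s\n",
              paste(x$indicators$id, collapse = ", ")))
  invisible(x)
}

#' The Batil camp preset
#'
#' Returns the packaged supervision-area count table of the Batil camp
#' WASH assessment (six SAs, n = 19 per respondent group) together with
#' its indicator panel (programme targets and the published
#' population-weighted camp averages) and a synthetic camp frame whose
#' true coverages equal the observed per-SA proportions, so simulated
#' surveys reproduce the observed counts in expectation. SA populations
#' were never published, so the preset camp uses equal SA populations;
#' village structure is a fixed ten near-equal villages per SA.
#'
#' @return List with elements `counts`, `indicators` (both data frames)
#'   and `camp` (an `"lqas_camp"`).
#' @examples
#' bp <- batil_preset()
#' fit <- lqas(bp$counts, bp$indicators)
#' @export
batil_preset <- function() {
  counts <- batil_counts()
  ind_tab <- batil_indicators()
  ind_ids <- setdiff(names(counts), c("sa_id", "n"))
  n_sas <- nrow(counts)
  sa_id <- counts$sa_id
  sa_pop <- rep(38000L %/% n_sas, n_sas)
  sa_pop[seq_len(38000L %% n_sas)] <- sa_pop[seq_len(38000L %% n_sas)] + 1L
  nv <- 10L
  villages <- do.call(rbind, lapply(seq_len(n_sas), function(i) {
    vp <- rep(sa_pop[i] %/% nv, nv)
    vp[seq_len(sa_pop[i] %% nv)] <- vp[seq_len(sa_pop[i] %% nv)] + 1L
    data.frame(sa_id = sa_id[i],
               village_id = sprintf("%s-V%02d", sa_id[i], seq_len(nv)),
               population = vp,
               households = pmax(1L, as.integer(round(vp / 6))))
  }))
  truth <- as.matrix(counts[, ind_ids]) / counts$n
  rownames(truth) <- sa_id
  ind <- data.frame(id = ind_tab$id, group = ind_tab$group,
                    target = ind_tab$target,
                    p0 = truth[1, ind_tab$id], gamma = 0)
  camp <- structure(
    list(sas = data.frame(sa_id = sa_id,
                          amenity_distance = seq_len(n_sas) - 1),
         villages = villages, truth = truth, indicators = ind,
         caregiver_fraction = 0.6, head_present = 0.9, config = NULL),
    class = "lqas_camp")
  list(counts = counts, indicators = ind_tab, camp = camp,
       populations = data.frame(sa_id = sa_id, population = sa_pop))
}

#' Recovery experiment: does the pipeline recover known truth?
#'
#' Simulates many replicate surveys of a camp with known ground truth
#' and summarises how well estimation and classification recover it:
#' per indicator, the bias and RMSE of the camp coverage estimator and
#' the empirical coverage of its 95% confidence interval; per (SA,
#' indicator), the proportion of replicates classified "met" under the
#' target rule, to be compared with the exact alpha/beta guarantees of
#' the design.
#'
#' Because every respondent's response is Bernoulli at the SA truth
#' regardless of which village or household was selected, per-SA counts
#' are distributed `Binomial(n_per_sa, truth)` under the full pipeline;
#' `method = "binomial"` (the default) draws them directly, which is
#' distributionally identical and fast enough for 10,000 replicates.
#' `method = "full"` runs the complete village/household selection
#' machinery per replicate.
#'
#' @param camp An `"lqas_camp"`.
#' @param design A [survey_design()].
#' @param n_replicates Number of replicate surveys (at least 100).
#' @param seed Optional RNG seed.
#' @param method `"binomial"` or `"full"` (see Details).
#' @return List of class `"lqas_recovery"`: `estimates` (per indicator:
#'   truth, mean estimate, bias, rmse, ci_coverage), `classification`
#'   (per SA and indicator: truth, met rate under the target rule,
#'   decision rule used), `n_replicates`.
#' @export
recovery_experiment <- function(camp, design = survey_design(),
                                n_replicates = 1000, seed = NULL,
                                method = c("binomial", "full")) {
  stopifnot(inherits(camp, "lqas_camp"))
  method <- match.arg(method)
  if (n_replicates < 100)
    stop("'n_replicates' must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nps <- design$n_per_sa
  ind <- camp$indicators
  sa_id <- camp$sas$sa_id
  sa_pop <- vapply(sa_id, function(s)
    sum(camp$villages$population[camp$villages$sa_id == s]), numeric(1))
  W <- sa_pop / sum(sa_pop)
  truth_w <- as.numeric(W %*% camp$truth)
  names(truth_w) <- ind$id

  # replicate counts: array [replicate, sa, indicator]
  counts <- array(NA_integer_,
                  c(n_replicates, length(sa_id), nrow(ind)),
                  dimnames = list(NULL, sa_id, ind$id))
  if (method == "binomial") {
    for (s in seq_along(sa_id)) for (j in seq_len(nrow(ind)))
      counts[, s, j] <- stats::rbinom(n_replicates, nps,
                                      camp$truth[s, j])
  } else {
    for (r in seq_len(n_replicates)) {
      tab <- tabulate_survey(run_survey(camp, design))
      counts[r, , ] <- as.matrix(tab[match(sa_id, tab$sa_id), ind$id])
    }
  }

  ph <- counts / nps
  est <- sapply(seq_len(nrow(ind)), function(j) ph[, , j] %*% W)
  se <- sapply(seq_len(nrow(ind)), function(j)
    sqrt((ph[, , j] * (1 - ph[, , j]) / (nps - 1)) %*% W^2))
  covered <- abs(est - rep(truth_w, each = n_replicates)) <=
    design$z * se
  estimates <- data.frame(
    indicator = ind$id, truth = truth_w,
    mean_estimate = colMeans(est),
    bias = colMeans(est) - truth_w,
    rmse = sqrt(colMeans((est - rep(truth_w,
                                    each = n_replicates))^2)),
    ci_coverage = colMeans(covered), row.names = NULL)

  cls <- do.call(rbind, lapply(seq_len(nrow(ind)), function(j) {
    tg <- ind$target[j]
    if (is.na(tg)) return(NULL)
    rule <- lqas_rule(nps, tg, max(tg - design$gap, 0),
                      error_cap = design$error_cap)
    data.frame(sa_id = sa_id, indicator = ind$id[j],
               truth = camp$truth[, j], d = rule$d,
               alpha = rule$alpha, beta = rule$beta,
               met_rate = colMeans(counts[, , j, drop = FALSE][, , 1] >=
                                     rule$d))
  }))
  rownames(cls) <- NULL
  structure(list(estimates = estimates, classification = cls,
                 n_replicates = n_replicates, method = method),
            class = "lqas_recovery")
}

#' @export
print.lqas_recovery <- function(x, digits = 3, ...) {
  cat(sprintf("Recovery experiment (%d replicates, %s sampling)\n\n",
              x$n_replicates, x$method))
  e <- x$estimates
  e[-1] <- lapply(e[-1], round, digits)
  print(e, row.names = FALSE)
  invisible(x)
}
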