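# Simulation of the field respondent-selection pipeline: systematic PPS
# allocation of interview locations to Sheik villages, segmentation
# sampling of households with a random-walk fallback in villages too
# small or featureless to segment, and parallel sampling of the two
# respondent groups.

#' Survey design settings
#'
#' Bundles the design constants of an LQAS camp survey: sample size per
#' SA per respondent group, classification threshold gap and error cap,
#' CI multiplier, and the household-selection tuning knobs.
#'
#' @param n_per_sa Interviews per SA per respondent group (default 19).
#' @param gap Distance between upper and lower thresholds (default 0.30).
#' @param error_cap Maximum tolerated misclassification error (0.10).
#' @param z Confidence-interval multiplier (1.96).
#' @param landmark_threshold Villages with fewer households than this
#'   lack the landmarks needed for segmentation and fall back to the
#'   random walk (default 12).
#' @param step_prob Geometric step parameter of the random walk (0.6).
#' @param segment_min Segment size at which segmentation stops splitting
#'   and draws uniformly (10).
#' @param max_segments Maximum segments per split (4).
#' @return A list of class `"survey_design"`.
#' @export
survey_design <- function(n_per_sa = 19, gap = 0.30, error_cap = 0.10,
                          z = 1.96, landmark_threshold = 12,
                          step_prob = 0.6, segment_min = 10,
                          max_segments = 4) {
  check_count(n_per_sa, "n_per_sa", positive = TRUE)
  if (gap <= 0 || gap >= 1) stop("'gap' must be in (0, 1)", call. = FALSE)
  structure(list(n_per_sa = as.integer(n_per_sa), gap = gap,
                 error_cap = error_cap, z = z,
                 landmark_threshold = landmark_threshold,
                 step_prob = step_prob, segment_min = segment_min,
                 max_segments = max_segments),
            class = "survey_design")
}

#' Systematic PPS allocation of interview locations
#'
#' Allocates `k` interview locations to villages with probability
#' proportional to population by the systematic (cumulative-total,
#' random-start) method: populations are cumulated, the total is divided
#' into `k` equal intervals, a single uniform start is drawn, and the
#' village containing each of the `k` equally spaced points receives a
#' location. A village may receive several locations; with `k` villages
#' of equal size each receives exactly one.
#'
#' @param villages Data frame with columns `village_id` and `population`
#'   (all positive).
#' @param k Number of interview locations.
#' @return Data frame of class `"interview_plan"` with columns
#'   `village_id` and `locations` (positive integers summing to `k`).
#' @export
pps_allocate <- function(villages, k) {
  if (!is.data.frame(villages) || nrow(villages) == 0 ||
      !all(c("village_id", "population") %in% names(villages)))
    stop("'villages' must be a non-empty data frame with columns ",
         "'village_id' and 'population'", call. = FALSE)
  if (any(villages$population <= 0))
    stop("village populations must be positive", call. = FALSE)
  check_count(k, "k", positive = TRUE)
  cum <- cumsum(as.numeric(villages$population))
  total <- cum[length(cum)]
  interval <- total / k
  pts <- stats::runif(1, 0, interval) + (seq_len(k) - 1) * interval
  idx <- vapply(pts, function(u) which.max(cum >= u), integer(1))
  tab <- table(factor(idx, levels = seq_len(nrow(villages))))
  keep <- tab > 0
  structure(data.frame(village_id = villages$village_id[keep],
                       locations = as.integer(tab[keep])),
            class = c("interview_plan", "data.frame"), k = k)
}

#' Segmentation sampling of a household
#'
#' Selects one household from a village of `n` by recursive
#' segmentation: the current range is split into at most `max_segments`
#' roughly equal segments, one segment is chosen with probability
#' proportional to its size, and the process recurses until the segment
#' holds at most `segment_min` households, from which one is drawn
#' uniformly. Because segment choice is exactly size-proportional at
#' every level, the overall selection is uniform over the `n`
#' households.
#'
#' @param n Number of households in the village (positive integer).
#' @param segment_min Stop splitting at or below this size (default 10).
#' @param max_segments Maximum segments per split (default 4).
#' @return A household index in `1:n`.
#' @export
segmentation_select <- function(n, segment_min = 10, max_segments = 4) {
  check_count(n, "n", positive = TRUE)
  lo <- 1L; hi <- as.integer(n)
  while (hi - lo + 1L > segment_min) {
    m <- hi - lo + 1L
    s <- min(max_segments, max(2L, ceiling(m / segment_min)))
    sizes <- rep(m %/% s, s) + c(rep(1L, m %% s), rep(0L, s - m %% s))
    pick <- sample.int(s, 1L, prob = sizes)
    lo <- lo + if (pick > 1L) sum(sizes[seq_len(pick - 1L)]) else 0L
    hi <- lo + sizes[pick] - 1L
  }
  if (lo == hi) lo else sample(lo:hi, 1L)
}

#' Random-walk selection of a household
#'
#' Field fallback used where a village lacks the landmarks for
#' segmentation: the data collector enters at a uniformly chosen
#' household, picks a direction at random, and walks a geometric number
#' of doors, turning back on reaching either end of the household list.
#' The reflection at the ends makes the selection deliberately *not*
#' exactly uniform — the walk slightly favours households near the
#' entry-side interior — mirroring the documented bias of the field
#' technique; for villages of up to 20 households the total-variation
#' distance from uniform stays below 0.1 at the default step
#' probability.
#'
#' @param n Number of households (positive integer).
#' @param step_prob Success probability of the geometric step count
#'   (default 0.6; smaller values walk further).
#' @return A household index in `1:n`.
#' @export
random_walk_select <- function(n, step_prob = 0.6) {
  check_count(n, "n", positive = TRUE)
  if (n == 1L) return(1L)
  pos <- sample.int(n, 1L) +
    sample(c(-1L, 1L), 1L) * stats::rgeom(1L, step_prob)
  while (pos < 1L || pos > n) {
    if (pos < 1L) pos <- 2L - pos
    if (pos > n) pos <- 2L * n - pos
  }
  as.integer(pos)
}

#' Parallel sampling of the two respondent groups
#'
#' From a selected household, finds one head of household and one
#' caregiver of a child under five by moving to the next nearest door
#' until each group has a respondent: candidates are scanned outward by
#' index distance, the lower index first on ties.
#'
#' @param has_head Logical vector: household has a head present.
#' @param has_caregiver Logical vector: household has a caregiver of a
#'   child 0-59 months present.
#' @param start Index of the selected household.
#' @return List with elements `head` and `caregiver`, each a household
#'   index or `NA` if the village holds no such respondent.
#' @export
parallel_sample <- function(has_head, has_caregiver, start) {
  n <- length(has_head)
  if (length(has_caregiver) != n)
    stop("occupancy vectors must have equal length", call. = FALSE)
  if (start < 1 || start > n)
    stop("'start' outside the household list", call. = FALSE)
  start <- as.integer(start)
  scan <- function(flag) {
    for (d in 0:(n - 1L)) {
      for (i in c(start - d, start + d)) {
        if (i >= 1L && i <= n && flag[i]) return(as.integer(i))
      }
    }
    NA_integer_
  }
  list(head = scan(has_head), caregiver = scan(has_caregiver))
}

#' Simulate a complete LQAS camp survey
#'
#' Runs the full respondent-selection pipeline over a camp frame: for
#' each SA, interview locations are PPS-allocated to Sheik villages;
#' at each location a household is selected by segmentation (or by the
#' random walk where the village is below the landmark threshold); the
#' two respondent groups are filled in parallel from the selected
#' household outward; and each respondent's indicator responses are
#' Bernoulli draws at the SA's true coverage. A village lacking a
#' respondent type escalates the location to the next village of the
#' SA.
#'
#' @param camp A camp frame from [generate_camp()] or [batil_preset()].
#' @param design A [survey_design()].
#' @param seed Optional RNG seed; a fixed seed makes the survey output
#'   fully reproducible.
#' @return Data frame of class `"lqas_survey"`: one row per respondent
#'   with `sa_id`, `village_id`, `household`, `respondent_group`,
#'   `selection_method` and one 0/1 column per indicator (NA for the
#'   other group's indicators). Exactly `n_per_sa` rows per group per
#'   SA.
#' @seealso [tabulate_survey()] to reduce the records to an SA count
#'   table ready for [lqas()].
#' @export
run_survey <- function(camp, design = survey_design(), seed = NULL) {
  stopifnot(inherits(camp, "lqas_camp"), inherits(design, "survey_design"))
  if (!is.null(seed)) set.seed(seed)
  ind <- camp$indicators
  recs <- list()
  for (s in camp$sas$sa_id) {
    vil <- camp$villages[camp$villages$sa_id == s, , drop = FALSE]
    plan <- pps_allocate(vil, design$n_per_sa)
    queue <- rep(match(plan$village_id, vil$village_id), plan$locations)
    for (v0 in queue) {
      placed <- FALSE
      for (off in 0:(nrow(vil) - 1L)) {     # escalate on missing groups
        v <- (v0 - 1L + off) %% nrow(vil) + 1L
        h <- vil$households[v]
        start <- if (h >= design$landmark_threshold)
          segmentation_select(h, design$segment_min, design$max_segments)
        else random_walk_select(h, design$step_prob)
        method <- if (h >= design$landmark_threshold) "segmentation"
                  else "random_walk"
        occ_head <- stats::runif(h) < camp$head_present
        occ_cg <- stats::runif(h) < camp$caregiver_fraction
        hit <- parallel_sample(occ_head, occ_cg, start)
        if (is.na(hit$head) || is.na(hit$caregiver)) next
        for (grp in c("head_of_household", "caregiver")) {
          ids <- ind$id[ind$group == grp]
          resp <- stats::setNames(rep(NA_integer_, nrow(ind)), ind$id)
          resp[ids] <- stats::rbinom(length(ids), 1L, camp$truth[s, ids])
          recs[[length(recs) + 1L]] <- c(
            list(sa_id = s, village_id = vil$village_id[v],
                 household = hit[[if (grp == "caregiver") "caregiver"
                                  else "head"]],
                 respondent_group = grp, selection_method = method),
            as.list(resp))
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "SA '%s' exhausted: no village holds both respondent groups", s),
          call. = FALSE)
    }
  }
  out <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(out) <- c("lqas_survey", "data.frame")
  out
}

#' Tabulate survey records into an SA count table
#'
#' Reduces the per-respondent records of [run_survey()] to the count
#' table consumed by [lqas()]: per SA and indicator, the number of
#' positive responses among the indicator's respondent group.
#'
#' @param records An `"lqas_survey"` data frame.
#' @return Data frame with columns `sa_id`, `n` and one column per
#'   indicator.
#' @export
tabulate_survey <- function(records) {
  meta <- c("sa_id", "village_id", "household", "respondent_group",
            "selection_method")
  ind <- setdiff(names(records), meta)
  sas <- unique(records$sa_id)
  nper <- vapply(sas, function(s) {
    sum(records$sa_id == s &
          records$respondent_group == "head_of_household")
  }, integer(1))
  out <- data.frame(sa_id = sas, n = nper)
  for (id in ind)
    out[[id]] <- vapply(sas, function(s)
      sum(records[[id]][records$sa_id == s], na.rm = TRUE), integer(1))
  rownames(out) <- NULL
  out
}
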