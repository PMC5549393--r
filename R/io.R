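# Plain-CSV input/output for count tables and camp frames, the packaged
# Batil fixture, and the end-to-end pipeline runner.

#' Read a supervision-area count table
#'
#' Reads a CSV with header `sa_id, n, <indicator...>`: one row per SA,
#' the per-SA sample size in `n`, and one integer column of successes
#' per indicator. Validation failures (duplicate SA, non-integer cells,
#' counts exceeding `n`) are hard errors naming the offending SA and
#' indicator.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame.
#' @export
read_sa_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  counts <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed counts CSV: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(counts) == 0) stop("counts file is empty: ", path, call. = FALSE)
  validate_sa_counts(counts)
}

#' Write a supervision-area count table
#'
#' @param counts A count table as returned by [read_sa_counts()] or
#'   [tabulate_survey()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sa_counts <- function(counts, path) {
  validate_sa_counts(counts)
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a camp sampling frame
#'
#' A camp frame CSV has columns `sa_id, village_id, population,
#' households`, one row per Sheik village.
#'
#' @param path CSV path.
#' @return Data frame of villages.
#' @export
read_camp_frame <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sa_id", "village_id", "population", "households")
  if (!all(need %in% names(v)))
    stop("camp frame must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(v$population <= 0) || any(v$households < 1))
    stop("camp frame has non-positive populations or households",
         call. = FALSE)
  v
}

#' @rdname read_camp_frame
#' @param villages Villages data frame (e.g. `camp$villages`).
#' @export
write_camp_frame <- function(villages, path) {
  utils::write.csv(villages, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged Batil camp fixture
#'
#' `batil_counts()` returns the published SA count table of the Batil
#' camp WASH assessment (six SAs, 19 respondents per group per SA,
#' eleven indicators). `batil_indicators()` returns the matching
#' indicator panel: respondent group, programme target, and the
#' published population-weighted camp average feeding the homogeneity
#' rule (`NA` where none was set or published — the sanitation
#' indicators had no programme target and diarrhoea prevalence carries
#' no decision rule).
#'
#' @return A data frame.
#' @export
batil_counts <- function() {
  read_sa_counts(system.file("extdata", "batil_counts.csv",
                             package = "lqascamp", mustWork = TRUE))
}

#' @rdname batil_counts
#' @export
batil_indicators <- function() {
  utils::read.csv(system.file("extdata", "batil_indicators.csv",
                              package = "lqascamp", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Run the full assessment pipeline and write its artifacts
#'
#' Orchestrates generate -> simulate -> classify/estimate -> report. With
#' `counts` given (or `preset = "batil"`) the simulation stage is
#' skipped and the observed table is analysed directly; with a `camp`
#' a survey is first simulated. All intermediate tables are written as
#' CSV under `out_dir`, together with a rendered classification table,
#' and the fitted `"lqas"` object is returned.
#'
#' @param out_dir Output directory (created if needed).
#' @param counts Optional observed count table.
#' @param indicators Optional indicator panel (see [lqas()]).
#' @param populations Optional SA population table.
#' @param camp Optional `"lqas_camp"` to simulate from.
#' @param design A [survey_design()].
#' @param preset `"none"` or `"batil"` (loads the packaged fixture).
#' @param seed Optional RNG seed, recorded in the run log.
#' @return The fitted [lqas()] object, invisibly.
#' @export
run_pipeline <- function(out_dir, counts = NULL, indicators = NULL,
                         populations = NULL, camp = NULL,
                         design = survey_design(),
                         preset = c("none", "batil"), seed = NULL) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (preset == "batil") {
    bp <- batil_preset()
    counts <- counts %||% bp$counts
    indicators <- indicators %||% bp$indicators
  }
  if (is.null(counts)) {
    if (is.null(camp))
      stop("supply 'counts', 'camp', or preset = \"batil\"", call. = FALSE)
    records <- run_survey(camp, design)
    utils::write.csv(records, file.path(out_dir, "survey_records.csv"),
                     row.names = FALSE)
    counts <- tabulate_survey(records)
    if (is.null(indicators))
      indicators <- data.frame(id = camp$indicators$id,
                               group = camp$indicators$group,
                               target = camp$indicators$target)
  }
  write_sa_counts(counts, file.path(out_dir, "sa_counts.csv"))
  fit <- lqas(counts, indicators, populations, gap = design$gap,
              error_cap = design$error_cap, z = design$z)
  utils::write.csv(fit$flags, file.path(out_dir, "flags.csv"),
                   row.names = FALSE)
  est <- do.call(rbind, lapply(names(fit$estimates), function(m)
    cbind(method = m, fit$estimates[[m]])))
  utils::write.csv(est, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$ranking, file.path(out_dir, "priority.csv"),
                   row.names = FALSE)
  tab <- utils::capture.output(print(fit))
  writeLines(c(sprintf("# seed: %s", deparse(seed)),
               sprintf("# lqascamp %s",
                       as.character(utils::packageVersion("lqascamp"))),
               tab),
             file.path(out_dir, "classification_table.txt"))
  invisible(fit)
}
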