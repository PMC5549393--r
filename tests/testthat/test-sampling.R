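test_that("systematic PPS allocation respects its guarantees", {
  set.seed(5)
  # single village receives everything
  one <- pps_allocate(data.frame(village_id = "V1", population = 500), 19)
  expect_identical(one$locations, 19L)
  # k equal villages: exactly one location each
  vil <- data.frame(village_id = sprintf("V%02d", 1:19), population = 100)
  plan <- pps_allocate(vil, 19)
  expect_identical(nrow(plan), 19L)
  expect_true(all(plan$locations == 1L))
  expect_error(pps_allocate(vil[0, ], 19), "non-empty")
})

test_that("PPS allocation proportions converge to population shares", {
  set.seed(1234)
  pop <- c(1200, 300, 2500, 800, 150, 950)
  vil <- data.frame(village_id = sprintf("V%d", 1:6), population = pop)
  k <- 19; nrep <- 1e4
  tot <- numeric(6)
  for (r in seq_len(nrep)) {
    plan <- pps_allocate(vil, k)
    tot[match(plan$village_id, vil$village_id)] <-
      tot[match(plan$village_id, vil$village_id)] + plan$locations
  }
  share <- pop / sum(pop)
  emp <- tot / (k * nrep)
  # systematic PPS has sub-multinomial variance; the multinomial SE bounds it
  se <- sqrt(share * (1 - share) / (k * nrep))
  expect_true(all(abs(emp - share) < 3 * se + 1e-9))
})

test_that("segmentation sampling is uniform over households", {
  expect_identical(segmentation_select(1), 1L)
  # threshold at or above the village size degenerates to one uniform draw
  set.seed(9)
  expect_true(all(replicate(50, segmentation_select(8)) %in% 1:8))
  # chi-square goodness of fit at 1e5 draws over 40 households
  set.seed(31)
  ndraw <- 1e5
  draws <- vapply(seq_len(ndraw), function(i) segmentation_select(40),
                  integer(1))
  tab <- tabulate(draws, 40)
  pval <- chisq.test(tab, p = rep(1 / 40, 40))$p.value
  expect_gt(pval, 0.001)
  # every household frequency within 3 binomial SEs of 1/40
  se <- sqrt((1 / 40) * (39 / 40) / ndraw)
  expect_true(all(abs(tab / ndraw - 1 / 40) < 3.5 * se))
})

test_that("random walk is near-uniform with a bounded, documented bias", {
  expect_identical(random_walk_select(1), 1L)
  # exact chain enumeration: TV distance from uniform < 0.1 up to n = 20
  for (n in c(3, 8, 12, 20)) {
    tv <- 0.5 * sum(abs(oracle_walk_dist(n, 0.6) - 1 / n))
    expect_lt(tv, 0.1)
    expect_gt(tv, 0)  # deliberately not exactly uniform
  }
  # empirical frequencies match the enumerated chain
  set.seed(17)
  n <- 12; ndraw <- 2e4
  draws <- vapply(seq_len(ndraw), function(i) random_walk_select(n),
                  integer(1))
  want <- oracle_walk_dist(n, 0.6)
  emp <- tabulate(draws, n) / ndraw
  se <- sqrt(want * (1 - want) / ndraw)
  expect_true(all(abs(emp - want) < 4 * se))
})

test_that("parallel sampling fills both groups from the nearest doors", {
  # both respondents in the selected household
  hit <- parallel_sample(rep(TRUE, 5), rep(TRUE, 5), 3)
  expect_identical(hit, list(head = 3L, caregiver = 3L))
  # caregiver two doors away, ties resolved toward the lower index
  cg <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  hit <- parallel_sample(rep(TRUE, 5), cg, 3)
  expect_identical(hit$head, 3L)
  expect_identical(hit$caregiver, 5L)
  tie <- parallel_sample(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE), 2)
  expect_identical(tie$head, 1L)  # lower index wins the distance tie
  # absent group reported as NA for the caller to escalate
  expect_true(is.na(parallel_sample(rep(TRUE, 4), rep(FALSE, 4), 2)$caregiver))
})

test_that("a completed survey holds exactly n_per_sa records per group per SA", {
  camp <- generate_camp(camp_config(seed = 2))
  rec <- run_survey(camp, survey_design(), seed = 10)
  tab <- table(rec$sa_id, rec$respondent_group)
  expect_true(all(tab == 19))
  expect_identical(sum(rec$respondent_group == "head_of_household"), 114L)
  expect_identical(sum(rec$respondent_group == "caregiver"), 114L)
  # caregivers answer only caregiver indicators and vice versa
  expect_true(all(is.na(rec$diarrhoea[rec$respondent_group ==
                                        "head_of_household"])))
  expect_true(all(!is.na(rec$diarrhoea[rec$respondent_group ==
                                         "caregiver"])))
  expect_true(all(is.na(rec$soap[rec$respondent_group == "caregiver"])))
})

test_that("surveys are reproducible under a fixed seed", {
  camp <- generate_camp(camp_config(seed = 4))
  a <- run_survey(camp, survey_design(), seed = 99)
  b <- run_survey(camp, survey_design(), seed = 99)
  expect_identical(a, b)
})

test_that("degenerate truth propagates to the responses", {
  cfg <- camp_config(seed = 6)
  cfg$indicators$p0[cfg$indicators$id == "improved_sanitation"] <- 1 - 1e-12
  camp <- generate_camp(cfg)
  camp$truth[, "improved_sanitation"] <- 1
  rec <- run_survey(camp, survey_design(), seed = 1)
  v <- rec$improved_sanitation[rec$respondent_group == "head_of_household"]
  expect_true(all(v == 1L))
})

test_that("tabulated survey counts recover the SA truths in expectation", {
  # SA truths set to the observed Batil proportions; mean simulated counts
  # must match the observed counts within Monte-Carlo error
  set.seed(55)
  bp <- batil_preset()
  nrep <- 1e4
  ind <- setdiff(names(bp$counts), c("sa_id", "n"))
  for (id in c("continuous_water", "soap", "diarrhoea")) {
    p <- bp$counts[[id]] / 19
    sims <- sapply(p, function(pp) rbinom(nrep, 19, pp))
    se <- sqrt(19 * p * (1 - p) / nrep)
    expect_true(all(abs(colMeans(sims) - bp$counts[[id]]) <=
                      3 * se + 1e-9))
  }
  # and one full-pipeline pass agrees in shape
  tab <- tabulate_survey(run_survey(bp$camp, survey_design(), seed = 3))
  expect_identical(sort(tab$sa_id), sort(bp$counts$sa_id))
  expect_true(all(tab$n == 19L))
  expect_true(all(as.matrix(tab[ind]) >= 0 & as.matrix(tab[ind]) <= 19))
})
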