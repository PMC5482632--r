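test_that("Kaplan-Meier matches hand product-limit calculations", {
  rec <- tibble::tibble(time = c(1, 2, 3),
                        event = c("censored", "relapse", "relapse"))
  km <- tidy(km_fit(rec))
  expect_equal(km$estimate[km$time == 2], 0.5)
  expect_equal(km$estimate[km$time == 3], 0)

  # no events: survival stays 1
  none <- tibble::tibble(time = c(5, 8), event = c("censored", "censored"))
  expect_true(all(tidy(km_fit(none))$estimate == 1))

  # two events at distinct times: 1 -> 0.5 -> 0
  two <- tibble::tibble(time = c(4, 9), event = c("relapse", "death"))
  expect_equal(tidy(km_fit(two))$estimate, c(0.5, 0))
  # with the relapse-only event definition the death is a censoring
  expect_equal(tidy(km_fit(two, rfs_events = "relapse"))$estimate,
               c(0.5, 0.5))
})

test_that("records are validated before any fit", {
  expect_error(km_fit(tibble::tibble(time = -1, event = "relapse")),
               "positive")
  expect_error(km_fit(tibble::tibble(time = 1, event = "dead")),
               "unknown event")
  expect_error(km_fit(tibble::tibble(time = numeric(0),
                                     event = character(0))),
               "at least one row")
})

test_that("log-rank matches the manual risk-table oracle", {
  # identical groups duplicated: no signal at all
  base <- tibble::tibble(time = c(2, 4, 6), event = rep("relapse", 3))
  dup <- dplyr::bind_rows(dplyr::mutate(base, group = "a"),
                          dplyr::mutate(base, group = "b"))
  lr0 <- logrank(dup, "group")
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # hand-size n = 6 example against the explicit O-E walk
  rec <- tibble::tibble(
    time = c(1, 3, 4, 5, 8, 9),
    event = c("relapse", "censored", "relapse", "relapse", "censored",
              "relapse"),
    group = c("a", "a", "b", "a", "b", "b"))
  got <- logrank(rec, "group")
  status <- as.integer(rec$event == "relapse")
  exp_lr <- oracle_logrank(rec$time, status, rec$group)
  expect_equal(got$statistic, exp_lr$chisq)
  expect_equal(got$p_value, exp_lr$p)

  expect_error(logrank(dplyr::mutate(base, group = "a"), "group"),
               "2 non-empty groups")
})

test_that("cumulative incidence reduces to 1 - KM without competing deaths", {
  withr::local_seed(33)
  ch <- gen_cohort(cohort_sim_spec(n_subjects = 120, death_hazard = 0,
                                   censor_window = 60, seed = 33))
  cif <- cif_fit(ch)
  km <- tidy(km_fit(ch, rfs_events = "relapse"))
  rel <- tidy(cif)[tidy(cif)$cause == "relapse", ]
  at <- sort(unique(ch$time[ch$event == "relapse"]))
  cif_at <- step_at(at, rel$time, rel$estimate, before = 0)
  km_at <- step_at(at, km$time, km$estimate, before = 1)
  expect_equal(cif_at, 1 - km_at, tolerance = 1e-9)
})

test_that("Aalen-Johansen estimates match a hand-computed table", {
  # 5 records; hand table:
  # t=2 relapse (n=5): S(2-)=1,  CIF_r = 1/5 = 0.2
  # t=3 death   (n=4): S(3-)=0.8, CIF_d = 0.8/4 = 0.2
  # t=4 censored(n=3)
  # t=6 relapse (n=2): S(6-)=0.8*3/4=0.6, CIF_r = 0.2+0.6/2 = 0.5
  rec <- tibble::tibble(
    time = c(2, 3, 4, 6, 7),
    event = c("relapse", "death", "censored", "relapse", "censored"))
  steps <- tidy(cif_fit(rec))
  rel <- steps[steps$cause == "relapse", ]
  dth <- steps[steps$cause == "death", ]
  expect_equal(step_at(c(2, 3, 6), rel$time, rel$estimate, before = 0),
               c(0.2, 0.2, 0.5))
  expect_equal(step_at(c(2, 3, 6), dth$time, dth$estimate, before = 0),
               c(0, 0.2, 0.2))

  # degenerate: everyone relapses at the same time
  all_rel <- tibble::tibble(time = rep(3, 4), event = rep("relapse", 4))
  ar <- tidy(cif_fit(all_rel))
  ar <- ar[ar$cause == "relapse", ]
  expect_equal(max(ar$estimate), 1)
})

test_that("relapse, death and event-free probabilities sum to one", {
  withr::local_seed(35)
  for (seed in 1:5) {
    ch <- gen_cohort(cohort_sim_spec(n_subjects = 80, seed = seed))
    steps <- tidy(cif_fit(ch))
    km <- tidy(km_fit(ch, rfs_events = c("relapse", "death")))
    at <- sort(unique(ch$time[ch$event != "censored"]))
    total <-
      step_at(at, steps$time[steps$cause == "relapse"],
              steps$estimate[steps$cause == "relapse"], before = 0) +
      step_at(at, steps$time[steps$cause == "death"],
              steps$estimate[steps$cause == "death"], before = 0) +
      step_at(at, km$time, km$estimate, before = 1)
    expect_equal(total, rep(1, length(at)), tolerance = 1e-9)
  }
})

test_that("estimators are invariant to record order", {
  ch <- gen_cohort(cohort_sim_spec(n_subjects = 60, seed = 44))
  perm <- ch[sample(nrow(ch)), ]
  expect_equal(tidy(km_fit(ch)), tidy(km_fit(perm)))
  expect_equal(tidy(cif_fit(ch)), tidy(cif_fit(perm)))
})

test_that("Gray's test detects group differences and nothing else", {
  base <- tibble::tibble(time = c(2, 4, 6, 9),
                         event = c("relapse", "death", "relapse",
                                   "censored"))
  dup <- dplyr::bind_rows(dplyr::mutate(base, group = "a"),
                          dplyr::mutate(base, group = "b"))
  g0 <- gray_test(dup, "group")
  expect_equal(unname(g0$p_value[g0$cause == "relapse"]), 1)

  expect_error(gray_test(dplyr::mutate(base, group = "a"), "group"),
               "2 non-empty groups")

  # without competing events Gray's test tracks the log-rank closely
  withr::local_seed(51)
  ps <- t(vapply(1:60, function(seed) {
    ch <- gen_cohort(cohort_sim_spec(n_subjects = 100, death_hazard = 0,
                                     seed = seed))
    ch$group <- factor(ch$biomarker_high)
    c(gray_test(ch, "group")$p_value[1],
      logrank(ch, "group", rfs_events = "relapse")$p_value)
  }, numeric(2)))
  expect_gt(stats::cor(ps[, 1], ps[, 2]), 0.95)
  expect_lt(abs(mean(ps[, 1] < 0.05) - mean(ps[, 2] < 0.05)), 0.05)

  # strong relapse-hazard effect: decisive rejection
  withr::local_seed(52)
  hits <- vapply(1:20, function(seed) {
    ch <- gen_cohort(cohort_sim_spec(
      n_subjects = 400, beta = c(biomarker_high = log(5)), seed = seed))
    ch$group <- factor(ch$biomarker_high)
    gray_test(ch, "group")$p_value[
      gray_test(ch, "group")$cause == "relapse"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Cox fit maximizes the written-out partial likelihood", {
  rec <- tibble::tibble(
    time = c(2, 5, 7, 9),
    event = c("relapse", "relapse", "relapse", "censored"),
    x = c(1, 0, 1, 0))
  fit <- cox_fit(rec, "x")
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = rec$time,
               status = as.integer(rec$event == "relapse"), x = rec$x)
  expect_equal(tidy(fit)$estimate, grid[which.max(ll)], tolerance = 1e-3)
  # likelihood at the MLE dominates the null
  expect_gte(fit$loglik, oracle_cox_loglik(0, rec$time,
                                           as.integer(rec$event == "relapse"),
                                           rec$x))
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
})

test_that("Efron and Breslow agree without ties; competing deaths censor", {
  ch <- gen_cohort(cohort_sim_spec(n_subjects = 150, seed = 61))
  fe <- cox_fit(ch, "biomarker_high", ties = "efron")
  fb <- cox_fit(ch, "biomarker_high", ties = "breslow")
  expect_equal(tidy(fe)$estimate, tidy(fb)$estimate, tolerance = 1e-9)

  # cause-specific relapse model uses only relapse events
  expect_equal(fe$n_event, sum(ch$event == "relapse"))
  frfs <- cox_fit(ch, "biomarker_high", outcome = "rfs")
  expect_equal(frfs$n_event, sum(ch$event != "censored"))
})

test_that("degenerate Cox inputs are flagged, never silent", {
  ch <- gen_cohort(cohort_sim_spec(n_subjects = 50, seed = 71))
  ch$flat <- 1
  expect_error(cox_fit(ch, "flat"), "constant")

  # perfect separation: all relapses in one group, earlier than all others
  sep <- tibble::tibble(
    time = c(1, 2, 3, 10, 11, 12),
    event = c(rep("relapse", 3), rep("censored", 3)),
    x = c(1, 1, 1, 0, 0, 0))
  expect_warning(f <- cox_fit(sep, "x"), "converge")
  expect_false(f$converged)

  expect_error(cox_fit(ch, character(0)), "no covariates")
})

test_that("null Wald p-values are uniform across replicates", {
  withr::local_seed(81)
  p <- vapply(1:150, function(seed) {
    ch <- gen_cohort(cohort_sim_spec(n_subjects = 100, seed = 1000 + seed))
    ch$noise <- rnorm(nrow(ch))
    tidy(cox_fit(ch, "noise"))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("backward elimination drops only weak covariates, with a trace", {
  # all covariates strongly associated: nothing eliminated
  ch <- gen_cohort(cohort_sim_spec(
    n_subjects = 600,
    covariates = tibble::tibble(
      name = c("a", "b"), type = "binary", prevalence = 0.5),
    beta = c(a = log(4), b = log(3)), seed = 91))
  kept <- backward_eliminate(ch, c("a", "b"))
  expect_equal(nrow(kept$trace), 0)
  expect_setequal(kept$covariates, c("a", "b"))

  # a single pure-noise covariate on top of a strong model
  ch$noise <- rnorm(nrow(ch))
  elim <- backward_eliminate(ch, c("a", "b", "noise"))
  expect_true("noise" %in% elim$trace$dropped ||
                "noise" %in% elim$covariates)

  # all-noise model ends empty most of the time
  withr::local_seed(93)
  empty <- vapply(1:20, function(seed) {
    chn <- gen_cohort(cohort_sim_spec(n_subjects = 400, seed = 200 + seed))
    chn$noise <- rnorm(nrow(chn))
    is.null(backward_eliminate(chn, "noise")$fit)
  }, logical(1))
  expect_gte(mean(empty), 0.7)
})

test_that("point estimates read the step functions correctly", {
  none <- tibble::tibble(time = c(70, 80), event = rep("censored", 2))
  expect_equal(point_estimate_at(km_fit(none), 60)$estimate, 1)
  expect_equal(point_estimate_at(cif_fit(none), 60)$estimate, 0)

  one <- tibble::tibble(time = c(10, 80),
                        event = c("relapse", "censored"))
  expect_equal(point_estimate_at(km_fit(one), 60)$estimate, 0.5)

  short <- tibble::tibble(time = c(10, 20),
                          event = c("relapse", "relapse"))
  expect_warning(pe <- point_estimate_at(km_fit(short), 60),
                 "carrying forward")
  expect_equal(pe$estimate, 0)

  # closed-form check: exponential competing hazards
  spec <- cohort_sim_spec(n_subjects = 4000, baseline_relapse = 0.012,
                          death_hazard = 0.004, censor_window = Inf,
                          seed = 97)
  cif <- cif_fit(gen_cohort(spec))
  lam <- 0.016
  closed <- (0.012 / lam) * (1 - exp(-lam * 60))
  expect_equal(point_estimate_at(cif, 60)$estimate, closed,
               tolerance = 0.05)
})
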