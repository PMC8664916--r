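# hand-built trajectory sets with known counts
fake_traj <- function(runs, arch, lh = life_history_params(n_eq = 100),
                      final_release_day = 0L, stochastic = TRUE) {
  structure(list(runs = runs, legend = arch$gset$legend, gset = arch$gset,
                 arch_name = arch$name, effector = arch$effector,
                 horizon = nrow(runs[[1]]$female) - 1L, n_patches = 1L,
                 reps = length(runs), seed = 0L, stochastic = stochastic,
                 final_release_day = final_release_day, lh = lh),
            class = "trajectory_set")
}

hs <- homing_suppression_architecture()

test_that("carrier frequency counts females with at least one effector copy", {
  nG <- nrow(hs$gset$legend)
  fem <- array(0, dim = c(3, nG, 1))
  # day 0: 3 of 4 females carry H; day 1: none alive; day 2: all carriers
  hw <- match("F|drive:W/H", hs$gset$legend$label)
  ww <- match("F|drive:W/W", hs$gset$legend$label)
  fem[1, hw, 1] <- 3; fem[1, ww, 1] <- 1
  fem[3, hw, 1] <- 5
  run <- list(female = fem, male = array(0, dim = c(3, nG, 1)),
              juvenile = matrix(0, 3, 1))
  cf <- carrier_frequency(fake_traj(list(run), hs))
  expect_equal(cf, c(0.75, NA, 1))
  expect_error(carrier_frequency(fake_traj(list(run), hs), "drive", "Z"),
               "unknown allele")
})

test_that("window of protection counts days at or above threshold", {
  expect_equal(window_of_protection(rep(0.5, 50))$days, 0)
  expect_equal(window_of_protection(rep(1.0, 100))$days, 100)
  s <- rep(0.2, 60); s[11:50] <- 0.93
  w <- window_of_protection(s)
  expect_equal(w$days, 40)
  expect_equal(w$longest_run, 40)
  # split runs: total vs longest-contiguous differ
  s2 <- c(rep(0.95, 10), 0.1, rep(0.95, 5))
  w2 <- window_of_protection(s2)
  expect_equal(w2$days, 15); expect_equal(w2$longest_run, 10)
  expect_error(window_of_protection(numeric(0)), "empty")
})

test_that("window of protection is monotone non-increasing in the threshold", {
  set.seed(1)
  s <- pmin(1, pmax(0, cumsum(rnorm(300, 0, 0.05)) + 0.9))
  days <- vapply(seq(0.1, 1, by = 0.05),
                 function(th) window_of_protection(s, th)$days, 0)
  expect_true(all(diff(days) <= 0))
})

test_that("elimination statistics summarize absorbing extinctions", {
  nG <- nrow(hs$gset$legend)
  mk_run <- function(elim_day, horizon = 30) {
    fem <- array(0, dim = c(horizon + 1, nG, 1))
    alive <- if (is.na(elim_day)) horizon + 1 else elim_day
    fem[seq_len(alive), 1, 1] <- 5
    list(female = fem, male = array(0, dim = c(horizon + 1, nG, 1)),
         juvenile = matrix(0, horizon + 1, 1))
  }
  # 2 of 4 reps extinct, both 14 days after the final release (day 2)
  tr <- fake_traj(list(mk_run(17), mk_run(17), mk_run(NA), mk_run(NA)), hs,
                  final_release_day = 3L)
  es <- elimination_stats(tr)
  expect_equal(es$probability, 0.5)
  expect_equal(es$mean_weeks, 2)
  es_all <- elimination_stats(fake_traj(list(mk_run(5), mk_run(9)), hs))
  expect_equal(es_all$probability, 1)
  es_none <- elimination_stats(fake_traj(list(mk_run(NA)), hs))
  expect_equal(es_none$probability, 0)
  expect_true(is.na(es_none$mean_weeks))
})

test_that("rebound time finds recovery after the post-release minimum", {
  # never suppressed below the target -> 0 weeks
  expect_equal(rebound_time(rep(100, 200), 100, final_release_day = 10)$weeks, 0)
  # V-shaped series first reaching 95% of baseline 70 days post-release
  s <- c(rep(100, 21),                      # days 0..20
         seq(98, 20, length.out = 35),      # days 21..55: decline
         seq(21, 94, length.out = 34),      # days 56..89: recovery below target
         96, rep(100, 50))                  # day 90: recrossing
  rt <- rebound_time(s, 100, 0.95, final_release_day = 20)
  expect_equal(rt$weeks, 10)
  # monotone decline: flagged, no rebound
  rt2 <- rebound_time(seq(100, 0, length.out = 80), 100, final_release_day = 5)
  expect_false(rt2$rebounded)
  expect_true(is.na(rt2$weeks))
})

test_that("metric_report on a deterministic run equals its own mean trajectory", {
  cfg <- make_sim_fixture("homing_suppression", scale = 0.02, horizon = 150,
                          reps = 1, seed = 3)
  cfg <- sim_config(cfg$architecture, cfg$lifecycle, cfg$releases,
                    cfg$migration, modifyList(cfg$run, list(stochastic = FALSE)))
  traj <- run_config(cfg)
  rep_ <- metric_report(traj)
  cf_mean <- carrier_frequency(traj, patch = 1, rep = "mean")
  cf_one <- carrier_frequency(traj, patch = 1, rep = 1)
  expect_identical(cf_mean, cf_one)
  expect_equal(rep_$wop[[1]]$days, window_of_protection(cf_one)$days)
  expect_null(rep_$elimination)  # deterministic runs carry no extinction draws
})
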