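men_arch <- mendelian_architecture(locus_map(locus("grna", "autosomal", c("W", "G"))))

test_that("the all-wild-type equilibrium is stationary", {
  lh <- life_history_params(n_eq = 10000)
  st <- equilibrium_state(men_arch, lh)
  adults <- function(s) sum(s$M) + sum(s$U) + sum(s$Fm)
  expect_equal(adults(st), 10000)
  # one deterministic day reproduces the state to numerical precision
  dyn <- drivesim:::precompute_dynamics(men_arch, lh)
  s1 <- drivesim:::step_day(st, dyn, stochastic = FALSE)
  expect_lt(max(abs(s1$L - st$L) / pmax(st$L, 1)), 1e-9)
  expect_equal(adults(s1), 10000, tolerance = 1e-9)
  # a full simulated year stays within 5% of the target
  s <- st
  for (d in 1:365) s <- drivesim:::step_day(s, dyn, stochastic = FALSE)
  expect_lt(abs(adults(s) - 10000) / 10000, 0.05)
  # empty world
  st0 <- equilibrium_state(men_arch, life_history_params(n_eq = 0))
  expect_equal(drivesim:::state_total(st0), 0)
})

test_that("infeasible life histories are rejected with a clear error", {
  expect_error(life_history_params(fecundity = 0.5, n_eq = 100), "rm too large")
})

test_that("stochastic runs are seed-reproducible and extinction is absorbing", {
  lh <- tiny_lh()
  t1 <- simulate_drive(men_arch, lh, horizon = 40, reps = 2, seed = 42)
  t2 <- simulate_drive(men_arch, lh, horizon = 40, reps = 2, seed = 42)
  expect_identical(t1$runs[[1]]$female, t2$runs[[1]]$female)
  expect_identical(t1$runs[[2]]$male, t2$runs[[2]]$male)
  t3 <- simulate_drive(men_arch, lh, horizon = 40, reps = 2, seed = 43)
  expect_false(identical(t1$runs[[1]]$female, t3$runs[[1]]$female))
  # an empty patch stays empty under stochastic dynamics
  dyn <- drivesim:::precompute_dynamics(men_arch, lh)
  s <- drivesim:::new_patch_state(nrow(men_arch$gset$legend), lh)
  for (d in 1:30) s <- drivesim:::step_day(s, dyn, stochastic = TRUE)
  expect_equal(drivesim:::state_total(s), 0)
})

test_that("stochastic means track the deterministic trajectory", {
  lh <- life_history_params(n_eq = 10000)
  det <- simulate_drive(men_arch, lh, horizon = 30, reps = 1, seed = 1,
                        stochastic = FALSE)
  sto <- simulate_drive(men_arch, lh, horizon = 30, reps = 100, seed = 1)
  det_f <- rowSums(det$runs[[1]]$female[, , 1])
  mean_f <- rowSums(Reduce(`+`, lapply(sto$runs, function(r) r$female[, , 1])) / 100)
  expect_lt(max(abs(mean_f - det_f) / det_f), 0.02)
})

test_that("releases add males on scheduled days only", {
  lh <- tiny_lh()
  sched <- release_schedule(patch = 1, genotype = men_arch$release_label,
                            size = 100, n_releases = 12, interval = 7, start = 1)
  expect_identical(drivesim:::release_days(sched), as.integer(seq(1, 78, by = 7)))
  expect_equal(sum(rep(100, 12)), 1200)
  st <- equilibrium_state(men_arch, lh)
  st2 <- apply_release(st, men_arch$gset, men_arch$release_label, 100)
  expect_equal(sum(st2$M) - sum(st$M), 100)
  expect_error(apply_release(st, men_arch$gset, "M|nonsense", 10), "unknown")
  expect_error(apply_release(st, men_arch$gset, men_arch$wild_female, 10), "male")
})

test_that("migration conserves adults and matches the expected daily rate", {
  lh <- tiny_lh(n_eq = 1000)
  mig0 <- migration_matrix(0, 2, lh$t_gen)
  mig <- migration_matrix(0.01, 2, lh$t_gen)
  expect_equal(mig$m_daily, 0.01 / lh$t_gen)
  states <- list(equilibrium_state(men_arch, lh), equilibrium_state(men_arch, lh))
  expect_identical(migrate(states, mig0, stochastic = FALSE), states)
  # deterministic expected movers: N * m/t_gen out of each patch
  lh2 <- life_history_params(n_eq = 0)
  empty <- drivesim:::new_patch_state(nrow(men_arch$gset$legend), lh)
  out <- migrate(list(states[[1]], empty), migration_matrix(1, 2, lh$t_gen),
                 stochastic = FALSE)
  moved <- drivesim:::state_total(out[[2]])
  expect_equal(moved, 1000 * (1 / lh$t_gen), tolerance = 1e-9)
  # stochastic conservation
  set.seed(9)
  out2 <- migrate(lapply(states, drivesim:::round_state), mig, stochastic = TRUE)
  tot_before <- sum(vapply(lapply(states, drivesim:::round_state),
                           drivesim:::state_total, 0))
  expect_equal(sum(vapply(out2, drivesim:::state_total, 0)), tot_before)
})

test_that("a neutral allele shows no systematic frequency drift", {
  lh <- tiny_lh(n_eq = 2000)
  rel <- release_schedule(genotype = "M|grna:G/G", size = 500,
                          n_releases = 1, start = 1)
  traj <- simulate_drive(men_arch, lh, releases = rel, horizon = 700,
                         reps = 1, seed = 1, stochastic = FALSE)
  allele_freq <- function(day) {
    f <- traj$runs[[1]]$female[day + 1, , 1]
    m <- traj$runs[[1]]$male[day + 1, , 1]
    cnt <- f + m
    copies <- drivesim:::allele_count(men_arch$gset, "grna", "G")
    sum(cnt * copies) / (2 * sum(cnt))
  }
  drift_per_gen <- abs(allele_freq(650) - allele_freq(500)) / (150 / lh$t_gen)
  expect_lt(drift_per_gen, 1e-6)
  expect_gt(allele_freq(650), 0.01)  # the allele is actually segregating
})

test_that("a fixed perfect Y-shredder drives females monotonically to zero", {
  arch <- x_shredder_architecture("Y", shredder_params(1, 0), fitness_params(0, 0, 0))
  lh <- tiny_lh(n_eq = 1000)
  st <- equilibrium_state(arch, lh)
  # fix the shredder in every male: adults, mates-on-record, and the male
  # juveniles already in the aquatic pipeline
  smale <- match("M|shredder:S;xchrom:Xs", arch$gset$legend$label)
  wmale <- match(arch$wild_male, arch$gset$legend$label)
  st$M[smale] <- st$M[wmale]; st$M[wmale] <- 0
  st$Fm[, smale] <- st$Fm[, wmale]; st$Fm[, wmale] <- 0
  for (stage in c("E", "L", "P")) {
    st[[stage]][, smale] <- st[[stage]][, wmale]
    st[[stage]][, wmale] <- 0
  }
  dyn <- drivesim:::precompute_dynamics(arch, lh)
  fem <- function(s) sum(s$U) + sum(s$Fm)
  s <- st
  # let the pre-existing (wild-type-fathered) female juveniles eclose first
  flush <- lh$t_egg + lh$t_larva + lh$t_pupa + 1
  for (d in seq_len(flush)) s <- drivesim:::step_day(s, dyn, stochastic = FALSE)
  prev <- fem(s)
  for (d in 1:200) {
    s <- drivesim:::step_day(s, dyn, stochastic = FALSE)
    expect_lte(fem(s), prev + 1e-9)
    prev <- fem(s)
  }
  expect_lt(fem(s), 1e-3)
})

test_that("trajectory_long emits a tidy day/patch/sex/genotype table", {
  lh <- tiny_lh(n_eq = 200)
  traj <- simulate_drive(men_arch, lh, horizon = 3, reps = 2, seed = 1)
  long <- trajectory_long(traj)
  expect_named(long, c("rep", "day", "patch", "sex", "genotype", "count"))
  expect_setequal(unique(long$day), 0:3)
  d0 <- long[long$day == 0 & long$rep == 1, ]
  expect_equal(sum(d0$count), 200)
})
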