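test_that("generators are bit-reproducible under a fixed seed", {
  d <- sim_design(S = 20)
  a <- simulate_occupancy(d, seed = 5)
  b <- simulate_occupancy(d, seed = 5)
  expect_identical(a$records$datetime, b$records$datetime)
  expect_identical(a$data$yA, b$data$yA)
  c2 <- simulate_occupancy(d, seed = 6)
  expect_false(identical(a$records$datetime, c2$records$datetime))
  s1 <- simulate_activity(d, seed = 5)
  s2 <- simulate_activity(d, seed = 5)
  expect_identical(s1$events$sun_time, s2$events$sun_time)
})

test_that("latent-state frequencies match the state probabilities", {
  d <- sim_design(S = 10000L, years = 2009, preset = "test")
  sim <- simulate_occupancy(d, seed = 17)
  states <- sim$truth$latent_state[["2009"]]
  freq <- table(factor(states, levels = c("AB", "A", "B", "none"))) / 10000
  expected <- state_probs(0.4, 0.9, 0.2)
  for (s in names(expected)) {
    se3 <- 3 * sqrt(expected[[s]] * (1 - expected[[s]]) / 10000)
    expect_lt(abs(freq[[s]] - expected[[s]]), se3 + 1e-9)
  }
})

test_that("conditional occupancy boundaries behave as constructed", {
  ## psiBA = 1, psiBa ~ 0: B occurs only where A is present
  d <- sim_design(S = 2000L, years = 2009,
                  occupancy = c(psiA = 0.5, psiBA = 1, psiBa = 0.001),
                  detection = c(pA = 0.3, pB = 0.3, rA = 0.3, rBA = 0.3,
                                rBa = 0.3))
  sim <- simulate_occupancy(d, seed = 23)
  st <- sim$truth$latent_state[["2009"]]
  expect_lt(sum(st == "B"), 10)      # ~ 2000 * 0.5 * 0.001 expected
  expect_gt(sum(st == "AB"), 0)
  ## psiBA = psiBa: empirical interaction factor near 1 at large S
  d2 <- sim_design(S = 5000L, years = 2009,
                   occupancy = c(psiA = 0.4, psiBA = 0.6, psiBa = 0.6),
                   detection = c(pA = 0.3, pB = 0.3, rA = 0.3, rBA = 0.3,
                                 rBa = 0.3))
  sim2 <- simulate_occupancy(d2, seed = 29)
  st2 <- sim2$truth$latent_state[["2009"]]
  zA <- st2 %in% c("AB", "A"); zB <- st2 %in% c("AB", "B")
  emp_sif <- mean(zA & zB) / (mean(zA) * mean(zB))
  expect_lt(abs(emp_sif - 1), 0.1)
  expect_equal(sim2$truth$sif, 1)
})

test_that("true overlap oracle is a proper similarity on mixtures", {
  vm <- function(mu, k) list(w = 1, mu = mu, kappa = k)
  expect_equal(true_overlap(vm(0, 3), vm(0, 3)), 1, tolerance = 1e-6)
  expect_lt(true_overlap(vm(0, 5), vm(pi, 5)), 0.03)
  s1 <- list(w = c(0.7, 0.3), mu = c(0, pi), kappa = c(2, 1))
  s2 <- vm(1, 2)
  expect_equal(true_overlap(s1, s2), true_overlap(s2, s1))
  d <- true_overlap(s1, s2)
  expect_true(d > 0 && d < 1)
})

test_that("activity generator matches its truth at scale", {
  d <- sim_design(n_events = c(jaguar = 500, puma = 500, deer = 500,
                               peccary = 500, calf = 500), years = 2009)
  sim <- simulate_activity(d, seed = 77)
  ev <- sim$events
  ## identical spec vs itself has truth 1; predator-prey truth well below
  expect_equal(sim$truth$delta["jaguar", "jaguar"], 1, tolerance = 1e-6)
  jd_truth <- sim$truth$delta["jaguar", "deer"]
  jag <- ev$sun_time[ev$species == "jaguar"]
  deer <- ev$sun_time[ev$species == "deer"]
  expect_lt(abs(overlap_delta1(jag, deer) - jd_truth), 0.07)
  ## clock-time export keeps the circular pattern ingestible
  sim2 <- simulate_activity(sim_design(years = 2009), seed = 3,
                            clock_times = TRUE)
  expect_true(all(!is.na(sim2$events$datetime)))
})
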