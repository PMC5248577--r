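test_that("von Mises primitives are stable and self-consistent", {
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  for (k in c(0.5, 2, 50, 500))
    expect_equal(mean(dvonmises(th, 1, k)) * 2 * pi, 1, tolerance = 1e-6)
  set.seed(2)
  x <- rvonmises(5000, 2, 3)
  mu_hat <- atan2(mean(sin(x)), mean(cos(x)))
  expect_lt(abs(mu_hat - 2), 0.06)
  expect_lt(abs(kappa_ml(x) - 3), 0.35)
  expect_lt(kappa_ml(runif(5000, 0, 2 * pi)), 0.1)
  set.seed(9); a <- rvonmises(10, 0, 1)
  set.seed(9); b <- rvonmises(10, 0, 1)
  expect_identical(a, b)
})

test_that("circular KDE integrates to one and finds the mode", {
  set.seed(3)
  x <- rvonmises(3000, pi, 2)
  d <- vm_kernel_density(x)
  expect_equal(mean(d$values) * 2 * pi, 1, tolerance = 1e-9)
  expect_true(all(d$values >= 0))
  expect_lt(abs(d$grid[which.max(d$values)] - pi), 0.15)
  expect_error(vm_kernel_density(1.2), "at least 2")
  ## flat-density limit
  u <- runif(10000, 0, 2 * pi)
  du <- vm_kernel_density(u)
  expect_true(all(abs(du$values - 1 / (2 * pi)) < 0.1 / (2 * pi)))
})

test_that("overlap coefficient is a symmetric, rotation-invariant metric", {
  set.seed(6)
  x <- rvonmises(300, 1, 2)
  expect_equal(overlap_delta1(x, x), 1)
  y <- rvonmises(300, 4, 1)
  expect_equal(overlap_delta1(x, y), overlap_delta1(y, x))
  rot <- 1.1
  expect_equal(overlap_delta1((x + rot) %% (2 * pi), (y + rot) %% (2 * pi)),
               overlap_delta1(x, y), tolerance = 0.02)
  d <- overlap_delta1(x, y)
  expect_true(d >= 0 && d <= 1)
  ## widely separated concentrated densities barely overlap
  a <- rvonmises(1000, 0, 20); b <- rvonmises(1000, pi, 20)
  expect_lt(overlap_delta1(a, b), 0.05)
  ## consistency against the numerically integrated truth
  a2 <- rvonmises(1000, 0, 1); b2 <- rvonmises(1000, pi / 2, 1)
  truth <- true_overlap(list(w = 1, mu = 0, kappa = 1),
                        list(w = 1, mu = pi / 2, kappa = 1))
  expect_lt(abs(overlap_delta1(a2, b2) - truth), 0.05)
  ## the large-sample variant agrees at this n and is exact on identity
  expect_lt(abs(overlap_delta4(a2, b2) - truth), 0.05)
  expect_equal(overlap_delta4(x, x), 1)
})

test_that("bootstrap interval is seeded, ordered and degenerate-safe", {
  set.seed(8)
  x <- rvonmises(60, 0, 2); y <- rvonmises(60, 2, 1)
  ci1 <- bootstrap_ci(x, y, reps = 200, seed = 5)
  ci2 <- bootstrap_ci(x, y, reps = 200, seed = 5)
  expect_identical(ci1[c("delta1", "ci_low", "ci_high")],
                   ci2[c("delta1", "ci_low", "ci_high")])
  expect_true(ci1$ci_low <= ci1$ci_high)
  expect_true(ci1$ci_low >= 0 && ci1$ci_high <= 1)
  ## identical samples: estimate exactly 1, upper bound at the top
  ci3 <- bootstrap_ci(x, x, reps = 200, seed = 5)
  expect_equal(ci3$delta1, 1)
  expect_gt(ci3$ci_high, 0.97)
  expect_error(bootstrap_ci(x, y, reps = 50), "100")
})

test_that("activity classification integrates the sun-time windows", {
  ## uniform density: proportions equal the windows' angular fractions
  m <- 128L
  flat <- structure(list(grid = seq(0, 2 * pi, length.out = m + 1)[-(m + 1)],
                         values = rep(1 / (2 * pi), m), kappa = 1e-4,
                         n = 100L, adjust = 1),
                    class = "activity_density")
  cl <- classify_activity(flat, day_hours = 12)
  expect_equal(sum(cl$proportions), 1, tolerance = 1e-6)
  ## at 12 h day: crepuscular = 4 h of 24 = pi/3 radians fraction
  expect_equal(unname(cl$proportions["crepuscular"]), 4 / 24,
               tolerance = 0.01)
  expect_equal(unname(cl$proportions["diurnal"]), 10 / 24, tolerance = 0.01)
  ## density concentrated at solar midnight is nocturnal
  set.seed(12)
  night <- vm_kernel_density(rvonmises(200, 0, 4))
  expect_equal(classify_activity(night)$label, "nocturnal")
  noonish <- vm_kernel_density(rvonmises(200, pi, 4))
  expect_equal(classify_activity(noonish)$label, "diurnal")
})
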