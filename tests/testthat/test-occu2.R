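test_that("logit links are mutually inverse with domain checks", {
  expect_equal(inv_logit(0), 0.5)
  xs <- -5:5
  expect_equal(logit(inv_logit(xs)), as.numeric(xs))
  expect_equal(inv_logit(-745), 0, tolerance = 1e-12)  # limit to 0
  expect_error(logit(0), "inside")
  expect_error(logit(1.2), "inside")
})

test_that("latent-state probabilities match the conditional construction", {
  expect_equal(state_probs(0.28, 1, 1),
               c(AB = 0.28, A = 0, B = 0.72, none = 0))
  expect_equal(state_probs(0.5, 0.5, 0.5),
               c(AB = 0.25, A = 0.25, B = 0.25, none = 0.25))
  set.seed(4)
  for (i in 1:25) {
    p <- runif(3)
    expect_equal(sum(state_probs(p[1], p[2], p[3])), 1)
  }
})

test_that("occasion probabilities follow the conditional detection tables", {
  pars <- list(pA = 0.2, pB = 0.3, rA = 0.03, rBA = 0.04, rBa = 0.05)
  expect_equal(occasion_prob("AB", 1, 1, pars), 0.03 * 0.04)
  expect_equal(occasion_prob("none", 1, 0, pars), 0)
  expect_equal(occasion_prob("A", 0, 1, pars), 0)     # no false B detections
  expect_equal(occasion_prob("AB", NA, NA, pars), 1)  # masked occasion
  for (s in c("AB", "A", "B", "none")) {
    tot <- sum(vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                      function(o) occasion_prob(s, o[1], o[2], pars),
                      numeric(1)))
    expect_equal(tot, 1)
  }
})

test_that("site likelihood marginalises the latent states", {
  p <- list(psiA = 0.5, psiBA = 0.5, psiBa = 0.5, pA = 0.5, pB = 0.5,
            rA = 0.5, rBA = 0.5, rBa = 0.5)
  ## hand enumeration: 0.25*(0.25 + 0.5 + 0.5 + 1)
  expect_equal(site_loglik(0, 0, p), log(0.5625))
  ## a (1,1) observation eliminates every state but AB
  p2 <- random_params()
  yA <- c(1, 0); yB <- c(1, 1)
  manual <- p2$psiA * p2$psiBA *
    (p2$rA * p2$rBA) * ((1 - p2$rA) * p2$rBa)
  expect_equal(site_loglik(yA, yB, p2), log(manual))
})

test_that("site likelihood equals brute-force enumeration on small instances", {
  set.seed(21)
  for (i in 1:150) {
    p <- random_params()
    J <- sample(1:4, 1)
    h <- random_history(J)
    expect_equal(site_loglik(h$yA, h$yB, p),
                 log(oracle_site_lik(h$yA, h$yB, p)),
                 tolerance = 1e-10)
  }
})

test_that("AICc follows the small-sample formula and guards n", {
  expect_equal(aicc(-1176, 8, 400), 2352 + 16 + 144 / 391)
  expect_equal(aicc(-100, 0, 50), 200)                 # no penalty at K = 0
  expect_equal(aicc(-100, 4, 1e9), 208, tolerance = 1e-6)  # AIC limit
  expect_error(aicc(-100, 8, 9), "n")
})

test_that("Akaike weights and model likelihoods are normalised", {
  tab <- akaike_table(c(100, 100))
  expect_equal(tab$weight, c(0.5, 0.5))
  tab2 <- akaike_table(c(2368.11, 2373.41, 2377.57))
  expect_equal(sum(tab2$weight), 1)
  expect_equal(round(tab2$mlik[2], 2), 0.07)
  expect_true(all(diff(tab2$mlik) <= 0))
})

test_that("SIF and joint occupancy follow the derived-parameter formulas", {
  expect_equal(sif(0.28, 1, 1), 1)
  expect_equal(round(sif(0.28, 1, 0.91), 4), 1.0693)
  expect_equal(psi2(0.28, 1), 0.28)
  expect_equal(psi2(0.3, 0), 0)
  set.seed(7)
  for (i in 1:25) {
    p <- runif(3, 0.05, 0.95)
    expect_equal(sif(p[1], p[2], p[2]), 1)      # independence by construction
    psiB <- p[1] * p[2] + (1 - p[1]) * p[3]
    expect_lte(psi2(p[1], p[2]), min(p[1], psiB) + 1e-12)
  }
  expect_error(sif(0.5, 0, 0), "undefined")
})

test_that("model strings for the candidate set parse to the right designs", {
  strings <- c(
    "psiA(deer) psiBA(y*peccary) psiBa(y*peccary) pA=rA(.) pB=rBA=rBa(.)",
    "psiA(deer) psiBA(y*peccary) psiBa(y*calf) pA=rA(.) pB=rBA=rBa(.)",
    "psiA(deer) psiBA(y*peccary) psiBa(.) pA=rA(.) pB=rBA=rBa(.)",
    "psiA(deer) psiBA(y*peccary) psiBa(deer) pA=rA(.) pB=rBA=rBa(.)",
    "psiA(deer) psiBA(y*peccary) psiBa(calf) pA=rA(.) pB=rBA=rBa(.)")
  for (s in strings) {
    m <- parse_model_string(s)
    expect_s3_class(m, "occu2_model")
    expect_equal(deparse(m$formulas$psiA[[2]]), "deer")
    expect_equal(deparse(m$formulas$psiBA[[2]]), "year * peccary")
    expect_true(any(vapply(m$share, function(g)
      setequal(g, c("pB", "rBA", "rBa")), logical(1))))
  }
  expect_error(parse_model_string("psiX(.)"), "unknown")
})

test_that("fit matches an independent single-species oracle when B is absent", {
  set.seed(5)
  S <- 150L; J <- 10L
  z <- rbinom(S, 1, 0.6)
  yA <- matrix(rbinom(S * J, 1, 0.4) * z, S, J)
  yB <- matrix(0L, S, J)
  cov <- data.frame(site = sprintf("s%03d", 1:S), year = 2009)
  dat <- occu2_data(yA, yB, cov)
  m <- occu2_model(share = list(c("pA", "rA"), c("pB", "rBA", "rBa"),
                                c("psiBA", "psiBa")))
  f <- fit_occu2(m, dat, nstart = 2)
  est <- predict(f, "psiA", cov[1, , drop = FALSE])$estimate
  estp <- predict(f, "pA", cov[1, , drop = FALSE])$estimate
  ## oracle: directly maximise the classic single-season occupancy
  ## likelihood for species A (probability scale, box-constrained)
  nd <- rowSums(yA)
  nll1 <- function(par) {
    psi <- par[1]; p <- par[2]
    -sum(ifelse(nd > 0,
                log(psi) + nd * log(p) + (J - nd) * log(1 - p),
                log(psi * (1 - p)^J + 1 - psi)))
  }
  op <- optim(c(0.5, 0.3), nll1, method = "L-BFGS-B",
              lower = 1e-4, upper = 1 - 1e-4)
  expect_equal(est, op$par[1], tolerance = 1e-3)
  expect_equal(estp, op$par[2], tolerance = 1e-3)
})

test_that("multi-start optimisation is reproducible and seed-stable", {
  sim <- simulate_occupancy(sim_design(S = 80, years = 2009,
                                       preset = "test"), seed = 9)
  m <- occu2_model()
  f1 <- fit_occu2(m, sim$data, seed = 1, nstart = 3)
  f2 <- fit_occu2(m, sim$data, seed = 2, nstart = 3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  f3 <- fit_occu2(m, sim$data, seed = 1, nstart = 3)
  expect_identical(coef(f1), coef(f3))
})

test_that("a zero-effect covariate never decreases the maximised likelihood", {
  sim <- simulate_occupancy(sim_design(S = 80, years = 2009,
                                       preset = "test"), seed = 14)
  f0 <- fit_occu2(occu2_model(), sim$data, nstart = 2)
  f1 <- fit_occu2(occu2_model(psiA = ~road), sim$data, nstart = 2)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("likelihood is invariant to site reordering", {
  sim <- simulate_occupancy(sim_design(S = 50, years = 2009,
                                       preset = "test"), seed = 3)
  d <- sim$data
  set.seed(1); perm <- sample(nrow(d$yA))
  d2 <- occu2_data(d$yA[perm, ], d$yB[perm, ], d$covariates[perm, ])
  f1 <- fit_occu2(occu2_model(), d, nstart = 1)
  f2 <- fit_occu2(occu2_model(), d2, nstart = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("real parameters are recovered within 3 SE at informative scale", {
  sim <- simulate_occupancy(sim_design(S = 500, years = 2009,
                                       preset = "test", miss_rate = 0),
                            seed = 42)
  f <- fit_occu2(occu2_model(share = NULL), sim$data, nstart = 2)
  expect_true(f$converged)
  d <- derived_estimates(f)
  truth <- c(psiA = 0.4, psiBA = 0.9, psiBa = 0.2, pA = 0.3, pB = 0.3,
             rA = 0.3, rBA = 0.3, rBa = 0.3)
  for (p in names(truth)) {
    row <- d[d$parameter == p, ]
    expect_lt(abs(row$estimate - truth[[p]]), 3 * row$se + 1e-9)
  }
  s <- sif_se(f)
  expect_true(all(s$se >= 0))
  expect_lt(abs(s$sif - sif(0.4, 0.9, 0.2)), 3 * s$se)
})

test_that("simulate() method draws histories preserving the mask", {
  sim <- simulate_occupancy(sim_design(S = 40, years = 2009,
                                       preset = "test"), seed = 2)
  f <- fit_occu2(occu2_model(), sim$data, nstart = 1)
  reps <- simulate(f, nsim = 2, seed = 1)
  expect_length(reps, 2)
  expect_identical(is.na(reps[[1]]$yA), is.na(sim$data$yA))
  expect_true(all(reps[[1]]$yA %in% c(0L, 1L, NA)))
})
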