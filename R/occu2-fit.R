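#' Latent-state probabilities
#'
#' Probability of the four latent co-occurrence states
#' \{both, A only, B only, neither\} given the three occupancy
#' parameters. Always sums to 1.
#'
#' @param psiA occupancy probability of species A.
#' @param psiBA occupancy of B given A present.
#' @param psiBa occupancy of B given A absent.
#' @return numeric vector (or 4-column matrix for vector input) with
#'   components `AB, A, B, none`.
#' @examples
#' state_probs(0.28, 1, 1)   # c(0.28, 0, 0.72, 0)
#' @export
state_probs <- function(psiA, psiBA, psiBa) {
  out <- cbind(AB = psiA * psiBA,
               A = psiA * (1 - psiBA),
               B = (1 - psiA) * psiBa,
               none = (1 - psiA) * (1 - psiBa))
  if (nrow(out) == 1L) drop(out) else out
}

#' Per-occasion observation probability
#'
#' Probability of an observed detection pair `(yA, yB)` on one survey
#' occasion, conditional on the latent state. A missing occasion
#' (`yA = NA`) contributes probability 1 (it is skipped). No false
#' positives: a species absent in the latent state cannot be detected.
#'
#' @param state one of `"AB"`, `"A"`, `"B"`, `"none"`.
#' @param yA,yB observed detections (0/1), or `NA` for a masked occasion.
#' @param params named list or vector with elements
#'   `pA, pB, rA, rBA, rBa` (probability scale).
#' @return probability.
#' @export
occasion_prob <- function(state, yA, yB, params) {
  if (is.na(yA) || is.na(yB)) return(1)
  p <- as.list(params)
  switch(state,
    AB = {
      if (yA == 1 && yB == 1) p$rA * p$rBA
      else if (yA == 1) p$rA * (1 - p$rBA)
      else if (yB == 1) (1 - p$rA) * p$rBa
      else (1 - p$rA) * (1 - p$rBa)
    },
    A = if (yB == 1) 0 else if (yA == 1) p$pA else 1 - p$pA,
    B = if (yA == 1) 0 else if (yB == 1) p$pB else 1 - p$pB,
    none = if (yA == 0 && yB == 0) 1 else 0,
    stop("unknown latent state: ", state))
}

## Sufficient statistics per site: counts of the four observable outcomes
## over unmasked occasions. Time-constant detection makes these sufficient.
history_counts <- function(yA, yB) {
  ok <- !is.na(yA)
  a <- yA == 1L & ok; b <- yB == 1L & ok
  cbind(m = rowSums(ok),
        n11 = rowSums(a & b, na.rm = TRUE),
        n10 = rowSums(a & !b, na.rm = TRUE),
        n01 = rowSums(!a & b, na.rm = TRUE),
        n00 = rowSums(ok & !a & !b, na.rm = TRUE))
}

## Vectorised site log-likelihoods from counts and an S x 8 real-parameter
## matrix. Marginalises the latent state.
site_loglik_counts <- function(cts, reals) {
  reals <- clamp01(reals)
  psiA <- reals[, "psiA"]; psiBA <- reals[, "psiBA"]; psiBa <- reals[, "psiBa"]
  pA <- reals[, "pA"]; pB <- reals[, "pB"]
  rA <- reals[, "rA"]; rBA <- reals[, "rBA"]; rBa <- reals[, "rBa"]
  m <- cts[, "m"]; n11 <- cts[, "n11"]; n10 <- cts[, "n10"]
  n01 <- cts[, "n01"]; n00 <- cts[, "n00"]
  sA <- n11 + n10; sB <- n11 + n01
  llAB <- n11 * log(rA * rBA) + n10 * log(rA * (1 - rBA)) +
    n01 * log((1 - rA) * rBa) + n00 * log((1 - rA) * (1 - rBa))
  llA <- ifelse(sB > 0, -Inf, sA * log(pA) + (m - sA) * log(1 - pA))
  llB <- ifelse(sA > 0, -Inf, sB * log(pB) + (m - sB) * log(1 - pB))
  ll0 <- ifelse(sA + sB > 0, -Inf, 0)
  lp <- cbind(log(psiA) + log(psiBA) + llAB,
              log(psiA) + log1p(-psiBA) + llA,
              log1p(-psiA) + log(psiBa) + llB,
              log1p(-psiA) + log1p(-psiBa) + ll0)
  out <- logsumexp_rows(lp)
  out[m == 0] <- 0      # fully masked sites contribute nothing
  out
}

#' Log-likelihood of one site's paired detection history
#'
#' Marginalises the four latent co-occurrence states: the sum over
#' states of the state probability times the product of per-occasion
#' observation probabilities over unmasked occasions.
#'
#' @param yA,yB detection vectors (0/1, `NA` = masked occasion; the mask
#'   must be shared).
#' @param params named list or vector with the eight parameters
#'   `psiA, psiBA, psiBa, pA, pB, rA, rBA, rBa` (probability scale).
#' @return log-probability of the observed history.
#' @export
site_loglik <- function(yA, yB, params) {
  params <- as.list(params)
  if (all(is.na(yA)))
    warning("all occasions masked: site contributes 0")
  cts <- history_counts(matrix(yA, 1L), matrix(yB, 1L))
  reals <- matrix(unlist(params[OCCU2_PARAMS]), 1L,
                  dimnames = list(NULL, OCCU2_PARAMS))
  unname(drop(site_loglik_counts(cts, reals)))
}

#' Fit the conditional two-species occupancy model
#'
#' Maximum-likelihood fit by quasi-Newton (BFGS) optimisation of the
#' logit-scale coefficients, with seeded multi-start to guard against
#' local optima. The coefficient covariance is the inverse of the
#' numerically differentiated Hessian at the optimum; when the Hessian
#' is singular (typically a boundary estimate such as psiBA -> 1)
#' standard errors are reported absent and the fit is retained with a
#' flag.
#'
#' @param model an [occu2_model()] (or a model string, passed through
#'   [parse_model_string()]).
#' @param data an [occu2_data()] object.
#' @param start optional full coefficient start vector.
#' @param seed integer seed for the multi-start draws.
#' @param nstart number of random starts (logit-scale U(-2, 2)) in
#'   addition to the zero start.
#' @param control passed to [stats::optim()].
#' @return an object of class `occu2_fit` with methods `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `predict`, `simulate`.
#' @export
fit_occu2 <- function(model, data, start = NULL, seed = 1L, nstart = 5L,
                      control = list(maxit = 1000L, reltol = 1e-12)) {
  if (is.character(model)) model <- parse_model_string(model)
  stopifnot(inherits(model, "occu2_model"), inherits(data, "occu2_data"))
  design <- occu2_design(model, data$covariates)
  cts <- history_counts(data$yA, data$yB)
  S <- nrow(cts)
  n_eff <- sum(cts[, "m"] > 0)   # site-year units contributing data
  nll <- function(beta) {
    reals <- occu2_reals_matrix(design, beta, S)
    -sum(site_loglik_counts(cts, reals))
  }
  starts <- list(rep(0, design$K))
  if (!is.null(start)) {
    stopifnot(length(start) == design$K)
    starts <- c(list(start), starts)
  }
  rng <- local({ set.seed(seed)
    lapply(seq_len(nstart), function(i) stats::runif(design$K, -2, 2)) })
  starts <- c(starts, rng)
  best <- NULL
  for (s0 in starts) {
    op <- tryCatch(stats::optim(s0, nll, method = "BFGS", control = control),
                   error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("all optimisation starts failed")
  beta <- best$par
  ## gradient norm at the optimum (central differences)
  gr <- numeric(design$K); h <- 1e-5
  for (j in seq_len(design$K)) {
    e <- numeric(design$K); e[j] <- h
    gr[j] <- (nll(beta + e) - nll(beta - e)) / (2 * h)
  }
  boundary <- any(abs(beta) > 10)
  ## gradient tolerance relative to the log-likelihood scale
  converged <- best$convergence == 0 &&
    (sqrt(sum(gr^2)) < 1e-6 * max(1, abs(best$value)) || boundary)
  H <- tryCatch(stats::optimHess(beta, nll), error = function(e) NULL)
  inv_ok <- function(M) {
    V <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) NULL
    else (V + t(V)) / 2
  }
  vcov <- matrix(NA_real_, design$K, design$K)
  if (!is.null(H)) {
    V <- inv_ok(H)
    if (!is.null(V)) {
      vcov <- V
    } else {
      ## boundary estimates make the Hessian singular; treat the
      ## saturated coefficients as constants and invert the rest
      free <- abs(beta) <= 10
      if (any(free)) {
        Vf <- inv_ok(H[free, free, drop = FALSE])
        if (!is.null(Vf)) vcov[free, free] <- Vf
      }
    }
  }
  names(beta) <- design$coef_names
  dimnames(vcov) <- list(design$coef_names, design$coef_names)
  structure(list(model = model, data = data, design = design,
                 coefficients = beta, loglik = -best$value, K = design$K,
                 n = n_eff, vcov = vcov, converged = converged,
                 boundary = boundary, grad_norm = sqrt(sum(gr^2)),
                 seed = seed, call = match.call()),
            class = "occu2_fit")
}

#' @export
coef.occu2_fit <- function(object, ...) object$coefficients

#' @export
vcov.occu2_fit <- function(object, ...) object$vcov

#' @export
logLik.occu2_fit <- function(object, ...)
  structure(object$loglik, df = object$K, nobs = object$n, class = "logLik")

#' @export
print.occu2_fit <- function(x, ...) {
  cat("Conditional two-species occupancy model fit\n")
  cat("  model: ", x$model$label, "\n", sep = "")
  cat(sprintf("  logLik %.3f  K %d  n %d  AICc %.2f\n",
              x$loglik, x$K, x$n, aicc(x)))
  if (!x$converged) cat("  WARNING: optimiser did not converge cleanly\n")
  if (x$boundary)
    cat("  note: boundary estimate(s); SEs there are unreliable\n")
  invisible(x)
}

#' Predict real-scale parameters
#'
#' Back-transforms the linear predictor for one parameter type at new
#' covariate values, with delta-method standard errors.
#'
#' @param object an `occu2_fit`.
#' @param param one of the eight parameter names.
#' @param newdata covariate data frame (defaults to the fitted data).
#' @param type `"real"` (probability scale) or `"link"` (logit scale).
#' @param ... unused.
#' @return data frame with `estimate` and `se`.
#' @export
predict.occu2_fit <- function(object, param = "psiA", newdata = NULL,
                              type = c("real", "link"), ...) {
  type <- match.arg(type)
  stopifnot(param %in% OCCU2_PARAMS)
  newdata <- newdata %||% object$data$covariates
  b <- Filter(function(z) param %in% z$members, object$design$blocks)[[1]]
  X <- stats::model.matrix(b$terms, stats::model.frame(
    b$terms, newdata, na.action = stats::na.fail, xlev = b$xlev))
  beta <- object$coefficients[b$idx]
  V <- object$vcov[b$idx, b$idx, drop = FALSE]
  eta <- drop(X %*% beta)
  ok <- is.finite(diag(V))   # boundary coefficients carry NA variance
  se_eta <- rep(NA_real_, length(eta))
  if (any(ok)) {
    Xok <- X[, ok, drop = FALSE]
    se_eta <- sqrt(pmax(rowSums((Xok %*% V[ok, ok, drop = FALSE]) * Xok), 0))
  }
  uses_bad <- rowSums(abs(X[, !ok, drop = FALSE])) > 0
  if (type == "link") {
    se_eta[uses_bad] <- NA_real_
    return(data.frame(estimate = eta, se = se_eta))
  }
  ## on the probability scale a saturated coefficient contributes ~0
  data.frame(estimate = stats::plogis(eta),
             se = stats::dlogis(eta) * se_eta)
}

#' Simulate detection histories from a fitted model
#'
#' Draws latent states and paired daily detections at the fitted
#' (site-specific) parameter values, preserving the missing-occasion
#' mask of the fitted data.
#'
#' @param object an `occu2_fit`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `occu2_data` objects.
#' @export
simulate.occu2_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  reals <- occu2_reals_matrix(object$design, object$coefficients,
                              nrow(object$data$yA))
  lapply(seq_len(nsim), function(i)
    simulate_histories_at(reals, is.na(object$data$yA),
                          object$data$covariates, object$data$species))
}

## Shared generator core: draw latent states + daily detections for an
## S x 8 real-parameter matrix and a mask.
simulate_histories_at <- function(reals, mask, covariates, species) {
  S <- nrow(reals); J <- ncol(mask)
  sp <- state_probs(reals[, "psiA"], reals[, "psiBA"], reals[, "psiBa"])
  if (is.null(dim(sp))) sp <- matrix(sp, 1L)
  state <- vapply(seq_len(S), function(i)
    sample.int(4L, 1L, prob = sp[i, ]), integer(1))  # 1=AB 2=A 3=B 4=none
  yA <- matrix(0L, S, J); yB <- matrix(0L, S, J)
  for (i in seq_len(S)) {
    if (state[i] == 1L) {
      a <- stats::rbinom(J, 1L, reals[i, "rA"])
      bprob <- ifelse(a == 1L, reals[i, "rBA"], reals[i, "rBa"])
      yA[i, ] <- a; yB[i, ] <- stats::rbinom(J, 1L, bprob)
    } else if (state[i] == 2L) {
      yA[i, ] <- stats::rbinom(J, 1L, reals[i, "pA"])
    } else if (state[i] == 3L) {
      yB[i, ] <- stats::rbinom(J, 1L, reals[i, "pB"])
    }
  }
  yA[mask] <- NA_integer_; yB[mask] <- NA_integer_
  dimnames(yA) <- dimnames(yB) <- dimnames(mask)
  out <- occu2_data(yA, yB, covariates, species = species)
  attr(out, "latent_state") <- c("AB", "A", "B", "none")[state]
  out
}
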