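#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`, with the effective
#' sample size `n` taken as the number of site-year units contributing
#' data. Accepts either a fitted model or raw components.
#'
#' @param object an `occu2_fit`, or the maximised log-likelihood.
#' @param K free-parameter count (when `object` is numeric).
#' @param n effective sample size (when `object` is numeric).
#' @param label model label used in error messages.
#' @return the AICc value.
#' @export
aicc <- function(object, K = NULL, n = NULL, label = "model") {
  if (inherits(object, "occu2_fit")) {
    label <- object$model$label
    K <- object$K; n <- object$n; object <- object$loglik
  }
  if (n <= K + 1)
    stop("AICc undefined for ", label, ": n (", n, ") <= K + 1 (", K + 1, ")")
  -2 * object + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from AICc values
#'
#' @param aicc numeric vector of AICc values.
#' @return data frame with `dAICc` (difference from the best model),
#'   `weight` (normalised relative support) and `mlik`
#'   (model likelihood, `exp(-dAICc/2)`).
#' @export
akaike_table <- function(aicc) {
  d <- aicc - min(aicc)
  ml <- exp(-d / 2)
  data.frame(dAICc = d, weight = ml / sum(ml), mlik = ml)
}

#' Rank fitted models by AICc
#'
#' @param fits a (preferably named) list of `occu2_fit` objects.
#' @return data frame sorted ascending by AICc with columns
#'   `model, K, loglik, AICc, dAICc, weight, mlik`.
#' @export
model_selection_table <- function(fits) {
  if (inherits(fits, "occu2_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  labs <- names(fits) %||% vapply(fits, function(f) f$model$label,
                                  character(1))
  if (is.null(names(fits)))
    labs <- vapply(fits, function(f) f$model$label, character(1))
  tab <- data.frame(model = labs,
                    K = vapply(fits, function(f) f$K, integer(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    AICc = vapply(fits, aicc, numeric(1)))
  tab <- cbind(tab, akaike_table(tab$AICc))
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  tab
}

#' Species Interaction Factor
#'
#' The derived co-occurrence parameter
#' `phi = psiA * psiBA / (psiA * (psiA * psiBA + (1 - psiA) * psiBa))`,
#' i.e. the joint occupancy of both species divided by the product of
#' the two marginal occupancies. `phi = 1` means the species occur
#' independently; `phi > 1` that the subordinate species co-occurs with
#' the dominant one more often than expected under independence;
#' `phi < 1` indicates avoidance.
#'
#' @param psiA,psiBA,psiBa occupancy parameters (vectorised).
#' @return the interaction factor.
#' @examples
#' sif(0.28, 1, 1)       # 1: B is everywhere, so no association
#' sif(0.4, 0.9, 0.2)    # > 1: aggregation
#' @export
sif <- function(psiA, psiBA, psiBa) {
  psiB <- psiA * psiBA + (1 - psiA) * psiBa
  den <- psiA * psiB
  if (any(den <= 0)) stop("SIF undefined: zero marginal occupancy")
  psiA * psiBA / den
}

#' Joint occupancy
#'
#' `psi2 = psiA * psiBA`: the proportion of sites used by both species
#' at the same time.
#'
#' @inheritParams sif
#' @return joint occupancy probability.
#' @export
psi2 <- function(psiA, psiBA) psiA * psiBA

## Representative covariate row per year group: the within-group sample
## mean of each numeric covariate, year set to the group level.
year_profile_rows <- function(covariates) {
  lv <- levels(covariates$year)
  num <- names(covariates)[vapply(covariates, is.numeric, logical(1))]
  rows <- lapply(lv, function(g) {
    sub <- covariates[covariates$year == g, , drop = FALSE]
    row <- sub[1, , drop = FALSE]
    for (v in num) row[[v]] <- mean(sub[[v]])
    row$year <- factor(g, levels = lv)
    row
  })
  do.call(rbind, rows)
}

## Real-scale parameter value for one param at one covariate row, for an
## arbitrary coefficient vector (used for numeric delta-method gradients).
real_at <- function(fit, beta, param, row) {
  b <- Filter(function(z) param %in% z$members, fit$design$blocks)[[1]]
  X <- stats::model.matrix(b$terms, stats::model.frame(
    b$terms, row, na.action = stats::na.fail, xlev = b$xlev))
  stats::plogis(drop(X %*% beta[b$idx]))
}

## Delta-method SE of g(beta) via central-difference gradient. Boundary
## coefficients carry NA variance; they are held as constants (their
## gradient is numerically zero through the saturated link) unless the
## derived quantity genuinely depends on them, in which case NA.
delta_se <- function(fun, beta, vcov, h = 1e-5) {
  g <- vapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- h
    (fun(beta + e) - fun(beta - e)) / (2 * h)
  }, numeric(1))
  ok <- is.finite(diag(vcov))
  ## derived SEs are conditional on boundary constraints: a residual
  ## probability-scale gradient below 1e-3 through a saturated
  ## coefficient is negligible at reporting precision
  if (any(abs(g[!ok]) > 1e-3)) return(NA_real_)
  if (!any(ok)) return(NA_real_)
  V <- vcov[ok, ok, drop = FALSE]; g <- g[ok]
  sqrt(max(drop(t(g) %*% V %*% g), 0))
}

#' Derived per-year estimates: reals, joint occupancy and SIF
#'
#' Evaluates the eight real-scale parameters, `psi2` and the Species
#' Interaction Factor for each year group at that group's mean covariate
#' values, with delta-method standard errors propagated through the
#' coefficient covariance.
#'
#' @param fit an `occu2_fit`.
#' @return data frame, one row per (year, parameter), columns
#'   `year, parameter, estimate, se`.
#' @export
derived_estimates <- function(fit) {
  prof <- year_profile_rows(fit$data$covariates)
  beta <- fit$coefficients; V <- fit$vcov
  out <- list()
  for (i in seq_len(nrow(prof))) {
    row <- prof[i, , drop = FALSE]
    vals <- vapply(OCCU2_PARAMS, function(p) real_at(fit, beta, p, row),
                   numeric(1))
    ses <- vapply(OCCU2_PARAMS, function(p)
      delta_se(function(b) real_at(fit, b, p, row), beta, V), numeric(1))
    phi <- sif(vals["psiA"], vals["psiBA"], vals["psiBa"])
    phi_se <- delta_se(function(b)
      sif(real_at(fit, b, "psiA", row), real_at(fit, b, "psiBA", row),
          real_at(fit, b, "psiBa", row)), beta, V)
    p2 <- psi2(vals["psiA"], vals["psiBA"])
    p2_se <- delta_se(function(b)
      psi2(real_at(fit, b, "psiA", row), real_at(fit, b, "psiBA", row)),
      beta, V)
    out[[i]] <- data.frame(
      year = as.character(row$year),
      parameter = c(OCCU2_PARAMS, "psi2", "SIF"),
      estimate = c(vals, p2, phi),
      se = c(ses, p2_se, phi_se), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Delta-method SE of the Species Interaction Factor by year
#'
#' @param fit an `occu2_fit`.
#' @return data frame `year, sif, se`.
#' @export
sif_se <- function(fit) {
  d <- derived_estimates(fit)
  d <- d[d$parameter == "SIF", c("year", "estimate", "se")]
  names(d) <- c("year", "sif", "se")
  rownames(d) <- NULL
  d
}

#' @export
summary.occu2_fit <- function(object, ...) {
  d <- derived_estimates(object)
  wide_est <- stats::reshape(d[c("year", "parameter", "estimate")],
                             idvar = "parameter", timevar = "year",
                             direction = "wide")
  structure(list(fit = object, derived = d, table = wide_est),
            class = "summary.occu2_fit")
}

#' @export
print.summary.occu2_fit <- function(x, digits = 2, ...) {
  print(x$fit)
  cat("\nDerived real-scale estimates (per year group, at within-year",
      "mean covariates):\n")
  d <- x$derived
  years <- unique(d$year)
  params <- unique(d$parameter)
  m <- matrix("", length(params), length(years),
              dimnames = list(params, years))
  for (i in seq_len(nrow(d)))
    m[d$parameter[i], d$year[i]] <-
      sprintf("%.*f ± %s", digits, d$estimate[i],
              ifelse(is.na(d$se[i]), "NA", sprintf("%.*f", digits, d$se[i])))
  print(m, quote = FALSE)
  invisible(x)
}
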