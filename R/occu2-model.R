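## The eight parameter types of the conditional two-species model, in
## canonical order. A = dominant species, B = subordinate.
OCCU2_PARAMS <- c("psiA", "psiBA", "psiBa", "pA", "pB", "rA", "rBA", "rBa")

#' Specify a conditional two-species occupancy model
#'
#' Declares, for each of the eight parameter types, a design formula on
#' the site-year covariates (logit link, additive), plus optional
#' sharing constraints forcing sets of parameters to be identical
#' (e.g. `pA = rA`: detection of A unaffected by B's presence). The
#' parameter types are:
#' \describe{
#'   \item{psiA}{occupancy of species A}
#'   \item{psiBA / psiBa}{occupancy of B given A present / absent}
#'   \item{pA / pB}{detection of A given B absent / of B given A absent}
#'   \item{rA}{detection of A given both present}
#'   \item{rBA / rBa}{detection of B given both present and A
#'     detected / not detected}
#' }
#' Detection is time-constant within the survey month; designs vary over
#' site-year units only. The survey year is available as the factor
#' covariate `year`.
#'
#' @param psiA,psiBA,psiBa,pA,pB,rA,rBA,rBa one-sided formulas, e.g.
#'   `~1`, `~deer`, `~year * peccary`.
#' @param share list of character vectors naming parameters forced
#'   equal; each group uses the formula of its first member. Default:
#'   detection independent of the other species
#'   (`pA = rA`, `pB = rBA = rBa`), the structure retained by the
#'   survey's model selection.
#' @param label optional display label.
#' @return an `occu2_model` object.
#' @examples
#' occu2_model(psiA = ~deer, psiBA = ~year * peccary,
#'             psiBa = ~year * peccary)
#' @export
occu2_model <- function(psiA = ~1, psiBA = ~1, psiBa = ~1,
                        pA = ~1, pB = ~1, rA = ~1, rBA = ~1, rBa = ~1,
                        share = list(c("pA", "rA"), c("pB", "rBA", "rBa")),
                        label = NULL) {
  forms <- list(psiA = psiA, psiBA = psiBA, psiBa = psiBa, pA = pA,
                pB = pB, rA = rA, rBA = rBA, rBa = rBa)
  stopifnot(all(vapply(forms, inherits, logical(1), "formula")))
  share <- share %||% list()
  for (g in share) {
    bad <- setdiff(g, OCCU2_PARAMS)
    if (length(bad)) stop("unknown parameter(s) in share: ",
                          paste(bad, collapse = ", "))
    if (length(g) < 2) stop("share groups need at least two members")
  }
  if (anyDuplicated(unlist(share)))
    stop("a parameter may appear in at most one share group")
  structure(list(formulas = forms, share = share,
                 label = label %||% format_occu2_model(forms, share)),
            class = "occu2_model")
}

format_occu2_model <- function(forms, share) {
  grp <- block_map(share)
  shown <- character(0)
  out <- character(0)
  for (p in OCCU2_PARAMS) {
    b <- grp[[p]]
    if (b$name %in% shown) next
    shown <- c(shown, b$name)
    rhs <- deparse(forms[[b$members[1]]][[2]])
    rhs <- if (rhs == "1") "(.)" else paste0("(", rhs, ")")
    out <- c(out, paste0(paste(b$members, collapse = "="), rhs))
  }
  paste(out, collapse = " ")
}

## Map each parameter to its block (share group or singleton).
block_map <- function(share) {
  out <- list()
  for (p in OCCU2_PARAMS) {
    g <- Filter(function(s) p %in% s, share)
    if (length(g)) out[[p]] <- list(name = g[[1]][1], members = g[[1]])
    else out[[p]] <- list(name = p, members = p)
  }
  out
}

#' @export
print.occu2_model <- function(x, ...) {
  cat("<occu2_model> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Parse a MARK-style model string
#'
#' Converts compact model strings such as
#' `"psiA(deer) psiBA(y*peccary) psiBa(y*peccary) pA=rA(.) pB=rBA=rBa(.)"`
#' into an [occu2_model()]. `y` denotes the year group factor, `.` an
#' intercept-only design, `=` a sharing constraint. Parameters not
#' mentioned default to intercept-only, unconstrained.
#'
#' @param string the model string.
#' @return an `occu2_model` object.
#' @export
parse_model_string <- function(string) {
  toks <- strsplit(trimws(string), "\\s+")[[1]]
  forms <- stats::setNames(rep(list(~1), length(OCCU2_PARAMS)), OCCU2_PARAMS)
  share <- list()
  for (tk in toks) {
    m <- regmatches(tk, regexec("^([A-Za-z=]+)\\(([^)]*)\\)$", tk))[[1]]
    if (length(m) != 3) stop("cannot parse model token: ", tk)
    pars <- strsplit(m[2], "=", fixed = TRUE)[[1]]
    bad <- setdiff(pars, OCCU2_PARAMS)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    des <- trimws(m[3])
    f <- if (des == ".") ~1 else
      stats::as.formula(paste0("~", gsub("\\by\\b", "year", des)))
    for (p in pars) forms[[p]] <- f
    if (length(pars) > 1) share <- c(share, list(pars))
  }
  do.call(occu2_model, c(forms, list(share = share, label = string)))
}

## Build the per-block design matrices for a covariate table.
## Returns list(blocks = list(name, members, X, idx), K, coef_names).
occu2_design <- function(model, covariates) {
  grp <- block_map(model$share)
  seen <- character(0); blocks <- list()
  for (p in OCCU2_PARAMS) {
    b <- grp[[p]]
    if (b$name %in% seen) next
    seen <- c(seen, b$name)
    f <- model$formulas[[b$members[1]]]
    tt <- stats::terms(f)
    mf <- stats::model.frame(tt, covariates, na.action = stats::na.fail)
    X <- stats::model.matrix(tt, mf)
    if (qr(X)$rank < ncol(X))
      stop("design for block '", b$name, "' is rank-deficient")
    blocks[[b$name]] <- list(name = b$name, members = b$members,
                             terms = tt, X = X,
                             xlev = stats::.getXlevels(tt, mf))
  }
  k <- vapply(blocks, function(b) ncol(b$X), integer(1))
  ends <- cumsum(k)
  for (i in seq_along(blocks))
    blocks[[i]]$idx <- seq.int(ends[i] - k[i] + 1L, ends[i])
  coef_names <- unlist(lapply(blocks, function(b)
    paste(b$name, colnames(b$X), sep = ":")), use.names = FALSE)
  list(blocks = blocks, K = sum(k), coef_names = coef_names)
}

## Per-site probability-scale parameters (S x 8 matrix) from a coefficient
## vector and a design.
occu2_reals_matrix <- function(design, beta, n_sites) {
  out <- matrix(NA_real_, n_sites, length(OCCU2_PARAMS),
                dimnames = list(NULL, OCCU2_PARAMS))
  for (b in design$blocks) {
    eta <- drop(b$X %*% beta[b$idx])
    for (p in b$members) out[, p] <- stats::plogis(eta)
  }
  out
}
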