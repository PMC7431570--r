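# Fine-Gray subdistribution-hazard models --------------------------------

# spells -> multistate event factor ("censor" first level) on the last spell
.spell_event_factor <- function(spells, endpoints = cr_endpoints()) {
  ev <- spells$event
  ev[ev == "none"] <- "censor"
  factor(ev, levels = c("censor", endpoints))
}

#' Fit a Fine-Gray subdistribution-hazard model for one endpoint
#'
#' Animals failing from competing endpoints remain in the endpoint's risk set
#' past their failure, weighted by the inverse probability of censoring
#' Ghat(t)/Ghat(min(T_i, t)) from a Kaplan-Meier fit to the pooled censoring
#' distribution (only administrative censoring counts as censoring; all six
#' analysis endpoints are events or competing events). The weighted risk-set
#' expansion comes from [survival::finegray()], which carries each animal's
#' last observed spell covariates forward after a competing failure - well
#' defined here because all three covariates are external, calendar-driven
#' quantities; this carry-forward is a recorded methodological assumption.
#' The weighted partial likelihood is then maximized with Breslow ties and
#' cluster-robust variance as in [cr_cox()].
#'
#' With no competing events and no censoring all weights are 1 and the fit
#' reduces exactly to the cause-specific Cox model.
#'
#' @param spells A `cr_spells` data frame from [split_spells()].
#' @param endpoint The endpoint whose subdistribution hazard is modeled.
#' @param covariates Character vector of covariates (`lib_kill`, `winter`,
#'   `census2`, `census3`) entering the linear predictor.
#' @param tvc Character vector of covariates given a per-year time-varying
#'   coefficient (episode-split exactly at event times, as in [cr_cox()]).
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @param cluster Cluster robust variance on `animal_id` (default `TRUE`).
#' @return A `cr_fg` fit: subhazard coefficients (exponentiating to SHRs),
#'   robust covariance, Breslow baseline cumulative subhazard at the
#'   reference profile, the censoring-survival curve used for the weights,
#'   and fit statistics.
#' @export
cr_fg <- function(spells, endpoint, covariates = c("lib_kill", "winter"),
                  tvc = character(0), ties = c("breslow", "efron"),
                  cluster = TRUE) {
  ties <- match.arg(ties)
  if (!endpoint %in% cr_endpoints()) {
    .cr_stop(paste("unknown endpoint:", endpoint), class = "wolfcr_taxonomy_error")
  }
  sp <- as.data.frame(spells)
  sp$census2 <- as.integer(sp$census == 2L)
  sp$census3 <- as.integer(sp$census == 3L)
  sp$fstat <- .spell_event_factor(sp)
  if (!any(sp$fstat == endpoint)) {
    .cr_stop(paste("no events of endpoint", endpoint), class = "wolfcr_data_error")
  }
  ok_cov <- c("lib_kill", "winter", "census2", "census3")
  bad <- setdiff(c(covariates, tvc), ok_cov)
  if (length(bad)) {
    .cr_stop(paste("unknown covariate(s):", paste(bad, collapse = ", ")),
      class = "wolfcr_spec_error"
    )
  }

  fg <- finegray(Surv(tstart, tstop, fstat) ~ .,
    data = sp[, c("animal_id", "tstart", "tstop", "fstat", ok_cov)],
    etype = endpoint, id = animal_id
  )

  # censoring-survival curve behind the IPCW weights (pooled KM)
  last <- sp[!duplicated(sp$animal_id, fromLast = TRUE), ]
  cens <- as.integer(last$fstat == "censor")
  gkm <- survfit(Surv(last$tstop, cens) ~ 1)

  if (length(tvc)) {
    fg <- .expand_rows(fg, fg$fgstop[fg$fgstatus > 0],
      start = "fgstart", stop = "fgstop", status = "fgstatus"
    )
  }
  cols <- covariates
  for (cv in tvc) {
    nm <- paste("tvc", cv, sep = "_")
    fg[[nm]] <- fg[[cv]] * (fg$fgstop / 365.25)
    cols <- c(cols, nm)
  }

  fml <- as.formula(paste(
    "Surv(fgstart, fgstop, fgstatus) ~",
    paste(cols, collapse = " + ")
  ))
  eng <- if (cluster) {
    coxph(fml, data = fg, weights = fgwt, ties = ties, cluster = animal_id,
      x = TRUE, y = TRUE,
      control = coxph.control(eps = 1e-9, iter.max = 100))
  } else {
    coxph(fml, data = fg, weights = fgwt, ties = ties, robust = TRUE,
      x = TRUE, y = TRUE,
      control = coxph.control(eps = 1e-9, iter.max = 100))
  }
  beta <- stats::coef(eng)
  if (anyNA(beta)) {
    .cr_stop("Fine-Gray fit failed: NA coefficients", class = "wolfcr_fit_error")
  }
  g <- length(unique(fg$animal_id))
  v <- eng$var * if (cluster) g / (g - 1) else 1
  dimnames(v) <- list(names(beta), names(beta))

  lp <- as.numeric(eng$x %*% beta)
  bdf <- data.frame(
    stratum = endpoint, tstart = fg$fgstart, tstop = fg$fgstop,
    status = fg$fgstatus, stringsAsFactors = FALSE
  )
  bh <- .breslow_baseline(bdf, lp, weights = fg$fgwt)

  nevent <- sum(fg$fgstatus)
  p <- length(beta)
  ll <- eng$loglik[2]
  out <- list(
    coefficients = beta,
    var = v,
    naive.var = if (cluster) eng$naive.var else eng$naive.var,
    loglik = eng$loglik,
    n = nrow(fg),
    nevent = nevent,
    g = g,
    endpoint = endpoint,
    covariates = covariates,
    tvc = tvc,
    ties = ties,
    basehaz = bh,
    censoring_km = data.frame(time = gkm$time, surv = gkm$surv),
    weights_range = range(fg$fgwt),
    aic = -2 * ll + 2 * p,
    bic = -2 * ll + p * log(nevent),
    engine = eng,
    data = fg,
    meta = list(
      ipcw = "Kaplan-Meier on pooled administrative censoring",
      carry_forward = "covariate paths carried forward after competing failure"
    )
  )
  class(out) <- "cr_fg"
  out
}

#' @export
coef.cr_fg <- function(object, ...) object$coefficients

#' @export
vcov.cr_fg <- function(object, ...) object$var

#' @export
logLik.cr_fg <- function(object, ...) {
  structure(object$loglik[2],
    df = length(object$coefficients),
    nobs = object$nevent, class = "logLik"
  )
}

#' @export
print.cr_fg <- function(x, digits = 3, ...) {
  cat("Fine-Gray subdistribution fit, endpoint:", x$endpoint, "\n")
  cat(sprintf(
    "  weighted rows = %d, events = %d, clusters = %d, ties = %s\n",
    x$n, x$nevent, x$g, x$ties
  ))
  tab <- .coef_table(x)
  names(tab)[names(tab) == "hr"] <- "shr"
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("LL = %.2f, AIC = %.2f, BIC = %.2f\n", x$loglik[2], x$aic, x$bic))
  invisible(x)
}

#' @export
summary.cr_fg <- function(object, level = 0.95, ...) {
  tab <- .coef_table(object, level = level)
  names(tab)[names(tab) == "hr"] <- "shr"
  out <- list(table = tab, ic = information_criteria(object),
    endpoint = object$endpoint, meta = object$meta)
  class(out) <- "summary.cr_fg"
  out
}

#' @export
print.summary.cr_fg <- function(x, digits = 3, ...) {
  cat("Fine-Gray fit, endpoint:", x$endpoint, "\n")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
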