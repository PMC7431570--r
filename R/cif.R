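# Cumulative incidence functions -----------------------------------------

.new_cif <- function(endpoint, time, cif, estimator, profile = NULL) {
  out <- data.frame(time = time, cif = cif)
  attr(out, "endpoint") <- endpoint
  attr(out, "estimator") <- estimator
  attr(out, "profile") <- profile
  class(out) <- c("cr_cif", "data.frame")
  out
}

#' Evaluate a CIF curve at given times
#'
#' Step-function evaluation (right-continuous).
#'
#' @param cif A `cr_cif` curve.
#' @param times Numeric vector of analysis times (days).
#' @return Numeric vector of cumulative incidences.
#' @export
cif_at <- function(cif, times) {
  idx <- findInterval(times, cif$time)
  c(0, cif$cif)[idx + 1L]
}

#' Nonparametric (Aalen-Johansen) cumulative incidence
#'
#' The Aalen-Johansen estimator `CIF_k(t) = sum_{u <= t} S(u-) d_k(u)/n(u)`,
#' computed by [survival::survfit()] on the multistate counting-process data.
#' With a single endpoint and no competing events it equals 1 minus the
#' Kaplan-Meier survival curve exactly.
#'
#' @param spells A `cr_spells` data frame.
#' @param endpoints Endpoints to return curves for (default all present).
#' @param ids Optional vector of animal ids selecting a subcohort (a
#'   covariate-profile filter); must be nonempty.
#' @return Named list of `cr_cif` curves (estimator tag `"nonparametric"`).
#' @export
cif_aj <- function(spells, endpoints = cr_endpoints(), ids = NULL) {
  sp <- as.data.frame(spells)
  if (!is.null(ids)) {
    sp <- sp[sp$animal_id %in% ids, ]
    if (nrow(sp) == 0L) {
      .cr_stop("empty group selection", class = "wolfcr_data_error")
    }
  }
  sp$fstat <- .spell_event_factor(sp, endpoints = cr_endpoints())
  sf <- survfit(Surv(tstart, tstop, fstat) ~ 1, data = sp, id = animal_id)
  states <- sf$states
  out <- list()
  for (k in endpoints) {
    j <- match(k, states)
    ci <- if (is.na(j)) rep(0, length(sf$time)) else sf$pstate[, j]
    out[[k]] <- .new_cif(k, sf$time, ci, "nonparametric")
  }
  out
}

#' Cox-derived cumulative incidence for a covariate profile
#'
#' Product-integral composition of the joint fit's per-stratum Breslow
#' baseline hazard steps: at each event time `u`, each endpoint's hazard
#' increment at the profile is `dH_k(u|x) = dH0_k(u) exp(x . beta_k)`;
#' overall survival is the product-limit `S(u) = prod_{v <= u}
#' (1 - sum_k dH_k(v|x))` and `CIF_k` accumulates `S(u-) dH_k(u|x)`. By
#' construction `sum_k CIF_k(t) + S(t) = 1` at every step. Fits carrying tvc
#' terms cannot provide incidence predictions (non-proportionality); refit
#' without the tvc, as [select_model()] does via its `cif_spec`.
#'
#' @param fit A `cr_cox` fit without tvc terms.
#' @param profile Named list of covariate values, e.g.
#'   `list(lib_kill = 1, winter = 0, census = 1)`.
#' @param endpoints Endpoints to return curves for.
#' @return Named list of `cr_cif` curves (estimator tag `"cox_derived"`),
#'   with the overall survival curve attached as attribute `"surv"`.
#' @export
cif_from_cox <- function(fit, profile = list(lib_kill = 0, winter = 0, census = 1),
                         endpoints = cr_endpoints()) {
  if (nrow(fit$spec$tvc) > 0L) {
    .cr_stop(paste(
      "fit has time-varying coefficients and cannot provide incidence",
      "predictions; refit the same specification without the tvc terms"
    ), class = "wolfcr_tvc_error")
  }
  prof <- profile
  if (is.null(prof$census)) prof$census <- 1L
  prof$census2 <- as.integer(prof$census == 2L)
  prof$census3 <- as.integer(prof$census == 3L)

  bh <- fit$basehaz
  strata_present <- unique(bh$stratum)
  times <- sort(unique(bh$time))
  dh <- matrix(0, nrow = length(times), ncol = length(strata_present),
    dimnames = list(NULL, strata_present))
  for (k in strata_present) {
    s <- bh[bh$stratum == k, ]
    tm <- fit$spec$terms
    eta <- 0
    for (i in seq_len(nrow(tm))) {
      if (tm$stratum[i] == k) {
        eta <- eta + fit$coefficients[[.term_name(tm$covariate[i], tm$stratum[i])]] *
          prof[[tm$covariate[i]]]
      }
    }
    dh[match(s$time, times), k] <- s$dhaz * exp(eta)
  }
  dtot <- rowSums(dh)
  surv_step <- pmax(1 - dtot, 0)
  s_minus <- cumprod(c(1, surv_step[-length(surv_step)]))
  s_after <- cumprod(surv_step)
  out <- list()
  for (k in endpoints) {
    inc <- if (k %in% strata_present) cumsum(s_minus * dh[, k]) else rep(0, length(times))
    out[[k]] <- .new_cif(k, times, inc, "cox_derived", profile = profile)
  }
  attr(out, "surv") <- data.frame(time = times, surv = s_after)
  out
}

#' Fine-Gray-derived cumulative incidence for a covariate profile
#'
#' Complementary log-log composition of the subdistribution fit:
#' `CIF_k(t|x) = 1 - exp(-Lambda0_k(t))^exp(x . beta)`, so a profile with
#' SHR > 1 dominates the reference profile at every time.
#'
#' @param fit A `cr_fg` fit without tvc terms.
#' @param profile Named list of covariate values (see [cif_from_cox()]).
#' @return A `cr_cif` curve (estimator tag `"fg_derived"`).
#' @export
cif_from_fg <- function(fit, profile = list(lib_kill = 0, winter = 0, census = 1)) {
  if (length(fit$tvc)) {
    .cr_stop(paste(
      "Fine-Gray fit has time-varying coefficients and cannot provide",
      "incidence predictions; refit without the tvc terms"
    ), class = "wolfcr_tvc_error")
  }
  prof <- profile
  if (is.null(prof$census)) prof$census <- 1L
  prof$census2 <- as.integer(prof$census == 2L)
  prof$census3 <- as.integer(prof$census == 3L)
  eta <- 0
  for (cv in fit$covariates) {
    eta <- eta + fit$coefficients[[cv]] * prof[[cv]]
  }
  bh <- fit$basehaz
  cif <- 1 - exp(-bh$cumhaz * exp(eta))
  .new_cif(fit$endpoint, bh$time, cif, "fg_derived", profile = profile)
}

#' @export
print.cr_cif <- function(x, ...) {
  cat(sprintf(
    "CIF curve [%s] endpoint %s: %d steps, CIF(max t = %g) = %.4f\n",
    attr(x, "estimator"), attr(x, "endpoint"), nrow(x),
    if (nrow(x)) max(x$time) else 0, if (nrow(x)) x$cif[nrow(x)] else 0
  ))
  invisible(x)
}

#' @export
plot.cr_cif <- function(x, add = FALSE, ...) {
  if (!add) {
    plot(c(0, x$time), c(0, x$cif),
      type = "s", xlab = "days since collaring",
      ylab = "cumulative incidence", ylim = c(0, 1), ...
    )
  } else {
    graphics::lines(c(0, x$time), c(0, x$cif), type = "s", ...)
  }
  invisible(x)
}
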