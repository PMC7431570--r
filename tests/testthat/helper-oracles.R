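# Independent oracles and small fixture builders used across the suite.

# Brute-force Breslow log partial likelihood for single-stratum
# counting-process data; the reference implementation tests are checked
# against (kept deliberately naive and independent of the fitting path).
pl_breslow <- function(beta, tstart, tstop, status, x) {
  eta <- as.matrix(x) %*% as.matrix(beta)
  ll <- 0
  for (t in sort(unique(tstop[status == 1]))) {
    dead <- which(status == 1 & tstop == t)
    atrisk <- which(tstart < t & t <= tstop)
    ll <- ll + sum(eta[dead]) - length(dead) * log(sum(exp(eta[atrisk])))
  }
  ll
}

# Day-by-day scan of covariate values: the brute-force spell oracle.
# Day t of a record (t = 1..T) falls on calendar date collar_date + (t - 1).
scan_spells <- function(record, calendars) {
  tt <- as.integer(as.Date(record$end_date) - as.Date(record$collar_date))
  days <- as.Date(record$collar_date) + 0:(tt - 1)
  lv <- paste(
    calendar_level(calendars, "policy", days),
    calendar_level(calendars, "season", days),
    calendar_level(calendars, "census", days),
    sep = "-"
  )
  r <- rle(lv)
  stops <- cumsum(r$lengths)
  data.frame(
    tstart = c(0L, utils::head(stops, -1)),
    tstop = stops,
    key = r$values,
    stringsAsFactors = FALSE
  )
}

# single-spell cohort in cr_spells layout (time-fixed covariates)
make_spells <- function(time, event, lib_kill = 0L, winter = 0L, census = 1L,
                        id = NULL) {
  n <- length(time)
  out <- data.frame(
    animal_id = if (is.null(id)) sprintf("A%03d", seq_len(n)) else as.character(id),
    tstart = 0,
    tstop = as.numeric(time),
    lib_kill = rep_len(lib_kill, n),
    winter = rep_len(winter, n),
    census = rep_len(census, n),
    event = as.character(event),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cr_spells", "data.frame")
  out
}

# small calibrated no-tvc simulation truth used by recovery tests
recovery_config <- function(n) {
  zero <- matrix(0, 4, 6,
    dimnames = list(c("lib_kill", "winter", "census2", "census3"), cr_endpoints())
  )
  sim_config(
    n_animals = n,
    baseline = c(
      ltf = 2.6e-4, poached = 8.2e-5, legal = 6.6e-5,
      nonhuman = 1.18e-4, collision = 7.5e-5, uncertain = 4.9e-5
    ),
    tvc = zero
  )
}

# truth log-HR for the terms of a fitted spec, from a sim config
truth_for_terms <- function(fit, config) {
  tn <- fit$spec$terms
  mapply(function(cv, k) config$loghr[cv, k], tn$covariate, tn$stratum)
}
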