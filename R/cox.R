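# Stratified joint Cox engine on Lunn-McNeil augmented data --------------

#' Model specifications for joint endpoint fits
#'
#' A model specification lists covariate-by-endpoint interaction terms and,
#' optionally, time-varying coefficient (tvc) terms. Covariates are
#' `lib_kill`, `winter`, `census2`, `census3` (the census dummies contrast
#' eras 2 and 3 against era 1). A tvc term multiplies its covariate by
#' analysis time in years (`t / 365.25`), evaluated at event times, so the
#' fitted coefficient exponentiates to a multiplicative change in the hazard
#' ratio per year of monitoring.
#'
#' `spec_full()` interacts every covariate with every endpoint.
#' `spec_m5()` is the parsimonious default pattern used for reporting:
#' `lib_kill` on all six endpoints, `winter` on LTF, poached, nonhuman and
#' collision, `census2` on poached, with tvc terms on `lib_kill` for the
#' legal endpoint and on `winter` for LTF.
#'
#' @param terms Named list: covariate name to character vector of endpoint
#'   strata it acts on.
#' @param tvc Named list in the same shape for tvc terms (default none).
#' @return A `cr_spec` object.
#' @export
model_spec <- function(terms, tvc = list()) {
  flat <- function(lst) {
    if (length(lst) == 0L) {
      return(data.frame(covariate = character(0), stratum = character(0)))
    }
    do.call(rbind, lapply(names(lst), function(cv) {
      data.frame(covariate = cv, stratum = lst[[cv]], stringsAsFactors = FALSE)
    }))
  }
  ok_cov <- c("lib_kill", "winter", "census2", "census3")
  tdf <- flat(terms)
  vdf <- flat(tvc)
  bad <- setdiff(unique(c(tdf$covariate, vdf$covariate)), ok_cov)
  if (length(bad)) {
    .cr_stop(paste("unknown covariate(s):", paste(bad, collapse = ", ")),
      class = "wolfcr_spec_error"
    )
  }
  bad <- setdiff(unique(c(tdf$stratum, vdf$stratum)), cr_endpoints())
  if (length(bad)) {
    .cr_stop(paste("unknown endpoint stratum(s):", paste(bad, collapse = ", ")),
      class = "wolfcr_spec_error"
    )
  }
  out <- list(terms = tdf, tvc = vdf)
  class(out) <- "cr_spec"
  out
}

#' @rdname model_spec
#' @param endpoints Endpoint strata for `spec_full()`.
#' @param covariates Covariates for `spec_full()`.
#' @export
spec_full <- function(endpoints = cr_endpoints(),
                      covariates = c("lib_kill", "winter", "census2", "census3")) {
  model_spec(setNames(rep(list(endpoints), length(covariates)), covariates))
}

#' @rdname model_spec
#' @param tvc_terms Include the two default tvc terms in `spec_m5()`?
#' @export
spec_m5 <- function(tvc_terms = TRUE) {
  model_spec(
    terms = list(
      lib_kill = cr_endpoints(),
      winter = c("ltf", "poached", "nonhuman", "collision"),
      census2 = "poached"
    ),
    tvc = if (tvc_terms) list(lib_kill = "legal", winter = "ltf") else list()
  )
}

#' @export
print.cr_spec <- function(x, ...) {
  cat("Joint Cox model specification:", nrow(x$terms), "terms,",
    nrow(x$tvc), "tvc terms\n")
  if (nrow(x$terms)) {
    for (cv in unique(x$terms$covariate)) {
      cat(sprintf("  %-9s : %s\n", cv,
        paste(x$terms$stratum[x$terms$covariate == cv], collapse = ", ")))
    }
  }
  if (nrow(x$tvc)) {
    for (i in seq_len(nrow(x$tvc))) {
      cat(sprintf("  tvc %s x %s (per year)\n", x$tvc$covariate[i], x$tvc$stratum[i]))
    }
  }
  invisible(x)
}

.term_name <- function(cov, k, tvc = FALSE) {
  if (tvc) paste("tvc", cov, k, sep = "_") else paste(cov, k, sep = "_")
}

# split rows at interior cut times; only the final piece keeps the status
.expand_rows <- function(df, times, start = "tstart", stop = "tstop",
                         status = "status") {
  times <- sort(unique(times))
  ts <- df[[start]]
  te <- df[[stop]]
  lo <- findInterval(ts, times) + 1L
  hi <- findInterval(te - 1e-9, times)
  ncut <- pmax(hi - lo + 1L, 0L)
  npiece <- ncut + 1L
  ridx <- rep.int(seq_len(nrow(df)), npiece)
  out <- df[ridx, , drop = FALSE]
  first <- cumsum(c(0L, npiece[-length(npiece)])) + 1L
  lastp <- cumsum(npiece)
  newstart <- numeric(length(ridx))
  newstart[first] <- ts
  if (any(ncut > 0L)) {
    has <- which(ncut > 0L)
    newstart[-first] <- times[unlist(
      lapply(has, function(i) lo[i]:hi[i]),
      use.names = FALSE
    )]
  }
  newstop <- numeric(length(ridx))
  newstop[-lastp] <- newstart[-first]
  newstop[lastp] <- te
  out[[start]] <- newstart
  out[[stop]] <- newstop
  st <- integer(length(ridx))
  st[lastp] <- df[[status]]
  out[[status]] <- st
  rownames(out) <- NULL
  out
}

# weighted risk-set sums Sum w over {tstart < t <= tstop} at each t, O(n log n)
.risk_sum <- function(t, tstart, tstop, w) {
  o1 <- order(tstop)
  s1 <- tstop[o1]
  c1 <- cumsum(w[o1])
  tot <- c1[length(c1)]
  i1 <- findInterval(t - 1e-9, s1)
  a <- tot - ifelse(i1 > 0L, c1[pmax(i1, 1L)], 0)
  o2 <- order(tstart)
  s2 <- tstart[o2]
  c2 <- cumsum(w[o2])
  i2 <- findInterval(t - 1e-9, s2)
  b <- tot - ifelse(i2 > 0L, c2[pmax(i2, 1L)], 0)
  a - b
}

# Breslow baseline hazard increments per stratum at the reference profile
.breslow_baseline <- function(df, lp, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(df))
  wexp <- weights * exp(lp)
  out <- lapply(split(seq_len(nrow(df)), df$stratum), function(ix) {
    s <- df[ix, ]
    we <- wexp[ix]
    evt <- s$status > 0
    if (!any(evt)) {
      return(data.frame(
        stratum = s$stratum[1], time = numeric(0),
        dhaz = numeric(0), cumhaz = numeric(0)
      ))
    }
    tu <- sort(unique(s$tstop[evt]))
    d <- vapply(split(weights[ix][evt], factor(s$tstop[evt], levels = tu)),
      sum, numeric(1))
    risk <- .risk_sum(tu, s$tstart, s$tstop, we)
    dh <- as.numeric(d) / risk
    data.frame(
      stratum = s$stratum[1], time = tu, dhaz = dh,
      cumhaz = cumsum(dh), stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a stratified joint Cox model on augmented data
#'
#' Maximizes the endpoint-stratified partial likelihood over counting-process
#' spells (Breslow tie handling by default), with robust variance from
#' score residuals summed within animal clusters and scaled by the
#' finite-cluster factor g/(g-1). Terms whose stratum has no events, or whose
#' covariate does not vary within the stratum, are dropped with a warning.
#' Time-varying coefficient terms are handled exactly by episode-splitting the
#' affected strata at their event times, so the covariate-by-time product is
#' evaluated at the event times entering the partial likelihood.
#'
#' @param data A `cr_augmented` data frame from [build_augmented()].
#' @param spec A `cr_spec` from [model_spec()] and friends.
#' @param ties `"breslow"` (default) or `"efron"`. The stored baseline hazard
#'   is always the Breslow step estimate at the reference profile.
#' @param cluster Cluster robust variance on `animal_id` (default `TRUE`).
#' @return A `cr_cox` fit object with coefficients, robust covariance,
#'   log-likelihood, AIC/BIC (event count as effective sample size), the
#'   per-stratum Breslow baseline cumulative hazard, and the underlying
#'   `survival::coxph` engine fit.
#' @export
cr_cox <- function(data, spec = spec_full(), ties = c("breslow", "efron"),
                   cluster = TRUE) {
  ties <- match.arg(ties)
  df <- as.data.frame(data)
  need <- c("animal_id", "stratum", "tstart", "tstop", "lib_kill", "winter",
    "census", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    .cr_stop(paste("augmented data missing column(s):", paste(miss, collapse = ", ")),
      class = "wolfcr_data_error"
    )
  }
  df$census2 <- as.integer(df$census == 2L)
  df$census3 <- as.integer(df$census == 3L)

  ev_by_stratum <- tapply(df$status, df$stratum, sum)

  keep_term <- function(tab, tvc) {
    ok <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      k <- tab$stratum[i]
      cv <- tab$covariate[i]
      if (!k %in% names(ev_by_stratum) || ev_by_stratum[[k]] < 1) {
        warning(sprintf("dropping term %s x %s: no events in stratum", cv, k),
          call. = FALSE
        )
        next
      }
      x <- df[[cv]][df$stratum == k]
      if ((!tvc && length(unique(x)) < 2L) || (tvc && all(x == 0))) {
        warning(sprintf("dropping term %s x %s: covariate constant in stratum", cv, k),
          call. = FALSE
        )
        next
      }
      ok[i] <- TRUE
    }
    tab[ok, , drop = FALSE]
  }
  terms <- keep_term(spec$terms, tvc = FALSE)
  tvc <- keep_term(spec$tvc, tvc = TRUE)

  if (nrow(terms) + nrow(tvc) == 0L) {
    .cr_stop("no estimable terms in specification", class = "wolfcr_spec_error")
  }

  # exact tvc handling: episode-split affected strata at their event times.
  # Rows whose tvc covariate is zero carry a zero product at every time, so
  # only rows with a nonzero tvc covariate need splitting.
  tvc_strata <- unique(tvc$stratum)
  if (length(tvc_strata)) {
    parts <- lapply(split(df, df$stratum), function(s) {
      k <- s$stratum[1]
      if (!k %in% tvc_strata) {
        return(s)
      }
      cvs <- tvc$covariate[tvc$stratum == k]
      active <- Reduce(`|`, lapply(cvs, function(cv) s[[cv]] != 0))
      if (!any(active)) {
        return(s)
      }
      rbind(.expand_rows(s[active, ], s$tstop[s$status > 0]), s[!active, ])
    })
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
  }

  cols <- character(0)
  for (i in seq_len(nrow(terms))) {
    nm <- .term_name(terms$covariate[i], terms$stratum[i])
    df[[nm]] <- df[[terms$covariate[i]]] * as.integer(df$stratum == terms$stratum[i])
    cols <- c(cols, nm)
  }
  for (i in seq_len(nrow(tvc))) {
    nm <- .term_name(tvc$covariate[i], tvc$stratum[i], tvc = TRUE)
    df[[nm]] <- df[[tvc$covariate[i]]] *
      as.integer(df$stratum == tvc$stratum[i]) * (df$tstop / 365.25)
    cols <- c(cols, nm)
  }

  fml <- as.formula(paste(
    "Surv(tstart, tstop, status) ~",
    paste(cols, collapse = " + "), "+ strata(stratum)"
  ))
  eng <- if (cluster) {
    coxph(fml, data = df, ties = ties, cluster = animal_id,
      x = TRUE, y = TRUE, model = FALSE,
      control = coxph.control(eps = 1e-9, iter.max = 100))
  } else {
    coxph(fml, data = df, ties = ties,
      x = TRUE, y = TRUE, model = FALSE,
      control = coxph.control(eps = 1e-9, iter.max = 100))
  }
  beta <- stats::coef(eng)
  if (anyNA(beta)) {
    .cr_stop("joint Cox fit failed: NA coefficients (separation or collinearity)",
      class = "wolfcr_fit_error"
    )
  }
  g <- length(unique(df$animal_id))
  if (cluster) {
    v <- eng$var * g / (g - 1)
    naive <- eng$naive.var
  } else {
    v <- eng$var
    naive <- eng$var
  }
  dimnames(v) <- list(names(beta), names(beta))

  lp <- as.numeric(eng$x %*% beta)
  bh <- .breslow_baseline(df, lp)

  nevent <- sum(df$status)
  p <- length(beta)
  ll <- eng$loglik[2]
  out <- list(
    coefficients = beta,
    var = v,
    naive.var = naive,
    loglik = eng$loglik,
    n = nrow(df),
    nevent = nevent,
    nevent_by_stratum = ev_by_stratum,
    g = g,
    ties = ties,
    cluster = cluster,
    spec = list(terms = terms, tvc = tvc),
    basehaz = bh,
    aic = -2 * ll + 2 * p,
    bic = -2 * ll + p * log(nevent),
    iter = eng$iter,
    engine = eng,
    data = df,
    meta = list(
      ties = ties,
      robust = if (cluster) "Lin-Wei sandwich, cluster-summed scores, x g/(g-1)" else "none",
      bic_n = "number of events",
      baseline = "Breslow steps at reference profile"
    )
  )
  class(out) <- "cr_cox"
  out
}

#' @export
coef.cr_cox <- function(object, ...) object$coefficients

#' @export
vcov.cr_cox <- function(object, ...) object$var

#' @export
logLik.cr_cox <- function(object, ...) {
  structure(object$loglik[2],
    df = length(object$coefficients),
    nobs = object$nevent, class = "logLik"
  )
}

#' Log-likelihood, AIC and BIC of a fit
#'
#' AIC is `-2 LL + 2 p`; BIC uses the number of events as the effective
#' sample size (`-2 LL + p log(n_events)`), the common survival-analysis
#' convention, recorded in the fit metadata.
#'
#' @param fit A `cr_cox` or `cr_fg` fit.
#' @return List with `LL`, `AIC`, `BIC`, `p`, `n_events`.
#' @export
information_criteria <- function(fit) {
  list(
    LL = unname(fit$loglik[2]), AIC = fit$aic, BIC = fit$bic,
    p = length(fit$coefficients), n_events = fit$nevent
  )
}

.coef_table <- function(fit, level = 0.95) {
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- qnorm((1 + level) / 2)
  data.frame(
    term = names(beta),
    coef = beta,
    hr = exp(beta),
    se_robust = se,
    lower = exp(beta - z * se),
    upper = exp(beta + z * se),
    z = beta / se,
    p = 2 * pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
print.cr_cox <- function(x, digits = 3, ...) {
  cat("Stratified joint Cox fit (Lunn-McNeil augmented),",
    length(unique(x$data$stratum)), "endpoint strata\n")
  cat(sprintf(
    "  n rows = %d, events = %d, clusters = %d, ties = %s\n",
    x$n, x$nevent, x$g, x$ties
  ))
  tab <- .coef_table(x)
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "LL = %.2f, AIC = %.2f, BIC = %.2f (BIC n = events)\n",
    x$loglik[2], x$aic, x$bic
  ))
  invisible(x)
}

#' @export
summary.cr_cox <- function(object, level = 0.95, ...) {
  out <- list(
    table = .coef_table(object, level = level),
    ic = information_criteria(object),
    nevent_by_stratum = object$nevent_by_stratum,
    meta = object$meta
  )
  class(out) <- "summary.cr_cox"
  out
}

#' @export
print.summary.cr_cox <- function(x, digits = 3, ...) {
  tab <- x$table
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "LL = %.2f, AIC = %.2f, BIC = %.2f, p = %d, events = %d\n",
    x$ic$LL, x$ic$AIC, x$ic$BIC, x$ic$p, x$ic$n_events
  ))
  invisible(x)
}

#' @export
residuals.cr_cox <- function(object,
                             type = c("martingale", "schoenfeld", "score",
                               "dfbeta", "coxsnell"), ...) {
  type <- match.arg(type)
  if (type == "coxsnell") {
    mart <- stats::residuals(object$engine, type = "martingale")
    return(object$data$status - mart)
  }
  stats::residuals(object$engine, type = type, ...)
}

#' Linear predictors for covariate profiles
#'
#' @param object A `cr_cox` fit.
#' @param newdata Data frame with covariate columns (`lib_kill`, `winter`,
#'   `census`) and a `stratum` column; tvc terms additionally need `tstop`.
#' @param type `"lp"` (linear predictor) or `"risk"` (`exp(lp)`).
#' @param ... Unused.
#' @export
predict.cr_cox <- function(object, newdata, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  df <- as.data.frame(newdata)
  if (!"census" %in% names(df)) df$census <- 1L
  if (!"tstop" %in% names(df)) df$tstop <- 0
  df$census2 <- as.integer(df$census == 2L)
  df$census3 <- as.integer(df$census == 3L)
  lp <- numeric(nrow(df))
  tm <- object$spec$terms
  for (i in seq_len(nrow(tm))) {
    nm <- .term_name(tm$covariate[i], tm$stratum[i])
    lp <- lp + object$coefficients[[nm]] *
      df[[tm$covariate[i]]] * as.integer(df$stratum == tm$stratum[i])
  }
  tv <- object$spec$tvc
  for (i in seq_len(nrow(tv))) {
    nm <- .term_name(tv$covariate[i], tv$stratum[i], tvc = TRUE)
    lp <- lp + object$coefficients[[nm]] *
      df[[tv$covariate[i]]] * as.integer(df$stratum == tv$stratum[i]) *
      (df$tstop / 365.25)
  }
  if (type == "risk") exp(lp) else lp
}

# Diagnostics -------------------------------------------------------------

#' Schoenfeld residual test of proportional hazards
#'
#' Scaled Schoenfeld residuals are regressed on analysis time (identity
#' transform by default, matching the per-year tvc parameterization); returns
#' per-term and global chi-square tests plus the residual-versus-time series
#' for plotting, which should show no trend under proportional hazards.
#'
#' @param fit A `cr_cox` fit.
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return A `cr_zph` object: `table` (chisq, df, p per term and GLOBAL),
#'   `time`, `residuals` (matrix of scaled Schoenfeld residuals).
#' @export
cr_zph <- function(fit, transform = "identity") {
  z <- cox.zph(fit$engine, transform = transform)
  out <- list(
    table = as.data.frame(z$table),
    time = z$time,
    residuals = z$y,
    transform = transform
  )
  class(out) <- "cr_zph"
  out
}

#' @export
print.cr_zph <- function(x, digits = 4, ...) {
  cat("Schoenfeld residual proportionality test (transform:",
    x$transform, ")\n")
  print(round(x$table, digits))
  invisible(x)
}

#' Cox-Snell residual goodness-of-fit series
#'
#' Cox-Snell residuals (fitted cumulative hazard at exit, per animal and
#' stratum) are unit-exponential under a correctly specified model, so their
#' Nelson-Aalen cumulative hazard should track the identity line. Returns the
#' residuals, the overlay series and the sup-distance from the identity over
#' the bulk of the residual range.
#'
#' @param fit A `cr_cox` fit.
#' @param upper Upper end of the range over which the sup-distance is taken
#'   (default 2, covering the bulk of a unit exponential).
#' @return A `cr_coxsnell` object: `residuals` (per animal-stratum data
#'   frame), `curve` (residual value vs Nelson-Aalen cumulative hazard) and
#'   `sup_dist`.
#' @export
cox_snell_gof <- function(fit, upper = 2) {
  mart <- stats::residuals(fit$engine, type = "martingale")
  rrow <- fit$data$status - mart
  key <- paste(fit$data$animal_id, fit$data$stratum, sep = "\r")
  r <- tapply(rrow, key, sum)
  d <- tapply(fit$data$status, key, sum)
  resdf <- data.frame(
    animal_id = sub("\r.*$", "", names(r)),
    stratum = sub("^.*\r", "", names(r)),
    coxsnell = as.numeric(r),
    event = as.integer(d),
    stringsAsFactors = FALSE, row.names = NULL
  )
  sf <- survfit(Surv(resdf$coxsnell, resdf$event) ~ 1)
  curve <- data.frame(residual = sf$time, na_cumhaz = sf$cumhaz)
  inb <- curve$residual <= upper
  sup <- if (any(inb)) max(abs(curve$na_cumhaz[inb] - curve$residual[inb])) else NA_real_
  out <- list(residuals = resdf, curve = curve, sup_dist = sup, upper = upper)
  class(out) <- "cr_coxsnell"
  out
}

#' @export
print.cr_coxsnell <- function(x, ...) {
  cat(sprintf(
    "Cox-Snell GOF: %d animal-stratum residuals, sup |NA - identity| = %.4f on [0, %g]\n",
    nrow(x$residuals), x$sup_dist, x$upper
  ))
  invisible(x)
}

#' @export
plot.cr_coxsnell <- function(x, ...) {
  plot(x$curve$residual, x$curve$na_cumhaz,
    type = "s",
    xlab = "Cox-Snell residual", ylab = "Nelson-Aalen cumulative hazard", ...
  )
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# Model ladder ------------------------------------------------------------

#' Fit a ladder of nested joint Cox models and choose one
#'
#' Reproduces the backwards selection procedure: start from the full
#' interaction model and repeatedly drop the weakest non-policy term by
#' robust Wald statistic, always retaining the `lib_kill` policy terms.
#' Models are ranked by AIC (BIC and LL reported alongside). If the chosen
#' model carries a tvc term, incidence prediction is blocked by
#' non-proportionality, so the same specification without its tvc terms is
#' returned as `cif_spec` for CIF computation.
#'
#' @param data A `cr_augmented` data frame.
#' @param ladder Optional list of `cr_spec` objects; when `NULL` a ladder of
#'   `n_models` specifications is built by iterative dropping.
#' @param n_models Number of models in the automatic ladder (default 7).
#' @param ties,cluster Passed to [cr_cox()].
#' @return A `cr_ladder` object: `table` (ranked fit statistics), `fits`,
#'   `chosen` (best converged fit), `spec` and `cif_spec`.
#' @export
select_model <- function(data, ladder = NULL, n_models = 7,
                         ties = "breslow", cluster = TRUE) {
  if (is.null(ladder)) {
    ladder <- list()
    spec <- spec_full()
    fit <- suppressWarnings(cr_cox(data, spec, ties = ties, cluster = cluster))
    # guard against monotone-likelihood (separation): a non-policy term whose
    # coefficient runs away is dropped before the ladder is built
    repeat {
      nt <- nrow(fit$spec$terms)
      sep <- abs(fit$coefficients[seq_len(nt)]) > 8 &
        fit$spec$terms$covariate != "lib_kill"
      if (!any(sep)) break
      warning(sprintf(
        "dropping separated term(s): %s",
        paste(names(fit$coefficients)[which(sep)], collapse = ", ")
      ), call. = FALSE)
      spec <- list(
        terms = fit$spec$terms[!sep, , drop = FALSE],
        tvc = fit$spec$tvc
      )
      class(spec) <- "cr_spec"
      fit <- suppressWarnings(cr_cox(data, spec, ties = ties, cluster = cluster))
    }
    # rebuild spec from terms that survived estimability filtering
    spec <- list(terms = fit$spec$terms, tvc = fit$spec$tvc)
    class(spec) <- "cr_spec"
    ladder[[1]] <- spec
    while (length(ladder) < n_models) {
      tab <- .coef_table(fit)
      droppable <- fit$spec$terms$covariate != "lib_kill"
      if (!any(droppable)) break
      tnames <- .mapply(.term_name,
        list(fit$spec$terms$covariate, fit$spec$terms$stratum), NULL
      )
      zz <- abs(tab$z[match(unlist(tnames), tab$term)])
      weakest <- which(droppable)[which.min(zz[droppable])]
      spec <- list(
        terms = fit$spec$terms[-weakest, , drop = FALSE],
        tvc = fit$spec$tvc
      )
      class(spec) <- "cr_spec"
      ladder[[length(ladder) + 1]] <- spec
      fit <- suppressWarnings(cr_cox(data, spec, ties = ties, cluster = cluster))
    }
  }
  if (length(ladder) == 0L) {
    .cr_stop("empty model ladder", class = "wolfcr_spec_error")
  }
  for (sp in ladder) {
    if (!"lib_kill" %in% sp$terms$covariate) {
      .cr_stop("every ladder model must retain lib_kill policy terms",
        class = "wolfcr_spec_error"
      )
    }
  }
  fits <- vector("list", length(ladder))
  rows <- vector("list", length(ladder))
  for (i in seq_along(ladder)) {
    fi <- tryCatch(
      suppressWarnings(cr_cox(data, ladder[[i]], ties = ties, cluster = cluster)),
      error = function(e) e
    )
    fits[[i]] <- fi
    if (inherits(fi, "error")) {
      rows[[i]] <- data.frame(
        model = paste0("M", i), p = NA, LL = NA, AIC = NA, BIC = NA,
        converged = FALSE, reason = conditionMessage(fi),
        stringsAsFactors = FALSE
      )
    } else {
      ic <- information_criteria(fi)
      rows[[i]] <- data.frame(
        model = paste0("M", i), p = ic$p, LL = ic$LL, AIC = ic$AIC,
        BIC = ic$BIC, converged = TRUE, reason = "",
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged)
  if (length(ok) == 0L) {
    .cr_stop("no ladder model converged", class = "wolfcr_fit_error")
  }
  best <- ok[which.min(tab$AIC[ok])]
  tab$rank <- NA_integer_
  tab$rank[ok] <- rank(tab$AIC[ok], ties.method = "first")
  chosen_spec <- ladder[[best]]
  cif_spec <- chosen_spec
  tvc_dropped <- FALSE
  if (nrow(chosen_spec$tvc)) {
    cif_spec <- list(
      terms = chosen_spec$terms,
      tvc = chosen_spec$tvc[0, , drop = FALSE]
    )
    class(cif_spec) <- "cr_spec"
    tvc_dropped <- TRUE
  }
  out <- list(
    table = tab, fits = fits, ladder = ladder,
    chosen = fits[[best]], chosen_index = best,
    spec = chosen_spec, cif_spec = cif_spec, tvc_dropped = tvc_dropped
  )
  class(out) <- "cr_ladder"
  out
}

#' @export
print.cr_ladder <- function(x, digits = 2, ...) {
  tab <- x$table
  tab$LL <- round(tab$LL, digits)
  tab$AIC <- round(tab$AIC, digits)
  tab$BIC <- round(tab$BIC, digits)
  print(tab, row.names = FALSE)
  cat("Chosen: model", x$chosen_index, "by AIC")
  if (x$tvc_dropped) {
    cat(" (tvc terms set aside for CIF computation)")
  }
  cat("\n")
  invisible(x)
}
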