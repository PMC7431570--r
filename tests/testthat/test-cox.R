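cal <- default_calendars()

test_that("null partial likelihood matches direct evaluation on a toy", {
  sp <- make_spells(
    time = c(10, 20, 30, 40, 50, 60),
    event = c("ltf", "none", "ltf", "poached", "none", "ltf"),
    winter = c(1, 0, 1, 0, 1, 0)
  )
  aug <- build_augmented(sp, endpoints = c("ltf", "poached"))
  fit <- suppressWarnings(cr_cox(aug, model_spec(list(winter = c("ltf", "poached")))))
  # oracle: per-stratum Breslow log PL at beta = 0
  ll0 <- 0
  for (k in c("ltf", "poached")) {
    s <- aug[aug$stratum == k, ]
    ll0 <- ll0 + pl_breslow(0, s$tstart, s$tstop, s$status, s$winter)
  }
  expect_equal(unname(fit$loglik[1]), ll0, tolerance = 1e-10)
})

test_that("fitted coefficient matches brute-force partial-likelihood maximization", {
  # 8 animals, one stratum, one binary covariate, distinct event times
  sp <- make_spells(
    time = c(12, 25, 33, 47, 58, 64, 71, 90),
    event = c("ltf", "ltf", "none", "ltf", "ltf", "none", "ltf", "ltf"),
    winter = c(1, 0, 1, 1, 0, 0, 1, 0)
  )
  aug <- build_augmented(sp, endpoints = "ltf")
  fit <- suppressWarnings(cr_cox(aug, model_spec(list(winter = "ltf"))))
  oracle <- stats::optimize(
    function(b) pl_breslow(b, sp$tstop * 0, sp$tstop, as.integer(sp$event == "ltf"), sp$winter),
    interval = c(-5, 5), maximum = TRUE, tol = 1e-10
  )$maximum
  expect_equal(unname(coef(fit)[1]), oracle, tolerance = 1e-6)
})

test_that("fully interacted stratified joint fit equals six separate endpoint fits", {
  g <- generate_cohort(sim_config(n_animals = 350), cal, seed = 31)
  sp <- split_spells(g$cohort, cal)
  aug <- build_augmented(sp)
  joint <- suppressWarnings(cr_cox(aug,
    spec_full(covariates = c("lib_kill", "winter")),
    cluster = FALSE
  ))
  for (k in unique(aug$stratum[aug$status == 1])) {
    # oracle: endpoint-specific Cox fit with competing endpoints censored
    sep <- survival::coxph(
      survival::Surv(tstart, tstop, as.integer(event == k)) ~ lib_kill + winter,
      data = sp, ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, iter.max = 100)
    )
    nm <- paste(c("lib_kill", "winter"), k, sep = "_")
    present <- nm %in% names(coef(joint))
    expect_equal(
      unname(coef(joint)[nm[present]]),
      unname(coef(sep)[c("lib_kill", "winter")[present]]),
      tolerance = 1e-6
    )
  }
})

test_that("duplicating every animal's rows leaves estimates and robust SEs unchanged", {
  g <- generate_cohort(sim_config(n_animals = 250), cal, seed = 8)
  sp <- split_spells(g$cohort, cal)
  aug <- build_augmented(sp)
  spec <- model_spec(list(lib_kill = "ltf", winter = c("ltf", "poached")))
  f1 <- suppressWarnings(cr_cox(aug, spec))
  aug2 <- rbind(aug, aug)
  f2 <- suppressWarnings(cr_cox(aug2, spec))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  # same clusters: robust SEs invariant; naive SEs shrink
  expect_equal(sqrt(diag(vcov(f2))), sqrt(diag(vcov(f1))), tolerance = 1e-6)
  expect_true(all(sqrt(diag(f2$naive.var)) < sqrt(diag(f1$naive.var))))
})

test_that("information criteria: likelihood monotone in nesting, noise terms raise AIC", {
  g <- generate_cohort(sim_config(n_animals = 300), cal, seed = 17)
  aug <- build_augmented(split_spells(g$cohort, cal))
  small <- suppressWarnings(cr_cox(aug, model_spec(list(winter = "ltf"))))
  big <- suppressWarnings(cr_cox(aug, model_spec(list(
    winter = "ltf", lib_kill = c("ltf", "poached")
  ))))
  expect_gte(big$loglik[2], small$loglik[2])
  ic <- information_criteria(small)
  expect_equal(ic$AIC, -2 * ic$LL + 2 * ic$p)
  expect_equal(ic$BIC, -2 * ic$LL + ic$p * log(ic$n_events))

  # adding a pure-noise covariate raises AIC in the majority of replicates
  worse <- 0
  for (r in 1:20) {
    set.seed(700 + r)
    n <- 200
    x <- rbinom(n, 1, 0.5)
    noise <- rbinom(n, 1, 0.5)
    tt <- ceiling(rexp(n, 0.01 * exp(0.5 * x)))
    sp1 <- make_spells(tt, "ltf", winter = x, lib_kill = noise)
    aug1 <- build_augmented(sp1, "ltf")
    a <- suppressWarnings(cr_cox(aug1, model_spec(list(winter = "ltf"))))
    b <- suppressWarnings(cr_cox(aug1, model_spec(list(winter = "ltf", lib_kill = "ltf"))))
    worse <- worse + (b$aic > a$aic)
  }
  expect_gt(worse, 10)
})

test_that("tvc terms are estimated on exact event-time episode splits", {
  # simulate a per-year decaying effect and recover both coefficients
  set.seed(55)
  n <- 1500
  x <- rbinom(n, 1, 0.5)
  horizon <- 2000
  b <- seq(0, horizon, by = 30)
  mids <- (utils::head(b, -1) + b[-1]) / 2 / 365.25
  tt <- numeric(n)
  ev <- character(n)
  for (i in 1:n) {
    r <- 0.0012 * exp(x[i] * (log(3.13) + log(0.69) * mids))
    d <- sample_event_time(diff(b), matrix(r, ncol = 1, dimnames = list(NULL, "ltf")))
    tt[i] <- if (d$endpoint == "censored") horizon else max(1, ceiling(d$time))
    ev[i] <- if (d$endpoint == "censored") "none" else "ltf"
  }
  sp <- make_spells(tt, ev, winter = x)
  aug <- build_augmented(sp, "ltf")
  fit <- suppressWarnings(cr_cox(aug, model_spec(
    terms = list(winter = "ltf"), tvc = list(winter = "ltf")
  )))
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[["winter_ltf"]] - log(3.13)), 3 * se[["winter_ltf"]])
  expect_lt(abs(coef(fit)[["tvc_winter_ltf"]] - log(0.69)), 3 * se[["tvc_winter_ltf"]])
})

test_that("Schoenfeld test detects a decaying effect and skips constant covariates", {
  # power: effect decaying at 0.69/year, n = 2000
  rejections <- 0
  for (rep in 1:6) {
    set.seed(900 + rep)
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    horizon <- 2000
    b <- seq(0, horizon, by = 30)
    mids <- (utils::head(b, -1) + b[-1]) / 2 / 365.25
    tt <- numeric(n)
    ev <- character(n)
    for (i in 1:n) {
      r <- 0.0012 * exp(x[i] * (log(3.13) + log(0.69) * mids))
      d <- sample_event_time(diff(b), matrix(r, ncol = 1, dimnames = list(NULL, "ltf")))
      tt[i] <- if (d$endpoint == "censored") horizon else max(1, ceiling(d$time))
      ev[i] <- if (d$endpoint == "censored") "none" else "ltf"
    }
    aug <- build_augmented(make_spells(tt, ev, winter = x), "ltf")
    fit <- suppressWarnings(cr_cox(aug, model_spec(list(winter = "ltf"))))
    z <- cr_zph(fit)
    rejections <- rejections + (z$table["winter_ltf", "p"] < 0.05)
  }
  expect_gte(rejections, 4) # power > 0.8 at this design

  # a covariate constant within its stratum is dropped at fit time
  sp <- make_spells(c(10, 20, 30), c("ltf", "ltf", "none"), winter = 1L)
  aug <- build_augmented(sp, "ltf")
  expect_error(
    suppressWarnings(cr_cox(aug, model_spec(list(winter = "ltf")))),
    class = "wolfcr_spec_error"
  )
  expect_warning(
    try(cr_cox(aug, model_spec(list(winter = "ltf"))), silent = TRUE),
    "constant in stratum"
  )
})

test_that("Cox-Snell residuals are unit-exponential under a correct model", {
  set.seed(66)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)
  tt <- pmin(ceiling(rexp(n, 0.002 * exp(0.8 * x1 + 0.6 * x2))), 3000)
  ev <- ifelse(tt < 3000, "ltf", "none")
  sp <- make_spells(tt, ev, lib_kill = x1, winter = x2)
  aug <- build_augmented(sp, "ltf")
  fit <- suppressWarnings(cr_cox(aug, model_spec(list(lib_kill = "ltf", winter = "ltf"))))
  gof <- cox_snell_gof(fit)
  expect_lt(gof$sup_dist, 0.1)
  # exact mass identity: residuals sum to the event count (Breslow baseline)
  expect_equal(sum(gof$residuals$coxsnell), sum(aug$status), tolerance = 1e-6)

  # all-censored data: residuals equal the (zero-event) cumulative hazard
  sp0 <- make_spells(c(50, 60, 70), "none", winter = c(0, 1, 0))
  aug0 <- build_augmented(sp0, "ltf")
  expect_error(
    suppressWarnings(cr_cox(aug0, model_spec(list(winter = "ltf")))),
    class = "wolfcr_spec_error"
  ) # no events at all: nothing estimable, flagged rather than fit
})

test_that("model ladder ranks fits, keeps policy terms, and handles ladders of one", {
  g <- generate_cohort(sim_config(n_animals = 350), cal, seed = 21)
  aug <- build_augmented(split_spells(g$cohort, cal))
  one <- select_model(aug, ladder = list(spec_m5(tvc_terms = FALSE)))
  expect_equal(one$chosen_index, 1L)
  expect_equal(nrow(one$table), 1L)

  auto <- suppressWarnings(select_model(aug, n_models = 4))
  expect_equal(sum(auto$table$converged), nrow(auto$table))
  expect_true(all(vapply(
    auto$ladder,
    function(s) "lib_kill" %in% s$terms$covariate, logical(1)
  )))
  expect_equal(auto$table$rank[auto$chosen_index], 1L)

  bad <- model_spec(list(winter = "ltf"))
  expect_error(select_model(aug, ladder = list(bad)), class = "wolfcr_spec_error")
})

test_that("a chosen model with tvc terms hands back a tvc-free spec for CIFs", {
  g <- generate_cohort(sim_config(n_animals = 300), cal, seed = 77)
  aug <- build_augmented(split_spells(g$cohort, cal))
  lad <- suppressWarnings(
    select_model(aug, ladder = list(spec_m5(), spec_m5(tvc_terms = FALSE)))
  )
  if (lad$chosen_index == 1L) {
    expect_true(lad$tvc_dropped)
    expect_equal(nrow(lad$cif_spec$tvc), 0L)
    expect_equal(lad$cif_spec$terms, lad$spec$terms)
  } else {
    expect_false(lad$tvc_dropped)
  }
})
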