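cal <- default_calendars()

test_that("zero rates with a finite horizon censor at the horizon", {
  d <- sample_event_time(c(100, 200), matrix(0, 2, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(d$endpoint, "censored")
  expect_equal(d$time, 300)
  expect_error(
    sample_event_time(c(100, Inf), matrix(0, 2, 1, dimnames = list(NULL, "a"))),
    class = "wolfcr_config_error"
  )
})

test_that("competing exponentials: branching fraction and waiting time match closed form", {
  set.seed(123)
  l1 <- 0.004
  l2 <- 0.002
  n <- 10000
  rates <- matrix(c(l1, l2), 1, 2, dimnames = list(NULL, c("ltf", "poached")))
  draws <- replicate(n, {
    d <- sample_event_time(1e6, rates)
    c(d$time, d$endpoint == "ltf")
  })
  p1 <- mean(draws[2, ])
  se <- sqrt(p1 * (1 - p1) / n)
  expect_lt(abs(p1 - l1 / (l1 + l2)), 3 * se)
  m <- mean(draws[1, ])
  expect_lt(abs(m - 1 / (l1 + l2)), 3 * sd(draws[1, ]) / sqrt(n))
})

test_that("a doubled second-segment rate doubles the hazard across the boundary", {
  set.seed(321)
  n <- 10000
  rates <- matrix(c(0.002, 0.004), 2, 1, dimnames = list(NULL, "ltf"))
  tt <- replicate(n, sample_event_time(c(300, 300), rates)$time)
  # interval event probabilities just before and just after the boundary
  # match the piecewise-exponential closed form (rates 0.002 then 0.004)
  r1 <- sum(tt >= 200)
  p1 <- sum(tt >= 200 & tt < 300) / r1
  r2 <- sum(tt >= 300)
  p2 <- sum(tt >= 300 & tt < 400) / r2
  q1 <- 1 - exp(-0.002 * 100)
  q2 <- 1 - exp(-0.004 * 100)
  expect_lt(abs(p1 - q1), 3 * sqrt(q1 * (1 - q1) / r1))
  expect_lt(abs(p2 - q2), 3 * sqrt(q2 * (1 - q2) / r2))
  # implied per-day hazard doubles across the boundary
  h1 <- -log(1 - p1) / 100
  h2 <- -log(1 - p2) / 100
  expect_equal(h2 / h1, 2, tolerance = 0.15)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_animals = 120)
  g1 <- generate_cohort(cfg, cal, seed = 77)
  g2 <- generate_cohort(cfg, cal, seed = 77)
  expect_identical(g1$cohort, g2$cohort)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g1$cohort, p1)
  write_cohort(g2$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
  g3 <- generate_cohort(cfg, cal, seed = 78)
  expect_false(identical(g1$cohort$end_date, g3$cohort$end_date))
})

test_that("zero hazards yield a fully censored cohort at the administrative end", {
  cfg <- sim_config(n_animals = 25, baseline = setNames(rep(0, 6), cr_endpoints()),
    unresolved_frac = 0)
  g <- generate_cohort(cfg, cal, seed = 1)
  expect_true(all(g$cohort$endpoint == "censored"))
  expect_true(all(g$cohort$end_date == cfg$admin_end))
})

test_that("endpoint mix matches numeric integration of the configured hazards", {
  # oracle: per-animal expected endpoint probabilities by piecewise-exponential
  # integration over its own covariate path (no-tvc configuration)
  cfg <- recovery_config(4000)
  g <- generate_cohort(cfg, cal, seed = 405)
  coh <- g$cohort
  chg <- sort(unique(as.integer(cal$start_date)))
  admin <- as.integer(cfg$admin_end)
  probs <- matrix(0, nrow(coh), 7,
    dimnames = list(NULL, c(cr_endpoints(), "censored"))
  )
  for (i in seq_len(nrow(coh))) {
    ci <- as.integer(coh$collar_date[i])
    h <- admin - ci
    cuts <- chg[chg > ci & chg < ci + h] - ci
    b <- c(0, cuts, h)
    d0 <- as.Date(ci + b[-length(b)], origin = "1970-01-01")
    x <- cbind(
      lib_kill = calendar_level(cal, "policy", d0),
      winter = calendar_level(cal, "season", d0),
      census2 = as.integer(calendar_level(cal, "census", d0) == 2L),
      census3 = as.integer(calendar_level(cal, "census", d0) == 3L)
    )
    rates <- exp(matrix(log(cfg$baseline), nrow(x), 6, byrow = TRUE) + x %*% cfg$loghr)
    lam <- rowSums(rates)
    dur <- diff(b)
    surv_in <- exp(-cumsum(lam * dur))
    surv_at <- c(1, surv_in[-length(surv_in)])
    pev <- surv_at * (1 - exp(-lam * dur)) # P(first event in segment)
    probs[i, 1:6] <- colSums(pev * rates / lam)
    probs[i, 7] <- surv_in[length(surv_in)]
  }
  expected <- colSums(probs)
  observed <- table(factor(coh$endpoint, levels = colnames(probs)))
  for (k in colnames(probs)) {
    se <- sqrt(sum(probs[, k] * (1 - probs[, k])))
    expect_lt(abs(observed[[k]] - expected[[k]]), 4 * se)
  }
})

test_that("default cohort approximates the printed endpoint mix", {
  g <- generate_cohort(sim_config(), cal, seed = 2024)
  tab <- table(factor(g$cohort$endpoint, levels = cr_taxonomy())) / 513
  printed <- c(
    collision = 0.047, legal = 0.062, poached = 0.172, nonhuman = 0.150,
    uncertain = 0.041, ltf = 0.450, censored = 0.078
  )
  for (k in names(printed)) {
    se <- sqrt(printed[[k]] * (1 - printed[[k]]) / 513)
    expect_lt(abs(tab[[k]] - printed[[k]]), 0.015 + 3 * se)
  }
  # unresolved flags mark a subset of the censored records
  expect_true(all(g$cohort$endpoint[g$cohort$unresolved] == "censored"))
  expect_equal(sum(g$cohort$unresolved), round(26 / 513 * 513))
})

test_that("subdistribution simulator reproduces its configured CIF truth", {
  n <- 10000
  x <- data.frame(
    lib_kill = rep(c(0, 1), each = n / 2),
    winter = rep(c(0, 1), times = n / 2)
  )
  sp <- simulate_fg_cohort(n, seed = 5, x = x, p_ref = 0.30)
  tr <- attr(sp, "truth")
  for (cell in list(c(0, 0), c(1, 1))) {
    sel <- x$lib_kill == cell[1] & x$winter == cell[2]
    eta <- log(1.19) * cell[1] + log(2.89) * cell[2]
    truth <- 1 - (1 - 0.30)^exp(eta) # plateau ~ horizon CIF (rate is fast)
    emp <- mean(sp$event[sel] == "ltf" & sp$tstop[sel] <= tr$horizon)
    se <- sqrt(truth * (1 - truth) / sum(sel))
    expect_lt(abs(emp - truth), 4 * se + 0.005)
  }
})
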