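cal <- default_calendars()

test_that("scenario thresholds follow the printed formulas", {
  expect_equal(scenario_threshold(0.4, "MAIN"), 0.4)
  expect_equal(scenario_threshold(0.4, "HIGH"), 0.7)
  expect_equal(scenario_threshold(0.4, "LOW"), 0.2)
  expect_equal(scenario_threshold(0, "HIGH"), 0.5)
  expect_equal(scenario_threshold(1, "LOW"), 0.5)
  expect_error(scenario_threshold(1.2, "MAIN"), class = "wolfcr_domain_error")
})

test_that("degenerate probabilities decide deterministically", {
  for (lab in c("MAIN", "LOW", "HIGH")) {
    sc <- run_scenario(c(0, 0), lab, seed = 3)
    expect_equal(sc$p_sim, c(0, 0))
    expect_equal(sc$decision, c("censored", "censored"))
  }
})

test_that("p_fg = 0.5 under LOW is imputed LTF across many seeds", {
  # P(p_sim > 0.25 | Bin(1000, 0.5)) is ~1 - 1e-57
  for (s in 1:100) {
    sc <- run_scenario(0.5, "LOW", seed = s)
    expect_equal(sc$decision, "ltf")
  }
})

test_that("decisions are reproducible and monotone across scenario thresholds", {
  set.seed(42)
  p <- runif(26, 0.05, 0.95)
  main1 <- run_scenario(p, "MAIN", seed = 11)
  main2 <- run_scenario(p, "MAIN", seed = 11)
  expect_identical(main1, main2)
  low <- run_scenario(p, "LOW", seed = 11)
  high <- run_scenario(p, "HIGH", seed = 11)
  # shared seed means shared p_sim, so LOW >= MAIN >= HIGH decisions
  expect_identical(low$p_sim, main1$p_sim)
  expect_true(all(low$decision[main1$decision == "ltf"] == "ltf"))
  expect_true(all(main1$decision[high$decision == "ltf"] == "ltf"))
})

test_that("adding an animal does not perturb the others' substreams", {
  p <- c(0.3, 0.6, 0.8)
  a <- run_scenario(p, "MAIN", seed = 5)
  b <- run_scenario(c(p, 0.5), "MAIN", seed = 5)
  expect_equal(b$p_sim[1:3], a$p_sim)
})

test_that("the MAIN threshold makes moderate-probability animals near-coin-flips", {
  set.seed(9)
  p <- runif(26, 0.25, 0.75)
  frac <- mean(vapply(1:40, function(s) {
    mean(run_scenario(p, "MAIN", seed = 1000 + s)$decision == "ltf")
  }, numeric(1)))
  expect_lt(abs(frac - 0.5), 0.1) # the study's realization was 12 of 26
})

test_that("predicted LTF probability follows the stated product rule", {
  # synthetic fit object with a known baseline CIF and coefficients
  fake <- list(
    basehaz = data.frame(stratum = "ltf", time = c(30, 78), dhaz = NA,
      cumhaz = c(-log(0.95), -log(0.90))),
    coefficients = c(lib_kill = log(1.5), winter = log(4 / 3)),
    endpoint = "ltf", covariates = c("lib_kill", "winter")
  )
  class(fake) <- "cr_fg"
  p <- predict_ltf_probability(fake, list(lib_kill = 1, winter = 1), horizon = 78)
  expect_equal(p, 0.10 * 2, tolerance = 1e-12) # CIF0 = 0.10, e^(b1+b2) = 2
  p0 <- predict_ltf_probability(fake, list(lib_kill = 0, winter = 0), horizon = 78)
  expect_equal(p0, 0.10, tolerance = 1e-12)
  pc <- predict_ltf_probability(fake, list(lib_kill = 1, winter = 1),
    horizon = 78, mode = "cloglog"
  )
  expect_equal(pc, 1 - 0.90^2, tolerance = 1e-12)
  fake$coefficients <- c(lib_kill = log(20), winter = 0)
  expect_warning(
    pbig <- predict_ltf_probability(fake, list(lib_kill = 1, winter = 0), horizon = 78),
    "clamped"
  )
  expect_equal(pbig, 1)
})

test_that("model-predicted LTF probability approximates a known simulation truth", {
  sp <- simulate_fg_cohort(5000, seed = 60, p_ref = 0.30)
  fg <- suppressWarnings(cr_fg(sp, "ltf", covariates = c("lib_kill", "winter")))
  horizon <- attr(sp, "truth")$horizon
  truth <- 1 - (1 - 0.30)^exp(log(1.19) + log(2.89))
  p <- predict_ltf_probability(fg, list(lib_kill = 1, winter = 1),
    horizon = horizon, mode = "cloglog"
  )
  expect_lt(abs(p - truth), 0.05)
})

test_that("imputation application conserves counts and enforces coverage", {
  coh <- as_cohort(data.frame(
    animal_id = c("A", "B", "C", "D"),
    collar_date = "2010-01-01",
    end_date = "2012-04-14",
    endpoint = c("ltf", "censored", "censored", "censored"),
    unresolved = c(FALSE, TRUE, TRUE, FALSE)
  ))
  sc <- run_scenario(c(0.9, 0.9), "LOW", seed = 2, animal_id = c("B", "C"))
  out <- apply_imputation(coh, sc)
  expect_equal(sum(out$endpoint == "ltf"), 1 + sum(sc$decision == "ltf"))
  expect_true(all(!out$unresolved))
  expect_equal(out$end_date, coh$end_date) # imputed at the administrative end

  # empty decision set leaves the cohort unchanged
  empty <- sc[0, ]
  expect_identical(apply_imputation(coh, empty), coh)

  # decision for a non-unresolved animal is a consistency error
  bad <- run_scenario(0.9, "LOW", seed = 2, animal_id = "D")
  expect_error(apply_imputation(coh, bad), class = "wolfcr_consistency_error")
  # unresolved animal without a decision is an error too
  part <- run_scenario(0.9, "LOW", seed = 2, animal_id = "B")
  expect_error(apply_imputation(coh, part), class = "wolfcr_consistency_error")
})
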