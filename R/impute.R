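# Simulation-based LTF endpoint imputation -------------------------------
#
# Animals whose records vanish near the administrative end of the study are
# either lost-to-follow-up or survived past the study; their status is
# imputed by simulation. A Fine-Gray imputation model (LTF endpoint, all
# unresolved records censored at the administrative end) supplies each
# animal's model probability of LTF; Bernoulli simulation at that probability
# then decides the status against a scenario-specific threshold.

#' Scenario threshold for LTF imputation
#'
#' MAIN uses the model probability itself as the threshold; HIGH raises it
#' halfway to 1 (`p + (1 - p)/2`), making LTF imputation rarer; LOW halves it
#' (`p - p/2`), making LTF imputation near-certain for moderate `p`.
#' Scenario labels refer to the threshold height.
#'
#' @param p_fg Model probability of LTF, in `[0, 1]`.
#' @param label `"MAIN"`, `"HIGH"` or `"LOW"`.
#' @return The threshold probability.
#' @export
scenario_threshold <- function(p_fg, label = c("MAIN", "HIGH", "LOW")) {
  label <- match.arg(toupper(label), c("MAIN", "HIGH", "LOW"))
  if (any(p_fg < 0) || any(p_fg > 1)) {
    .cr_stop("p_fg must lie in [0, 1]", class = "wolfcr_domain_error")
  }
  switch(label,
    MAIN = p_fg,
    HIGH = p_fg + (1 - p_fg) / 2,
    LOW = p_fg - p_fg / 2
  )
}

#' Model probability of LTF for an exposure profile
#'
#' The baseline subdistribution CIF of the imputation model at the horizon,
#' multiplied by the exponentiated `lib_kill` and `winter` coefficients
#' (the literal product rule), clamped to `[0, 1]` with a warning when the
#' raw product exceeds 1. An alternate exact complementary-log-log mode
#' (`1 - (1 - CIF0)^exp(x beta)`) is available for comparison.
#'
#' @param im_fit A `cr_fg` imputation-model fit with LTF as its endpoint.
#' @param exposure Named list of covariate values the animals experienced
#'   over the exposure window (default liberalized killing in winter).
#' @param horizon Analysis time (days) at which the baseline CIF is taken.
#' @param mode `"product"` (default, the literal rule) or `"cloglog"`.
#' @return Probability of LTF.
#' @export
predict_ltf_probability <- function(im_fit, exposure = list(lib_kill = 1, winter = 1),
                                    horizon, mode = c("product", "cloglog")) {
  mode <- match.arg(mode)
  bh <- im_fit$basehaz
  idx <- findInterval(horizon, bh$time)
  cif0 <- if (idx >= 1L) 1 - exp(-bh$cumhaz[idx]) else 0
  eta <- 0
  for (cv in intersect(names(exposure), names(im_fit$coefficients))) {
    eta <- eta + im_fit$coefficients[[cv]] * exposure[[cv]]
  }
  if (mode == "cloglog") {
    return(1 - (1 - cif0)^exp(eta))
  }
  p <- cif0 * exp(eta)
  if (p > 1) {
    warning("predicted LTF probability exceeds 1; clamped", call. = FALSE)
    p <- 1
  }
  p
}

#' Run an imputation scenario
#'
#' For each animal, `n_draws` Bernoulli draws at its model LTF probability
#' give a simulated success fraction `p_sim`; the animal is imputed LTF iff
#' `p_sim` strictly exceeds the scenario threshold (ties, possible because
#' `p_sim` has resolution `1/n_draws`, are censored). Each animal draws from
#' its own substream derived from `(seed, animal index)`, so adding an animal
#' does not perturb the others' draws, and the same seed yields the same
#' `p_sim` across scenario labels (which makes LOW >= MAIN >= HIGH decision
#' monotonicity hold realization-by-realization).
#'
#' @param p_fg Per-animal model probabilities of LTF.
#' @param label Scenario label (`"MAIN"`, `"LOW"`, `"HIGH"`).
#' @param n_draws Bernoulli draws per animal (default 1000).
#' @param seed Master seed for the per-animal substreams.
#' @param animal_id Optional ids (default index).
#' @return A `cr_scenario` data frame: `animal_id`, `p_fg`, `threshold`,
#'   `p_sim`, `decision`.
#' @export
run_scenario <- function(p_fg, label = "MAIN", n_draws = 1000, seed = 1,
                         animal_id = NULL) {
  label <- match.arg(toupper(label), c("MAIN", "HIGH", "LOW"))
  if (any(p_fg < 0) || any(p_fg > 1)) {
    .cr_stop("p_fg must lie in [0, 1]", class = "wolfcr_domain_error")
  }
  if (is.null(animal_id)) animal_id <- as.character(seq_along(p_fg))
  p_sim <- vapply(seq_along(p_fg), function(i) {
    sub <- (as.numeric(seed) + 48271 * i) %% 2147483647
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(sub))
    rbinom(1L, n_draws, p_fg[i]) / n_draws
  }, numeric(1))
  thr <- scenario_threshold(p_fg, label)
  out <- data.frame(
    animal_id = as.character(animal_id),
    p_fg = p_fg,
    threshold = thr,
    p_sim = p_sim,
    decision = ifelse(p_sim > thr, "ltf", "censored"),
    stringsAsFactors = FALSE
  )
  attr(out, "label") <- label
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  class(out) <- c("cr_scenario", "data.frame")
  out
}

# save/restore the global RNG state so substreams do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Apply imputation decisions to a cohort
#'
#' Animals decided `ltf` receive an LTF endpoint at their recorded
#' administrative end date (their maximum survival time - the conservative
#' choice, since they may have disappeared earlier); the rest stay censored.
#' Decisions must cover exactly the cohort's unresolved animals.
#'
#' @param cohort A `cr_cohort` with `unresolved` flags.
#' @param scenario A `cr_scenario` from [run_scenario()].
#' @return The modified cohort.
#' @export
apply_imputation <- function(cohort, scenario) {
  cohort <- as_cohort(cohort)
  if (nrow(scenario) == 0L) {
    return(cohort)
  }
  unres <- cohort$animal_id[cohort$unresolved]
  extra <- setdiff(scenario$animal_id, unres)
  if (length(extra)) {
    .cr_stop(paste(
      "scenario decides animal(s) not flagged unresolved:",
      paste(extra, collapse = ", ")
    ), class = "wolfcr_consistency_error")
  }
  missing_dec <- setdiff(unres, scenario$animal_id)
  if (length(missing_dec)) {
    .cr_stop(paste(
      "unresolved animal(s) without a decision:",
      paste(missing_dec, collapse = ", ")
    ), class = "wolfcr_consistency_error")
  }
  ltf_ids <- scenario$animal_id[scenario$decision == "ltf"]
  sel <- cohort$animal_id %in% ltf_ids
  cohort$endpoint[sel] <- "ltf"
  cohort$unresolved[cohort$animal_id %in% unres] <- FALSE
  cohort
}
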