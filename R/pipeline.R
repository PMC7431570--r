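# End-to-end analysis pipeline -------------------------------------------

#' Pipeline run configuration
#'
#' A fully serializable description of one analysis run: the cohort source
#' (a `cr_cohort` data frame, a cohort CSV path, or a simulation
#' configuration), the calendars, the model ladder, the imputation
#' scenarios, and one master seed from which all stage substreams derive.
#'
#' @param cohort Optional `cr_cohort` or path to a cohort CSV.
#' @param sim Optional `cr_simconfig`; used when `cohort` is `NULL`.
#' @param calendars Calendar data frame (default [default_calendars()]).
#' @param ladder Optional list of `cr_spec` for [select_model()].
#' @param scenarios Imputation scenario labels to run (default MAIN, LOW,
#'   HIGH; set to `character(0)` to skip imputation).
#' @param imputation_window Days of liberalized-killing winter exposure used
#'   for the imputation-model prediction horizon (default 78, the final
#'   liberalized period).
#' @param n_draws Bernoulli draws per animal in the imputation simulation.
#' @param ties Tie handling for all fits.
#' @param seed Master seed.
#' @return A `cr_runconfig` list.
#' @export
run_config <- function(cohort = NULL, sim = sim_config(),
                       calendars = default_calendars(),
                       ladder = NULL,
                       scenarios = c("MAIN", "LOW", "HIGH"),
                       imputation_window = 78,
                       n_draws = 1000,
                       ties = "breslow",
                       seed = 1L) {
  out <- list(
    cohort = cohort, sim = sim, calendars = calendars, ladder = ladder,
    scenarios = scenarios, imputation_window = imputation_window,
    n_draws = n_draws, ties = ties, seed = as.integer(seed)
  )
  class(out) <- "cr_runconfig"
  out
}

.stage <- function(log, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    .cr_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      class = "wolfcr_stage_error"
    )
  })
  log[[length(log) + 1]] <- list(
    stage = name,
    seconds = round(proc.time()[["elapsed"]] - t0, 3)
  )
  list(res = res, log = log)
}

#' Run the full competing-risks analysis pipeline
#'
#' Stages: cohort (simulate or ingest) -> validation -> spell splitting ->
#' Lunn-McNeil augmentation -> joint Cox model ladder -> Fine-Gray fits per
#' endpoint -> CIFs (nonparametric, Cox-derived, Fine-Gray-derived, by
#' policy level) -> hazard-ratio distribution summaries -> imputation
#' scenarios with per-scenario refits of the joint model. All randomness
#' derives from the master seed; a manifest records seeds and versions.
#'
#' @param config A `cr_runconfig` from [run_config()].
#' @return A `cr_run` bundle: `cohort`, `validation`, `spells`, `ladder`,
#'   `fit` (chosen joint fit), `cif_fit` (same spec without tvc),
#'   `coef_table`, `fg_fits`, `cifs`, `hr_summaries`, `imputation`,
#'   `manifest`, `log`.
#' @export
run_pipeline <- function(config = run_config()) {
  log <- list()
  seed <- config$seed

  st <- .stage(log, "cohort", {
    if (is.null(config$cohort)) {
      generate_cohort(config$sim, config$calendars, seed = seed)$cohort
    } else if (is.character(config$cohort)) {
      read_cohort(config$cohort)
    } else {
      as_cohort(config$cohort)
    }
  })
  cohort <- st$res
  log <- st$log

  st <- .stage(log, "validate", {
    v <- validate_cohort(cohort, window = .cal_window(config$calendars))
    if (!v$ok) .cr_stop("cohort failed validation", class = "wolfcr_cohort_error")
    v
  })
  validation <- st$res
  log <- st$log

  st <- .stage(log, "spells", split_spells(cohort, config$calendars))
  spells <- st$res
  log <- st$log

  st <- .stage(log, "augment", build_augmented(spells))
  aug <- st$res
  log <- st$log

  st <- .stage(log, "model_ladder", {
    select_model(aug, ladder = config$ladder, ties = config$ties)
  })
  ladder <- st$res
  log <- st$log
  fit <- ladder$chosen
  cif_fit <- if (ladder$tvc_dropped) {
    suppressWarnings(cr_cox(aug, ladder$cif_spec, ties = config$ties))
  } else {
    fit
  }

  st <- .stage(log, "finegray", {
    fits <- list()
    for (k in cr_endpoints()) {
      covs <- ladder$cif_spec$terms$covariate[ladder$cif_spec$terms$stratum == k]
      if (length(covs) == 0L) covs <- "lib_kill"
      fits[[k]] <- tryCatch(
        suppressWarnings(cr_fg(spells, k, covariates = covs, ties = config$ties)),
        error = function(e) NULL
      )
    }
    fits
  })
  fg_fits <- st$res
  log <- st$log

  st <- .stage(log, "cifs", {
    out <- list()
    for (lib in c(0, 1)) {
      prof <- list(lib_kill = lib, winter = 0, census = 1)
      key <- if (lib == 1) "liberalized" else "full_protection"
      cox_cifs <- cif_from_cox(cif_fit, prof)
      fg_cifs <- lapply(cr_endpoints(), function(k) {
        if (is.null(fg_fits[[k]])) NULL else cif_from_fg(fg_fits[[k]], prof)
      })
      names(fg_cifs) <- cr_endpoints()
      out[[key]] <- list(cox_derived = cox_cifs, fg_derived = fg_cifs)
    }
    out$nonparametric <- cif_aj(spells)
    out
  })
  cifs <- st$res
  log <- st$log

  st <- .stage(log, "hr_summaries", {
    tab <- .coef_table(fit)
    out <- list()
    for (k in cr_endpoints()) {
      nm <- .term_name("lib_kill", k)
      row <- tab[tab$term == nm, ]
      if (nrow(row) == 1L) {
        d <- hr_distribution(row$hr, se = row$se_robust)
        out[[k]] <- list(
          endpoint = k, hr = row$hr, lower = row$lower, upper = row$upper,
          p_above_1 = prob_hr_side(d, side = "above"),
          p_below_1 = prob_hr_side(d, side = "below"),
          density = hr_density(d)
        )
      }
    }
    out
  })
  hr_summaries <- st$res
  log <- st$log

  imputation <- NULL
  if (length(config$scenarios) && any(cohort$unresolved)) {
    st <- .stage(log, "imputation", {
      im_fit <- fg_fits[["ltf"]]
      if (is.null(im_fit)) {
        im_fit <- suppressWarnings(cr_fg(spells, "ltf",
          covariates = c("lib_kill", "winter"), ties = config$ties
        ))
      }
      unres <- cohort$animal_id[cohort$unresolved]
      p <- predict_ltf_probability(im_fit,
        exposure = list(lib_kill = 1, winter = 1),
        horizon = config$imputation_window
      )
      p_fg <- rep(p, length(unres))
      res <- list(p_fg = setNames(p_fg, unres), scenarios = list())
      for (lab in config$scenarios) {
        sc <- run_scenario(p_fg, lab,
          n_draws = config$n_draws,
          seed = seed + 1000L, animal_id = unres
        )
        coh2 <- apply_imputation(cohort, sc)
        sp2 <- split_spells(coh2, config$calendars)
        aug2 <- build_augmented(sp2)
        fit2 <- suppressWarnings(cr_cox(aug2, ladder$spec, ties = config$ties))
        res$scenarios[[lab]] <- list(
          scenario = sc,
          n_imputed_ltf = sum(sc$decision == "ltf"),
          coef_table = .coef_table(fit2)
        )
      }
      res
    })
    imputation <- st$res
    log <- st$log
  }

  manifest <- list(
    package = "wolfcr",
    version = as.character(packageVersion("wolfcr")),
    seed = seed,
    ties = config$ties,
    n_animals = nrow(cohort),
    scenarios = config$scenarios,
    schema = "cr_run/1"
  )

  out <- list(
    cohort = cohort, validation = validation, spells = spells,
    ladder = ladder, fit = fit, cif_fit = cif_fit,
    coef_table = .coef_table(fit), fg_fits = fg_fits, cifs = cifs,
    hr_summaries = hr_summaries, imputation = imputation,
    manifest = manifest, log = log
  )
  class(out) <- "cr_run"
  out
}

#' @export
print.cr_run <- function(x, ...) {
  cat("wolfcr pipeline run:", x$manifest$n_animals, "animals, seed",
    x$manifest$seed, "\n")
  cat("  stages:", paste(vapply(x$log, `[[`, "", "stage"), collapse = " -> "), "\n")
  cat("  chosen joint model: index", x$ladder$chosen_index, "of",
    nrow(x$ladder$table), "\n")
  invisible(x)
}

# HR/SHR table in the conventional endpoint column order
.report_table <- function(coef_tab, covariates, endpoints = cr_endpoints(),
                          label = "HR") {
  rows <- lapply(covariates, function(cv) {
    vals <- vapply(endpoints, function(k) {
      r <- coef_tab[coef_tab$term == .term_name(cv, k), ]
      if (nrow(r) == 1L) {
        sprintf("%.2f (%.2f-%.2f)", r$hr, r$lower, r$upper)
      } else {
        "1 (ref)"
      }
    }, character(1))
    c(variable = cv, vals)
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- c(paste0("variable_", label), endpoints)
  tab
}

#' Render a plain-text report of a pipeline run
#'
#' One document with the endpoint-mix validation, the model-selection table,
#' the coefficient table (HR with 95\% CI per endpoint, columns ordered LTF,
#' poached, legal, nonhuman, collision, uncertain), Fine-Gray SHR summaries,
#' CIF values at the curve ends, hazard-ratio side probabilities, imputation
#' scenario results, and the design-decision metadata. Sections whose inputs
#' are missing from the bundle are skipped with a notice.
#'
#' @param bundle A `cr_run` from [run_pipeline()].
#' @param file Optional path; when given the report is also written there.
#' @return Invisibly, the report as a character vector of lines.
#' @export
render_report <- function(bundle, file = NULL) {
  if (!inherits(bundle, "cr_run") || is.null(bundle$manifest)) {
    .cr_stop("empty or invalid run bundle", class = "wolfcr_report_error")
  }
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("wolfcr analysis report (schema ", bundle$manifest$schema, ")")
  add("seed: ", bundle$manifest$seed, "; animals: ", bundle$manifest$n_animals)
  add("")
  add("== Endpoint mix ==")
  tb <- bundle$validation$tabulation
  for (i in seq_len(nrow(tb))) {
    add(sprintf("  %-10s n = %4d (%.1f%%)", tb$endpoint[i], tb$n[i],
      100 * tb$proportion[i]))
  }
  add("")
  add("== Model ladder (AIC/BIC/LL) ==")
  lt <- bundle$ladder$table
  for (i in seq_len(nrow(lt))) {
    add(sprintf(
      "  %s: p = %s, LL = %.2f, AIC = %.2f, BIC = %.2f%s", lt$model[i],
      lt$p[i], lt$LL[i], lt$AIC[i], lt$BIC[i],
      if (isTRUE(lt$rank[i] == 1L)) "  <- chosen" else ""
    ))
  }
  add("")
  add("== Joint Cox hazard ratios (95% CI) ==")
  covs <- unique(bundle$fit$spec$terms$covariate)
  rt <- .report_table(bundle$coef_table, covs)
  add(paste(names(rt), collapse = "\t"))
  for (i in seq_len(nrow(rt))) add(paste(unlist(rt[i, ]), collapse = "\t"))
  add("")
  if (!is.null(bundle$fg_fits)) {
    add("== Fine-Gray subhazard ratios (95% CI) ==")
    for (k in cr_endpoints()) {
      f <- bundle$fg_fits[[k]]
      if (is.null(f)) next
      tab <- .coef_table(f)
      for (i in seq_len(nrow(tab))) {
        add(sprintf(
          "  %-10s %-12s SHR %.2f (%.2f-%.2f)", k, tab$term[i],
          tab$hr[i], tab$lower[i], tab$upper[i]
        ))
      }
    }
    add("")
  } else {
    add("[notice] Fine-Gray fits missing; SHR section skipped")
  }
  add("== Cumulative incidence at end of follow-up ==")
  for (key in c("full_protection", "liberalized")) {
    if (is.null(bundle$cifs[[key]])) next
    for (k in cr_endpoints()) {
      cx <- bundle$cifs[[key]]$cox_derived[[k]]
      fg <- bundle$cifs[[key]]$fg_derived[[k]]
      add(sprintf(
        "  %-16s %-10s cox %.3f%s", key, k,
        if (nrow(cx)) cx$cif[nrow(cx)] else 0,
        if (!is.null(fg)) sprintf(", fg %.3f", fg$cif[nrow(fg)]) else ""
      ))
    }
  }
  add("")
  add("== Policy hazard-ratio distributions ==")
  for (k in names(bundle$hr_summaries)) {
    h <- bundle$hr_summaries[[k]]
    add(sprintf(
      "  %-10s HR %.2f (%.2f-%.2f): P(>1) = %d%%, P(<1) = %d%%", k,
      h$hr, h$lower, h$upper, h$p_above_1$percent, h$p_below_1$percent
    ))
  }
  add("")
  if (!is.null(bundle$imputation)) {
    add("== LTF imputation scenarios ==")
    for (lab in names(bundle$imputation$scenarios)) {
      sc <- bundle$imputation$scenarios[[lab]]
      nm <- .term_name("lib_kill", "ltf")
      r <- sc$coef_table[sc$coef_table$term == nm, ]
      add(sprintf(
        "  %-5s imputed LTF: %d; lib_kill x LTF HR %.3f (%.3f-%.3f)", lab,
        sc$n_imputed_ltf, r$hr, r$lower, r$upper
      ))
    }
    add("")
  }
  add("== Metadata ==")
  for (nm in names(bundle$fit$meta)) {
    add("  ", nm, ": ", bundle$fit$meta[[nm]])
  }
  if (!is.null(file)) writeLines(ln, file)
  invisible(ln)
}
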