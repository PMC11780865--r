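# Pipeline orchestration: the file-level entry points the command-line
# wrapper (inst/scripts/stc-cli.R) calls. Each stage writes CSV results
# plus a JSON run manifest sufficient to reproduce the run.

.write_manifest <- function(path, fields) {
  base <- list(package = "stcsurv",
               version = as.character(utils::packageVersion("stcsurv")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(c(base, fields), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a synthetic STC scenario to disk
#'
#' Materialises [make_rcc_scenario()] in the same CSV/JSON formats
#' real inputs use: `index.csv` plus one directory per comparator with
#' `curve.csv`, `risk.csv` and `baseline.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n,n_comparator Arm sizes.
#' @param null_effect Generate the zero-effect scenario.
#' @return The scenario, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, n = 350, n_comparator = 400,
                         null_effect = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- make_rcc_scenario(seed = seed, n = n,
                                 n_comparator = n_comparator,
                                 null_effect = null_effect)
  write_ipd(sc$index, file.path(out_dir, "index.csv"))
  for (cmp in sc$comparators) {
    cdir <- file.path(out_dir, gsub("[^A-Za-z0-9]+", "_", cmp$label))
    dir.create(cdir, showWarnings = FALSE)
    write_digitized_curve(cmp$curve, file.path(cdir, "curve.csv"))
    write_risk_table(cmp$risk, file.path(cdir, "risk.csv"))
    write_aggregate_baseline(cmp$baseline, file.path(cdir, "baseline.json"))
    jsonlite::write_json(list(total_events = attr(cmp$risk, "total_events")),
                         file.path(cdir, "meta.json"), auto_unbox = TRUE)
  }
  .write_manifest(file.path(out_dir, "manifest.json"),
                  list(stage = "simulate", seed = seed, n = n,
                       n_comparator = n_comparator, null_effect = null_effect))
  invisible(sc)
}

#' Run the two-stage model selection and write the selection report
#'
#' Stage 1 ranks all candidate distributions (no covariates) by AIC;
#' stage 2 searches covariate subsets on the winner. Writes
#' `selection_stage1.csv`, `selection_stage2.csv`, the serialized winning
#' model (`model.json`) and a manifest.
#'
#' @param data An [as_ipd()] dataset (or a path to an IPD CSV).
#' @param config An [stc_config()]; `candidate_covariates` drives stage 2.
#' @param out_dir Output directory.
#' @return A list of class `stc_fit_run`: `stage1`, `stage2`,
#'   `sensitivities`.
#' @export
run_fit <- function(data, config = stc_config(), out_dir = NULL) {
  if (is.character(data)) data <- read_ipd(data)
  s1 <- stage1_select(data, config)
  winner_spec <- s1[1, c("family", "link", "m")]
  s2 <- stage2_select(data, winner_spec, config$candidate_covariates)
  sens <- sensitivity_set(s1, s2, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(
      as_tibble(s1) |> select("family", "link", "m", "loglik", "n_params",
                              "aic", "converged", "rank", "role"),
      file.path(out_dir, "selection_stage1.csv"))
    readr::write_csv(s2$report, file.path(out_dir, "selection_stage2.csv"))
    write_model_json(s2$model, file.path(out_dir, "model.json"))
    .write_manifest(
      file.path(out_dir, "manifest.json"),
      list(stage = "fit", seed = config$seed,
           n_candidates = nrow(s1), n_subsets = s2$n_fits,
           non_converged = sum(!s1$converged),
           winner = list(family = winner_spec$family, link = winner_spec$link,
                         m = winner_spec$m,
                         covariates = s2$covariates),
           knot_rule = "quantiles of log uncensored event times",
           covariate_strategy = config$covariate_strategy))
  }
  structure(list(stage1 = s1, stage2 = s2, sensitivities = sens,
                 data = data, config = config),
            class = "stc_fit_run")
}

#' Compare the fitted index model against comparator bundles
#'
#' For each comparator: read (or accept) its digitized curve, risk table
#' and aggregate baseline; reconstruct pseudo-IPD by the Guyot algorithm;
#' align the selected covariates with what the trial reports and refit;
#' then run the dual bootstrap for RMST differences and landmark hazard
#' ratios. Writes one results CSV row per comparator x estimand, predicted
#' curves, and a manifest recording seed, B, bandwidth, knot rule and the
#' per-comparator dropped covariates.
#'
#' @param fit_run A [run_fit()] result.
#' @param comparators Either a directory written by [run_simulate()] or a
#'   list of bundles (`label`, `curve`, `risk`, `baseline`, optional
#'   `total_events`).
#' @param config An [stc_config()].
#' @param out_dir Output directory (optional).
#' @param naive Use the KM-only naive comparison instead of the model.
#' @return A tibble of class `stc_results`: one row per comparator and
#'   estimand, with an `effects` attribute holding the [stc_effect]
#'   objects.
#' @export
run_compare <- function(fit_run, comparators, config = fit_run$config,
                        out_dir = NULL, naive = FALSE) {
  if (is.character(comparators)) comparators <- .read_comparator_dir(comparators)
  data <- fit_run$data
  selected <- fit_run$stage2$covariates
  winner <- fit_run$stage1[1, ]
  effects <- list(); rows <- list(); dropped_log <- list()
  for (cmp in comparators) {
    covs <- if (config$covariate_strategy == "none") character() else {
      align_covariates(selected, cmp$baseline)
    }
    dropped <- setdiff(selected, covs)
    spec <- list(family = winner$family, link = winner$link, m = winner$m,
                 covariates = covs)
    pseudo <- guyot_reconstruct(cmp$curve, cmp$risk,
                                total_events = cmp$total_events %||%
                                  attr(cmp$risk, "total_events"),
                                arm_label = cmp$label)
    eff <- bootstrap_compare(data, pseudo, spec, cmp$baseline,
                             config = config, naive = naive)
    effects[[cmp$label]] <- eff
    rows[[cmp$label]] <- tidy(eff)
    dropped_log[[cmp$label]] <- dropped
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!naive) {
        fit <- .fit_spec(data, spec$family, spec$link, spec$m, covariates = covs)
        pred <- predict_at_population(fit, cmp$baseline,
                                      dropped_covariates = dropped)
        readr::write_csv(pred$curve,
                         file.path(out_dir, sprintf("curve_%s.csv",
                                                    gsub("[^A-Za-z0-9]+", "_", cmp$label))))
      }
    }
  }
  res <- bind_rows(rows)
  if (!is.null(out_dir)) {
    readr::write_csv(res, file.path(out_dir, "results.csv"))
    .write_manifest(
      file.path(out_dir, "manifest.json"),
      list(stage = "compare", seed = config$seed, bootstrap_B = config$bootstrap_B,
           bandwidth = config$bandwidth,
           knot_rule = "quantiles of log uncensored event times",
           covariate_strategy = config$covariate_strategy, naive = naive,
           landmarks = config$landmark_times,
           selected_covariates = selected,
           dropped_covariates = dropped_log,
           replicates_dropped = lapply(effects, function(e) e$n_dropped)))
  }
  structure(res, effects = effects, class = c("stc_results", class(res)))
}

.read_comparator_dir <- function(dir) {
  subdirs <- list.dirs(dir, recursive = FALSE)
  lapply(subdirs, function(d) {
    meta_path <- file.path(d, "meta.json")
    te <- if (file.exists(meta_path)) {
      jsonlite::read_json(meta_path)$total_events
    } else NULL
    baseline <- read_aggregate_baseline(file.path(d, "baseline.json"))
    list(label = baseline$trial_label,
         curve = read_digitized_curve(file.path(d, "curve.csv")),
         risk = read_risk_table(file.path(d, "risk.csv"), total_events = te),
         baseline = baseline,
         total_events = te)
  })
}

#' Serialize / deserialize a fitted model as JSON
#'
#' @param model An [stc_model()].
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(family = model$family, link = model$link, knots = model$knots,
         mu = model$mu, gamma = model$gamma,
         beta = as.list(model$beta), baseline = as.list(model$baseline),
         centering = as.list(model$centering),
         loglik = model$loglik, n_params = model$n_params, aic = model$aic,
         converged = model$converged, covariates = model$covariates,
         n = model$n, n_event = model$n_event),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stc_model(family = o$family, link = o$link %||% NA_character_,
            knots = o$knots %||% numeric(), mu = o$mu,
            gamma = o$gamma %||% numeric(),
            beta = unlist(o$beta) %||% setNames(numeric(), character()),
            baseline = unlist(o$baseline) %||% numeric(),
            centering = unlist(o$centering),
            loglik = o$loglik, n_params = o$n_params, aic = o$aic,
            converged = o$converged, n = o$n, n_event = o$n_event)
}
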