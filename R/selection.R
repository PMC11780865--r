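#' Analysis configuration
#'
#' Collects the tunable settings of an STC run: the candidate model space,
#' covariates, landmark times, bootstrap size and seed.
#'
#' @param candidate_families Parametric families to consider.
#' @param knot_counts Internal knot counts for spline candidates.
#' @param links Spline links to consider.
#' @param candidate_covariates Covariates eligible for stage-2 selection.
#' @param landmark_times Landmark times (months) for hazard ratios.
#' @param bootstrap_B Bootstrap replicates (>= 1).
#' @param seed Integer seed for all randomness.
#' @param covariate_strategy `"aic_subset"` (stage-2 AIC search) or
#'   `"all_reported"` (adjust for every candidate covariate the comparator
#'   reports) or `"none"`.
#' @param bandwidth Kernel-hazard bandwidth ("auto" or months).
#' @return A list of class `stc_config`.
#' @export
stc_config <- function(candidate_families = stc_family_names(),
                       knot_counts = 1:3,
                       links = c("hazard", "odds", "normal"),
                       candidate_covariates = character(),
                       landmark_times = c(6, 12, 18, 24),
                       bootstrap_B = 1000,
                       seed = 1L,
                       covariate_strategy = c("aic_subset", "all_reported", "none"),
                       bandwidth = "auto") {
  stopifnot(bootstrap_B >= 1, all(landmark_times > 0))
  structure(list(candidate_families = candidate_families,
                 knot_counts = knot_counts, links = links,
                 candidate_covariates = candidate_covariates,
                 landmark_times = landmark_times,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed),
                 covariate_strategy = match.arg(covariate_strategy),
                 bandwidth = bandwidth),
            class = "stc_config")
}

#' Enumerate the candidate survival distributions
#'
#' The default model space: 7 standard parametric families plus splines
#' with 1--3 internal knots under each of the hazard, odds and normal
#' links -- 16 candidate distributions in all.
#'
#' @param config An [stc_config()].
#' @return A tibble with one row per candidate: `family`, `link`, `m`.
#' @export
enumerate_candidates <- function(config = stc_config()) {
  parametric <- tibble(family = config$candidate_families,
                       link = NA_character_, m = NA_integer_)
  splines <- if (length(config$knot_counts) && length(config$links)) {
    tidyr::expand_grid(m = as.integer(config$knot_counts), link = config$links) |>
      mutate(family = "spline") |>
      select("family", "link", "m")
  } else tibble(family = character(), link = character(), m = integer())
  bind_rows(parametric, splines)
}

.fit_spec <- function(data, family, link, m, covariates = character()) {
  if (identical(family, "spline")) {
    tryCatch(fit_spline(data, m = m, link = link, covariates = covariates),
             error = function(e) {
               stc_model("spline", link = link, converged = FALSE,
                         beta = setNames(rep(NA_real_, length(covariates)), covariates))
             })
  } else {
    fit_parametric(data, family, covariates = covariates)
  }
}

#' Stage 1: choose the survival distribution with no covariates
#'
#' Fits every candidate distribution without covariates, drops
#' non-converged fits, and ranks by AIC (ties: fewer parameters, then the
#' enumeration order). The top-ranked distribution is the base case; the
#' next three are retained for sensitivity analyses.
#'
#' @param data An [as_ipd()] dataset.
#' @param config An [stc_config()].
#' @return A tibble of class `stc_stage1` with one row per candidate
#'   (converged fits ranked first by AIC) and a `model` list-column.
#' @export
stage1_select <- function(data, config = stc_config()) {
  grid <- enumerate_candidates(config)
  grid$spec_order <- seq_len(nrow(grid))
  fits <- pmap(grid[c("family", "link", "m")], function(family, link, m) {
    .fit_spec(data, family, link, m)
  })
  res <- grid |>
    mutate(model = fits,
           loglik = map_dbl(fits, "loglik"),
           n_params = map_dbl(fits, ~ .x$n_params %||% NA_real_),
           aic = map_dbl(fits, "aic"),
           converged = map_lgl(fits, "converged"))
  if (!any(res$converged)) {
    abort("no candidate distribution converged", class = "stc_selection_error")
  }
  res <- res |>
    arrange(desc(.data$converged), .data$aic, .data$n_params, .data$spec_order) |>
    mutate(rank = ifelse(.data$converged, cumsum(.data$converged), NA_integer_),
           role = dplyr::case_when(rank == 1 ~ "base",
                                   rank %in% 2:4 ~ "sensitivity",
                                   TRUE ~ NA_character_))
  class(res) <- c("stc_stage1", class(res))
  res
}

# all subsets of a candidate covariate list, empty set first,
# then by size and enumeration order
.covariate_subsets <- function(candidates) {
  p <- length(candidates)
  if (p == 0) return(list(character()))
  idx <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  subsets <- lapply(seq_len(nrow(idx)), function(i) candidates[unlist(idx[i, ])])
  subsets[order(lengths(subsets))]
}

#' Stage 2: choose the covariate subset for the selected distribution
#'
#' Exhaustively fits all `2^p` covariate subsets on the stage-1 winning
#' distribution and returns the lowest-AIC converged fit, assuming (as the
#' two-stage shortcut does) that the optimal covariate choice does not
#' depend on the baseline distribution. The ten best subsets are kept as a
#' report.
#'
#' @param data An [as_ipd()] dataset.
#' @param spec A one-row data frame (or list) with `family`, `link`, `m` --
#'   typically the top row of [stage1_select()].
#' @param candidates Candidate covariate names (at most 16, exhaustive
#'   enumeration guard).
#' @param keep_top How many subsets to keep in the report.
#' @return A list of class `stc_stage2`: `model` (the winner), `report`
#'   (top subsets tibble) and `n_fits`.
#' @export
stage2_select <- function(data, spec, candidates, keep_top = 10) {
  stopifnot(length(candidates) <= 16)
  subsets <- .covariate_subsets(candidates)
  fits <- map(subsets, function(cv) {
    .fit_spec(data, spec$family, spec$link, spec$m, covariates = cv)
  })
  report <- tibble(
    covariates = map_chr(subsets, ~ if (length(.x)) paste(.x, collapse = "+") else "(none)"),
    n_covariates = lengths(subsets),
    loglik = map_dbl(fits, "loglik"),
    n_params = map_dbl(fits, ~ .x$n_params %||% NA_real_),
    aic = map_dbl(fits, "aic"),
    converged = map_lgl(fits, "converged"),
    order = seq_along(subsets))
  ok <- which(report$converged)
  if (length(ok) == 0) {
    abort("no covariate subset converged", class = "stc_selection_error")
  }
  ranked <- ok[order(report$aic[ok], report$n_params[ok], report$order[ok])]
  structure(list(model = fits[[ranked[1]]],
                 covariates = subsets[[ranked[1]]],
                 report = report[ranked[seq_len(min(keep_top, length(ranked)))], ] |>
                   select(-"order"),
                 n_fits = length(subsets)),
            class = "stc_stage2")
}

#' @export
print.stc_stage2 <- function(x, ...) {
  cat(sprintf("Stage-2 covariate selection (%d subsets fitted)\n", x$n_fits))
  cat("  winner:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  print(x$report)
  invisible(x)
}

#' Assemble the sensitivity analysis set
#'
#' The six sensitivity analyses around a base-case model: the next three
#' lowest-AIC distributions refit with the stage-2 covariate set; the
#' winning distribution with all candidate covariates and with none; and
#' the naive KM-only comparison (no model at all).
#'
#' @param stage1 A [stage1_select()] ranking.
#' @param stage2 A [stage2_select()] result.
#' @param config An [stc_config()].
#' @return A tibble: `label`, `family`, `link`, `m`, `covariates`
#'   (list-column), `naive`.
#' @export
sensitivity_set <- function(stage1, stage2, config = stc_config()) {
  conv <- stage1[stage1$converged, ]
  if (nrow(conv) < 4) {
    warn(sprintf("only %d converged stage-1 models; sensitivity set is shorter", nrow(conv)))
  }
  nxt <- conv[seq_len(min(4, nrow(conv))), ][-1, ]
  base <- conv[1, ]
  sel <- stage2$covariates
  out <- bind_rows(
    if (nrow(nxt) > 0) tibble(label = sprintf("aic_rank_%d", nxt$rank),
                              family = nxt$family, link = nxt$link, m = nxt$m,
                              covariates = rep(list(sel), nrow(nxt)), naive = FALSE),
    tibble(label = "all_covariates", family = base$family, link = base$link,
           m = base$m, covariates = list(config$candidate_covariates), naive = FALSE),
    tibble(label = "no_covariates", family = base$family, link = base$link,
           m = base$m, covariates = list(character()), naive = FALSE),
    tibble(label = "naive_km", family = NA_character_, link = NA_character_,
           m = NA_integer_, covariates = list(character()), naive = TRUE))
  out
}
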