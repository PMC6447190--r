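#' Specification of a synthetic cohort
#'
#' Defines the population from which synthetic participants are drawn.
#' Each participant's true 75% threshold in each condition is a draw from
#' a normal distribution (truncated below at `trunc_lower` to keep
#' thresholds positive) around that condition's population mean; the
#' observer's psychometric spread is `sigma_factor` times their threshold.
#' Population means sit in the 0.20-0.37 range typical of speed-change
#' discrimination; the scenarios set the pattern across conditions:
#'
#' * `"null"` — all 8 conditions share the same mean (World = Retina; no
#'   effects anywhere).
#' * `"suppression"` — stereomotion suppression: each Control condition's
#'   mean is `control_factor` (default 0.7) times its main condition's.
#' * `"speed"` — a speed effect confined to the Retina pair: Fast means
#'   are `fast_factor` (default 0.75) times Slow means for Retina and
#'   Retina Control only.
#'
#' @param n_participants Number of participants (default 9).
#' @param scenario One of `"null"`, `"suppression"`, `"speed"`.
#' @param base_threshold Population mean threshold for unaffected
#'   conditions (default 0.30).
#' @param between_sd Between-participant SD of true thresholds
#'   (default 0.08).
#' @param sigma_factor Observer spread as a fraction of their threshold
#'   (default 0.5).
#' @param control_factor,fast_factor Scenario effect sizes.
#' @param trunc_lower Lower truncation for drawn thresholds.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(scenario = "suppression", seed = 7)
#' @export
cohort_spec <- function(n_participants = 9,
                        scenario = c("null", "suppression", "speed"),
                        base_threshold = 0.30,
                        between_sd = 0.08,
                        sigma_factor = 0.5,
                        control_factor = 0.7,
                        fast_factor = 0.75,
                        trunc_lower = 0.01,
                        seed = 1) {
  scenario <- tryCatch(
    match.arg(scenario),
    error = function(e) abort(paste0(
      "Unknown scenario '", scenario[1],
      "'. Available scenarios: null, suppression, speed."
    ))
  )
  if (n_participants < 1) abort("`n_participants` must be >= 1.")
  if (base_threshold <= 0) abort("`base_threshold` must be > 0.")
  if (between_sd < 0) abort("`between_sd` must be >= 0.")
  if (sigma_factor <= 0) abort("`sigma_factor` must be > 0.")
  structure(
    list(
      n_participants = n_participants, scenario = scenario,
      base_threshold = base_threshold, between_sd = between_sd,
      sigma_factor = sigma_factor, control_factor = control_factor,
      fast_factor = fast_factor, trunc_lower = trunc_lower,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Population mean thresholds implied by a cohort spec
#'
#' @param spec A [cohort_spec()].
#' @return A tibble: `condition`, `family`, `speed_class`, `mean_threshold`.
#' @export
scenario_means <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- condition_grid()
  base <- spec$base_threshold
  grid$mean_threshold <- base
  if (spec$scenario == "suppression") {
    is_control <- grid$family %in% c("WorldControl", "RetinaControl")
    grid$mean_threshold[is_control] <- base * spec$control_factor
  } else if (spec$scenario == "speed") {
    hit <- grid$family %in% c("Retina", "RetinaControl") &
      grid$speed_class == "Fast"
    grid$mean_threshold[hit] <- base * spec$fast_factor
  }
  grid
}

# normal truncated below via inverse-CDF; exact, no rejection loop
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (all(sd == 0)) return(pmax(rep_len(mean, n), lower))
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

#' Generate a full synthetic cohort of trial records
#'
#' Draws each participant's true threshold per condition from the
#' population defined by the spec, then simulates the complete main
#' experiment (8 conditions x 7 levels x 3 blocks x 10 trials) through the
#' synthetic observer. The drawn true thresholds are attached as the
#' `"true_thresholds"` attribute for parameter-recovery studies.
#'
#' @param spec A [cohort_spec()].
#' @param geom A [viewing_geometry()].
#' @return A trial tibble (`participant`, `condition`, `family`,
#'   `speed_class`, `level`, `block`, `trial`, `change_interval`,
#'   `prop_change`, `correct`), 1680 rows per participant.
#' @examples
#' trials <- generate_cohort(cohort_spec(n_participants = 2, seed = 3))
#' dplyr::count(trials, participant)
#' @export
generate_cohort <- function(spec, geom = viewing_geometry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  means <- scenario_means(spec)
  ids <- sprintf("P%02d", seq_len(spec$n_participants))
  truth <- withr::with_seed(spec$seed, {
    tidyr::crossing(participant = ids, means) |>
      dplyr::mutate(
        alpha = rtruncnorm_lower(dplyr::n(), .data$mean_threshold,
                                 spec$between_sd, spec$trunc_lower),
        sigma = spec$sigma_factor * .data$alpha
      )
  })
  sched <- build_experiment(ids, seed = spec$seed + 1L)
  models <- dplyr::select(truth, "participant", "condition", "alpha", "sigma")
  trials <- simulate_responses(sched, models, geom = geom, seed = spec$seed + 2L)
  attr(trials, "true_thresholds") <- truth
  trials
}

#' True thresholds attached to a generated cohort
#'
#' @param trials Output of [generate_cohort()].
#' @return The tibble of drawn per-participant true thresholds.
#' @export
true_thresholds <- function(trials) {
  tt <- attr(trials, "true_thresholds")
  if (is.null(tt)) abort("No 'true_thresholds' attribute; not a generated cohort?")
  tt
}
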