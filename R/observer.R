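#' Ground-truth psychometric observer model
#'
#' A synthetic 2IFC observer whose probability of a correct response at
#' proportion speed change `x` follows the constrained cumulative normal
#' `guess + (1 - guess - lapse) * pnorm((x - alpha) / sigma)`. With the 2IFC
#' guess rate 0.5 and zero lapse, `alpha` is exactly the 75% threshold.
#'
#' @param alpha Location: proportion speed change at 75% correct.
#' @param sigma Spread (same units); > 0.
#' @param guess Guess rate; 0.5 for 2IFC.
#' @param lapse Lapse rate in `[0, 0.06]`; default 0.
#' @return An object of class `observer_model`.
#' @examples
#' m <- observer_model(0.30, 0.15)
#' p_correct(0.30, m) # 0.75
#' @export
observer_model <- function(alpha, sigma, guess = 0.5, lapse = 0) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (lapse < 0 || lapse > 0.06) abort("`lapse` must lie in [0, 0.06].")
  if (guess < 0 || guess >= 1) abort("`guess` must lie in [0, 1).")
  structure(list(alpha = alpha, sigma = sigma, guess = guess, lapse = lapse),
            class = "observer_model")
}

#' Probability of a correct 2IFC response
#'
#' @param x Proportion speed change (>= 0). Vectorised.
#' @param model An [observer_model()].
#' @return Probability in `[guess, 1 - lapse]`, nondecreasing in `x`.
#' @export
p_correct <- function(x, model) {
  stopifnot(inherits(model, "observer_model"))
  model$guess + (1 - model$guess - model$lapse) *
    pnorm((x - model$alpha) / model$sigma)
}

#' Simulate 2IFC responses over a trial schedule
#'
#' Fills in the `correct` column of a schedule from [build_experiment()]:
#' each trial is an independent Bernoulli draw with success probability
#' given by that condition's observer model evaluated at the trial level's
#' proportion speed change. No sequential dependencies are modelled (the
#' main experiment gives no feedback).
#'
#' @param schedule Trial schedule tibble (`condition`, `level`, ...).
#' @param models Either a tibble with columns `condition`, `alpha`, `sigma`
#'   (optionally `guess`, `lapse`), one row per condition in the schedule —
#'   or, for per-participant heterogeneity, with a `participant` column as
#'   well; or a single [observer_model()] applied to every condition.
#' @param geom A [viewing_geometry()] (fixes the level -> proportion map).
#' @param seed Integer seed.
#' @return The schedule with an integer `correct` column (0/1) appended.
#' @examples
#' sched <- build_experiment("P01", seed = 1)
#' models <- dplyr::mutate(condition_grid(), alpha = 0.3, sigma = 0.15)
#' trials <- simulate_responses(sched, models, seed = 2)
#' mean(trials$correct)
#' @export
simulate_responses <- function(schedule, models, geom = viewing_geometry(),
                               seed = 1) {
  stopifnot(is.data.frame(schedule))
  if (inherits(models, "observer_model")) {
    models <- dplyr::mutate(
      dplyr::distinct(schedule, .data$condition),
      alpha = models$alpha, sigma = models$sigma,
      guess = models$guess, lapse = models$lapse
    )
  }
  stopifnot(is.data.frame(models))
  if (!"guess" %in% names(models)) models$guess <- 0.5
  if (!"lapse" %in% names(models)) models$lapse <- 0
  keys <- intersect(c("participant", "condition"), names(models))
  absent <- dplyr::anti_join(
    dplyr::distinct(schedule, dplyr::pick(dplyr::all_of(keys))),
    models,
    by = keys
  )
  if (nrow(absent) > 0) {
    abort(paste0("No observer model for: ",
                 paste(do.call(paste, c(absent, sep = "/")), collapse = ", "), "."))
  }
  if (any(models$sigma <= 0)) abort("All model `sigma` values must be > 0.")
  models <- dplyr::select(models, dplyr::all_of(c(keys, "alpha", "sigma",
                                                  "guess", "lapse")))
  pc <- level_prop_changes(geom)
  trials <- schedule |>
    dplyr::left_join(dplyr::select(pc, "condition", "level", "prop_change"),
                     by = c("condition", "level")) |>
    dplyr::left_join(models, by = keys)
  p <- trials$guess + (1 - trials$guess - trials$lapse) *
    pnorm((trials$prop_change - trials$alpha) / trials$sigma)
  withr::with_seed(as.integer(seed), {
    trials$correct <- rbinom(nrow(trials), 1L, p)
  })
  dplyr::select(trials, dplyr::all_of(names(schedule)), "prop_change", "correct")
}
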