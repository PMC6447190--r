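#' The eight experimental conditions
#'
#' Four stimulus families (World, WorldControl, Retina, RetinaControl)
#' crossed with two speed classes (Fast: 40 cm/s standard; Slow: 20 cm/s).
#'
#' @return A tibble: `condition`, `family`, `speed_class` (8 rows).
#' @examples
#' condition_grid()
#' @export
condition_grid <- function() {
  tidyr::crossing(
    family = c("World", "WorldControl", "Retina", "RetinaControl"),
    speed_class = c("Fast", "Slow")
  ) |>
    dplyr::mutate(condition = paste(.data$family, .data$speed_class, sep = "-")) |>
    dplyr::select("condition", "family", "speed_class")
}

#' Method-of-constant-stimuli speed ladder
#'
#' Seven levels of world speeds around a standard: level k has
#' `(standard_v - (k-1) * step, standard_v + (k-1) * step)`, so the mean of
#' the two speeds equals the standard at every level and the total distance
#' travelled (with the change at the temporal midpoint) is conserved. The
#' Fast ladder uses a 5 cm/s step (40,40 ... 10,70), the Slow ladder
#' 2.5 cm/s (20,20 ... 5,35).
#'
#' @param standard_v Standard world speed, cm/s.
#' @param step Per-level speed offset, cm/s.
#' @param n_levels Number of levels (default 7).
#' @return A tibble: `level`, `v_before`, `v_after`.
#' @examples
#' level_ladder(40, 5)
#' @export
level_ladder <- function(standard_v, step, n_levels = 7) {
  if (standard_v <= 0 || step <= 0) abort("`standard_v` and `step` must be > 0.")
  k <- seq_len(n_levels)
  v_before <- standard_v - (k - 1) * step
  if (any(v_before <= 0)) {
    abort("Ladder reaches a nonpositive pre-change speed; reduce `step` or `n_levels`.")
  }
  tibble(level = k, v_before = v_before, v_after = standard_v + (k - 1) * step)
}

#' Proportion speed change at the changepoint
#'
#' The task's difficulty statistic: `(c - b) / c`, where `b` and `c` are
#' the retinal speeds immediately before and after the step change. Note
#' the denominator is the post-change speed, so the statistic lies in
#' `[0, 1)` for speed increases.
#'
#' @param b Speed immediately before the change (arcmin/s), `b <= c`.
#' @param c Speed immediately after the change (arcmin/s), > 0.
#' @return Proportion in `[0, 1)`. Vectorised.
#' @examples
#' proportion_speed_change(7.6, 87.4)
#' @export
proportion_speed_change <- function(b, c) {
  if (any(c <= 0)) abort("`c` must be > 0.")
  if (any(b > c)) abort("`b` must not exceed `c` (speed steps up).")
  (c - b) / c
}

#' Proportion speed change for every condition and level
#'
#' For World and World Control conditions `b` and `c` are the cyclopean
#' instantaneous retinal speeds at the changepoint of the world trajectory;
#' because both are evaluated at the same depth, the proportion reduces to
#' the world-speed proportion `(v_after - v_before) / v_after`. For Retina
#' and Retina Control conditions they are the piecewise-constant speeds
#' from [retina_speed_ladder()].
#'
#' @param geom A [viewing_geometry()].
#' @return A tibble: `condition`, `family`, `speed_class`, `level`,
#'   `prop_change`.
#' @examples
#' level_prop_changes()
#' @export
level_prop_changes <- function(geom = viewing_geometry()) {
  speed_table(geom) |>
    dplyr::mutate(prop_change = proportion_speed_change(.data$b, .data$c)) |>
    dplyr::select("condition", "family", "speed_class", "level", "prop_change")
}

#' Build a full 2IFC trial schedule
#'
#' One run of the main experiment per participant: every condition x level
#' x block x trial cell, with the speed-change interval position (1 or 2)
#' assigned uniformly at random. With the default design (8 conditions, 7
#' levels, 3 blocks, 10 trials per level per block) each participant
#' contributes 1680 trials.
#'
#' @param participants Character vector of participant ids.
#' @param conditions A condition tibble as from [condition_grid()].
#' @param blocks Number of blocks per condition.
#' @param trials_per_level Trials per level within a block.
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return A tibble: `participant`, `condition`, `family`, `speed_class`,
#'   `level`, `block`, `trial`, `change_interval`.
#' @examples
#' nrow(build_experiment("P01", seed = 1)) # 1680
#' @export
build_experiment <- function(participants = "P01",
                             conditions = condition_grid(),
                             blocks = 3,
                             trials_per_level = 10,
                             seed = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  schedule <- tidyr::crossing(
    participant = participants,
    conditions,
    level = 1:7,
    block = seq_len(blocks),
    trial = seq_len(trials_per_level)
  )
  withr::with_seed(as.integer(seed), {
    schedule$change_interval <- sample(c(1L, 2L), nrow(schedule), replace = TRUE)
  })
  dplyr::select(schedule, "participant", "condition", "family", "speed_class",
                "level", "block", "trial", "change_interval")
}

#' Participant exclusion on highest-level accuracy
#'
#' Applies the study's quality-control rule: a participant is excluded if
#' their accuracy at the highest speed-change level (level 7) falls below
#' `min_accuracy` in two or more conditions.
#'
#' @param trials Trial tibble with columns `participant`, `condition`,
#'   `level`, `correct` (complete for every participant x condition).
#' @param min_accuracy Accuracy criterion at the top level (default 0.8).
#' @param max_low_conditions Most conditions allowed below criterion
#'   before exclusion (default 1, i.e. excluded at 2 or more).
#' @return A tibble: `participant`, `n_below`, `excluded`, `reason`.
#' @export
qc_exclude <- function(trials, min_accuracy = 0.8, max_low_conditions = 1) {
  required <- c("participant", "condition", "level", "correct")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  top <- dplyr::filter(trials, .data$level == max(trials$level))
  cells <- tidyr::crossing(
    participant = unique(trials$participant),
    condition = unique(trials$condition)
  )
  have <- dplyr::distinct(top, .data$participant, .data$condition)
  absent <- dplyr::anti_join(cells, have, by = c("participant", "condition"))
  if (nrow(absent) > 0) {
    abort(paste0(
      "Incomplete trial table: no top-level trials for ",
      paste(absent$participant, absent$condition, sep = "/", collapse = ", "), "."
    ))
  }
  top |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(n_below = sum(.data$accuracy < min_accuracy), .groups = "drop") |>
    dplyr::mutate(
      excluded = .data$n_below > max_low_conditions,
      reason = dplyr::if_else(
        .data$excluded,
        paste0("top-level accuracy < ", min_accuracy, " in ",
               .data$n_below, " conditions"),
        NA_character_
      )
    )
}

#' Training-block pass criterion
#'
#' Participants proceed to the main experiment only after at least
#' `min_correct` correct responses out of `n_total` trials in the final
#' training block (50 of 60 by default).
#'
#' @param n_correct Correct responses in the final training block.
#' @param n_total Trials in the final training block.
#' @param min_correct Pass criterion.
#' @return Logical. Vectorised over `n_correct`.
#' @export
training_pass <- function(n_correct, n_total = 60, min_correct = 50) {
  if (any(n_correct < 0 | n_correct > n_total)) {
    abort("`n_correct` must lie in [0, n_total].")
  }
  n_correct >= min_correct
}
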