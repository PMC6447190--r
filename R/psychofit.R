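#' Aggregate trial records to per-level binomial counts
#'
#' @param trials Tibble with columns `prop_change` (or `level` plus the
#'   design mapping) and `correct`.
#' @return A tibble: `prop_change`, `n_correct`, `n_total`.
#' @export
aggregate_trials <- function(trials) {
  stopifnot(all(c("prop_change", "correct") %in% names(trials)))
  trials |>
    dplyr::group_by(prop_change = .data$prop_change) |>
    dplyr::summarise(
      n_correct = sum(.data$correct),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$prop_change)
}

psych_negll <- function(par, x, k, n, guess, lapse) {
  alpha <- par[1]
  sigma <- exp(par[2])
  p <- guess + (1 - guess - lapse) * pnorm((x - alpha) / sigma)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Maximum-likelihood fit of the constrained psychometric function
#'
#' Fits the 2IFC cumulative-normal model
#' `p(x) = guess + (1 - guess - lapse) * pnorm((x - alpha) / sigma)` to
#' per-level binomial counts by maximising the product-binomial likelihood,
#' with the guess rate fixed at 0.5 and the lapse rate fixed at 0 (both
#' configurable). `sigma` is optimised in log space; `alpha` is initialised
#' at the level whose empirical accuracy brackets 75% and `sigma` at half
#' the level range, then refined by Nelder-Mead.
#'
#' Datasets in which no level rises above the guess rate carry no
#' information about the threshold: the fit is flagged non-identifiable
#' and the threshold reported as `NA`, never extrapolated.
#'
#' @param data A tibble with columns `prop_change`, `n_correct`, `n_total`
#'   (as from [aggregate_trials()]), at least 2 distinct levels.
#' @param guess Fixed guess rate (0.5 for 2IFC).
#' @param lapse Fixed lapse rate in `[0, 0.06]`.
#' @return An object of class `psychfit`: `alpha_hat`, `sigma_hat`,
#'   `guess`, `lapse`, `log_likelihood`, `deviance`, `converged`,
#'   `identifiable`, `threshold_75`, plus the data.
#' @examples
#' d <- tibble::tibble(
#'   prop_change = seq(0, 0.9, length.out = 7),
#'   n_total = 30,
#'   n_correct = c(14, 17, 19, 24, 27, 29, 30)
#' )
#' fit <- fit_psychometric(d)
#' threshold_75(fit)
#' @export
fit_psychometric <- function(data, guess = 0.5, lapse = 0) {
  stopifnot(all(c("prop_change", "n_correct", "n_total") %in% names(data)))
  if (lapse < 0 || lapse > 0.06) abort("`lapse` must lie in [0, 0.06].")
  data <- dplyr::arrange(as_tibble(data), .data$prop_change)
  x <- data$prop_change
  k <- data$n_correct
  n <- data$n_total
  if (any(n <= 0)) abort("Every level needs `n_total` > 0.")
  if (any(k < 0 | k > n)) abort("`n_correct` must lie in [0, n_total].")
  if (length(unique(x)) < 2) abort("Need at least 2 distinct levels to fit.")

  acc <- k / n
  # no level above chance (nothing to locate) or every level perfect
  # (location unbounded below, spread at zero): non-identifiable
  identifiable <- max(acc) > guess && !all(k == n)
  # initial alpha: level where accuracy first crosses the 75% point
  target <- guess + (1 - guess - lapse) / 2
  above <- which(acc >= target)
  alpha0 <- if (length(above) > 0) x[above[1]] else max(x)
  sigma0 <- max(diff(range(x)) / 2, 1e-3)

  opt <- optim(
    c(alpha0, log(sigma0)), psych_negll,
    x = x, k = k, n = n, guess = guess, lapse = lapse,
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-12)
  )
  alpha_hat <- opt$par[1]
  sigma_hat <- exp(opt$par[2])
  at_bound <- sigma_hat < 1e-6 || sigma_hat > 1e3 ||
    alpha_hat < min(x) - 10 * diff(range(x)) ||
    alpha_hat > max(x) + 10 * diff(range(x))
  if (at_bound) identifiable <- FALSE
  converged <- opt$convergence == 0 && identifiable

  ll <- -opt$value
  p_sat <- pmin(pmax(acc, 1e-12), 1 - 1e-12)
  ll_sat <- sum(k * log(p_sat) + (n - k) * log(1 - p_sat))
  structure(
    list(
      alpha_hat = alpha_hat,
      sigma_hat = sigma_hat,
      guess = guess,
      lapse = lapse,
      log_likelihood = ll,
      deviance = 2 * (ll_sat - ll),
      converged = converged,
      identifiable = identifiable,
      threshold_75 = if (converged && guess == 0.5 && lapse == 0) alpha_hat
                     else if (converged) threshold_at(alpha_hat, sigma_hat, guess, lapse, 0.75)
                     else NA_real_,
      data = data
    ),
    class = "psychfit"
  )
}

# x where the constrained model reaches `p`; NA when p is unreachable
threshold_at <- function(alpha, sigma, guess, lapse, p) {
  top <- 1 - lapse
  if (p <= guess || p >= top) return(NA_real_)
  alpha + sigma * qnorm((p - guess) / (top - guess))
}

#' 75% threshold of a fitted psychometric function
#'
#' The proportion speed change at which the fitted function reaches 75%
#' correct. Under the fixed 2IFC guess rate of 0.5 and zero lapse this is
#' exactly the fitted location `alpha_hat`.
#'
#' @param fit A converged [fit_psychometric()] object.
#' @return Proportion speed change at 75% correct.
#' @export
threshold_75 <- function(fit) {
  stopifnot(inherits(fit, "psychfit"))
  if (!fit$converged) {
    abort("Fit did not converge (or is non-identifiable); no threshold is defined.")
  }
  fit$threshold_75
}

#' Predicted probability correct from a fit
#'
#' @param object A `psychfit`.
#' @param newdata Optional tibble with a `prop_change` column.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$prop_change else newdata$prop_change
  object$guess + (1 - object$guess - object$lapse) *
    pnorm((x - object$alpha_hat) / object$sigma_hat)
}

#' @export
print.psychfit <- function(x, ...) {
  cat("<psychfit> alpha =", signif(x$alpha_hat, 4),
      " sigma =", signif(x$sigma_hat, 4),
      " (guess", x$guess, ", lapse", x$lapse, ")\n")
  cat("  logLik", signif(x$log_likelihood, 6),
      " deviance", signif(x$deviance, 4),
      " converged:", x$converged, "\n")
  if (is.na(x$threshold_75)) cat("  75% threshold: not defined\n")
  else cat("  75% threshold:", signif(x$threshold_75, 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.psychfit <- function(x, ...) {
  tibble(
    term = c("alpha", "sigma"),
    estimate = c(x$alpha_hat, x$sigma_hat),
    fixed = FALSE
  ) |>
    dplyr::bind_rows(tibble(
      term = c("guess", "lapse"),
      estimate = c(x$guess, x$lapse),
      fixed = TRUE
    ))
}

#' @exportS3Method generics::glance
glance.psychfit <- function(x, ...) {
  tibble(
    threshold_75 = x$threshold_75,
    log_likelihood = x$log_likelihood,
    deviance = x$deviance,
    converged = x$converged,
    n_levels = nrow(x$data),
    n_trials = sum(x$data$n_total)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.psychfit <- function(object, ...) {
  grid <- tibble(prop_change = seq(
    min(object$data$prop_change), max(object$data$prop_change),
    length.out = 200
  ))
  grid$p <- predict(object, grid)
  obs <- dplyr::mutate(object$data, accuracy = .data$n_correct / .data$n_total)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$prop_change)) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p), colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$accuracy, size = .data$n_total),
                        alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = "Proportion speed change", y = "Proportion correct") +
    ggplot2::theme_minimal()
}

#' Fit thresholds for every participant x condition
#'
#' Pools each participant's trials per condition (210 with the default
#' design), fits the constrained psychometric function and extracts the
#' 75% threshold.
#'
#' @param trials Trial tibble with `participant`, `condition`, `correct`
#'   and either `prop_change` or `level` (mapped via the design).
#' @param geom A [viewing_geometry()] used when `prop_change` is absent.
#' @param guess,lapse Fixed rates passed to [fit_psychometric()].
#' @return A tibble: `participant`, `condition`, `family`, `speed_class`
#'   (when derivable), `alpha_hat`, `sigma_hat`, `threshold_75`,
#'   `deviance`, `converged`.
#' @examples
#' sched <- build_experiment("P01", seed = 1)
#' models <- dplyr::mutate(condition_grid(), alpha = 0.3, sigma = 0.15)
#' trials <- simulate_responses(sched, models, seed = 2)
#' fit_thresholds(trials)
#' @export
fit_thresholds <- function(trials, geom = viewing_geometry(),
                           guess = 0.5, lapse = 0) {
  if (!"prop_change" %in% names(trials)) {
    pc <- level_prop_changes(geom)
    trials <- dplyr::left_join(
      trials, dplyr::select(pc, "condition", "level", "prop_change"),
      by = c("condition", "level")
    )
  }
  out <- trials |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_psychometric(aggregate_trials(d), guess = guess, lapse = lapse)
      tibble(
        alpha_hat = fit$alpha_hat,
        sigma_hat = fit$sigma_hat,
        threshold_75 = fit$threshold_75,
        deviance = fit$deviance,
        converged = fit$converged
      )
    }) |>
    dplyr::ungroup()
  grid <- condition_grid()
  if (all(out$condition %in% grid$condition)) {
    out <- dplyr::left_join(out, grid, by = "condition") |>
      dplyr::select("participant", "condition", "family", "speed_class",
                    dplyr::everything())
  }
  out
}
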