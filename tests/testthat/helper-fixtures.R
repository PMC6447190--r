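# shared fixtures built in code

fast_geom <- viewing_geometry()

world_trace <- function(v_before, v_after, geom = fast_geom) {
  trace_retinal(
    build_world_interval(speed_change_interval(v_before, v_after), geom),
    geom
  )
}

# binomial counts drawn from a ground-truth observer at the given levels
draw_counts <- function(alpha, sigma, levels, n_per_level, seed) {
  m <- observer_model(alpha, sigma)
  withr::with_seed(seed, {
    tibble::tibble(
      prop_change = levels,
      n_total = n_per_level,
      n_correct = rbinom(length(levels), n_per_level, p_correct(levels, m))
    )
  })
}

# a random complete 2x2 within-subject table
random_2x2 <- function(n = 9, seed = 1, effect = 0) {
  withr::with_seed(seed, {
    d <- tidyr::crossing(
      subject = sprintf("s%02d", seq_len(n)),
      a = c("a1", "a2"), b = c("b1", "b2")
    )
    d$y <- rnorm(nrow(d)) + ifelse(d$a == "a1", effect, 0)
    d
  })
}

# classical RM-ANOVA via base aov() with an Error() stratum, as an
# independent route to the same decomposition
aov_oracle <- function(d) {
  d2 <- dplyr::mutate(d,
    subject = factor(subject), a = factor(a), b = factor(b)
  )
  fit <- stats::aov(y ~ a * b + Error(subject / (a * b)), data = d2)
  s <- summary(fit)
  pull <- function(stratum) {
    tab <- s[[stratum]][[1]]
    list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
         ss_eff = tab[["Sum Sq"]][1], ss_err = tab[["Sum Sq"]][2])
  }
  list(
    a = pull("Error: subject:a"),
    b = pull("Error: subject:b"),
    ab = pull("Error: subject:a:b")
  )
}
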