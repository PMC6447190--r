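test_that("rm_anova_2x2 agrees with base aov's Error-stratum decomposition", {
  for (seed in c(7, 21, 100)) {
    d <- random_2x2(n = 9, seed = seed, effect = 0.3)
    mine <- tidy(rm_anova_2x2(d, y, subject, a, b))
    ref <- aov_oracle(d)
    expect_equal(mine$f, c(ref$a$f, ref$b$f, ref$ab$f), tolerance = 1e-9)
    expect_equal(mine$p, c(ref$a$p, ref$b$p, ref$ab$p), tolerance = 1e-9)
    expect_equal(mine$ss_effect, c(ref$a$ss_eff, ref$b$ss_eff, ref$ab$ss_eff),
                 tolerance = 1e-9)
  }
})

test_that("ANOVA is invariant to adding a constant and reports partial eta^2", {
  d <- random_2x2(n = 9, seed = 3, effect = 0.2)
  base <- tidy(rm_anova_2x2(d, y, subject, a, b))
  shifted <- tidy(rm_anova_2x2(dplyr::mutate(d, y = y + 100),
                               y, subject, a, b))
  expect_equal(base$f, shifted$f, tolerance = 1e-9)
  expect_equal(base$p, shifted$p, tolerance = 1e-9)
  expect_equal(base$partial_eta_sq, shifted$partial_eta_sq, tolerance = 1e-9)
  # identity eta_p^2 = F / (F + df_den) for 1-df effects
  expect_equal(base$partial_eta_sq, base$f / (base$f + base$df_den),
               tolerance = 1e-12)
  expect_equal(base$df_num, rep(1L, 3))
  expect_equal(base$df_den, rep(8L, 3))
})

test_that("ANOVA input validation and degenerate variance handling", {
  d <- random_2x2(n = 9, seed = 5)
  expect_error(rm_anova_2x2(d[-1, ], y, subject, a, b), "complete")
  d3 <- dplyr::mutate(d, a = dplyr::if_else(subject == "s01" & a == "a1",
                                            "a3", a))
  expect_error(rm_anova_2x2(d3, y, subject, a, b), "2 levels")
  # additive subject + effect structure: zero error variance for factor a
  da <- tidyr::crossing(subject = sprintf("s%d", 1:5),
                        a = c("a1", "a2"), b = c("b1", "b2"))
  da$y <- as.numeric(factor(da$subject)) + ifelse(da$a == "a1", 1, 0)
  w <- capture_warnings(res <- rm_anova_2x2(da, y, subject, a, b))
  expect_match(w, "infinite", all = FALSE)
  expect_equal(tidy(res)$f[1], Inf)
})

test_that("between-subject CIs use the t quantile", {
  d <- tibble::tibble(
    participant = rep(sprintf("s%d", 1:9), 2),
    condition = rep(c("c1", "c2"), each = 9),
    y = c(rep(0.5, 9), seq(0.1, 0.9, length.out = 9))
  )
  ci <- between_subject_ci(d, y, condition)
  expect_equal(ci$half_width[ci$condition == "c1"], 0)
  c2 <- dplyr::filter(d, condition == "c2")
  expect_equal(ci$half_width[ci$condition == "c2"],
               qt(0.975, 8) * sd(c2$y) / 3, tolerance = 1e-12)
  # n = 9, sd = 0.09 gives the textbook 2.306 * 0.03 half width
  d9 <- tibble::tibble(participant = 1:9, condition = "c",
                       y = scale(rnorm(9))[, 1] * 0.09 + 0.3)
  expect_equal(between_subject_ci(d9, y, condition)$half_width,
               qt(0.975, 8) * 0.09 / 3, tolerance = 1e-9)
  expect_equal(qt(0.975, 8) * 0.03, 0.0692, tolerance = 1e-3)
  # degenerate confidence level collapses the interval
  expect_equal(between_subject_ci(d, y, condition, level = 0)$half_width,
               c(0, 0))
  expect_error(between_subject_ci(d[1, ], y, condition), "2 subjects")
})

test_that("JZS Bayes factor favors the null at t = 0 and matches the
           Cauchy-delta quadrature oracle", {
  oracle_bf <- function(t_stat, n, r) {
    nu <- n - 1
    delta <- seq(-12, 12, length.out = 40001)
    f <- suppressWarnings(
      dt(t_stat, nu, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, r)
    )
    num <- sum((f[-1] + f[-length(f)]) / 2 * diff(delta))
    num / dt(t_stat, nu)
  }
  null_d <- c(-0.1, 0.05, 0.02, -0.03, 0.08, -0.06, 0.01, 0.02, -0.04)
  bf0 <- jzs_paired_bf(null_d)
  expect_lt(bf0$bf10, 1)
  expect_equal(bf0$bf01, 1 / bf0$bf10)
  # a fixture engineered to t = 3.0 at n = 9: sd 1, mean 1
  d3 <- scale(1:9)[, 1] + 1
  t3 <- mean(d3) / (sd(d3) / 3)
  expect_equal(t3, 3, tolerance = 1e-12)
  bf3 <- jzs_paired_bf(d3)
  expect_equal(bf3$bf10, oracle_bf(3, 9, 0.5), tolerance = 1e-4)
  expect_equal(bf0$bf10, oracle_bf(bf0$t, 9, 0.5), tolerance = 1e-4)
  # prior collapsing to the null gives BF -> 1
  expect_equal(jzs_paired_bf(d3, cauchy_scale = 1e-6)$bf10, 1,
               tolerance = 1e-3)
  expect_error(jzs_paired_bf(rep(0.2, 9)), "Zero-variance")
  expect_error(jzs_paired_bf(0.5), "at least 2")
})

test_that("BF10 grows monotonically in |t| at fixed n", {
  make_d <- function(t_target, n = 9) {
    base <- scale(seq_len(n))[, 1]          # mean 0, sd 1
    base + t_target / sqrt(n)               # t = t_target exactly
  }
  ts <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, function(t) jzs_paired_bf(make_d(t))$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("planned comparisons produce three ANOVAs with Bayes factors", {
  trials <- generate_cohort(cohort_spec(n_participants = 5, seed = 8,
                                        scenario = "suppression"))
  th <- fit_thresholds(trials)
  res <- planned_comparisons(th)
  expect_setequal(names(res),
                  c("world_vs_retina", "world_vs_control", "retina_vs_control"))
  for (r in res) {
    expect_s3_class(r$anova, "rm_anova_2x2")
    expect_s3_class(r$bf, "jzs_bf")
    expect_gt(r$bf$bf10, 0)
  }
})
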