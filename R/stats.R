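#' 2x2 repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a 2x2 fully-crossed design
#' with one observation per subject per cell. Each effect (factor A,
#' factor B, and their interaction) is tested against its own
#' subject-by-effect interaction mean square, with `df = (1, n - 1)`.
#' The effect size reported is partial eta squared,
#' `SS_effect / (SS_effect + SS_error_effect)`, which for these designs
#' equals `F / (F + df_den)`. No sphericity correction is needed: both
#' factors have two levels.
#'
#' @param data Long tibble with one row per subject x cell.
#' @param value Column holding the response (e.g. `threshold_75`).
#' @param subject Column identifying the subject.
#' @param factor_a,factor_b Columns holding the two 2-level factors.
#' @return An object of class `rm_anova_2x2`; `tidy()` returns a tibble
#'   with one row per effect (`effect`, `ss_effect`, `ss_error`, `df_num`,
#'   `df_den`, `f`, `p`, `partial_eta_sq`).
#' @examples
#' d <- tidyr::crossing(subject = 1:9, a = c("x", "y"), b = c("u", "v"))
#' d$y <- rnorm(nrow(d))
#' tidy(rm_anova_2x2(d, y, subject, a, b))
#' @export
rm_anova_2x2 <- function(data, value, subject, factor_a, factor_b) {
  value <- rlang::enquo(value)
  subject <- rlang::enquo(subject)
  factor_a <- rlang::enquo(factor_a)
  factor_b <- rlang::enquo(factor_b)
  d <- dplyr::transmute(
    as_tibble(data),
    s = as.character(!!subject),
    a = as.character(!!factor_a),
    b = as.character(!!factor_b),
    y = !!value
  )
  la <- sort(unique(d$a))
  lb <- sort(unique(d$b))
  subjects <- unique(d$s)
  n <- length(subjects)
  if (length(la) != 2 || length(lb) != 2) {
    abort("Both factors must have exactly 2 levels.")
  }
  if (n < 2) abort("Need at least 2 subjects.")
  full <- tidyr::crossing(s = subjects, a = la, b = lb)
  if (nrow(d) != nrow(full) ||
      nrow(dplyr::anti_join(full, d, by = c("s", "a", "b"))) > 0) {
    abort("Design must be complete: one observation per subject per cell.")
  }
  if (any(is.na(d$y))) abort("Missing values in the response.")

  # cell / marginal means
  Y <- array(NA_real_, c(n, 2, 2))
  for (r in seq_len(nrow(d))) {
    Y[match(d$s[r], subjects), match(d$a[r], la), match(d$b[r], lb)] <- d$y[r]
  }
  m <- mean(Y)
  m_s <- apply(Y, 1, mean)
  m_a <- apply(Y, 2, mean)
  m_b <- apply(Y, 3, mean)
  m_ab <- apply(Y, c(2, 3), mean)
  m_sa <- apply(Y, c(1, 2), mean)
  m_sb <- apply(Y, c(1, 3), mean)

  ss_a <- 2 * n * sum((m_a - m)^2)
  ss_b <- 2 * n * sum((m_b - m)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 2)) - outer(rep(1, 2), m_b) + m)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) - outer(rep(1, n), m_a) + m)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) - outer(rep(1, n), m_b) + m)^2)
  resid <- Y
  for (i in seq_len(n)) {
    for (j in 1:2) {
      for (k in 1:2) {
        resid[i, j, k] <- Y[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
          m_s[i] + m_a[j] + m_b[k] - m
      }
    }
  }
  ss_abs <- sum(resid^2)

  one_effect <- function(name, ss_eff, ss_err) {
    df_num <- 1L
    df_den <- n - 1L
    if (ss_err <= .Machine$double.eps * max(1, ss_eff)) {
      warn(paste0("Zero error variance for effect ", name,
                  "; F reported as infinite."))
      f <- if (ss_eff > 0) Inf else NaN
      p <- if (ss_eff > 0) 0 else NaN
    } else {
      f <- (ss_eff / df_num) / (ss_err / df_den)
      p <- pf(f, df_num, df_den, lower.tail = FALSE)
    }
    tibble(
      effect = name, ss_effect = ss_eff, ss_error = ss_err,
      df_num = df_num, df_den = df_den, f = f, p = p,
      partial_eta_sq = ss_eff / (ss_eff + ss_err)
    )
  }
  a_name <- rlang::as_name(factor_a)
  b_name <- rlang::as_name(factor_b)
  effects <- dplyr::bind_rows(
    one_effect(a_name, ss_a, ss_as),
    one_effect(b_name, ss_b, ss_bs),
    one_effect(paste0(a_name, ":", b_name), ss_ab, ss_abs)
  )
  structure(
    list(effects = effects, n = n,
         factor_a = a_name, factor_b = b_name,
         levels_a = la, levels_b = lb),
    class = "rm_anova_2x2"
  )
}

#' @export
print.rm_anova_2x2 <- function(x, ...) {
  cat("2x2 repeated-measures ANOVA (n =", x$n, "subjects)\n")
  eff <- dplyr::mutate(
    x$effects,
    f = signif(.data$f, 4), p = signif(.data$p, 4),
    partial_eta_sq = signif(.data$partial_eta_sq, 3)
  )
  print(as.data.frame(dplyr::select(eff, "effect", "df_num", "df_den",
                                    "f", "p", "partial_eta_sq")),
        row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rm_anova_2x2 <- function(x, ...) x$effects

#' @exportS3Method generics::glance
glance.rm_anova_2x2 <- function(x, ...) {
  tibble(n_subjects = x$n, n_effects = nrow(x$effects))
}

#' Between-subject confidence intervals per condition
#'
#' Classic t-based per-condition interval: `mean +/- t * sd / sqrt(n)`
#' with `t` the two-sided `level` quantile at `n - 1` degrees of freedom
#' (the error bars of a condition-means bar plot).
#'
#' @param data Long tibble with one row per subject x condition.
#' @param value Column holding the response.
#' @param condition Column identifying the condition.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `condition`, `n`, `mean`, `half_width`, `lower`,
#'   `upper`.
#' @export
between_subject_ci <- function(data, value, condition, level = 0.95) {
  if (level < 0 || level >= 1) abort("`level` must lie in [0, 1).")
  value <- rlang::enquo(value)
  condition <- rlang::enquo(condition)
  out <- as_tibble(data) |>
    dplyr::group_by(condition = !!condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(!!value),
      sd = sd(!!value),
      .groups = "drop"
    )
  if (any(out$n < 2)) abort("Need at least 2 subjects per condition.")
  out |>
    dplyr::mutate(
      half_width = qt(1 - (1 - level) / 2, .data$n - 1) * .data$sd / sqrt(.data$n),
      lower = .data$mean - .data$half_width,
      upper = .data$mean + .data$half_width
    ) |>
    dplyr::select("condition", "n", "mean", "half_width", "lower", "upper")
}

#' JZS Bayes factor for a paired contrast
#'
#' Default Bayes factor for a one-sample (paired-difference) t test with a
#' zero-centred Cauchy prior of width `cauchy_scale` on the standardised
#' effect size (the Jeffreys-Zellner-Siow prior). Computed via the
#' equivalent scale-mixture form: the Cauchy prior on delta is an
#' inverse-gamma(1/2, scale^2/2) mixture of normals on the g parameter,
#' giving a one-dimensional integral evaluated by adaptive quadrature to a
#' relative tolerance of 1e-8. This is an approximation to, not a
#' reproduction of, model-averaged Bayesian RM-ANOVA factors.
#'
#' @param differences Per-subject paired differences.
#' @param cauchy_scale Prior width (default 0.5).
#' @return An object of class `jzs_bf` with `bf10`, `bf01`, `t`, `n`,
#'   `cauchy_scale`.
#' @examples
#' jzs_paired_bf(c(0.1, 0.12, 0.05, 0.2, 0.08, 0.15, 0.02, 0.1, 0.09))
#' @export
jzs_paired_bf <- function(differences, cauchy_scale = 0.5) {
  n <- length(differences)
  if (n < 2) abort("Need at least 2 paired differences.")
  if (cauchy_scale <= 0) abort("`cauchy_scale` must be > 0.")
  s <- sd(differences)
  if (s == 0) abort("Zero-variance differences: the t statistic is undefined.")
  t_stat <- mean(differences) / (s / sqrt(n))
  bf10 <- jzs_bf_from_t(t_stat, n, cauchy_scale)
  structure(
    list(bf10 = bf10, bf01 = 1 / bf10, t = t_stat, n = n,
         cauchy_scale = cauchy_scale),
    class = "jzs_bf"
  )
}

# Rouder et al. (2009) one-sample JZS Bayes factor via the g integral.
# Substituting g = r^2 q makes the mixing density a parameter-free
# inverse-gamma(1/2, 1/2), which keeps the quadrature stable for any r.
jzs_bf_from_t <- function(t_stat, n, r) {
  nu <- n - 1
  marg_alt <- integrate(
    function(q) {
      ng <- 1 + n * r^2 * q
      ng^(-0.5) *
        (1 + t_stat^2 / (ng * nu))^(-(nu + 1) / 2) *
        q^(-1.5) * exp(-1 / (2 * q)) / sqrt(2 * pi)
    },
    lower = 0, upper = Inf, rel.tol = 1e-8
  )$value
  marg_null <- (1 + t_stat^2 / nu)^(-(nu + 1) / 2)
  marg_alt / marg_null
}

#' @export
print.jzs_bf <- function(x, ...) {
  cat("JZS paired Bayes factor (Cauchy width", x$cauchy_scale, ")\n")
  cat("  t =", signif(x$t, 4), " n =", x$n, "\n")
  cat("  BF10 =", signif(x$bf10, 5), "  BF01 =", signif(x$bf01, 5), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.jzs_bf <- function(x, ...) {
  tibble(bf10 = x$bf10, bf01 = x$bf01, t = x$t, n = x$n,
         cauchy_scale = x$cauchy_scale)
}

#' The study's three planned 2x2 comparisons
#'
#' Runs the three planned repeated-measures ANOVAs on a threshold table —
#' World vs Retina, World vs World Control, Retina vs Retina Control, each
#' crossed with Fast vs Slow — plus a JZS Bayes factor for each pairwise
#' family contrast (collapsed over speed).
#'
#' @param thresholds Tibble with `participant`, `family`, `speed_class`,
#'   `threshold_75` (8 rows per participant).
#' @param cauchy_scale Prior width for the Bayes factors.
#' @return A named list of three elements (`world_vs_retina`,
#'   `world_vs_control`, `retina_vs_control`), each containing the
#'   `rm_anova_2x2` object and the `jzs_bf` for the family contrast.
#' @export
planned_comparisons <- function(thresholds, cauchy_scale = 0.5) {
  pairs <- list(
    world_vs_retina = c("World", "Retina"),
    world_vs_control = c("World", "WorldControl"),
    retina_vs_control = c("Retina", "RetinaControl")
  )
  purrr::map(pairs, function(fams) {
    sub <- dplyr::filter(thresholds, .data$family %in% fams)
    aov2 <- rm_anova_2x2(sub, threshold_75, participant, family, speed_class)
    diffs <- sub |>
      dplyr::group_by(.data$participant, .data$family) |>
      dplyr::summarise(m = mean(.data$threshold_75), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "family", values_from = "m")
    d <- diffs[[fams[1]]] - diffs[[fams[2]]]
    list(anova = aov2, bf = jzs_paired_bf(d, cauchy_scale))
  })
}
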