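#' Per-subject neurofeedback success test
#'
#' One-sided two-sample Welch t-test of the neurofeedback-period cEFP values
#' against the baseline values; a subject is successful when
#' `p(NF < BL) < alpha`. The cEFP series is autocorrelated at the 3-s packet
#' scale, so the nominal sample size overstates the effective one; no
#' correction is applied (none is standard for this design) and the caveat is
#' documented.
#'
#' @param rec Tibble for one subject with columns `value` and `period`
#'   (`"BL"` or `"NF1"`..`"NF4"`; anything starting with `"NF"` counts as NF).
#' @param alpha Significance threshold.
#' @return One-row tibble: `t`, `p`, `success`, `mean_bl`, `mean_nf`.
#' @export
subject_success <- function(rec, alpha = 0.05) {
  bl <- rec$value[rec$period == "BL"]
  nf <- rec$value[startsWith(rec$period, "NF")]
  if (length(bl) < 2L || length(nf) < 2L) {
    abort("need >= 2 values per condition.")
  }
  if (sd(bl) == 0 && sd(nf) == 0) abort("degenerate variance in both conditions.")
  tt <- stats::t.test(nf, bl, alternative = "less")
  tibble(t = unname(tt$statistic), p = tt$p.value,
         success = tt$p.value < alpha,
         mean_bl = mean(bl), mean_nf = mean(nf))
}

#' Success table for a whole neurofeedback study
#'
#' @param records Long tibble with columns `subject_id`, `group`, `period`,
#'   `value`.
#' @param alpha Per-subject significance threshold.
#' @return Tibble with one row per subject (group, t, p, success, means).
#' @export
nf_success_table <- function(records, alpha = 0.05) {
  records |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::group_modify(~ subject_success(.x, alpha)) |>
    dplyr::ungroup()
}

#' 2x2 mixed-design ANOVA on per-subject condition means
#'
#' Between-subject factor group (test vs sham), within-subject factor
#' condition (BL vs NF), computed from sums of squares on the per-subject
#' (BL mean, NF mean) pairs; the interaction has df `(1, n_subjects - 2)`.
#' Planned simple-effects F tests of condition within each group use the
#' pooled within-subject error.
#'
#' @param records Long tibble with `subject_id`, `group` (two levels),
#'   `period`, `value`.
#' @return List of class `nf_anova`: `table` (tibble: effect, df1, df2, F,
#'   p), `simple_effects` (condition within each group) and `cell_means`.
#' @export
mixed_anova_2x2 <- function(records) {
  cm <- records |>
    dplyr::mutate(condition = ifelse(.data$period == "BL", "BL", "NF")) |>
    dplyr::group_by(.data$subject_id, .data$group, .data$condition) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  wide <- tidyr::pivot_wider(cm, names_from = "condition", values_from = "value")
  groups <- unique(wide$group)
  if (length(groups) != 2L) abort("exactly two groups required.")
  ng <- table(wide$group)
  if (any(ng < 2L)) abort("each group needs >= 2 subjects.")
  n <- nrow(wide)
  # Per-subject sum (between-subject part) and difference (within part).
  subj_mean <- (wide$BL + wide$NF) / 2
  diff <- wide$NF - wide$BL
  g <- factor(wide$group, levels = groups)
  grand <- mean(subj_mean)
  gmeans <- tapply(subj_mean, g, mean)
  # Between-subject stratum (on subject means; each mean carries 2 scores).
  ss_group <- 2 * sum(ng * (gmeans - grand)^2)
  ss_subj <- 2 * sum((subj_mean - gmeans[g])^2)
  df_subj <- n - 2L
  # Within-subject stratum (on condition differences).
  dmeans <- tapply(diff, g, mean)
  dgrand <- sum(ng * dmeans) / n
  ss_cond <- n * dgrand^2 / 2
  ss_inter <- sum(ng * dmeans^2) / 2 - ss_cond
  ss_err_w <- sum((diff - dmeans[g])^2) / 2
  ms_err_w <- ss_err_w / df_subj
  fratio <- function(ss_eff, ms_err) {
    if (ss_eff < 1e-300) 0 else ss_eff / ms_err  # zero effect: F = 0 even with zero error
  }
  tab <- tibble(
    effect = c("group", "condition", "group:condition"),
    df1 = 1L, df2 = df_subj,
    F = c(fratio(ss_group, ss_subj / df_subj), fratio(ss_cond, ms_err_w),
          fratio(ss_inter, ms_err_w)))
  tab$p <- stats::pf(tab$F, tab$df1, tab$df2, lower.tail = FALSE)
  se <- purrr::map_dfr(groups, function(gr) {
    d <- dmeans[[gr]]
    ngr <- sum(g == gr)
    Fv <- ngr * d^2 / (2 * ms_err_w)
    tibble(group = gr, mean_change = d, df1 = 1L, df2 = df_subj, F = Fv,
           p = stats::pf(Fv, 1, df_subj, lower.tail = FALSE))
  })
  structure(list(table = tab, simple_effects = se,
                 cell_means = cm, n_subjects = n),
            class = "nf_anova")
}

#' @export
print.nf_anova <- function(x, ...) {
  cat(sprintf("<nf_anova> 2x2 mixed design, %d subjects\n", x$n_subjects))
  print(x$table)
  invisible(x)
}

#' @param x An `nf_anova`.
#' @param ... Unused.
#' @return The ANOVA table tibble.
#' @rdname mixed_anova_2x2
#' @method tidy nf_anova
#' @export
tidy.nf_anova <- function(x, ...) x$table

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities, with margins fixed, of every table at
#' most as probable as the observed one.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d).
#' @return Two-sided p value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("counts must be non-negative integers.")
  }
  if (sum(cells) == 0) abort("all-zero table.")
  r1 <- a + b
  k <- a + c          # first-column margin
  n <- sum(cells)
  lo <- max(0L, k - (n - r1))
  hi <- min(r1, k)
  probs <- stats::dhyper(lo:hi, r1, n - r1, k)
  p_obs <- stats::dhyper(a, r1, n - r1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Simulate a neurofeedback study with planted down-regulation
#'
#' Generates one baseline and four neurofeedback periods per subject (3-s
#' samples). Test-group subjects receive a planted negative shift of the NF
#' mean; sham subjects none. Defaults reflect a down-regulation study on a
#' normalized cEFP signal: group-level effect -0.85, moderate between-subject
#' heterogeneity, 7-minute periods.
#'
#' @param n_test,n_sham Group sizes.
#' @param effect_mean Planted mean NF-vs-BL shift for test subjects.
#' @param effect_sd Between-subject sd of the planted shift.
#' @param baseline_mean,baseline_sd Between-subject baseline level.
#' @param within_sd Within-period sample noise sd.
#' @param samples_per_period 3-s samples per 7-minute period.
#' @param n_nf_periods Number of NF periods.
#' @param seed RNG seed.
#' @return Long tibble: `subject_id`, `group`, `period`, `value`.
#' @export
simulate_nf_study <- function(n_test = 7L, n_sham = 6L, effect_mean = -0.85,
                              effect_sd = 0.3, baseline_mean = 0.01,
                              baseline_sd = 0.06, within_sd = 0.5,
                              samples_per_period = 140L, n_nf_periods = 4L,
                              seed = 1L) {
  with_seed(seed, {
    subs <- tibble(
      subject_id = sprintf("nf%02d", seq_len(n_test + n_sham)),
      group = rep(c("test", "sham"), c(n_test, n_sham)),
      bl_level = rnorm(n_test + n_sham, baseline_mean, baseline_sd),
      effect = c(rnorm(n_test, effect_mean, effect_sd), rep(0, n_sham)))
    periods <- c("BL", paste0("NF", seq_len(n_nf_periods)))
    purrr::pmap_dfr(subs, function(subject_id, group, bl_level, effect) {
      purrr::map_dfr(periods, function(p) {
        mu <- bl_level + if (p == "BL") 0 else effect
        tibble(subject_id = subject_id, group = group, period = p,
               value = rnorm(samples_per_period, mu, within_sd))
      })
    })
  })
}
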