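test_that("per-subject success is the one-sided Welch comparison", {
  vals <- rnorm(280)
  rec <- tibble::tibble(value = rep(vals[1:140], 2),
                        period = rep(c("BL", "NF1"), each = 140))
  same <- subject_success(rec)
  expect_false(same$success)
  expect_equal(same$mean_nf - same$mean_bl, 0)
  # planted shift at the study's reported magnitude is detected
  set.seed(1)
  rec2 <- tibble::tibble(
    value = c(rnorm(140, 0, 0.1), rnorm(140, -0.8, 0.1)),
    period = rep(c("BL", "NF1"), each = 140))
  hit <- subject_success(rec2)
  expect_true(hit$success)
  expect_lt(hit$p, 1e-6)
  # alpha = 0 never succeeds
  expect_false(subject_success(rec2, alpha = 0)$success)
  expect_error(subject_success(tibble::tibble(value = 1, period = "BL")), ">= 2")
})

test_that("the mixed ANOVA matches aov on balanced data and is invariant", {
  recs <- simulate_nf_study(n_test = 6, n_sham = 6, seed = 2)
  a <- mixed_anova_2x2(recs)
  expect_equal(a$table$df2, rep(10L, 3))
  cm <- a$cell_means
  cm$subject_id <- factor(cm$subject_id)
  fit <- summary(stats::aov(value ~ group * condition +
                              Error(subject_id / condition), data = cm))
  f_aov <- c(fit[["Error: subject_id"]][[1]]["group", "F value"],
             fit[["Error: subject_id:condition"]][[1]]["condition", "F value"],
             fit[["Error: subject_id:condition"]][[1]]["group:condition", "F value"])
  expect_equal(a$table$F, unname(f_aov), tolerance = 1e-8)
  # all-equal means give F = 0
  flat <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:6),
                             period = c("BL", "NF1")) |>
    dplyr::mutate(group = ifelse(subject_id %in% sprintf("s%d", 1:3),
                                 "test", "sham"),
                  value = 1)
  flat <- dplyr::bind_rows(flat, flat)  # two values per cell
  a0 <- mixed_anova_2x2(flat)
  expect_equal(a0$table$F, rep(0, 3))
  # 13 subjects (7 + 6): interaction df = (1, 11); unbalanced interaction
  # term still matches aov exactly
  recs13 <- simulate_nf_study(n_test = 7, n_sham = 6, seed = 3)
  a13 <- mixed_anova_2x2(recs13)
  expect_equal(a13$table$df1[3], 1L)
  expect_equal(a13$table$df2[3], 11L)
  cm13 <- a13$cell_means
  cm13$subject_id <- factor(cm13$subject_id)
  fit13 <- summary(stats::aov(value ~ group * condition +
                                Error(subject_id / condition), data = cm13))
  expect_equal(a13$table$F[3],
               fit13[["Error: subject_id:condition"]][[1]]["group:condition", "F value"],
               ignore_attr = TRUE, tolerance = 1e-8)
  # invariant to subject order and to adding a constant
  perm <- recs13[sample(nrow(recs13)), ]
  ap <- mixed_anova_2x2(perm)
  expect_equal(ap$table$F, a13$table$F, tolerance = 1e-10)
  shifted <- dplyr::mutate(recs13, value = value + 5)
  expect_equal(mixed_anova_2x2(shifted)$table$F, a13$table$F, tolerance = 1e-8)
  expect_error(mixed_anova_2x2(dplyr::filter(recs13, subject_id != "nf08",
                                             subject_id != "nf09",
                                             subject_id != "nf10",
                                             subject_id != "nf11",
                                             subject_id != "nf12")),
               ">= 2 subjects")
})

test_that("fisher enumeration equals the reference test on all small tables", {
  for (a in 0:6) for (b in 0:4) for (c in 0:4) for (d in 0:6) {
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    mine <- fisher_exact_2x2(a, b, c, d)
    ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
  # the study's printed success table, by full enumeration
  expect_equal(fisher_exact_2x2(6, 1, 1, 5), 50 / 1716, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("a planted down-regulation study is detected in most replicates", {
  ok <- vapply(1:50, function(s) {
    recs <- simulate_nf_study(seed = s)
    succ <- nf_success_table(recs)
    counts <- succ |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(yes = sum(success), no = sum(!success))
    tt <- counts[counts$group == "test", ]
    sh <- counts[counts$group == "sham", ]
    fisher_p <- fisher_exact_2x2(tt$yes, tt$no, sh$yes, sh$no)
    inter_p <- mixed_anova_2x2(recs)$table$p[3]
    fisher_p < 0.05 && inter_p < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
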