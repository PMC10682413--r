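test_that("basal levels are the mean of the four baseline samples", {
  toy <- toy_dialysate(2)
  b <- compute_basal(toy)
  expect_true(all(b$basal_nM == 2))
  # (1, 2, 3, 4) -> 2.5
  toy2 <- toy_dialysate(1)
  toy2$conc_nM[toy2$neurotransmitter == "DA" & toy2$sample_index <= 4] <- 1:4
  b2 <- compute_basal(toy2)
  expect_equal(b2$basal_nM[b2$neurotransmitter == "DA"], 2.5)
  # missing baseline sample is an error
  expect_error(compute_basal(dplyr::filter(toy, sample_index != 2)),
               "baseline")
  # generator round-trip: noiseless control basal equals configured basal
  d <- noiseless_cohort()
  b3 <- compute_basal(d)
  da <- b3$basal_nM[b3$group == "control" & b3$neurotransmitter == "DA"]
  expect_true(all(da == 0.8))
})

test_that("cumulative levels sum the four block samples", {
  toy <- toy_dialysate(1)
  cum <- cumulative_levels(toy)
  expect_true(all(cum$cumulative_nM == 4))
  expect_equal(nrow(cum), 5 * 4)   # 1 subject x 5 NTs x 4 K+
  toy0 <- toy
  toy0$conc_nM[toy0$k_mM == 30] <- 0
  expect_true(all(cumulative_levels(toy0)$cumulative_nM[
    cumulative_levels(toy0)$k_mM == 30] == 0))
  # mean variant
  expect_true(all(cumulative_levels(toy, stat = "mean")$cumulative_nM == 1))
  expect_error(cumulative_levels(dplyr::filter(toy, k_mM != 60)), "block")
  # independent summation oracle on the noiseless generated cohort
  d <- noiseless_cohort() |> dplyr::filter(subject == "control_01")
  cum_d <- cumulative_levels(d)
  oracle <- tapply(d$conc_nM, list(d$neurotransmitter, d$k_mM), sum)
  for (i in seq_len(nrow(cum_d))) {
    expect_equal(cum_d$cumulative_nM[i],
                 oracle[cum_d$neurotransmitter[i], as.character(cum_d$k_mM[i])])
  }
})

test_that("percent-basal series keep 13 points and divide element-wise", {
  toy <- toy_dialysate(1)
  toy$conc_nM <- rep(seq(0.5, 8, by = 0.5), 5)   # 16 distinct values per NT
  pct <- percent_basal_series(toy)
  per <- pct |> dplyr::count(subject, neurotransmitter)
  expect_true(all(per$n == 13))
  da <- pct |> dplyr::filter(neurotransmitter == "DA")
  basal <- mean(seq(0.5, 2, by = 0.5))
  expect_equal(da$pct_basal, 100 * seq(2, 8, by = 0.5) / basal)
  # sample equal to basal -> 100%; 3.94x basal -> 394%
  expect_equal(100 * basal / basal, 100)
  expect_equal(100 * (3.94 * basal) / basal, 394)
  # zero basal excluded with diagnostic
  toy0 <- toy_dialysate(1)
  toy0$conc_nM[toy0$neurotransmitter == "GABA" & toy0$sample_index <= 4] <- 0
  pct0 <- percent_basal_series(toy0)
  expect_false("GABA" %in% pct0$neurotransmitter)
  expect_equal(attr(pct0, "excluded")$neurotransmitter, "GABA")
})

test_that("group comparisons match the textbook pooled t formula", {
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  lv <- tibble::tibble(
    subject = sprintf("s%d", 1:6),
    group = rep(c("control", "acute"), each = 3),
    neurotransmitter = "DA", k_mM = 4,
    cumulative_nM = c(x, y))
  cc <- compare_cumulative(lv)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(cc$t, t_hand, tolerance = 1e-10)
  expect_equal(cc$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)
  expect_equal(cc$fold_change, mean(y) / mean(x))
  # identical groups -> t = 0, p = 1
  lv0 <- lv; lv0$cumulative_nM <- 3
  cc0 <- compare_cumulative(lv0)
  expect_equal(cc0$t, 0)
  expect_equal(cc0$p, 1)
})

test_that("noiseless defaults reproduce all printed fold changes exactly", {
  cc <- compare_cumulative(cumulative_levels(noiseless_cohort()))
  fold <- function(nt, k, a, b) {
    cc$fold_change[cc$neurotransmitter == nt & cc$k_mM == k &
                     cc$group_a == a & cc$group_b == b]
  }
  expect_equal(fold("DA", 4, "control", "acute"), 2.71, tolerance = 1e-9)
  expect_equal(fold("DA", 4, "control", "chronic"), 2.14, tolerance = 1e-9)
  expect_equal(fold("5HT", 4, "control", "acute"), 1.75, tolerance = 1e-9)
  expect_equal(fold("5HT", 4, "control", "chronic"), 1.96, tolerance = 1e-9)
  expect_equal(fold("NE", 4, "control", "chronic"), 1.60, tolerance = 1e-9)
  expect_equal(fold("DA", 120, "control", "chronic"), 1.69, tolerance = 1e-9)
})

test_that("percent-basal is scale-invariant and cumulative scales linearly", {
  d <- noiseless_cohort() |> dplyr::filter(subject == "control_01")
  d2 <- d |> dplyr::mutate(conc_nM = conc_nM * 3.7)
  expect_equal(percent_basal_series(d2)$pct_basal,
               percent_basal_series(d)$pct_basal)
  expect_equal(cumulative_levels(d2)$cumulative_nM,
               3.7 * cumulative_levels(d)$cumulative_nM)
})

test_that("cumulative record count is subjects x 5 NTs x 4 K+ levels", {
  cum <- cumulative_levels(noiseless_cohort())
  expect_equal(nrow(cum), 28 * 5 * 4)
})

test_that("time-course ANOVA has the reported df shape and a hand-checkable core", {
  pct <- percent_basal_series(noiseless_cohort())
  # make the response non-degenerate for the F computation
  d <- generate_dialysate(sim_cohort_config(seed = 3))
  tc <- timecourse_anova(percent_basal_series(d))
  a <- tc$DA$anova
  expect_equal(a$df1[a$effect == "group"], 2)
  expect_equal(unique(a$df2), 325)
  expect_equal(a$df1[a$effect == "interaction"], 24)
  # constant series -> zero-variance flag
  toy <- toy_dialysate(1)
  toy2 <- toy_dialysate(1, subject = "acute_01", group = "acute")
  tc0 <- timecourse_anova(percent_basal_series(dplyr::bind_rows(toy, toy2)))
  expect_true(all(tc0$DA$anova$statistic == 0))
  # ragged series rejected
  pct_r <- percent_basal_series(d)
  expect_error(timecourse_anova(pct_r[-1, ]), "ragged")
  # toy 2 groups x 3 times with 2 subjects against the textbook oracle
  set.seed(6)
  toy3 <- tidyr::expand_grid(group = c("a", "b"), subject_i = 1:2,
                             time_min = c(0, 20, 40)) |>
    dplyr::mutate(subject = paste0(group, subject_i),
                  neurotransmitter = "DA",
                  pct_basal = rnorm(dplyr::n(), 100, 20))
  h <- hand_two_way(toy3$pct_basal, toy3$group, toy3$time_min)
  a3 <- timecourse_anova(toy3)$DA$anova
  expect_equal(a3$statistic[a3$effect == "group"], h$F_a, tolerance = 1e-10)
  expect_equal(a3$statistic[a3$effect == "time_min"], h$F_b, tolerance = 1e-10)
  expect_equal(a3$statistic[a3$effect == "interaction"], h$F_ab,
               tolerance = 1e-10)
})
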