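make_levels <- function(values, group = "control", k = 4) {
  # values: named list nt -> vector over subjects
  n <- length(values[[1]])
  tidyr::expand_grid(subject = sprintf("s%02d", 1:n),
                     neurotransmitter = names(values)) |>
    dplyr::mutate(group = group, k_mM = k,
                  cumulative_nM = vapply(seq_len(dplyr::n()), function(i) {
                    values[[neurotransmitter[i]]][match(subject[i],
                                                        sprintf("s%02d", 1:n))]
                  }, numeric(1)))
}

test_that("pairwise correlations match closed forms and flag degeneracy", {
  base <- c(1, 3, 2, 5, 4)
  vals <- list(DA = base, `5HT` = 2 * base, NE = -base + 10,
               Glu = c(2, 1, 4, 3, 6), GABA = rep(1, 5))
  pc <- pairwise_correlations(make_levels(vals))
  expect_equal(nrow(pc), 10)
  pick <- function(a, b) pc[pc$nt_a %in% c(a, b) & pc$nt_b %in% c(a, b), ]
  # proportional pair -> r = 1; antithetic pair -> r = -1
  expect_equal(pick("DA", "5HT")$r, 1, tolerance = 1e-12)
  expect_equal(pick("DA", "NE")$r, -1, tolerance = 1e-12)
  # hand-computed r and exact t-transform p for an arbitrary pair
  x <- vals$DA; y <- vals$Glu; n <- 5
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), n - 2)
  got <- pick("DA", "Glu")
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
  # constant series -> degenerate flag, excluded from networks
  expect_true(all(pc$degenerate[pc$nt_a == "GABA" | pc$nt_b == "GABA"]))
  net <- build_network(pc)
  expect_false(any(net$edges$nt_a == "GABA" | net$edges$nt_b == "GABA"))
})

test_that("the edge rule requires both r >= 0.5 and p < 0.05", {
  pairs <- tibble::tibble(
    group = "control", k_mM = 4,
    nt_a = c("DA", "DA", "DA"), nt_b = c("5HT", "NE", "Glu"),
    r = c(0.49, 0.9, 0.8), p = c(0.001, 0.2, 0.01),
    n = 10, degenerate = FALSE)
  net <- build_network(pairs)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$nt_a, "DA")
  expect_equal(net$edges$nt_b, "Glu")
  # raising the threshold never adds edges
  for (rt in c(0.6, 0.7, 0.9)) {
    expect_lte(nrow(build_network(pairs, r_min = rt)$edges),
               nrow(build_network(pairs, r_min = rt - 0.1)$edges))
  }
})

test_that("a designed Glu-GABA coupling yields exactly that edge in the 4 mM control network", {
  # n = 30 subjects keeps the family-wise false-edge budget of the 9 null
  # pairs near 2% so "exactly one edge" is achievable at the stated rate
  hits <- vapply(1:40, function(s) {
    d <- glu_gaba_cohort(seed = 1000 + s, n = 30)
    cum <- cumulative_levels(d) |>
      dplyr::filter(group == "control", k_mM == 4)
    net <- build_network(pairwise_correlations(cum))
    found <- any((net$edges$nt_a == "Glu" & net$edges$nt_b == "GABA") |
                   (net$edges$nt_a == "GABA" & net$edges$nt_b == "Glu"))
    found && nrow(net$edges) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("correlation-distribution ANOVA has (2, 27) df and a hand-checkable core", {
  set.seed(12)
  pairs <- tidyr::expand_grid(group = c("control", "acute", "chronic"),
                              pair = 1:10) |>
    dplyr::mutate(k_mM = 30, nt_a = "DA", nt_b = "NE",
                  r = runif(dplyr::n(), -0.5, 0.9),
                  p = 0.5, n = 10, degenerate = FALSE)
  res <- compare_correlation_distributions(pairs)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 27)
  # identical r distributions -> F = 0
  p0 <- pairs |> dplyr::mutate(r = 0.3)
  expect_equal(compare_correlation_distributions(p0)$anova$statistic, 0)
  # one-way toy vs hand computation: 2 groups x 3 values
  toy <- tibble::tibble(group = rep(c("a", "b"), each = 3), k_mM = 4,
                        nt_a = "DA", nt_b = "NE",
                        r = c(0.1, 0.2, 0.3, 0.5, 0.7, 0.6),
                        p = 0.5, n = 10, degenerate = FALSE)
  res2 <- compare_correlation_distributions(toy)
  gm <- mean(toy$r)
  ss_b <- 3 * sum((tapply(toy$r, toy$group, mean) - gm)^2)
  ss_w <- sum((toy$r - rep(tapply(toy$r, toy$group, mean), each = 3))^2)
  F_hand <- (ss_b / 1) / (ss_w / 4)
  expect_equal(res2$anova$statistic, F_hand, tolerance = 1e-10)
})

test_that("networks are symmetric under pair relabeling and capped at 10 edges", {
  d <- glu_gaba_cohort(seed = 77, n = 10)
  cum <- cumulative_levels(d) |> dplyr::filter(group == "control", k_mM == 4)
  pc <- pairwise_correlations(cum)
  flipped <- pc |> dplyr::rename(nt_a = nt_b, nt_b = nt_a)
  expect_lte(nrow(build_network(pc)$edges), 10)
  expect_equal(nrow(build_network(pc)$edges), nrow(build_network(flipped)$edges))
})

test_that("null edge counts match the analytic family-wise expectation", {
  # with n = 10 subjects, r >= 0.5 & p < 0.05 reduces to r >= r_crit where
  # t_crit = qt(0.975, 8); expected edges per network = 10 * P(r >= r_crit)
  n <- 10
  t_crit <- qt(0.975, n - 2)
  r_crit <- t_crit / sqrt(n - 2 + t_crit^2)
  q_null <- pt(t_crit, n - 2, lower.tail = FALSE)
  expect_gt(r_crit, 0.5)   # the p-rule dominates at this n
  zero <- lapply(designed_coupling("glu_gaba"), function(m) m * 0)
  counts <- vapply(1:1000, function(s) {
    d <- generate_dialysate(
      sim_cohort_config(n_control = n, n_acute = 2, n_chronic = 2,
                        seed = 90000 + s, noise_cv = 0.3, subject_sd = 0),
      profiles = flat_profiles(1), coupling = zero)
    lv <- cumulative_levels(d) |> dplyr::filter(group == "control", k_mM == 4)
    nrow(build_network(pairwise_correlations(lv))$edges)
  }, numeric(1))
  expected <- 10 * q_null
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.02)
})
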