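#' Pairwise Pearson correlations of cumulative levels
#'
#' Pearson product-moment correlation, with a two-tailed p-value from the
#' exact t transform on n - 2 degrees of freedom, for each of the 10
#' neurotransmitter pairs, computed across subjects from per-subject
#' cumulative levels of one group at one K+ level. Pairs with zero variance
#' in either variable have undefined r and are flagged.
#'
#' @param levels [cumulative_levels()] rows for exactly one group x K+.
#' @return Tibble (`group`, `k_mM`, `nt_a`, `nt_b`, `r`, `p`, `n`,
#'   `degenerate`).
#' @export
pairwise_correlations <- function(levels) {
  stopifnot(length(unique(levels$group)) == 1,
            length(unique(levels$k_mM)) == 1)
  wide <- levels %>%
    select("subject", "neurotransmitter", "cumulative_nM") %>%
    pivot_wider(names_from = "neurotransmitter", values_from = "cumulative_nM")
  nts <- intersect(NT_LEVELS, names(wide))
  if (nrow(wide) < 3) stop("need at least 3 subjects")
  prs <- utils::combn(nts, 2, simplify = FALSE)
  bind_rows(lapply(prs, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(group = levels$group[1], k_mM = levels$k_mM[1],
                    nt_a = pr[1], nt_b = pr[2], r = NA_real_, p = NA_real_,
                    n = length(x), degenerate = TRUE))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(group = levels$group[1], k_mM = levels$k_mM[1],
           nt_a = pr[1], nt_b = pr[2],
           r = unname(ct$estimate), p = ct$p.value, n = length(x),
           degenerate = FALSE)
  }))
}

#' Threshold a correlation network
#'
#' Retains an undirected edge for every pair with signed `r >= r_min` and
#' `p < p_alpha` (both conditions jointly); edge weight is `r`. Degenerate
#' pairs never form edges.
#'
#' @param pairs Tibble from [pairwise_correlations()].
#' @param r_min Correlation threshold (applied to signed r).
#' @param p_alpha Significance threshold.
#' @return A `corr_network` list: `nodes`, `edges` tibble, `group`, `k_mM`,
#'   and the thresholds.
#' @export
build_network <- function(pairs, r_min = 0.5, p_alpha = 0.05) {
  edges <- pairs %>%
    filter(!.data$degenerate, .data$r >= r_min, .data$p < p_alpha) %>%
    select("nt_a", "nt_b", weight = "r", "p")
  structure(list(nodes = NT_LEVELS,
                 edges = edges,
                 group = pairs$group[1], k_mM = pairs$k_mM[1],
                 r_min = r_min, p_alpha = p_alpha),
            class = "corr_network")
}

#' Correlation networks for every group x K+ level
#'
#' @param levels Tibble from [cumulative_levels()] (all groups, all K+).
#' @param r_min,p_alpha Edge thresholds, as in [build_network()].
#' @return List with `pairs` (all correlations) and `networks` (a list of
#'   `corr_network` objects named `group_kmM`).
#' @export
correlation_networks <- function(levels, r_min = 0.5, p_alpha = 0.05) {
  combos <- levels %>% distinct(.data$group, .data$k_mM) %>%
    arrange(match(.data$group, GROUP_LEVELS), .data$k_mM)
  pairs <- bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    pairwise_correlations(levels %>%
      filter(.data$group == combos$group[i], .data$k_mM == combos$k_mM[i]))
  }))
  networks <- lapply(seq_len(nrow(combos)), function(i) {
    build_network(pairs %>%
      filter(.data$group == combos$group[i], .data$k_mM == combos$k_mM[i]),
      r_min, p_alpha)
  })
  names(networks) <- paste0(combos$group, "_", combos$k_mM)
  list(pairs = pairs, networks = networks)
}

#' Compare correlation distributions across groups
#'
#' One-way ANOVA on the 10 pairwise r values per group at one K+ level
#' (3 groups x 10 pairs gives a (2, 27) df test), followed by Tukey HSD.
#'
#' @param pairs Tibble from [pairwise_correlations()] covering all groups
#'   at a single K+ level.
#' @return List with `anova` (one-row tibble: `df1`, `df2`, `statistic`,
#'   `p`) and `tukey`.
#' @export
compare_correlation_distributions <- function(pairs) {
  stopifnot(length(unique(pairs$k_mM)) == 1)
  counts <- pairs %>% filter(!.data$degenerate) %>% count(.data$group)
  if (nrow(counts) < 2 || any(counts$n < 2)) stop("missing pairs per group")
  d <- pairs %>% filter(!.data$degenerate)
  if (all(d$r == d$r[1])) {
    return(list(anova = tibble(df1 = nrow(counts) - 1,
                               df2 = nrow(d) - nrow(counts),
                               statistic = 0, p = NA_real_),
                tukey = tibble()))
  }
  fit <- aov(r ~ factor(group), data = d)
  tab <- summary(fit)[[1]]
  list(anova = tibble(df1 = tab[1, "Df"], df2 = tab[2, "Df"],
                      statistic = tab[1, "F value"], p = tab[1, "Pr(>F)"]),
       tukey = tukey_one_way(d$r, d$group))
}
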