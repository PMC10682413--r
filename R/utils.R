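#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Mean daily dose rate of a fractionated exposure
#'
#' Converts a total absorbed dose delivered over a number of exposure days to
#' a mean daily dose rate. The default arguments describe the chronic
#' regimen used with the 33-beam GCR simulation: 49.9 cGy over 4 weeks at
#' 6 exposure days per week (24 days), i.e. 2.08 cGy/day.
#'
#' @param total_cgy Total dose in cGy.
#' @param exposure_days Number of days on which dose was delivered.
#' @param digits Decimal places to round to (`NULL` for unrounded).
#' @return Dose rate in cGy/day.
#' @examples
#' dose_rate_cgy_per_day()          # 2.08
#' dose_rate_cgy_per_day(40, 1)     # acute: all in one day
#' @export
dose_rate_cgy_per_day <- function(total_cgy = 49.9, exposure_days = 24,
                                  digits = 2) {
  stopifnot(total_cgy > 0, exposure_days > 0)
  rate <- total_cgy / exposure_days
  if (is.null(digits)) rate else round(rate, digits)
}

#' Box-plot summary statistics
#'
#' Median, quartiles and Tukey-style whiskers: the lowest datum above
#' Q1 - 1.5 IQR and the highest datum below Q3 + 1.5 IQR. Quantiles use the
#' default (type 7) convention.
#'
#' @param x Numeric vector.
#' @return A one-row tibble with `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n`.
#' @export
box_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("box_stats(): no finite values")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  tibble(median = q[2], q1 = q[1], q3 = q[3],
         whisker_lo = lo, whisker_hi = hi, n = length(x))
}

# shared two-way fixed-effects ANOVA helper: value ~ A * B, subjects as
# replicates. Returns one row per term with df pairs against the residual.
anova_two_way <- function(data, value, a, b) {
  d <- data.frame(
    y = data[[value]],
    A = factor(data[[a]]),
    B = factor(data[[b]])
  )
  counts <- table(d$A, d$B)
  balanced <- length(unique(as.vector(counts))) == 1
  zero_var <- isTRUE(all(d$y == d$y[1]))
  fit <- aov(y ~ A * B, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  res_df <- tab[terms == "Residuals", "Df"]
  if (length(res_df) == 0) res_df <- 0   # saturated design (1 rep per cell)
  fvals <- if ("F value" %in% colnames(tab)) tab[1:3, "F value"] else NA_real_
  pvals <- if ("Pr(>F)" %in% colnames(tab)) tab[1:3, "Pr(>F)"] else NA_real_
  out <- tibble(
    effect = c(a, b, "interaction"),
    df1 = tab[1:3, "Df"],
    df2 = res_df,
    statistic = fvals,
    p = pvals
  )
  if (zero_var) {
    out$statistic <- 0
    out$p <- NA_real_
  }
  attr(out, "balanced") <- balanced
  attr(out, "zero_variance") <- zero_var
  attr(out, "fit") <- fit
  # unbalanced designs are computed with sequential (Type I) sums of
  # squares and flagged via the attribute rather than interrupting runs
  out
}

# tidy TukeyHSD on a one-way layout
tukey_one_way <- function(values, groups) {
  d <- data.frame(y = values, g = factor(groups))
  if (all(d$y == d$y[1])) {
    return(tibble(contrast = character(), diff = numeric(),
                  lwr = numeric(), upr = numeric(), p_adj = numeric()))
  }
  tk <- TukeyHSD(aov(y ~ g, data = d))$g
  tibble(contrast = rownames(tk), diff = tk[, "diff"],
         lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"])
}
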