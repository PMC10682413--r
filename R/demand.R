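#' Fit the exponential model of demand
#'
#' Fits `log10 Q = log10 Q0 + k (exp(-alpha Q0 C) - 1)` to each
#' consumption-vs-price curve (one curve per subject x milk concentration)
#' by nonlinear least squares on `log10(Q + 0.1)`; the 0.1 offset makes
#' zero-consumption points representable. Free parameters are `Q0` and
#' `alpha`; `k` is either a single constant estimated jointly across all
#' curves of the dataset (`k_mode = "shared"`, the default) or a fixed
#' positive value. Each curve is fit by bounded multi-start quasi-Newton
#' minimisation (starts at `Q0 = max(Q)` and
#' `alpha` in 1e-4, 1e-3, 1e-2).
#'
#' Curves with zero consumption at every price cannot be represented by the
#' model and are reported with status `"rejected_zero_consumption"`.
#'
#' @param observations Tibble with `subject`, `group`, `milk_pct`, `price`,
#'   `consumption`.
#' @param k_mode `"shared"` or a fixed positive numeric value of `k`.
#' @return A tibble of per-curve fits (`q0`, `alpha`, `k`,
#'   `essential_value`, `r2`, `ss`, `df`, `se_q0`, `se_alpha`, `converged`,
#'   `status`, and a `cov` list-column with the unscaled parameter
#'   covariance), with attribute `k` holding the shared/fixed value.
#' @export
fit_demand <- function(observations, k_mode = "shared") {
  obs <- observations %>%
    group_by(.data$subject, .data$group, .data$milk_pct)
  keys <- group_keys(obs)
  curves <- group_split(obs)
  for (cu in curves) {
    if (length(unique(cu$price)) < 3) {
      stop("each curve needs at least 3 distinct prices")
    }
  }
  if (identical(k_mode, "shared")) {
    ssk <- function(k) {
      sum(vapply(curves, function(cu) {
        fit_demand_curve(cu$price, cu$consumption, k)$ss
      }, numeric(1)), na.rm = TRUE)
    }
    k <- optimize(ssk, c(0.25, 8), tol = 1e-4)$minimum
  } else {
    stopifnot(is.numeric(k_mode), k_mode > 0)
    k <- k_mode
  }
  fits <- lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    f <- fit_demand_curve(cu$price, cu$consumption, k)
    bind_cols(keys[i, ],
           tibble(q0 = f$q0, alpha = f$alpha, k = k,
           essential_value = f$essential_value,
           r2 = f$r2, ss = f$ss, df = f$df,
           se_q0 = f$se[1], se_alpha = f$se[2],
           cov = list(f$cov),
           converged = f$converged, status = f$status))
  })
  out <- bind_rows(fits)
  attr(out, "k") <- k
  out
}

# single-curve fit at fixed k. The observed log consumption is
# log10(Q + 0.1); the prediction gets the same offset so that exact model
# data fit with zero residual while zero consumption stays representable.
# Starting values come from a profile search: for fixed decay b = alpha*Q0
# the un-offset model is linear in log10 Q0, giving a closed-form profile
# that locates the basin; a quasi-Newton polish on (log Q0, log alpha)
# finishes the fit.
fit_demand_curve <- function(C, Q, k) {
  y <- log10(Q + 0.1)
  if (all(Q == 0)) {
    return(list(q0 = NA_real_, alpha = NA_real_, essential_value = NA_real_,
                r2 = NA_real_, ss = NA_real_, df = length(C) - 2,
                se = c(NA_real_, NA_real_), cov = NULL,
                converged = FALSE, status = "rejected_zero_consumption"))
  }
  obj <- function(th) {
    q0 <- exp(th[1]); al <- exp(th[2])
    pred <- 10^(log10(q0) + k * (exp(-al * q0 * C) - 1))
    sum((y - log10(pred + 0.1))^2)
  }
  # profile stage on the un-offset model: y ~ lq0 + k*(exp(-b*C) - 1)
  profile_ss <- function(lb) {
    z <- k * (exp(-exp(lb) * C) - 1)
    lq0 <- mean(y - z)
    sum((y - lq0 - z)^2)
  }
  lbs <- log(10^seq(-4, 1, by = 0.1))
  lb0 <- lbs[which.min(vapply(lbs, profile_ss, numeric(1)))]
  lb <- optimize(profile_ss, c(lb0 - 0.3, lb0 + 0.3))$minimum
  z <- k * (exp(-exp(lb) * C) - 1)
  q0_prof <- max(10^mean(y - z), 1e-6)
  starts <- list(c(log(q0_prof), lb - log(q0_prof)))
  q0_alt <- max(max(Q), 0.5)
  for (al in c(1e-3, 1e-2)) starts[[length(starts) + 1]] <- c(log(q0_alt), log(al))
  best <- NULL
  for (st in starts) {
    o <- optim(st, obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- optim(best$par, obj, method = "BFGS",
                control = list(reltol = 1e-15, maxit = 1000))
  q0 <- exp(best$par[1]); al <- exp(best$par[2])
  ss <- best$value
  n <- length(C); df <- n - 2
  ee <- exp(-al * q0 * C)
  pred <- 10^(log10(q0) + k * (ee - 1))
  w <- pred / (pred + 0.1)   # chain factor from the offset on the log scale
  J <- w * cbind(1 / (q0 * log(10)) - k * al * C * ee,
                 -k * q0 * C * ee)
  cov <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  se <- if (!is.null(cov) && df > 0) sqrt(pmax(ss / df * diag(cov), 0))
        else c(NA_real_, NA_real_)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ss / sst else NA_real_
  list(q0 = q0, alpha = al, essential_value = 1 / al,
       r2 = r2, ss = ss, df = df, se = se, cov = cov,
       converged = best$convergence == 0,
       status = if (best$convergence == 0) "ok" else "not_converged")
}

#' Normalize a demand curve by its fitted Q0
#'
#' Consumption is expressed as a percentage of Q0 and price as the response
#' requirement to produce 1% of Q0 (`price * Q0 / 100`), so curves with
#' different absolute response rates are comparable.
#'
#' @param fits Tibble from [fit_demand()].
#' @param observations The observations that were fit.
#' @return Observations with `norm_consumption` and `norm_price` columns.
#' @export
normalize_demand <- function(fits, observations) {
  ok <- fits %>% filter(.data$status == "ok")
  if (any(ok$q0 <= 0)) stop("normalization requires Q0 > 0")
  observations %>%
    inner_join(ok %>% select("subject", "milk_pct", "q0"),
               by = c("subject", "milk_pct")) %>%
    mutate(norm_consumption = 100 * .data$consumption / .data$q0,
           norm_price = .data$price * .data$q0 / 100) %>%
    select(-"q0")
}

#' Regression standard errors of demand parameters
#'
#' `SE_i = sqrt((SS / DF) * Cov_ii)` with `SS` the residual sum of squares,
#' `DF` the residual degrees of freedom and `Cov` the unscaled parameter
#' covariance (inverse Gram matrix of the Jacobian at the optimum).
#'
#' @param fits Tibble from [fit_demand()].
#' @return Long tibble (`subject`, `milk_pct`, `parameter`, `se`).
#' @export
param_se <- function(fits) {
  ok <- fits %>% filter(!is.na(.data$ss))
  if (any(ok$df <= 0)) stop("param_se() requires residual DF > 0")
  bind_rows(lapply(seq_len(nrow(ok)), function(i) {
    cov <- ok$cov[[i]]
    se <- if (is.null(cov)) c(NA_real_, NA_real_)
          else sqrt(pmax(ok$ss[i] / ok$df[i] * diag(cov), 0))
    tibble(subject = ok$subject[i], milk_pct = ok$milk_pct[i],
           parameter = c("q0", "alpha"), se = se)
  }))
}

#' Two-way ANOVA on demand parameters
#'
#' Milk concentration x treatment group fixed-effects ANOVA (subjects as
#' replicates) on a per-subject parameter table, e.g. Q0 or essential
#' value. With the default design (3 groups x 4 concentrations x 8
#' subjects) the concentration effect is tested on (3, 84) df.
#'
#' @param parameter_table Tibble with `subject`, `group`, `milk_pct` and a
#'   `value` column.
#' @param value Name of the value column.
#' @return Term table as from the shared two-way ANOVA helper, with
#'   attributes `balanced` and `zero_variance`.
#' @export
demand_anova <- function(parameter_table, value = "value") {
  anova_two_way(parameter_table, value, "milk_pct", "group")
}
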