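# Survival machinery for two-arm recurrence analysis: product-limit
# estimation, the two-group log-rank test, and a single-binary-covariate
# proportional-hazards fit with Breslow tie handling. Implemented from first
# principles; the `survival` package serves only as an independent oracle in
# the test suite.

as_surv_df <- function(records, time = "time_months", event = "event") {
  if (is.data.frame(records)) {
    data.frame(time = records[[time]], event = as.integer(records[[event]] != 0))
  } else stopf("records must be a data.frame with %s and %s", time, event)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param records data.frame with columns `time_months` and `event` (1 =
#'   event, 0 = right-censored) for one arm.
#' @return An object of class `km_curve`: `times` (distinct event times),
#'   `n_risk`, `n_event`, `survival` (product-limit estimates at the event
#'   times), `variance` (Greenwood), `n_at_risk_all` (risk set just before
#'   each time).
#' @export
km_estimator <- function(records) {
  d <- as_surv_df(records)
  if (nrow(d) < 1) stopf("need >= 1 record")
  if (any(d$time < 0)) stopf("negative times are invalid")
  et <- sort(unique(d$time[d$event == 1]))
  n_risk <- n_event <- integer(length(et))
  surv <- var_g <- numeric(length(et))
  s <- 1
  gsum <- 0
  for (i in seq_along(et)) {
    t0 <- et[i]
    n_risk[i] <- sum(d$time >= t0)
    n_event[i] <- sum(d$time == t0 & d$event == 1)
    s <- s * (1 - n_event[i] / n_risk[i])
    if (n_risk[i] > n_event[i]) {
      gsum <- gsum + n_event[i] / (n_risk[i] * (n_risk[i] - n_event[i]))
    } else gsum <- Inf
    surv[i] <- s
    var_g[i] <- if (is.finite(gsum)) s^2 * gsum else 0  # S = 0: variance 0
  }
  structure(list(times = et, n_risk = n_risk, n_event = n_event,
                 survival = surv, variance = var_g, n = nrow(d)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d event time(s)\n", x$n, length(x$times)))
  print(data.frame(time = x$times, n_risk = x$n_risk, n_event = x$n_event,
                   survival = x$survival, se = sqrt(x$variance)),
        row.names = FALSE)
  invisible(x)
}

# shared risk-set bookkeeping for the two-group statistics: per distinct
# event time, events and at-risk counts overall and in group 1
two_group_tables <- function(time, event, group) {
  et <- sort(unique(time[event == 1]))
  out <- data.frame(time = et, d = 0L, d1 = 0L, r = 0L, r1 = 0L)
  for (i in seq_along(et)) {
    t0 <- et[i]
    at <- time >= t0
    out$r[i] <- sum(at)
    out$r1[i] <- sum(at & group == 1L)
    ev <- time == t0 & event == 1
    out$d[i] <- sum(ev)
    out$d1[i] <- sum(ev & group == 1L)
  }
  out
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events over the shared risk sets; chi-square with
#' 1 df (hypergeometric variance with the standard tie correction).
#'
#' @param records_a,records_b data.frames with `time_months`, `event`.
#' @return list with `statistic`, `p_value`, `observed`, `expected` (both
#'   length 2, arms A then B).
#' @export
logrank_test <- function(records_a, records_b) {
  a <- as_surv_df(records_a); b <- as_surv_df(records_b)
  time <- c(a$time, b$time); event <- c(a$event, b$event)
  group <- rep(c(0L, 1L), c(nrow(a), nrow(b)))
  if (sum(event) < 1) stopf("no events: log-rank test undefined")
  tb <- two_group_tables(time, event, group)
  e1 <- tb$d * tb$r1 / tb$r
  v1 <- ifelse(tb$r > 1,
               tb$d * (tb$r1 / tb$r) * (1 - tb$r1 / tb$r) *
                 (tb$r - tb$d) / (tb$r - 1), 0)
  o1 <- sum(tb$d1); E1 <- sum(e1); V <- sum(v1)
  if (V <= 0) stopf("log-rank variance is zero (all events in degenerate risk sets)")
  stat <- (o1 - E1)^2 / V
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = c(sum(tb$d) - o1, o1), expected = c(sum(tb$d) - E1, E1))
}

# Breslow partial log-likelihood, score and information for a single binary
# covariate; tb as from two_group_tables with x = 1 for group B
breslow_loglik <- function(beta, tb) {
  eb <- exp(beta)
  s0 <- (tb$r - tb$r1) + tb$r1 * eb
  list(loglik = sum(tb$d1) * beta - sum(tb$d * log(s0)),
       score = sum(tb$d1) - sum(tb$d * tb$r1 * eb / s0),
       info = sum(tb$d * (tb$r - tb$r1) * tb$r1 * eb / s0^2))
}

#' Two-arm proportional-hazards estimate
#'
#' Maximizes the partial likelihood for a single binary covariate (arm B vs
#' arm A) with Breslow tie handling, by safeguarded Newton-Raphson. Reports
#' the Wald 95% CI and p-value, the log-rank p-value, and the
#' Mantel-Haenszel O/E ratio as a cross-check. When one arm has no events
#' the hazard ratio is non-estimable: the point estimate degenerates to 0 or
#' Inf and a one-sided 95% profile-likelihood bound is reported instead.
#'
#' @param records_a reference arm data.frame (`time_months`, `event`).
#' @param records_b comparison arm; the returned HR is arm B relative to A.
#' @return An object of class `hr_result`: `hazard_ratio`, `ci95`,
#'   `p_value` (Wald), `p_logrank`, `method`, `non_estimable`, `oe_ratio`.
#' @export
hazard_ratio <- function(records_a, records_b) {
  a <- as_surv_df(records_a); b <- as_surv_df(records_b)
  if (nrow(a) < 1 || nrow(b) < 1) stopf("both arms need >= 1 subject")
  time <- c(a$time, b$time); event <- c(a$event, b$event)
  group <- rep(c(0L, 1L), c(nrow(a), nrow(b)))
  if (sum(event) < 1) stopf("no events: hazard ratio undefined")
  tb <- two_group_tables(time, event, group)
  d1 <- sum(tb$d1); d0 <- sum(tb$d) - d1
  lr <- logrank_test(records_a, records_b)

  if (d0 == 0L || d1 == 0L) {
    # monotone likelihood: the partial likelihood plateaus as beta -> +Inf
    # when the reference arm has no events (HR = Inf), or -Inf when the
    # comparison arm has none (HR = 0). One-sided 95% profile bound where the
    # log-likelihood drops qchisq(0.90, 1)/2 below its supremum.
    lim <- if (d1 == 0L) -20 else 20  # beta at which the loglik plateaus
    ll_sup <- breslow_loglik(lim, tb)$loglik
    drop <- stats::qchisq(0.90, 1) / 2
    f <- function(bb) breslow_loglik(bb, tb)$loglik - (ll_sup - drop)
    bound <- tryCatch(stats::uniroot(f, sort(c(-lim, lim)), tol = 1e-8)$root,
                      error = function(e) NA_real_)
    hr <- if (d1 == 0L) 0 else Inf
    ci <- if (d1 == 0L) c(0, exp(bound)) else c(exp(bound), Inf)
    return(structure(list(hazard_ratio = hr, ci95 = ci,
                          p_value = NA_real_, p_logrank = lr$p_value,
                          method = "breslow-partial-likelihood",
                          non_estimable = TRUE,
                          oe_ratio = NA_real_), class = "hr_result"))
  }

  beta <- 0
  for (it in 1:50) {
    g <- breslow_loglik(beta, tb)
    step <- g$score / g$info
    step <- max(min(step, 2), -2)  # safeguard
    beta <- beta + step
    if (abs(step) < 1e-10) break
  }
  info <- breslow_loglik(beta, tb)$info
  se <- 1 / sqrt(info)
  oe <- (sum(tb$d1) / lr$expected[2]) / ((sum(tb$d) - sum(tb$d1)) / lr$expected[1])
  structure(list(hazard_ratio = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 p_logrank = lr$p_value,
                 method = "breslow-partial-likelihood",
                 non_estimable = FALSE,
                 oe_ratio = oe), class = "hr_result")
}

#' @export
print.hr_result <- function(x, ...) {
  if (x$non_estimable) {
    cat(sprintf("hr_result: non-estimable (one arm has no events); one-sided 95%% bound [%.3g, %.3g]\n",
                x$ci95[1], x$ci95[2]))
  } else {
    cat(sprintf("hr_result: HR %.3g (95%% CI %.3g-%.3g), Wald P = %.3g, log-rank P = %.3g\n",
                x$hazard_ratio, x$ci95[1], x$ci95[2], x$p_value, x$p_logrank))
  }
  invisible(x)
}

#' Pairwise survival contrasts across the declared arms
#'
#' Runs [km_estimator()] per arm plus [logrank_test()] and [hazard_ratio()]
#' for each requested pair (the three-arm comparison — single-negative,
#' single-positive, multi-resection-cleared — reduces to declared pairwise
#' contrasts).
#'
#' @param cohort data.frame with `arm`, `time_months`, `event`.
#' @param contrasts list of length-2 character vectors `c(reference, comparison)`;
#'   default: every arm pair.
#' @return list with `km` (named list of `km_curve`s) and `contrasts`
#'   (named list of `hr_result`s).
#' @export
survival_analysis <- function(cohort, contrasts = NULL) {
  arms <- sort(unique(cohort$arm))
  if (is.null(contrasts)) {
    contrasts <- utils::combn(arms, 2, simplify = FALSE)
  }
  km <- lapply(stats::setNames(arms, arms), function(a) {
    km_estimator(cohort[cohort$arm == a, ])
  })
  res <- lapply(contrasts, function(cp) {
    hazard_ratio(cohort[cohort$arm == cp[1], ], cohort[cohort$arm == cp[2], ])
  })
  names(res) <- vapply(contrasts, function(cp) paste(cp[2], "vs", cp[1]),
                       character(1))
  list(km = km, contrasts = res)
}
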