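#' Per-day success curve from trial records
#'
#' Computes the percentage of rewarded trials per (stage, day), ordered
#' initial stage first.  Days with fewer trials than the protocol prescribes
#' are computed over the available trials with a warning.
#'
#' @param records Trial records (see [validate_trial_records()] for the
#'   schema); one subject, or several if a `subject` column is present.
#' @param trials_per_day Expected trials per day (for the completeness check).
#' @return Tibble with `subject` (if present), `stage`, `day`, `pct_correct`.
#' @export
success_curve <- function(records, trials_per_day = 10) {
  gv <- intersect("subject", names(records))
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(gv, "stage", "day")))) |>
    dplyr::summarise(pct_correct = 100 * mean(.data$outcome),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(gv, "stage", "day"))))
  if (any(out$n < trials_per_day)) {
    warn("some days have fewer trials than the protocol prescribes; success computed over available trials",
         class = "snplastr_incomplete_day")
  }
  out$n <- NULL
  out
}

#' Days to reach and maintain a success criterion
#'
#' The earliest day `d` such that the daily success rate meets the threshold
#' on day `d` and every later day of the stage.  A subject that never
#' satisfies this is censored: the returned value is `length(curve) + 1` with
#' attribute `censored = TRUE` (the worst rank for downstream rank tests).
#'
#' @param curve Per-day success percentages for one stage.
#' @param threshold Criterion, percent.
#' @return Integer day, possibly censored (see Details).
#' @export
days_to_criterion <- function(curve, threshold = 80) {
  if (length(curve) == 0) {
    abort("empty success curve", class = "snplastr_shape_error")
  }
  ok <- curve >= threshold
  # earliest d with all(ok[d:end]): scan the reversed cumulative conjunction
  all_from <- rev(cumprod(rev(ok))) > 0
  if (any(all_from)) {
    which.max(all_from)
  } else {
    structure(length(curve) + 1L, censored = TRUE)
  }
}

group_levels <- c("light_on", "light_off", "GFP")

normalise_group <- function(group) {
  if (is.numeric(group)) {
    if (!all(group %in% 0:2)) {
      abort("numeric group codes must be 0 (light_on), 1 (light_off), 2 (GFP)",
            class = "snplastr_data_error")
    }
    return(factor(group_levels[group + 1], levels = group_levels))
  }
  g <- as.character(group)
  if (!all(g %in% group_levels)) {
    abort(paste0("unknown group label(s): ",
                 paste(unique(setdiff(g, group_levels)), collapse = ", ")),
          class = "snplastr_data_error")
  }
  factor(g, levels = group_levels)
}

#' Design matrix of the fixed-effects trial-outcome logistic regression
#'
#' Builds the regression of each trial's binary outcome on experimental
#' group, task stage, and trial number, with group-by-stage and
#' trial-by-stage interactions.  Group enters as treatment contrasts with
#' light-on (cholinergic silencing) as the reference level, so the
#' group-by-stage coefficients test whether each control group's advantage is
#' specific to the reversal stage.
#'
#' Trial number is, by default, a running index within each stage
#' (1..80 initial, restarting 1..120 in reversal); `trial_coding =
#' "day.trial"` uses the decimal day-dot-trial coding instead (day 1 trial 2
#' = 1.2), which rescales the trial coefficient without changing its sign.
#'
#' @param records Trial records for a cohort.
#' @param trial_coding `"running"` or `"day.trial"`.
#' @param trials_per_day Trials per day (for the running index).
#' @return List with `design` (numeric matrix with named columns) and
#'   `outcome` (0/1 vector).
#' @export
build_trial_design <- function(records, trial_coding = c("running", "day.trial"),
                             trials_per_day = 10) {
  trial_coding <- match.arg(trial_coding)
  grp <- normalise_group(records$group)
  stage <- as.numeric(records$stage)
  if (!all(stage %in% c(0, 1))) {
    abort("stage must be coded 0 (initial) / 1 (reversal)",
          class = "snplastr_data_error")
  }
  trial <- switch(trial_coding,
    running = (records$day - 1) * trials_per_day + records$trial,
    day.trial = records$day + records$trial / 10
  )
  g_off <- as.numeric(grp == "light_off")
  g_gfp <- as.numeric(grp == "GFP")
  design <- cbind(
    `(Intercept)` = 1,
    group_light_off = g_off,
    group_GFP = g_gfp,
    trial = trial,
    stage = stage,
    `trial:stage` = trial * stage,
    `group_light_off:stage` = g_off * stage,
    `group_GFP:stage` = g_gfp * stage
  )
  list(design = design, outcome = as.numeric(records$outcome))
}

#' Model frame for the mixed-effects (subject-specific) extension
#'
#' The subject-level extension adds a per-subject intercept and a
#' per-subject trial slope to the fixed-effects regression.  This package
#' does not estimate random effects itself; this helper returns a model
#' frame ready for off-the-shelf GLMM machinery, e.g.
#' `lme4::glmer(outcome ~ group * stage + trial * stage + (1 + trial | subject),
#' family = binomial)`.
#'
#' @inheritParams build_trial_design
#' @return A data.frame with `outcome`, `group` (factor, light-on reference),
#'   `stage`, `trial`, `subject`.
#' @export
subject_model_frame <- function(records, trial_coding = c("running", "day.trial"),
                            trials_per_day = 10) {
  trial_coding <- match.arg(trial_coding)
  trial <- switch(trial_coding,
    running = (records$day - 1) * trials_per_day + records$trial,
    day.trial = records$day + records$trial / 10
  )
  data.frame(
    outcome = as.numeric(records$outcome),
    group = normalise_group(records$group),
    stage = as.numeric(records$stage),
    trial = trial,
    subject = as.factor(records$subject)
  )
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald standard errors.  Convergence is
#' declared when the log-likelihood improves by less than `tol`.  Perfect
#' separation (a coefficient diverging beyond `beta_limit`) and rank
#' deficiency raise classed errors naming the offending column.
#'
#' @param design Numeric design matrix (include the intercept column).
#' @param outcome 0/1 response vector.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum IRLS iterations.
#' @param beta_limit Divergence bound used to flag separation.
#' @return An object of class `snplast_glm` with `coefficients`, `se`,
#'   `z`, `p_value`, `log_lik`, `aic`, `n`, `iterations`, `converged`.
#' @export
fit_logistic_irls <- function(design, outcome, tol = 1e-8, max_iter = 100,
                              beta_limit = 30) {
  X <- as.matrix(design)
  y <- as.numeric(outcome)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort(paste0("design matrix is rank deficient (collinear column(s): ",
                 paste(bad, collapse = ", "), ")"),
          class = "snplastr_collinearity_error")
  }
  log1pexp <- function(e) pmax(e, 0) + log1p(exp(-abs(e)))
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / wt
    fit <- stats::lm.wfit(X, z, wt)
    beta <- fit$coefficients
    if (any(abs(beta) > beta_limit)) {
      bad <- colnames(X)[which.max(abs(beta))]
      abort(paste0("perfect separation detected (diverging coefficient: ",
                   bad, ")"),
            class = "snplastr_separation_error")
    }
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    if (max(abs(y - mu)) < 1e-8) {
      bad <- colnames(X)[which.max(abs(beta))]
      abort(paste0("perfect separation detected (fitted probabilities ",
                   "degenerate; diverging coefficient: ", bad, ")"),
            class = "snplastr_separation_error")
    }
    ll <- sum(y * eta - log1pexp(eta))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  mu <- plogis(drop(X %*% beta))
  W <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(W))
  se <- sqrt(diag(solve(info)))
  zstat <- beta / se
  structure(
    list(coefficients = setNames(beta, colnames(X)),
         se = setNames(se, colnames(X)),
         z = setNames(zstat, colnames(X)),
         p_value = setNames(2 * stats::pnorm(-abs(zstat)), colnames(X)),
         log_lik = ll_old,
         aic = 2 * ncol(X) - 2 * ll_old,
         n = length(y), iterations = it,
         converged = converged),
    class = "snplast_glm"
  )
}

#' Fit the trial-outcome logistic regression to a cohort
#'
#' Convenience wrapper: [build_trial_design()] then [fit_logistic_irls()].
#'
#' @inheritParams build_trial_design
#' @param ... Passed to [fit_logistic_irls()].
#' @return An `snplast_glm` object.
#' @export
fit_trial_glm <- function(records, trial_coding = c("running", "day.trial"),
                          trials_per_day = 10, ...) {
  d <- build_trial_design(records, trial_coding, trials_per_day)
  fit_logistic_irls(d$design, d$outcome, ...)
}

#' @export
print.snplast_glm <- function(x, ...) {
  cat("<snplast_glm> logistic regression,", x$n, "trials\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname fit_logistic_irls
#' @param x An `snplast_glm`.
#' @param ... Unused.
#' @export
tidy.snplast_glm <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(x$z),
         p.value = unname(x$p_value))
}

#' @rdname fit_logistic_irls
#' @export
glance.snplast_glm <- function(x, ...) {
  tibble(logLik = x$log_lik, AIC = x$aic, nobs = x$n,
         iterations = x$iterations, converged = x$converged)
}

#' Kruskal-Wallis rank test of group differences
#'
#' Rank-based comparison of two or more groups (tie-corrected H statistic,
#' chi-squared approximation with groups - 1 degrees of freedom); used for
#' comparing fitted neuromodulator parameters between experimental groups.
#' Delegates to [stats::kruskal.test()].  If every observation is identical
#' the tie correction degenerates; this is reported as H = 0, p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length.
#' @return Tibble with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) {
    abort("need at least two groups", class = "snplastr_data_error")
  }
  if (any(tabulate(g, nlevels(g)) == 0)) {
    abort("every group needs at least one observation",
          class = "snplastr_data_error")
  }
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(values, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value)
}
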