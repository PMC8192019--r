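make_records <- function(outcomes, subject = "m1", group = "GFP",
                         days_initial = 8, days_reversal = 12,
                         trials_per_day = 10) {
  n <- (days_initial + days_reversal) * trials_per_day
  stopifnot(length(outcomes) == n)
  tibble::tibble(
    subject = subject, group = group,
    stage = rep(c(0L, 1L), c(days_initial, days_reversal) * trials_per_day),
    day = c(rep(seq_len(days_initial), each = trials_per_day),
            rep(seq_len(days_reversal), each = trials_per_day)),
    trial = rep(seq_len(trials_per_day), days_initial + days_reversal),
    outcome = outcomes
  )
}

test_that("success curves aggregate trials per stage and day", {
  rec <- make_records(rep(1L, 200))
  sc <- success_curve(rec)
  expect_equal(nrow(sc), 20)
  expect_true(all(sc$pct_correct == 100))
  # a day with 8/10 rewards scores 80%
  out <- rep(1L, 200)
  out[1:10] <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  sc2 <- success_curve(make_records(out))
  expect_equal(sc2$pct_correct[sc2$stage == 0 & sc2$day == 1], 80)
  # incomplete day warns but still computes
  expect_warning(success_curve(rec[-1, ]), class = "snplastr_incomplete_day")
  # consistency with the simulator's own daily summary
  s <- run_session(eta_ach = 0, eta_da = 0, seed = 13)
  rec_s <- dplyr::transmute(
    s$trials, subject = "a", group = "GFP",
    stage = as.integer(stage == "reversal"), day = day, trial = trial,
    outcome = as.integer(outcome == "reward")
  )
  expect_equal(success_curve(rec_s)$pct_correct, s$daily$pct_correct)
})

test_that("days-to-criterion is reach-and-maintain with censoring", {
  expect_equal(days_to_criterion(rep(100, 8)), 1)
  expect_equal(days_to_criterion(c(70, 90, 70, 90, 90, 90, 90, 90)), 4)
  cens <- days_to_criterion(rep(50, 12))
  expect_equal(as.integer(cens), 13L)
  expect_true(isTRUE(attr(cens, "censored")))
  expect_error(days_to_criterion(numeric(0)), class = "snplastr_shape_error")
  # monotone: raising any day's success never increases the returned day
  set.seed(55)
  for (k in 1:50) {
    cv <- runif(12, 0, 100)
    d0 <- as.integer(days_to_criterion(cv))
    i <- sample(12, 1)
    cv[i] <- min(100, cv[i] + runif(1, 0, 50))
    expect_lte(as.integer(days_to_criterion(cv)), d0)
  }
})

test_that("the trial-outcome design uses light-on as reference", {
  rec <- make_records(rep(1L, 200), group = "light_on")
  d <- build_trial_design(rec)
  expect_equal(nrow(d$design), 200)
  expect_equal(colnames(d$design),
               c("(Intercept)", "group_light_off", "group_GFP", "trial",
                 "stage", "trial:stage", "group_light_off:stage",
                 "group_GFP:stage"))
  # light-on rows: group contrasts and group-by-stage interactions all zero
  expect_true(all(d$design[, c("group_light_off", "group_GFP",
                               "group_light_off:stage",
                               "group_GFP:stage")] == 0))
  # running trial index restarts at the stage switch
  expect_equal(unname(d$design[1:80, "trial"]), as.numeric(1:80))
  expect_equal(unname(d$design[81, "trial"]), 1)
  # decimal day.trial coding
  d2 <- build_trial_design(rec, trial_coding = "day.trial")
  expect_equal(unname(d2$design[12, "trial"]), 2.2)  # day 2, trial 2
  # numeric group codes are accepted (0 = light_on)
  rec$group <- 0
  expect_silent(build_trial_design(rec))
  rec$group <- "mystery"
  expect_error(build_trial_design(rec), class = "snplastr_data_error")
})

test_that("IRLS reproduces closed forms and the reference fitter", {
  # intercept-only: logit of the success fraction
  y <- c(rep(1, 30), rep(0, 70))
  f <- fit_logistic_irls(cbind(`(Intercept)` = rep(1, 100)), y)
  expect_equal(unname(f$coefficients), qlogis(0.3), tolerance = 1e-8)
  # balanced 2x2 design: slope equals the empirical log odds ratio
  x <- rep(c(0, 1), each = 200)
  set.seed(33)
  y2 <- rbinom(400, 1, plogis(-0.5 + 1.2 * x))
  X2 <- cbind(`(Intercept)` = 1, x = x)
  f2 <- fit_logistic_irls(X2, y2)
  tab <- table(x, y2)
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_equal(unname(f2$coefficients["x"]), lor, tolerance = 1e-8)
  # agreement with stats::glm on a random multi-column design
  set.seed(34)
  X3 <- cbind(1, matrix(rnorm(300 * 3), 300, 3))
  colnames(X3) <- c("(Intercept)", "a", "b", "c")
  y3 <- rbinom(300, 1, plogis(X3 %*% c(0.2, -0.5, 0.8, 0)))
  f3 <- fit_logistic_irls(X3, y3, tol = 1e-12)
  ref <- stats::glm(y3 ~ X3[, -1], family = stats::binomial())
  expect_equal(unname(f3$coefficients), unname(coef(ref)), tolerance = 1e-8)
  # glm reports SEs from its final IRLS working weights, which sit ~1e-5
  # from the exact Fisher information at the MLE; compare loosely
  expect_equal(unname(f3$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
  expect_equal(f3$log_lik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(f3$aic, stats::AIC(ref), tolerance = 1e-6)
  # degenerate inputs
  expect_error(fit_logistic_irls(cbind(1, x), rep(1, 400)),
               class = "snplastr_separation_error")
  expect_error(fit_logistic_irls(cbind(1, x, x), y2),
               class = "snplastr_collinearity_error")
})

test_that("IRLS matches a brute-force likelihood grid on a two-parameter toy", {
  set.seed(35)
  x <- rnorm(250)
  y <- rbinom(250, 1, plogis(0.4 - 0.9 * x))
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_logistic_irls(X, y)
  b_grid <- oracle_grid_logistic(X, y)
  expect_equal(unname(f$coefficients), b_grid, tolerance = 1e-6)
})

test_that("rank test behaves on constructed groups", {
  # three groups shifted by large offsets
  v <- c(rnorm(10), rnorm(10) + 50, rnorm(10) + 100)
  g <- rep(letters[1:3], each = 10)
  kt <- kruskal_wallis(v, g)
  expect_lt(kt$p.value, 0.001)
  expect_equal(kt$df, 2)
  # identical values everywhere: degenerate ties reported as H = 0
  kt0 <- kruskal_wallis(rep(1, 20), rep(c("a", "b"), 10))
  expect_equal(kt0$statistic, 0)
  expect_equal(kt0$p.value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), class = "snplastr_data_error")
})

test_that("the subject-level model frame is ready for GLMM tools", {
  rec <- make_records(rep(c(0L, 1L), 100))
  mf <- subject_model_frame(rec)
  expect_equal(names(mf), c("outcome", "group", "stage", "trial", "subject"))
  expect_s3_class(mf$group, "factor")
  expect_equal(levels(mf$group), c("light_on", "light_off", "GFP"))
  expect_equal(nrow(mf), 200)
})
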