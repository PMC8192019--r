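#' Specification of a synthetic behavioural cohort
#'
#' Describes a cohort with the structure of the optogenetic study: three
#' groups (GFP control, light-off control, light-on cholinergic silencing;
#' default sizes 8 / 16 / 21) run through the two-stage protocol.  Two
#' generators are available:
#'
#' * `"mechanistic"` — each subject is a simulated agent whose
#'   (`eta_ach`, `eta_da`) is drawn from its group's region of parameter
#'   space (controls from `region_control`, light-on from the
#'   reduced-acetylcholine `region_reduced`), then run through
#'   [run_session()].
#' * `"glm"` — each trial outcome is Bernoulli with success probability given
#'   by the trial-outcome logistic model (the same design as
#'   [build_trial_design()]) with coefficient vector `beta` plus Gaussian
#'   per-subject intercepts (sd `sd_b0`) and trial slopes (sd `sd_b4`).
#'
#' The default regions are qualitative: group regions are reported
#' graphically in the source study, so the defaults are honest rectangles
#' (controls at moderate ratios, light-on shifted toward zero acetylcholine,
#' overlapping enough that a single cohort's rank test is not guaranteed to
#' reach significance).
#'
#' @param group_sizes Named integer vector (GFP, light_off, light_on).
#' @param generator `"mechanistic"` or `"glm"`.
#' @param region_control,region_reduced [param_region()]s for the mechanistic
#'   generator.
#' @param grid [grid_spec()] whose points region draws snap to.
#' @param beta Named coefficient vector matching [build_trial_design()] columns
#'   (glm generator).
#' @param sd_b0,sd_b4 Subject-effect standard deviations (glm generator).
#' @param protocol A [protocol_spec()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(GFP = 8, light_off = 16, light_on = 21),
                        generator = c("mechanistic", "glm"),
                        region_control = param_region(c(9.5e-4, 2.35e-3),
                                                      c(0.1, 0.55)),
                        region_reduced = param_region(c(9.5e-4, 2.35e-3),
                                                      c(0, 0.45)),
                        grid = grid_spec(),
                        beta = default_cohort_beta(),
                        sd_b0 = 0.5, sd_b4 = 0.01,
                        protocol = protocol_spec()) {
  generator <- match.arg(generator)
  stopifnot(all(group_sizes >= 1),
            all(c("GFP", "light_off", "light_on") %in% names(group_sizes)),
            sd_b0 >= 0, sd_b4 >= 0)
  structure(
    list(group_sizes = group_sizes, generator = generator,
         region_control = region_control, region_reduced = region_reduced,
         grid = grid, beta = beta, sd_b0 = sd_b0, sd_b4 = sd_b4,
         protocol = protocol),
    class = "cohort_spec"
  )
}

#' Default generating coefficients for the glm cohort generator
#'
#' Chosen so that synthetic cohorts resemble the study's behaviour: ~25%
#' success on day one rising above 90% by the end of initial learning, a
#' perseveration drop at the stage switch, and a reversal-stage advantage for
#' both control groups over light-on (the group-by-stage interactions).
#'
#' @return Named numeric vector matching [build_trial_design()] columns.
#' @export
default_cohort_beta <- function() {
  c(`(Intercept)` = -1.2, group_light_off = 0.1, group_GFP = 0.1,
    trial = 0.045, stage = -0.8, `trial:stage` = -0.01,
    `group_light_off:stage` = 0.7, `group_GFP:stage` = 0.7)
}

subject_table <- function(group_sizes) {
  groups <- rep(names(group_sizes), group_sizes)
  tibble(
    subject = sprintf("%s_%02d", groups,
                      unlist(lapply(group_sizes, seq_len))),
    group = groups
  )
}

#' Generate a mechanistic cohort of simulated agents
#'
#' Draws each subject's (`eta_ach`, `eta_da`) from its group's region,
#' simulates a full session, and converts the outcomes to trial records in
#' the shared schema.  The hidden per-subject truth is returned separately
#' and never mixed into the records, so it can serve parameter-recovery
#' tests.
#'
#' @param spec A [cohort_spec()] with `generator = "mechanistic"`.
#' @param seed Master seed; per-subject session seeds are derived from it.
#' @param network A [build_network()].
#' @return List with `records` (tibble: subject, group, stage, day, trial,
#'   outcome) and `truth` (tibble: subject, group, eta_ach, eta_da).
#' @export
generate_mechanistic_cohort <- function(spec = cohort_spec(), seed = 1,
                                        network = build_network()) {
  if (spec$generator != "mechanistic") {
    abort("spec$generator must be 'mechanistic'",
          class = "snplastr_configuration_error")
  }
  set.seed(seed)
  subjects <- subject_table(spec$group_sizes)
  params <- dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    region <- if (subjects$group[i] == "light_on") spec$region_reduced
              else spec$region_control
    sample_group_parameters(region, 1, spec$grid)
  }))
  session_seeds <- sample.int(.Machine$integer.max, nrow(subjects))
  records <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- run_session(params$eta_ach[i], params$eta_da[i],
                     seed = session_seeds[i], protocol = spec$protocol,
                     network = network)
    records[[i]] <- s$trials |>
      dplyr::transmute(
        subject = subjects$subject[i], group = subjects$group[i],
        stage = as.integer(.data$stage == "reversal"),
        day = .data$day, trial = .data$trial,
        outcome = as.integer(.data$outcome == "reward")
      )
  }
  list(
    records = dplyr::bind_rows(records),
    truth = dplyr::bind_cols(subjects, params)
  )
}

#' Generate a cohort from the trial-outcome logistic model
#'
#' Each trial's success probability is the inverse logit of the fixed-effects
#' linear predictor (coefficients `spec$beta`) plus the subject's random
#' intercept and trial slope.  Linear predictors beyond +/-30 pin the
#' probability and raise a saturation warning.
#'
#' @inheritParams generate_mechanistic_cohort
#' @param spec A [cohort_spec()] with `generator = "glm"`.
#' @return List with `records` and `truth` (list: `beta`,
#'   `subject_effects` tibble with b0, b4 per subject).
#' @export
generate_glm_cohort <- function(spec = cohort_spec(generator = "glm"),
                                seed = 1) {
  if (spec$generator != "glm") {
    abort("spec$generator must be 'glm'",
          class = "snplastr_configuration_error")
  }
  set.seed(seed)
  subjects <- subject_table(spec$group_sizes)
  subjects$b0 <- rnorm(nrow(subjects), 0, spec$sd_b0)
  subjects$b4 <- rnorm(nrow(subjects), 0, spec$sd_b4)

  proto <- spec$protocol
  frame <- tidyr::expand_grid(
    subjects[, c("subject", "group")],
    tibble(
      stage = rep(c(0L, 1L), c(proto$days_initial, proto$days_reversal) *
                    proto$trials_per_day),
      day = c(rep(seq_len(proto$days_initial), each = proto$trials_per_day),
              rep(seq_len(proto$days_reversal), each = proto$trials_per_day)),
      trial = rep(seq_len(proto$trials_per_day),
                  proto$days_initial + proto$days_reversal)
    )
  )
  frame$outcome <- 0L
  d <- build_trial_design(frame, trials_per_day = proto$trials_per_day)
  lp <- drop(d$design %*% spec$beta[colnames(d$design)])
  eff <- subjects[match(frame$subject, subjects$subject), ]
  lp <- lp + eff$b0 + eff$b4 * d$design[, "trial"]
  if (any(abs(lp) > 30)) {
    warn("some linear predictors exceed +/-30; probabilities pinned",
         class = "snplastr_saturation_warning")
  }
  frame$outcome <- rbinom(length(lp), 1, plogis(lp))
  list(
    records = as_tibble(frame),
    truth = list(beta = spec$beta,
                 subject_effects = subjects[, c("subject", "group",
                                                "b0", "b4")])
  )
}

#' Validate trial records against the shared schema
#'
#' Both real behavioural data and synthetic cohorts share one table schema:
#' one row per trial with `subject`, `group` (GFP / light_off / light_on, or
#' codes 0/1/2 with 0 = light_on), `stage` (0 initial, 1 reversal), `day`,
#' `trial` (within-day index), `outcome` (0/1).
#'
#' @param records A data frame.
#' @param protocol A [protocol_spec()] giving the stage day bounds.
#' @return The records, invisibly, as a tibble; errors describe the first
#'   violated constraint.
#' @export
validate_trial_records <- function(records, protocol = protocol_spec()) {
  need <- c("subject", "group", "stage", "day", "trial", "outcome")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "snplastr_data_error")
  }
  normalise_group(records$group)
  if (!all(records$outcome %in% c(0, 1))) {
    abort("outcome must be binary 0/1", class = "snplastr_data_error")
  }
  if (!all(records$stage %in% c(0, 1))) {
    abort("stage must be 0 (initial) or 1 (reversal)",
          class = "snplastr_data_error")
  }
  max_days <- ifelse(records$stage == 0, protocol$days_initial,
                     protocol$days_reversal)
  if (any(records$day < 1 | records$day > max_days)) {
    abort("day out of stage bounds", class = "snplastr_data_error")
  }
  if (any(records$trial < 1 | records$trial > protocol$trials_per_day)) {
    abort("trial index out of bounds", class = "snplastr_data_error")
  }
  invisible(as_tibble(records))
}

#' Read / write trial records as CSV
#'
#' Plain-text interchange in the shared schema (`subject, group, stage, day,
#' trial, outcome`); validation is applied on read.
#'
#' @param path File path.
#' @param records Trial records.
#' @return `read_trial_records` returns a validated tibble.
#' @export
read_trial_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_records(df)
  as_tibble(df)
}

#' @rdname read_trial_records
#' @export
write_trial_records <- function(records, path) {
  validate_trial_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
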