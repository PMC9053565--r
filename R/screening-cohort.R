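#' Synthetic cohort generator settings
#'
#' Defaults emulate the reported study conditions of an elderly cohort
#' assessed over five newscast sessions: per-impairment-level `sim` means and
#' SDs (absent 0.42 +/- 0.17, mild 0.29 +/- 0.17, severe 0.08 +/- 0.10),
#' per-level mean answer lengths in characters (54.20 / 37.75 / 30.84),
#' session-to-session difficulty shifts, stress/focus performance effects,
#' and the prevalence patterns of the study (57% impaired: 40% mild, 17%
#' severe; impaired users more often stressed and less often focused).
#' Draws are censored to \[0, 1\]; the pre-censoring location of every
#' (level, session) cell is calibrated numerically so the censored mean
#' equals the configured target, keeping marginal per-level means on
#' specification.
#'
#' @param p_impairment Named probabilities for absent/mild/severe.
#' @param sim_mean,sim_sd Named per-level `sim` means and SDs.
#' @param session_shift 3 x 5 matrix (rows absent/mild/severe) of additive
#'   shifts of the `sim` mean per session, encoding that sessions differ in
#'   difficulty and that the pattern differs by impairment level; rows are
#'   approximately zero-mean so level means stay on target. A length-5
#'   vector is recycled across levels.
#' @param len_mean Named per-level mean response lengths (characters).
#' @param len_sd Response-length SD.
#' @param sim_icc,len_icc Share of the configured variance attributable to a
#'   stable per-user intercept (responses cluster within a person: verbosity
#'   strongly, comprehension moderately). The marginal per-level SD stays at
#'   `sim_sd`/`len_sd`.
#' @param p_stress Probability of being stressed, by absent/impaired status.
#' @param p_focus Probability of being focused, by absent/impaired status.
#' @param stress_effect,focus_effect Shifts of a user's `sim` location
#'   attributable to stress (negative) and focus (positive); centred within
#'   level so marginals are unaffected.
#' @param p_studies,p_technology Probabilities of superior education and of
#'   technological skills.
#' @param age_probs 3 x 4 matrix of age-band probabilities (rows
#'   absent/mild/severe), encoding that impairment rises with age.
#' @return A list of class `cohort_settings`.
#' @export
cohort_settings <- function(p_impairment = c(absent = 0.43, mild = 0.40, severe = 0.17),
                            sim_mean = c(absent = 0.42, mild = 0.29, severe = 0.08),
                            sim_sd = c(absent = 0.17, mild = 0.17, severe = 0.10),
                            session_shift = rbind(
                              absent = c(-0.03, 0.33, -0.30, 0.06, -0.08),
                              mild   = c(-0.06, 0.36, -0.18, -0.10, -0.02),
                              severe = c(-0.01, 0.05, -0.07, -0.08, 0.12)
                            ),
                            len_mean = c(absent = 54.20, mild = 37.75, severe = 30.84),
                            len_sd = 15,
                            sim_icc = 0.3,
                            len_icc = 0.6,
                            p_stress = c(absent = 1 - 0.9167, impaired = 1 - 0.6111),
                            p_focus = c(absent = 0.90, impaired = 0.65),
                            stress_effect = 0.12,
                            focus_effect = 0.12,
                            p_studies = 0.47,
                            p_technology = 0.57,
                            age_probs = rbind(
                              absent = c(0.40, 0.45, 0.13, 0.02),
                              mild   = c(0.20, 0.50, 0.27, 0.03),
                              severe = c(0.10, 0.40, 0.40, 0.10)
                            )) {
  s <- list(p_impairment = p_impairment, sim_mean = sim_mean, sim_sd = sim_sd,
            session_shift = session_shift, len_mean = len_mean, len_sd = len_sd,
            sim_icc = sim_icc, len_icc = len_icc,
            p_stress = p_stress, p_focus = p_focus,
            stress_effect = stress_effect, focus_effect = focus_effect,
            p_studies = p_studies, p_technology = p_technology,
            age_probs = age_probs)
  probs <- c(p_impairment, p_stress, p_focus, p_studies, p_technology,
             as.vector(age_probs))
  if (any(probs < 0 | probs > 1) || abs(sum(p_impairment) - 1) > 1e-8 ||
      any(abs(rowSums(age_probs) - 1) > 1e-8)) {
    abort("cohort settings contain invalid probabilities",
          class = "cogniscore_settings_error")
  }
  if (any(sim_sd <= 0) || len_sd <= 0) {
    abort("standard deviations must be positive",
          class = "cogniscore_settings_error")
  }
  if (sim_icc < 0 || sim_icc >= 1 || len_icc < 0 || len_icc >= 1) {
    abort("intra-class correlations must lie in [0, 1)",
          class = "cogniscore_settings_error")
  }
  if (is.vector(session_shift)) {
    session_shift <- matrix(session_shift, nrow = 3, ncol = 5, byrow = TRUE,
                            dimnames = list(c("absent", "mild", "severe")))
    s$session_shift <- session_shift
  }
  if (!all(dim(session_shift) == c(3, 5))) {
    abort("session_shift must be a 3 x 5 matrix or a length-5 vector",
          class = "cogniscore_settings_error")
  }
  structure(s, class = "cohort_settings")
}

# mean of a normal censored to [0, 1]
censored_mean <- function(mu, sd) {
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  mu * (pnorm(b) - pnorm(a)) + sd * (dnorm(a) - dnorm(b)) + (1 - pnorm(b))
}

# location mu such that the [0,1]-censored N(mu, sd) has the target mean
calibrate_mu <- function(target, sd) {
  uniroot(function(m) censored_mean(m, sd) - target,
          interval = c(-2, 3), tol = 1e-10)$root
}

#' Simulate a screening cohort
#'
#' Generates participant profiles and five-session dialogue records whose
#' `sim` scores and answer lengths follow the configured impairment-level
#' conditions (see [cohort_settings()]). Deterministic for a fixed seed.
#'
#' @param n_users Number of participants.
#' @param settings A [cohort_settings()] object.
#' @param seed Integer seed.
#' @return A list with `profiles` (one row per user: `user_id`, `age_band`,
#'   `focus`, `stress`, `studies`, `technology`, `impairment`) and
#'   `sessions` (one row per user x session x question: `user_id`,
#'   `session`, `question`, `sim`, `response_chars`).
#' @examples
#' cohort <- simulate_cohort(30, seed = 7)
#' head(cohort$profiles)
#' @export
simulate_cohort <- function(n_users, settings = cohort_settings(), seed = 1) {
  stopifnot(n_users >= 1)
  levels3 <- c("absent", "mild", "severe")
  # calibrated locations per (level, session) cell
  # stress/focus effects contribute to the observed spread; the residual
  # between/within components keep the marginal SD at the configured value
  var_eff <- vapply(c("absent", "impaired"), function(st) {
    pf <- settings$p_focus[[st]]
    ps <- settings$p_stress[[st]]
    settings$focus_effect^2 * pf * (1 - pf) +
      settings$stress_effect^2 * ps * (1 - ps)
  }, numeric(1))
  mu_cell <- vapply(levels3, function(lv) {
    vapply(seq_len(5), function(s) {
      target <- min(max(settings$sim_mean[[lv]] + settings$session_shift[lv, s],
                        0.005), 0.995)
      calibrate_mu(target, settings$sim_sd[[lv]])
    }, numeric(1))
  }, numeric(5))
  with_local_seed(seed, {
    impairment <- sample(levels3, n_users, replace = TRUE,
                         prob = settings$p_impairment)
    status <- ifelse(impairment == "absent", "absent", "impaired")
    focus <- rbinom(n_users, 1, settings$p_focus[status]) == 1
    stress <- rbinom(n_users, 1, settings$p_stress[status]) == 1
    profiles <- tibble(
      user_id = sprintf("u%04d", seq_len(n_users)),
      age_band = vapply(impairment, function(lv) {
        sample.int(4, 1, prob = settings$age_probs[lv, ])
      }, integer(1)),
      focus = focus,
      stress = stress,
      studies = rbinom(n_users, 1, settings$p_studies) == 1,
      technology = rbinom(n_users, 1, settings$p_technology) == 1,
      impairment = factor(impairment, levels = levels3)
    )
    # centred stress/focus effects leave per-level marginal means intact
    user_effect <- settings$focus_effect * (focus - settings$p_focus[status]) -
      settings$stress_effect * (stress - settings$p_stress[status])
    # per-user intercepts: the between/within split preserves the marginal SD
    sim_resid <- sqrt(pmax(settings$sim_sd[impairment]^2 - var_eff[status],
                           1e-6))
    sim_between <- sim_resid * sqrt(settings$sim_icc)
    sim_within <- sim_resid * sqrt(1 - settings$sim_icc)
    len_between <- settings$len_sd * sqrt(settings$len_icc)
    len_within <- settings$len_sd * sqrt(1 - settings$len_icc)
    b_sim <- rnorm(n_users, 0, sim_between)
    b_len <- rnorm(n_users, 0, len_between)
    sessions <- tidyr::expand_grid(
      user = seq_len(n_users), session = 1:5, question = 1:4
    )
    mu <- mu_cell[cbind(sessions$session, match(impairment[sessions$user], levels3))] +
      user_effect[sessions$user] + b_sim[sessions$user]
    sims <- pmin(pmax(rnorm(nrow(sessions), mu, sim_within[sessions$user]), 0), 1)
    lens <- pmax(round(rnorm(nrow(sessions),
                             settings$len_mean[impairment[sessions$user]] +
                               b_len[sessions$user],
                             len_within)), 0)
    sessions <- tibble(
      user_id = profiles$user_id[sessions$user],
      session = sessions$session,
      question = sessions$question,
      sim = sims,
      response_chars = as.integer(lens)
    )
  })
  list(profiles = profiles, sessions = sessions)
}

#' Per-participant screening feature vector
#'
#' Builds the 11-feature screening table: the four boolean profile flags
#' (focus, stress, studies, technology), the nominal age band, the average
#' number of characters over answered responses, and the `sim` score of
#' question 4 (the attention-demanding question) in each of the five
#' sessions. A missing question-4 score counts as 0. The mild and severe
#' impairment annotations collapse into the binary screening label
#' (`present` vs `absent`).
#'
#' @param profiles,sessions As returned by [simulate_cohort()], or real
#'   records with the same columns.
#' @return Tibble with one row per user: `user_id`, the 11 features and
#'   `label`.
#' @export
extract_features <- function(profiles, sessions) {
  unknown <- setdiff(unique(sessions$user_id), profiles$user_id)
  if (length(unknown)) {
    abort(paste0("sessions reference unknown user(s): ",
                 toString(head(unknown, 3))),
          class = "cogniscore_integrity_error")
  }
  chars <- sessions %>%
    group_by(.data$user_id) %>%
    summarise(num_chars = {
      answered <- .data$response_chars[.data$response_chars > 0]
      if (length(answered)) mean(answered) else 0
    }, .groups = "drop")
  q4 <- sessions %>%
    filter(.data$question == 4) %>%
    mutate(feature = paste0("sim_s", .data$session, "q4")) %>%
    select("user_id", "feature", "sim") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "sim")
  out <- profiles %>%
    select("user_id", "focus", "stress", "studies", "technology",
           age = "age_band", "impairment") %>%
    left_join(chars, by = "user_id") %>%
    left_join(q4, by = "user_id")
  sim_cols <- paste0("sim_s", 1:5, "q4")
  for (col in sim_cols) {
    if (!col %in% names(out)) out[[col]] <- 0
    out[[col]][is.na(out[[col]])] <- 0
  }
  out$num_chars[is.na(out$num_chars)] <- 0
  out$label <- factor(ifelse(out$impairment == "absent", "absent", "present"),
                      levels = c("absent", "present"))
  out[, c("user_id", "focus", "stress", "studies", "technology", "age",
          "num_chars", sim_cols, "label")]
}
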