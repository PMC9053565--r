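test_that("cohort simulation is deterministic and respects configured shapes", {
  c1 <- simulate_cohort(50, seed = 9)
  c2 <- simulate_cohort(50, seed = 9)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$sessions, c2$sessions)
  expect_equal(nrow(c1$profiles), 50)
  expect_equal(nrow(c1$sessions), 50 * 5 * 4)
  expect_true(all(c1$sessions$sim >= 0 & c1$sessions$sim <= 1))
  expect_true(all(c1$sessions$response_chars >= 0))
  expect_true(all(c1$profiles$age_band %in% 1:4))
  c3 <- simulate_cohort(50, seed = 10)
  expect_false(identical(c1$sessions$sim, c3$sessions$sim))
})

test_that("impairment levels order mean sim and response length as configured", {
  cohort <- simulate_cohort(300, seed = 4)
  joined <- dplyr::left_join(cohort$sessions, cohort$profiles, by = "user_id")
  means <- joined %>%
    dplyr::group_by(impairment) %>%
    dplyr::summarise(sim = mean(sim), len = mean(response_chars))
  m <- setNames(means$sim, as.character(means$impairment))
  l <- setNames(means$len, as.character(means$impairment))
  expect_true(m["absent"] > m["mild"] && m["mild"] > m["severe"])
  expect_true(l["absent"] > l["mild"] && l["mild"] > l["severe"])
})

test_that("per-level marginal sim means land within 3 cluster-robust SEs of target", {
  st <- cohort_settings()
  cohort <- simulate_cohort(400, seed = 4)
  joined <- dplyr::left_join(cohort$sessions, cohort$profiles, by = "user_id")
  user_means <- joined %>%
    dplyr::group_by(user_id, impairment) %>%
    dplyr::summarise(sim = mean(sim), .groups = "drop")
  for (lv in c("absent", "mild", "severe")) {
    x <- user_means$sim[user_means$impairment == lv]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - st$sim_mean[[lv]]), 3 * se, label = lv)
  }
})

test_that("invalid cohort settings are rejected", {
  expect_error(cohort_settings(p_impairment = c(absent = 0.5, mild = 0.4,
                                                severe = 0.4)),
               class = "cogniscore_settings_error")
  expect_error(cohort_settings(sim_sd = c(absent = 0, mild = 0.1, severe = 0.1)),
               class = "cogniscore_settings_error")
  expect_error(cohort_settings(sim_icc = 1),
               class = "cogniscore_settings_error")
  expect_error(cohort_settings(session_shift = matrix(0, 2, 5)),
               class = "cogniscore_settings_error")
  # a length-5 vector recycles over levels
  st <- cohort_settings(session_shift = c(-0.1, 0.1, 0, 0, 0))
  expect_equal(dim(st$session_shift), c(3L, 5L))
})

test_that("feature extraction yields the 11 screening features plus label", {
  cohort <- simulate_cohort(40, seed = 2)
  feats <- extract_features(cohort$profiles, cohort$sessions)
  expect_equal(names(feats),
               c("user_id", "focus", "stress", "studies", "technology", "age",
                 "num_chars", paste0("sim_s", 1:5, "q4"), "label"))
  expect_equal(nrow(feats), 40)
  expect_s3_class(feats$label, "factor")
  expect_equal(levels(feats$label), c("absent", "present"))
  # label collapses mild and severe into present
  expect_equal(
    as.character(feats$label),
    ifelse(cohort$profiles$impairment == "absent", "absent", "present")
  )
  # num_chars averages only answered (non-empty) responses
  one <- cohort$profiles[1, ]
  sess <- tibble::tibble(user_id = one$user_id, session = 1L,
                         question = 1:4, sim = c(0.5, 0.5, 0.5, 0.8),
                         response_chars = c(0L, 10L, 20L, 0L))
  f <- extract_features(one, sess)
  expect_equal(f$num_chars, 15)
  expect_equal(f$sim_s1q4, 0.8)
  # sessions with no question 4 fall back to 0
  expect_equal(f$sim_s2q4, 0)
  silent <- sess
  silent$response_chars <- 0L
  expect_equal(extract_features(one, silent)$num_chars, 0)
})

test_that("sessions naming unknown users are rejected", {
  cohort <- simulate_cohort(5, seed = 2)
  bad <- cohort$sessions
  bad$user_id[1] <- "ghost"
  expect_error(extract_features(cohort$profiles, bad),
               class = "cogniscore_integrity_error")
})

test_that("gain ratio is 1 for a perfect binary predictor and 0 for an unrelated one", {
  y <- factor(rep(c("absent", "present"), each = 20))
  df <- tibble::tibble(
    user_id = sprintf("u%02d", 1:40),
    perfect = rep(c(FALSE, TRUE), each = 20),
    constant = TRUE,
    unrelated = rep(c(FALSE, TRUE), times = 20),
    label = y
  )
  rk <- gain_ratio_rank(df)
  gr <- setNames(rk$gain_ratio, rk$feature)
  expect_equal(unname(gr["perfect"]), 1)
  expect_equal(unname(gr["constant"]), 0)
  expect_equal(unname(gr["unrelated"]), 0)
  expect_equal(rk$feature[1], "perfect")
})

test_that("categorical gain ratio matches the entropy oracle on random tables", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    x <- sample(letters[1:3], n, replace = TRUE)
    y <- factor(sample(c("absent", "present"), n, replace = TRUE))
    if (length(unique(y)) < 2) next
    df <- tibble::tibble(user_id = as.character(seq_len(n)),
                         f = factor(x), label = y)
    rk <- gain_ratio_rank(df)
    expect_equal(rk$gain_ratio, oracle_gain_ratio(x, y), label = rep)
  }
})

test_that("numeric features are discretized at the gain-maximizing midpoint", {
  # x < 5 vs x > 5 separates the classes; threshold must sit between 4 and 6
  df <- tibble::tibble(
    user_id = as.character(1:8),
    x = c(1, 2, 3, 4, 6, 7, 8, 9),
    label = factor(rep(c("absent", "present"), each = 4))
  )
  rk <- gain_ratio_rank(df)
  expect_equal(rk$gain_ratio, 1)
  expect_equal(rk$threshold, 5)
  # discretized ratio matches the oracle on the induced binary attribute
  expect_equal(rk$gain_ratio, oracle_gain_ratio(df$x <= rk$threshold, df$label))
})

test_that("gain ratio with a single observed class errors", {
  df <- tibble::tibble(user_id = as.character(1:4), x = 1:4,
                       label = factor(rep("absent", 4),
                                      levels = c("absent", "present")))
  expect_error(gain_ratio_rank(df), class = "cogniscore_ranking_error")
})

test_that("grouped folds never split a user's rows across train and test", {
  cohort <- simulate_cohort(30, seed = 6)
  feats <- extract_features(cohort$profiles, cohort$sessions)
  # duplicate rows per user to make leakage possible in principle
  doubled <- dplyr::bind_rows(feats, feats)
  spy_backend <- local({
    seen <- new.env()
    list(
      name = "spy",
      fit = function(x, y) {
        assign("train_rows", nrow(x), envir = seen)
        names(which.max(table(y)))
      },
      predict = function(model, x) rep(model, nrow(x))
    )
  })
  report <- grouped_kfold_evaluate(doubled, spy_backend, k = 5, seed = 1)
  folds <- report$folds
  # every user appears in exactly one fold
  expect_equal(nrow(folds), 30)
  expect_equal(anyDuplicated(folds$group), 0)
  # pooled confusion covers every row exactly once
  expect_equal(sum(report$confusion), nrow(doubled))
})

test_that("a perfect backend evaluates at 100% and a majority stub at the base rate", {
  cohort <- simulate_cohort(60, seed = 3)
  feats <- extract_features(cohort$profiles, cohort$sessions)
  # smuggle the truth in as a feature: any sound evaluator must score 100%
  feats2 <- feats
  feats2$truth_code <- as.character(feats2$label)
  oracle_backend <- list(
    name = "oracle",
    fit = function(x, y) NULL,
    predict = function(model, x) x$truth_code
  )
  r <- grouped_kfold_evaluate(feats2, oracle_backend, k = 10, seed = 1)
  expect_equal(r$accuracy, 100)
  expect_true(all(r$class_metrics$precision == 100))
  expect_true(all(r$class_metrics$f_measure == 100))
  rm <- grouped_kfold_evaluate(feats, "majority", k = 10, seed = 1)
  base_rate <- 100 * max(table(feats$label)) / nrow(feats)
  expect_lt(abs(rm$accuracy - base_rate), 15)
})

test_that("asking for more folds than users errors", {
  cohort <- simulate_cohort(5, seed = 2)
  feats <- extract_features(cohort$profiles, cohort$sessions)
  expect_error(grouped_kfold_evaluate(feats, "majority", k = 10),
               class = "cogniscore_fold_error")
})

test_that("all shipped backends run end to end on a small cohort", {
  cohort <- simulate_cohort(40, seed = 8)
  feats <- extract_features(cohort$profiles, cohort$sessions)
  for (b in c("dt", "rf", "svm", "nb", "majority")) {
    r <- grouped_kfold_evaluate(feats, b, k = 5, seed = 8)
    expect_true(r$accuracy >= 0 && r$accuracy <= 100, label = b)
    expect_equal(sum(r$confusion), 40, label = b)
  }
  expect_error(grouped_kfold_evaluate(feats, list(name = "x")),
               class = "cogniscore_settings_error")
})

test_that("report accessors and plots are well formed", {
  cohort <- simulate_cohort(40, seed = 8)
  feats <- extract_features(cohort$profiles, cohort$sessions)
  r <- grouped_kfold_evaluate(feats, "dt", k = 5, seed = 8)
  expect_equal(generics::glance(r)$accuracy, r$accuracy)
  expect_equal(generics::tidy(r), r$class_metrics)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  rk <- gain_ratio_rank(feats)
  expect_s3_class(ggplot2::autoplot(rk), "ggplot")
})
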