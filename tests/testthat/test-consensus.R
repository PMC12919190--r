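test_that("panel summaries use the sample (n-1) standard deviation", {
  s <- summarize_panel(c(1, 2, 2))
  expect_equal(round(s$mean, 2), 1.67)
  expect_equal(round(s$sd, 2), 0.58) # population formula would give 0.47
  expect_gt(s$sd, 0.5)

  expect_equal(summarize_panel(c(2, 2, 2))$sd, 0)
  expect_equal(summarize_panel(c(2, 2, 2))$mean, 2)

  # oracle: direct n-1 formula
  sc <- c(0, 2, 4)
  expect_equal(
    summarize_panel(sc)$sd,
    sqrt(sum((sc - mean(sc))^2) / (length(sc) - 1))
  )
  expect_equal(summarize_panel(sc)$sd, 2)

  expect_error(summarize_panel(2), class = "kinscore_insufficient_raters_error")
  expect_error(summarize_panel(c(1, 7)), class = "kinscore_domain_error")
})

test_that("rating_summaries summarizes each clip of a tidy ratings table", {
  ratings <- tibble::tibble(
    clip_id = rep(c("a", "b"), each = 3L),
    rater = rep(paste0("r", 1:3), 2L),
    score = c(1, 2, 2, 3, 3, 3)
  )
  out <- rating_summaries(ratings)
  expect_equal(out$mean[out$clip_id == "a"], 5 / 3)
  expect_equal(out$sd[out$clip_id == "b"], 0)
  expect_equal(out$n_raters, c(3L, 3L))
})

test_that("agreement categories follow the all/two-of-three/none definitions", {
  expect_equal(agreement_category(c(2, 2, 2)), "complete")
  expect_equal(agreement_category(c(1, 2, 2)), "majority")
  expect_equal(agreement_category(c(0, 1, 2)), "none")
  # general-n mode: strict majority required
  expect_equal(agreement_category(c(1, 1, 2, 2)), "none")
  expect_equal(agreement_category(c(1, 1, 1, 2, 2)), "majority")
})

test_that("agreement percentages decompose panels and sum to 100", {
  panels <- list(c(1, 1, 1), c(1, 2, 2), c(0, 1, 2), c(3, 3, 3))
  ag <- agreement_percentages(panels)
  expect_equal(ag$complete_pct, 50)
  expect_equal(ag$majority_pct, 25)
  expect_equal(ag$none_pct, 25)
  expect_equal(ag$majority_or_better_pct, 75)
  expect_equal(ag$complete_pct + ag$majority_pct + ag$none_pct, 100)
  expect_error(agreement_percentages(list()), class = "kinscore_empty_input_error")
})

test_that("agreement percentages match exhaustive enumeration of all 125 panels", {
  grid <- expand.grid(r1 = 0:4, r2 = 0:4, r3 = 0:4)
  panels <- lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  # independent oracle: classify by the number of distinct scores
  n_distinct <- vapply(
    panels, function(p) length(unique(p)), integer(1L)
  )
  expect_equal(sum(n_distinct == 1L), 5L)
  expect_equal(sum(n_distinct == 3L), 60L)
  expect_equal(sum(n_distinct == 2L), 60L)

  ag <- agreement_percentages(panels)
  expect_equal(ag$complete_pct, 5 / 125 * 100)
  expect_equal(ag$majority_pct, 60 / 125 * 100)
  expect_equal(ag$none_pct, 60 / 125 * 100)
})

test_that("complexity regression reproduces exact lines and handles minimal input", {
  pts <- data.frame(complexity = c(2, 3, 5, 7), y = -5 * c(2, 3, 5, 7) + 90)
  fit <- suppressWarnings(complexity_regression(pts)) # lm flags the exact fit
  expect_equal(fit$slope, -5, tolerance = 1e-10)
  expect_equal(fit$intercept, 90, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  minimal <- data.frame(complexity = c(2, 2, 7), y = c(80, 82, 40))
  fit2 <- complexity_regression(minimal)
  expect_true(is.finite(fit2$p_value))

  expect_error(
    complexity_regression(data.frame(complexity = c(2, 2, 2), y = 1:3)),
    class = "kinscore_insufficient_data_error"
  )

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "complexity"], -5, tolerance = 1e-10)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-10)
})

test_that("rater panels with complexity-growing noise yield the expected slopes", {
  set.seed(31)
  complexities <- c(2, 3, 5, 7)
  rows <- lapply(complexities, function(cx) {
    panels <- lapply(1:250, function(i) {
      simulate_panel(sample(0:4, 1L), cx,
        rater_biases = rnorm(3, 0, 0.2),
        noise_base = 0.15, noise_per_cue = 0.07
      )
    })
    ag <- agreement_percentages(panels)
    data.frame(
      complexity = cx, complete = ag$complete_pct,
      sd = mean(vapply(panels, sd, numeric(1L)))
    )
  })
  df <- do.call(rbind, rows)
  fit_complete <- complexity_regression(
    data.frame(complexity = df$complexity, y = df$complete)
  )
  fit_sd <- complexity_regression(
    data.frame(complexity = df$complexity, y = df$sd)
  )
  expect_lt(fit_complete$slope, 0)
  expect_gt(fit_sd$slope, 0)
})

test_that("within-one-class accuracy uses the continuous panel mean", {
  expect_equal(within_pm1_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(within_pm1_accuracy(c(2.6, 2.8), c(1.67, 1.67)), 0.5)
  expect_error(within_pm1_accuracy(1:3, 1:2), class = "kinscore_input_error")
  expect_error(
    within_pm1_accuracy(numeric(0), numeric(0)),
    class = "kinscore_empty_input_error"
  )
})

test_that("distribution-aware accuracy reproduces the printed band for a 1,2,2 panel", {
  s <- summarize_panel(c(1, 2, 2))
  # strict mode: band [1.67 - 0.58, 1.67 + 0.58] = [1.09, 2.25]
  expect_equal(
    distribution_aware_accuracy(2.0, s$mean, s$sd, strict_paper = TRUE), 1
  )
  expect_equal(
    distribution_aware_accuracy(1.0, s$mean, s$sd, strict_paper = TRUE), 0
  )
  expect_equal(
    distribution_aware_accuracy(2.26, s$mean, s$sd, strict_paper = TRUE), 0
  )
  expect_equal(
    distribution_aware_accuracy(2.25, s$mean, s$sd, strict_paper = TRUE), 1
  )
})

test_that("distribution-aware accuracy is monotone in band width and floor", {
  set.seed(41)
  mu <- runif(40, 0, 4)
  t <- runif(40, 0, 4)
  sdv <- runif(40, 0, 1.2)
  a1 <- distribution_aware_accuracy(mu, t, sdv, width_k = 1)
  a15 <- distribution_aware_accuracy(mu, t, sdv, width_k = 1.5)
  expect_gte(a15, a1)
  f0 <- distribution_aware_accuracy(mu, t, sdv, sigma_floor = 0)
  f5 <- distribution_aware_accuracy(mu, t, sdv, sigma_floor = 0.5)
  expect_gte(f5, f0)
  # vacuously wide band
  expect_equal(distribution_aware_accuracy(mu, t, rep(10, 40)), 1)
})

test_that("composite scores are additive and the medication contrast counts improvement", {
  expect_equal(composite_score(2), 2)
  expect_equal(composite_score(rep(1, 13)), 13)
  preds <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 4L),
    med_state = rep(c("off", "off", "on", "on"), 2L),
    mu_hat = c(2, 3, 1, 2, 1, 1, 1, 1)
  )
  comp <- composite_scores(preds)
  expect_equal(
    comp$composite[comp$patient_id == "p1" & comp$med_state == "off"], 5
  )
  expect_equal(sum(comp$composite), sum(preds$mu_hat), tolerance = 1e-9)

  ct <- medication_contrast(comp)
  expect_equal(ct$deltas$delta[ct$deltas$patient_id == "p1"], -2)
  expect_equal(ct$deltas$delta[ct$deltas$patient_id == "p2"], 0)
  expect_equal(ct$fraction_improved, 0.5)

  same <- comp
  same$composite[same$med_state == "on"] <-
    same$composite[same$med_state == "off"]
  expect_equal(medication_contrast(same)$fraction_improved, 0)

  unmatched <- comp[comp$med_state == "off", ]
  expect_error(medication_contrast(unmatched), class = "kinscore_input_error")
})
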