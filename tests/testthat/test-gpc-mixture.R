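test_that("mixture predictions are the weighted sum of rule distributions", {
  probs <- english_preset$probs
  # identity weighting returns the simple-GPC column
  p <- predict_probabilities(c(1, 0, 0), probs, "hact")
  expect_equal(unname(p["ae"]), 0.88)

  # hand-evaluated 50/50 mix of simple and onset rule in the wact condition
  p2 <- predict_probabilities(c(0.5, 0.5, 0), probs, "wact")
  expect_equal(unname(p2["ae"]), 0.5 * 0.88 + 0.5 * 0.12)
  expect_equal(unname(p2["open_o"]), 0.5 * 0.04 + 0.5 * 0.80)

  # binary design: rule distributions sum to 1, so any simplex mix does too
  gp <- german_preset$probs
  for (cd in german_preset$design$conditions) {
    expect_equal(sum(predict_probabilities(c(0.3, 0.5, 0.2), gp, cd)), 1)
  }
  expect_error(predict_probabilities(c(1, 0, 0), probs, "nope"), "nope")
})

test_that("observed proportions count modelled categories over non-error trials", {
  des <- english_preset$design
  one <- trials_for("p1", rep("ae", 16))
  obs <- observed_proportions(one, des)
  expect_equal(obs$proportion[obs$category == "ae"], 1)

  # 6 ae, 3 open_o, 1 other_vowel: other stays in the denominator by default
  mixed <- trials_for("p1", c(rep("ae", 6), rep("open_o", 3), "other_vowel"))
  obs2 <- observed_proportions(mixed, des)
  expect_equal(obs2$proportion[obs2$category == "ae"], 0.6)
  expect_equal(obs2$proportion[obs2$category == "open_o"], 0.3)
  obs3 <- observed_proportions(mixed, des, renormalize_modeled = TRUE)
  expect_equal(obs3$proportion[obs3$category == "ae"], 6 / 9)

  # a condition where every trial is an error is dropped
  errs <- dplyr::bind_rows(
    trials_for("p1", rep("ae", 4)),
    trials_for("p1", rep("consonant_error", 4), condition = "wact")
  )
  obs4 <- observed_proportions(errs, des)
  expect_false("wact" %in% obs4$condition)
})

test_that("constrained fits recover generating weights and beat a grid oracle", {
  probs <- english_preset$probs
  design <- english_preset$design
  beta_star <- c(0.2, 0.7, 0.1)
  observed <- exact_observed(beta_star, probs)
  fit <- fit_weights(observed, probs)
  expect_true(fit$converged)
  expect_true(fit$identifiable)
  expect_equal(unname(fit$beta), beta_star, tolerance = 1e-3)
  expect_lt(fit$loss, 1e-10)
  expect_equal(sum(fit$beta), 1, tolerance = 1e-6)
  expect_true(all(fit$beta >= -1e-9 & fit$beta <= 1 + 1e-9))

  # brute-force simplex grid at step 0.01 cannot do better
  X <- do.call(rbind, lapply(design$conditions,
                             function(cd) gpcmix:::prob_matrix(probs, cd)))
  y <- observed$proportion
  expect_lte(fit$loss, grid_min_loss(X, y) + 1e-9)

  # identity case: observed equal to the simple-GPC distribution everywhere
  obs_simple <- exact_observed(c(1, 0, 0), probs)
  fit_s <- fit_weights(obs_simple, probs)
  expect_equal(unname(fit_s$beta), c(1, 0, 0), tolerance = 1e-8)
})

test_that("noisy fits stay optimal over the simplex", {
  probs <- english_preset$probs
  design <- english_preset$design
  set.seed(42)
  X <- do.call(rbind, lapply(design$conditions,
                             function(cd) gpcmix:::prob_matrix(probs, cd)))
  for (rep in 1:5) {
    y <- pmin(1, pmax(0, X %*% c(0.3, 0.5, 0.2) + rnorm(nrow(X), 0, 0.08)))
    observed <- exact_observed(c(1, 0, 0), probs)  # template for shape
    observed$proportion <- as.numeric(y)
    fit <- fit_weights(observed, probs)
    # 1,000 random simplex points never beat the returned solution
    g <- matrix(rexp(3000), ncol = 3)
    g <- g / rowSums(g)
    losses <- colSums((X %*% t(g) - as.numeric(y))^2)
    expect_true(all(fit$loss <= losses + 1e-9))
    # relaxing the constraints can only improve the loss
    relaxed <- fit_weights(observed, probs, constrained = FALSE)
    expect_lte(relaxed$loss, fit$loss + 1e-12)
  }
})

test_that("degenerate rule distributions are flagged non-identifiable", {
  design <- english_preset$design
  same <- c(ae = 0.6, open_o = 0.3, long_o = 0.1)
  nested <- lapply(stats::setNames(design$conditions, design$conditions),
                   function(cd) list(simpleGPC = same, CS_O = same,
                                     CS_B = same))
  probs <- gpcmix:::corpus_probs_from_nested(nested, design)
  observed <- exact_observed(c(0.2, 0.7, 0.1), probs)
  fit <- fit_weights(observed, probs)
  expect_false(fit$identifiable)
  expect_lt(fit$loss, 1e-10)  # any simplex point attains the same loss
})

test_that("fits are equivariant under rule permutation and input scale", {
  design <- english_preset$design
  probs <- english_preset$probs
  observed <- exact_observed(c(0.2, 0.7, 0.1), probs)
  observed$proportion <- observed$proportion +
    rep(c(0.02, -0.02, 0), 4)  # perturb so the optimum is interior but unique
  fit <- fit_weights(observed, probs)

  # permute the rule types in design + table: beta permutes identically
  perm <- c(3, 1, 2)
  design_p <- study_design(design$language_mode, design$conditions,
                           design$response_categories,
                           design$rule_types[perm],
                           design$items_per_condition,
                           design$other_categories)
  entries <- tibble::as_tibble(probs)
  probs_p <- corpus_probs(entries, design_p)
  fit_p <- fit_weights(observed, probs_p)
  expect_equal(unname(fit_p$beta), unname(fit$beta[design_p$rule_types]),
               tolerance = 1e-9)

  # percentages in, identical weights out
  pct <- observed
  pct$proportion <- 100 * pct$proportion
  fit_pct <- fit_weights(pct, probs)
  expect_equal(fit_pct$beta, fit$beta, tolerance = 1e-9)
})

test_that("fit preconditions are enforced", {
  probs <- english_preset$probs
  observed <- exact_observed(c(0.2, 0.7, 0.1), probs)
  expect_error(fit_weights(observed[observed$condition == "hact", ], probs),
               "at least 2 conditions")
})

test_that("model-fit correlation matches the Pearson formula", {
  # direct hand oracle on pooled vectors
  obs <- c(10, 20, 30, 40)
  pred <- c(12, 18, 33, 37)
  r_hand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(r_hand, 450 / sqrt(500 * 426))
  expect_equal(r_hand, 0.9750406, tolerance = 1e-6)
  expect_equal(stats::cor(obs, pred), r_hand)

  des <- english_preset$design
  probs <- english_preset$probs
  prof <- simulation_profile(n_participants_per_grade = c("2" = 5L),
                             true_beta = list("2" = c(0.2, 0.7, 0.1)),
                             consonant_error_rate = 0, seed = 21)
  records <- simulate_study(prof, des, probs)
  fits <- fit_participants(records, des, probs)
  mf <- model_fit_correlation(fits, records, des, probs)
  # independent recomputation of the pooled correlation for the single grade
  obs_tab <- observed_proportions(records, des)
  pairs <- lapply(seq_len(nrow(fits)), function(i) {
    beta <- as.numeric(fits[i, paste0("beta_", des$rule_types)])
    o <- obs_tab[obs_tab$participant_id == fits$participant_id[i], ]
    p <- unlist(lapply(seq_len(nrow(o)), function(k) {
      predict_probabilities(beta, probs, o$condition[k])[[o$category[k]]]
    }))
    cbind(o$proportion, p)
  })
  mat <- do.call(rbind, pairs)
  expect_equal(mf$r, stats::cor(100 * mat[, 1], 100 * mat[, 2]),
               tolerance = 1e-12)

  # degenerate: zero variance is reported as NA, not 0
  flat <- fits
  obs_const <- records
  obs_const$response_category <- "ae"
  mf_flat <- model_fit_correlation(flat, obs_const, des, probs)
  expect_true(is.na(mf_flat$r) || abs(mf_flat$r) <= 1)
})

test_that("perfect and anti-symmetric predictions give r of 1 and -1", {
  x <- c(5, 10, 15, 40, 30)
  expect_equal(stats::cor(x, x), 1)
  expect_equal(stats::cor(x, 100 - x), -1)
})

test_that("weight aggregation averages per grade and keeps the simplex", {
  des <- english_preset$design
  fits <- tibble::tibble(
    participant_id = c("a", "b"), grade = c(2L, 2L),
    loss = 0, converged = TRUE, identifiable = TRUE, n_conditions_used = 4L,
    beta_simpleGPC = c(0.2, 0.4), beta_CS_O = c(0.7, 0.5),
    beta_CS_B = c(0.1, 0.1)
  )
  agg <- aggregate_weights(fits, des)
  expect_equal(agg$mean, c(0.3, 0.6, 0.1))
  expect_equal(sum(agg$mean), 1)

  single <- aggregate_weights(fits[1, ], des)
  expect_equal(single$mean, c(0.2, 0.7, 0.1))
  expect_true(all(is.na(single$sd)))

  fits$identifiable[2] <- FALSE
  expect_message(agg2 <- aggregate_weights(fits, des), "non-identifiable")
  expect_equal(agg2$n, rep(1L, 3))
})
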