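test_that("probabilities softmax-normalize and respect beta = 0 flatness", {
  flat <- mep_markov_params(alpha = c(maintenance_E = 0, maintenance_Mk = 0,
                                      exhaustion = 0),
                            beta = c(maintenance_E = 0, maintenance_Mk = 0,
                                     exhaustion = 0))
  for (g in c(1, 5, 13)) {
    p <- transition_probabilities(flat, g)
    expect_equal(unname(p), rep(0.25, 4), tolerance = 1e-12)
  }
  m <- default_outcome_model()
  for (g in 1:13)
    expect_equal(sum(transition_probabilities(m, g)), 1, tolerance = 1e-12)
  expect_error(transition_probabilities(m, 0), ">= 1")
})

test_that("fitting symmetric data recovers flat quarter probabilities", {
  set.seed(31)
  ev <- data.frame(
    from_state = "start",
    generation = rep(1:6, each = 200),
    outcome = sample(c("expansion", "maintenance_E", "maintenance_Mk",
                       "exhaustion"), 1200, replace = TRUE))
  fit <- mep_markov(ev, shared = TRUE)
  expect_true(fit$converged)
  for (g in c(1, 6)) {
    p <- transition_probabilities(fit, g)
    expect_true(all(abs(p - 0.25) < 0.06))
  }
})

test_that("maximum likelihood recovers known parameters from sequences", {
  truth <- default_outcome_model(2 / 3)
  seqs <- simulate_outcome_sequences(truth, 500, seed = 11)
  fit <- mep_markov(events_from_sequences(seqs), shared = TRUE)
  expect_true(fit$converged)
  for (g in 1:13) {
    expect_true(all(abs(transition_probabilities(fit, g) -
                        transition_probabilities(truth, g)) < 0.05))
  }
  # covariance symmetric positive semidefinite
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-8)
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-10))
})

test_that("degenerate inputs produce warnings, not crashes", {
  one <- data.frame(from_state = "start", generation = 1,
                    outcome = "exhaustion")
  w <- capture_warnings(fit <- mep_markov(one, shared = TRUE))
  expect_true(any(grepl("separation", w)))
  expect_s3_class(fit, "mep_markov")
  # an outcome never observed: boundary warning
  set.seed(4)
  ev <- data.frame(from_state = "start", generation = rep(1:3, each = 50),
                   outcome = sample(c("expansion", "maintenance_E"), 150,
                                    replace = TRUE))
  expect_warning(mep_markov(ev, shared = TRUE), "boundary")
})

test_that("predictions normalize, clamp CIs and contain point estimates", {
  truth <- default_outcome_model()
  seqs <- simulate_outcome_sequences(truth, 300, seed = 21)
  fit <- mep_markov(events_from_sequences(seqs), shared = TRUE)
  pr <- predict(fit, generations = 1:13, interval = "delta")
  sums <- tapply(pr$p, pr$generation, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(pr$lo >= 0 & pr$hi <= 1))
  expect_true(all(pr$lo <= pr$p + 1e-12 & pr$p <= pr$hi + 1e-12))
  # beta = 0: predictions constant in g
  flat <- mep_markov_params(alpha = c(maintenance_E = 0.3,
                                      maintenance_Mk = -0.2,
                                      exhaustion = -1))
  pf <- predict(flat, generations = 1:5, interval = "none")
  for (o in unique(pf$outcome))
    expect_equal(length(unique(round(pf$p[pf$outcome == o], 12))), 1L)
  # bootstrap intervals broadly agree with delta intervals
  prb <- predict(fit, generations = c(1, 7, 13), interval = "bootstrap",
                 nboot = 100, seed = 5)
  prd <- pr[pr$generation %in% c(1, 7, 13), ]
  expect_true(all(abs(prb$lo - prd$lo) < 0.06))
  expect_true(all(abs(prb$hi - prd$hi) < 0.06))
})

test_that("simulated sequences are deterministic, absorbing and truncated", {
  m <- default_outcome_model()
  s1 <- simulate_outcome_sequences(m, 50, seed = 77)
  s2 <- simulate_outcome_sequences(m, 50, seed = 77)
  expect_identical(s1, s2)
  for (s in s1) {
    # exhaustion, if present, is terminal and uncensored
    ix <- which(s$outcome == "exhaustion")
    if (length(ix)) {
      expect_equal(ix, nrow(s))
      expect_false(attr(s, "censored"))
    } else {
      expect_true(attr(s, "censored"))
      expect_equal(nrow(s), 13L)
    }
    expect_equal(s$generation, seq_len(nrow(s)))
  }
  # forced exhaustion: every sequence has length 1
  always <- mep_markov_params(alpha = c(maintenance_E = -30,
                                        maintenance_Mk = -30,
                                        exhaustion = 30))
  for (s in simulate_outcome_sequences(always, 20, seed = 1)) {
    expect_equal(s$outcome, "exhaustion")
  }
})

test_that("empirical outcome frequencies match model probabilities", {
  m <- default_outcome_model()
  ev <- events_from_sequences(simulate_outcome_sequences(m, 4000, seed = 13))
  for (g in c(1, 4, 8)) {
    sub <- ev[ev$generation == g, ]
    emp <- table(factor(sub$outcome, levels = m$outcomes)) / nrow(sub)
    p <- transition_probabilities(m, g)
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_true(all(abs(emp - p) < 4 * se + 1e-3))
  }
})

test_that("reduced model never beats the full model on likelihood", {
  truth <- default_outcome_model()
  ev <- events_from_sequences(simulate_outcome_sequences(truth, 400, seed = 3))
  full <- suppressWarnings(mep_markov(ev, shared = FALSE))
  red <- mep_markov(ev, shared = TRUE)
  expect_gte(full$logLik, red$logLik - 1e-6)
})

test_that("homogeneity test returns zero LR for time-free truth structure", {
  flat <- mep_markov_params(alpha = c(maintenance_E = 0.5,
                                      maintenance_Mk = -0.5,
                                      exhaustion = -1),
                            beta = c(maintenance_E = 0, maintenance_Mk = 0,
                                     exhaustion = 0))
  ev <- events_from_sequences(simulate_outcome_sequences(flat, 400, seed = 8))
  ht <- homogeneity_test(ev)
  expect_s3_class(ht, "htest")
  expect_gte(ht$statistic[["LR"]], 0)
  expect_equal(ht$parameter[["df"]], 3)
  # strong time dependence is detected decisively
  ht2 <- homogeneity_test(events_from_sequences(
    simulate_outcome_sequences(default_outcome_model(), 400, seed = 9)))
  expect_lt(ht2$p.value, 1e-10)
})

test_that("uniform generational-age mixture averages exhaustion probabilities", {
  expect_equal(first_division_exhaustion(rep(1, 13)), 1)
  expect_equal(first_division_exhaustion((1:13) / 13), 7 / 13)
  m <- default_outcome_model()
  direct <- mean(vapply(1:13, function(g)
    transition_probabilities(m, g)[["exhaustion"]], numeric(1)))
  expect_equal(first_division_exhaustion(m), direct)
})
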