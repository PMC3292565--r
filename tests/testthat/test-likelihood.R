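single3 <- itec_model(3, effects_p = "trap")
pars3 <- list(phi = 0.8, p = 0.5, p_aware = 0.6)

test_that("forward likelihood reproduces hand-enumerated path probabilities", {
  # history 11: single live path A -> A, probability phi * pA = 0.48
  m2 <- itec_model(2, effects_p = "trap")
  expect_equal(history_loglik(c(1, 1), pars3, m2), log(0.48),
               tolerance = 1e-12)
  # history 101: unique path A -> U -> A, phi(1-pA) * phi p = 0.128
  expect_equal(exp(history_loglik(c(1, 0, 1), pars3, single3)), 0.128,
               tolerance = 1e-12)
})

test_that("forward algorithm agrees with brute-force path summation", {
  set.seed(42)
  for (K in 4:5) {
    model <- itec_model(K, effects_phi = c("time", "transience"),
                        effects_p = c("time", "trap"))
    for (rep in 1:10) {
      phi1 <- runif(K - 1); phi2 <- runif(K - 1)
      p <- runif(K - 1); pA <- runif(K - 1)
      pars <- list(phi1 = phi1, phi2 = phi2, p = p, p_aware = pA)
      pv <- c(0, p); pAv <- c(0, pA)
      h <- integer(K)
      f <- sample(K - 1, 1)
      h[f] <- 1L
      h[(f + 1):K] <- rbinom(K - f, 1, 0.5)
      expect_equal(history_loglik(h, pars, model),
                   brute_single_loglik(h, phi1, phi2, pv, pAv),
                   tolerance = 1e-12)
      # removed at last capture: brute force drops the tail the same way
      expect_equal(history_loglik(h, pars, model, removed = TRUE),
                   brute_single_loglik(h, phi1, phi2, pv, pAv,
                                       removed = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("pattern likelihoods sum to one over all observable histories", {
  model <- itec_model(4, effects_p = "trap")
  pars <- list(phi = 0.75, p = 0.35, p_aware = 0.62)
  pats <- all_patterns_after_release(4, 1)
  tot <- sum(exp(apply(pats, 1, history_loglik, params = pars,
                       model = model)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("censoring drops the never-seen-again tail", {
  m4 <- itec_model(4, effects_p = "trap")
  pars <- list(phi = 0.8, p = 0.5, p_aware = 0.6)
  h <- c(1, 1, 0, 0)
  expect_gt(history_loglik(h, pars, m4, removed = TRUE),
            history_loglik(h, pars, m4, removed = FALSE))
  # removal at the release occasion leaves nothing to model
  expect_equal(history_loglik(c(0, 1, 0, 0), pars, m4, removed = TRUE), 0)
})

test_that("dataset likelihood weights by count and matches per-history sums", {
  d1 <- encounter_data(c("101", "110", "100"), count = c(3, 2, 1))
  ll <- dataset_loglik(d1, pars3, single3)
  by_hand <- 3 * history_loglik(c(1, 0, 1), pars3, single3) +
    2 * history_loglik(c(1, 1, 0), pars3, single3) +
    1 * history_loglik(c(1, 0, 0), pars3, single3)
  expect_equal(ll, by_hand, tolerance = 1e-12)
  # duplicating a row is the same as incrementing its count
  d2 <- encounter_data(c("101", "101", "101", "110", "110", "100"))
  expect_equal(dataset_loglik(d2, pars3, single3), ll, tolerance = 1e-12)
  # the CJS collapse: pA = p gives the same value with or without trap
  m_cjs <- itec_model(3, effects_p = character())
  pars_cjs <- list(phi = 0.8, p = 0.5)
  expect_equal(dataset_loglik(d1, list(phi = 0.8, p = 0.5, p_aware = 0.5),
                              single3),
               dataset_loglik(d1, pars_cjs, m_cjs), tolerance = 1e-12)
})

test_that("invalid histories and codes are rejected", {
  expect_error(history_loglik(c(0, 0, 0), pars3, single3), "no capture")
  expect_error(history_loglik(c(1, 2, 0), pars3, single3), "code 2")
  expect_error(history_loglik(c(1, 1), pars3, single3), "occasions")
  d <- encounter_data(c("102"))
  expect_error(dataset_loglik(d, pars3, single3), "code 2")
})

test_that("two-state forward agrees with the five-state brute force", {
  model <- itec_model(4, state_space = "two_state")
  set.seed(99)
  for (rep in 1:10) {
    pars <- list(phi = runif(2), p = runif(2), p_aware = runif(2),
                 psi12 = runif(1), psi21 = runif(1))
    h <- integer(4)
    f <- sample(3, 1)
    h[f] <- sample(1:2, 1)
    h[(f + 1):4] <- sample(0:2, 4 - f, replace = TRUE)
    expect_equal(history_loglik(h, pars, model),
                 brute_two_state_loglik(h, pars$phi, pars$p, pars$p_aware,
                                        pars$psi12, pars$psi21),
                 tolerance = 1e-12)
  }
  # free pi1 multiplies in the initial-state term
  pars <- list(phi = c(0.8, 0.7), p = c(0.4, 0.3), p_aware = c(0.6, 0.5),
               psi12 = 0.2, psi21 = 0.1)
  h <- c(2, 0, 1, 0)
  base <- history_loglik(h, pars, model)
  with_pi <- history_loglik(h, c(pars, pi1 = 0.7), model)
  expect_equal(with_pi, base + log(1 - 0.7), tolerance = 1e-12)
})
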