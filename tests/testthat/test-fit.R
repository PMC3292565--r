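# one moderate simulated dataset shared across fitting tests
sim_model <- itec_model(6, effects_p = "trap")
sim_data <- simulate_itec(
  itec_scenario(even_cohorts(400, 6), 6,
                list(phi = 0.8, p = 0.4, p_aware = 0.7), seed = 21))
sim_fit <- itec(sim_data, sim_model)

test_that("maximum-likelihood fit recovers the generating parameters", {
  expect_true(sim_fit$converged)
  truth <- c(phi = 0.8, p = 0.4, pA = 0.7)
  expect_lt(max(abs(sim_fit$estimates - truth)), 0.1)
  # truth inside the 95% Wald interval for this realization
  expect_true(all(sim_fit$ci[, 1] < truth & truth < sim_fit$ci[, 2]))
  expect_equal(sim_fit$aic, -2 * sim_fit$logLik + 2 * sim_fit$npar)
  expect_length(sim_fit$rank_deficient, 0)
})

test_that("the maximum is a fixed point of the optimizer", {
  refit <- itec(sim_data, sim_model, start = sim_fit$coefficients)
  expect_lt(abs(refit$logLik - sim_fit$logLik), 1e-8)
})

test_that("standard accessors behave like other model fits", {
  expect_named(coef(sim_fit), c("phi", "p", "pA"))
  expect_equal(unname(coef(sim_fit, "link")),
               unname(stats::qlogis(coef(sim_fit))))
  ll <- logLik(sim_fit)
  expect_s3_class(ll, "logLik")
  expect_equal(AIC(sim_fit), sim_fit$aic)
  expect_equal(dim(vcov(sim_fit)), c(3, 3))
  ci <- confint(sim_fit)
  expect_true(all(ci[, 1] >= 0 & ci[, 2] <= 1))
  expect_true(all(ci[, 1] < coef(sim_fit) & coef(sim_fit) < ci[, 2]))
  expect_output(print(sim_fit), "trap-awareness states")
  expect_output(print(summary(sim_fit)), "log-likelihood")
})

test_that("terminal parameters of the fully time-dependent CJS are flagged", {
  d <- simulate_itec(itec_scenario(even_cohorts(400, 5), 5,
                                   list(phi = 0.75, p = 0.5), seed = 5))
  fit <- itec(d, itec_model(5, effects_phi = "time", effects_p = "time",
                            censoring = TRUE),
              method = "naive")
  expect_true(all(c("phi[4]", "p[5]") %in% fit$rank_deficient))
  expect_true(all(is.na(fit$ci[c("phi[4]", "p[5]"), ])))
})

test_that("AIC comparison ranks models and refuses mixed data", {
  fit_naive <- itec(sim_data, sim_model, method = "naive")
  tab <- compare_fits(itec = sim_fit, naive = fit_naive)
  expect_s3_class(tab, "itec_aictab")
  expect_equal(tab$dAIC[1], 0)
  # trap effect is strong in the simulation: ITEC ranks first
  expect_equal(tab$method[1], "state")
  # nesting: the constrained model cannot beat the unconstrained loglik
  expect_lte(fit_naive$logLik, sim_fit$logLik)
  one <- compare_fits(sim_fit)
  expect_equal(one$dAIC, 0)
  other <- simulate_itec(itec_scenario(50, 6,
                                       list(phi = 0.8, p = 0.4), seed = 9))
  fit_other <- itec(other, itec_model(6, effects_p = character()))
  expect_error(compare_fits(sim_fit, fit_other), "same data")
})

test_that("mismatched data and model specifications are rejected", {
  expect_error(itec(sim_data, itec_model(7, effects_p = "trap")),
               "occasions")
  d2 <- encounter_data(c("1020", "1100"))
  expect_error(itec(d2, itec_model(4, effects_p = "trap")), "code 2")
  expect_error(itec(d2, itec_model(4, state_space = "two_state"),
                    method = "split"), "single-state")
})

test_that("simulate() on a fit reproduces the release structure", {
  s <- simulate(sim_fit, seed = 2)
  expect_s3_class(s, "encounter_data")
  expect_equal(sum(s$count), sum(sim_data$count))
  cohorts <- function(x) {
    rel <- apply(x$histories > 0, 1, which.max)
    vapply(1:5, function(t) sum(x$count[rel == t]), 0)
  }
  expect_equal(cohorts(s), cohorts(sim_data))
})
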