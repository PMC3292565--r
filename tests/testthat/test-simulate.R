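base_params <- list(phi = 0.8, p = 0.4, p_aware = 0.6)

test_that("deterministic limits of the generative process", {
  d1 <- simulate_itec(itec_scenario(20, 4, list(phi = 1, p = 1), seed = 1))
  expect_true(all(d1$histories == 1L))
  d0 <- simulate_itec(itec_scenario(20, 4, list(phi = 0, p = 0.5),
                                    seed = 1))
  expect_true(all(rowSums(d0$histories) == 1L))
  expect_true(all(d0$histories[, 1] == 1L))
})

test_that("simulation is reproducible by seed", {
  sc <- itec_scenario(even_cohorts(100, 5), 5, base_params, seed = 4)
  a <- simulate_itec(sc)
  b <- simulate_itec(sc)
  expect_identical(a$histories, b$histories)
  expect_identical(a$removed, b$removed)
  c_ <- simulate_itec(sc, seed = 5)
  expect_false(identical(a$histories, c_$histories))
})

test_that("pattern enumeration gives exact probabilities that sum to one", {
  sc <- itec_scenario(100, 3, base_params, seed = 2)
  tab <- history_pattern_probs(sc)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  # seen at 2 (aware at release), then missed while aware
  expect_equal(tab$prob[tab$pattern == "110"],
               0.8 * 0.6 * (1 - 0.8 * 0.6), tolerance = 1e-12)
  # missed at 2 (aware), reverts to unaware, caught at 3
  expect_equal(tab$prob[tab$pattern == "101"],
               0.8 * 0.4 * 0.8 * 0.4, tolerance = 1e-12)
  # pA = p collapses to the closed-form CJS enumeration
  sc_cjs <- itec_scenario(100, 3, list(phi = 0.8, p = 0.4), seed = 2)
  tab_cjs <- history_pattern_probs(sc_cjs)
  phi <- 0.8; p <- 0.4
  expect_equal(tab_cjs$prob[tab_cjs$pattern == "111"], (phi * p)^2)
  expect_equal(tab_cjs$prob[tab_cjs$pattern == "110"],
               phi * p * (1 - phi * p))
  expect_error(history_pattern_probs(
    itec_scenario(10, 6, base_params, seed = 1)), "K <= 5")
})

test_that("empirical pattern frequencies match the exact enumeration", {
  sc <- itec_scenario(20000, 4, base_params, seed = 8)
  d <- simulate_itec(sc)
  pat <- apply(d$histories, 1, paste, collapse = "")
  tab <- history_pattern_probs(sc)
  obs <- vapply(tab$pattern, function(q) sum(pat == q), 0)
  expect_equal(sum(obs), 20000)
  gof <- suppressWarnings(chisq.test(obs, p = tab$prob))
  expect_gt(gof$p.value, 0.001)
  # re-encounter fraction at occasion 2 near phi * pA
  expect_lt(abs(mean(d$histories[, 2]) - 0.8 * 0.6),
            3 * sqrt(0.48 * 0.52 / 20000))
})

test_that("transients depress apparent first-interval survival", {
  tf <- 0.3
  sc <- itec_scenario(30000, 3, base_params, transient_fraction = tf,
                      seed = 12)
  tab <- history_pattern_probs(sc)
  # P(seen at occasion 2) = (1 - tf) * phi * pA
  p2 <- sum(tab$prob[substr(tab$pattern, 2, 2) == "1"])
  expect_equal(p2, (1 - tf) * 0.8 * 0.6, tolerance = 1e-12)
  d <- simulate_itec(sc)
  expect_lt(abs(mean(d$histories[, 2]) - p2), 3 * sqrt(p2 * (1 - p2) / 30000))
})

test_that("two-state simulation respects the generative process", {
  sc <- itec_scenario(15000, 3,
                      list(phi = c(0.9, 0.8), p = c(0.5, 0.4),
                           p_aware = c(0.7, 0.6), psi12 = 0.2, psi21 = 0.1,
                           pi1 = 0.65),
                      state_space = "two_state", seed = 3)
  d <- simulate_itec(sc)
  expect_true(all(d$histories[, 1] %in% 1:2))
  frac1 <- mean(d$histories[, 1] == 1L)
  expect_lt(abs(frac1 - 0.65), 3 * sqrt(0.65 * 0.35 / 15000))
  tab <- history_pattern_probs(sc)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  # release in 1, re-seen in 1 at occasion 2 (pi1 * phi1 * psi11 * pA1),
  # then missed at occasion 3 while trap aware in state 1
  expect_equal(tab$prob[tab$pattern == "110"],
               0.65 * 0.9 * 0.8 * 0.7 *
                 (1 - 0.9 * (0.8 * 0.7 + 0.2 * 0.6)),
               tolerance = 1e-12)
})

test_that("removals censor histories at a capture", {
  sc <- itec_scenario(even_cohorts(500, 5), 5, base_params,
                      removal_prob = 0.2, seed = 44)
  d <- simulate_itec(sc)
  expect_gt(sum(d$removed), 0)
  for (i in which(d$removed)) {
    last <- max(which(d$histories[i, ] > 0))
    expect_true(all(d$histories[i, seq_len(5) > last] == 0L))
  }
})

test_that("scenario validation catches contradictions", {
  expect_error(itec_scenario(10, 4, list(phi = 0.8, p = 0.4, phi1 = 0.5,
                                         phi2 = 0.8),
                             transient_fraction = 0.2), "not both")
  expect_error(itec_scenario(10, 4, list(phi = 0.8, p = 0.4),
                             state_space = "two_state"), "pi1")
  expect_error(itec_scenario(c(5, 5), 4, base_params), "cohort sizes")
})
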