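test_that("single-state composite matrix matches the S.P factorization", {
  b <- single_state_matrices(phi = 0.8, p = 0.5, p_aware = 0.6)
  expect_equal(unname(b$Pi["A", ]), c(0.48, 0.32, 0.20))
  expect_equal(unname(b$Pi["U", ]), c(0.40, 0.40, 0.20))
  expect_equal(b$Pi, b$S %*% b$T %*% b$P)

  # no mortality, no trap effect: A and U rows collapse
  b1 <- single_state_matrices(1, 0.5, 0.5)
  expect_equal(unname(b1$Pi["A", ]), c(0.5, 0.5, 0))
  expect_equal(unname(b1$Pi["U", ]), c(0.5, 0.5, 0))

  # certain death
  b0 <- single_state_matrices(0, 0.5, 0.6)
  expect_equal(unname(b0$Pi["A", ]), c(0, 0, 1))
  expect_equal(unname(b0$Pi["U", ]), c(0, 0, 1))
})

test_that("constructed matrices are row-stochastic with an absorbing dead state", {
  set.seed(11)
  for (i in 1:60) {
    u <- runif(7)
    b <- single_state_matrices(u[1], u[2], u[3])
    for (M in list(b$S, b$T, b$P, b$Pi, b$E))
      expect_equal(rowSums(M), setNames(rep(1, nrow(M)), rownames(M)),
                   tolerance = 1e-12)
    expect_identical(unname(b$Pi["D", "D"]), 1)
    b2 <- two_state_matrices(u[1:2], u[3:4], u[5:6], psi12 = u[7],
                             psi21 = u[1], pi1 = u[2])
    for (M in list(b2$S, b2$T, b2$P, b2$Pi, b2$E))
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
    expect_identical(unname(b2$Pi["D", "D"]), 1)
    expect_equal(sum(b2$init), 1)
    # T preserves awareness: aware states map only to aware states
    expect_equal(unname(b2$T[c("A1", "A2"), c("U1", "U2")]),
                 matrix(0, 2, 2))
    expect_equal(unname(b2$T[c("U1", "U2"), c("A1", "A2")]),
                 matrix(0, 2, 2))
    # P resolves awareness from capture: live rows end aware iff captured
    expect_true(all(b2$P[1:4, 5] == 0))
    # awareness bookkeeping on the composite: mass landing in A-type
    # columns of a live row = survival x capture prob for that awareness
    expect_equal(unname(sum(b$Pi["A", "A"])), u[1] * u[3])
    expect_equal(unname(sum(b$Pi["U", "A"])), u[1] * u[2])
  }
})

test_that("setting pA = p collapses the trap-awareness model to the CJS", {
  b <- single_state_matrices(0.7, 0.45, 0.45)
  expect_equal(unname(b$Pi["A", ]), unname(b$Pi["U", ]))
})

test_that("two-state composite reproduces the worked transition and blocks", {
  b <- two_state_matrices(phi = c(0.8, 0.9), p = c(0.4, 0.5),
                          p_aware = c(0.6, 0.7), psi12 = 0.3, psi21 = 0.1,
                          pi1 = 0.7)
  # survive, stay in state 1, miss capture: phi1 * psi11 * (1 - pA1)
  expect_equal(unname(b$Pi["A1", "U1"]), 0.8 * 0.7 * 0.4)
  expect_equal(b$Pi, b$S %*% b$T %*% b$P)
  expect_equal(unname(b$init), c(0.7, 0, 0.3, 0, 0))
  # degenerate events: A1 -> code 1, A2 -> code 2, others -> 0
  expect_equal(unname(b$E["A1", ]), c(0, 1, 0))
  expect_equal(unname(b$E["A2", ]), c(0, 0, 1))
  expect_equal(unname(b$E[c("U1", "U2", "D"), "0"]), c(1, 1, 1))

  # zero transition probabilities give a block-diagonal composite
  bb <- two_state_matrices(c(0.8, 0.9), c(0.4, 0.5), c(0.6, 0.7),
                           psi12 = 0, psi21 = 0)
  expect_equal(unname(bb$Pi[c("A1", "U1"), c("A2", "U2")]), matrix(0, 2, 2))
  expect_equal(unname(bb$Pi[c("A2", "U2"), c("A1", "U1")]), matrix(0, 2, 2))
})

test_that("additive trap effect acts on the logit of capture", {
  expect_equal(additive_trap_effect(0.5, 0), 0.5)
  expect_equal(additive_trap_effect(0.5, log(9)), 0.9)
  expect_equal(additive_trap_effect(c(0.2, 0.5, 0.8), 40),
               c(1, 1, 1), tolerance = 1e-10)
  # monotone in m
  ms <- seq(-3, 3, by = 0.5)
  vals <- vapply(ms, function(m) additive_trap_effect(0.4, m), 0)
  expect_true(all(diff(vals) > 0))
  expect_error(additive_trap_effect(1, 0.5), "strictly inside")
  expect_error(additive_trap_effect(0, 0.5), "strictly inside")
})

test_that("invalid probabilities are rejected by name", {
  expect_error(single_state_matrices(1.2, 0.5, 0.5), "phi")
  expect_error(single_state_matrices(0.5, -0.1, 0.5), "'p'")
  expect_error(two_state_matrices(0.5, 0.5, 0.5, psi12 = 2, psi21 = 0),
               "psi12")
})
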