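#' Define a simulation scenario
#'
#' Describes the generative process of the trap-awareness model for
#' [simulate_itec()]: release cohort sizes, occasions, true parameters,
#' transients and losses on capture.
#'
#' Transients — newly marked animals that permanently emigrate right after
#' release, depressing apparent first-interval survival — can be specified
#' either as a mixture (`transient_fraction`, with residents surviving at
#' `phi`) or directly through apparent survival classes `phi1`/`phi2` in
#' `params`; the two are mutually exclusive. Under the mixture, apparent
#' first-interval survival is `(1 - transient_fraction) * phi`.
#'
#' @param n_released releases (first captures) per occasion: a vector of
#'   length K-1 for occasions 1..K-1, or a scalar meaning one cohort
#'   released at occasion 1.
#' @param n_occasions number of occasions K.
#' @param params named list of true parameters as in [history_loglik()]:
#'   `phi` (or `phi1`/`phi2`), `p`, `p_aware` (or additive effect `m`);
#'   scalars or vectors of length K-1. Two-state scenarios additionally
#'   need `psi12`, `psi21`, `pi1`.
#' @param state_space `"single"` or `"two_state"`.
#' @param transient_fraction probability that a newly marked animal is a
#'   transient (single-state only).
#' @param removal_prob probability that any capture after release is a
#'   removal (loss on capture).
#' @param seed default integer seed for [simulate_itec()].
#' @return An object of class `"itec_scenario"`.
#' @export
itec_scenario <- function(n_released, n_occasions, params,
                          state_space = c("single", "two_state"),
                          transient_fraction = 0, removal_prob = 0,
                          seed = 1) {
  state_space <- match.arg(state_space)
  K <- as.integer(n_occasions)
  if (K < 2L) stop("'n_occasions' must be >= 2")
  if (length(n_released) == 1L)
    n_released <- c(n_released, rep.int(0L, K - 2L))
  n_released <- as.integer(n_released)
  if (length(n_released) != K - 1L || any(n_released < 0L))
    stop("'n_released' must give nonnegative cohort sizes for occasions 1..K-1")
  if (sum(n_released) == 0L) stop("no animals released")
  check_prob(transient_fraction, "transient_fraction")
  check_prob(removal_prob, "removal_prob")
  if (state_space == "two_state") {
    if (transient_fraction > 0)
      stop("transients are supported for single-state scenarios only")
    if (is.null(params$pi1))
      stop("two-state scenarios require 'pi1' in 'params'")
  }
  if (transient_fraction > 0 &&
      (!is.null(params$phi1) || !is.null(params$phi2)))
    stop("give either 'transient_fraction' or explicit phi1/phi2, not both")
  model <- itec_model(K, state_space, effects_phi =
                        if (!is.null(params$phi1)) "transience"
                        else character(),
                      effects_p = "trap")
  expanded <- normalize_params(params, model)  # validates
  structure(
    list(n_released = n_released, n_occasions = K, params = params,
         expanded = expanded, state_space = state_space,
         transient_fraction = transient_fraction,
         removal_prob = removal_prob, seed = as.integer(seed)),
    class = "itec_scenario")
}

#' @export
print.itec_scenario <- function(x, ...) {
  cat("Simulation scenario (", x$state_space, "-state): ",
      sum(x$n_released), " releases over ", x$n_occasions,
      " occasions\n", sep = "")
  if (x$transient_fraction > 0)
    cat("  transient fraction:", x$transient_fraction, "\n")
  if (x$removal_prob > 0)
    cat("  removal probability per capture:", x$removal_prob, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate encounter histories under the trap-awareness model
#'
#' Draws encounter histories by the exact generative process: each animal
#' starts trap aware at its release occasion (in state of interest 1 or 2
#' with probability `pi1` / `1 - pi1` in the two-state case) and evolves
#' by the survival, state-transition and trap-awareness steps; observation
#' codes follow the degenerate event matrix. An animal that is not caught
#' reverts immediately to trap unaware.
#'
#' One pseudo-random stream drives the whole scenario, consumed in a fixed
#' documented order — cohorts by release occasion, individuals within
#' cohort, occasions within individual; within an occasion: survival,
#' state transition (two-state), capture, removal — so a given seed yields
#' byte-identical output.
#'
#' @param scenario an [itec_scenario()].
#' @param seed integer seed; defaults to the scenario's.
#' @return An [encounter_data()] object with the scenario attached as
#'   attribute `"truth"`.
#' @export
simulate_itec <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "itec_scenario"))
  set.seed(seed)
  K <- scenario$n_occasions
  ex <- scenario$expanded
  two <- scenario$state_space == "two_state"
  tf <- scenario$transient_fraction
  rp <- scenario$removal_prob
  n_total <- sum(scenario$n_released)
  Hs <- matrix(0L, n_total, K)
  rem <- logical(n_total)
  i <- 0L
  for (r in seq_len(K - 1L)) {
    for (k in seq_len(scenario$n_released[r])) {
      i <- i + 1L
      h <- integer(K)
      if (two) {
        s <- if (stats::runif(1) < ex$pi1) 1L else 2L
        h[r] <- s
      } else {
        h[r] <- 1L
        transient <- tf > 0 && stats::runif(1) < tf
      }
      aware <- TRUE
      if (r < K) for (t in (r + 1L):K) {
        if (two) {
          phi_t <- ex$phi[s]
        } else {
          phi_t <- if (t - 1L == r) {
            if (!two && transient) 0 else ex$phi1[t - 1L]
          } else ex$phi2[t - 1L]
        }
        if (stats::runif(1) >= phi_t) break  # dies during the interval
        if (two) {
          sw <- if (s == 1L) ex$psi12 else ex$psi21
          if (stats::runif(1) < sw) s <- 3L - s
          pc <- if (aware) ex$pA[s] else ex$p[s]
        } else {
          pc <- if (aware) ex$pA[t] else ex$p[t]
        }
        caught <- stats::runif(1) < pc
        aware <- caught
        if (caught) {
          h[t] <- if (two) s else 1L
          if (rp > 0 && stats::runif(1) < rp) {
            rem[i] <- TRUE
            break
          }
        }
      }
      Hs[i, ] <- h
    }
  }
  out <- encounter_data(Hs, removed = rem)
  attr(out, "truth") <- scenario
  attr(out, "seed") <- seed
  out
}

#' Exact probabilities of all observable history patterns
#'
#' Enumerates, for each release cohort of a small scenario (K <= 5, no
#' removals), every observable encounter pattern and its exact probability
#' by brute-force summation over all hidden operational-state paths. This
#' is deliberately independent of the forward algorithm and serves as an
#' enumeration oracle: within each release cohort the probabilities sum
#' to 1.
#'
#' @param scenario an [itec_scenario()] with `n_occasions <= 5` and
#'   `removal_prob = 0`.
#' @return A data frame with columns `release`, `pattern` (the codes over
#'   all K occasions as a string) and `prob`.
#' @export
history_pattern_probs <- function(scenario) {
  stopifnot(inherits(scenario, "itec_scenario"))
  K <- scenario$n_occasions
  if (K > 5L) stop("pattern enumeration is limited to K <= 5")
  if (scenario$removal_prob > 0)
    stop("pattern enumeration requires removal_prob = 0")
  ex <- scenario$expanded
  two <- scenario$state_space == "two_state"
  tf <- scenario$transient_fraction
  model <- itec_model(K, scenario$state_space,
                      effects_phi = if (!two) "transience" else character(),
                      effects_p = "trap")
  # per-interval matrices; single-state carries a transient-free phi1
  res <- list()
  for (r in which(scenario$n_released > 0L)) {
    codes <- if (two) 0:2 else 0:1
    tail_pats <- if (r < K)
      as.matrix(expand.grid(rep(list(codes), K - r)))
    else matrix(integer(), 1L, 0L)
    rel_codes <- if (two) 1:2 else 1L
    for (rc in rel_codes) {
      for (q in seq_len(nrow(tail_pats))) {
        pat <- integer(K)
        pat[r] <- rc
        if (r < K) pat[(r + 1L):K] <- tail_pats[q, ]
        pr <- path_sum_prob(pat, r, ex, model)
        if (!two && tf > 0) {
          all_zero <- r == K || all(pat[(r + 1L):K] == 0L)
          pr <- (1 - tf) * pr + tf * as.numeric(all_zero)
        }
        if (two)
          pr <- pr * if (rc == 1L) ex$pi1 else 1 - ex$pi1
        res[[length(res) + 1L]] <-
          data.frame(release = r,
                     pattern = paste(pat, collapse = ""), prob = pr)
      }
    }
  }
  do.call(rbind, res)
}

# Brute-force probability of one observation pattern given release at r:
# explicit sum over every hidden-state path, kept independent of the
# forward recursion.
path_sum_prob <- function(pat, r, expanded, model) {
  K <- model$n_occasions
  n_states <- if (model$state_space == "two_state") 5L else 3L
  init_state <- if (model$state_space == "two_state") {
    if (pat[r] == 1L) 1L else 3L
  } else 1L
  if (r == K) return(1)
  steps <- K - r
  paths <- as.matrix(expand.grid(rep(list(seq_len(n_states)), steps)))
  total <- 0
  for (q in seq_len(nrow(paths))) {
    z <- c(init_state, paths[q, ])
    pr <- 1
    for (s in seq_len(steps)) {
      t <- r + s
      M <- interval_matrices(expanded, t, model,
                             first_interval = (s == 1L))
      pr <- pr * M$Pi[z[s], z[s + 1L]] *
        M$E[z[s + 1L], as.character(pat[t])]
      if (pr == 0) break
    }
    total <- total + pr
  }
  total
}
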