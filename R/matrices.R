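#' Per-occasion matrices of the single-state trap-awareness model
#'
#' Builds the hidden-Markov building blocks of the immediate-trap-effect
#' model over the operational states (A, U, D): trap aware, trap unaware,
#' dead. States are assessed at the end of each capture session; an animal
#' is trap aware at the end of a session if and only if it was captured
#' during that session.
#'
#' The one-interval transition factorizes as `Pi = S %*% P`, where the
#' survival process `S` acts between sessions and the trap-awareness
#' process `P` resolves capture (and hence awareness) at the next session:
#' row A of `Pi` is `(phi * pA, phi * (1 - pA), 1 - phi)` and row U is
#' `(phi * p, phi * (1 - p), 1 - phi)`. The initial state at release is A
#' with probability 1, and the event matrix `E` is degenerate: state A
#' emits code 1 ("encountered"), states U and D emit code 0.
#'
#' @param phi survival probability over the interval, in `[0, 1]`.
#' @param p capture probability of trap-unaware animals, in `[0, 1]`.
#' @param p_aware capture probability of trap-aware animals (default `p`,
#'   which collapses the model to the CJS).
#' @return A list of class `"itec_matrices"` with elements `S`, `T`
#'   (identity here), `P`, `Pi = S %*% T %*% P`, `E` (states x events) and
#'   `init`, all over states `c("A", "U", "D")` in that fixed order.
#' @examples
#' b <- single_state_matrices(phi = 0.8, p = 0.5, p_aware = 0.6)
#' b$Pi  # row A: 0.48 0.32 0.20; row U: 0.40 0.40 0.20
#' @export
single_state_matrices <- function(phi, p, p_aware = p) {
  check_prob(phi, "phi")
  check_prob(p, "p")
  check_prob(p_aware, "p_aware")
  st <- c("A", "U", "D")
  S <- rbind(c(phi, 0, 1 - phi),
             c(0, phi, 1 - phi),
             c(0, 0, 1))
  Tm <- diag(3)
  P <- rbind(c(p_aware, 1 - p_aware, 0),
             c(p, 1 - p, 0),
             c(0, 0, 1))
  E <- rbind(c(0, 1),   # A: just captured
             c(1, 0),   # U: not captured
             c(1, 0))   # D: not captured
  dimnames(S) <- dimnames(Tm) <- dimnames(P) <- list(st, st)
  dimnames(E) <- list(st, c("0", "1"))
  init <- c(A = 1, U = 0, D = 0)
  structure(list(S = S, T = Tm, P = P, Pi = S %*% Tm %*% P, E = E,
                 init = init),
            class = "itec_matrices")
}

#' Per-occasion matrices of the two-state trap-awareness model
#'
#' Builds the hidden-Markov building blocks of the multistate
#' immediate-trap-effect model over the five operational states
#' (A1, U1, A2, U2, D): trap awareness crossed with two states of interest
#' (e.g. two sites or breeding states), plus dead. The one-interval
#' transition factorizes into three steps, `Pi = S %*% T %*% P`: survival
#' `S` (state-specific), the transition `T` between states of interest
#' (which preserves awareness and takes place by the end of the interval),
#' and the trap-awareness process `P` that resolves capture at the next
#' session. For example, the entry A1 -> U1 of `Pi` is
#' `phi1 * psi11 * (1 - pA1)`: survive, stay in state 1, and miss capture.
#'
#' At initial release an animal is necessarily trap aware, in state of
#' interest 1 with probability `pi1`: `init = (pi1, 0, 1 - pi1, 0, 0)`.
#' The state of interest of a captured animal is recognized without error,
#' so the event matrix is degenerate: A1 emits code 1, A2 emits code 2,
#' and U1, U2, D emit code 0.
#'
#' @param phi survival probabilities, length 2 (state 1, state 2) or a
#'   scalar recycled to both states.
#' @param p capture probabilities of trap-unaware animals, length 2 or
#'   scalar.
#' @param p_aware capture probabilities of trap-aware animals, length 2 or
#'   scalar (default `p`).
#' @param psi12,psi21 transition probabilities between the states of
#'   interest (`psi11 = 1 - psi12`, `psi22 = 1 - psi21`).
#' @param pi1 probability that an initial release is in state of
#'   interest 1.
#' @return A list of class `"itec_matrices"` with elements `S`, `T`, `P`,
#'   `Pi`, `E` and `init` over states `c("A1","U1","A2","U2","D")` in that
#'   fixed order; events are codes `c("0","1","2")`.
#' @examples
#' b <- two_state_matrices(phi = c(0.8, 0.9), p = 0.4, p_aware = 0.6,
#'                         psi12 = 0.3, psi21 = 0.1, pi1 = 0.7)
#' b$Pi["A1", "U1"]  # 0.8 * 0.7 * 0.4 = 0.224
#' @export
two_state_matrices <- function(phi, p, p_aware = p, psi12, psi21, pi1 = 1) {
  phi <- rep_len(phi, 2L); p <- rep_len(p, 2L)
  p_aware <- rep_len(p_aware, 2L)
  check_prob(phi, "phi")
  check_prob(p, "p")
  check_prob(p_aware, "p_aware")
  check_prob(psi12, "psi12")
  check_prob(psi21, "psi21")
  check_prob(pi1, "pi1")
  st <- c("A1", "U1", "A2", "U2", "D")
  S <- rbind(c(phi[1], 0, 0, 0, 1 - phi[1]),
             c(0, phi[1], 0, 0, 1 - phi[1]),
             c(0, 0, phi[2], 0, 1 - phi[2]),
             c(0, 0, 0, phi[2], 1 - phi[2]),
             c(0, 0, 0, 0, 1))
  Tm <- rbind(c(1 - psi12, 0, psi12, 0, 0),
              c(0, 1 - psi12, 0, psi12, 0),
              c(psi21, 0, 1 - psi21, 0, 0),
              c(0, psi21, 0, 1 - psi21, 0),
              c(0, 0, 0, 0, 1))
  P <- rbind(c(p_aware[1], 1 - p_aware[1], 0, 0, 0),
             c(p[1], 1 - p[1], 0, 0, 0),
             c(0, 0, p_aware[2], 1 - p_aware[2], 0),
             c(0, 0, p[2], 1 - p[2], 0),
             c(0, 0, 0, 0, 1))
  E <- rbind(c(0, 1, 0),
             c(1, 0, 0),
             c(0, 0, 1),
             c(1, 0, 0),
             c(1, 0, 0))
  dimnames(S) <- dimnames(Tm) <- dimnames(P) <- list(st, st)
  dimnames(E) <- list(st, c("0", "1", "2"))
  init <- c(A1 = pi1, U1 = 0, A2 = 1 - pi1, U2 = 0, D = 0)
  structure(list(S = S, T = Tm, P = P, Pi = S %*% Tm %*% P, E = E,
                 init = init),
            class = "itec_matrices")
}

#' @export
print.itec_matrices <- function(x, digits = 4, ...) {
  cat("One-interval matrices of the trap-awareness model (Pi = S T P)\n")
  cat("Composite transition Pi:\n")
  print(round(x$Pi, digits))
  cat("Event matrix E (states x codes):\n")
  print(x$E)
  cat("Initial state:", paste(names(x$init), round(x$init, digits),
                              sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Additive trap effect on the logit of capture
#'
#' Applies a shared trap effect `m` on the logit scale to a vector of
#' time-varying capture probabilities of trap-unaware animals, giving the
#' capture probabilities of trap-aware animals:
#' `logit(pA_t) = logit(p_t) + m`. Positive `m` is trap-happiness,
#' negative `m` trap-shyness, `m = 0` no trap effect.
#'
#' @param p vector of capture probabilities, each strictly inside (0, 1).
#' @param m additive effect on the logit scale (any real).
#' @return Vector of trap-aware capture probabilities, same length as `p`.
#' @examples
#' additive_trap_effect(0.5, log(9))      # 0.9
#' additive_trap_effect(c(0.2, 0.5), 0)   # unchanged
#' @export
additive_trap_effect <- function(p, m) {
  if (anyNA(p) || any(p <= 0 | p >= 1))
    stop("parameter 'p' must lie strictly inside (0, 1): logit undefined at 0 and 1")
  if (!is.numeric(m) || length(m) != 1L || is.na(m))
    stop("parameter 'm' must be a single real number")
  stats::plogis(stats::qlogis(p) + m)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop("parameter '", name, "' must be a probability in [0, 1]")
  invisible(x)
}

# Interval matrices used by the forward recursions; params in the
# expanded form of param_layout()/normalize_params(). For single-state,
# occasion indexes the capture session at the interval's end.
interval_matrices <- function(params, occasion, model,
                              first_interval = FALSE) {
  if (model$state_space == "two_state") {
    two_state_matrices(params$phi, params$p, params$pA,
                       params$psi12, params$psi21,
                       if (is.na(params$pi1)) 1 else params$pi1)
  } else {
    phi <- if (first_interval) params$phi1[occasion - 1L]
           else params$phi2[occasion - 1L]
    single_state_matrices(phi, params$p[occasion], params$pA[occasion])
  }
}
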