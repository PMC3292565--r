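#' Log-likelihood of one encounter history
#'
#' Exact conditional log-likelihood of a single encounter history under the
#' trap-awareness hidden Markov model, computed by the forward algorithm.
#' The likelihood conditions on the first capture (CJS-style): the animal
#' is released trap aware, and only the observations strictly after first
#' capture contribute. For a removed (censored) animal the recursion stops
#' at the removal occasion, so no never-seen-again terms are added.
#'
#' For the two-state model the recursion conditions on the observed state
#' of interest at release (states are recognized without error). When
#' `params$pi1` is supplied, the initial-state term `pi1` or `1 - pi1` is
#' included as well; by default it is omitted, i.e. treated as conditioned
#' out (the release state being observed).
#'
#' @param history integer vector of codes over the K occasions.
#' @param params named list of natural-scale parameters: `phi` (or `phi1`
#'   and `phi2` for the transient model), `p`, and either `p_aware` or an
#'   additive logit trap effect `m`; scalars or time-varying vectors of
#'   length K-1. Two-state models take `phi`, `p`, `p_aware` (length 2 or
#'   scalar), `psi12`, `psi21` and optionally `pi1`.
#' @param model an [itec_model()] specification.
#' @param removed logical: censored (lost) at its last capture.
#' @return The log-likelihood (a single number; `-Inf` is possible at
#'   boundary parameter values).
#' @examples
#' m <- itec_model(3, effects_p = "trap")
#' pars <- list(phi = 0.8, p = 0.5, p_aware = 0.6)
#' # unique live path A -> U -> A: 0.8*(1-0.6) * 0.8*0.5 = 0.128
#' exp(history_loglik(c(1, 0, 1), pars, m))
#' @export
history_loglik <- function(history, params, model, removed = FALSE) {
  history <- as.integer(history)
  K <- model$n_occasions
  if (length(history) != K)
    stop("history length ", length(history), " does not match the model's ",
         K, " occasions")
  if (!any(history > 0L)) stop("history contains no capture")
  if (model$state_space == "single" && any(history == 2L))
    stop("code 2 encountered in a single-state model")
  pp <- normalize_params(params, model)
  f <- which(history > 0L)[1L]
  last <- if (removed && model$censoring) max(which(history > 0L)) else K
  # initial state conditional on the observed release code
  init_term <- 0
  if (model$state_space == "two_state") {
    alpha <- if (history[f] == 1L) c(1, 0, 0, 0, 0) else c(0, 0, 1, 0, 0)
    if (!is.na(pp$pi1))
      init_term <- log(if (history[f] == 1L) pp$pi1 else 1 - pp$pi1)
  } else {
    alpha <- c(1, 0, 0)
  }
  if (last > f) {
    for (t in (f + 1L):last) {
      M <- interval_matrices(pp, t, model, first_interval = (t == f + 1L))
      alpha <- drop(alpha %*% M$Pi) * M$E[, as.character(history[t])]
    }
  }
  init_term + log(sum(alpha))
}

#' Log-likelihood of an encounter dataset
#'
#' Sum of per-history conditional log-likelihoods weighted by row counts.
#'
#' @param data an [encounter_data()] object.
#' @param params natural-scale parameter list, as in [history_loglik()].
#' @param model an [itec_model()] specification.
#' @return The total log-likelihood.
#' @export
dataset_loglik <- function(data, params, model) {
  stopifnot(inherits(data, "encounter_data"))
  if (data$n_occasions != model$n_occasions)
    stop("data has ", data$n_occasions, " occasions but the model expects ",
         model$n_occasions)
  pp <- normalize_params(params, model)
  nll <- make_state_nll(data, model)
  ll <- -nll(expanded = pp)
  if (is.na(ll)) {
    # locate the offending history for a usable message
    for (i in seq_len(nrow(data$histories))) {
      li <- history_loglik(data$histories[i, ], params, model,
                           removed = data$removed[i])
      if (is.na(li))
        stop("non-finite likelihood for history ",
             paste(data$histories[i, ], collapse = ""))
    }
  }
  ll
}

# Builds the vectorized negative log-likelihood used by the optimizer.
# Returns a function of a link-scale vector theta (or, alternatively, of a
# pre-expanded parameter list) evaluating -sum(count * loglik).
make_state_nll <- function(data, model) {
  if (model$state_space == "single" && any(data$histories == 2L))
    stop("code 2 encountered in a single-state model")
  agg <- aggregate_histories(data)
  H <- agg$histories
  w <- agg$count
  K <- model$n_occasions
  f <- first_capture(H)
  last <- ifelse(agg$removed & model$censoring, last_capture(H), K)
  layout <- param_layout(model)
  if (model$state_space == "two_state") {
    n <- nrow(H)
    # event-conditioning masks by code, states (A1,U1,A2,U2,D)
    Em <- rbind(`0` = c(0, 1, 0, 1, 1),
                `1` = c(1, 0, 0, 0, 0),
                `2` = c(0, 0, 1, 0, 0))
    release_code <- H[cbind(seq_len(n), f)]
    function(theta = NULL, expanded = layout$expand(theta)) {
      Pi <- two_state_matrices(expanded$phi, expanded$p, expanded$pA,
                               expanded$psi12, expanded$psi21)$Pi
      alpha <- matrix(0, n, 5L)
      # release conditions on the observed state: A1 for code 1, A2 for 2
      alpha[cbind(seq_len(n), ifelse(release_code == 1L, 1L, 3L))] <- 1
      for (t in 2:K) {
        act <- f < t & t <= last
        if (!any(act)) next
        B <- alpha[act, , drop = FALSE] %*% Pi
        alpha[act, ] <- B * Em[H[act, t] + 1L, , drop = FALSE]
      }
      L <- rowSums(alpha)
      -sum(w * log(pmax(L, 1e-300)))
    }
  } else {
    cap <- H > 0L
    function(theta = NULL, expanded = layout$expand(theta)) {
      phi1 <- expanded$phi1; phi2 <- expanded$phi2
      p <- expanded$p; pA <- expanded$pA
      aA <- rep.int(1, length(w)); aU <- aD <- rep.int(0, length(w))
      for (t in 2:K) {
        act <- f < t & t <= last
        if (!any(act)) next
        phi_t <- ifelse(f[act] == t - 1L, phi1[t - 1L], phi2[t - 1L])
        sA <- aA[act] * phi_t
        sU <- aU[act] * phi_t
        sD <- aD[act] + (aA[act] + aU[act]) * (1 - phi_t)
        seen <- cap[act, t]
        aA[act] <- ifelse(seen, sA * pA[t] + sU * p[t], 0)
        aU[act] <- ifelse(seen, 0, sA * (1 - pA[t]) + sU * (1 - p[t]))
        aD[act] <- ifelse(seen, 0, sD)
      }
      L <- aA + aU + aD
      -sum(w * log(pmax(L, 1e-300)))
    }
  }
}
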