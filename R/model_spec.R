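#' Specify an immediate-trap-effect capture-recapture model
#'
#' Declares the state space and the effects acting on survival and capture
#' probabilities of an open-population model with an immediate trap effect
#' on capture (ITEC): a trap response that lasts exactly one occasion, after
#' which a missed animal reverts to its naive, trap-unaware state.
#'
#' Effects on survival (`effects_phi`):
#' \describe{
#'   \item{`"time"`}{one survival probability per interval.}
#'   \item{`"transience"`}{two survival classes by time since first
#'     release: `phi1` for the first interval after initial marking
#'     (depressed by transients that permanently emigrate) and `phi2`
#'     afterwards.}
#' }
#' Effects on capture (`effects_p`):
#' \describe{
#'   \item{`"trap"`}{trap-aware animals (captured at the previous occasion)
#'     have their own capture probability `pA` distinct from the unaware
#'     `p`. Without `"trap"` the model is the naive Cormack-Jolly-Seber
#'     (CJS) model with `pA == p`.}
#'   \item{`"time"`}{one capture probability per occasion (occasions
#'     2..K).}
#'   \item{`"additive"`}{trap and time act additively on the logit:
#'     `logit(pA_t) = logit(p_t) + m` with a single trap effect `m` shared
#'     across occasions. Requires both `"time"` and `"trap"`.}
#' }
#'
#' The two-state model crosses trap awareness with two states of interest
#' (e.g. two sites or breeding states), giving operational states
#' A1, U1, A2, U2, dead, with state-specific survival and capture
#' probabilities and transition probabilities `psi12`, `psi21` between the
#' states of interest. The two-state surface is constant-parameter only.
#'
#' @param n_occasions integer number of capture occasions K (>= 2).
#' @param state_space `"single"` or `"two_state"`.
#' @param effects_phi subset of `c("time", "transience")`.
#' @param effects_p subset of `c("time", "trap", "additive")`.
#' @param censoring honor loss-on-capture (removal) flags (default TRUE).
#' @return An object of class `"itec_model"`.
#' @examples
#' # the model of a classic trap-dependence analysis with transients:
#' # two survival classes, time-dependent capture, additive trap effect
#' itec_model(10, effects_phi = "transience",
#'            effects_p = c("time", "trap", "additive"))
#' @export
itec_model <- function(n_occasions,
                       state_space = c("single", "two_state"),
                       effects_phi = character(),
                       effects_p = "trap",
                       censoring = TRUE) {
  state_space <- match.arg(state_space)
  K <- as.integer(n_occasions)
  if (is.na(K) || K < 2L) stop("'n_occasions' must be an integer >= 2")
  effects_phi <- as.character(effects_phi)
  effects_p <- as.character(effects_p)
  if (!all(effects_phi %in% c("time", "transience")))
    stop("'effects_phi' must be a subset of c(\"time\", \"transience\")")
  if (!all(effects_p %in% c("time", "trap", "additive")))
    stop("'effects_p' must be a subset of c(\"time\", \"trap\", \"additive\")")
  if ("additive" %in% effects_p &&
      !all(c("time", "trap") %in% effects_p))
    stop("an additive trap effect requires both \"time\" and \"trap\" in 'effects_p'")
  if (state_space == "two_state" &&
      (length(effects_phi) || length(setdiff(effects_p, "trap"))))
    stop("the two-state model supports constant parameters only ",
         "(effects_p = \"trap\" or none)")
  structure(
    list(n_occasions = K, state_space = state_space,
         effects_phi = sort(effects_phi), effects_p = sort(effects_p),
         censoring = isTRUE(censoring)),
    class = "itec_model")
}

#' @export
print.itec_model <- function(x, ...) {
  eff <- function(e) if (length(e)) paste(e, collapse = " + ") else "constant"
  cat("ITEC model specification\n")
  cat("  occasions:  ", x$n_occasions, "\n", sep = "")
  cat("  state space:", if (x$state_space == "single")
    " A / U / dead" else " A1 / U1 / A2 / U2 / dead", "\n", sep = "")
  cat("  survival:   ", eff(x$effects_phi), "\n", sep = "")
  cat("  capture:    ", eff(x$effects_p),
      if (!"trap" %in% x$effects_p) "  [naive CJS: pA = p]", "\n", sep = "")
  layout <- param_layout(x)
  cat("  parameters: ", length(layout$names), " (",
      paste(layout$names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Internal description of the free parameter vector implied by a model:
# names, link per parameter ("logit" or "identity"), and an expand()
# mapping the link-scale vector theta to per-occasion natural parameters.
#
# Single-state expansion returns:
#   phi1: length K-1, survival over interval t for an animal in its first
#         interval after marking (equals phi2 without transience)
#   phi2: length K-1, survival over interval t otherwise
#   p:    length K, capture probability of trap-unaware animals at occasion
#         t (p[1] unused: the likelihood conditions on first capture)
#   pA:   length K, capture probability of trap-aware animals
# Two-state expansion returns state-indexed scalars:
#   phi, p, pA (each length 2), psi12, psi21, pi1.
param_layout <- function(model) {
  K <- model$n_occasions
  if (model$state_space == "two_state") {
    nm <- c("phi[s1]", "phi[s2]", "p[s1]", "p[s2]")
    trap <- "trap" %in% model$effects_p
    if (trap) nm <- c(nm, "pA[s1]", "pA[s2]")
    nm <- c(nm, "psi12", "psi21")
    expand <- function(theta) {
      pr <- stats::plogis(theta)
      phi <- pr[1:2]; p <- pr[3:4]
      pA <- if (trap) pr[5:6] else p
      k <- if (trap) 6L else 4L
      list(phi = phi, p = p, pA = pA,
           psi12 = pr[k + 1L], psi21 = pr[k + 2L], pi1 = NA_real_)
    }
    return(list(names = nm, link = rep("logit", length(nm)),
                expand = expand))
  }
  time_phi <- "time" %in% model$effects_phi
  trans <- "transience" %in% model$effects_phi
  time_p <- "time" %in% model$effects_p
  trap <- "trap" %in% model$effects_p
  addi <- "additive" %in% model$effects_p

  ivl <- seq_len(K - 1L)
  occ <- 2:K
  nm_phi <-
    if (trans && time_phi) c(sprintf("phi1[%d]", ivl), sprintf("phi2[%d]", ivl))
    else if (trans) c("phi1", "phi2")
    else if (time_phi) sprintf("phi[%d]", ivl)
    else "phi"
  nm_p <- if (time_p) sprintf("p[%d]", occ) else "p"
  nm_trap <-
    if (!trap) character()
    else if (addi) "m"
    else if (time_p) sprintf("pA[%d]", occ)
    else "pA"
  nm <- c(nm_phi, nm_p, nm_trap)
  link <- rep("logit", length(nm))
  if (addi && trap) link[length(link)] <- "identity"
  n_phi <- length(nm_phi)
  n_p <- length(nm_p)
  expand <- function(theta) {
    th_phi <- theta[seq_len(n_phi)]
    th_p <- theta[n_phi + seq_len(n_p)]
    th_trap <- theta[n_phi + n_p + seq_len(length(nm_trap))]
    if (trans && time_phi) {
      phi1 <- stats::plogis(th_phi[ivl])
      phi2 <- stats::plogis(th_phi[K - 1L + ivl])
    } else if (trans) {
      phi1 <- rep.int(stats::plogis(th_phi[1L]), K - 1L)
      phi2 <- rep.int(stats::plogis(th_phi[2L]), K - 1L)
    } else {
      phi2 <- if (time_phi) stats::plogis(th_phi)
              else rep.int(stats::plogis(th_phi), K - 1L)
      phi1 <- phi2
    }
    lp <- if (time_p) c(NA_real_, th_p) else rep.int(th_p, K)
    p <- stats::plogis(lp)
    pA <- if (!trap) p
          else if (addi) stats::plogis(lp + th_trap)
          else if (time_p) stats::plogis(c(NA_real_, th_trap))
          else rep.int(stats::plogis(th_trap), K)
    list(phi1 = phi1, phi2 = phi2, p = p, pA = pA)
  }
  list(names = nm, link = link, expand = expand)
}

# Map a user-supplied natural-scale parameter list (phi or phi1/phi2, p,
# p_aware or m, psi12/psi21/pi1 for two-state) onto the expanded form used
# by the likelihood. Scalars are recycled; time-varying vectors must have
# length K-1 (survival, by interval) or K-1 (capture, occasions 2..K).
normalize_params <- function(params, model) {
  K <- model$n_occasions
  getp <- function(name, default = NULL) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  chk <- function(x, name, lo = 0, hi = 1) {
    if (anyNA(x) || any(x < lo | x > hi))
      stop("parameter '", name, "' outside [", lo, ", ", hi, "]")
    x
  }
  if (model$state_space == "two_state") {
    need <- function(name) {
      v <- getp(name)
      if (is.null(v)) stop("two-state model requires parameter '", name, "'")
      v
    }
    phi <- chk(rep_len(need("phi"), 2L), "phi")
    p <- chk(rep_len(need("p"), 2L), "p")
    pA <- if ("trap" %in% model$effects_p)
      chk(rep_len(need("p_aware"), 2L), "p_aware") else p
    psi12 <- chk(need("psi12"), "psi12")
    psi21 <- chk(need("psi21"), "psi21")
    pi1 <- getp("pi1", NA_real_)
    if (!is.na(pi1)) chk(pi1, "pi1")
    return(list(phi = phi, p = p, pA = pA,
                psi12 = psi12, psi21 = psi21, pi1 = pi1))
  }
  stretch <- function(x, len, name) {
    if (length(x) == 1L) rep.int(x, len)
    else if (length(x) == len) x
    else stop("parameter '", name, "' must have length 1 or ", len)
  }
  if (!is.null(params$phi1) || !is.null(params$phi2)) {
    phi1 <- chk(stretch(getp("phi1"), K - 1L, "phi1"), "phi1")
    phi2 <- chk(stretch(getp("phi2"), K - 1L, "phi2"), "phi2")
  } else {
    phi2 <- chk(stretch(getp("phi"), K - 1L, "phi"), "phi")
    phi1 <- phi2
  }
  p_in <- getp("p")
  if (is.null(p_in)) stop("parameter 'p' is required")
  p <- c(NA_real_, chk(stretch(p_in, K - 1L, "p"), "p"))
  if (!is.null(params$m)) {
    pA <- c(NA_real_, additive_trap_effect(p[-1L], params$m))
  } else if (!is.null(params$p_aware)) {
    pA <- c(NA_real_, chk(stretch(getp("p_aware"), K - 1L, "p_aware"),
                          "p_aware"))
  } else {
    pA <- p
  }
  p[1L] <- pA[1L] <- 0  # occasion-1 capture never enters the likelihood
  list(phi1 = phi1, phi2 = phi2, p = p, pA = pA)
}
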