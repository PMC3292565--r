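# Brute-force likelihood oracles: explicit summation over every hidden
# operational-state path, with the transition entries written out by hand.
# Deliberately independent of the package's forward recursion and matrix
# builders.

# Single-state oracle. phi1/phi2 vectors of length K-1 (phi1 applies to
# the first interval after first release), p/pA vectors of length K
# indexed by occasion.
brute_single_loglik <- function(h, phi1, phi2, p, pA, removed = FALSE) {
  K <- length(h)
  f <- which(h > 0)[1]
  last <- if (removed) max(which(h > 0)) else K
  if (last == f) return(0)
  steps <- last - f
  # states: 1 = A, 2 = U, 3 = D
  paths <- as.matrix(expand.grid(rep(list(1:3), steps)))
  total <- 0
  for (q in seq_len(nrow(paths))) {
    z <- c(1L, paths[q, ])
    pr <- 1
    for (s in seq_len(steps)) {
      t <- f + s
      phi <- if (s == 1) phi1[t - 1] else phi2[t - 1]
      pi_entry <- switch(paste(z[s], z[s + 1]),
        "1 1" = phi * pA[t], "1 2" = phi * (1 - pA[t]), "1 3" = 1 - phi,
        "2 1" = phi * p[t],  "2 2" = phi * (1 - p[t]),  "2 3" = 1 - phi,
        "3 3" = 1, 0)
      emit <- if (h[t] == 1) as.numeric(z[s + 1] == 1)
              else as.numeric(z[s + 1] != 1)
      pr <- pr * pi_entry * emit
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

# Two-state oracle with constant, state-specific parameters. States:
# 1 = A1, 2 = U1, 3 = A2, 4 = U2, 5 = D.
brute_two_state_loglik <- function(h, phi, p, pA, psi12, psi21,
                                   removed = FALSE) {
  K <- length(h)
  f <- which(h > 0)[1]
  last <- if (removed) max(which(h > 0)) else K
  start <- if (h[f] == 1) 1L else 3L
  if (last == f) return(0)
  steps <- last - f
  trans <- function(a, b) {
    # survival by state of interest, then psi transition (awareness
    # preserved), then capture resolution
    soi <- function(s) if (s <= 2) 1L else 2L
    aware <- function(s) s %in% c(1L, 3L)
    if (a == 5L) return(as.numeric(b == 5L))
    if (b == 5L) return(1 - phi[soi(a)])
    pr <- phi[soi(a)]
    pr <- pr * if (soi(a) == 1L) {
      if (soi(b) == 2L) psi12 else 1 - psi12
    } else {
      if (soi(b) == 1L) psi21 else 1 - psi21
    }
    pcap <- if (aware(a)) pA[soi(b)] else p[soi(b)]
    pr * if (aware(b)) pcap else 1 - pcap
  }
  emit <- function(s, code) {
    obs <- c(1L, 0L, 2L, 0L, 0L)[s]
    as.numeric(obs == code)
  }
  paths <- as.matrix(expand.grid(rep(list(1:5), steps)))
  total <- 0
  for (q in seq_len(nrow(paths))) {
    z <- c(start, paths[q, ])
    pr <- 1
    for (s in seq_len(steps)) {
      pr <- pr * trans(z[s], z[s + 1]) * emit(z[s + 1], h[f + s])
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

# All binary observation patterns of length K with a 1 in position r.
all_patterns_after_release <- function(K, r) {
  tails <- as.matrix(expand.grid(rep(list(0:1), K - r)))
  pats <- matrix(0L, nrow(tails), K)
  pats[, r] <- 1L
  if (K > r) pats[, (r + 1):K] <- as.matrix(tails)
  pats
}

# Equal release cohorts over occasions 1..K-1 summing to n.
even_cohorts <- function(n, K) {
  base <- n %/% (K - 1)
  extra <- n %% (K - 1)
  base + c(rep(1, extra), rep(0, K - 1 - extra))
}
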