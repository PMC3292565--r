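#' Split capture histories after each capture
#'
#' The traditional preparation of the data for modelling trap dependence:
#' each animal's history is cut after every capture, so that each capture
#' starts one fragment released at that occasion. A fragment ends at the
#' animal's next capture (inclusive) — that capture both terminates the
#' fragment and releases the next one, so no likelihood term is
#' double-counted — or runs to the last occasion for the final fragment.
#' A removed (censored) animal's fragment at the removal capture has no
#' tail and no later fragments exist.
#'
#' Since every fragment starts at a capture, the occasion immediately after
#' a fragment's release is in the trap-aware capture class (`pA`) and later
#' occasions in the unaware class (`p`): trap dependence becomes a
#' two-class time-since-release structure on capture probability. Only the
#' first fragment of an animal carries the transient survival class `phi1`
#' on its first interval.
#'
#' @param data single-state [encounter_data()].
#' @return An object of class `"split_history_set"`: a list with elements
#'   `histories` (fragments as rows over the full K occasions, zeros
#'   outside the fragment's span), `release`, `end`, `first_fragment`,
#'   `aware`, `count`, `source` (row index of the source animal in the
#'   aggregated data).
#' @examples
#' d <- encounter_data(c("1011"))
#' s <- split_histories(d)
#' s$release  # fragments released at occasions 1, 3, 4
#' @export
split_histories <- function(data) {
  stopifnot(inherits(data, "encounter_data"))
  if (any(data$histories == 2L))
    stop("the split-history formulation is implemented for single-state ",
         "data only")
  H <- data$histories
  K <- ncol(H)
  rows <- list()
  rel <- end <- src <- cnt <- integer()
  first <- logical()
  for (i in seq_len(nrow(H))) {
    caps <- which(H[i, ] > 0L)
    for (j in seq_along(caps)) {
      r <- caps[j]
      e <- if (j < length(caps)) caps[j + 1L]
           else if (data$removed[i]) r
           else K
      h <- integer(K)
      h[r] <- 1L
      if (e > r) h[e] <- H[i, e]
      rows[[length(rows) + 1L]] <- h
      rel <- c(rel, r); end <- c(end, e); src <- c(src, i)
      cnt <- c(cnt, data$count[i]); first <- c(first, j == 1L)
    }
  }
  structure(
    list(histories = do.call(rbind, rows), release = rel, end = end,
         first_fragment = first, aware = rep.int(TRUE, length(rel)),
         count = cnt, source = src, n_occasions = K),
    class = "split_history_set")
}

#' @export
print.split_history_set <- function(x, ...) {
  cat("Split capture histories: ", nrow(x$histories),
      " fragments from ", length(unique(x$source)), " source rows over ",
      x$n_occasions, " occasions\n", sep = "")
  invisible(x)
}

#' Convert split histories to encounter data
#'
#' Represents a [split_histories()] set as ordinary encounter data in the
#' traditional coding: each fragment spans the full set of occasions with
#' zeros outside its span, and every fragment that ends at a capture which
#' releases a further fragment is flagged as removed (loss on capture).
#' Writing the result with [write_inp()] reproduces the classic "special
#' preparation of the data" for external CJS software.
#'
#' @param x a `split_history_set`.
#' @param ... unused.
#' @return An [encounter_data()] object.
#' @export
as_encounter_data <- function(x, ...) UseMethod("as_encounter_data")

#' @export
as_encounter_data.split_history_set <- function(x, ...) {
  ends_in_capture <- x$end > x$release &
    x$histories[cbind(seq_len(nrow(x$histories)), x$end)] > 0L
  encounter_data(x$histories, count = x$count,
                 removed = ends_in_capture | x$end == x$release)
}

# Whole histories viewed as one "fragment" each: the structure consumed by
# the CJS likelihood for the naive (no trap dependence) fit.
cjs_fragments_whole <- function(data, model) {
  agg <- aggregate_histories(data)
  H <- agg$histories
  K <- ncol(H)
  f <- first_capture(H)
  e <- ifelse(agg$removed & model$censoring, last_capture(H), K)
  list(histories = H, release = f, end = e,
       first_fragment = rep.int(TRUE, nrow(H)),
       aware = rep.int(FALSE, nrow(H)),
       count = agg$count, source = seq_len(nrow(H)), n_occasions = K)
}

# Vectorized CJS negative log-likelihood over fragments: a two-state
# (alive/dead) recursion. Capture probability at the occasion right after
# a fragment's release is pA when the fragment is aware-class, p
# otherwise and at all later occasions; survival over the first interval
# of a first fragment is phi1, phi2 elsewhere.
make_cjs_nll <- function(frag, model) {
  H <- frag$histories
  K <- model$n_occasions
  stopifnot(ncol(H) == K)
  w <- frag$count
  rel <- frag$release
  end <- frag$end
  firstf <- frag$first_fragment
  aware <- frag$aware
  cap <- H > 0L
  layout <- param_layout(model)
  function(theta = NULL, expanded = layout$expand(theta)) {
    phi1 <- expanded$phi1; phi2 <- expanded$phi2
    p <- expanded$p; pA <- expanded$pA
    a <- rep.int(1, length(w))  # alive mass
    d <- rep.int(0, length(w))  # dead mass compatible with the record
    for (t in 2:K) {
      act <- rel < t & t <= end
      if (!any(act)) next
      phi_t <- ifelse(firstf[act] & rel[act] == t - 1L,
                      phi1[t - 1L], phi2[t - 1L])
      pc <- ifelse(aware[act] & rel[act] == t - 1L, pA[t], p[t])
      sa <- a[act] * phi_t
      sd <- d[act] + a[act] * (1 - phi_t)
      seen <- cap[act, t]
      a[act] <- ifelse(seen, sa * pc, sa * (1 - pc))
      d[act] <- ifelse(seen, 0, sd)
    }
    -sum(w * log(pmax(a + d, 1e-300)))
  }
}
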