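#' Encounter history data
#'
#' Container for open-population capture-recapture encounter histories.
#' Each row is one animal (or one cohort of identical histories) observed
#' over `K` capture occasions. Codes are `0` (not encountered), `1`
#' (encountered; in the two-state models, encountered in state of interest
#' 1) and `2` (encountered in state of interest 2).
#'
#' Animals enter the data at their first capture, so every history must
#' contain at least one nonzero code. An animal removed ("lost on capture",
#' i.e. censored) at its last capture is flagged with `removed = TRUE`; its
#' history contributes no likelihood terms after the removal occasion.
#'
#' @param histories integer matrix (rows = animals, columns = occasions)
#'   with codes 0/1/2, or a character vector of digit strings such as
#'   `"10110"`.
#' @param count integer multiplicities per row (default 1).
#' @param removed logical per row: censored at last capture (default FALSE).
#' @param group optional character/factor label per row.
#' @return An object of class `"encounter_data"`: a list with elements
#'   `histories`, `count`, `removed`, `group`, `n_occasions`.
#' @examples
#' d <- encounter_data(c("101", "110", "100"), count = c(5, 2, 1))
#' d
#' @export
encounter_data <- function(histories, count = NULL, removed = NULL,
                           group = NULL) {
  if (is.character(histories)) {
    lens <- nchar(histories)
    if (length(unique(lens)) != 1L)
      stop("encounter histories have unequal lengths")
    histories <- do.call(rbind, lapply(strsplit(histories, ""), as.integer))
  }
  histories <- as.matrix(histories)
  storage.mode(histories) <- "integer"
  n <- nrow(histories)
  K <- ncol(histories)
  if (n == 0L) stop("no encounter histories supplied")
  if (K < 2L) stop("at least 2 occasions are required")
  if (anyNA(histories) || any(!histories %in% 0:2))
    stop("observation codes must be 0, 1 or 2")
  if (any(rowSums(histories > 0L) == 0L))
    stop("every history must contain at least one capture")
  if (is.null(count)) count <- rep.int(1L, n)
  count <- as.integer(count)
  if (length(count) != n || any(count < 1L))
    stop("'count' must be a positive integer per history")
  if (is.null(removed)) removed <- rep.int(FALSE, n)
  removed <- as.logical(removed)
  if (length(removed) != n || anyNA(removed))
    stop("'removed' must be a logical flag per history")
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != n) stop("'group' must have one label per history")
  }
  structure(
    list(histories = unname(histories), count = count, removed = removed,
         group = group, n_occasions = K),
    class = "encounter_data")
}

#' @export
print.encounter_data <- function(x, ...) {
  n <- sum(x$count)
  cat("Encounter histories: ", n, " animals (", nrow(x$histories),
      " unique rows), ", x$n_occasions, " occasions\n", sep = "")
  cat("  captures: ", sum(x$count * rowSums(x$histories > 0L)),
      "; removed on capture: ", sum(x$count[x$removed]), sep = "")
  if (any(x$histories == 2L)) cat("; codes: 0/1/2 (two-state)")
  cat("\n")
  invisible(x)
}

#' @export
summary.encounter_data <- function(object, ...) {
  h <- object$histories
  w <- object$count
  first <- apply(h > 0L, 1L, which.max)
  out <- list(
    n = sum(w),
    n_occasions = object$n_occasions,
    captures_per_occasion = colSums((h > 0L) * w),
    releases_per_occasion = vapply(seq_len(object$n_occasions),
                                   function(t) sum(w[first == t]), 0),
    removed = sum(w[object$removed]),
    two_state = any(h == 2L))
  class(out) <- "summary.encounter_data"
  out
}

#' @export
print.summary.encounter_data <- function(x, ...) {
  cat("Encounter data: ", x$n, " animals over ", x$n_occasions,
      " occasions", if (x$two_state) " (two-state codes)", "\n", sep = "")
  m <- rbind(`first captures` = x$releases_per_occasion,
             `total captures` = x$captures_per_occasion)
  colnames(m) <- seq_len(x$n_occasions)
  print(m)
  if (x$removed > 0) cat("Removed (lost) on capture:", x$removed, "\n")
  invisible(x)
}

# First capture occasion of each row.
first_capture <- function(histories) {
  apply(histories > 0L, 1L, which.max)
}

# Last capture occasion of each row.
last_capture <- function(histories) {
  K <- ncol(histories)
  K + 1L - apply(histories[, K:1, drop = FALSE] > 0L, 1L, which.max)
}

# Collapse identical (history, removed, group) rows, summing counts.
# Used internally before likelihood evaluation.
aggregate_histories <- function(data) {
  key <- paste(apply(data$histories, 1L, paste, collapse = ""),
               data$removed,
               if (is.null(data$group)) "" else data$group)
  idx <- split(seq_along(key), key)
  rows <- vapply(idx, `[`, 0L, 1L)
  cnt <- vapply(idx, function(i) sum(data$count[i]), 0L)
  encounter_data(data$histories[rows, , drop = FALSE], count = cnt,
                 removed = data$removed[rows],
                 group = if (is.null(data$group)) NULL else data$group[rows])
}

# Order-insensitive fingerprint of a dataset, used to refuse AIC
# comparisons across different data.
data_signature <- function(data) {
  agg <- aggregate_histories(data)
  key <- paste(apply(agg$histories, 1L, paste, collapse = ""),
               agg$removed, agg$count)
  paste(sort(key), collapse = "|")
}
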