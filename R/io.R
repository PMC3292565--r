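#' Read a MARK-style .inp encounter history file
#'
#' Parses the MARK `.inp` dialect: records are semicolon-terminated, each
#' consisting of a history string of codes 0/1/2 followed by one or more
#' whitespace-separated integer group counts; `/* ... */` comments (also
#' spanning lines) are ignored. A record with no count is one animal. A
#' negative count follows the MARK convention for loss on capture: the
#' animals were removed at their last capture (`removed = TRUE`, count
#' taken absolute). With several count columns, one row per group is
#' produced, labelled `"g1"`, `"g2"`, ...
#'
#' @param path file path.
#' @return An [encounter_data()] object.
#' @examples
#' f <- tempfile(fileext = ".inp")
#' writeLines(c("/* toy */", "101 5;", "11 -2;"), f)
#' read_inp(f)
#' @export
read_inp <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # strip /* */ comments, non-greedy, across lines
  txt <- gsub("(?s)/\\*.*?\\*/", " ", txt, perl = TRUE)
  recs <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  hist <- character(); cnt <- integer(); rem <- logical(); grp <- character()
  multi <- FALSE
  for (k in seq_along(recs)) {
    tok <- strsplit(trimws(recs[k]), "[[:space:]]+")[[1L]]
    tok <- tok[nzchar(tok)]
    if (!length(tok)) next
    h <- tok[1L]
    if (grepl("[^0-9]", h) || grepl("[^012]", h))
      stop("record ", k, ": illegal characters in history '", h, "'")
    if (length(tok) > 1L) {
      if (!all(grepl("^-?[0-9]+$", tok[-1L])))
        stop("record ", k, ": non-integer count")
      counts <- as.integer(tok[-1L])
    } else counts <- 1L
    if (any(counts == 0L) && length(counts) == 1L)
      stop("record ", k, ": zero count")
    if (length(counts) > 1L) multi <- TRUE
    for (g in seq_along(counts)) {
      if (counts[g] == 0L) next
      hist <- c(hist, h)
      cnt <- c(cnt, abs(counts[g]))
      rem <- c(rem, counts[g] < 0L)
      grp <- c(grp, paste0("g", g))
    }
  }
  if (!length(hist)) stop("no records found in '", path, "'")
  if (length(unique(nchar(hist))) != 1L)
    stop("ragged history lengths in '", path, "'")
  encounter_data(hist, count = cnt, removed = rem,
                 group = if (multi) grp else NULL)
}

#' Write encounter data as a MARK-style .inp file
#'
#' Inverse of [read_inp()]: one record per row, `history count;`, count
#' negative for rows removed (lost) on capture. With a grouped dataset one
#' count column per group is written, in first-appearance order of the
#' labels. Reading the output back yields the same data.
#'
#' @param data an [encounter_data()] object (or a
#'   [split_histories()] set, converted via [as_encounter_data()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(data, path) {
  if (inherits(data, "split_history_set")) data <- as_encounter_data(data)
  stopifnot(inherits(data, "encounter_data"))
  h <- apply(data$histories, 1L, paste, collapse = "")
  signed <- ifelse(data$removed, -data$count, data$count)
  if (is.null(data$group)) {
    lines <- paste0(h, " ", signed, ";")
  } else {
    levels <- unique(data$group)
    cols <- matrix(0L, nrow(data$histories), length(levels))
    cols[cbind(seq_along(h), match(data$group, levels))] <- signed
    lines <- paste0(h, " ", apply(cols, 1L, paste, collapse = " "), ";")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read encounter histories from CSV
#'
#' Two layouts are supported. `"wide"`: one column per occasion (any
#' column named `count`, `removed` or `group` is interpreted as such; all
#' remaining columns are occasions in order). `"long"`: columns
#' `individual`, `occasion`, `code`; every individual must have exactly
#' one code for each occasion 1..K (duplicate or missing cells are
#' rejected).
#'
#' @param path file path.
#' @param layout `"wide"` or `"long"`.
#' @return An [encounter_data()] object.
#' @export
read_encounter_csv <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (layout == "wide") {
    special <- intersect(c("count", "removed", "group"), names(df))
    occ <- setdiff(names(df), special)
    if (length(occ) < 2L) stop("wide layout needs at least 2 occasion columns")
    Hm <- as.matrix(df[occ])
    if (!is.numeric(Hm) || anyNA(Hm) || any(Hm != as.integer(Hm)))
      stop("occasion columns must contain integer codes")
    encounter_data(Hm,
                   count = if ("count" %in% special) df$count else NULL,
                   removed = if ("removed" %in% special) df$removed else NULL,
                   group = if ("group" %in% special) df$group else NULL)
  } else {
    need <- c("individual", "occasion", "code")
    if (!all(need %in% names(df)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    if (anyNA(df[need])) stop("missing cells in long layout")
    if (any(df$code != as.integer(df$code)) ||
        any(df$occasion != as.integer(df$occasion)))
      stop("non-integer codes or occasions")
    if (anyDuplicated(df[c("individual", "occasion")]))
      stop("duplicate (individual, occasion) cells")
    ids <- unique(df$individual)
    K <- max(df$occasion)
    if (min(df$occasion) < 1L) stop("occasions must be numbered from 1")
    if (nrow(df) != length(ids) * K)
      stop("long layout must cover every (individual, occasion) cell")
    Hm <- matrix(0L, length(ids), K)
    Hm[cbind(match(df$individual, ids), df$occasion)] <- as.integer(df$code)
    encounter_data(Hm)
  }
}

#' Write encounter histories to CSV (wide layout)
#'
#' One column per occasion (`occ1`..`occK`) plus `count` and `removed`
#' (and `group` when present). [read_encounter_csv()] restores the data.
#'
#' @param data an [encounter_data()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_encounter_csv <- function(data, path) {
  stopifnot(inherits(data, "encounter_data"))
  df <- as.data.frame(data$histories)
  names(df) <- paste0("occ", seq_len(data$n_occasions))
  df$count <- data$count
  df$removed <- data$removed
  if (!is.null(data$group)) df$group <- data$group
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
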