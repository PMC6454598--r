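#' Context-selection regimes
#'
#' All three learners share the same notion of *context*: which event
#' occurrences count as neighbours of a target occurrence. Three regimes are
#' supported:
#'
#' * **baseline** — the record is linearized into one token sequence (visits
#'   in chronological order, events within a visit in seeded random order)
#'   and a classic fixed sliding window of `token_window` positions is used.
#' * **time, N = 0 (visit level)** — only the other distinct events of the
#'   same visit are context.
#' * **time, N > 0** — every event in every visit dated within `N` days
#'   before or after the target's visit is context (boundary inclusive, the
#'   target's own visit included, the target occurrence itself excluded).
#'   A published "30-day window" corresponds to half-window `N = 15`.
#'
#' @param mode `"time"` or `"baseline"`.
#' @param half_window_days Non-negative integer `N` (time mode; 0 = visit
#'   level).
#' @param token_window Positive integer (baseline mode; default 5).
#' @param seed Integer seed for the intra-visit shuffling used by the
#'   baseline linearization.
#' @return An object of class `context_spec`.
#' @examples
#' context_spec("time", half_window_days = 15)  # the "-T-month" regime
#' context_spec("time", half_window_days = 0)   # the "-T-visit" regime
#' context_spec("baseline", token_window = 5)
#' @export
context_spec <- function(mode = c("time", "baseline"),
                         half_window_days = 0L,
                         token_window = 5L,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "time") {
    if (!is.numeric(half_window_days) || half_window_days < 0) {
      stop("half_window_days must be a non-negative integer")
    }
  } else {
    if (!is.numeric(token_window) || token_window < 1) {
      stop("token_window must be a positive integer")
    }
  }
  structure(list(mode = mode,
                 half_window_days = as.integer(half_window_days),
                 token_window = as.integer(token_window),
                 seed = as.integer(seed)),
            class = "context_spec")
}

#' @export
print.context_spec <- function(x, ...) {
  if (x$mode == "baseline") {
    cat(sprintf("context_spec: baseline token window +/-%d\n", x$token_window))
  } else if (x$half_window_days == 0L) {
    cat("context_spec: time window, visit level (N = 0)\n")
  } else {
    cat(sprintf("context_spec: time window, +/-%d days\n",
                x$half_window_days))
  }
  invisible(x)
}

# Flatten one record into parallel vectors of token, visit number and day.
flatten_record <- function(record) {
  events <- lapply(record$visits, `[[`, "events")
  n <- lengths(events)
  days <- as.numeric(as.Date(vapply(record$visits,
                                    function(v) as.character(v$date), "")))
  list(token = unlist(events, use.names = FALSE),
       visit = rep.int(seq_along(events), n),
       day = rep.int(days, n))
}

#' Time-window context pairs for one patient
#'
#' For each event occurrence in the record, emits one (target, context) pair
#' for every *other* event occurrence whose visit date lies within `n_days`
#' of the target's visit date (inclusive). With `n_days = 0` the context is
#' exactly the other distinct events of the same visit.
#'
#' @param record A patient record (element of `corpus$records`).
#' @param n_days Non-negative half-window in days.
#' @param index Named integer token-to-index map ([vocab_index()]); pass
#'   `NULL` to get token strings instead of indices.
#' @return Two-column matrix with columns `target` and `context`; one row per
#'   ordered pair.
#' @export
time_context_pairs <- function(record, n_days, index = NULL) {
  if (n_days < 0) stop("n_days must be non-negative")
  fl <- flatten_record(record)
  m <- length(fl$token)
  if (m < 2L) {
    return(empty_pairs(index))
  }
  within <- abs(outer(fl$day, fl$day, "-")) <= n_days
  diag(within) <- FALSE
  hits <- which(within, arr.ind = TRUE)
  pairs_from_hits(fl$token, hits[, 1L], hits[, 2L], index)
}

#' Baseline fixed-window context pairs for one patient
#'
#' Linearizes the record (visits chronological, events within each visit
#' shuffled with `seed`) and emits standard skip-gram pairs within
#' `window` positions either side of each token.
#'
#' @param record A patient record.
#' @param window Positive token half-window (default 5).
#' @param seed Integer seed for the intra-visit shuffle.
#' @param index Named token-to-index map, or `NULL` for token strings.
#' @return Two-column `target`/`context` matrix of ordered pairs.
#' @export
baseline_pairs <- function(record, window = 5L, seed = 1L, index = NULL) {
  if (window < 1) stop("window must be >= 1")
  tokens <- linearize_record(record, seed)
  m <- length(tokens)
  if (m < 2L) {
    return(empty_pairs(index))
  }
  pos <- seq_len(m)
  d <- abs(outer(pos, pos, "-"))
  within <- d <= window & d > 0L
  hits <- which(within, arr.ind = TRUE)
  pairs_from_hits(tokens, hits[, 1L], hits[, 2L], index)
}

# One token sequence per patient: visits in date order, events within a
# visit in seeded random order (they are stored as an unordered set).
linearize_record <- function(record, seed = 1L) {
  with_seed(seed, {
    unlist(lapply(record$visits, function(v) {
      ev <- v$events
      if (length(ev) > 1L) ev <- sample(ev) else ev
    }), use.names = FALSE)
  })
}

empty_pairs <- function(index) {
  if (is.null(index)) {
    matrix(character(0), ncol = 2L, dimnames = list(NULL, c("target", "context")))
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("target", "context")))
  }
}

pairs_from_hits <- function(tokens, ti, ci, index) {
  if (is.null(index)) {
    out <- cbind(target = tokens[ti], context = tokens[ci])
  } else {
    out <- cbind(target = unname(index[tokens[ti]]),
                 context = unname(index[tokens[ci]]))
    if (anyNA(out)) stop("pair token missing from vocabulary index")
  }
  out
}

#' All context pairs of a corpus under a regime
#'
#' Concatenates per-record pair streams; in baseline mode each record's
#' shuffle seed is derived deterministically from `spec$seed` and the record
#' position.
#'
#' @param corpus An `ehr_corpus`.
#' @param spec A [context_spec()].
#' @return List with `pairs` (integer matrix, vocabulary indices),
#'   `record_id` (integer, which record each pair came from) and `epsilon`
#'   (per-record total distinct-event counts, for optional per-patient
#'   weighting).
#' @export
context_pairs <- function(corpus, spec) {
  stopifnot(inherits(spec, "context_spec"))
  index <- vocab_index(corpus)
  per <- vector("list", length(corpus$records))
  for (i in seq_along(corpus$records)) {
    r <- corpus$records[[i]]
    per[[i]] <- if (spec$mode == "time") {
      time_context_pairs(r, spec$half_window_days, index)
    } else {
      baseline_pairs(r, spec$token_window, seed = spec$seed + i, index)
    }
  }
  n <- vapply(per, nrow, 0L)
  list(pairs = do.call(rbind, per),
       record_id = rep.int(seq_along(per), n),
       epsilon = vapply(corpus$records, record_epsilon, 0L))
}

#' Temporal segmentation of a record for co-occurrence counting
#'
#' With `n_days = 0` each visit is its own segment. With `n_days > 0` visits
#' are grouped by a tumbling window: scanning in date order, a visit joins
#' the open segment while its date is within `2 * n_days` days of the
#' segment's first visit (a "30-day window" means a 30-day segment span),
#' otherwise it opens a new segment. Each segment is the concatenation (with
#' multiplicity across visits) of its visits' event tokens.
#'
#' @param record A patient record.
#' @param n_days Non-negative half-window in days.
#' @return List of character vectors, one token multiset per segment.
#' @export
segment_visits <- function(record, n_days) {
  if (n_days < 0) stop("n_days must be non-negative")
  events <- lapply(record$visits, `[[`, "events")
  if (n_days == 0L) {
    return(events)
  }
  span <- 2 * n_days
  days <- as.numeric(as.Date(vapply(record$visits,
                                    function(v) as.character(v$date), "")))
  seg_id <- integer(length(days))
  cur <- 1L
  anchor <- days[1L]
  for (i in seq_along(days)) {
    if (days[i] - anchor > span) {
      cur <- cur + 1L
      anchor <- days[i]
    }
    seg_id[i] <- cur
  }
  unname(lapply(split(events, seg_id), function(x) unlist(x, use.names = FALSE)))
}
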