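#' Longitudinal patient records
#'
#' A corpus holds one entry per patient: a chronologically ordered list of
#' visits, each carrying a calendar date (day resolution) and a *set* of coded
#' clinical events. Events are one of three types: `D` (ICD-9 diagnosis),
#' `M` (medication, generic name) or `P` (procedure, opaque identifier).
#' Throughout the package an event is identified by the token
#' `"<type>_<code>"`, e.g. `"D_493.22"` — the type prefix keeps the three code
#' namespaces disjoint, so a diagnosis and a procedure sharing a code string
#' never collide.
#'
#' @name records
NULL

EVENT_TYPES <- c("D", "M", "P")

#' Render a clinical event as its canonical token
#'
#' @param type One of `"D"`, `"M"`, `"P"`.
#' @param code Non-empty code string.
#' @return Character token `"<type>_<code>"`.
#' @examples
#' render_token("D", "493.22")
#' @export
render_token <- function(type, code) {
  if (!all(type %in% EVENT_TYPES)) {
    stop("event type must be one of ", paste(EVENT_TYPES, collapse = ", "))
  }
  if (any(!nzchar(code))) stop("event code must be non-empty")
  paste0(type, "_", code)
}

#' Split a canonical token back into type and code
#'
#' Inverse of [render_token()]: splits on the first underscore.
#'
#' @param token Character vector of tokens.
#' @return Data frame with columns `type` and `code`.
#' @export
split_token <- function(token) {
  type <- substr(token, 1L, 1L)
  sep <- substr(token, 2L, 2L)
  if (any(!type %in% EVENT_TYPES) || any(sep != "_")) {
    stop("malformed token(s): expected \"<D|M|P>_<code>\"")
  }
  data.frame(type = type, code = substring(token, 3L),
             stringsAsFactors = FALSE)
}

new_visit <- function(visit_id, date, events) {
  list(visit_id = as.character(visit_id),
       date = as.Date(date),
       events = unique(as.character(events)))
}

new_patient_record <- function(patient_id, visits) {
  if (length(visits) == 0L) stop("a patient record needs at least one visit")
  dates <- as.Date(vapply(visits, function(v) as.character(v$date), ""))
  visits <- visits[order(dates)]
  list(patient_id = as.character(patient_id), visits = visits)
}

#' Build a corpus from patient records
#'
#' @param records List of patient records (each a list with `patient_id` and
#'   `visits`; visits are sorted and events deduplicated on construction).
#' @param min_count Vocabulary frequency floor, see [build_vocabulary()].
#' @return An object of class `ehr_corpus`: a list with elements `records`
#'   and `vocabulary`.
#' @export
new_corpus <- function(records, min_count = 1L) {
  corpus <- structure(list(records = records, vocabulary = NULL),
                      class = "ehr_corpus")
  corpus$vocabulary <- build_vocabulary(corpus, min_count = min_count)
  corpus
}

#' @export
print.ehr_corpus <- function(x, ...) {
  nv <- sum(vapply(x$records, function(r) length(r$visits), 0L))
  cat(sprintf("ehr_corpus: %d patients, %d visits, %d vocabulary tokens\n",
              length(x$records), nv, nrow(x$vocabulary)))
  invisible(x)
}

# Visit-level token counts over the whole corpus (each distinct event in a
# visit counts once; repeats across visits accumulate).
token_counts <- function(records) {
  tokens <- unlist(lapply(records, function(r) {
    unlist(lapply(r$visits, `[[`, "events"), use.names = FALSE)
  }), use.names = FALSE)
  if (length(tokens) == 0L) {
    return(integer(0))
  }
  tab <- table(tokens)
  setNames(as.integer(tab), names(tab))
}

#' Build the vocabulary of a corpus
#'
#' Tokens with visit-level count at least `min_count`, ordered by descending
#' count with ties broken by token string (ascending), each assigned a stable
#' integer index `1..V`.
#'
#' @param corpus An `ehr_corpus`.
#' @param min_count Positive integer frequency floor (default 1: keep all).
#' @return Data frame with columns `token`, `count`, `index`.
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 1) {
    stop("min_count must be a positive integer")
  }
  counts <- token_counts(corpus$records)
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) {
    return(data.frame(token = character(0), count = integer(0),
                      index = integer(0), stringsAsFactors = FALSE))
  }
  ord <- order(-counts, names(counts), method = "radix")
  counts <- counts[ord]
  data.frame(token = names(counts) %||% character(0),
             count = as.integer(counts),
             index = seq_along(counts),
             stringsAsFactors = FALSE)
}

#' Token-to-index lookup for a corpus vocabulary
#'
#' @param corpus An `ehr_corpus`.
#' @return Named integer vector mapping token to index `1..V`.
#' @export
vocab_index <- function(corpus) {
  setNames(corpus$vocabulary$index, corpus$vocabulary$token)
}

parse_visit <- function(v, line) {
  for (f in c("visit_id", "datetime", "events")) {
    if (is.null(v[[f]])) {
      stop(sprintf("schema error at line %d: visit missing field '%s'",
                   line, f))
    }
  }
  date <- suppressWarnings(as.Date(as.character(v$datetime),
                                   format = "%Y-%m-%d"))
  if (is.na(date)) {
    stop(sprintf("schema error at line %d: unparseable datetime '%s'",
                 line, as.character(v$datetime)))
  }
  events <- vapply(v$events, function(e) {
    if (is.null(e$type) || is.null(e$code)) {
      stop(sprintf("schema error at line %d: event missing type or code",
                   line))
    }
    render_token(as.character(e$type), as.character(e$code))
  }, "")
  new_visit(v$visit_id, date, events)
}

#' Read patient records from a JSONL file
#'
#' One patient per line:
#' `{"patient_id": str, "visits": [{"visit_id": str, "datetime": "YYYY-MM-DD",`
#' `"events": [{"type": "D"|"M"|"P", "code": str}, ...]}, ...]}`.
#' Visits are re-sorted by date and events deduplicated per visit; the
#' vocabulary is built with `min_count = 1`.
#'
#' @param path Path to the JSONL file.
#' @return An `ehr_corpus`.
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("parse error at line %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
    if (is.null(obj$patient_id) || is.null(obj$visits)) {
      stop(sprintf("schema error at line %d: missing patient_id or visits", i))
    }
    visits <- lapply(obj$visits, parse_visit, line = i)
    records[[i]] <- new_patient_record(obj$patient_id, visits)
  }
  new_corpus(records)
}

#' Write a corpus to a JSONL file
#'
#' Inverse of [read_records()]: reading the written file reconstructs the
#' corpus field for field.
#'
#' @param corpus An `ehr_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in corpus$records) {
    visits <- lapply(r$visits, function(v) {
      ev <- split_token(v$events)
      list(visit_id = v$visit_id,
           datetime = format(v$date, "%Y-%m-%d"),
           events = lapply(seq_len(nrow(ev)), function(k) {
             list(type = ev$type[k], code = ev$code[k])
           }))
    })
    line <- jsonlite::toJSON(list(patient_id = r$patient_id, visits = visits),
                             auto_unbox = TRUE)
    writeLines(line, con)
  }
  invisible(path)
}

#' Drop patients with out-of-range visit dates
#'
#' Records with obviously wrong timestamps (any visit dated outside
#' `[min_date, max_date]`) are removed entirely; remaining records are
#' untouched and the vocabulary is rebuilt.
#'
#' @param corpus An `ehr_corpus`.
#' @param min_date,max_date Date bounds (inclusive), `min_date < max_date`.
#' @return A cleaned `ehr_corpus` (possibly empty).
#' @export
clean_records <- function(corpus, min_date, max_date) {
  min_date <- as.Date(min_date)
  max_date <- as.Date(max_date)
  if (!(min_date < max_date)) stop("min_date must precede max_date")
  keep <- vapply(corpus$records, function(r) {
    dates <- as.Date(vapply(r$visits, function(v) as.character(v$date), ""))
    all(dates >= min_date & dates <= max_date)
  }, TRUE)
  new_corpus(corpus$records[keep])
}

# Total number of distinct events across a patient's visits (the per-patient
# normalizer used by the weighted training option).
record_epsilon <- function(record) {
  sum(vapply(record$visits, function(v) length(v$events), 0L))
}
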