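# Fixture builders shared across the suite. Everything is constructed in
# code; day offsets are relative to a fixed origin so tests read naturally.

DAY0 <- as.Date("2005-06-01")

make_visit <- function(id, day, tokens) {
  ehrembed:::new_visit(id, DAY0 + day, tokens)
}

make_record <- function(patient_id, ...) {
  # ... = alternating day offsets and token vectors: 0, c("D_1"), 10, ...
  args <- list(...)
  stopifnot(length(args) %% 2 == 0)
  visits <- lapply(seq_len(length(args) / 2), function(k) {
    make_visit(sprintf("%s_v%d", patient_id, k),
               args[[2 * k - 1]], args[[2 * k]])
  })
  ehrembed:::new_patient_record(patient_id, visits)
}

make_corpus <- function(...) new_corpus(list(...))

# A random record with <= max_visits visits for brute-force oracles.
random_record <- function(patient_id, vocab_tokens, max_visits = 5) {
  n_vis <- sample.int(max_visits, 1)
  days <- sort(sample.int(60, n_vis))
  visits <- lapply(seq_len(n_vis), function(k) {
    ev <- sample(vocab_tokens, sample.int(min(4, length(vocab_tokens)), 1))
    make_visit(sprintf("%s_v%d", patient_id, k), days[k], ev)
  })
  ehrembed:::new_patient_record(patient_id, visits)
}

# An embedding with explicitly chosen vectors.
hand_embedding <- function(tokens, vectors) {
  ehrembed:::new_embedding(tokens, do.call(rbind, vectors), method = "hand")
}

# Tiny model (input + output matrices) for loss / softmax tests.
random_model <- function(V = 4, dim = 3, seed = 1) {
  set.seed(seed)
  tokens <- paste0("D_", seq_len(V))
  ehrembed:::new_embedding(tokens,
                           matrix(rnorm(V * dim), V, dim),
                           matrix(rnorm(V * dim), V, dim))
}

# Brute-force time-window context sets: all other event occurrences whose
# visit dates are within n days, enumerated with explicit loops.
brute_time_pairs <- function(record, n_days) {
  occ <- list()
  for (v in record$visits) {
    for (e in v$events) occ[[length(occ) + 1]] <- list(tok = e, day = v$date)
  }
  out <- list()
  for (t in seq_along(occ)) {
    for (k in seq_along(occ)) {
      if (k == t) next
      if (abs(as.numeric(occ[[k]]$day - occ[[t]]$day)) <= n_days) {
        out[[length(out) + 1]] <- c(occ[[t]]$tok, occ[[k]]$tok)
      }
    }
  }
  if (length(out) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("target", "context"))))
  }
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("target", "context"))
  m
}

# Sort a pair matrix into a canonical order for comparison.
canon_pairs <- function(m) {
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
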