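#' Character n-gram configuration for the subword model
#'
#' Conventions follow the reference FastText defaults: n-grams of length 3
#' to 6 over the boundary-wrapped token (`"<token>"`), plus the whole token
#' itself as a special unit. N-grams are taken over the *rendered* token
#' including its `D_`/`M_`/`P_` type prefix, so event-type information enters
#' subword space and ICD code prefixes (e.g. `493` shared by `493.22` and
#' `493.91`) become shared n-grams.
#'
#' @param min_n,max_n N-gram length range, `1 <= min_n <= max_n`.
#' @param add_boundaries Wrap tokens in `<`/`>` markers before extraction.
#' @param include_whole_token Add the (wrapped) whole token as a unit with
#'   its own vector.
#' @param freq_threshold_P Tokens with vocabulary count below this threshold
#'   compose from n-grams only (no whole-token vector). Default 0: every
#'   token gets one.
#' @param bucket_count Optional hashing-trick size; `NULL` (the default)
#'   keeps an exact n-gram table, which clinical vocabularies are small
#'   enough for. Hashing is a speed/memory device only.
#' @return An object of class `ngram_config`.
#' @export
ngram_config <- function(min_n = 3L, max_n = 6L, add_boundaries = TRUE,
                         include_whole_token = TRUE, freq_threshold_P = 0L,
                         bucket_count = NULL) {
  if (min_n < 1 || max_n < min_n) stop("need 1 <= min_n <= max_n")
  if (freq_threshold_P < 0) stop("freq_threshold_P must be >= 0")
  if (!is.null(bucket_count) && bucket_count < 1) {
    stop("bucket_count must be a positive integer or NULL")
  }
  structure(list(min_n = as.integer(min_n), max_n = as.integer(max_n),
                 add_boundaries = isTRUE(add_boundaries),
                 include_whole_token = isTRUE(include_whole_token),
                 freq_threshold_P = as.integer(freq_threshold_P),
                 bucket_count = bucket_count),
            class = "ngram_config")
}

# the whole-token unit is namespaced so it can never collide with a literal
# substring n-gram
whole_token_unit <- function(token) paste0("\x01", token)

#' Extract the character n-grams of a token
#'
#' All contiguous substrings of the (optionally boundary-wrapped) token with
#' length in `[min_n, max_n]`, in deterministic order (by start position,
#' then length), plus the whole-token unit when configured.
#'
#' @param token Non-empty token string.
#' @param config An [ngram_config()].
#' @param whole_token Override for the whole-token inclusion (used
#'   internally to honour `freq_threshold_P`); defaults to the config flag.
#' @return Character vector of n-grams (possibly with duplicates if a
#'   substring repeats; the set semantics of the model deduplicate).
#' @examples
#' extract_ngrams("M_aspirin", ngram_config(3, 3, add_boundaries = FALSE,
#'                                          include_whole_token = FALSE))
#' @export
extract_ngrams <- function(token, config = ngram_config(),
                           whole_token = config$include_whole_token) {
  if (!nzchar(token)) stop("token must be non-empty")
  s <- if (config$add_boundaries) paste0("<", token, ">") else token
  L <- nchar(s)
  grams <- character(0)
  for (start in seq_len(L)) {
    for (n in seq.int(config$min_n, config$max_n)) {
      if (start + n - 1L > L) break
      grams <- c(grams, substr(s, start, start + n - 1L))
    }
  }
  grams <- unique(grams)
  if (whole_token) grams <- c(grams, whole_token_unit(token))
  grams
}

ngram_ids <- function(grams, table_names, config) {
  if (is.null(config$bucket_count)) {
    match(grams, table_names)
  } else {
    gram_hash(grams) %% config$bucket_count + 1L
  }
}

# simple 31-ary polynomial rolling hash mod a Mersenne prime; only used by
# the optional hashing trick, so collisions just share a bucket as intended
gram_hash <- function(strings) {
  vapply(strings, function(s) {
    h <- 17
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, 1L, USE.NAMES = FALSE)
}

# Build the gram table and the per-token gram-id lists for a vocabulary.
build_gram_table <- function(vocabulary, config) {
  whole <- config$include_whole_token &
    vocabulary$count >= config$freq_threshold_P
  gram_sets <- lapply(seq_len(nrow(vocabulary)), function(i) {
    extract_ngrams(vocabulary$token[i], config, whole_token = whole[i])
  })
  if (any(lengths(gram_sets) == 0L)) {
    stop("degenerate n-gram config: some vocabulary tokens have no n-grams ",
         "and no whole-token unit, so they would have no parameters")
  }
  if (is.null(config$bucket_count)) {
    table_names <- sort(unique(unlist(gram_sets, use.names = FALSE)))
    n_grams <- length(table_names)
  } else {
    table_names <- NULL
    n_grams <- config$bucket_count
  }
  ids <- lapply(gram_sets, function(g) {
    sort(unique(ngram_ids(g, table_names, config)))
  })
  list(names = table_names, n_grams = n_grams, ids = ids)
}

#' Train time-sensitive subword (FastText-style) embeddings
#'
#' Same pair streams and negative-sampling objective as [train_sgns()], but
#' the target-side score is `s(C_v, C_t) = sum over g in G(C_v) of
#' z_g . v'_t`: the target's vector is the sum of its character n-gram
#' vectors, and gradients are distributed over those n-gram vectors. The
#' context (output) side keeps whole-token vectors. Deterministic per seed.
#'
#' @param corpus An `ehr_corpus`.
#' @param spec A [context_spec()].
#' @param sg_config An [sgns_config()] (dim, epochs, negatives, ...).
#' @param ng_config An [ngram_config()].
#' @return An object of class `ehr_fasttext`: `ngram_vectors` (one row per
#'   n-gram, rownames are the n-grams for the exact table), `output_vectors`,
#'   `vocabulary`, `config`, plus `meta` with per-epoch losses.
#' @export
train_fasttext <- function(corpus, spec, sg_config = sgns_config(),
                           ng_config = ngram_config()) {
  stopifnot(inherits(sg_config, "sgns_config"),
            inherits(ng_config, "ngram_config"))
  stream <- context_pairs(corpus, spec)
  check_pair_stream(stream, spec)
  tab <- build_gram_table(corpus$vocabulary, ng_config)
  V <- nrow(corpus$vocabulary)
  noise <- corpus$vocabulary$count ^ sg_config$noise_exponent
  w <- pair_weight_vector(stream, sg_config)
  offsets <- c(0L, cumsum(lengths(tab$ids)))
  fit <- fasttext_train_cpp(stream$pairs[, "target"] - 1L,
                            stream$pairs[, "context"] - 1L,
                            noise,
                            unlist(tab$ids, use.names = FALSE) - 1L,
                            offsets, tab$n_grams, V,
                            sg_config$dim, sg_config$epochs,
                            sg_config$learning_rate,
                            sg_config$learning_rate / 10,
                            sg_config$negatives, w,
                            as.double(sg_config$seed))
  ngram_vectors <- fit$input
  if (!is.null(tab$names)) rownames(ngram_vectors) <- tab$names
  output <- fit$output
  rownames(output) <- corpus$vocabulary$token
  structure(list(ngram_vectors = ngram_vectors,
                 output_vectors = output,
                 vocabulary = corpus$vocabulary,
                 config = ng_config,
                 meta = list(epoch_loss = as.numeric(fit$epoch_loss),
                             n_pairs = nrow(stream$pairs),
                             spec = spec, sg_config = sg_config,
                             gram_ids = tab$ids)),
            class = "ehr_fasttext")
}

#' @export
print.ehr_fasttext <- function(x, ...) {
  cat(sprintf("ehr_fasttext: %d tokens, %d n-gram vectors x %d dims\n",
              nrow(x$vocabulary), nrow(x$ngram_vectors),
              ncol(x$ngram_vectors)))
  invisible(x)
}

#' Compose a concept vector from its n-grams
#'
#' Exact sum of the n-gram vectors of `token` under the model's config — no
#' averaging. Works for out-of-vocabulary tokens: any n-gram seen in
#' training contributes; a token with no known n-grams returns the zero
#' vector with a warning.
#'
#' @param model An `ehr_fasttext`.
#' @param token Any non-empty token string.
#' @return Numeric vector of length `dim`.
#' @export
compose_vector <- function(model, token) {
  config <- model$config
  vi <- match(token, model$vocabulary$token)
  if (!is.na(vi)) {
    ids <- model$meta$gram_ids[[vi]]
    return(colSums(model$ngram_vectors[ids, , drop = FALSE]))
  }
  grams <- extract_ngrams(token, config, whole_token = FALSE)
  ids <- if (is.null(config$bucket_count)) {
    m <- match(grams, rownames(model$ngram_vectors))
    m[!is.na(m)]
  } else {
    unique(gram_hash(grams) %% config$bucket_count + 1L)
  }
  if (length(ids) == 0L) {
    warning("token '", token, "' has no known n-grams; returning zero vector")
    return(numeric(ncol(model$ngram_vectors)))
  }
  colSums(model$ngram_vectors[ids, , drop = FALSE])
}

#' Materialize composed vectors for the whole vocabulary
#'
#' @param model An `ehr_fasttext`.
#' @return An `ehr_embedding` whose input vectors are the composed token
#'   vectors and whose output vectors are the model's context vectors.
#' @export
fasttext_embedding <- function(model) {
  ids <- model$meta$gram_ids
  input <- t(vapply(ids, function(g) {
    colSums(model$ngram_vectors[g, , drop = FALSE])
  }, numeric(ncol(model$ngram_vectors))))
  new_embedding(model$vocabulary$token, input, model$output_vectors,
                method = "ft",
                meta = model$meta[c("epoch_loss", "n_pairs")])
}
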