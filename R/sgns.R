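#' Skip-gram training configuration
#'
#' Defaults follow word2vec conventions where the underlying study is silent:
#' 5 negatives per positive, unigram^0.75 noise distribution, linear
#' learning-rate decay from `learning_rate` to `learning_rate / 10` over the
#' whole run. The embedding dimension defaults to 200, the published setting.
#'
#' @param dim Embedding dimension (default 200).
#' @param epochs Training epochs (default 5).
#' @param learning_rate Initial SGD step size (default 0.025).
#' @param negatives Negative samples per positive pair (default 5).
#' @param noise_exponent Exponent on the unigram distribution for negative
#'   sampling (default 0.75).
#' @param per_patient_weight If `TRUE`, each pair's update is weighted by
#'   `1 / epsilon` for its patient, where `epsilon` is the patient's total
#'   distinct-event count — the explicit per-patient normalizer. Off by
#'   default: streaming pairs uniformly already weights patients by their
#'   pair counts, the usual word2vec behaviour.
#' @param seed Integer RNG seed for initialization, pair shuffling and
#'   negative draws.
#' @return An object of class `sgns_config`.
#' @export
sgns_config <- function(dim = 200L, epochs = 5L, learning_rate = 0.025,
                        negatives = 5L, noise_exponent = 0.75,
                        per_patient_weight = FALSE, seed = 1L) {
  if (dim < 1) stop("dim must be >= 1")
  if (negatives < 1) stop("negatives must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(dim = as.integer(dim), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 negatives = as.integer(negatives),
                 noise_exponent = noise_exponent,
                 per_patient_weight = isTRUE(per_patient_weight),
                 seed = as.integer(seed)),
            class = "sgns_config")
}

new_embedding <- function(tokens, input, output = NULL, method = "sg",
                          meta = list()) {
  rownames(input) <- tokens
  if (!is.null(output)) rownames(output) <- tokens
  structure(list(tokens = tokens, input = input, output = output,
                 method = method, meta = meta),
            class = "ehr_embedding")
}

#' @export
print.ehr_embedding <- function(x, ...) {
  cat(sprintf("ehr_embedding (%s): %d tokens x %d dims\n",
              x$method, length(x$tokens), ncol(x$input)))
  invisible(x)
}

#' Train time-sensitive skip-gram embeddings
#'
#' Streams (target, context) pairs from the chosen context regime and runs
#' negative-sampling SGD: the loss for a pair with negatives `n_1..n_k` is
#' `-log sigma(v'_c . v_t) - sum_j log sigma(-v'_nj . v_t)`. Negatives are
#' drawn from the unigram distribution raised to `noise_exponent`. The run is
#' single-threaded and fully determined by `config$seed`.
#'
#' The returned input vectors are the published embeddings; output vectors
#' are retained for scoring (see [softmax_prob()]).
#'
#' @param corpus An `ehr_corpus` with non-empty vocabulary.
#' @param spec A [context_spec()].
#' @param config An [sgns_config()].
#' @return An `ehr_embedding` with `input`, `output` and per-epoch mean loss
#'   in `meta$epoch_loss`.
#' @export
train_sgns <- function(corpus, spec, config = sgns_config()) {
  stopifnot(inherits(config, "sgns_config"))
  stream <- context_pairs(corpus, spec)
  check_pair_stream(stream, spec)
  V <- nrow(corpus$vocabulary)
  noise <- corpus$vocabulary$count ^ config$noise_exponent
  w <- pair_weight_vector(stream, config)
  fit <- sgns_train_cpp(stream$pairs[, "target"] - 1L,
                        stream$pairs[, "context"] - 1L,
                        noise, V, config$dim, config$epochs,
                        config$learning_rate, config$learning_rate / 10,
                        config$negatives, w, as.double(config$seed))
  new_embedding(corpus$vocabulary$token, fit$input, fit$output,
                method = "sg",
                meta = list(epoch_loss = as.numeric(fit$epoch_loss),
                            n_pairs = nrow(stream$pairs),
                            spec = spec, config = config))
}

check_pair_stream <- function(stream, spec) {
  if (is.null(stream$pairs) || nrow(stream$pairs) == 0L) {
    stop("no context pairs under this regime: every patient's events are ",
         "isolated (e.g. all visits carry a single event under the ",
         "visit-level window); widen the window or check the corpus")
  }
  invisible(stream)
}

pair_weight_vector <- function(stream, config) {
  if (!config$per_patient_weight) {
    return(numeric(0))
  }
  w <- 1 / stream$epsilon[stream$record_id]
  # keep the mean step size comparable to the unweighted run
  w / mean(w)
}

#' Full-softmax context probability (reference scorer)
#'
#' The exact skip-gram likelihood term: `p(context | target) =
#' exp(v'_c . v_t) / sum_C exp(v'_C . v_t)`. Training replaces it with the
#' sampled surrogate; this scorer is kept for testing and inspection.
#'
#' @param model An `ehr_embedding` with output vectors.
#' @param target,context Tokens in the model vocabulary.
#' @return Probability in (0, 1]; for a fixed target the values over all
#'   contexts sum to 1.
#' @export
softmax_prob <- function(model, target, context) {
  ti <- match(target, model$tokens)
  ci <- match(context, model$tokens)
  if (is.na(ti) || is.na(ci)) stop("unknown token")
  scores <- drop(model$output %*% model$input[ti, ])
  scores <- scores - max(scores)
  unname(exp(scores[ci]) / sum(exp(scores)))
}

#' Negative-sampling loss for one pair
#'
#' `-log sigma(v'_c . v_t) - sum_j log sigma(-v'_nj . v_t)`; the training
#' objective for a single (target, context) pair with explicit negatives.
#'
#' @param model An `ehr_embedding` (or any list with `tokens`, `input`,
#'   `output`).
#' @param target,context Tokens in the vocabulary.
#' @param negatives Non-empty character vector of negative tokens.
#' @return Non-negative loss value.
#' @export
ns_loss <- function(model, target, context, negatives) {
  if (length(negatives) < 1L) stop("need at least one negative sample")
  ti <- match(target, model$tokens)
  oi <- match(c(context, negatives), model$tokens)
  if (is.na(ti) || anyNA(oi)) stop("unknown token")
  ns_loss_raw(model$input[ti, ], model$output[oi[1L], ,drop = FALSE],
              model$output[oi[-1L], , drop = FALSE])$loss
}

# Loss plus analytic gradients on raw vectors; h is the target-side hidden
# vector (the token vector for skip-gram, the n-gram sum for the subword
# model). Used by the trainers' tests and the gradient checks.
ns_loss_raw <- function(h, out_pos, out_neg) {
  out_pos <- matrix(out_pos, ncol = length(h))
  out_neg <- matrix(out_neg, ncol = length(h))
  sp <- 1 / (1 + exp(-drop(out_pos %*% h)))
  sn <- 1 / (1 + exp(-drop(out_neg %*% h)))
  loss <- -log(sp) - sum(log(1 - sn))
  list(loss = loss,
       grad_h = drop((sp - 1) * out_pos) + drop(crossprod(out_neg, sn)),
       grad_pos = (sp - 1) * h,
       grad_neg = outer(sn, h))
}
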