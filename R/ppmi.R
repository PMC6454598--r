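#' Temporal co-occurrence counting
#'
#' Step 1 of the PPMI-SVD pipeline. The corpus is segmented in time
#' ([segment_visits()]; one segment per visit when `half_window_days = 0`,
#' tumbling windows of span `2 * half_window_days` days otherwise) and every
#' unordered pair of distinct tokens within a segment increments the
#' symmetric count matrix — by the product of the tokens' multiplicities in
#' the segment by default, or by 1 per segment with `binary = TRUE`. The
#' diagonal stays zero: a concept does not co-occur with itself.
#'
#' There is no baseline (token-window) co-occurrence mode: counting is
#' defined over time segments only, and a patient-level (unwindowed) count
#' is deliberately unsupported because patient timelines vary too much for
#' whole-timeline co-occurrence to be meaningful.
#'
#' @param corpus An `ehr_corpus`.
#' @param spec A [context_spec()] with `mode = "time"`.
#' @param binary Count each co-occurring pair once per segment instead of by
#'   multiplicity.
#' @return An object of class `ehr_cooc`: list with `counts` (sparse
#'   symmetric `Matrix` with vocabulary dimnames), `total_pairs`
#'   (`sum of counts over i < j`) and `tokens`.
#' @export
count_cooccurrence <- function(corpus, spec, binary = FALSE) {
  stopifnot(inherits(spec, "context_spec"))
  if (spec$mode != "time") {
    stop("co-occurrence counting is defined for time windows only; ",
         "the baseline token-window regime is unsupported here")
  }
  index <- vocab_index(corpus)
  V <- length(index)
  triplets <- list()
  for (r in corpus$records) {
    for (seg in segment_visits(r, spec$half_window_days)) {
      if (length(seg) < 2L) next
      mult <- table(seg)
      if (length(mult) < 2L) next
      toks <- unname(index[names(mult)])
      m <- as.numeric(mult)
      cp <- utils::combn(seq_along(toks), 2L)
      a <- cp[1L, ]; b <- cp[2L, ]
      w <- if (binary) rep(1, length(a)) else m[a] * m[b]
      triplets[[length(triplets) + 1L]] <- list(i = toks[a], j = toks[b], x = w)
    }
  }
  ii <- unlist(lapply(triplets, `[[`, "i"), use.names = FALSE) %||% integer(0)
  jj <- unlist(lapply(triplets, `[[`, "j"), use.names = FALSE) %||% integer(0)
  xx <- unlist(lapply(triplets, `[[`, "x"), use.names = FALSE) %||% numeric(0)
  counts <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii), x = c(xx, xx), dims = c(V, V),
    dimnames = list(names(index), names(index))
  )
  structure(list(counts = counts,
                 total_pairs = sum(xx),
                 tokens = names(index)),
            class = "ehr_cooc")
}

#' @export
print.ehr_cooc <- function(x, ...) {
  cat(sprintf("ehr_cooc: %d x %d, %d nonzero cells, %g total pairs\n",
              nrow(x$counts), ncol(x$counts),
              Matrix::nnzero(x$counts), x$total_pairs))
  invisible(x)
}

#' Positive pointwise mutual information transform
#'
#' Step 2: `M(i, j) = max(0, log p(i, j) - log p(i) - log p(j))` with the
#' probability space over *ordered* co-occurrence pairs — `p(i, j) =
#' C(i, j) / (2 * total_pairs)` and marginals `p(i)` equal to row sums over
#' the same denominator, the standard PPMI convention. Natural log; the log
#' base rescales `M` but leaves the SVD embeddings unchanged up to sign.
#' Cells with zero counts stay zero.
#'
#' @param cooc An `ehr_cooc`.
#' @return An object of class `ehr_ppmi`: list with sparse symmetric
#'   `values` and `tokens`.
#' @export
ppmi_transform <- function(cooc) {
  stopifnot(inherits(cooc, "ehr_cooc"))
  if (cooc$total_pairs < 1) {
    stop("empty co-occurrence matrix: no pairs to transform")
  }
  C <- methods::as(cooc$counts, "TsparseMatrix")
  denom <- 2 * cooc$total_pairs
  row_sums <- Matrix::rowSums(cooc$counts)
  # PMI(i,j) = log( C_ij * denom / (r_i * r_j) ); positive part only
  pmi <- log(C@x) + log(denom) - log(row_sums[C@i + 1L]) -
    log(row_sums[C@j + 1L])
  keep <- pmi > 0
  values <- Matrix::sparseMatrix(
    i = C@i[keep] + 1L, j = C@j[keep] + 1L, x = pmi[keep],
    dims = dim(C), dimnames = dimnames(cooc$counts)
  )
  structure(list(values = values, tokens = cooc$tokens),
            class = "ehr_ppmi")
}

#' Truncated SVD embeddings of a PPMI matrix
#'
#' Step 3: rank-`d` SVD `M ~ U S V^T`; the rows of `U` are the embeddings.
#' Column signs are canonicalized (largest-magnitude entry of each left
#' singular vector made positive) so the result is deterministic. With
#' `weight_singular = TRUE` the rows of `U S^(1/2)` are returned instead —
#' a common variant, not the default.
#'
#' @param ppmi An `ehr_ppmi` (or any symmetric matrix with dimnames).
#' @param d Embedding dimension, `1 <= d <= V`.
#' @param weight_singular Weight `U`'s columns by `sqrt(S)`.
#' @return List of class `ehr_svd` with `U` (V x d), `S` (length d,
#'   descending), `tokens` and `d`.
#' @export
svd_embed <- function(ppmi, d, weight_singular = FALSE) {
  M <- if (inherits(ppmi, "ehr_ppmi")) ppmi$values else ppmi
  tokens <- if (inherits(ppmi, "ehr_ppmi")) ppmi$tokens else rownames(M)
  V <- nrow(M)
  if (d < 1 || d > V) stop("d must satisfy 1 <= d <= V")
  dec <- svd(as.matrix(M), nu = d, nv = 0)
  U <- dec$u
  # sign convention: largest-|entry| of each column positive
  for (k in seq_len(d)) {
    piv <- which.max(abs(U[, k]))
    if (U[piv, k] < 0) U[, k] <- -U[, k]
  }
  S <- dec$d[seq_len(d)]
  if (weight_singular) U <- sweep(U, 2L, sqrt(S), "*")
  structure(list(U = U, S = S, tokens = tokens, d = d), class = "ehr_svd")
}

#' Train time-sensitive PPMI-SVD embeddings
#'
#' Convenience wrapper for the three-step pipeline: temporal co-occurrence
#' counts, PPMI transform, truncated SVD. Deterministic (no randomness).
#'
#' @param corpus An `ehr_corpus`.
#' @param spec A [context_spec()] with `mode = "time"`.
#' @param dim Embedding dimension (default 200, capped at V).
#' @param binary,weight_singular Passed through to the steps.
#' @return An `ehr_embedding` (input vectors = rows of `U`; no output
#'   vectors).
#' @export
train_ppmi <- function(corpus, spec, dim = 200L, binary = FALSE,
                       weight_singular = FALSE) {
  cooc <- count_cooccurrence(corpus, spec, binary = binary)
  M <- ppmi_transform(cooc)
  d <- min(as.integer(dim), length(M$tokens))
  dec <- svd_embed(M, d, weight_singular = weight_singular)
  new_embedding(dec$tokens, dec$U, output = NULL, method = "ppmi",
                meta = list(S = dec$S, spec = spec, dim = d))
}
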