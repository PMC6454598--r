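#' Intrinsic evaluation of concept embeddings
#'
#' A *grouping* assigns each evaluable token to one group (an ICD-9 prefix,
#' a CCS category, or a synthetic ground-truth label); all intrinsic metrics
#' are computed over `V(G)`, the grouped tokens present in the embedding
#' vocabulary. Three metrics are provided: the in-cluster distance
#' (cohesion — smaller is better), the out-cluster distance (decoupling —
#' larger is better), and MCSM, a DCG-style count of same-group concepts
#' among each concept's k nearest neighbours (larger is better).
#'
#' @name eval_intrinsic
NULL

#' ICD-9 prefix of a code
#'
#' The substring before the first `"."`; the whole code when there is no
#' dot. E.g. `493.22` and `493.91` share the prefix `493` (asthma).
#'
#' @param code Character vector of bare codes (no type prefix).
#' @return Character vector of prefixes.
#' @export
icd_prefix_group <- function(code) {
  if (any(!nzchar(code))) stop("code must be non-empty")
  sub("\\..*$", "", code)
}

#' Built-in grouping: ICD prefix over typed tokens
#'
#' Maps each token of the requested types to the ICD prefix of its code
#' part; other tokens are left out of the evaluation set. Diagnoses carry
#' ICD-9 codes in this data model, so the default restricts to `D`.
#'
#' @param tokens Character vector of `"<type>_<code>"` tokens.
#' @param types Event types to include (default `"D"`).
#' @return Named character vector token -> group (an `ehr grouping`).
#' @export
icd_prefix_grouping <- function(tokens, types = "D") {
  parts <- split_token(tokens)
  keep <- parts$type %in% types
  setNames(icd_prefix_group(parts$code[keep]), tokens[keep])
}

#' Read / write a grouping CSV
#'
#' Two columns `token,group`, header required.
#'
#' @param path CSV file path.
#' @return Named character vector token -> group.
#' @export
read_grouping <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("token", "group") %in% names(df))) {
    stop("grouping CSV must have columns 'token' and 'group'")
  }
  if (anyDuplicated(df$token)) {
    stop("grouping CSV maps some token to more than one group")
  }
  setNames(df$group, df$token)
}

#' @rdname read_grouping
#' @param grouping Named character vector token -> group.
#' @export
write_grouping <- function(grouping, path) {
  utils::write.csv(data.frame(token = names(grouping),
                              group = unname(grouping),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Cosine similarity
#'
#' `u . w / (|u| |w|)`. If either vector has zero norm the similarity is
#' defined as 0 (distance 1) and a warning is raised.
#'
#' @param u,w Numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, w) {
  if (length(u) != length(w)) stop("dimension mismatch")
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) {
    warning("zero-norm vector in cosine; returning similarity 0")
    return(0)
  }
  sum(u * w) / (nu * nw)
}

# Row-normalize; zero rows stay zero so their cosines come out as 0.
normalize_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  zero <- n == 0
  if (any(zero)) {
    warning(sum(zero), " zero-norm embedding row(s); cosines involving them",
            " are taken as 0")
    n[zero] <- 1
  }
  X / n
}

# restrict a grouping to the embedding vocabulary and return per-group
# index lists
eval_groups <- function(emb, grouping) {
  present <- names(grouping)[names(grouping) %in% emb$tokens]
  if (length(present) == 0L) {
    stop("no grouped token is present in the embedding vocabulary")
  }
  split(match(present, emb$tokens), unname(grouping[present]))
}

#' In-cluster (cohesion) distance
#'
#' For each group with at least two members in `V(G)`, the mean of
#' `1 - cosine` over all unordered member pairs; the reported value is the
#' unweighted mean of these per-group means. Smaller is better. Groups with
#' fewer than two members have no pairs and are skipped. With
#' `weighting = "concept"` the per-group means are instead weighted by group
#' size (a per-concept average) — a variant, not the default.
#'
#' @param emb An `ehr_embedding`.
#' @param grouping Named character vector token -> group.
#' @param weighting `"group"` (default) or `"concept"`.
#' @return `d_in` in `[0, 2]`.
#' @export
in_cluster_distance <- function(emb, grouping, weighting = c("group", "concept")) {
  weighting <- match.arg(weighting)
  groups <- eval_groups(emb, grouping)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) {
    stop("no group has >= 2 members in the embedding vocabulary")
  }
  Xn <- normalize_rows(emb$input)
  per_group <- vapply(groups, function(idx) {
    S <- tcrossprod(Xn[idx, , drop = FALSE])
    mean(1 - S[upper.tri(S)])
  }, 0)
  if (weighting == "group") {
    mean(per_group)
  } else {
    sum(per_group * lengths(groups)) / sum(lengths(groups))
  }
}

#' Out-cluster (decoupling) distance
#'
#' For each unordered pair of groups, the mean of `1 - cosine` over all
#' cross pairs (every member of one group against every member of the
#' other, normalized by the product of the group sizes); the reported value
#' is the unweighted mean over group pairs. Larger is better.
#'
#' @inheritParams in_cluster_distance
#' @return `d_out` in `[0, 2]`.
#' @export
out_cluster_distance <- function(emb, grouping) {
  groups <- eval_groups(emb, grouping)
  if (length(groups) < 2L) stop("need at least two groups")
  Xn <- normalize_rows(emb$input)
  gp <- utils::combn(length(groups), 2L)
  vals <- vapply(seq_len(ncol(gp)), function(k) {
    a <- groups[[gp[1L, k]]]; b <- groups[[gp[2L, k]]]
    S <- Xn[a, , drop = FALSE] %*% t(Xn[b, , drop = FALSE])
    mean(1 - S)
  }, 0)
  mean(vals)
}

#' Medical Conceptual Similarity Measure
#'
#' For each concept `v` in `V(G)`, its `k` nearest neighbours *within
#' `V(G)`* are found by cosine similarity (descending; ties broken by token
#' string, ascending) and the discounted hits are summed:
#' `sum over i = 1..k of I(neighbour i shares v's group) / log2(i + 1)`.
#' The score is the mean over concepts; its maximum is
#' `sum over i of 1 / log2(i + 1)`. The published neighbourhood size is
#' `k = 40`.
#'
#' @param emb An `ehr_embedding`.
#' @param grouping Named character vector token -> group.
#' @param k Neighbourhood size (default 40; capped at `|V(G)| - 1` with a
#'   warning).
#' @return Non-negative MCSM score.
#' @export
mcsm <- function(emb, grouping, k = 40L) {
  if (k < 1) stop("k must be >= 1")
  groups <- eval_groups(emb, grouping)
  idx <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  n <- length(idx)
  if (n < 2L) stop("need at least two grouped concepts in the vocabulary")
  if (k > n - 1L) {
    warning("k = ", k, " exceeds |V(G)| - 1 = ", n - 1L, "; truncating")
    k <- n - 1L
  }
  tokens <- emb$tokens[idx]
  Xn <- normalize_rows(emb$input[idx, , drop = FALSE])
  S <- tcrossprod(Xn)
  discounts <- 1 / log2(seq_len(k) + 1)
  scores <- vapply(seq_len(n), function(v) {
    others <- setdiff(seq_len(n), v)
    ord <- others[order(-S[v, others], tokens[others], method = "radix")]
    top <- ord[seq_len(k)]
    sum(discounts * (labels[top] == labels[v]))
  }, 0)
  mean(scores)
}

#' Nearest-neighbour concept query
#'
#' Top-`k` vocabulary tokens by cosine similarity to `token`, excluding the
#' query itself; ties broken by token string.
#'
#' @param emb An `ehr_embedding`.
#' @param token Query token (must be in the vocabulary).
#' @param k Number of neighbours (default 5; capped at `V - 1`).
#' @return Data frame with columns `token` and `similarity`, most similar
#'   first.
#' @export
knn_query <- function(emb, token, k = 5L) {
  vi <- match(token, emb$tokens)
  if (is.na(vi)) stop("unknown token '", token, "'")
  Xn <- normalize_rows(emb$input)
  sims <- drop(Xn %*% Xn[vi, ])
  others <- setdiff(seq_along(sims), vi)
  ord <- others[order(-sims[others], emb$tokens[others], method = "radix")]
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(token = emb$tokens[top], similarity = sims[top],
             stringsAsFactors = FALSE)
}

#' Full intrinsic metric report
#'
#' Computes `d_in`, `d_out` and MCSM for one embedding under one grouping.
#'
#' @param emb An `ehr_embedding`.
#' @param grouping Named character vector token -> group.
#' @param k MCSM neighbourhood size (default 40).
#' @param embedding_name,grouping_name Labels carried into the report.
#' @return An object of class `metric_report` (a list with `embedding`,
#'   `grouping`, `d_in`, `d_out`, `mcsm`, `k`, `n_concepts`).
#' @export
metric_report <- function(emb, grouping, k = 40L,
                          embedding_name = emb$method %||% "embedding",
                          grouping_name = "grouping") {
  structure(list(embedding = embedding_name,
                 grouping = grouping_name,
                 d_in = in_cluster_distance(emb, grouping),
                 d_out = out_cluster_distance(emb, grouping),
                 mcsm = mcsm(emb, grouping, k = k),
                 k = as.integer(k),
                 n_concepts = sum(names(grouping) %in% emb$tokens)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%-12s %-10s d_in %.4f  d_out %.4f  MCSM(k=%d) %.4f  (n=%d)\n",
              x$embedding, x$grouping, x$d_in, x$d_out, x$k, x$mcsm,
              x$n_concepts))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report A `metric_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
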