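#' Read and write embeddings in word2vec text format
#'
#' Header line `"V dim"`, then one line per token: the token followed by
#' `dim` space-separated decimals. Vectors are written with 6 decimal
#' places, which keeps files byte-reproducible across runs.
#'
#' @param emb An `ehr_embedding` (input vectors are written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(emb, path) {
  X <- emb$input
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(X), ncol(X)), con)
  body <- vapply(seq_len(nrow(X)), function(i) {
    paste(emb$tokens[i], paste(sprintf("%.6f", X[i, ]), collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_word2vec
#' @param method Label stored on the embedding read back in.
#' @return For `read_word2vec`, an `ehr_embedding` (input vectors only).
#' @export
read_word2vec <- function(path, method = "file") {
  lines <- readLines(path, warn = FALSE)
  hdr <- suppressWarnings(
    as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  )
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("malformed word2vec header: expected \"V dim\"")
  }
  if (length(lines) - 1L != hdr[1L]) {
    stop("word2vec file declares ", hdr[1L], " rows but has ",
         length(lines) - 1L)
  }
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  tokens <- vapply(parts, `[[`, "", 1L)
  X <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  if (ncol(X) != hdr[2L]) stop("row width disagrees with header dim")
  new_embedding(tokens, X, output = NULL, method = method)
}

#' Dump a sparse symmetric matrix in Matrix Market format
#'
#' Writes the co-occurrence counts or PPMI values to an `.mtx` file
#' alongside a `.tokens` file with the row/column labels.
#'
#' @param x An `ehr_cooc` or `ehr_ppmi`.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_sparse_mtx <- function(x, path) {
  M <- if (inherits(x, "ehr_cooc")) x$counts else x$values
  Matrix::writeMM(methods::as(M, "generalMatrix"), path)
  writeLines(x$tokens, paste0(path, ".tokens"))
  invisible(path)
}
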