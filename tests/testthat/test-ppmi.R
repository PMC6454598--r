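test_that("co-occurrence counting matches the worked segment examples", {
  # one segment {A,B}
  c1 <- count_cooccurrence(make_corpus(make_record("p1", 0, c("D_A", "D_B"))),
                           context_spec("time", 0))
  expect_equal(c1$counts["D_A", "D_B"], 1)
  expect_equal(c1$total_pairs, 1)
  expect_equal(Matrix::diag(c1$counts), c(0, 0), ignore_attr = TRUE)
  # segments {A,B} and {A,C}: no B-C count
  c2 <- count_cooccurrence(
    make_corpus(make_record("p1", 0, c("D_A", "D_B")),
                make_record("p2", 0, c("D_A", "D_C"))),
    context_spec("time", 0))
  expect_equal(c2$counts["D_A", "D_B"], 1)
  expect_equal(c2$counts["D_A", "D_C"], 1)
  expect_equal(c2$counts["D_B", "D_C"], 0)
  # multiplicity: A in two visits of one 30-day segment with B -> C(A,B) = 2
  c3 <- count_cooccurrence(
    make_corpus(make_record("p1", 0, c("D_A", "D_B"), 5, "D_A")),
    context_spec("time", 15))
  expect_equal(c3$counts["D_A", "D_B"], 2)
  # ... but binary counting collapses it to 1 per segment
  c3b <- count_cooccurrence(
    make_corpus(make_record("p1", 0, c("D_A", "D_B"), 5, "D_A")),
    context_spec("time", 15), binary = TRUE)
  expect_equal(c3b$counts["D_A", "D_B"], 1)
  expect_error(count_cooccurrence(c1, context_spec("baseline")),
               "time windows only")
})

test_that("counts equal a brute-force double loop over segments", {
  set.seed(19)
  vocab <- render_token("D", as.character(1:5))
  records <- lapply(1:4, function(i) random_record(sprintf("p%d", i), vocab))
  corpus <- new_corpus(records)
  spec <- context_spec("time", 10)
  got <- count_cooccurrence(corpus, spec)
  # oracle: explicit token-by-token loops
  want <- matrix(0, 5, 5, dimnames = list(got$tokens, got$tokens))
  for (r in records) {
    for (seg in segment_visits(r, 10)) {
      if (length(seg) < 2) next
      for (a in seq_along(seg)) {
        for (b in seq_along(seg)) {
          ta <- seg[a]; tb <- seg[b]
          if (a < b && ta != tb) {
            want[ta, tb] <- want[ta, tb] + 1
            want[tb, ta] <- want[tb, ta] + 1
          }
        }
      }
    }
  }
  expect_equal(as.matrix(got$counts)[got$tokens, got$tokens], want)
  expect_equal(got$total_pairs, sum(want) / 2)
})

test_that("ppmi transform reproduces hand arithmetic and clamps at zero", {
  # single pair (A,B): p(A,B) = 1/2 (ordered), p(A) = p(B) = 1/2 -> PMI = ln 2
  cooc <- count_cooccurrence(
    make_corpus(make_record("p1", 0, c("D_A", "D_B"))),
    context_spec("time", 0))
  M <- ppmi_transform(cooc)
  expect_equal(M$values["D_A", "D_B"], log(2))
  expect_equal(M$values["D_B", "D_A"], log(2))
  # symmetric and non-negative always
  sim <- generate_corpus(synth_config(n_patients = 20, n_groups = 3,
                                      codes_per_group = 4,
                                      background_codes = 2, seed = 5))
  M2 <- ppmi_transform(count_cooccurrence(sim$corpus, context_spec("time", 15)))
  expect_equal(M2$values, Matrix::t(M2$values))
  expect_gte(min(M2$values), 0)
  empty <- structure(list(counts = Matrix::Matrix(0, 2, 2, sparse = TRUE),
                          total_pairs = 0, tokens = c("D_A", "D_B")),
                     class = "ehr_cooc")
  expect_error(ppmi_transform(empty), "empty")
})

test_that("joint probabilities sum to one over ordered pairs", {
  sim <- generate_corpus(synth_config(n_patients = 15, n_groups = 2,
                                      codes_per_group = 5,
                                      background_codes = 2, seed = 9))
  cooc <- count_cooccurrence(sim$corpus, context_spec("time", 0))
  p <- as.matrix(cooc$counts) / (2 * cooc$total_pairs)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("near-independent tokens get near-zero PMI", {
  # exchangeable counts over 20 tokens approximate independence; the exact
  # residual PMI is log(V / (V - 1)) from the empty diagonal
  V <- 20
  counts <- matrix(4, V, V) - diag(4, V)
  dimnames(counts) <- list(paste0("D_", 1:V), paste0("D_", 1:V))
  cooc <- structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                         total_pairs = sum(counts) / 2,
                         tokens = rownames(counts)),
                    class = "ehr_cooc")
  M <- ppmi_transform(cooc)
  expect_equal(max(as.matrix(M$values)[upper.tri(counts)]),
               log(V / (V - 1)), tolerance = 1e-12)
  expect_lt(max(abs(as.matrix(M$values))), 0.06)
})

test_that("svd_embed matches a dense SVD oracle and canonicalizes signs", {
  expect_equal(svd_embed(diag(4), 4)$S, rep(1, 4))
  # exact rank-1 recovery
  x <- c(3, 1, 2, 0.5)
  M1 <- x %o% x
  dec1 <- svd_embed(M1, 1)
  recon <- dec1$U %*% diag(dec1$S, 1) %*% t(dec1$U)
  expect_lt(max(abs(recon - M1)), 1e-8)
  # random symmetric 20x20 vs dense truncation
  set.seed(23)
  A <- matrix(runif(400), 20)
  M <- pmax(A + t(A) - 1, 0); diag(M) <- 0
  rownames(M) <- colnames(M) <- paste0("D_", 1:20)
  dec <- svd_embed(M, 5)
  full <- svd(M)
  want <- full$u[, 1:5] %*% diag(full$d[1:5]) %*% t(full$v[, 1:5])
  # for symmetric M the right vectors are +/- the left ones; recover the
  # sign from u_k' M u_k and rebuild the rank-5 truncation from U, S alone
  signs <- vapply(1:5, function(k) {
    sign(drop(t(dec$U[, k]) %*% M %*% dec$U[, k]))
  }, 0)
  got <- dec$U %*% diag(dec$S * signs) %*% t(dec$U)
  expect_lt(norm(got - want, "F"), 1e-6)
  # singular values descending, columns orthonormal
  expect_true(all(diff(dec$S) <= 1e-12))
  expect_equal(crossprod(dec$U), diag(5), tolerance = 1e-8)
  # each column's largest-magnitude entry is positive
  for (k in 1:5) expect_gt(dec$U[which.max(abs(dec$U[, k])), k], 0)
  expect_error(svd_embed(M, 21), "1 <= d <= V")
})

test_that("scaling the PPMI matrix leaves embeddings unchanged up to sign", {
  set.seed(29)
  A <- matrix(runif(100), 10)
  M <- pmax(A + t(A) - 0.8, 0); diag(M) <- 0
  rownames(M) <- colnames(M) <- paste0("D_", 1:10)
  u1 <- svd_embed(M, 3)$U
  u2 <- svd_embed(M * 7.3, 3)$U
  expect_equal(abs(u1), abs(u2), tolerance = 1e-8)
})

test_that("train_ppmi wires the three steps into an embedding", {
  sim <- generate_corpus(synth_config(n_patients = 40, n_groups = 2,
                                      codes_per_group = 5,
                                      background_codes = 4, seed = 13))
  emb <- train_ppmi(sim$corpus, context_spec("time", 0), dim = 10)
  expect_s3_class(emb, "ehr_embedding")
  expect_equal(dim(emb$input), c(nrow(sim$corpus$vocabulary), 10))
  expect_true(all(is.finite(emb$input)))
  # deterministic: no RNG anywhere in the pipeline
  expect_identical(emb$input,
                   train_ppmi(sim$corpus, context_spec("time", 0), 10)$input)
})
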