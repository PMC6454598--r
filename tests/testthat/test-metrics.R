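test_that("icd prefix grouping strips at the first dot", {
  expect_equal(icd_prefix_group("493.22"), "493")
  expect_equal(icd_prefix_group("493.91"), "493")
  expect_equal(icd_prefix_group("V10"), "V10")
  expect_equal(icd_prefix_group("E950.1"), "E950")
  g <- icd_prefix_grouping(c("D_493.22", "D_493.91", "M_aspirin", "D_250.00"))
  expect_equal(unname(g[c("D_493.22", "D_493.91", "D_250.00")]),
               c("493", "493", "250"))
  expect_false("M_aspirin" %in% names(g))
})

test_that("cosine handles the standard identities and edge cases", {
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_warning(z <- cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_equal(z, 0)
  expect_error(cosine_similarity(1:2, 1:3), "dimension mismatch")
})

test_that("in/out-cluster distances match explicit pair loops", {
  tokens <- paste0("D_", 1:6)
  vecs <- list(c(1, 0), c(0.9, 0.1), c(0, 1), c(0.1, 0.9),
               c(-1, 0.2), c(-0.9, -0.1))
  emb <- hand_embedding(tokens, vecs)
  grouping <- setNames(rep(c("a", "b", "c"), each = 2), tokens)
  # oracle: explicit loops
  dist <- function(i, j) 1 - cosine_similarity(vecs[[i]], vecs[[j]])
  d_in_want <- mean(c(dist(1, 2), dist(3, 4), dist(5, 6)))
  cross <- function(a, b) mean(outer(a, b, Vectorize(dist)))
  d_out_want <- mean(c(cross(1:2, 3:4), cross(1:2, 5:6), cross(3:4, 5:6)))
  expect_equal(in_cluster_distance(emb, grouping), d_in_want)
  expect_equal(out_cluster_distance(emb, grouping), d_out_want)
  # identical vectors within groups -> d_in exactly 0
  same <- hand_embedding(tokens, rep(list(c(1, 2), c(3, -1), c(0, 2)),
                                     each = 2))
  expect_equal(in_cluster_distance(same, grouping), 0)
  # all vectors identical -> no decoupling at all
  flat <- hand_embedding(tokens, rep(list(c(1, 1)), 6))
  expect_equal(out_cluster_distance(flat, grouping), 0)
  # single pair group / two singleton groups reduce to 1 - cosine
  two <- hand_embedding(c("D_1", "D_2"), list(c(1, 0), c(1, 1)))
  expect_equal(in_cluster_distance(two, setNames(c("g", "g"), c("D_1", "D_2"))),
               1 - 1 / sqrt(2))
  expect_equal(out_cluster_distance(two, setNames(c("g", "h"),
                                                  c("D_1", "D_2"))),
               1 - 1 / sqrt(2))
  # errors when the structure degenerates
  expect_error(in_cluster_distance(two, setNames(c("g", "h"),
                                                 c("D_1", "D_2"))),
               ">= 2 members")
  expect_error(out_cluster_distance(two, setNames(c("g", "g"),
                                                  c("D_1", "D_2"))),
               "at least two groups")
  expect_error(in_cluster_distance(two, setNames("g", "D_99")),
               "no grouped token")
})

test_that("mcsm matches a brute-force ranking oracle and its closed forms", {
  tokens <- paste0("D_", 1:6)
  vecs <- list(c(1, 0), c(0.95, 0.05), c(0.9, 0.2), c(0, 1),
               c(0.05, 0.95), c(-0.3, 0.9))
  emb <- hand_embedding(tokens, vecs)
  grouping <- setNames(rep(c("a", "b"), each = 3), tokens)
  k <- 3
  # oracle: full similarity matrix + sort, explicit loop
  want <- mean(vapply(1:6, function(v) {
    sims <- vapply(1:6, function(u) {
      cosine_similarity(vecs[[v]], vecs[[u]])
    }, 0)
    others <- setdiff(1:6, v)
    ord <- others[order(-sims[others], tokens[others])]
    sum(vapply(1:k, function(i) {
      (grouping[tokens[ord[i]]] == grouping[tokens[v]]) / log2(i + 1)
    }, 0))
  }, 0))
  expect_equal(mcsm(emb, grouping, k = k), want)
  # all one group: exactly the DCG ceiling; k = 1 -> 1
  one <- setNames(rep("g", 6), tokens)
  expect_equal(mcsm(emb, one, k = 3), sum(1 / log2((1:3) + 1)))
  expect_equal(mcsm(emb, one, k = 1), 1)
  # no two concepts share a group -> 0
  all_diff <- setNames(letters[1:6], tokens)
  expect_equal(mcsm(emb, all_diff, k = 3), 0)
  # scale invariance
  scaled <- hand_embedding(tokens, lapply(vecs, function(v) v * 17))
  expect_equal(mcsm(scaled, grouping, k = k), want)
  # k larger than the pool truncates with a warning
  expect_warning(m <- mcsm(emb, grouping, k = 10), "truncating")
  expect_equal(m, mcsm(emb, grouping, k = 5))
})

test_that("knn_query ranks by cosine with deterministic tie-breaks", {
  emb <- hand_embedding(paste0("D_", 1:4),
                        list(c(1, 0), c(1, 0), c(0, 1), c(0.9, 0.1)))
  res <- knn_query(emb, "D_1", k = 3)
  # exact duplicate ranked first at similarity 1
  expect_equal(res$token[1], "D_2")
  expect_equal(res$similarity[1], 1)
  expect_equal(res$token, c("D_2", "D_4", "D_3"))
  # k >= V - 1 returns everything else
  expect_equal(nrow(knn_query(emb, "D_1", k = 99)), 3)
  expect_error(knn_query(emb, "D_99", 3), "unknown token")
  # ties broken by token string: D_1 and D_2 are identical vectors
  res3 <- knn_query(emb, "D_3", k = 4)
  tie <- res3$token[res3$similarity == res3$similarity[res3$token == "D_1"]]
  expect_equal(tie, sort(tie))
})

test_that("random embeddings with random grouping show no cohesion gap", {
  set.seed(101)
  n <- 500 # 50 groups x 10 members, 20 dims
  emb <- ehrembed:::new_embedding(sprintf("D_%03d", 1:n),
                                  matrix(rnorm(n * 20), n, 20))
  grouping <- setNames(sprintf("g%02d", rep(1:50, each = 10)), emb$tokens)
  d_in <- in_cluster_distance(emb, grouping)
  d_out <- out_cluster_distance(emb, grouping)
  expect_lt(abs(d_in - d_out), 0.05)
  expect_true(d_in >= 0 && d_in <= 2 && d_out >= 0 && d_out <= 2)
})

test_that("grouping CSV round-trips and validates", {
  g <- setNames(c("493", "493", "250"), c("D_493.22", "D_493.91", "D_250.00"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_grouping(g, path)
  expect_identical(read_grouping(path), g)
  writeLines(c("token,group", "D_1,a", "D_1,b"), path)
  expect_error(read_grouping(path), "more than one group")
  writeLines(c("a,b", "x,y"), path)
  expect_error(read_grouping(path), "columns")
})

test_that("metric_report bundles the three metrics and writes JSON", {
  tokens <- paste0("D_", 1:6)
  emb <- hand_embedding(tokens, list(c(1, 0), c(0.9, 0.1), c(0, 1),
                                     c(0.1, 0.9), c(-1, 0), c(-0.9, -0.1)))
  grouping <- setNames(rep(c("a", "b", "c"), each = 2), tokens)
  rep <- metric_report(emb, grouping, k = 2, embedding_name = "hand",
                       grouping_name = "toy")
  expect_equal(rep$d_in, in_cluster_distance(emb, grouping))
  expect_equal(rep$d_out, out_cluster_distance(emb, grouping))
  expect_equal(rep$mcsm, mcsm(emb, grouping, k = 2))
  expect_lte(rep$mcsm, sum(1 / log2((1:2) + 1)))
  path <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$d_in, rep$d_in, tolerance = 1e-8)
  expect_equal(back$embedding, "hand")
})
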