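test_that("co-occurrence counting matches hand enumeration on a tiny doc", {
  corpus <- list(list(doc_id = "d1", tokens = c("a", "b", "a")))
  cfg <- space_config(2, 2, 1, 1)
  cooc <- build_cooccurrence(corpus, cfg)
  m <- as.matrix(cooc$counts)
  # positions: a(1) b(2) a(3), window 1: pairs (1,2),(2,3) in both directions
  expect_equal(m["a", "b"], 2)
  expect_equal(m["b", "a"], 2)
  expect_equal(m["a", "a"], 0)
  expect_equal(m["b", "b"], 0)
})

test_that("co-occurrence equals the naive double-loop oracle on random corpora", {
  set.seed(42)
  vocab <- c("alpha", "beta", "gamma", "delta", "eps")
  for (rep in 1:5) {
    corpus <- random_corpus(20, 30, vocab)
    cfg <- space_config(5, 5, 3, 2)
    cooc <- build_cooccurrence(corpus, cfg)
    ref <- ref_cooccurrence(corpus, cooc$targets, cooc$contexts, 3)
    expect_equal(as.matrix(cooc$counts), ref, ignore_attr = FALSE)
  }
})

test_that("windows do not cross document boundaries", {
  two_docs <- list(list(doc_id = "d1", tokens = c("a", "b")),
                   list(doc_id = "d2", tokens = c("b", "a")))
  one_doc <- list(list(doc_id = "d1", tokens = c("a", "b", "b", "a")))
  cfg <- space_config(2, 2, 3, 1)
  m2 <- as.matrix(build_cooccurrence(two_docs, cfg)$counts)
  m1 <- as.matrix(build_cooccurrence(one_doc, cfg)$counts)
  expect_equal(m2["a", "a"], 0)  # the two a's sit in different documents
  expect_gt(m1["a", "a"], 0)
})

test_that("log weighting is entrywise ln(x+1), preserves zeros, is monotone", {
  expect_equal(log_weight(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(log_weight(matrix(exp(1) - 1, 1, 1))[1, 1], 1)
  set.seed(1)
  x <- matrix(rpois(30, 4), 5, 6)
  w <- log_weight(Matrix::Matrix(x, sparse = TRUE))
  ref <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) ref[i, j] <- log(x[i, j] + 1)
  expect_equal(as.matrix(w), ref, ignore_attr = TRUE)
  # monotone
  xs <- sort(runif(20, 0, 50))
  expect_true(all(diff(log1p(xs)) >= 0))
  expect_error(log_weight(matrix(-1, 1, 1)), "nonnegative")
})

test_that("rank-1 matrix yields identical word vectors at k = 1", {
  u <- c(1, 2, 3); v <- c(2, 1)
  m <- outer(u, v)
  rownames(m) <- c("aa", "bb", "cc")
  sp <- reduce_svd(m, 1)
  expect_equal(abs(sp$vectors[, 1]), rep(1, 3), ignore_attr = TRUE)
  expect_equal(length(unique(sign(sp$vectors[, 1]))), 1L)
})

test_that("truncated SVD matches the dense full-SVD oracle to 1e-8", {
  set.seed(9)
  m <- matrix(rpois(200, 2), 20, 10)
  rownames(m) <- replicate(20, paste(sample(letters, 6), collapse = ""))
  m[3, ] <- m[3, ] + 1  # ensure no all-zero row distracts from the check
  w <- log_weight(m)
  k <- 5
  sv <- svd(w)  # dense full-SVD oracle
  recon <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  # the truncation residual equals the tail singular values in closed form
  expect_equal(norm(w - recon, "F"), sqrt(sum(sv$d[(k + 1):10]^2)),
               tolerance = 1e-8)
  sp <- reduce_svd(w, k)
  ref_rows <- sv$u[, 1:k] %*% diag(sv$d[1:k])
  ref_rows <- ref_rows / sqrt(rowSums(ref_rows^2))
  # row Gram matrices are invariant to the per-column sign convention
  expect_equal(unname(sp$vectors %*% t(sp$vectors)),
               ref_rows %*% t(ref_rows), tolerance = 1e-8)
  expect_equal(sqrt(rowSums(sp$vectors^2)), rep(1, nrow(sp$vectors)),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("all-zero rows are flagged degenerate and excluded", {
  m <- rbind(aa = c(1, 2, 0), bb = c(0, 0, 0), cc = c(2, 1, 1))
  sp <- reduce_svd(m, 2)
  expect_identical(sp$degenerate, "bb")
  expect_false("bb" %in% sp$words)
})

test_that("full-rank SVD reproduces cosines of directly normalized rows", {
  set.seed(5)
  m <- matrix(runif(48), 8, 6)
  rownames(m) <- paste0("w", letters[1:8])
  sp <- reduce_svd(m, 6)
  direct <- m / sqrt(rowSums(m^2))
  for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
    expect_equal(cosine(sp, rownames(m)[pair[1]], rownames(m)[pair[2]]),
                 sum(direct[pair[1], ] * direct[pair[2], ]),
                 tolerance = 1e-8)
  }
})

test_that("space build is deterministic, including SVD signs", {
  set.seed(33)
  corpus <- random_corpus(15, 40, c("aa", "bb", "cc", "dd", "ee", "ff"))
  cfg <- space_config(6, 6, 2, 3)
  s1 <- semantic_space(corpus, cfg)
  s2 <- semantic_space(corpus, cfg)
  expect_identical(s1$vectors, s2$vectors)
})

test_that("cosine is symmetric, 1 on the diagonal, errors out of vocabulary", {
  sp <- toy_space(rbind(dog = c(1, 0), cat = c(1, 1), pen = c(0, 1)))
  expect_equal(cosine(sp, "dog", "dog"), 1)
  expect_equal(cosine(sp, "dog", "pen"), 0)
  expect_equal(cosine(sp, "dog", "cat"), cosine(sp, "cat", "dog"))
  expect_equal(cosine(sp, "dog", "cat"), 1 / sqrt(2))
  expect_error(cosine(sp, "dog", "zebra"), "zebra")
})

test_that("synonym test ranks match an exhaustive cosine sort", {
  set.seed(12)
  vecs <- matrix(rnorm(10 * 4), 10, 4)
  rownames(vecs) <- paste0("w", letters[1:10])
  sp <- toy_space(vecs)
  pairs <- data.frame(word = c("wa", "wc", "wf"),
                      synonym = c("wb", "wj", "wa"))
  st <- synonym_test(sp, pairs)
  for (r in seq_len(nrow(pairs))) {
    probe <- pairs$word[r]; syn <- pairs$synonym[r]
    sims <- drop(sp$vectors %*% sp$vectors[probe, ])
    names(sims) <- rownames(vecs)
    sims <- sims[names(sims) != probe]
    ranked <- names(sort(-sims))
    expect_identical(st$per_pair$rank[r], match(syn, ranked))
  }
  expect_equal(st$mrr, mean(1 / st$per_pair$rank))
})

test_that("synonym test skips out-of-vocabulary pairs and rejects empty input", {
  sp <- toy_space(rbind(dog = c(1, 0), cat = c(0, 1)))
  expect_error(synonym_test(sp, data.frame(a = character(0),
                                           b = character(0))),
               "no synonym pairs")
  expect_warning(st <- synonym_test(sp, data.frame(a = c("dog", "dog"),
                                                   b = c("cat", "zebra"))),
                 "skipped")
  expect_identical(st$n_skipped, 1L)
  expect_identical(nrow(st$per_pair), 1L)
})

test_that("space survives a write/read round trip with unit-norm validation", {
  set.seed(2)
  corpus <- random_corpus(10, 30, c("aa", "bb", "cc", "dd"))
  sp <- semantic_space(corpus, space_config(4, 4, 2, 2))
  f <- withr::local_tempfile()
  write_space(sp, f)
  back <- read_space(f)
  expect_identical(back$words, sp$words)
  expect_equal(back$vectors, sp$vectors, tolerance = 1e-15)
})
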