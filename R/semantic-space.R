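# LSA semantic space: windowed co-occurrence counts over a corpus,
# log-plus-one weighting, truncated SVD, unit-norm word vectors.

#' Semantic space configuration
#'
#' Holds the parameters of the space construction. The classical full-scale
#' configuration is 100,000 target words, 10,000 context words, a window of
#' 15 tokens on each side and 100 dimensions; the defaults here are a
#' desk-scale version suitable for simulation studies and tests, overridable
#' to full scale.
#'
#' @param n_target_words Row vocabulary size: the most frequent corpus words
#'   that receive vectors.
#' @param n_context_words Column vocabulary size: the most frequent corpus
#'   words used as contexts. Must not exceed `n_target_words`.
#' @param window_half_width Number of tokens on each side of the target that
#'   count as its context.
#' @param k Dimensionality of the reduced space.
#' @param scale_by_singular_values If `TRUE` (default) word vectors are rows
#'   of \eqn{U_k \Sigma_k} before unit normalization, preserving classical
#'   LSA's weighting of dominant dimensions; if `FALSE`, rows of \eqn{U_k}.
#' @return An object of class `space_config`.
#' @export
space_config <- function(n_target_words = 2000L, n_context_words = 500L,
                         window_half_width = 15L, k = 50L,
                         scale_by_singular_values = TRUE) {
  stopifnot(n_target_words >= 1, n_context_words >= 1,
            window_half_width >= 1, k >= 1)
  if (n_context_words > n_target_words)
    stop("n_context_words must not exceed n_target_words")
  if (k > min(n_target_words, n_context_words))
    stop("k must not exceed min(n_target_words, n_context_words)")
  structure(list(n_target_words = as.integer(n_target_words),
                 n_context_words = as.integer(n_context_words),
                 window_half_width = as.integer(window_half_width),
                 k = as.integer(k),
                 scale_by_singular_values = isTRUE(scale_by_singular_values)),
            class = "space_config")
}

# Most frequent corpus words; frequency ties broken lexicographically so the
# vocabulary (and hence the whole space) is deterministic.
.build_vocab <- function(freq, n, what) {
  ord <- order(-freq, names(freq), method = "radix")
  vocab <- names(freq)[ord]
  if (length(vocab) < n)
    warning(what, " vocabulary shrunk to ", length(vocab),
            " words (corpus has fewer types than requested)")
  utils::head(vocab, n)
}

#' Build the windowed co-occurrence matrix
#'
#' Counts, for every target-word occurrence, the context-word occurrences
#' within `window_half_width` positions on either side. Windows never cross
#' document boundaries, and a token is never its own context (offset zero is
#' excluded), though other occurrences of the same word type do count.
#'
#' @param corpus List of documents as returned by [read_corpus()].
#' @param config A [space_config()].
#' @return List with `targets`, `contexts` (character vocabularies) and
#'   `counts` (sparse `dgCMatrix`, targets x contexts).
#' @export
build_cooccurrence <- function(corpus, config = space_config()) {
  if (length(corpus) == 0L) stop("corpus is empty")
  token_list <- lapply(corpus, `[[`, "tokens")
  all_tokens <- unlist(token_list, use.names = FALSE)
  if (length(all_tokens) == 0L) stop("corpus contains no tokens")

  freq <- table(all_tokens)
  freq <- stats::setNames(as.integer(freq), names(freq))
  targets <- .build_vocab(freq, config$n_target_words, "target")
  contexts <- .build_vocab(freq, config$n_context_words, "context")

  ti <- match(all_tokens, targets)   # NA when not a target word
  ci <- match(all_tokens, contexts)
  doc_id <- rep.int(seq_along(token_list),
                    vapply(token_list, length, integer(1)))
  n <- length(all_tokens)

  rows <- integer(0); cols <- integer(0)
  for (off in seq_len(config$window_half_width)) {
    if (off >= n) break
    i <- seq_len(n - off)
    j <- i + off
    same_doc <- doc_id[i] == doc_id[j]
    # context following the target
    keep <- same_doc & !is.na(ti[i]) & !is.na(ci[j])
    rows <- c(rows, ti[i][keep]); cols <- c(cols, ci[j][keep])
    # context preceding the target
    keep <- same_doc & !is.na(ti[j]) & !is.na(ci[i])
    rows <- c(rows, ti[j][keep]); cols <- c(cols, ci[i][keep])
  }
  counts <- Matrix::sparseMatrix(
    i = rows, j = cols, x = rep.int(1, length(rows)),
    dims = c(length(targets), length(contexts)),
    dimnames = list(targets, contexts)
  )
  list(targets = targets, contexts = contexts,
       counts = methods::as(counts, "CsparseMatrix"))
}

#' Log-plus-one weighting
#'
#' Replaces each co-occurrence count x by ln(x + 1), moderating the impact
#' of high-frequency words. Zeros map to zero, so sparsity is preserved.
#'
#' @param cooc A co-occurrence object from [build_cooccurrence()], or a bare
#'   (sparse or dense) nonnegative matrix.
#' @return Same structure with weighted counts.
#' @export
log_weight <- function(cooc) {
  m <- if (is.list(cooc)) cooc$counts else cooc
  if (inherits(m, "sparseMatrix")) {
    if (any(m@x < 0)) stop("co-occurrence counts must be nonnegative")
    m@x <- log1p(m@x)
  } else {
    if (any(m < 0)) stop("co-occurrence counts must be nonnegative")
    m <- log1p(m)
  }
  if (is.list(cooc)) { cooc$counts <- m; cooc } else m
}

# Deterministic SVD sign convention: each left singular vector is flipped so
# that its largest-magnitude component (first index on ties) is positive.
.fix_svd_signs <- function(sv) {
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  sv
}

#' Reduce a weighted co-occurrence matrix to a semantic space
#'
#' Truncated rank-k SVD of the weighted matrix. Each target word's vector is
#' its row of \eqn{U_k \Sigma_k} (or \eqn{U_k}), rescaled to Euclidean norm
#' one. Words whose weighted row is all zero have no direction and are
#' excluded from the space, flagged as degenerate.
#'
#' @param weighted Output of [log_weight()] (list or bare matrix).
#' @param k Number of dimensions to retain; reduced with a warning if the
#'   matrix has fewer nonzero singular values.
#' @param scale_by_singular_values See [space_config()].
#' @return An object of class `semantic_space`: `words`, `vectors` (matrix
#'   with one unit-norm row per word), `k`, `singular_values`, `degenerate`.
#' @export
reduce_svd <- function(weighted, k, scale_by_singular_values = TRUE) {
  m <- if (is.list(weighted)) weighted$counts else weighted
  if (k <= 0) stop("k must be a positive integer")
  if (k > min(dim(m))) stop("k exceeds matrix dimensions")

  dense <- as.matrix(m)
  words <- rownames(dense)
  if (is.null(words)) words <- sprintf("w%d", seq_len(nrow(dense)))
  degenerate <- words[rowSums(abs(dense)) == 0]

  sv <- svd(dense)
  rank_tol <- max(dim(dense)) * .Machine$double.eps * sv$d[1L]
  n_pos <- sum(sv$d > rank_tol)
  if (n_pos < k) {
    warning("matrix has only ", n_pos, " nonzero singular values; k reduced")
    k <- n_pos
  }
  sv <- .fix_svd_signs(sv)
  vec <- sv$u[, seq_len(k), drop = FALSE]
  if (scale_by_singular_values)
    vec <- sweep(vec, 2L, sv$d[seq_len(k)], `*`)
  rownames(vec) <- words

  keep <- !words %in% degenerate
  vec <- vec[keep, , drop = FALSE]
  norms <- sqrt(rowSums(vec^2))
  # a nonzero row can still project to ~zero in the truncated space
  proj_zero <- norms < 1e-12
  if (any(proj_zero)) {
    degenerate <- c(degenerate, rownames(vec)[proj_zero])
    vec <- vec[!proj_zero, , drop = FALSE]
    norms <- norms[!proj_zero]
  }
  vec <- vec / norms

  structure(list(words = rownames(vec), vectors = vec, k = as.integer(k),
                 singular_values = sv$d[seq_len(k)],
                 degenerate = degenerate),
            class = "semantic_space")
}

#' Build an LSA semantic space from a corpus
#'
#' Convenience wrapper running [build_cooccurrence()], [log_weight()] and
#' [reduce_svd()] in sequence. The build is fully deterministic for a fixed
#' corpus and configuration.
#'
#' @param corpus List of documents as returned by [read_corpus()].
#' @param config A [space_config()].
#' @return A `semantic_space` object (see [reduce_svd()]) with the
#'   configuration attached.
#' @examples
#' docs <- list(list(doc_id = "d1", tokens = tokenize("the dog bit the cat")))
#' sp <- semantic_space(docs, space_config(5, 5, 2, 2))
#' @export
semantic_space <- function(corpus, config = space_config()) {
  cooc <- build_cooccurrence(corpus, config)
  space <- reduce_svd(log_weight(cooc), config$k,
                      config$scale_by_singular_values)
  space$config <- config
  space
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("Semantic space:", length(x$words), "words x", x$k, "dimensions\n")
  if (length(x$degenerate))
    cat("degenerate (excluded) words:", length(x$degenerate), "\n")
  invisible(x)
}

.space_lookup <- function(space, word) {
  i <- match(word, space$words)
  if (is.na(i)) stop("word not in semantic space: '", word, "'")
  space$vectors[i, ]
}

#' Cosine similarity between two words
#'
#' Since all stored vectors have unit norm, the cosine is the plain dot
#' product. Symmetric; 1 for a word with itself.
#'
#' @param space A `semantic_space`.
#' @param w1,w2 Words, both required to be in the space.
#' @return Similarity in \[-1, 1\].
#' @export
cosine <- function(space, w1, w2) {
  sum(.space_lookup(space, w1) * .space_lookup(space, w2))
}

#' Synonym test of space quality
#'
#' For each (probe, synonym) pair, ranks all other vocabulary words by
#' descending cosine to the probe (ties broken lexicographically) and
#' records the synonym's rank; rank 1 means the synonym is the probe's
#' nearest neighbour. Quality summaries are the mean reciprocal rank and
#' the fraction of pairs at rank 1.
#'
#' @param space A `semantic_space`.
#' @param pairs Two-column data frame or matrix: probe word, synonym.
#' @return Object of class `synonym_test`: per-pair data frame (`word`,
#'   `synonym`, `rank`, `cosine`), `mrr`, `frac_top1`, `n_skipped`.
#' @export
synonym_test <- function(space, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) stop("no synonym pairs supplied")
  res <- vector("list", nrow(pairs))
  skipped <- 0L
  for (r in seq_len(nrow(pairs))) {
    probe <- as.character(pairs[[1L]][r]); syn <- as.character(pairs[[2L]][r])
    if (!probe %in% space$words || !syn %in% space$words) {
      warning("synonym pair skipped (out of vocabulary): ",
              probe, " / ", syn)
      skipped <- skipped + 1L
      next
    }
    sims <- drop(space$vectors %*% .space_lookup(space, probe))
    others <- space$words != probe
    ord <- order(-sims[others], space$words[others], method = "radix")
    ranked <- space$words[others][ord]
    res[[r]] <- data.frame(word = probe, synonym = syn,
                           rank = match(syn, ranked),
                           cosine = unname(sims[space$words == syn]),
                           stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, res)
  if (is.null(per_pair)) stop("all synonym pairs were out of vocabulary")
  structure(list(per_pair = per_pair,
                 mrr = mean(1 / per_pair$rank),
                 frac_top1 = mean(per_pair$rank == 1L),
                 n_skipped = skipped),
            class = "synonym_test")
}

#' @export
print.synonym_test <- function(x, ...) {
  cat(sprintf(
    "Synonym test: %d pairs, mean reciprocal rank %.3f, rank-1 fraction %.3f",
    nrow(x$per_pair), x$mrr, x$frac_top1))
  if (x$n_skipped > 0L) cat(sprintf(" (%d skipped)", x$n_skipped))
  cat("\n")
  invisible(x)
}

#' Persist a semantic space as text
#'
#' Standard word-embedding text format: a header line `"<n_words> <k>"`,
#' then one line per word, `"word v1 ... vk"`.
#'
#' @param space A `semantic_space`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(space$words), space$k), con)
  body <- vapply(seq_along(space$words), function(i) {
    paste(space$words[i],
          paste(formatC(space$vectors[i, ], format = "g", digits = 17),
                collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Load a semantic space written by [write_space()]
#'
#' Validates that every loaded vector has unit norm.
#'
#' @param path Input file path.
#' @return A `semantic_space` object.
#' @export
read_space <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  n <- hdr[1L]; k <- hdr[2L]
  if (length(lines) != n + 1L) stop("malformed space file: row count mismatch")
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(k)))
  rownames(vec) <- words
  norms <- sqrt(rowSums(vec^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("space file contains non-unit vectors")
  structure(list(words = words, vectors = vec, k = k,
                 singular_values = NULL, degenerate = character(0)),
            class = "semantic_space")
}
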