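# Independent reference implementations used as oracles. Each is written
# as plainly as possible (character loops, double loops, exhaustive
# enumeration, generic numeric optimization) and never shares code with
# the package internals it checks.

# Character-by-character tokenizer: walk the string, accumulate letters,
# flush the buffer at every non-letter.
ref_tokenize <- function(text) {
  chars <- strsplit(tolower(text), "", fixed = TRUE)[[1L]]
  out <- character(0)
  buf <- ""
  for (ch in chars) {
    if (grepl("^\\p{L}$", ch, perl = TRUE)) {
      buf <- paste0(buf, ch)
    } else if (nzchar(buf)) {
      out <- c(out, buf)
      buf <- ""
    }
  }
  if (nzchar(buf)) out <- c(out, buf)
  out
}

# Naive O(N * h) co-occurrence counter: for every token position and every
# in-window offset, increment one dense cell.
ref_cooccurrence <- function(corpus, targets, contexts, h) {
  m <- matrix(0, length(targets), length(contexts),
              dimnames = list(targets, contexts))
  for (doc in corpus) {
    toks <- doc$tokens
    n <- length(toks)
    for (i in seq_len(n)) {
      if (!toks[i] %in% targets) next
      for (off in c(-(h:1), 1:h)) {
        j <- i + off
        if (j < 1 || j > n) next
        if (toks[j] %in% contexts) m[toks[i], toks[j]] <- m[toks[i], toks[j]] + 1
      }
    }
  }
  m
}

# Exhaustive pair-counting AUC: P(score_pos > score_neg) + 0.5 P(equal)
# over all positive x negative pairs.
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Generic numeric maximizer of the penalized logistic log-likelihood,
# entirely independent of the package's IRLS: BFGS on the analytic
# objective, polished by Nelder-Mead restarts.
ref_ridge_logistic <- function(X, y, lambda) {
  negll <- function(theta) {
    eta <- theta[1] + drop(X %*% theta[-1])
    -(sum(y * eta - log1p(exp(eta))) - lambda / 2 * sum(theta[-1]^2))
  }
  grad <- function(theta) {
    p <- 1 / (1 + exp(-(theta[1] + drop(X %*% theta[-1]))))
    -c(sum(y - p), drop(crossprod(X, y - p)) - lambda * theta[-1])
  }
  fit <- stats::optim(numeric(ncol(X) + 1), negll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  stats::optim(fit$par, negll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# Tiny hand-built semantic space from an explicit matrix of unit vectors.
toy_space <- function(vectors) {
  vectors <- vectors / sqrt(rowSums(vectors^2))
  structure(list(words = rownames(vectors), vectors = vectors,
                 k = ncol(vectors), singular_values = NULL,
                 degenerate = character(0)),
            class = "semantic_space")
}

# Random letter-only corpus over a small alphabet of word types.
random_corpus <- function(n_docs, doc_len, vocab) {
  lapply(seq_len(n_docs), function(d) {
    list(doc_id = paste0("d", d),
         tokens = sample(vocab, doc_len, replace = TRUE))
  })
}
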