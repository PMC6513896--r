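# Synthetic study generator: a topic-structured corpus and two labelled
# narrative groups whose topic mixtures differ by a controllable semantic
# shift. The analysis is bag-of-words, so a Dirichlet mixture-of-topics
# generator reproduces exactly the structure the method can see; token
# order carries no information by construction.

# Letter-only word identifiers (the tokenizer treats digits as separators).
.make_vocab <- function(v) {
  stopifnot(v <= 26^3)
  g <- expand.grid(a = letters, b = letters, c = letters,
                   stringsAsFactors = FALSE)
  paste0("w", g$c, g$b, g$a)[seq_len(v)]
}

#' Configuration of the synthetic study
#'
#' Defines a vocabulary partitioned into topics, a topic-mixture corpus
#' generator, and two narrative groups (DLD and control, in cohorts A and
#' B) whose mean topic mixtures are displaced by `group_shift`. Defaults
#' emulate the study design: 36 + 36 children in cohort A, 18 + 18 in
#' cohort B, and a log-normal narrative-length distribution calibrated so
#' that about half of the narratives are shorter than 100 words.
#'
#' @param vocab_size Number of word types.
#' @param n_topics Number of topics; the first half are "immature" topics
#'   (over-weighted in DLD narratives), the second half "mature".
#' @param n_docs Corpus size in documents.
#' @param doc_length_mean Mean document length in tokens (Poisson).
#' @param n_children Named integer vector `A_dld`, `A_control`, `B_dld`,
#'   `B_control`.
#' @param narrative_meanlog,narrative_sdlog Log-normal narrative-length
#'   parameters; the defaults give median 90 tokens, so roughly half the
#'   narratives fall under 100 words.
#' @param group_shift Euclidean distance between the DLD and control mean
#'   topic-mixture vectors; 0 makes the groups identical in distribution.
#' @param child_concentration Dirichlet concentration of per-child topic
#'   mixtures around the group mean (larger = less between-child
#'   variation).
#' @param topic_background Probability mass each topic spreads uniformly
#'   over the whole vocabulary (the rest is concentrated, Zipf-decaying,
#'   on the topic's own word block).
#' @param doc_concentration Dirichlet concentration of per-document topic
#'   mixtures (small values give topically focused documents).
#' @param seed Integer seed; identical seed implies identical output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(vocab_size = 400L, n_topics = 6L,
                             n_docs = 250L, doc_length_mean = 60,
                             n_children = c(A_dld = 36L, A_control = 36L,
                                            B_dld = 18L, B_control = 18L),
                             narrative_meanlog = log(90),
                             narrative_sdlog = 0.6,
                             group_shift = 0.2,
                             child_concentration = 30,
                             topic_background = 0.05,
                             doc_concentration = 0.3,
                             seed = 1L) {
  stopifnot(n_topics >= 2L, n_topics <= vocab_size, n_docs >= 1L,
            group_shift >= 0, doc_length_mean > 0,
            all(n_children >= 1L),
            all(c("A_dld", "A_control", "B_dld", "B_control") %in%
                  names(n_children)))
  cfg <- structure(list(vocab_size = as.integer(vocab_size),
                        n_topics = as.integer(n_topics),
                        n_docs = as.integer(n_docs),
                        doc_length_mean = doc_length_mean,
                        n_children = n_children,
                        narrative_meanlog = narrative_meanlog,
                        narrative_sdlog = narrative_sdlog,
                        group_shift = group_shift,
                        child_concentration = child_concentration,
                        topic_background = topic_background,
                        doc_concentration = doc_concentration,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  .group_centers(cfg)  # validate group_shift at construction time
  cfg
}

# Topic-word probability matrix (vocab_size x n_topics), deterministic in
# the config: topic t concentrates (1 - background) on its own vocabulary
# block with Zipf-decaying probabilities, plus a uniform background.
.topic_word_matrix <- function(cfg) {
  v <- cfg$vocab_size; t <- cfg$n_topics
  block <- sort(rep_len(seq_len(t), v))
  phi <- matrix(cfg$topic_background / v, nrow = v, ncol = t)
  for (tp in seq_len(t)) {
    own <- which(block == tp)
    zipf <- 1 / seq_along(own)
    phi[own, tp] <- phi[own, tp] + (1 - cfg$topic_background) * zipf /
      sum(zipf)
  }
  rownames(phi) <- .make_vocab(v)
  phi
}

# Mean topic mixtures of the two groups: the uniform mixture displaced by
# +/- (shift/2) along the immature-vs-mature direction.
.group_centers <- function(cfg) {
  t <- cfg$n_topics
  n_imm <- ceiling(t / 2)
  u <- c(rep(1, n_imm), rep(-1, t - n_imm))
  u <- u / sqrt(sum(u^2))
  base <- rep(1 / t, t)
  centers <- list(control = base - cfg$group_shift / 2 * u,
                  dld = base + cfg$group_shift / 2 * u)
  if (any(unlist(centers) < 0))
    stop("group_shift = ", cfg$group_shift,
         " produces invalid (negative) topic probabilities for ",
         t, " topics")
  centers
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  g / sum(g)
}

# Sample one token sequence from a topic mixture: the marginal word
# distribution of an i.i.d. token stream is phi %*% theta.
.sample_tokens <- function(n, theta, phi) {
  sample(rownames(phi), n, replace = TRUE, prob = drop(phi %*% theta))
}

#' Generate a topic-structured synthetic corpus
#'
#' Each document draws a topic mixture from a Dirichlet and emits tokens
#' from the implied mixture over topic word distributions; words belonging
#' to the same topic therefore co-occur and land near each other in the
#' learned semantic space.
#'
#' @param cfg A [synthetic_config()].
#' @return List of corpus documents (`doc_id`, `tokens`), deterministic in
#'   `cfg$seed`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  phi <- .topic_word_matrix(cfg)
  alpha <- rep(cfg$doc_concentration, cfg$n_topics)
  lapply(seq_len(cfg$n_docs), function(d) {
    theta <- .rdirichlet1(alpha)
    len <- max(1L, stats::rpois(1L, cfg$doc_length_mean))
    list(doc_id = sprintf("doc%05d", d),
         tokens = .sample_tokens(len, theta, phi))
  })
}

#' Generate labelled synthetic narratives
#'
#' Each child draws a personal topic mixture from a Dirichlet centred on
#' their group's mean mixture (control and DLD means differ by
#' `group_shift`), then a narrative length from the log-normal length
#' distribution, then tokens. Uses `cfg$seed + 1`, so corpus and narrative
#' streams are independent but jointly reproducible.
#'
#' @param cfg A [synthetic_config()].
#' @return A `narrative_set` data frame (see [read_narratives()]).
#' @export
generate_narratives <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  phi <- .topic_word_matrix(cfg)
  centers <- .group_centers(cfg)
  plan <- data.frame(
    cohort = c("A", "A", "B", "B"),
    group = c("dld", "control", "dld", "control"),
    n = as.integer(cfg$n_children[c("A_dld", "A_control",
                                    "B_dld", "B_control")]),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (r in seq_len(nrow(plan))) {
    for (i in seq_len(plan$n[r])) {
      theta <- .rdirichlet1(cfg$child_concentration *
                              centers[[plan$group[r]]])
      len <- max(5L, as.integer(round(stats::rlnorm(
        1L, cfg$narrative_meanlog, cfg$narrative_sdlog))))
      rows[[length(rows) + 1L]] <- list(
        child_id = sprintf("%s_%s_%02d", plan$cohort[r], plan$group[r], i),
        cohort = plan$cohort[r],
        group_label = if (plan$group[r] == "dld") 1L else 0L,
        tokens = .sample_tokens(len, theta, phi))
    }
  }
  out <- data.frame(
    child_id = vapply(rows, `[[`, character(1), "child_id"),
    cohort = factor(vapply(rows, `[[`, character(1), "cohort"),
                    levels = c("A", "B")),
    group_label = vapply(rows, `[[`, integer(1), "group_label"),
    stringsAsFactors = FALSE
  )
  out$tokens <- lapply(rows, `[[`, "tokens")
  class(out) <- c("narrative_set", class(out))
  out
}

#' Write a synthetic corpus to disk
#'
#' One line per document (the line dialect of [read_corpus()]).
#'
#' @param corpus List of corpus documents.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, function(d) paste(d$tokens, collapse = " "),
                    character(1)), path)
  invisible(path)
}
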