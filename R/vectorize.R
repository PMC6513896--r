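# Summarizing narratives as unit vectors in the semantic space.

#' Vectorize one narrative
#'
#' Sums the semantic vectors of the narrative's tokens that are present in
#' the space — each occurrence contributes once, so repeated words weigh
#' more — and rescales the sum to unit length. Tokens missing from the
#' space are ignored (counted in `n_tokens_total` only). The result does
#' not depend on token order: the representation is bag-of-words.
#'
#' @param tokens Character vector of tokens (same tokenizer as the corpus).
#' @param space A `semantic_space`.
#' @param child_id Identifier carried through to the result and to error
#'   messages.
#' @param types_only If `TRUE`, each distinct word type contributes once
#'   regardless of its number of occurrences. Default `FALSE`
#'   (occurrence-weighted sum).
#' @return List with `child_id`, `vector` (unit-norm, length `space$k`),
#'   `n_tokens_total`, `n_tokens_in_space`.
#' @export
vectorize <- function(tokens, space, child_id = NA_character_,
                      types_only = FALSE) {
  idx <- match(tokens, space$words)
  in_space <- !is.na(idx)
  n_in <- sum(in_space)
  if (n_in == 0L)
    stop("unrepresentable narrative (no in-space words): child_id=", child_id)
  idx_in <- idx[in_space]
  if (types_only) idx_in <- unique(idx_in)
  v <- colSums(space$vectors[idx_in, , drop = FALSE])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12)
    stop("unrepresentable narrative (summed vector is zero): child_id=",
         child_id)
  list(child_id = child_id, vector = v / nv,
       n_tokens_total = length(tokens), n_tokens_in_space = n_in)
}

#' Vectorize a narrative set
#'
#' Applies [vectorize()] to every narrative and assembles the results into
#' one table with the vector components as columns `v1..vk`.
#'
#' @param narratives A `narrative_set` from [read_narratives()] or
#'   [generate_narratives()].
#' @param space A `semantic_space`.
#' @param types_only See [vectorize()].
#' @return A data frame of class `narrative_vectors`: `child_id`, `cohort`,
#'   `group_label`, `n_tokens_total`, `n_tokens_in_space`, `v1..vk`.
#'   Unrepresentable narratives raise an error naming the child.
#' @export
narrative_vectors <- function(narratives, space, types_only = FALSE) {
  vs <- lapply(seq_len(nrow(narratives)), function(i) {
    vectorize(narratives$tokens[[i]], space,
              child_id = narratives$child_id[i], types_only = types_only)
  })
  mat <- do.call(rbind, lapply(vs, `[[`, "vector"))
  colnames(mat) <- paste0("v", seq_len(ncol(mat)))
  out <- data.frame(
    child_id = narratives$child_id,
    cohort = narratives$cohort,
    group_label = narratives$group_label,
    n_tokens_total = vapply(vs, `[[`, integer(1), "n_tokens_total"),
    n_tokens_in_space = vapply(vs, `[[`, integer(1), "n_tokens_in_space"),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(mat))
  class(out) <- c("narrative_vectors", class(out))
  out
}

# Extract the numeric vector matrix from a narrative_vectors table.
.vector_matrix <- function(nv) {
  vcols <- grep("^v[0-9]+$", names(nv), value = TRUE)
  m <- as.matrix(nv[, vcols, drop = FALSE])
  rownames(m) <- nv$child_id
  m
}

#' Write per-child narrative vectors to TSV
#'
#' @param nv A `narrative_vectors` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(nv, path) {
  df <- as.data.frame(nv)
  df$cohort <- as.character(df$cohort)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a narrative-vector TSV written by [write_vectors()]
#'
#' @param path Input TSV path.
#' @return A `narrative_vectors` data frame.
#' @export
read_vectors <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  df$cohort <- factor(df$cohort, levels = c("A", "B"))
  class(df) <- c("narrative_vectors", class(df))
  df
}
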