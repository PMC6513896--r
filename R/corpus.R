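# Reading and tokenizing the training corpus and the labelled narratives.

#' Tokenize raw text
#'
#' Splits text into lowercase word tokens. The token pattern is maximal runs
#' of letters: the text is lowercased and split on every non-letter character,
#' so punctuation and digits act as separators and never appear inside a
#' token. The same tokenizer must be applied to the corpus and to the
#' narratives so that narrative words map into the semantic space.
#'
#' @param raw_text Character vector; elements are concatenated with spaces
#'   before tokenization.
#' @return Character vector of tokens, in text order; `character(0)` for
#'   empty input.
#' @examples
#' tokenize("The dog, the dog!")
#' @export
tokenize <- function(raw_text) {
  if (length(raw_text) == 0L) return(character(0))
  txt <- tolower(paste(raw_text, collapse = " "))
  toks <- strsplit(txt, "[^\\p{L}]+", perl = TRUE)[[1L]]
  toks[nzchar(toks)]
}

#' Read a plain-text corpus
#'
#' Reads training documents either from a directory (one document per file)
#' or from a single file (one document per line). All documents are run
#' through [tokenize()].
#'
#' @param path Directory of `.txt` files, or a single text file.
#' @param dialect `"auto"` (directory means per-file, file means per-line),
#'   `"file"` or `"line"`.
#' @return List of corpus documents, each a list with `doc_id` and `tokens`.
#' @export
read_corpus <- function(path, dialect = c("auto", "file", "line")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("corpus path does not exist: ", path)
  if (dialect == "auto") dialect <- if (dir.exists(path)) "file" else "line"

  if (dialect == "file") {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    docs <- lapply(files, function(f) {
      list(doc_id = basename(f),
           tokens = tokenize(readLines(f, warn = FALSE, encoding = "UTF-8")))
    })
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    docs <- lapply(seq_along(lines), function(i) {
      list(doc_id = sprintf("line%06d", i), tokens = tokenize(lines[[i]]))
    })
  }
  if (length(docs) == 0L) stop("no documents found under: ", path)
  n_empty <- sum(vapply(docs, function(d) length(d$tokens) == 0L, logical(1)))
  if (n_empty > 0L)
    warning(n_empty, " document(s) have zero tokens after tokenization")
  message("read_corpus: ", length(docs), " document(s)")
  docs
}

# Accepted spellings for the two group labels.
.label_map <- c(
  "1" = 1L, "dld" = 1L,
  "0" = 0L, "control" = 0L, "typical" = 0L, "td" = 0L
)

.parse_label <- function(x, row) {
  key <- tolower(trimws(as.character(x)))
  if (!key %in% names(.label_map))
    stop("row ", row, ": unrecognized group_label '", x,
         "' (expected 0/1, DLD, control, typical or td)")
  .label_map[[key]]
}

#' Read labelled narrative transcripts
#'
#' Reads a tab-separated manifest with header columns `child_id`, `cohort`,
#' `group_label` and `text`. Group labels may be `0`/`1` or the synonyms
#' `DLD`, `control`, `typical`, `td` (case-insensitive); cohorts must be
#' `A` or `B`. Each row's text is tokenized with [tokenize()].
#'
#' @param path Path to the TSV manifest.
#' @return A data frame of class `narrative_set` with columns `child_id`,
#'   `cohort` (factor A/B), `group_label` (integer, DLD = 1) and a
#'   list-column `tokens`.
#' @seealso [write_narratives()]
#' @export
read_narratives <- function(path) {
  if (!file.exists(path)) stop("narrative manifest does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need <- c("child_id", "cohort", "group_label", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("narrative manifest lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("narrative manifest has no rows")

  cohort <- toupper(trimws(df$cohort))
  bad <- which(!cohort %in% c("A", "B"))
  if (length(bad))
    stop("row ", bad[1L], ": invalid cohort '", df$cohort[bad[1L]],
         "' (must be A or B)")
  labels <- vapply(seq_len(nrow(df)),
                   function(i) .parse_label(df$group_label[i], i), integer(1))
  out <- data.frame(child_id = df$child_id,
                    cohort = factor(cohort, levels = c("A", "B")),
                    group_label = labels,
                    stringsAsFactors = FALSE)
  out$tokens <- lapply(df$text, tokenize)
  class(out) <- c("narrative_set", class(out))
  out
}

#' Write narratives back to a TSV manifest
#'
#' Inverse of [read_narratives()] up to tokenization: the `text` column is
#' the space-joined token list, so reading the written file reproduces the
#' same narrative set.
#'
#' @param narratives A `narrative_set` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_narratives <- function(narratives, path) {
  df <- data.frame(
    child_id = narratives$child_id,
    cohort = as.character(narratives$cohort),
    group_label = narratives$group_label,
    text = vapply(narratives$tokens, paste, character(1), collapse = " "),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.narrative_set <- function(x, ...) {
  cat("Narrative set:", nrow(x), "children\n")
  tab <- table(cohort = x$cohort, group = ifelse(x$group_label == 1L,
                                                 "DLD", "control"))
  print(tab)
  len <- vapply(x$tokens, length, integer(1))
  cat(sprintf("narrative length: median %d tokens (range %d-%d)\n",
              as.integer(stats::median(len)), min(len), max(len)))
  invisible(x)
}
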