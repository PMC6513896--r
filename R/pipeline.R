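# End-to-end orchestration: simulate or load data, build the semantic
# space, vectorize narratives, run the leave-one-out SELIMI classifier,
# and write per-cohort diagnostic reports to a run directory.

#' Pipeline configuration
#'
#' Bundles every setting of a full run. Exactly one data source is used:
#' paths to an existing corpus and narrative manifest, or a
#' [synthetic_config()] for simulation.
#'
#' @param space A [space_config()].
#' @param lambda,cutoff Classifier settings (see [selimi()]).
#' @param select_lambda,standardize See [selimi()].
#' @param corpus_path,narratives_path Input paths, or `NULL` to simulate.
#' @param synth A [synthetic_config()] used when paths are `NULL`.
#' @param seed Master seed; when simulating it overrides `synth$seed`, so
#'   one integer reproduces the whole run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(space = space_config(),
                            lambda = 1, cutoff = 0.5,
                            select_lambda = FALSE, standardize = FALSE,
                            corpus_path = NULL, narratives_path = NULL,
                            synth = synthetic_config(), seed = 1L) {
  if (is.null(corpus_path) != is.null(narratives_path))
    stop("corpus_path and narratives_path must be given together")
  if (!is.null(synth) && !is.null(seed)) synth$seed <- as.integer(seed)
  structure(list(space = space, lambda = lambda, cutoff = cutoff,
                 select_lambda = select_lambda, standardize = standardize,
                 corpus_path = corpus_path,
                 narratives_path = narratives_path,
                 synth = synth, seed = as.integer(seed)),
            class = "pipeline_config")
}

.report_json <- function(summ, fit) {
  lapply(summ, function(s) {
    r <- s$report
    list(confusion = list(TP = r$confusion$TP, FN = r$confusion$FN,
                          FP = r$confusion$FP, TN = r$confusion$TN),
         sensitivity = r$sensitivity, specificity = r$specificity,
         lr_positive = if (is.infinite(r$lr_positive)) "Inf"
           else r$lr_positive,
         lr_negative = r$lr_negative,
         accuracy = r$accuracy, binomial_p = r$binomial_p, n = r$n,
         auc = s$roc$auc, printed = as.list(format_report(r)),
         lambda = fit$lambda, cutoff = fit$cutoff)
  })
}

#' Run the full SELIMI pipeline
#'
#' Simulates (or reads) a corpus and narratives, builds the semantic
#' space, vectorizes every narrative, scores each child by leave-one-out
#' ridge logistic regression — cohorts A and B fitted separately — and
#' evaluates diagnostic accuracy per cohort. All artifacts are written to
#' `out_dir`: `space.txt`, `vectors.tsv`, `selimi.tsv`, `report.json`,
#' `roc_<cohort>.tsv`, `config.json`, `log.txt`. A rerun with the same
#' configuration and seed reproduces every artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory, created if needed.
#' @return Invisibly, a list with `fit` (the [selimi()] object), `summary`
#'   (per-cohort diagnostics), `space`, `vectors` and `dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat("", file = log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cfg_json <- config
  cfg_json$space <- unclass(cfg_json$space)
  cfg_json$synth <- if (!is.null(cfg_json$synth)) unclass(cfg_json$synth)
  jsonlite::write_json(unclass(cfg_json),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  if (is.null(config$corpus_path)) {
    logf("simulating corpus and narratives (seed %d)", config$seed)
    corpus <- stage("simulate", generate_corpus(config$synth))
    narratives <- stage("simulate", generate_narratives(config$synth))
  } else {
    logf("reading corpus from %s", config$corpus_path)
    corpus <- stage("read_corpus", read_corpus(config$corpus_path))
    narratives <- stage("read_narratives",
                        read_narratives(config$narratives_path))
  }
  logf("corpus: %d documents; narratives: %d children",
       length(corpus), nrow(narratives))

  space <- stage("semantic_space", semantic_space(corpus, config$space))
  logf("semantic space: %d words x %d dims", length(space$words), space$k)
  write_space(space, file.path(out_dir, "space.txt"))

  vectors <- stage("vectorize", narrative_vectors(narratives, space))
  write_vectors(vectors, file.path(out_dir, "vectors.tsv"))

  fit <- stage("classify",
               selimi(vectors, lambda = config$lambda,
                      cutoff = config$cutoff,
                      select_lambda = config$select_lambda,
                      standardize = config$standardize))
  write_selimi(fit, file.path(out_dir, "selimi.tsv"))

  summ <- stage("evaluate", summary(fit))
  for (co in names(summ)) {
    write_roc(summ[[co]]$roc, file.path(out_dir,
                                        paste0("roc_", co, ".tsv")))
    logf("cohort %s: accuracy %.1f%%, AUC %.3f", co,
         100 * summ[[co]]$report$accuracy, summ[[co]]$roc$auc)
  }
  jsonlite::write_json(.report_json(summ, fit),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, summary = summ, space = space,
                 vectors = vectors, dir = out_dir))
}
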