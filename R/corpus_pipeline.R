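#' Pipeline configuration
#'
#' Collects the tunable parameters of the scoring pipeline. Defaults
#' follow the standard study conditions: screening at 100 tokens and 70%
#' coverage, 2000 bootstrap replicates. The `"study2"` preset switches to
#' 500 replicates (the large-corpus setting); `"study1"` is the default.
#' A stable hash of the configuration is embedded in score output for
#' provenance.
#'
#' @param min_tokens,min_coverage screening thresholds.
#' @param n_boot bootstrap replicate count.
#' @param seed integer seed used by every stochastic step.
#' @param conf confidence level for BCa intervals.
#' @param rescreen_halves whether split halves must themselves pass
#'   screening.
#' @param preset optional `"study1"` or `"study2"`; applied after the
#'   explicit arguments.
#' @param lexicon_path,function_words_path,coverage_path optional file
#'   paths overriding the packaged lists (used by the command-line tools).
#' @return A list of class `ev_config`.
#' @export
ev_config <- function(min_tokens = 100L, min_coverage = 0.70,
                      n_boot = 2000L, seed = 1L, conf = 0.95,
                      rescreen_halves = TRUE, preset = NULL,
                      lexicon_path = NULL, function_words_path = NULL,
                      coverage_path = NULL) {
  cfg <- list(min_tokens = as.integer(min_tokens),
              min_coverage = min_coverage, n_boot = as.integer(n_boot),
              seed = as.integer(seed), conf = conf,
              rescreen_halves = isTRUE(rescreen_halves),
              preset = preset, lexicon_path = lexicon_path,
              function_words_path = function_words_path,
              coverage_path = coverage_path)
  if (!is.null(preset)) {
    cfg$n_boot <- switch(match.arg(preset, c("study1", "study2")),
                         study1 = 2000L, study2 = 500L)
  }
  class(cfg) <- "ev_config"
  cfg
}

#' @rdname ev_config
#' @param path YAML file whose top-level keys are `ev_config()` arguments.
#' @export
read_ev_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ev_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(ev_config, vals)
}

#' @rdname ev_config
#' @param config an `ev_config`.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "ev_config"))
  rlang::hash(unclass(config))
}

.resolve_inputs <- function(config) {
  list(
    lexicon = if (is.null(config$lexicon_path)) ev_lexicon() else
      read_lexicon(config$lexicon_path),
    function_words = if (is.null(config$function_words_path))
      ev_function_words() else
      read_wordlist(config$function_words_path, role = "function_words"),
    coverage = if (is.null(config$coverage_path)) ev_coverage_vocab() else
      read_wordlist(config$coverage_path, role = "coverage_vocabulary")
  )
}

#' Screen and score a corpus
#'
#' Tokenizes each document, applies the inclusion screen, scores every
#' included document with [score_document()], and returns the score table
#' together with an exclusion log and provenance metadata (lexicon
#' name/version, configuration hash, document counts). Unreadable rows
#' (missing text) are logged and skipped.
#'
#' @param corpus a tibble/data frame with `doc_id`, `text`, and optional
#'   covariate columns (see [read_corpus()]).
#' @param lexicon an `emotion_lexicon`; defaults to the packaged one.
#' @param function_words,coverage_vocab word lists; packaged defaults.
#' @param categories named list of category word lists; defaults to the
#'   packaged demonstration categories.
#' @param config an [ev_config()].
#' @return An object of class `corpus_scores`: list with `scores` (one row
#'   per included document: metrics then pass-through covariates),
#'   `exclusions` (doc_id, token_count, coverage, reasons), `meta`.
#' @export
score_corpus <- function(corpus, lexicon = ev_lexicon(),
                         function_words = ev_function_words(),
                         coverage_vocab = ev_coverage_vocab(),
                         categories = ev_category_lists(),
                         config = ev_config()) {
  stopifnot(is.data.frame(corpus))
  if (!nrow(corpus)) stop("empty corpus")
  if (!all(c("doc_id", "text") %in% names(corpus))) {
    stop("corpus needs columns 'doc_id' and 'text'")
  }
  covars <- setdiff(names(corpus), c("doc_id", "text"))

  rows <- vector("list", nrow(corpus))
  excl <- vector("list", nrow(corpus))
  n_unreadable <- 0L
  for (i in seq_len(nrow(corpus))) {
    id <- as.character(corpus$doc_id[i])
    txt <- corpus$text[i]
    if (is.na(txt)) {
      n_unreadable <- n_unreadable + 1L
      excl[[i]] <- data.frame(doc_id = id, token_count = NA_integer_,
                              coverage = NA_real_, reasons = "unreadable",
                              stringsAsFactors = FALSE)
      next
    }
    doc <- tokenize(txt, doc_id = id)
    scr <- screen_document(doc, coverage_vocab,
                           min_tokens = config$min_tokens,
                           min_coverage = config$min_coverage)
    if (!scr$included) {
      excl[[i]] <- data.frame(doc_id = id, token_count = scr$token_count,
                              coverage = scr$coverage,
                              reasons = paste(scr$reasons, collapse = ";"),
                              stringsAsFactors = FALSE)
      next
    }
    row <- score_document(doc, lexicon, function_words, categories)
    row$coverage <- scr$coverage
    if (length(covars)) row <- cbind(row, corpus[i, covars, drop = FALSE])
    rows[[i]] <- row
  }
  scores <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  exclusions <- do.call(rbind, excl[!vapply(excl, is.null, logical(1))])
  if (is.null(exclusions)) {
    exclusions <- data.frame(doc_id = character(0),
                             token_count = integer(0),
                             coverage = numeric(0), reasons = character(0),
                             stringsAsFactors = FALSE)
  }
  if (is.null(scores)) stop("all documents were excluded by screening")
  structure(
    list(scores = tibble::as_tibble(scores),
         exclusions = tibble::as_tibble(exclusions),
         meta = list(lexicon = lexicon$name,
                     lexicon_version = lexicon$version,
                     config = config, config_hash = config_hash(config),
                     n_input = nrow(corpus), n_included = nrow(scores),
                     n_excluded = nrow(exclusions),
                     n_unreadable = n_unreadable)),
    class = "corpus_scores"
  )
}

#' @export
print.corpus_scores <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<corpus_scores: of %d documents, %d produced analyzable texts (%d excluded); lexicon %s v%s, config %s>\n",
    m$n_input, m$n_included, m$n_excluded, m$lexicon, m$lexicon_version,
    substr(m$config_hash, 1, 8)))
  invisible(x)
}

#' Write the per-document score table
#'
#' Writes a TSV with one row per included document; the configuration hash
#' and lexicon version go into `#`-prefixed header comments.
#'
#' @param x a `corpus_scores`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "corpus_scores"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# lexicon: %s v%s", x$meta$lexicon,
                     x$meta$lexicon_version), con)
  writeLines(sprintf("# config_hash: %s", x$meta$config_hash), con)
  utils::write.table(x$scores, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.metric_fun <- function(metric, lexicon, function_words, categories) {
  force(metric); force(lexicon); force(function_words); force(categories)
  function(doc) {
    row <- score_document(doc, lexicon, function_words, categories)
    if (!metric %in% names(row)) stop("unknown metric: ", metric)
    as.numeric(row[[metric]])
  }
}

#' Split-half reliability of a per-document metric
#'
#' Splits each document's token stream at its midpoint, scores the metric
#' on each half, and correlates first-half with second-half scores across
#' documents, with a BCa bootstrap interval. By default each half is
#' re-screened against the usual inclusion criteria (so only documents
#' with both halves analyzable enter); set `rescreen_halves = FALSE` in
#' the config to keep every screened document.
#'
#' @param corpus a corpus table (see [score_corpus()]).
#' @param metric name of a column produced by [score_document()], e.g.
#'   `"neg_ev"`.
#' @inheritParams score_corpus
#' @return A `correlation_result` (see [cor_ci()]), with the per-document
#'   half scores attached as attribute `"halves"`.
#' @export
split_half_reliability <- function(corpus, metric = "neg_ev",
                                   lexicon = ev_lexicon(),
                                   function_words = ev_function_words(),
                                   coverage_vocab = ev_coverage_vocab(),
                                   categories = ev_category_lists(),
                                   config = ev_config()) {
  f <- .metric_fun(metric, lexicon, function_words, categories)
  h1 <- numeric(0); h2 <- numeric(0); ids <- character(0)
  for (i in seq_len(nrow(corpus))) {
    if (is.na(corpus$text[i])) next
    doc <- tokenize(corpus$text[i], doc_id = as.character(corpus$doc_id[i]))
    scr <- screen_document(doc, coverage_vocab,
                           min_tokens = config$min_tokens,
                           min_coverage = config$min_coverage)
    if (!scr$included) next
    mid <- doc$token_count %/% 2L
    if (mid < 1L || doc$token_count - mid < 1L) next
    d1 <- structure(list(doc_id = doc$doc_id, tokens = doc$tokens[1:mid],
                         token_count = mid), class = "tokenized_document")
    d2 <- structure(list(doc_id = doc$doc_id,
                         tokens = doc$tokens[(mid + 1L):doc$token_count],
                         token_count = doc$token_count - mid),
                    class = "tokenized_document")
    if (config$rescreen_halves) {
      ok1 <- screen_document(d1, coverage_vocab, config$min_tokens,
                             config$min_coverage)$included
      ok2 <- screen_document(d2, coverage_vocab, config$min_tokens,
                             config$min_coverage)$included
      if (!ok1 || !ok2) next
    }
    ids <- c(ids, doc$doc_id)
    h1 <- c(h1, f(d1)); h2 <- c(h2, f(d2))
  }
  if (length(ids) < 3L) stop("fewer than 3 eligible documents")
  halves <- data.frame(doc_id = ids, half1 = h1, half2 = h2,
                       stringsAsFactors = FALSE)
  res <- cor_ci(halves, "half1", "half2", n_boot = config$n_boot,
                seed = config$seed, conf = config$conf)
  attr(res, "halves") <- tibble::as_tibble(halves)
  res
}

#' Test-retest correlation of a metric between two scored waves
#'
#' Joins two score tables on `doc_id` and correlates the metric across
#' matched pairs, with a BCa bootstrap interval. Unmatched ids are
#' recorded in the result's `"unmatched"` attribute.
#'
#' @param scores_t1,scores_t2 `corpus_scores` objects (or their `scores`
#'   tibbles) from the two waves.
#' @param metric score column name.
#' @param config an [ev_config()].
#' @return A `correlation_result`.
#' @export
test_retest <- function(scores_t1, scores_t2, metric = "neg_ev",
                        config = ev_config()) {
  s1 <- if (inherits(scores_t1, "corpus_scores")) scores_t1$scores else scores_t1
  s2 <- if (inherits(scores_t2, "corpus_scores")) scores_t2$scores else scores_t2
  stopifnot(metric %in% names(s1), metric %in% names(s2))
  common <- intersect(s1$doc_id, s2$doc_id)
  if (!length(common)) stop("no overlapping doc_id between waves")
  if (length(common) < 3L) stop("fewer than 3 matched pairs")
  pairs <- data.frame(
    doc_id = common,
    t1 = as.numeric(s1[[metric]][match(common, s1$doc_id)]),
    t2 = as.numeric(s2[[metric]][match(common, s2$doc_id)]),
    stringsAsFactors = FALSE
  )
  res <- cor_ci(pairs, "t1", "t2", n_boot = config$n_boot,
                seed = config$seed, conf = config$conf)
  attr(res, "unmatched") <- list(
    t1_only = setdiff(s1$doc_id, common),
    t2_only = setdiff(s2$doc_id, common))
  res
}
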