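#' Tokenize raw text into lowercase word tokens
#'
#' The tokenizer defines the word count that all per-document rates are
#' normalised by. Conventions: Unicode-aware case folding; curly
#' apostrophes normalised to ASCII `'`; hyphens and dashes split their
#' compounds; punctuation is stripped; internal apostrophes are kept, so a
#' contraction like "don't" is a single token; strings without a letter
#' (e.g. bare numbers) are dropped.
#'
#' @param raw a character scalar (may be empty).
#' @param doc_id document identifier carried through scoring.
#' @return An object of class `tokenized_document`: list with `doc_id`,
#'   `tokens` (character), `token_count`.
#' @examples
#' tokenize("A horse! A horse! My Kingdom for a horse!")$token_count  # 9
#' @export
tokenize <- function(raw, doc_id = "doc") {
  stopifnot(length(raw) == 1L)
  if (is.na(raw)) raw <- ""
  x <- tolower(enc2utf8(as.character(raw)))
  x <- gsub("[’‘ʼ`]", "'", x)
  x <- gsub("[-‐‑‒–—/_]", " ", x)
  m <- gregexpr("\\p{L}+(?:'\\p{L}+)*", x, perl = TRUE)
  tokens <- regmatches(x, m)[[1]]
  structure(list(doc_id = doc_id, tokens = tokens,
                 token_count = length(tokens)),
            class = "tokenized_document")
}

#' @export
print.tokenized_document <- function(x, ...) {
  cat(sprintf("<tokenized_document '%s': %d tokens>\n",
              x$doc_id, x$token_count))
  invisible(x)
}

#' Screen a document for inclusion
#'
#' Analyzable documents must have at least `min_tokens` tokens and at least
#' a `min_coverage` fraction of tokens identifiable, i.e. present in the
#' coverage vocabulary. Defaults follow the standard criteria of at least
#' 100 words with 70% identifiable.
#'
#' @param doc a `tokenized_document`.
#' @param coverage_vocab an `ev_wordlist` with role `coverage_vocabulary`.
#' @param min_tokens minimum token count.
#' @param min_coverage minimum identifiable fraction in `[0, 1]`.
#' @return A list of class `screening_result`: `doc_id`, `included`,
#'   `token_count`, `coverage`, `reasons` (character vector naming each
#'   failed criterion, empty when included).
#' @export
screen_document <- function(doc, coverage_vocab, min_tokens = 100L,
                            min_coverage = 0.70) {
  stopifnot(inherits(doc, "tokenized_document"),
            inherits(coverage_vocab, "ev_wordlist"))
  if (coverage_vocab$role != "coverage_vocabulary") {
    stop("coverage_vocab must have role 'coverage_vocabulary'")
  }
  n <- doc$token_count
  coverage <- if (n > 0L) {
    sum(doc$tokens %in% coverage_vocab$words) / n
  } else 0
  reasons <- character(0)
  if (n < min_tokens) {
    reasons <- c(reasons, sprintf("token_count<%d", as.integer(min_tokens)))
  }
  if (coverage < min_coverage) {
    reasons <- c(reasons, sprintf("coverage<%.2f", min_coverage))
  }
  structure(list(doc_id = doc$doc_id, included = length(reasons) == 0L,
                 token_count = n, coverage = coverage, reasons = reasons),
            class = "screening_result")
}

#' Read a corpus table or directory of plain-text files
#'
#' Tabular mode expects CSV or TSV (by extension) with required columns
#' `doc_id` and `text`; any other columns are carried through as
#' per-author covariates. Directory mode reads every `.txt` file, with the
#' file name stem as `doc_id`.
#'
#' @param path a CSV/TSV file or a directory of `.txt` files.
#' @return A tibble with columns `doc_id`, `text`, then covariates.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files in ", path)
    return(tibble::tibble(
      doc_id = tools::file_path_sans_ext(basename(files)),
      text = vapply(files, function(f) {
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
      }, character(1), USE.NAMES = FALSE)
    ))
  }
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE),
    tsv = ,
    txt = ,
    tab = utils::read.delim(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8", check.names = FALSE),
    stop("unsupported corpus file extension: ", ext)
  )
  if (!all(c("doc_id", "text") %in% names(df))) {
    stop("corpus table needs columns 'doc_id' and 'text'")
  }
  df$doc_id <- as.character(df$doc_id)
  df$text <- as.character(df$text)
  tibble::as_tibble(df[, c("doc_id", "text",
                           setdiff(names(df), c("doc_id", "text")))])
}
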