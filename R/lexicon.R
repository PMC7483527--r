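#' Construct an emotion lexicon from an entry table
#'
#' An emotion lexicon is a table of token patterns, each carrying a valence
#' (`negative`/`positive`), an emotion family (`sadness`, `fear`, `anger`,
#' `undifferentiated_negative`, `positive`), and a `lemma_group` identifier.
#' Inflectional variants of the same emotion word (e.g. *sad*, *sadly*,
#' *sadness*) share a `lemma_group` and are counted as one word when
#' diversity is scored. A pattern is either a literal lowercase token or a
#' prefix wildcard written with a single trailing asterisk (`furi*`).
#'
#' Validation enforces: unique patterns across the whole lexicon; lowercase,
#' nonempty patterns with at most one asterisk, only in final position;
#' `family = "positive"` if and only if `valence = "positive"`; and a single
#' valence and family per lemma group.
#'
#' @param entries data frame with columns `pattern`, `valence`, `family`,
#'   `lemma_group`.
#' @param name,version metadata strings recorded in score output.
#' @return An object of class `emotion_lexicon`.
#' @seealso [read_lexicon()], [match_token()], [ev_lexicon()]
#' @export
emotion_lexicon <- function(entries, name = "custom", version = "0") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  req <- c("pattern", "valence", "family", "lemma_group")
  if (!all(req %in% names(entries))) {
    stop("lexicon entries need columns: ", paste(req, collapse = ", "))
  }
  entries <- entries[req]
  pat <- entries$pattern
  if (any(!nzchar(pat))) stop("empty pattern in lexicon")
  if (any(pat != tolower(pat))) {
    stop("pattern not lowercase: ", pat[pat != tolower(pat)][1])
  }
  stars <- lengths(regmatches(pat, gregexpr("\\*", pat)))
  bad_star <- stars > 1L | (stars == 1L & !endsWith(pat, "*")) |
    pat == "*"
  if (any(bad_star)) {
    stop("malformed wildcard pattern: ", pat[bad_star][1],
         " (one asterisk allowed, final position only)")
  }
  dup <- pat[duplicated(pat)]
  if (length(dup)) stop("duplicate pattern: ", dup[1])
  if (!all(entries$valence %in% c("negative", "positive"))) {
    stop("valence must be 'negative' or 'positive'")
  }
  if (!all(entries$family %in% EV_FAMILIES)) {
    stop("unknown family: ",
         paste(setdiff(entries$family, EV_FAMILIES), collapse = ", "))
  }
  mism <- (entries$family == "positive") != (entries$valence == "positive")
  if (any(mism)) {
    stop("family/valence mismatch for pattern: ", pat[mism][1])
  }
  per_group <- split(entries[c("valence", "family")], entries$lemma_group)
  multi <- vapply(per_group, function(g) {
    length(unique(g$valence)) > 1L || length(unique(g$family)) > 1L
  }, logical(1))
  if (any(multi)) {
    stop("lemma group spans multiple valences/families: ",
         names(per_group)[multi][1])
  }

  is_wc <- endsWith(pat, "*")
  wc_prefix <- sub("\\*$", "", pat[is_wc])
  structure(
    list(
      entries = tibble::as_tibble(entries),
      name = name,
      version = version,
      literal_rows = setNames(which(!is_wc), pat[!is_wc]),
      wildcard = data.frame(
        prefix = wc_prefix,
        row = which(is_wc),
        stringsAsFactors = FALSE
      )[order(nchar(wc_prefix), decreasing = TRUE), , drop = FALSE]
    ),
    class = "emotion_lexicon"
  )
}

#' Read an emotion lexicon from its canonical TSV serialization
#'
#' The canonical dialect is UTF-8 tab-separated text with header
#' `pattern  valence  family  lemma_group`; lines starting with `#` are
#' comments. See [emotion_lexicon()] for the validation rules.
#'
#' @param path file path.
#' @param name,version metadata; `name` defaults to the file name.
#' @return An `emotion_lexicon`.
#' @export
read_lexicon <- function(path, name = basename(path), version = "1") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  emotion_lexicon(df, name = name, version = version)
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  grp <- unique(x$entries[c("lemma_group", "valence")])
  cat(sprintf(
    "<emotion_lexicon '%s' v%s: %d entries, %d lemma groups (%d negative, %d positive)>\n",
    x$name, x$version, nrow(x$entries), nrow(grp),
    sum(grp$valence == "negative"), sum(grp$valence == "positive")))
  invisible(x)
}

#' Count lemma headwords per valence
#'
#' @param lexicon an `emotion_lexicon`.
#' @return Named integer vector with elements `negative` and `positive`,
#'   counting distinct lemma groups (headwords), not surface forms.
#' @export
lexicon_sizes <- function(lexicon) {
  grp <- unique(lexicon$entries[c("lemma_group", "valence")])
  c(negative = sum(grp$valence == "negative"),
    positive = sum(grp$valence == "positive"))
}

#' Match tokens against an emotion lexicon
#'
#' Literal patterns take precedence over wildcards; among wildcard matches
#' the longest prefix wins. Tokens must already be case-folded (as produced
#' by [tokenize()]).
#'
#' @param lexicon an `emotion_lexicon`.
#' @param tokens character vector of lowercase tokens.
#' @return A data frame with one row per token and columns `token`,
#'   `lemma_group`, `valence`, `family` (`NA` where nothing matches).
#' @export
match_tokens <- function(lexicon, tokens) {
  u <- unique(tokens)
  row <- unname(lexicon$literal_rows[u])
  wc <- lexicon$wildcard
  todo <- which(is.na(row))
  if (length(todo) && nrow(wc)) {
    for (i in seq_len(nrow(wc))) {
      if (!length(todo)) break
      hit <- startsWith(u[todo], wc$prefix[i])
      row[todo[hit]] <- wc$row[i]
      todo <- todo[!hit]
    }
  }
  e <- lexicon$entries
  res <- data.frame(
    token = u,
    lemma_group = e$lemma_group[row],
    valence = e$valence[row],
    family = e$family[row],
    stringsAsFactors = FALSE
  )
  res[match(tokens, u), , drop = FALSE][, , drop = FALSE]
}

#' @rdname match_tokens
#' @param token a single lowercase token.
#' @return `match_token()` returns a list with `lemma_group`, `valence`,
#'   `family`, or `NULL` when the token is not in the lexicon.
#' @export
match_token <- function(lexicon, token) {
  stopifnot(length(token) == 1L)
  m <- match_tokens(lexicon, token)
  if (is.na(m$lemma_group)) return(NULL)
  list(lemma_group = m$lemma_group, valence = m$valence, family = m$family)
}

#' Construct or read a word list
#'
#' Word lists hold literal lowercase tokens and play one of several roles:
#' `function_words` (closed-class words excluded from the open-class
#' type/token ratio), `coverage_vocabulary` (words counted as identifiable
#' by the screening step), or `category` (a frequency-counted category such
#' as I-words or illness words). Files are UTF-8, one token per line,
#' `#` comments ignored.
#'
#' @param words character vector of tokens.
#' @param role one of `"function_words"`, `"coverage_vocabulary"`,
#'   `"category"`.
#' @param name label used in reports.
#' @return An object of class `ev_wordlist`.
#' @export
wordlist <- function(words, role = c("category", "function_words",
                                     "coverage_vocabulary"),
                     name = role) {
  role <- match.arg(role)
  words <- unique(words[nzchar(words)])
  if (!length(words)) stop("word list is empty")
  if (any(words != tolower(words))) stop("word list must be lowercase")
  structure(list(words = words, role = role, name = name),
            class = "ev_wordlist")
}

#' @rdname wordlist
#' @param path file path.
#' @export
read_wordlist <- function(path, role = c("category", "function_words",
                                         "coverage_vocabulary"),
                          name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  wordlist(lines, role = match.arg(role), name = name)
}

#' @export
print.ev_wordlist <- function(x, ...) {
  cat(sprintf("<ev_wordlist '%s' (%s): %d words>\n",
              x$name, x$role, length(x$words)))
  invisible(x)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "emovoc")
  if (!nzchar(p)) stop("packaged file not found: ", file)
  p
}

.pkg_cache <- new.env(parent = emptyenv())
.cached <- function(key, make) {
  if (!exists(key, envir = .pkg_cache)) assign(key, make(), envir = .pkg_cache)
  get(key, envir = .pkg_cache)
}

#' Packaged synthetic emotion dictionary
#'
#' A demonstration dictionary of words naming emotional states, organised
#' as 92 negative and 53 positive lemma headwords (the counts refer to
#' lemma groups; additional rows are inflected surface forms or prefix
#' wildcards). It is a synthetic reconstruction written for this package,
#' not any proprietary dictionary.
#'
#' @return An `emotion_lexicon`.
#' @export
ev_lexicon <- function() {
  .cached("lexicon", function() {
    read_lexicon(.extdata("emotion_lexicon_synthetic.tsv"),
                 name = "emovoc-synthetic", version = "1")
  })
}

#' Packaged synthetic word lists
#'
#' `ev_function_words()` returns the closed-class word list used by the
#' open-class type/token ratio; `ev_coverage_vocab()` the common-word list
#' behind the identifiability screen; `ev_content_words()` the open-class
#' filler vocabulary used by the synthetic corpus generator;
#' `ev_category_lists()` the demonstration category lists (cognitive
#' processing, I-words, we-words, illness, affiliation, achievement,
#' leisure). All are synthetic stand-ins packaged for demonstration and
#' testing; every scoring function also accepts user-supplied lists.
#'
#' @return An `ev_wordlist`, or for `ev_category_lists()` a named list of
#'   them.
#' @export
ev_function_words <- function() {
  .cached("function_words", function() {
    read_wordlist(.extdata("function_words_synthetic.txt"),
                  role = "function_words", name = "function_words")
  })
}

#' @rdname ev_function_words
#' @export
ev_coverage_vocab <- function() {
  .cached("coverage", function() {
    read_wordlist(.extdata("coverage_vocab_synthetic.txt"),
                  role = "coverage_vocabulary", name = "coverage")
  })
}

#' @rdname ev_function_words
#' @export
ev_content_words <- function() {
  .cached("content", function() {
    read_wordlist(.extdata("content_words_synthetic.txt"),
                  role = "category", name = "content_words")
  })
}

#' @rdname ev_function_words
#' @export
ev_category_lists <- function() {
  .cached("categories", function() {
    files <- c(
      cognitive_processing = "category_cognitive_processing_synthetic.txt",
      i_words = "category_i_words_synthetic.txt",
      we_words = "category_we_words_synthetic.txt",
      illness = "category_illness_synthetic.txt",
      affiliation = "category_affiliation_synthetic.txt",
      achievement = "category_achievement_synthetic.txt",
      leisure = "category_leisure_synthetic.txt"
    )
    out <- lapply(names(files), function(nm) {
      read_wordlist(.extdata(files[[nm]]), role = "category", name = nm)
    })
    names(out) <- names(files)
    out
  })
}

#' Valence slice of a lexicon, usable as a frequency category
#'
#' Returns a lightweight object representing "all tokens matching the given
#' valence of the lexicon" for use with [category_rate()]. This gives the
#' frequency-based emotional tone rates (repeats counted), the counterpart
#' of the diversity-based EV rates.
#'
#' @param lexicon an `emotion_lexicon`.
#' @param valence `"negative"` or `"positive"`.
#' @return An object of class `lexicon_slice`.
#' @export
lexicon_slice <- function(lexicon, valence = c("negative", "positive")) {
  valence <- match.arg(valence)
  structure(list(lexicon = lexicon, valence = valence,
                 name = paste0(valence, "_tone")),
            class = "lexicon_slice")
}
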