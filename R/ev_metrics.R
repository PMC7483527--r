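#' Emotion vocabulary (EV) rate of a document
#'
#' EV is a diversity measure: the number of unique emotion words — counted
#' at the lemma-group level, so inflections like *sad*, *sadly*, *sadness*
#' contribute one word — expressed per 100 tokens:
#' `EV = 100 * (# unique emotion words) / (total word count)`.
#' Repeating an emotion word does not raise the numerator; writing a new
#' one does. This is the counterpart of frequency-based category rates
#' ([category_rate()]), which count every occurrence.
#'
#' @param doc a `tokenized_document` with at least one token.
#' @param lexicon an `emotion_lexicon`.
#' @param valence `"negative"` or `"positive"` (which words go in the
#'   numerator; the denominator is always the full token count).
#' @return EV rate, a number in `[0, 100]`.
#' @examples
#' doc <- tokenize("he was so angry at me, but sadly there was nothing I could do")
#' ev_score(doc, ev_lexicon(), "negative")  # 2/14 * 100 = 14.29
#' @export
ev_score <- function(doc, lexicon, valence = c("negative", "positive")) {
  valence <- match.arg(valence)
  .check_nonempty(doc)
  m <- match_tokens(lexicon, doc$tokens)
  groups <- unique(m$lemma_group[!is.na(m$valence) & m$valence == valence])
  100 * length(groups) / doc$token_count
}

.check_nonempty <- function(doc) {
  stopifnot(inherits(doc, "tokenized_document"))
  if (doc$token_count == 0L) stop("empty document")
  invisible(doc)
}

#' Family-specific EV rates
#'
#' EV computed separately for each emotion family: sadness-, fear-, and
#' anger-related words, general undifferentiated negative words, and
#' positive words. Each rate uses that family's unique lemma groups in the
#' numerator over the full token count.
#'
#' @inheritParams ev_score
#' @return Named numeric vector over the five families.
#' @export
family_ev_scores <- function(doc, lexicon) {
  .check_nonempty(doc)
  m <- match_tokens(lexicon, doc$tokens)
  m <- m[!is.na(m$family), , drop = FALSE]
  counts <- vapply(EV_FAMILIES, function(f) {
    length(unique(m$lemma_group[m$family == f]))
  }, integer(1))
  100 * counts / doc$token_count
}

#' Bundle of EV scores for one document
#'
#' @inheritParams ev_score
#' @return One-row tibble: `doc_id`, `token_count`, `neg_ev`, `pos_ev`,
#'   `ev_<family>` for the five families, `unique_neg`, `unique_pos`.
#' @export
ev_scores <- function(doc, lexicon) {
  .check_nonempty(doc)
  m <- match_tokens(lexicon, doc$tokens)
  m <- m[!is.na(m$valence), , drop = FALSE]
  ug <- unique(m[c("lemma_group", "valence", "family")])
  fam <- vapply(EV_FAMILIES, function(f) sum(ug$family == f), integer(1))
  out <- tibble::tibble(
    doc_id = doc$doc_id,
    token_count = doc$token_count,
    neg_ev = 100 * sum(ug$valence == "negative") / doc$token_count,
    pos_ev = 100 * sum(ug$valence == "positive") / doc$token_count,
    unique_neg = sum(ug$valence == "negative"),
    unique_pos = sum(ug$valence == "positive")
  )
  rates <- as.list(100 * fam / doc$token_count)
  names(rates) <- paste0("ev_", EV_FAMILIES)
  tibble::as_tibble(c(out, rates))[, c(
    "doc_id", "token_count", "neg_ev", "pos_ev",
    paste0("ev_", EV_FAMILIES), "unique_neg", "unique_pos")]
}

#' Frequency-based category rate
#'
#' The percentage of tokens, repeats counted, matching a category — either
#' a literal word list or a valence slice of the emotion lexicon (emotional
#' tone). A text repeating one emotion word ten times and a text using ten
#' different ones get the same category rate; they differ in EV.
#'
#' @param doc a nonempty `tokenized_document`.
#' @param category an `ev_wordlist` or a [lexicon_slice()].
#' @return Percentage in `[0, 100]`.
#' @export
category_rate <- function(doc, category) {
  .check_nonempty(doc)
  hits <- if (inherits(category, "ev_wordlist")) {
    doc$tokens %in% category$words
  } else if (inherits(category, "lexicon_slice")) {
    m <- match_tokens(category$lexicon, doc$tokens)
    !is.na(m$valence) & m$valence == category$valence
  } else {
    stop("category must be an ev_wordlist or lexicon_slice")
  }
  100 * sum(hits) / doc$token_count
}

#' Type/token ratio (general vocabulary size)
#'
#' The raw type/token ratio is the number of unique words (types) over the
#' number of total words (tokens), as a percentage. The open-class variant
#' — used as the general-vocabulary proxy in validation analyses — first
#' removes function words (closed-class) and all words matching the
#' emotion lexicon from both numerator and denominator.
#'
#' @param doc a nonempty `tokenized_document`.
#' @param function_words an `ev_wordlist` with role `function_words`.
#' @param lexicon an `emotion_lexicon` whose matches are excluded from the
#'   open-class variant.
#' @return One-row tibble: `doc_id`, `raw_ttr`, `open_class_ttr` (`NA` when
#'   no open-class tokens remain), `open_class_tokens`.
#' @examples
#' ttr(tokenize("A horse! A horse! My Kingdom for a horse!"),
#'     ev_function_words(), ev_lexicon())  # raw_ttr = 5/9 * 100
#' @export
ttr <- function(doc, function_words, lexicon) {
  .check_nonempty(doc)
  stopifnot(inherits(function_words, "ev_wordlist"))
  raw <- 100 * length(unique(doc$tokens)) / doc$token_count
  m <- match_tokens(lexicon, doc$tokens)
  open <- doc$tokens[!(doc$tokens %in% function_words$words) &
                       is.na(m$valence)]
  tibble::tibble(
    doc_id = doc$doc_id,
    raw_ttr = raw,
    open_class_ttr = if (length(open)) {
      100 * length(unique(open)) / length(open)
    } else NA_real_,
    open_class_tokens = length(open)
  )
}

#' Score one document on every configured metric
#'
#' Joins [ev_scores()], [ttr()], and [category_rate()] for the negative and
#' positive tone slices plus each supplied category list into one row.
#'
#' @inheritParams ttr
#' @param categories named list of `ev_wordlist` objects; each contributes
#'   a `rate_<name>` column.
#' @return One-row tibble.
#' @export
score_document <- function(doc, lexicon, function_words,
                           categories = list()) {
  ev <- ev_scores(doc, lexicon)
  tt <- ttr(doc, function_words, lexicon)[c("raw_ttr", "open_class_ttr")]
  tone <- tibble::tibble(
    rate_negative_tone = category_rate(doc, lexicon_slice(lexicon, "negative")),
    rate_positive_tone = category_rate(doc, lexicon_slice(lexicon, "positive"))
  )
  cats <- lapply(categories, function(cl) category_rate(doc, cl))
  if (length(cats)) names(cats) <- paste0("rate_", names(categories))
  tibble::as_tibble(c(ev, tt, tone, cats))
}
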