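# Shared fixtures and independent brute-force oracles.
# The oracles deliberately avoid the package's lookup structures: they scan
# the raw entry table token by token so metric results can be checked
# against a second, independent implementation.

tiny_lexicon <- function() {
  emotion_lexicon(data.frame(
    pattern = c("sad", "sadly", "sadness", "angry", "furi*", "happy",
                "afraid", "awful"),
    valence = c("negative", "negative", "negative", "negative", "negative",
                "positive", "negative", "negative"),
    family = c("sadness", "sadness", "sadness", "anger", "anger",
               "positive", "fear", "undifferentiated_negative"),
    lemma_group = c("sad", "sad", "sad", "angry", "furious", "happy",
                    "afraid", "awful"),
    stringsAsFactors = FALSE
  ), name = "tiny")
}

lexicon_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("pattern\tvalence\tfamily\tlemma_group", rows), path)
  path
}

# --- oracle: entry-table scan matching ---------------------------------

oracle_match <- function(entries, token) {
  wild <- endsWith(entries$pattern, "*")
  lit <- which(!wild & entries$pattern == token)
  if (length(lit)) return(entries[lit[1], , drop = FALSE])
  pre <- sub("\\*$", "", entries$pattern[wild])
  hits <- which(startsWith(token, pre))
  if (!length(hits)) return(NULL)
  best <- hits[which.max(nchar(pre[hits]))]
  entries[which(wild)[best], , drop = FALSE]
}

oracle_unique_groups <- function(tokens, entries, valence = NULL,
                                 family = NULL) {
  groups <- character(0)
  for (tok in tokens) {
    m <- oracle_match(entries, tok)
    if (is.null(m)) next
    if (!is.null(valence) && m$valence != valence) next
    if (!is.null(family) && m$family != family) next
    groups <- union(groups, m$lemma_group)
  }
  groups
}

oracle_ev <- function(tokens, entries, valence) {
  100 * length(oracle_unique_groups(tokens, entries, valence)) /
    length(tokens)
}

oracle_family_ev <- function(tokens, entries, family) {
  100 * length(oracle_unique_groups(tokens, entries, family = family)) /
    length(tokens)
}

oracle_tone <- function(tokens, entries, valence) {
  n <- 0L
  for (tok in tokens) {
    m <- oracle_match(entries, tok)
    if (!is.null(m) && m$valence == valence) n <- n + 1L
  }
  100 * n / length(tokens)
}

oracle_wordlist_rate <- function(tokens, words) {
  100 * sum(vapply(tokens, function(t) t %in% words, logical(1))) /
    length(tokens)
}

oracle_open_class_ttr <- function(tokens, entries, function_words) {
  open <- character(0)
  for (tok in tokens) {
    if (tok %in% function_words) next
    if (!is.null(oracle_match(entries, tok))) next
    open <- c(open, tok)
  }
  if (!length(open)) return(NA_real_)
  100 * length(unique(open)) / length(open)
}

# oracle: partial correlation via explicit normal-equation projection
oracle_partial_cor <- function(x, y, C) {
  X <- cbind(1, as.matrix(C))
  beta_x <- solve(t(X) %*% X, t(X) %*% x)
  beta_y <- solve(t(X) %*% X, t(X) %*% y)
  rx <- x - X %*% beta_x
  ry <- y - X %*% beta_y
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# small simulated corpora used across files
small_sim <- function(n = 30, seed = 99, verbosity_mean = 150,
                      verbosity_sd = 30, ...) {
  simulate_corpus(
    sim_config(n_authors = n, verbosity_mean = verbosity_mean,
               verbosity_sd = verbosity_sd, ...),
    seed = seed)
}

covered_filler <- function(n_words = 60) {
  # filler drawn from the packaged coverage list, free of emotion matches
  w <- ev_content_words()$words
  w <- w[is.na(match_tokens(ev_lexicon(), w)$valence)]
  head(w, n_words)
}
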