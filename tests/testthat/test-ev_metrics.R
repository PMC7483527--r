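example_doc <- function() {
  tokenize("he was so angry at me, but sadly there was nothing I could do")
}

test_that("EV is unique lemma groups per 100 tokens", {
  doc <- example_doc()
  lex <- ev_lexicon()
  expect_equal(round(ev_score(doc, lex, "negative"), 2), 14.29)
  expect_equal(ev_score(doc, lex, "positive"), 0)
  # duplication doubles tokens but not groups, halving the rate
  twice <- tokenize(paste(rep(paste(doc$tokens, collapse = " "), 2),
                          collapse = " "))
  expect_equal(round(ev_score(twice, lex, "negative"), 2), 7.14)
  # no emotion words at all
  expect_equal(ev_score(tokenize("the cat sat on the mat"), lex, "negative"), 0)
  expect_error(ev_score(tokenize(""), lex, "negative"), "empty document")
})

test_that("family EV rates split the negative side correctly", {
  doc <- example_doc()
  fam <- family_ev_scores(doc, ev_lexicon())
  expect_equal(round(unname(fam["sadness"]), 2), 7.14)
  expect_equal(round(unname(fam["anger"]), 2), 7.14)
  expect_equal(unname(fam["fear"]), 0)
  expect_equal(unname(fam["positive"]), 0)
  # an all-positive document zeroes every negative family
  fam2 <- family_ev_scores(tokenize("happy glad joyful calm"), ev_lexicon())
  expect_true(all(fam2[c("sadness", "fear", "anger",
                         "undifferentiated_negative")] == 0))
  expect_true(fam2["positive"] > 0)
})

test_that("diversity vs frequency: repeated words count once in EV", {
  lex <- tiny_lexicon()
  doc <- tokenize("sad sad sad happy")
  expect_equal(category_rate(doc, lexicon_slice(lex, "negative")), 75)
  expect_equal(ev_score(doc, lex, "negative"), 25)
  expect_equal(category_rate(doc, lexicon_slice(lex, "positive")), 25)
  expect_equal(category_rate(tokenize("no category words here"),
                             wordlist(c("zzz"), role = "category")), 0)
})

test_that("appending tokens moves unique counts exactly as diversity dictates", {
  lex <- ev_lexicon()
  base <- "he was so angry at me but sadly there was nothing i could do"
  s0 <- ev_scores(tokenize(base), lex)
  # repeat of an existing lemma group: count fixed, rate strictly lower
  s_rep <- ev_scores(tokenize(paste(base, "sadness")), lex)
  expect_equal(s_rep$unique_neg, s0$unique_neg)
  expect_lt(s_rep$neg_ev, s0$neg_ev)
  # new lemma group: count up by exactly one
  s_new <- ev_scores(tokenize(paste(base, "afraid")), lex)
  expect_equal(s_new$unique_neg, s0$unique_neg + 1L)
})

test_that("negative family unique counts sum to unique_neg on random docs", {
  lex <- ev_lexicon()
  sim <- small_sim(n = 15, seed = 21)
  for (txt in sim$corpus$text) {
    doc <- tokenize(txt)
    s <- ev_scores(doc, lex)
    fam <- family_ev_scores(doc, lex)
    neg_fams <- c("sadness", "fear", "anger", "undifferentiated_negative")
    fam_counts <- round(fam[neg_fams] * doc$token_count / 100)
    expect_equal(sum(fam_counts), s$unique_neg)
    expect_equal(round(s$neg_ev * doc$token_count / 100), s$unique_neg)
  }
})

test_that("category rate is additive over disjoint categories", {
  a <- wordlist(c("horse", "kingdom"), role = "category")
  b <- wordlist(c("my", "for"), role = "category")
  ab <- wordlist(c("horse", "kingdom", "my", "for"), role = "category")
  doc <- tokenize("A horse! A horse! My Kingdom for a horse!")
  expect_equal(category_rate(doc, a) + category_rate(doc, b),
               category_rate(doc, ab))
})

test_that("TTR matches the worked exclamation and degenerate cases", {
  t <- ttr(tokenize("A horse! A horse! My Kingdom for a horse!"),
           ev_function_words(), ev_lexicon())
  expect_equal(round(t$raw_ttr, 2), 55.56)  # 5 types / 9 tokens
  expect_equal(ttr(tokenize("go go go go"), ev_function_words(),
                   ev_lexicon())$raw_ttr, 25)
  allfn <- ttr(tokenize("the of and to in"), ev_function_words(),
               ev_lexicon())
  expect_true(is.na(allfn$open_class_ttr))
  expect_equal(allfn$open_class_tokens, 0L)
  expect_error(ttr(tokenize(""), ev_function_words(), ev_lexicon()),
               "empty")
})

test_that("all metrics agree with the brute-force oracle on simulated docs", {
  lex <- ev_lexicon()
  entries <- lex$entries
  fn_words <- ev_function_words()$words
  sim <- small_sim(n = 12, seed = 5)
  for (txt in sim$corpus$text) {
    doc <- tokenize(txt)
    expect_equal(ev_score(doc, lex, "negative"),
                 oracle_ev(doc$tokens, entries, "negative"))
    expect_equal(ev_score(doc, lex, "positive"),
                 oracle_ev(doc$tokens, entries, "positive"))
    fam <- family_ev_scores(doc, lex)
    for (f in names(fam)) {
      expect_equal(unname(fam[f]), oracle_family_ev(doc$tokens, entries, f))
    }
    expect_equal(category_rate(doc, lexicon_slice(lex, "negative")),
                 oracle_tone(doc$tokens, entries, "negative"))
    expect_equal(ttr(doc, ev_function_words(), lex)$open_class_ttr,
                 oracle_open_class_ttr(doc$tokens, entries, fn_words))
  }
})

test_that("score_document assembles every configured column", {
  row <- score_document(example_doc(), ev_lexicon(), ev_function_words(),
                        ev_category_lists())
  expect_true(all(c("neg_ev", "pos_ev", "ev_sadness", "raw_ttr",
                    "open_class_ttr", "rate_negative_tone",
                    "rate_i_words", "rate_illness") %in% names(row)))
  expect_equal(row$rate_i_words, 200 / 14)  # "me" and "i"
})
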