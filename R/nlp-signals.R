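#' Match suicide-related language against a lexicon
#'
#' Tokenizes on unicode word boundaries with case-folding. Keywords and
#' single-token slang match whole tokens only; multi-token slang and
#' multi-word phrases match contiguous token sequences (so a phrase split
#' across a line break still matches); emoji are matched as codepoint
#' subsequences anywhere in the raw text, before tokenization. No distinction
#' is made between intent, jokes or hyperbole — the match type records the
#' pattern class only.
#'
#' @param text a single character string.
#' @param lexicon a [lexicon_spec()].
#' @return list with `flag` (logical) and `matched_terms` (tibble with one
#'   row per match occurrence: `pattern`, `match_type`).
#' @export
match_suicide_language <- function(text, lexicon = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  res <- .match_lexicon_batch(text, lexicon)
  list(flag = res$flag[1], matched_terms = res$matched[[1]])
}

# Vectorized matcher: tokenizes all texts in one pass and reuses the
# lexicon's precompiled pattern tokens; emoji counts are computed with one
# vectorized scan per emoji.
.match_lexicon_batch <- function(texts, lexicon) {
  stopifnot(inherits(lexicon, "lexicon_spec"))
  n <- length(texts)
  toks <- tokenize_words(texts)
  pat <- vector("list", n)
  typ <- vector("list", n)
  add_hits <- function(i, pattern, type, times) {
    if (times > 0) {
      pat[[i]] <<- c(pat[[i]], rep(pattern, times))
      typ[[i]] <<- c(typ[[i]], rep(type, times))
    }
  }
  single <- lexicon$keywords
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) == 0) next
    hit_any <- any(tk %in% single)
    if (hit_any) {
      for (k in single) add_hits(i, k, "keyword", sum(tk == k))
    }
    for (j in seq_along(lexicon$slang_terms)) {
      st <- lexicon$slang_tokens[[j]]
      if (all(st %in% tk)) {
        add_hits(i, lexicon$slang_terms[j], "slang", .count_ngram(tk, st))
      }
    }
    for (j in seq_along(lexicon$multiword_phrases)) {
      mt <- lexicon$multiword_tokens[[j]]
      if (all(mt %in% tk)) {
        add_hits(i, lexicon$multiword_phrases[j], "multiword",
                 .count_ngram(tk, mt))
      }
    }
  }
  for (e in lexicon$emoji_set) {
    cnt <- stringr::str_count(texts, stringr::fixed(e))
    for (i in which(cnt > 0)) add_hits(i, e, "emoji", cnt[i])
  }
  matched <- lapply(seq_len(n), function(i) {
    tibble(pattern = pat[[i]] %||% character(0),
           match_type = typ[[i]] %||% character(0))
  })
  list(flag = vapply(matched, nrow, 1L) > 0, matched = matched)
}

.count_ngram <- function(tokens, ngram) {
  k <- length(ngram)
  n <- length(tokens)
  if (k == 0 || n < k) return(0L)
  if (k == 1) return(sum(tokens == ngram))
  hits <- 0L
  for (i in seq_len(n - k + 1)) {
    if (all(tokens[i:(i + k - 1)] == ngram)) hits <- hits + 1L
  }
  hits
}

#' Construct a sentiment scorer
#'
#' A scorer is a deterministic callable contract: text -> list(label, scores)
#' with label in {negative, neutral, positive} and scores a named numeric
#' vector over the three labels summing to 1. Adapters for external
#' transformer models can be wrapped with this constructor; the bundled
#' default is [rule_sentiment_scorer()].
#'
#' @param fn function(text) -> list(label, scores).
#' @param name,version identifying tokens.
#' @return object of class `sentiment_scorer`.
#' @export
sentiment_scorer <- function(fn, name, version = "0") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, name = name, version = version),
            class = "sentiment_scorer")
}

#' Rule-based valence scorer (deterministic default)
#'
#' Counts valence-marked tokens from the bundled positive/negative wordlists;
#' a negator ("not", "never", "no") within the two preceding tokens flips a
#' token's valence. The label is the majority valence; neutral on ties or
#' when no valence token is present. Scores are the hit proportions (neutral
#' gets mass 1 only when there are no hits).
#'
#' @param valence wordlists as from [default_valence_words()].
#' @param negator_window how many preceding tokens a negator can flip
#'   (default 2).
#' @return a [sentiment_scorer()].
#' @export
rule_sentiment_scorer <- function(valence = default_valence_words(),
                                  negator_window = 2) {
  force(valence); force(negator_window)
  fn <- function(text) {
    tokens <- tokenize_words(text)[[1]]
    n <- length(tokens)
    npos <- 0L; nneg <- 0L
    for (i in seq_len(n)) {
      pol <- if (tokens[i] %in% valence$positive) 1L
             else if (tokens[i] %in% valence$negative) -1L else 0L
      if (pol == 0L) next
      lo <- max(1L, i - negator_window)
      if (i > 1 && any(tokens[lo:(i - 1L)] %in% valence$negators)) pol <- -pol
      if (pol > 0) npos <- npos + 1L else nneg <- nneg + 1L
    }
    tot <- npos + nneg
    if (tot == 0L) {
      list(label = "neutral",
           scores = c(negative = 0, neutral = 1, positive = 0))
    } else {
      label <- if (nneg > npos) "negative"
               else if (npos > nneg) "positive" else "neutral"
      list(label = label,
           scores = c(negative = nneg / tot, neutral = 0, positive = npos / tot))
    }
  }
  sentiment_scorer(fn, name = "rule-valence", version = "0.1")
}

#' Classify the sentiment of one text entry
#'
#' Returns the scorer's output unchanged. A scorer failure yields a neutral
#' label with a warning so a stream is never aborted mid-pipeline.
#'
#' @param text a single character string.
#' @param scorer a [sentiment_scorer()].
#' @return list with `label` and `scores`.
#' @export
classify_sentiment <- function(text, scorer = rule_sentiment_scorer()) {
  stopifnot(inherits(scorer, "sentiment_scorer"))
  tryCatch(scorer$fn(text), error = function(e) {
    warning("sentiment scorer failed (", conditionMessage(e),
            "); labeling neutral", call. = FALSE)
    list(label = "neutral", scores = c(negative = 0, neutral = 1, positive = 0))
  })
}

#' Detect first-person singular self-reference
#'
#' TRUE iff the case-folded token list contains a first-person singular
#' pronoun from the configured closed list.
#'
#' @param text character vector.
#' @param pronouns token list (default [default_pronouns()]).
#' @return logical vector.
#' @export
detect_self_reference <- function(text, pronouns = default_pronouns()) {
  vapply(tokenize_words(text), function(tk) any(tk %in% pronouns), logical(1))
}

#' Label every entry of a participant record
#'
#' Applies the suicide-language lexicon, the sentiment scorer and the
#' self-reference rule to each entry. `negative_self_ref` is TRUE iff the
#' sentiment label is negative AND a first-person pronoun is present, so
#' negative-self-reference entries are a subset of negative entries by
#' construction (asserted).
#'
#' @param record a [participant_record()].
#' @param lexicon a [lexicon_spec()].
#' @param scorer a [sentiment_scorer()].
#' @param pronouns self-reference token list.
#' @return tibble of class `entry_labels`, one row per entry: entry_id,
#'   suicide_flag, matched_terms (list column), sentiment_label,
#'   score_negative/neutral/positive, negative, negative_self_ref.
#' @export
label_entries <- function(record, lexicon = default_lexicon(),
                          scorer = rule_sentiment_scorer(),
                          pronouns = default_pronouns()) {
  stopifnot(inherits(record, "participant_record"))
  texts <- record$entries$text
  lex <- .match_lexicon_batch(texts, lexicon)
  sent <- lapply(texts, classify_sentiment, scorer = scorer)
  selfref <- detect_self_reference(texts, pronouns)
  labels <- tibble(
    entry_id = record$entries$entry_id,
    suicide_flag = lex$flag,
    matched_terms = lex$matched,
    sentiment_label = vapply(sent, `[[`, character(1), "label"),
    score_negative = vapply(sent, function(s) s$scores[["negative"]], 1),
    score_neutral = vapply(sent, function(s) s$scores[["neutral"]], 1),
    score_positive = vapply(sent, function(s) s$scores[["positive"]], 1)
  )
  labels$negative <- labels$sentiment_label == "negative"
  labels$negative_self_ref <- labels$negative & selfref
  stopifnot(all(labels$negative_self_ref <= labels$negative))
  stopifnot(nrow(labels) == nrow(record$entries))
  class(labels) <- c("entry_labels", class(labels))
  labels
}
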