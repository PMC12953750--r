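# Bundled demonstration vocabularies. The shipped lexicon is a small,
# NON-CLINICAL demonstration list: the validated youth suicide lexicon used in
# the field is external IP and is not reproduced here. Users load their own
# lexicon from YAML/JSON via lexicon_from_file(). The engine, not the list, is
# what this package provides.

#' Construct a suicide-language lexicon
#'
#' A lexicon combines four pattern classes: single-token keywords, slang
#' terms (tokens or short phrases), multi-word phrases (token sequences of
#' length >= 2) and emoji (codepoint sequences matched anywhere in the raw
#' text). All text patterns are case-folded at construction.
#'
#' @param keywords character vector of single tokens.
#' @param slang_terms character vector of tokens or short phrases.
#' @param multiword_phrases character vector of phrases (>= 2 tokens each).
#' @param emoji_set character vector of emoji codepoint sequences.
#' @param name,version identifying tokens stored with the spec.
#' @return object of class `lexicon_spec`.
#' @export
lexicon_spec <- function(keywords, slang_terms, multiword_phrases, emoji_set,
                         name = "custom", version = "0") {
  fold <- function(x) unique(stringr::str_to_lower(stringr::str_trim(x)))
  keywords <- fold(keywords)
  slang_terms <- fold(slang_terms)
  multiword_phrases <- fold(multiword_phrases)
  emoji_set <- unique(emoji_set)
  if (length(keywords) + length(slang_terms) + length(multiword_phrases) +
      length(emoji_set) == 0) {
    stop("lexicon is empty: at least one pattern is required", call. = FALSE)
  }
  if (any(vapply(tokenize_words(keywords), length, 1L) != 1L)) {
    stop("keywords must be single tokens", call. = FALSE)
  }
  if (any(vapply(tokenize_words(multiword_phrases), length, 1L) < 2L)) {
    stop("multiword_phrases must contain at least two tokens each", call. = FALSE)
  }
  structure(
    list(keywords = keywords, slang_terms = slang_terms,
         multiword_phrases = multiword_phrases, emoji_set = emoji_set,
         name = name, version = version,
         # pattern token sequences, precompiled once so matching is cheap
         slang_tokens = tokenize_words(slang_terms),
         multiword_tokens = tokenize_words(multiword_phrases)),
    class = "lexicon_spec"
  )
}

#' @export
print.lexicon_spec <- function(x, ...) {
  cat(sprintf("<lexicon_spec '%s' v%s: %d keywords, %d slang, %d multiword, %d emoji>\n",
              x$name, x$version, length(x$keywords), length(x$slang_terms),
              length(x$multiword_phrases), length(x$emoji_set)))
  invisible(x)
}

#' Default demonstration lexicon
#'
#' A small demonstration lexicon spanning all four pattern classes. It is NOT
#' a clinically validated instrument and exists so the engine and the
#' synthetic-data closure tests are runnable out of the box.
#'
#' @return a [lexicon_spec()].
#' @export
default_lexicon <- function() {
  lexicon_spec(
    keywords = c("suicide", "suicidal", "selfharm", "overdose", "unalive"),
    slang_terms = c("kms", "kys", "sewerslide", "oding", "unaliving"),
    multiword_phrases = c("end it all", "no reason to live",
                          "want to disappear forever"),
    emoji_set = c("☠", "\U0001FAA6", "\U0001F5E1"),
    name = "demo-youth-lexicon", version = "0.1"
  )
}

#' Load a lexicon from a YAML or JSON file
#'
#' The file must provide `keywords`, `slang_terms`, `multiword_phrases`,
#' `emoji_set` and may provide `name` and `version`.
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return a [lexicon_spec()].
#' @export
lexicon_from_file <- function(path) {
  cfg <- read_config_file(path)
  lexicon_spec(
    keywords = unlist(cfg$keywords),
    slang_terms = unlist(cfg$slang_terms),
    multiword_phrases = unlist(cfg$multiword_phrases),
    emoji_set = unlist(cfg$emoji_set) %||% character(),
    name = cfg$name %||% "file", version = as.character(cfg$version %||% "0")
  )
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
}

#' Bundled valence wordlists for the rule-based sentiment scorer
#'
#' @return list with `positive`, `negative` and `negators` character vectors.
#' @export
default_valence_words <- function() {
  list(
    positive = c("good", "great", "love", "loved", "happy", "amazing",
                 "awesome", "fun", "nice", "best", "excited", "glad",
                 "proud", "beautiful", "wonderful"),
    negative = c("bad", "awful", "terrible", "horrible", "hate", "hated",
                 "hates", "worst", "miserable", "angry", "sad", "upset",
                 "crying", "lonely", "anxious", "stressed", "annoying",
                 "disgusting", "hurts"),
    negators = c("not", "never", "no")
  )
}

#' First-person singular pronoun list for self-reference detection
#'
#' A closed token list (the field sometimes uses POS taggers instead; the
#' closed list keeps the rule transparent and deterministic).
#'
#' @return character vector of case-folded tokens.
#' @export
default_pronouns <- function() {
  c("i", "me", "my", "mine", "myself", "i'm", "i've", "i'd", "i'll", "im")
}

# Seed words per topic. Sets are pairwise disjoint in the default spec so the
# bag-of-words embedder gives unambiguous assignments on template text; user
# specs may overlap (overlaps are reported at load).
.default_topic_seeds <- function() {
  list(
    treatment = c("therapy", "therapist", "medication", "meds", "psychiatrist",
                  "counseling", "appointment", "prescription"),
    family = c("mom", "dad", "brother", "sister", "grandma", "grandpa",
               "cousin", "parents"),
    sleep = c("insomnia", "nap", "bedtime", "pillow", "dreams", "awake",
              "oversleep", "melatonin"),
    sex = c("sexting", "hookup", "crush", "dating", "flirting", "boyfriend",
            "girlfriend", "situationship"),
    school = c("homework", "exam", "teacher", "classroom", "grades", "quiz",
               "semester", "algebra"),
    death = c("funeral", "grave", "coffin", "cemetery", "afterlife",
              "obituary", "burial", "mourning"),
    substance_use = c("weed", "vape", "alcohol", "drunk", "edibles",
                      "nicotine", "stoned", "vodka"),
    eating = c("calories", "snack", "dinner", "breakfast", "lunch",
               "appetite", "recipe", "vegetarian"),
    friends = c("bestie", "squad", "hangout", "sleepover", "groupchat",
                "classmates", "buddies", "pals"),
    future = c("college", "career", "internship", "moving", "apartment",
               "roadtrip", "graduation", "gapyear")
  )
}
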