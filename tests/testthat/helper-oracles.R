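# Independent brute-force oracles and fixture builders used across tests.

# Independent tokenizer: lowercase, map everything except letters/digits/
# apostrophes to spaces, split, trim edge apostrophes. Fixtures avoid exotic
# apostrophe runs so this agrees with the package tokenizer by construction.
oracle_tokenize <- function(text) {
  x <- tolower(gsub("’", "'", text))
  x <- gsub("[^\\p{L}\\p{N}']+", " ", x, perl = TRUE)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks <- gsub("^'+|'+$", "", toks)
  toks[nzchar(toks)]
}

# Exhaustive lexicon scan: every pattern against every token / n-gram window /
# codepoint window.
oracle_match_lexicon <- function(text, lexicon) {
  toks <- oracle_tokenize(text)
  pat <- character(0); typ <- character(0)
  count_seq <- function(seq_toks) {
    k <- length(seq_toks); n <- length(toks)
    if (k == 0 || n < k) return(0L)
    hits <- 0L
    for (i in seq_len(n - k + 1)) {
      if (identical(toks[i:(i + k - 1)], seq_toks)) hits <- hits + 1L
    }
    hits
  }
  for (p in lexicon$keywords) {
    m <- sum(toks == p)
    if (m > 0) { pat <- c(pat, rep(p, m)); typ <- c(typ, rep("keyword", m)) }
  }
  for (p in lexicon$slang_terms) {
    m <- count_seq(oracle_tokenize(p))
    if (m > 0) { pat <- c(pat, rep(p, m)); typ <- c(typ, rep("slang", m)) }
  }
  for (p in lexicon$multiword_phrases) {
    m <- count_seq(oracle_tokenize(p))
    if (m > 0) { pat <- c(pat, rep(p, m)); typ <- c(typ, rep("multiword", m)) }
  }
  for (p in lexicon$emoji_set) {
    cp <- strsplit(text, "")[[1]]
    pc <- strsplit(p, "")[[1]]
    k <- length(pc); m <- 0L
    if (length(cp) >= k) {
      for (i in seq_len(length(cp) - k + 1)) {
        if (identical(cp[i:(i + k - 1)], pc)) m <- m + 1L
      }
    }
    if (m > 0) { pat <- c(pat, rep(p, m)); typ <- c(typ, rep("emoji", m)) }
  }
  list(flag = length(pat) > 0,
       matched = tibble::tibble(pattern = pat, match_type = typ))
}

sort_matches <- function(df) df[order(df$pattern, df$match_type), , drop = FALSE]

# Pairwise-scan segmentation oracle: walk consecutive event pairs, split on
# app change or gap > threshold, concatenate fragments, drop empties.
oracle_segment <- function(events, pause_threshold) {
  n <- nrow(events)
  if (n == 0) return(list())
  groups <- list()
  cur <- 1L
  for (i in seq_len(n)) {
    if (i == 1) { groups[[1]] <- i; next }
    gap <- as.numeric(difftime(events$timestamp[i], events$timestamp[i - 1],
                               units = "secs"))
    if (events$app_id[i] != events$app_id[i - 1] || gap > pause_threshold) {
      cur <- cur + 1L
      groups[[cur]] <- i
    } else {
      groups[[cur]] <- c(groups[[cur]], i)
    }
  }
  out <- lapply(groups, function(idx) {
    list(timestamp = events$timestamp[idx[1]],
         app_id = events$app_id[idx[1]],
         text = paste0(events$fragment[idx], collapse = ""))
  })
  Filter(function(e) nchar(trimws(e$text)) > 0, out)
}

# Direct-summation cosine oracle for seeded topic assignment.
oracle_assign_topic <- function(text, spec) {
  toks <- oracle_tokenize(text)
  toks <- toks[toks %in% spec$vocab]
  if (length(toks) == 0) return(list(topic = "OUTLIER", similarity = 0))
  tf <- table(toks)
  sims <- vapply(spec$topics, function(tp) {
    sw <- spec$seed_words[[tp]]
    num <- sum(tf[names(tf) %in% sw])
    num / (sqrt(sum(tf^2)) * sqrt(length(sw)))
  }, numeric(1))
  best <- which.max(sims)
  if (sims[best] >= spec$assignment_threshold) {
    list(topic = spec$topics[best], similarity = unname(sims[best]))
  } else {
    list(topic = "OUTLIER", similarity = unname(sims[best]))
  }
}

# Fixture corpus for the lexicon oracle: template text with case mangling,
# punctuation noise, line breaks inside phrases, plus pattern-free text.
make_lexicon_corpus <- function(n = 500, seed = 42) {
  set.seed(seed)
  pools <- acutelang:::template_pools()
  lex <- default_lexicon()
  pieces <- c(pools$neutral, pools$negative_plain, pools$suicide$text,
              unlist(pools$topic), lex$keywords, lex$slang_terms,
              lex$multiword_phrases, lex$emoji_set)
  vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    txt <- paste(sample(pieces, k, replace = TRUE), collapse = " ")
    if (runif(1) < 0.3) txt <- toupper(txt)
    if (runif(1) < 0.3) txt <- gsub(" ", "\n", txt)
    if (runif(1) < 0.4) txt <- paste0(txt, sample(c("!!", "...", "??", ","), 1))
    if (runif(1) < 0.2) txt <- paste("random filler words", txt)
    txt
  }, character(1))
}

# Keyboard-event fixture with mixed app changes and gap structure.
make_event_fixture <- function(n = 1000, seed = 7, pid = "EV1") {
  set.seed(seed)
  gaps <- sample(c(1, 5, 30, 59, 60, 61, 120, 600), n, replace = TRUE)
  ts <- as.POSIXct("2023-04-01 08:00:00", tz = "UTC") + cumsum(gaps)
  frags <- sample(c("hello ", "ok", "see u soon ", "what ", "", " ", "later",
                    "math homework ", "lol "), n, replace = TRUE)
  tibble::tibble(
    participant_id = pid,
    timestamp = ts,
    app_id = sample(c("messages", "notes", "search"), n, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2)),
    fragment = frags
  )
}

# Small homogeneous config used by several metric tests.
null_config <- function(seed, pid = sprintf("P%03d", seed), days = 90,
                        mean = 100, elevation_suicide = 1,
                        elevation_onset_days_before = 1,
                        weekend_multiplier_suicide = 1, ...) {
  synthetic_config(participant_id = pid, study_days = days,
                   hospitalization_day = days, study_start = as.Date("2023-01-02"),
                   entries_per_day_mean = mean, entries_per_day_dispersion = 10,
                   base_rate_suicide = 0.02, base_rate_negative = 0.30,
                   elevation_suicide = elevation_suicide, elevation_negative = 1,
                   elevation_onset_days_before = elevation_onset_days_before,
                   missing_day_prob = 0,
                   weekend_multiplier_suicide = weekend_multiplier_suicide,
                   rng_seed = seed, ...)
}
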