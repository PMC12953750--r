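# Template pools for the synthetic generator. All texts are synthetic and
# non-identifying. The pools are engineered to be unambiguous under the
# default labelers, which is what makes label-recovery closure exact:
#   - only negative templates contain valence tokens (never preceded by a
#     negator), so the rule scorer labels exactly the negative entries;
#   - only the self-reference variants contain first-person pronouns;
#   - only suicide templates contain lexicon patterns, and they are free of
#     valence tokens, pronouns and topic seed words;
#   - topic templates draw their content words only from that topic's seed
#     set, and all filler vocabulary is outside every reserved list.

template_pools <- function() {
  neutral <- c(
    "gonna watch the new episode tonight",
    "what time does practice start",
    "the bus was late again",
    "did u see that video",
    "send the notes from earlier",
    "the weather looks cloudy today",
    "that song has been stuck all day",
    "remember to bring the charger",
    "the game went into overtime",
    "walking over in ten minutes",
    "the printer ran out of ink",
    "two tickets left for saturday",
    "the wifi keeps dropping again",
    "practice got rescheduled to thursday",
    "what chapter are we on",
    "the store closes at nine",
    "left the umbrella at the gym",
    "the new update changed everything around",
    "whats the address for tomorrow",
    "the dog learned a new trick",
    "ordering the usual for pickup",
    "the library was packed today",
    "rehearsal runs until seven tonight",
    "the trail was muddy after the rain",
    "saving a seat near the window",
    "the phone needs a new case",
    "coach posted the lineup already",
    "the elevator is out again",
    "paint dried darker than expected",
    "the playlist needs new songs"
  )

  negative_plain <- c(
    "this is awful",
    "worst day ever",
    "everything is terrible",
    "so angry right now",
    "that was horrible",
    "feeling sad tonight",
    "so upset about everything",
    "everyone was so annoying today",
    "absolutely miserable out here",
    "this whole week has been awful",
    "so stressed about tomorrow",
    "feeling anxious again tonight",
    "crying over the same thing again",
    "the whole thing was disgusting",
    "so lonely lately"
  )

  negative_selfref <- c(
    "i hate this so much",
    "my whole day was terrible",
    "i feel miserable",
    "i am so upset",
    "everything makes me sad",
    "i hated every minute",
    "my head hurts and everything is awful",
    "i am the worst"
  )

  suicide <- tibble::tibble(
    text = c(
      "been reading about suicide again",
      "suicidal thoughts again tonight",
      "searched overdose amounts earlier",
      "unalive jokes in class again",
      "selfharm scars showing again",
      "kms fr fr",
      "ngl kms at this point",
      "kys energy today",
      "sewerslide vibes again",
      "oding sounds easier tonight",
      "want to end it all",
      "there is no reason to live",
      "just want to disappear forever",
      "feeling like ☠ today",
      "\U0001FAA6 soon",
      "that \U0001F5E1 feeling again"
    ),
    subtype = c(rep("keyword", 5), rep("slang", 5), rep("multiword", 3),
                rep("emoji", 3))
  )

  patterns <- c(
    "talking about %s and %s again",
    "%s and %s stuff later today",
    "thinking about %s after the %s thing",
    "%s then %s this week",
    "all about %s and %s tonight",
    "%s before %s tomorrow",
    "that %s and %s situation again",
    "%s talk and %s talk all week"
  )
  pairs <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                c(2, 5), c(4, 7), c(6, 1), c(8, 3))
  seeds <- .default_topic_seeds()
  topic <- lapply(seeds, function(sw) {
    vapply(seq_along(patterns), function(i) {
      sprintf(patterns[i], sw[pairs[[i]][1]], sw[pairs[[i]][2]])
    }, character(1))
  })

  list(neutral = neutral, negative_plain = negative_plain,
       negative_selfref = negative_selfref, suicide = suicide, topic = topic)
}

# Assemble entry texts from drawn labels. Vectorized over entries.
compose_entry_texts <- function(topic, negative, self_ref, suicide, pools) {
  n <- length(negative)
  base <- character(n)
  no_topic <- is.na(topic) | topic == "OUTLIER"
  base[no_topic] <- sample(pools$neutral, sum(no_topic), replace = TRUE)
  for (t in unique(topic[!no_topic])) {
    idx <- which(!no_topic & topic == t)
    base[idx] <- sample(pools$topic[[t]], length(idx), replace = TRUE)
  }
  neg_part <- character(n)
  sr <- negative & self_ref
  np <- negative & !self_ref
  neg_part[sr] <- sample(pools$negative_selfref, sum(sr), replace = TRUE)
  neg_part[np] <- sample(pools$negative_plain, sum(np), replace = TRUE)
  sui_part <- character(n)
  sui_part[suicide] <- sample(pools$suicide$text, sum(suicide), replace = TRUE)
  out <- base
  out[negative] <- paste(out[negative], neg_part[negative])
  out[suicide] <- paste(out[suicide], sui_part[suicide])
  out
}
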