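#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats loess predict rbinom rnbinom runif setNames
#' @importFrom utils head tail
NULL

# Timestamps are local civil clock times; we carry them as POSIXct in UTC so
# no DST arithmetic ever applies, and serialize without a zone designator.
.TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

format_timestamp <- function(x) format(x, .TS_FORMAT, tz = "UTC")

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, format = .TS_FORMAT, tz = "UTC")
  bad <- !is.na(x) & is.na(out)
  # tolerate a plain "YYYY-MM-DD HH:MM:SS" variant
  if (any(bad)) {
    alt <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
    out[bad] <- alt
  }
  out
}

civil_date <- function(timestamp) as.Date(timestamp, tz = "UTC")

#' Tokenize text on unicode word boundaries
#'
#' Case-folds and extracts word tokens (letters/digits, with internal
#' apostrophes kept so contractions such as "i'm" stay one token). Emoji and
#' punctuation are dropped; emoji are matched separately on raw text by the
#' lexicon engine.
#'
#' @param text character vector.
#' @return list of character vectors, one per input element.
#' @export
tokenize_words <- function(text) {
  text <- stringr::str_replace_all(text, "’", "'")
  text <- stringr::str_to_lower(text)
  stringr::str_extract_all(text, "[\\p{L}\\p{N}]+(?:'[\\p{L}\\p{N}]+)*")
}

count_words <- function(text) {
  lengths(stringr::str_split(stringr::str_trim(text), "\\s+")) *
    (nchar(stringr::str_trim(text)) > 0)
}

is_probability <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)

is_weekend <- function(dates) format(dates, "%u") %in% c("6", "7")
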