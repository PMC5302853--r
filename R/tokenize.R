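# Tokenization and clause segmentation.
#
# Messages are lowercased (after Unicode NFKC normalization), user mentions
# (@...), hashtags (#...) and URLs are removed, clause breaks are taken at
# sentence punctuation (. ! ? ; :) and message boundaries, and remaining
# punctuation is stripped from token edges. Tokens left with no letter or
# digit (stray symbols, emoji) are dropped.

tokenize <- function(text) {
  strsplit(trimws(text), "[[:space:]]+")[[1L]]
}

normalize_tokens <- function(tokens) {
  if (!length(tokens)) return(character(0L))
  tokens <- stringi::stri_trans_nfkc(tokens)
  tokens <- tolower(tokens)
  # strip leading/trailing punctuation and symbols
  tokens <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", tokens, perl = TRUE)
  tokens[grepl("[[:alnum:]]", tokens)]
}

#' Segment a message into clauses of normalized tokens
#'
#' A clause is a maximal run of tokens between sentence punctuation marks
#' (\code{. ! ? ; :}) or message boundaries. Mentions, hashtags and URLs are
#' excluded before segmentation, everything is lowercased, and leftover
#' punctuation is stripped from token edges. The empty result is allowed.
#'
#' @param text A single character string (one message).
#' @return A list of character vectors, one per clause; each vector holds
#'   the clause's tokens in order.
#' @examples
#' segment_clauses("I LOVE Pizza")                        # list(c("i","love","pizza"))
#' segment_clauses("Eating #pizza with @bob at http://x.co")
#' segment_clauses("pizza. running")                      # two clauses
#' @export
segment_clauses <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("'text' must be a single string")
  text <- stringi::stri_trans_nfkc(text)
  text <- tolower(text)
  # remove URLs, user mentions, hashtags as whole tokens
  text <- gsub("(?:https?://|www\\.)[^[:space:]]+", " ", text, perl = TRUE)
  text <- gsub("(^|[[:space:]])[@#][^[:space:]]+", " ", text, perl = TRUE)
  pieces <- strsplit(text, "[.!?;:]+")[[1L]]
  clauses <- lapply(pieces, function(p) normalize_tokens(tokenize(p)))
  clauses[lengths(clauses) > 0L]
}

# Segment every message of a corpus data.frame (id, region, text) into
# clauses; returns a list with parallel vectors: tokens (list of character
# vectors), region, message_id.
segment_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus),
            all(c("id", "region", "text") %in% names(corpus)))
  per_msg <- lapply(corpus$text, segment_clauses)
  n_cl <- lengths(per_msg)
  list(tokens = unlist(per_msg, recursive = FALSE),
       region = rep(as.character(corpus$region), n_cl),
       message_id = rep(as.character(corpus$id), n_cl))
}
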