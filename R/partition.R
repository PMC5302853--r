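# Serial text partitioning.
#
# Two corpus-level functions drive the greedy segmentation:
#
#  * f(s), the random-partition frequency of phrase s: the expected number
#    of times s appears as a cell when each of the L-1 internal gaps of a
#    clause of length L independently receives a boundary with probability
#    1/2 and clause edges are always boundaries. A single occurrence of s
#    spanning positions i..j of a clause contributes
#    (1/2)^(len-1) * (1/2)^[i>1] * (1/2)^[j<L].
#
#  * L(s), the context-local likelihood: each phrase of length l belongs to
#    l one-wildcard context patterns (token k replaced by a wildcard); for
#    a context C the likelihood P(s|C) = f(s) / sum of f over phrases
#    matching C, and L(s) is the minimum over s's contexts (the most
#    prevalent context). L is zero on the empty phrase and on phrases with
#    f = 0 or length above the cap.
#
# The partitioner walks a clause left to right, growing the current phrase
# while L strictly increases and flushing it to the partition otherwise.

WILDCARD <- "★" # cannot occur in a normalized token

phrase_key <- function(tokens) paste(tokens, collapse = " ")

#' One-wildcard context patterns of a phrase
#'
#' A phrase of length l is a member of exactly l contexts, the k-th obtained
#' by replacing token k with a wildcard; e.g. \code{c("new","york","city")}
#' belongs to \code{(*,york,city)}, \code{(new,*,city)} and
#' \code{(new,york,*)}.
#'
#' @param tokens Character vector of phrase tokens (length >= 1).
#' @return Character vector of \code{length(tokens)} context patterns, each
#'   a space-joined token sequence with one wildcard.
#' @export
phrase_contexts <- function(tokens) {
  if (!length(tokens)) stop("empty phrase has no contexts")
  vapply(seq_along(tokens), function(k) {
    ctx <- tokens
    ctx[k] <- WILDCARD
    phrase_key(ctx)
  }, character(1L))
}

#' Random-partition phrase statistics over a corpus
#'
#' Computes, for every contiguous phrase of up to \code{max_len} tokens
#' occurring in the clauses, its random-partition frequency f(s), the totals
#' of f over every one-wildcard context pattern, and the context-local
#' likelihood L(s) derived from the two.
#'
#' @param clauses A list of character vectors (one clause each), or a single
#'   character vector treated as one clause.
#' @param max_len Maximum phrase length in tokens (default 5).
#' @return An object of class \code{"phrase_stats"}: a list with data.tables
#'   \code{f} (phrase, f), \code{contexts} (pattern, total),
#'   \code{L} (phrase, L), and \code{max_len}, \code{n_clauses}.
#' @examples
#' st <- phrase_stats(list(c("a", "b", "c")))
#' phrase_frequency(st, "a")     # 0.5
#' phrase_frequency(st, c("a", "b", "c")) # 0.25
#' @export
phrase_stats <- function(clauses, max_len = 5L) {
  if (is.character(clauses)) clauses <- list(clauses)
  stopifnot(is.list(clauses), max_len >= 1L)
  clauses <- clauses[lengths(clauses) > 0L]
  if (!length(clauses))
    return(structure(list(
      f = data.table::data.table(phrase = character(), f = numeric(),
                                 key = "phrase"),
      contexts = data.table::data.table(pattern = character(),
                                        total = numeric(), key = "pattern"),
      L = data.table::data.table(phrase = character(), L = numeric(),
                                 key = "phrase"),
      max_len = as.integer(max_len), n_clauses = 0L),
      class = "phrase_stats"))

  toks <- unlist(clauses, use.names = FALSE)
  len <- lengths(clauses)
  clen <- rep(len, len)              # clause length, per token
  pos <- sequence(len)               # position within clause, per token
  n <- length(toks)

  occ_phrase <- vector("list", max_len)
  occ_w <- vector("list", max_len)
  ctx_pattern <- list()
  ctx_w <- list()
  ci <- 0L

  for (ell in seq_len(max_len)) {
    keep <- pos + ell - 1L <= clen   # occurrence fits inside its clause
    if (!any(keep)) break
    idx <- which(keep)
    parts <- lapply(seq_len(ell) - 1L, function(k) toks[idx + k])
    ph <- do.call(paste, parts)
    w <- (0.5)^(ell - 1L) *
      ifelse(pos[idx] > 1L, 0.5, 1) *
      ifelse(pos[idx] + ell - 1L < clen[idx], 0.5, 1)
    occ_phrase[[ell]] <- ph
    occ_w[[ell]] <- w
    for (k in seq_len(ell)) {
      wparts <- parts
      wparts[[k]] <- rep(WILDCARD, length(idx))
      ci <- ci + 1L
      ctx_pattern[[ci]] <- do.call(paste, wparts)
      ctx_w[[ci]] <- w
    }
  }

  occ <- data.table::data.table(
    phrase = unlist(occ_phrase, use.names = FALSE),
    w = unlist(occ_w, use.names = FALSE))
  f_tab <- occ[, list(f = sum(w)), by = "phrase"]
  data.table::setkeyv(f_tab, "phrase")

  ctx <- data.table::data.table(
    pattern = unlist(ctx_pattern, use.names = FALSE),
    w = unlist(ctx_w, use.names = FALSE))
  ctx_tab <- ctx[, list(total = sum(w)), by = "pattern"]
  data.table::setkeyv(ctx_tab, "pattern")

  # L(s): min over s's contexts of f(s) / context total. Rebuild the
  # (phrase, pattern) incidence at occurrence level, unique it, join totals.
  inc_phrase <- list()
  ii <- 0L
  for (ell in seq_along(occ_phrase)) {
    if (is.null(occ_phrase[[ell]])) next
    for (k in seq_len(ell)) {
      ii <- ii + 1L
      inc_phrase[[ii]] <- occ_phrase[[ell]]
    }
  }
  inc <- unique(data.table::data.table(
    phrase = unlist(inc_phrase, use.names = FALSE),
    pattern = unlist(ctx_pattern, use.names = FALSE)))
  inc[, `:=`(total = ctx_tab[inc, on = "pattern", x.total],
             f = f_tab[inc, on = "phrase", x.f])]
  L_tab <- inc[, list(L = min(f / total)), by = "phrase"]
  data.table::setkeyv(L_tab, "phrase")

  structure(list(f = f_tab, contexts = ctx_tab, L = L_tab,
                 max_len = as.integer(max_len),
                 n_clauses = length(clauses)),
            class = "phrase_stats")
}

#' @export
print.phrase_stats <- function(x, ...) {
  cat(sprintf("<phrase_stats: %d clauses, %d phrases (max_len %d), %d contexts>\n",
              x$n_clauses, nrow(x$f), x$max_len, nrow(x$contexts)))
  invisible(x)
}

#' Random-partition frequency of a phrase
#'
#' @param stats A \code{"phrase_stats"} object.
#' @param tokens Character vector of phrase tokens.
#' @return f(s); 0 for unobserved phrases.
#' @export
phrase_frequency <- function(stats, tokens) {
  stopifnot(inherits(stats, "phrase_stats"))
  key <- phrase_key(tokens)
  v <- stats$f[list(key), on = "phrase", x.f]
  if (is.na(v)) 0 else v
}

#' Context-local likelihood of a phrase
#'
#' Returns the minimum over the phrase's one-wildcard contexts of
#' f(s) divided by the context's total f. Zero on the empty phrase and on
#' phrases unobserved in the corpus or longer than the length cap.
#'
#' @inheritParams phrase_frequency
#' @return L(s) in [0, 1].
#' @export
local_likelihood <- function(stats, tokens) {
  stopifnot(inherits(stats, "phrase_stats"))
  if (!length(tokens)) return(0)
  if (length(tokens) > stats$max_len) return(0)
  v <- stats$L[list(phrase_key(tokens)), on = "phrase", x.L]
  if (is.na(v)) 0 else v
}

#' Serially partition one clause
#'
#' Greedy left-to-right segmentation: the current phrase is grown by the
#' next token while the context-local likelihood strictly increases, and is
#' flushed to the partition otherwise. The cells concatenate back to the
#' clause token-for-token.
#'
#' @param tokens Character vector, the clause.
#' @param stats \code{"phrase_stats"} built over the corpus the clause
#'   belongs to.
#' @return A list of character vectors, the partition cells in order.
#' @export
serial_partition <- function(tokens, stats) {
  stopifnot(inherits(stats, "phrase_stats"))
  if (!length(tokens)) stop("cannot partition an empty clause")
  cells <- list()
  cur <- tokens[1L]
  curL <- local_likelihood(stats, cur)
  for (i in seq_along(tokens)[-1L]) {
    cand <- c(cur, tokens[i])
    candL <- local_likelihood(stats, cand)
    if (candL > curL) {
      cur <- cand
      curL <- candL
    } else {
      cells[[length(cells) + 1L]] <- cur
      cur <- tokens[i]
      curL <- local_likelihood(stats, cur)
    }
  }
  cells[[length(cells) + 1L]] <- cur
  cells
}

# Batch partitioner: runs the greedy segmentation over many clauses at once
# using vectorized keyed lookups of the precomputed L table. Returns a
# data.table(clause_id, cell_idx, phrase) with cells in clause order.
partition_clauses <- function(clauses, stats) {
  stopifnot(inherits(stats, "phrase_stats"), is.list(clauses))
  n <- length(clauses)
  if (!n) return(data.table::data.table(clause_id = integer(),
                                        cell_idx = integer(),
                                        phrase = character()))
  len <- lengths(clauses)
  if (any(len == 0L)) stop("cannot partition an empty clause")
  Ltab <- stats$L
  lookupL <- function(keys) {
    v <- Ltab[list(keys), on = "phrase", x.L]
    v[is.na(v)] <- 0
    v
  }
  maxlen <- max(len)
  # ragged token columns
  tokcol <- vector("list", maxlen)
  toks <- unlist(clauses, use.names = FALSE)
  starts <- cumsum(c(1L, len[-n]))
  for (i in seq_len(maxlen)) {
    col <- rep(NA_character_, n)
    has <- len >= i
    col[has] <- toks[starts[has] + (i - 1L)]
    tokcol[[i]] <- col
  }

  out_id <- list(); out_phrase <- list(); oi <- 0L
  cur <- tokcol[[1L]]
  curL <- lookupL(cur)
  if (maxlen > 1L) for (i in 2L:maxlen) {
    act <- which(len >= i)
    if (!length(act)) break
    tk <- tokcol[[i]][act]
    cand <- paste(cur[act], tk)
    candL <- lookupL(cand)
    grow <- candL > curL[act]
    g <- act[grow]; s <- act[!grow]
    if (length(g)) {
      cur[g] <- cand[grow]
      curL[g] <- candL[grow]
    }
    if (length(s)) {
      oi <- oi + 1L
      out_id[[oi]] <- s
      out_phrase[[oi]] <- cur[s]
      cur[s] <- tokcol[[i]][s]
      curL[s] <- lookupL(cur[s])
    }
  }
  oi <- oi + 1L
  out_id[[oi]] <- seq_len(n)
  out_phrase[[oi]] <- cur

  res <- data.table::data.table(
    clause_id = unlist(out_id, use.names = FALSE),
    phrase = unlist(out_phrase, use.names = FALSE))
  data.table::setorderv(res, "clause_id")
  res[, cell_idx := seq_len(.N), by = "clause_id"]
  data.table::setcolorder(res, c("clause_id", "cell_idx", "phrase"))
  res[]
}

#' Partition a segmented corpus
#'
#' Builds (or reuses) corpus-level phrase statistics in a first pass and
#' serially partitions every clause in a second pass.
#'
#' @param clauses List of character vectors (clauses), e.g. the
#'   \code{tokens} element from segmenting a corpus.
#' @param region Character vector of per-clause region labels (recycled if
#'   length 1).
#' @param stats Optional precomputed \code{"phrase_stats"}; built from
#'   \code{clauses} with \code{max_len} when omitted.
#' @param max_len Phrase length cap used when building \code{stats}.
#' @return An object of class \code{"corpus_partition"}: a data.table with
#'   columns \code{region}, \code{clause_id}, \code{cell_idx},
#'   \code{phrase}, carrying the \code{"phrase_stats"} as attribute
#'   \code{stats}.
#' @export
partition_corpus <- function(clauses, region = "all", stats = NULL,
                             max_len = 5L) {
  if (length(region) == 1L) region <- rep(region, length(clauses))
  stopifnot(length(region) == length(clauses))
  if (is.null(stats)) stats <- phrase_stats(clauses, max_len = max_len)
  cells <- partition_clauses(clauses, stats)
  cells[, region := as.character(region[clause_id])]
  data.table::setcolorder(cells, c("region", "clause_id", "cell_idx", "phrase"))
  data.table::setattr(cells, "stats", stats)
  data.table::setattr(cells, "class",
                      c("corpus_partition", class(cells)))
  cells[]
}

#' Count lexicon lemmas in a partitioned corpus
#'
#' A lexicon phrase is counted once per partition cell that exactly equals
#' it -- a phrase absorbed into a larger cell (e.g. "apple" inside "apple of
#' my eye") is not counted. Counts are aggregated to lemmas per region;
#' lemmas whose corpus-wide count falls below \code{min_count} are dropped
#' (rare phrases carry no reliable signal).
#'
#' @param partition A \code{"corpus_partition"} (or any data.frame with
#'   columns \code{region} and \code{phrase}, one row per cell).
#' @param lex A \code{"lexicon"} object.
#' @param min_count Minimum corpus-wide lemma count to retain (default 5,
#'   i.e. lemmas seen four or fewer times are excluded).
#' @return An object of class \code{"region_lemma_counts"}: a data.frame
#'   with columns \code{region}, \code{lemma}, \code{count}, and attribute
#'   \code{side}.
#' @export
count_lexicon_lemmas <- function(partition, lex, min_count = 5L) {
  stopifnot(inherits(lex, "lexicon"),
            is.data.frame(partition),
            all(c("region", "phrase") %in% names(partition)))
  cells <- data.table::as.data.table(partition)[, c("region", "phrase")]
  map <- data.table::data.table(phrase = lex$entries$phrase,
                                lemma = lex$entries$lemma)
  hits <- cells[map, on = "phrase", nomatch = NULL]
  if (nrow(hits) == 0L) {
    counts <- data.frame(region = character(), lemma = character(),
                         count = numeric())
  } else {
    agg <- hits[, list(count = as.numeric(.N)), by = c("region", "lemma")]
    tot <- agg[, list(total = sum(count)), by = "lemma"]
    keep <- tot[total >= min_count, lemma]
    agg <- agg[lemma %in% keep]
    data.table::setorderv(agg, c("region", "lemma"))
    counts <- as.data.frame(agg)
  }
  structure(counts, side = lex$side, class = c("region_lemma_counts",
                                               class(counts)))
}
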