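# Phrase-shift decompositions.
#
# The difference between a comparison text and a reference text decomposes
# exactly over lemmas:
#   C(comp) - C(ref) = sum_s [score(s) - C_ref] [p_comp(s) - p_ref(s)]
# (the C_ref term cancels because both p's sum to one). Each lemma's
# contribution is normalized to a signed percentage
#   deltaC(s) = 100 [score(s) - C_ref] [p_comp(s) - p_ref(s)] / |C_comp - C_ref|
# so contributions sum to +100 when the comparison scores above the
# reference and -100 otherwise. Contributions fall into four categories by
# the sign of the score deviation (+/-) and of the usage deviation (up/down).

#' Equal-weight pooled reference distribution
#'
#' Pools the per-region usage distributions with equal weight per region
#' (not by message volume), standing in for the corpus-wide average text.
#'
#' @param counts A \code{"region_lemma_counts"} table covering one or more
#'   regions.
#' @param lex The matching-side \code{"lexicon"}.
#' @return An object of class \code{"reference_distribution"}: a list with
#'   \code{side}, \code{p_ref} (named probability vector over lemmas) and
#'   \code{C_ref} (the reference caloric score).
#' @export
pooled_reference <- function(counts, lex) {
  stopifnot(inherits(lex, "lexicon"), is.data.frame(counts))
  regions <- unique(counts$region)
  if (!length(regions)) stop("no regions to pool")
  lemmas <- sort(unique(counts$lemma))
  acc <- stats::setNames(numeric(length(lemmas)), lemmas)
  for (r in regions) {
    v <- region_count_vector(counts, r)
    if (sum(v) <= 0) stop("region ", r, " has an empty distribution")
    acc[names(v)] <- acc[names(v)] + v / sum(v)
  }
  p_ref <- acc / length(regions)
  C_ref <- sum(lemma_score(lex, names(p_ref)) * p_ref)
  structure(list(side = lex$side, p_ref = p_ref, C_ref = C_ref),
            class = "reference_distribution")
}

#' Classify a shift contribution
#'
#' The score sign is \code{"+"} when the lemma's caloric score exceeds the
#' reference score, and the usage arrow is \code{"up"} when the lemma is
#' used more in the comparison than in the reference. The four categories
#' are \code{"+up"}, \code{"-down"}, \code{"+down"}, \code{"-up"}.
#'
#' @param score Lemma caloric score.
#' @param c_ref Reference caloric score.
#' @param p_comp,p_ref Usage probabilities in comparison and reference.
#' @return The category string.
#' @export
classify_contribution <- function(score, c_ref, p_comp, p_ref) {
  if (score == c_ref && p_comp == p_ref)
    stop("both deviations are zero; the contribution is empty")
  paste0(if (score > c_ref) "+" else "-",
         if (p_comp > p_ref) "up" else "down")
}

#' Phrase-shift decomposition against a reference
#'
#' @param counts A \code{"region_lemma_counts"} table restricted to the
#'   comparison region, or a named count vector.
#' @param ref A \code{"reference_distribution"} from [pooled_reference()].
#' @param lex The matching-side \code{"lexicon"}.
#' @param comparison Label for the comparison text (defaults to the region
#'   in \code{counts} when available).
#' @param top Number of leading terms retained in printing (the full term
#'   table is always stored); default 23.
#' @return An object of class \code{"phrase_shift"}: a list with
#'   \code{side}, \code{comparison}, \code{net} (+100 or -100),
#'   \code{C_comp}, \code{C_ref}, \code{category_totals} (named numeric over
#'   the four categories), \code{terms} (data.frame lemma, delta, category,
#'   sorted by decreasing |delta|; exact-zero contributions omitted) and
#'   \code{top}.
#' @export
phrase_shift <- function(counts, ref, lex, comparison = NULL, top = 23L) {
  stopifnot(inherits(ref, "reference_distribution"),
            inherits(lex, "lexicon"))
  if (lex$side != ref$side) stop("lexicon and reference sides differ")
  if (is.data.frame(counts)) {
    if (is.null(comparison) && length(unique(counts$region)) == 1L)
      comparison <- unique(counts$region)
    if (length(unique(counts$region)) != 1L)
      stop("'counts' must hold a single comparison region")
    counts <- stats::setNames(counts$count, counts$lemma)
  }
  if (is.null(comparison)) comparison <- "comparison"
  if (!length(counts) || sum(counts) <= 0) stop("empty comparison distribution")

  lemmas <- sort(union(names(counts), names(ref$p_ref)))
  p_comp <- stats::setNames(numeric(length(lemmas)), lemmas)
  p_comp[names(counts)] <- counts / sum(counts)
  p_ref <- stats::setNames(numeric(length(lemmas)), lemmas)
  p_ref[names(ref$p_ref)] <- ref$p_ref

  score <- lemma_score(lex, lemmas)
  C_comp <- sum(score * p_comp)
  dC <- C_comp - ref$C_ref
  if (dC == 0)
    stop("comparison and reference have equal caloric scores; shift undefined")

  delta <- 100 * (score - ref$C_ref) * (p_comp - p_ref) / abs(dC)
  keep <- delta != 0
  category <- character(sum(keep))
  ki <- which(keep)
  for (i in seq_along(ki)) {
    j <- ki[i]
    category[i] <- classify_contribution(score[j], ref$C_ref,
                                         p_comp[j], p_ref[j])
  }
  terms <- data.frame(lemma = lemmas[keep], delta = delta[keep],
                      category = category, stringsAsFactors = FALSE)
  terms <- terms[order(-abs(terms$delta), terms$lemma, method = "radix"), ]
  rownames(terms) <- NULL

  cats <- c("+up", "-down", "+down", "-up")
  category_totals <- vapply(cats, function(cc)
    sum(terms$delta[terms$category == cc]), numeric(1L))

  structure(list(side = lex$side, comparison = comparison,
                 net = sign(dC) * 100, C_comp = C_comp, C_ref = ref$C_ref,
                 category_totals = category_totals, terms = terms,
                 top = as.integer(top)),
            class = "phrase_shift")
}

#' @export
print.phrase_shift <- function(x, ...) {
  cat(sprintf("<phrase_shift side=%s '%s' vs reference: net %+d%%, C %0.2f vs %0.2f>\n",
              x$side, x$comparison, as.integer(x$net), x$C_comp, x$C_ref))
  cat("category totals (%):",
      paste(sprintf("%s %+0.2f", names(x$category_totals),
                    x$category_totals), collapse = ", "), "\n")
  n <- min(x$top, nrow(x$terms))
  print(utils::head(x$terms, n))
  if (nrow(x$terms) > n)
    cat("... and", nrow(x$terms) - n, "more terms\n")
  invisible(x)
}

#' Most distinguishing lemma of a shift
#'
#' Among lemmas used more in the comparison than in the reference (usage
#' arrow up) whose contribution is aligned with the net shift, returns the
#' one with the largest absolute contribution -- the phrase whose increased
#' usage most moves the comparison away from the reference. Returns
#' \code{NA} when no term qualifies.
#'
#' @param shift A \code{"phrase_shift"} object.
#' @return A lemma id, or \code{NA_character_}.
#' @export
distinguishing_lemma <- function(shift) {
  stopifnot(inherits(shift, "phrase_shift"))
  t <- shift$terms
  qual <- grepl("up$", t$category) & sign(t$delta) == sign(shift$net)
  if (!any(qual)) return(NA_character_)
  t <- t[qual, ]
  ord <- order(-abs(t$delta), t$lemma, method = "radix")
  t$lemma[ord[1L]]
}

#' Export a phrase shift
#'
#' Writes the shift as JSON (side, comparison, net, category totals, terms)
#' and optionally a flat TSV of terms for plotting.
#'
#' @param shift A \code{"phrase_shift"} object.
#' @param path Output path; a \code{.json} and/or \code{.tsv} suffix picks
#'   the format.
#' @param all_terms Write every term (default) or only the leading
#'   \code{shift$top}.
#' @return \code{path}, invisibly.
#' @export
write_shift <- function(shift, path, all_terms = TRUE) {
  stopifnot(inherits(shift, "phrase_shift"))
  terms <- if (all_terms) shift$terms else utils::head(shift$terms, shift$top)
  if (grepl("\\.tsv$", path)) {
    utils::write.table(terms, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    obj <- list(side = shift$side, comparison = shift$comparison,
                reference = "pooled", net = shift$net,
                category_totals = as.list(shift$category_totals),
                terms = terms)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
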