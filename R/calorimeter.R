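#' Score a region-labelled corpus for caloric input and output
#'
#' Runs the full instrument: messages are segmented into clauses,
#' corpus-level phrase statistics are built in a first pass, every clause is
#' serially partitioned in a second pass, lexicon lemmas are counted only
#' where a partition cell exactly equals a lexicon phrase, and per-region
#' caloric input, output, ratio and difference are computed.
#'
#' @param corpus A data.frame with columns \code{id}, \code{region},
#'   \code{text} (see [read_corpus()]), one row per message.
#' @param food,activity The two \code{"lexicon"} objects.
#' @param max_len Phrase length cap for the partitioner (default 5 tokens).
#' @param min_count Minimum corpus-wide lemma count to retain (default 5).
#' @param alpha Mixing weight for \code{C_diff}; mean-matched when
#'   \code{NULL}.
#' @return An object of class \code{"calorimeter"}: a list with
#'   \code{profiles} (a \code{"caloric_profiles"} data.frame),
#'   \code{counts_in}, \code{counts_out} (per-region lemma counts),
#'   \code{food}, \code{activity} (the lexicons), \code{alpha} and corpus
#'   summary counts (\code{n_messages}, \code{n_clauses},
#'   \code{n_phrases}).
#' @examples
#' fx <- make_fixture_lexicons(8, 8, seed = 7)
#' prof <- plant_usage_profiles(fx$food, fx$activity, n_regions = 3,
#'                              messages = 120, seed = 7)
#' sim <- simulate_corpus(prof, fx$food, fx$activity, seed = 7)
#' cal <- calorimeter(sim$corpus, fx$food, fx$activity, min_count = 1)
#' cal$profiles
#' @export
calorimeter <- function(corpus, food, activity, max_len = 5L,
                        min_count = 5L, alpha = NULL) {
  stopifnot(inherits(food, "lexicon"), inherits(activity, "lexicon"))
  if (food$side != "input" || activity$side != "output")
    stop("'food' must be an input-side lexicon and 'activity' output-side")
  seg <- segment_corpus(corpus)
  if (!length(seg$tokens)) stop("corpus contains no clauses after cleaning")
  stats <- phrase_stats(seg$tokens, max_len = max_len)
  part <- partition_corpus(seg$tokens, seg$region, stats = stats)
  counts_in <- count_lexicon_lemmas(part, food, min_count = min_count)
  counts_out <- count_lexicon_lemmas(part, activity, min_count = min_count)
  profiles <- caloric_profiles(counts_in, counts_out, food, activity,
                               alpha = alpha)
  structure(list(profiles = profiles,
                 counts_in = counts_in, counts_out = counts_out,
                 food = food, activity = activity,
                 alpha = attr(profiles, "alpha"),
                 n_messages = nrow(corpus),
                 n_clauses = length(seg$tokens),
                 n_phrases = nrow(stats$f)),
            class = "calorimeter")
}

#' @export
print.calorimeter <- function(x, ...) {
  cat(sprintf("<calorimeter: %d messages, %d clauses, %d regions, alpha = %.3f>\n",
              x$n_messages, x$n_clauses, nrow(x$profiles), x$alpha))
  print(utils::head(x$profiles, 10L))
  if (nrow(x$profiles) > 10L)
    cat("... and", nrow(x$profiles) - 10L, "more regions\n")
  invisible(x)
}

#' @export
summary.calorimeter <- function(object, ...) {
  p <- object$profiles
  dr_in <- dynamic_range(p$C_in)
  dr_out <- dynamic_range(p$C_out)
  rk <- rank_regions(p, "C_rat")
  cat("Caloric scoring of", nrow(p), "regions\n")
  cat(sprintf("  C_in  range %.1f-%.1f kcal/100g (ratio %.2f)\n",
              dr_in$min, dr_in$max, dr_in$ratio))
  cat(sprintf("  C_out range %.1f-%.1f kcal/h   (ratio %.2f)\n",
              dr_out$min, dr_out$max, dr_out$ratio))
  cat(sprintf("  alpha (mean-matched unless supplied) = %.3f\n", object$alpha))
  cat("  C_rat ranking (top 5):",
      paste(utils::head(rk$region, 5L), collapse = ", "), "\n")
  invisible(list(dynamic_range_in = dr_in, dynamic_range_out = dr_out,
                 ranking = rk, alpha = object$alpha))
}

#' Deviation-from-mean histogram of a caloric measure
#'
#' Horizontal bars of each region's deviation from the grand mean, ordered
#' by decreasing measure -- the standard ranking display for these indices.
#'
#' @param x A \code{"calorimeter"} object.
#' @param measure Which measure to plot (default \code{C_rat}).
#' @param ... Further arguments passed to [graphics::barplot()].
#' @return The rank table, invisibly.
#' @export
plot.calorimeter <- function(x, measure = c("C_rat", "C_in", "C_out", "C_diff"),
                             ...) {
  measure <- match.arg(measure)
  rk <- rank_regions(x$profiles, measure)
  graphics::barplot(rev(rk$deviation), names.arg = rev(rk$region),
                    horiz = TRUE, las = 1,
                    xlab = paste("deviation of", measure, "from mean"), ...)
  invisible(rk)
}

#' Phrase shift of one region against the pooled reference
#'
#' Convenience wrapper: builds the equal-weight pooled reference over all
#' regions and decomposes the chosen region's deviation from it.
#'
#' @param x A \code{"calorimeter"} object.
#' @param region Region label present in the profiles.
#' @param side \code{"input"} (food) or \code{"output"} (activity).
#' @param top Terms retained in printing.
#' @return A \code{"phrase_shift"} object.
#' @export
region_shift <- function(x, region, side = c("input", "output"), top = 23L) {
  stopifnot(inherits(x, "calorimeter"))
  side <- match.arg(side)
  counts <- if (side == "input") x$counts_in else x$counts_out
  lex <- if (side == "input") x$food else x$activity
  if (!region %in% counts$region) stop("unknown region: ", region)
  ref <- pooled_reference(counts, lex)
  phrase_shift(counts[counts$region == region, ], ref, lex,
               comparison = region, top = top)
}
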