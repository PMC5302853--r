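# Per-region caloric indices.
#
# The caloric score of a text on one side (food or activity) is the
# lexicon-score-weighted mean of its lemma usage distribution:
#   C(T) = sum_s score(s) p(s|T),   p(s|T) = f(s|T) / sum_s f(s|T).
# Caloric ratio C_rat = C_out / C_in and caloric difference
# C_diff(alpha) = alpha C_out - (1 - alpha) C_in combine the two sides.

# named count vector for one region out of a region_lemma_counts table
region_count_vector <- function(counts, region) {
  rows <- counts$region == region
  stats::setNames(counts$count[rows], counts$lemma[rows])
}

#' Score-weighted mean caloric score of a usage distribution
#'
#' @param counts Named numeric vector of lemma counts (names are lemma ids),
#'   or a \code{"region_lemma_counts"} table holding a single region.
#' @param lex The matching-side \code{"lexicon"}.
#' @return The weighted mean score: kcal/100 g for food, kcal/hour for
#'   activity.
#' @export
caloric_score <- function(counts, lex) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.data.frame(counts)) {
    if (length(unique(counts$region)) != 1L)
      stop("'counts' must hold a single region; use caloric_profiles() for many")
    counts <- stats::setNames(counts$count, counts$lemma)
  }
  if (!length(counts) || sum(counts) <= 0)
    stop("cannot score an empty usage distribution")
  if (any(counts < 0)) stop("negative lemma count")
  scores <- lemma_score(lex, names(counts))
  sum(scores * counts) / sum(counts)
}

#' Caloric ratio
#'
#' \code{C_out / C_in}. A relative, comparative index: the value 1 is not
#' salient and does not indicate caloric balance.
#'
#' @param c_in,c_out Caloric input and output scores; \code{c_in} must be
#'   positive.
#' @return The ratio.
#' @export
caloric_ratio <- function(c_in, c_out) {
  if (any(c_in <= 0)) stop("caloric input must be positive")
  c_out / c_in
}

#' Caloric difference
#'
#' \code{alpha * C_out - (1 - alpha) * C_in} with \code{alpha} in [0, 1].
#'
#' @param c_in,c_out Caloric input and output scores.
#' @param alpha Mixing weight in [0, 1].
#' @return The difference, on a kcal scale.
#' @export
caloric_difference <- function(c_in, c_out, alpha) {
  if (any(alpha < 0) || any(alpha > 1)) stop("'alpha' must lie in [0, 1]")
  alpha * c_out - (1 - alpha) * c_in
}

#' Tune alpha by matching effective means
#'
#' Chooses alpha so that the effective means of the two sides agree across
#' regions, \code{alpha * <C_out> = (1 - alpha) * <C_in>} with unweighted
#' regional means, i.e. \code{alpha = <C_in> / (<C_in> + <C_out>)}. The
#' regional mean of \code{C_diff(alpha)} is then zero.
#'
#' @param profiles A \code{"caloric_profiles"} data.frame (or any data.frame
#'   with columns \code{C_in}, \code{C_out}).
#' @return alpha in (0, 1).
#' @export
tune_alpha_mean_match <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L)
  m_in <- mean(profiles$C_in)
  m_out <- mean(profiles$C_out)
  if (!is.finite(m_in) || !is.finite(m_out) || m_in <= 0 || m_out <= 0)
    stop("mean caloric scores must be positive")
  m_in / (m_in + m_out)
}

#' Tune alpha against a target indicator
#'
#' Grid search for the alpha maximizing the absolute Spearman correlation
#' between \code{C_diff(alpha)} across regions and a target indicator
#' (e.g. diabetes rates), turning the caloric difference into an estimator
#' of that indicator. |rho| is piecewise constant in alpha, so an exact
#' grid search is deterministic; ties return the smallest alpha.
#'
#' @param profiles A \code{"caloric_profiles"} data.frame.
#' @param indicator Named numeric vector, region -> indicator value; must
#'   cover all regions in \code{profiles}.
#' @param step Grid resolution in (0, 1); default 0.001.
#' @return The selected alpha.
#' @export
tune_alpha_to_indicator <- function(profiles, indicator, step = 0.001) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) < 3L) stop("need at least 3 regions")
  if (step <= 0 || step >= 1) stop("'step' must lie in (0, 1)")
  if (is.null(names(indicator)) ||
      !all(profiles$region %in% names(indicator)))
    stop("'indicator' must be named and cover all regions")
  y <- indicator[profiles$region]
  grid <- seq(0, 1, by = step)
  objective <- vapply(grid, function(a) {
    abs(spearman_rho(caloric_difference(profiles$C_in, profiles$C_out, a),
                     y)$rho)
  }, numeric(1L))
  grid[which.max(objective)] # which.max takes the first, i.e. smallest alpha
}

#' Dominant lemma of a usage distribution
#'
#' The lemma with the largest contribution \code{score(s) * p(s|T)} to the
#' caloric score -- a function of both usage volume and caloric score. Ties
#' resolve to the lexicographically first lemma.
#'
#' @inheritParams caloric_score
#' @return A lemma id.
#' @export
dominant_lemma <- function(counts, lex) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.data.frame(counts)) counts <- stats::setNames(counts$count, counts$lemma)
  if (!length(counts)) stop("empty usage distribution")
  # argmax of score * p equals argmax of score * count (shared denominator),
  # and the latter keeps integer-count ties exact
  contrib <- lemma_score(lex, names(counts)) * counts
  ord <- order(-contrib, names(counts), method = "radix")
  names(counts)[ord[1L]]
}

#' Dynamic range of a set of caloric scores
#'
#' @param values Positive numeric vector.
#' @return A list with \code{min}, \code{max} and \code{ratio} (max/min,
#'   rounded to 2 decimals for reporting).
#' @export
dynamic_range <- function(values) {
  if (any(values <= 0)) stop("values must be positive")
  lo <- min(values); hi <- max(values)
  list(min = lo, max = hi, ratio = round(hi / lo, 2L))
}

#' Rank regions by a caloric measure
#'
#' Rank 1 is the largest value; ties share consecutive ranks in
#' lexicographic region order. Deviations from the grand mean are returned
#' alongside, ready for deviation histograms.
#'
#' @param profiles A \code{"caloric_profiles"} data.frame.
#' @param measure One of \code{"C_in"}, \code{"C_out"}, \code{"C_rat"},
#'   \code{"C_diff"}.
#' @return A data.frame with columns \code{region}, \code{value},
#'   \code{rank}, \code{deviation} (value minus grand mean), ordered by
#'   rank.
#' @export
rank_regions <- function(profiles,
                         measure = c("C_rat", "C_in", "C_out", "C_diff")) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L)
  v <- profiles[[measure]]
  ord <- order(-v, profiles$region, method = "radix")
  out <- data.frame(region = profiles$region[ord],
                    value = v[ord],
                    rank = seq_along(v),
                    deviation = v[ord] - mean(v))
  rownames(out) <- NULL
  out
}

#' Per-region caloric profiles
#'
#' Computes caloric input, output, ratio and difference for every region
#' appearing in both sides' lemma counts. Regions with no matched phrases
#' on a side are excluded with a warning (the weighted mean is undefined on
#' empty support).
#'
#' @param counts_in,counts_out \code{"region_lemma_counts"} for the food and
#'   activity side.
#' @param lex_in,lex_out The matching lexicons.
#' @param alpha Mixing weight for \code{C_diff}; when \code{NULL} (default)
#'   it is set by [tune_alpha_mean_match()] on the computed profiles.
#' @return An object of class \code{"caloric_profiles"}: a data.frame with
#'   columns \code{region}, \code{C_in}, \code{C_out}, \code{C_rat},
#'   \code{C_diff}, \code{n_in}, \code{n_out}, with the alpha used stored in
#'   attribute \code{alpha}.
#' @export
caloric_profiles <- function(counts_in, counts_out, lex_in, lex_out,
                             alpha = NULL) {
  stopifnot(inherits(lex_in, "lexicon"), inherits(lex_out, "lexicon"))
  if (lex_in$side != "input" || lex_out$side != "output")
    stop("lexicon sides do not match their arguments")
  r_in <- unique(counts_in$region)
  r_out <- unique(counts_out$region)
  regions <- sort(intersect(r_in, r_out))
  dropped <- setdiff(union(r_in, r_out), regions)
  if (length(dropped))
    warning("region(s) with no matched phrases on one side excluded: ",
            paste(dropped, collapse = ", "))
  if (!length(regions)) stop("no region has counts on both sides")

  C_in <- C_out <- n_in <- n_out <- numeric(length(regions))
  for (i in seq_along(regions)) {
    ci <- region_count_vector(counts_in, regions[i])
    co <- region_count_vector(counts_out, regions[i])
    C_in[i] <- caloric_score(ci, lex_in)
    C_out[i] <- caloric_score(co, lex_out)
    n_in[i] <- sum(ci)
    n_out[i] <- sum(co)
  }
  prof <- data.frame(region = regions, C_in = C_in, C_out = C_out,
                     C_rat = caloric_ratio(C_in, C_out),
                     C_diff = NA_real_, n_in = n_in, n_out = n_out)
  if (is.null(alpha)) alpha <- tune_alpha_mean_match(prof)
  prof$C_diff <- caloric_difference(prof$C_in, prof$C_out, alpha)
  structure(prof, alpha = alpha,
            class = c("caloric_profiles", class(prof)))
}

#' Write map/histogram-ready profiles to TSV
#'
#' Exports region, the four measures, their ranks, supporting token counts
#' and deviation-from-mean columns.
#'
#' @param profiles A \code{"caloric_profiles"} data.frame.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "caloric_profiles"))
  out <- profiles
  for (m in c("C_in", "C_out", "C_rat")) {
    rk <- rank_regions(profiles, m)
    out[[paste0("rank_", sub("C_", "", m))]] <-
      rk$rank[match(out$region, rk$region)]
    out[[paste0("dev_", sub("C_", "", m))]] <-
      rk$deviation[match(out$region, rk$region)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
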