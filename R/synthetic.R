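# Synthetic fixtures: lexicons, region-labelled corpora with planted
# phrase-usage multinomials, and indicator tables with planted monotone
# links. Everything is driven by one explicit seed; filler vocabulary is
# disjoint from lexicon tokens by construction (except explicit decoys), so
# pipeline lemma counts can be compared to the generator's ground truth
# exactly.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a named substream seed below 2^31 from a base seed
substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

#' Generate fixture food and activity lexicons
#'
#' Food scores are drawn uniformly on [20, 600] kcal per 100 g and activity
#' METs on [0.95, 14], the realistic ranges of nutrient databases and the
#' physical-activity compendium. Both sides include multi-token phrases of
#' 2-4 tokens. The food lexicon always contains the single-token phrase
#' \code{"apple"}, and the returned object names a decoy idiom
#' (\code{"apple of my eye"}) that shares that token but is NOT a lexicon
#' entry; planting the decoy in a corpus must not inflate the
#' \code{"apple"} lemma count.
#'
#' @param n_food,n_activity Number of entries per side (>= 2).
#' @param seed Integer seed; the same seed reproduces the lexicons exactly.
#' @param body_mass_kg Reference mass for the activity side.
#' @return A list with elements \code{food} and \code{activity} (both
#'   \code{"lexicon"} objects) and \code{decoy} (the idiom string).
#' @export
make_fixture_lexicons <- function(n_food = 30L, n_activity = 30L, seed = 1L,
                                  body_mass_kg = 80.7) {
  if (n_food < 2L || n_activity < 2L) stop("need at least 2 entries per side")
  with_seed(substream(seed, "lexicons"), {
    make_side <- function(n, prefix, lo, hi, fixed) {
      if (nrow(fixed) > n) fixed <- fixed[seq_len(n), , drop = FALSE]
      # tokens are disjoint across phrases, so a phrase's identity is never
      # confounded with another entry's tokens
      pool <- sample(sprintf("%s%03d", prefix, seq_len(5L * n + 40L)))
      rows <- fixed
      next_tok <- 1L
      while (nrow(rows) < n) {
        k <- sample(1:4, 1L, prob = c(0.55, 0.25, 0.12, 0.08))
        ph <- paste(pool[next_tok:(next_tok + k - 1L)], collapse = " ")
        next_tok <- next_tok + k
        rows <- rbind(rows, data.frame(
          phrase = ph,
          lemma = sprintf("%s_L%03d", toupper(prefix), nrow(rows) + 1L),
          score = round(stats::runif(1L, lo, hi), 2L),
          stringsAsFactors = FALSE))
      }
      rows
    }
    food_fixed <- data.frame(
      phrase = c("apple", "pizza"),
      lemma = c("FOOD_APPLE", "FOOD_PIZZA"),
      score = c(52, 266), stringsAsFactors = FALSE)
    act_fixed <- data.frame(
      phrase = c("running", "watching tv"),
      lemma = c("ACT_RUN", "ACT_TV"),
      score = c(8.0, 1.0), stringsAsFactors = FALSE)
    food <- lexicon(make_side(n_food, "food", 20, 600, food_fixed),
                    side = "input")
    activity <- lexicon(make_side(n_activity, "act", 0.95, 14, act_fixed),
                        side = "output", body_mass_kg = body_mass_kg)
    list(food = food, activity = activity, decoy = "apple of my eye")
  })
}

#' Plant per-region usage profiles
#'
#' Builds one usage multinomial per region and side, with a caloric
#' gradient planted across regions: region r's lemma weights are
#' proportional to \code{exp(beta_r * z(score))} where \code{z} is the
#' standardized lemma score and \code{beta_r} runs linearly from
#' \code{-spread} to \code{+spread}. Later regions therefore favour
#' higher-calorie lemmas, giving a known ordering of planted mean caloric
#' scores.
#'
#' @param food,activity The two \code{"lexicon"} objects.
#' @param n_regions Number of regions.
#' @param messages Messages per region.
#' @param spread Gradient strength (0 = identical regions); default 1.
#' @param filler_tokens Filler tokens per message (default 4).
#' @param seed Integer seed.
#' @return A list of per-region profiles; each has \code{region},
#'   \code{messages}, \code{filler_tokens}, \code{p_in}, \code{p_out}
#'   (named multinomials over lemmas) and \code{true_C_in},
#'   \code{true_C_out} (planted mean caloric scores).
#' @export
plant_usage_profiles <- function(food, activity, n_regions = 10L,
                                 messages = 1000L, spread = 1,
                                 filler_tokens = 4L, seed = 1L) {
  stopifnot(inherits(food, "lexicon"), inherits(activity, "lexicon"),
            n_regions >= 1L, messages >= 1L)
  beta <- if (n_regions == 1L) 0 else
    seq(-spread, spread, length.out = n_regions)
  mk_p <- function(lex, b) {
    sc <- lex$scores
    z <- if (stats::sd(sc) > 0) (sc - mean(sc)) / stats::sd(sc) else sc * 0
    w <- exp(b * z)
    w / sum(w)
  }
  lapply(seq_len(n_regions), function(r) {
    p_in <- mk_p(food, beta[r])
    p_out <- mk_p(activity, beta[r])
    list(region = sprintf("R%02d", r), messages = as.integer(messages),
         filler_tokens = as.integer(filler_tokens),
         p_in = p_in, p_out = p_out,
         true_C_in = sum(food$scores * p_in),
         true_C_out = sum(activity$scores * p_out))
  })
}

#' Simulate a region-labelled corpus with planted phrase usage
#'
#' Each message carries a filler clause (tokens from a vocabulary disjoint
#' from all lexicon tokens) plus one food phrase and one activity phrase
#' sampled from the region's planted multinomials, each set off by sentence
#' punctuation as its own clause -- the short-burst style of social-media
#' mentions. A decoy idiom can be planted at a given per-message rate; its
#' tokens never appear in lexicon entries other than the shared head word.
#'
#' Multiword expressions only cohere under serial partitioning when their
#' prefixes occur with varied continuations (otherwise the prefix is already
#' maximally likely in its contexts and strict-growth segmentation splits
#' the phrase). Natural text supplies that variation; the generator plants a
#' minimal amount of it by following a multi-token phrase, occasionally,
#' with a "false start" clause -- the phrase's prefix plus a junk token --
#' at rates 0.3, 0.1 and 0.05 for prefix lengths 1, 2 and 3. These rates
#' make the context-local likelihood strictly increasing along every
#' planted phrase, so each emission is recovered as exactly one cell and
#' pipeline counts can be compared with the generator's truth exactly.
#' False-start junk tokens belong to no lexicon entry.
#'
#' @param profiles Output of [plant_usage_profiles()].
#' @param food,activity The \code{"lexicon"} objects the profiles refer to.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param filler_vocab Size of the filler vocabulary (default 300).
#' @param decoy Optional decoy idiom string (e.g. from
#'   [make_fixture_lexicons()]).
#' @param decoy_rate Per-message probability of appending the decoy clause.
#' @return A list with \code{corpus} (data.frame \code{id}, \code{region},
#'   \code{text}) and \code{truth}: ground-truth per-region lemma counts
#'   \code{counts_in}, \code{counts_out} (data.frames region, lemma,
#'   count) and \code{n_decoy} per region.
#' @export
simulate_corpus <- function(profiles, food, activity, seed = 1L,
                            filler_vocab = 300L, decoy = NULL,
                            decoy_rate = 0) {
  stopifnot(inherits(food, "lexicon"), inherits(activity, "lexicon"))
  bad_in <- setdiff(unlist(lapply(profiles, function(p) names(p$p_in))),
                    names(food$scores))
  bad_out <- setdiff(unlist(lapply(profiles, function(p) names(p$p_out))),
                     names(activity$scores))
  if (length(bad_in) || length(bad_out))
    stop("profile references unknown lemma(s): ",
         paste(c(bad_in, bad_out), collapse = ", "))

  # one representative phrase per lemma (the first in the entry table)
  lemma_phrase <- function(lex) {
    e <- lex$entries
    stats::setNames(e$phrase[!duplicated(e$lemma)],
                    e$lemma[!duplicated(e$lemma)])
  }
  ph_in <- lemma_phrase(food)
  ph_out <- lemma_phrase(activity)
  filler <- sprintf("zz%04d", seq_len(filler_vocab))

  # per-lemma prefix strings (with a per-phrase junk continuation token)
  # used for the false-start clauses that keep multiword phrases coherent
  FALSE_START_RATE <- c(0.3, 0.1, 0.05)
  prefix_table <- function(phrases, tag) {
    lapply(seq_along(phrases), function(i) {
      toks <- strsplit(phrases[[i]], " ", fixed = TRUE)[[1L]]
      k <- length(toks)
      if (k < 2L) return(character(0L))
      vapply(seq_len(k - 1L), function(j)
        paste(c(toks[seq_len(j)], sprintf("xq%s%03dj%d", tag, i, j)),
              collapse = " "), character(1L))
    })
  }
  pre_in <- prefix_table(ph_in, "f")
  names(pre_in) <- names(ph_in)
  pre_out <- prefix_table(ph_out, "a")
  names(pre_out) <- names(ph_out)

  false_starts <- function(draws, pre) {
    out <- rep("", length(draws))
    k1 <- lengths(pre[draws]) # prefixes available = phrase length - 1
    for (j in seq_along(FALSE_START_RATE)) {
      hit <- k1 >= j & stats::runif(length(draws)) < FALSE_START_RATE[j]
      if (any(hit))
        out[hit] <- paste0(out[hit], " ",
                           vapply(pre[draws[hit]], `[[`, "", j), ".")
    }
    out
  }

  with_seed(substream(seed, "corpus"), {
    msgs <- list(); regions <- list(); ids <- list()
    counts_in <- list(); counts_out <- list(); n_decoy <- integer(0L)
    for (pi in seq_along(profiles)) {
      pr <- profiles[[pi]]
      m <- pr$messages
      draw_in <- sample(names(pr$p_in), m, replace = TRUE, prob = pr$p_in)
      draw_out <- sample(names(pr$p_out), m, replace = TRUE, prob = pr$p_out)
      fill <- matrix(sample(filler, m * pr$filler_tokens, replace = TRUE),
                     nrow = m)
      fill_txt <- do.call(paste, as.data.frame(fill, stringsAsFactors = FALSE))
      has_decoy <- if (!is.null(decoy) && decoy_rate > 0)
        stats::runif(m) < decoy_rate else rep(FALSE, m)
      txt <- paste0(fill_txt, ". ", ph_in[draw_in], ". ", ph_out[draw_out], ".",
                    false_starts(draw_in, pre_in),
                    false_starts(draw_out, pre_out),
                    ifelse(has_decoy, paste0(" ", decoy, "."), ""))
      msgs[[pi]] <- txt
      regions[[pi]] <- rep(pr$region, m)
      ids[[pi]] <- sprintf("%s-%06d", pr$region, seq_len(m))
      ti <- table(draw_in); to <- table(draw_out)
      counts_in[[pi]] <- data.frame(region = pr$region,
                                    lemma = names(ti),
                                    count = as.numeric(ti),
                                    stringsAsFactors = FALSE)
      counts_out[[pi]] <- data.frame(region = pr$region,
                                     lemma = names(to),
                                     count = as.numeric(to),
                                     stringsAsFactors = FALSE)
      n_decoy <- c(n_decoy, sum(has_decoy))
    }
    corpus <- data.frame(id = unlist(ids), region = unlist(regions),
                         text = unlist(msgs), stringsAsFactors = FALSE)
    truth <- list(counts_in = do.call(rbind, counts_in),
                  counts_out = do.call(rbind, counts_out),
                  n_decoy = stats::setNames(
                    n_decoy, vapply(profiles, `[[`, "", "region")))
    list(corpus = corpus, truth = truth)
  })
}

#' Simulate an indicator table with planted links
#'
#' Linked indicators are \code{slope * measure + Normal(0, noise_sd)}
#' across regions; \code{n_null} additional columns are independent
#' standard normals, for false-discovery-rate calibration.
#'
#' @param profiles A \code{"caloric_profiles"} data.frame.
#' @param links A data.frame with columns \code{indicator}, \code{measure}
#'   (one of \code{C_in}, \code{C_out}, \code{C_rat}, \code{C_diff}),
#'   \code{slope}, \code{noise_sd}; may have zero rows.
#' @param n_null Number of null indicator columns.
#' @param seed Integer seed.
#' @return A data.frame with a \code{region} column and one column per
#'   indicator.
#' @export
simulate_indicators <- function(profiles, links = NULL, n_null = 0L,
                                seed = 1L) {
  stopifnot(is.data.frame(profiles))
  n <- nrow(profiles)
  out <- data.frame(region = profiles$region, stringsAsFactors = FALSE)
  with_seed(substream(seed, "indicators"), {
    if (!is.null(links) && nrow(links)) {
      stopifnot(all(c("indicator", "measure", "slope", "noise_sd")
                    %in% names(links)))
      for (i in seq_len(nrow(links))) {
        m <- links$measure[i]
        if (!m %in% names(profiles)) stop("unknown measure: ", m)
        if (links$noise_sd[i] < 0) stop("noise_sd must be >= 0")
        out[[links$indicator[i]]] <-
          links$slope[i] * profiles[[m]] +
          stats::rnorm(n, 0, links$noise_sd[i])
      }
    }
    if (n_null > 0L) {
      for (j in seq_len(n_null))
        out[[sprintf("null%03d", j)]] <- stats::rnorm(n)
    }
    out
  })
}

#' Write a corpus as JSON Lines
#'
#' One object per line: \code{{"id": ..., "region": ..., "text": ...}}.
#'
#' @param corpus A data.frame with columns \code{id}, \code{region},
#'   \code{text}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(is.data.frame(corpus),
            all(c("id", "region", "text") %in% names(corpus)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(corpus[, c("id", "region", "text")], con,
                       verbose = FALSE)
  invisible(path)
}

#' Read a JSON Lines corpus
#'
#' @param path Path to a JSONL file of \code{{id, region, text}} records.
#' @return A data.frame with columns \code{id}, \code{region}, \code{text}.
#' @export
read_corpus <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  out <- jsonlite::stream_in(con, verbose = FALSE)
  missing_cols <- setdiff(c("id", "region", "text"), names(out))
  if (length(missing_cols))
    stop("corpus records lack field(s): ",
         paste(missing_cols, collapse = ", "))
  out
}
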