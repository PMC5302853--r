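#' Convert a MET value to kilocalories per hour
#'
#' A MET (Metabolic Equivalent of Task) is a multiple of the resting
#' metabolic rate; 1 MET is defined as 1 kcal per kg of body mass per hour,
#' so at a reference mass of \code{body_mass_kg} kilograms an activity of
#' intensity \code{met} expends \code{met * body_mass_kg} kcal per hour.
#' The default reference mass of 80.7 kg is the average adult weight used
#' when scoring activity lexicons.
#'
#' @param met Positive numeric, activity intensity in METs.
#' @param body_mass_kg Positive numeric, reference body mass in kilograms.
#' @return Numeric, kilocalories expended per hour.
#' @examples
#' met_to_kcal_per_hour(1.0)          # 80.7
#' met_to_kcal_per_hour(8.0, 100)     # 800
#' @export
met_to_kcal_per_hour <- function(met, body_mass_kg = 80.7) {
  if (!is.numeric(met) || any(!is.finite(met)) || any(met <= 0))
    stop("'met' must be positive and finite")
  if (!is.numeric(body_mass_kg) || length(body_mass_kg) != 1L ||
      !is.finite(body_mass_kg) || body_mass_kg <= 0)
    stop("'body_mass_kg' must be a single positive number")
  met * body_mass_kg
}

#' Construct a caloric phrase lexicon
#'
#' A lexicon maps phrases (sequences of lowercase tokens) to lemmas, and
#' lemmas to a caloric score. Food ("input") lexicons carry kcal per 100 g;
#' activity ("output") lexicons carry METs, which are converted to kcal per
#' hour at the reference body mass. All phrases sharing a lemma must carry
#' the same raw score, since a lemma is by definition a group of phrases with
#' one caloric value.
#'
#' @param entries A data.frame with columns \code{phrase}, \code{lemma},
#'   \code{score}. Phrases are token-normalized (lowercased, punctuation
#'   stripped) on construction.
#' @param side Either \code{"input"} (food) or \code{"output"} (activity).
#' @param body_mass_kg Reference body mass used to convert METs for
#'   \code{side = "output"}; ignored for food lexicons.
#' @return An object of class \code{"lexicon"}: a list with elements
#'   \code{side}, \code{entries} (normalized data.frame), \code{body_mass_kg}
#'   and \code{scores} (named numeric vector, lemma -> caloric score).
#' @seealso [read_lexicon()], [lemma_score()]
#' @export
lexicon <- function(entries, side = c("input", "output"), body_mass_kg = 80.7) {
  side <- match.arg(side)
  required <- c("phrase", "lemma", "score")
  if (!is.data.frame(entries) || !all(required %in% names(entries)))
    stop("'entries' must be a data.frame with columns phrase, lemma, score")
  if (nrow(entries) == 0L) stop("lexicon has no entries")

  phrase <- vapply(entries$phrase, function(p)
    paste(normalize_tokens(tokenize(p)), collapse = " "), character(1L),
    USE.NAMES = FALSE)
  lemma <- as.character(entries$lemma)
  score <- as.numeric(entries$score)

  if (any(!nzchar(phrase))) stop("lexicon contains an empty phrase")
  if (anyDuplicated(phrase))
    stop("duplicate phrase within lexicon side: ",
         paste(unique(phrase[duplicated(phrase)]), collapse = ", "))
  if (any(!is.finite(score)) || any(score < 0))
    stop("lexicon scores must be finite and nonnegative")
  if (side == "output" && any(score == 0))
    stop("activity entries must have MET > 0")

  # one score per lemma: phrases in a lemma are categorically equivalent
  by_lemma <- split(score, lemma)
  bad <- names(by_lemma)[vapply(by_lemma, function(s)
    length(unique(s)) > 1L, logical(1L))]
  if (length(bad))
    stop("inconsistent scores within lemma(s): ", paste(bad, collapse = ", "))

  raw <- vapply(by_lemma, `[[`, numeric(1L), 1L)
  scores <- if (side == "output") met_to_kcal_per_hour(raw, body_mass_kg) else raw

  structure(
    list(side = side,
         entries = data.frame(phrase = phrase, lemma = lemma, score = score,
                              stringsAsFactors = FALSE),
         body_mass_kg = body_mass_kg,
         scores = scores),
    class = "lexicon")
}

#' Read a lexicon from a TSV file
#'
#' Expects a UTF-8 tab-separated file with header columns
#' \code{phrase}, \code{lemma}, \code{score}.
#'
#' @param path Path to the TSV file.
#' @inheritParams lexicon
#' @return A \code{"lexicon"} object.
#' @export
read_lexicon <- function(path, side = c("input", "output"),
                         body_mass_kg = 80.7) {
  side <- match.arg(side)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(c("phrase", "lemma", "score"), names(tab))
  if (length(missing_cols))
    stop("lexicon file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  lexicon(tab, side = side, body_mass_kg = body_mass_kg)
}

#' Write a lexicon to a TSV file
#'
#' Writes the raw entries (phrase, lemma, score); reading the file back with
#' [read_lexicon()] reproduces the lexicon.
#'
#' @param x A \code{"lexicon"} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(x, path) {
  stopifnot(inherits(x, "lexicon"))
  utils::write.table(x$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Caloric score of a lemma
#'
#' Food lemmas score kcal per 100 g; activity lemmas score kcal per hour at
#' the lexicon's reference body mass.
#'
#' @param x A \code{"lexicon"} object.
#' @param lemma_id Character vector of lemma identifiers.
#' @return Numeric vector of caloric scores.
#' @export
lemma_score <- function(x, lemma_id) {
  stopifnot(inherits(x, "lexicon"))
  unknown <- setdiff(lemma_id, names(x$scores))
  if (length(unknown))
    stop("unknown lemma(s): ", paste(unknown, collapse = ", "))
  unname(x$scores[lemma_id])
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon side=%s: %d phrases, %d lemmas, scores %s>\n",
              x$side, nrow(x$entries), length(x$scores),
              if (x$side == "input") "kcal/100g"
              else sprintf("kcal/h @ %.1f kg", x$body_mass_kg)))
  invisible(x)
}
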