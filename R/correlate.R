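# Correlation of caloric measures against indicator tables.
#
# Spearman's rank correlation (Pearson correlation of average ranks, ties
# averaged) with a two-sided p-value from the t-approximation on n - 2
# degrees of freedom, and Benjamini-Hochberg step-up q-values across the
# whole family of measure x indicator tests.

#' Spearman rank correlation with t-approximation p-value
#'
#' @param x,y Paired numeric vectors (n >= 3), aligned on region.
#' @return A list with \code{rho}, \code{p} (two-sided) and \code{n}.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Pearson correlation with least-squares fit
#'
#' @param x,y Paired numeric vectors (n >= 3); \code{x} must not be
#'   constant.
#' @return A list with \code{rho}, \code{slope}, \code{intercept} and
#'   \code{n}.
#' @export
pearson_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L) stop("'x' is constant; fit undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(rho = stats::cor(x, y),
       slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       n = n)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts a family of p-values by the step-up procedure controlling the
#' false discovery rate; a q-value is read like a p-value.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Read an indicator table from TSV
#'
#' Expects a header row with a \code{region} column followed by one numeric
#' column per indicator.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with a \code{region} column and numeric indicator
#'   columns.
#' @export
read_indicators <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"region" %in% names(tab)) stop("indicator table needs a 'region' column")
  for (nm in setdiff(names(tab), "region")) {
    if (!is.numeric(tab[[nm]]))
      stop("non-numeric indicator column: ", nm)
  }
  tab
}

#' Correlation table of caloric measures against indicators
#'
#' Computes Spearman correlations between every requested caloric measure
#' and every indicator, adjusts all tests as a single Benjamini-Hochberg
#' family (optionally per measure), and sorts indicators by ascending
#' q-value for the caloric ratio (or the first requested measure). Regions
#' with missing indicator cells are dropped pairwise per indicator.
#'
#' @param profiles A \code{"caloric_profiles"} data.frame.
#' @param indicators A data.frame with a \code{region} column and numeric
#'   indicator columns (see [read_indicators()]).
#' @param measures Caloric measures to test (default \code{C_in},
#'   \code{C_out}, \code{C_rat}).
#' @param family \code{"all"} (one BH family across every measure x
#'   indicator test, the default) or \code{"per_measure"}.
#' @return An object of class \code{"correlation_table"}: a data.frame with
#'   one row per indicator and, per measure, columns \code{rho_<m>},
#'   \code{p_<m>}, \code{q_<m>}, \code{n_<m>}, plus a \code{signif} band
#'   marker (\code{"**"} q < 0.01, \code{"*"} q < 0.05) on the sorting
#'   measure.
#' @export
correlation_table <- function(profiles, indicators,
                              measures = c("C_in", "C_out", "C_rat"),
                              family = c("all", "per_measure")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(profiles), is.data.frame(indicators),
            "region" %in% names(indicators))
  measures <- match.arg(measures, c("C_in", "C_out", "C_rat", "C_diff"),
                        several.ok = TRUE)
  ind_names <- setdiff(names(indicators), "region")
  if (!length(ind_names)) stop("no indicator columns")
  common <- intersect(profiles$region, indicators$region)
  if (length(common) < 3L) stop("fewer than 3 regions shared with indicators")

  rows <- expand.grid(indicator = ind_names, measure = measures,
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    x <- profiles[[rows$measure[i]]][match(common, profiles$region)]
    y <- indicators[[rows$indicator[i]]][match(common, indicators$region)]
    s <- spearman_rho(x, y)
    res[[i]] <- c(rho = s$rho, p = s$p, n = s$n)
  }
  res <- do.call(rbind, res)
  rows$rho <- res[, "rho"]; rows$p <- res[, "p"]; rows$n <- res[, "n"]
  if (family == "all") {
    rows$q <- bh_qvalues(rows$p)
  } else {
    rows$q <- NA_real_
    for (m in measures) {
      sel <- rows$measure == m
      rows$q[sel] <- bh_qvalues(rows$p[sel])
    }
  }

  # wide layout, one row per indicator
  out <- data.frame(indicator = ind_names, stringsAsFactors = FALSE)
  for (m in measures) {
    sel <- rows$measure == m
    idx <- match(out$indicator, rows$indicator[sel])
    out[[paste0("rho_", m)]] <- rows$rho[sel][idx]
    out[[paste0("p_", m)]] <- rows$p[sel][idx]
    out[[paste0("q_", m)]] <- rows$q[sel][idx]
    out[[paste0("n_", m)]] <- rows$n[sel][idx]
  }
  sort_m <- if ("C_rat" %in% measures) "C_rat" else measures[1L]
  qcol <- out[[paste0("q_", sort_m)]]
  out <- out[order(qcol, out$indicator, method = "radix"), ]
  qcol <- out[[paste0("q_", sort_m)]]
  out$signif <- ifelse(qcol < 0.01, "**", ifelse(qcol < 0.05, "*", ""))
  rownames(out) <- NULL
  structure(out, n_tests = nrow(rows), family = family,
            sort_measure = sort_m,
            class = c("correlation_table", class(out)))
}

#' Write a correlation table to TSV
#'
#' @param x A \code{"correlation_table"}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_correlation_table <- function(x, path) {
  stopifnot(inherits(x, "correlation_table"))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
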