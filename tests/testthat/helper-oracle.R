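# Independent oracles and small fixture builders used across the suite.

# Exact random-partition frequencies by brute force: enumerate all 2^(L-1)
# boundary configurations of each clause (edges always boundaries), count
# the cells each configuration produces, and average with equal weight.
# Completely independent of the weight-formula implementation.
brute_force_f <- function(clauses, max_len = Inf) {
  acc <- new.env(parent = emptyenv())
  add <- function(key, v) {
    assign(key, v + (if (exists(key, acc, inherits = FALSE))
      get(key, acc) else 0), acc)
  }
  for (cl in clauses) {
    L <- length(cl)
    n_cfg <- 2^(max(L - 1, 0))
    for (cfg in seq_len(n_cfg) - 1L) {
      gaps <- if (L > 1) as.logical(bitwAnd(cfg, 2^(seq_len(L - 1) - 1)) > 0)
      else logical(0)
      bounds <- c(0L, which(gaps), L)
      for (b in seq_len(length(bounds) - 1L)) {
        cell <- cl[(bounds[b] + 1L):bounds[b + 1L]]
        if (length(cell) <= max_len)
          add(paste(cell, collapse = " "), 1 / n_cfg)
      }
    }
  }
  vals <- mget(ls(acc), envir = acc)
  unlist(vals)
}

# step-up BH adjustment written out longhand (cross-check for bh_qvalues)
bh_longhand <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

random_clause <- function(len, vocab = letters[1:6]) {
  sample(vocab, len, replace = TRUE)
}

# two-lemma worked fixture: scores a=100, b=300
tiny_lexicon <- function(side = "input") {
  lexicon(data.frame(phrase = c("aa", "bb"),
                     lemma = c("a", "b"),
                     score = c(100, 300)),
          side = "input")
}

counts_df <- function(region, lemma, count) {
  structure(data.frame(region = region, lemma = lemma, count = count,
                       stringsAsFactors = FALSE),
            side = "input",
            class = c("region_lemma_counts", "data.frame"))
}

# profiles table with given C_in / C_out vectors
profiles_df <- function(C_in, C_out, alpha = 0.5,
                        region = sprintf("R%02d", seq_along(C_in))) {
  structure(data.frame(region = region, C_in = C_in, C_out = C_out,
                       C_rat = C_out / C_in,
                       C_diff = alpha * C_out - (1 - alpha) * C_in,
                       n_in = 100, n_out = 100),
            alpha = alpha,
            class = c("caloric_profiles", "data.frame"))
}
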