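test_that("clause segmentation lowercases, strips noise and splits on punctuation", {
  expect_equal(segment_clauses("I LOVE Pizza"), list(c("i", "love", "pizza")))
  expect_equal(segment_clauses("Eating #pizza with @bob at http://x.co"),
               list(c("eating", "with", "at")))
  expect_equal(segment_clauses("pizza. running"),
               list("pizza", "running"))
  expect_equal(segment_clauses("went running! then... pizza?"),
               list(c("went", "running"), "then", "pizza"))
  expect_equal(segment_clauses("@only #tags http://x.co"), list())
  expect_equal(segment_clauses(""), list())
})

test_that("random-partition frequencies match hand-enumerated values", {
  st1 <- phrase_stats(list("a"))
  expect_equal(phrase_frequency(st1, "a"), 1)

  st <- phrase_stats(list(c("a", "b", "c")))
  expect_equal(phrase_frequency(st, "a"), 0.5)
  expect_equal(phrase_frequency(st, "b"), 0.25)
  expect_equal(phrase_frequency(st, "c"), 0.5)
  expect_equal(phrase_frequency(st, c("a", "b")), 0.25)
  expect_equal(phrase_frequency(st, c("b", "c")), 0.25)
  expect_equal(phrase_frequency(st, c("a", "b", "c")), 0.25)
  expect_equal(phrase_frequency(st, "zzz"), 0)

  st4 <- phrase_stats(rep(list(c("new", "york", "city")), 4))
  expect_equal(phrase_frequency(st4, "new"), 2)
  expect_equal(phrase_frequency(st4, "york"), 1)
  expect_equal(phrase_frequency(st4, "city"), 2)
  expect_equal(phrase_frequency(st4, c("new", "york")), 1)
  expect_equal(phrase_frequency(st4, c("york", "city")), 1)
  expect_equal(phrase_frequency(st4, c("new", "york", "city")), 1)
})

test_that("frequencies equal the brute-force enumeration oracle", {
  set.seed(11)
  clauses <- lapply(sample(1:8, 20, replace = TRUE), random_clause)
  st <- phrase_stats(clauses, max_len = 5)
  oracle <- brute_force_f(clauses, max_len = 5)
  got <- stats::setNames(st$f$f, st$f$phrase)
  expect_setequal(names(got), names(oracle))
  expect_equal(got[order(names(got))], oracle[order(names(oracle))],
               tolerance = 1e-12)
})

test_that("a phrase of length l has exactly l one-wildcard contexts", {
  ctx <- phrase_contexts(c("new", "york", "city"))
  expect_length(ctx, 3L)
  expect_setequal(ctx, c("★ york city", "new ★ city", "new york ★"))
  expect_equal(phrase_contexts("a"), "★")
  expect_equal(phrase_contexts(c("a", "b")), c("★ b", "a ★"))
  expect_error(phrase_contexts(character(0)), "empty")
})

test_that("local likelihood follows the context-minimum definition", {
  st <- phrase_stats(rep(list(c("new", "york", "city")), 4))
  expect_equal(local_likelihood(st, character(0)), 0)
  expect_equal(local_likelihood(st, "new"), 2 / 5) # unigram pool 2+1+2
  expect_equal(local_likelihood(st, c("new", "york")), 1)
  expect_equal(local_likelihood(st, c("new", "york", "city")), 1)
  expect_equal(local_likelihood(st, "absent"), 0)
  expect_equal(local_likelihood(st, letters[1:9]), 0) # beyond max_len
})

test_that("L stays in [0,1] and is 1 only for sole context members", {
  set.seed(23)
  for (rep in 1:5) {
    clauses <- lapply(sample(2:7, 12, replace = TRUE), random_clause)
    st <- phrase_stats(clauses)
    expect_true(all(st$L$L > 0 & st$L$L <= 1))
    # phrases with L == 1 must be the unique member of each of their contexts
    ones <- st$L$phrase[st$L$L == 1]
    for (ph in ones) {
      toks <- strsplit(ph, " ", fixed = TRUE)[[1]]
      for (ctx in phrase_contexts(toks)) {
        tot <- st$contexts$total[st$contexts$pattern == ctx]
        expect_equal(tot, phrase_frequency(st, toks))
      }
    }
  }
})

test_that("serial partition follows the greedy hand trace and is lossless", {
  st <- phrase_stats(rep(list(c("new", "york", "city")), 4))
  expect_equal(serial_partition(c("new", "york", "city"), st),
               list(c("new", "york"), "city"))
  expect_equal(serial_partition("new", st), list("new"))

  # growth requires a STRICT increase: when no extension raises L, every
  # token is its own cell ("q" dominates the unigram pool; "q r" shares
  # both its contexts with other bigrams)
  st_flat <- phrase_stats(c(rep(list("q"), 60),
                            list(c("q", "r"), c("q", "s"), c("t", "r"), "r")))
  expect_gt(local_likelihood(st_flat, "q"),
            local_likelihood(st_flat, c("q", "r")))
  expect_equal(serial_partition(c("q", "r"), st_flat), list("q", "r"))

  # conservation: cells concatenate to the clause, token for token
  set.seed(31)
  clauses <- lapply(sample(1:9, 25, replace = TRUE), random_clause)
  st2 <- phrase_stats(clauses)
  for (cl in clauses) {
    cells <- serial_partition(cl, st2)
    expect_equal(unlist(cells), cl)
  }
})

test_that("batch partitioner agrees with the per-clause partitioner", {
  set.seed(47)
  clauses <- lapply(sample(1:9, 40, replace = TRUE),
                    random_clause, vocab = letters[1:4])
  st <- phrase_stats(clauses)
  part <- partition_corpus(clauses, region = "x", stats = st)
  for (i in seq_along(clauses)) {
    got <- part$phrase[part$clause_id == i]
    want <- vapply(serial_partition(clauses[[i]], st),
                   paste, character(1), collapse = " ")
    expect_equal(got, want)
  }
})

test_that("adding an unrelated clause never changes f of untouched phrases", {
  base <- list(c("a", "b"), c("b", "c", "a"))
  st0 <- phrase_stats(base)
  st1 <- phrase_stats(c(base, list(c("x", "y", "z"))))
  for (ph in st0$f$phrase) {
    toks <- strsplit(ph, " ", fixed = TRUE)[[1]]
    expect_equal(phrase_frequency(st1, toks), phrase_frequency(st0, toks))
  }
})

test_that("lemma counting matches exact cells only and applies min_count", {
  lx <- lexicon(data.frame(phrase = c("apple", "pizza"),
                           lemma = c("F_APPLE", "F_PIZZA"),
                           score = c(52, 266)), side = "input")
  cells <- data.frame(
    region = c("A", "A", "A", "B"),
    phrase = c("apple", "apple of my eye", "pizza", "pizza"))
  counts <- count_lexicon_lemmas(cells, lx, min_count = 1)
  cv <- stats::setNames(counts$count, paste(counts$region, counts$lemma))
  expect_equal(cv[["A F_APPLE"]], 1) # the idiom cell does not count
  expect_equal(cv[["A F_PIZZA"]], 1)
  expect_equal(cv[["B F_PIZZA"]], 1)

  # corpus-wide threshold: apple (1 occurrence) dropped at min_count = 2
  counts2 <- count_lexicon_lemmas(cells, lx, min_count = 2)
  expect_false("F_APPLE" %in% counts2$lemma)
  expect_true("F_PIZZA" %in% counts2$lemma)
})
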