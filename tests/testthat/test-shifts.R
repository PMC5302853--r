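lexs <- lexicon(data.frame(phrase = c("aa", "bb"),
                           lemma = c("a", "b"),
                           score = c(100, 300)), side = "input")

test_that("pooled reference averages per-region distributions equally", {
  one <- counts_df("A", c("a", "b"), c(1, 3))
  ref1 <- pooled_reference(one, lexs)
  expect_equal(ref1$p_ref, c(a = 0.25, b = 0.75))
  expect_equal(ref1$C_ref, 250)

  two <- counts_df(c("A", "B"), c("a", "b"), c(5, 7)) # p = (1,0) and (0,1)
  ref2 <- pooled_reference(two, lexs)
  expect_equal(ref2$p_ref, c(a = 0.5, b = 0.5))

  three <- counts_df(c("A", "A", "B", "B", "C", "C"),
                     rep(c("a", "b"), 3),
                     c(2, 8, 5, 5, 8, 2)) # p(a) = 0.2, 0.5, 0.8
  expect_equal(pooled_reference(three, lexs)$p_ref[["a"]], 0.5)
})

test_that("the worked two-lemma shift decomposes as calculated by hand", {
  # reference p = (0.5, 0.5) so C_ref = 200; comparison p = (0.25, 0.75)
  # so C_comp = 250; delta(a) = +50 (-down), delta(b) = +50 (+up)
  ref <- pooled_reference(counts_df(c("A", "B"), c("a", "b"), c(1, 1)), lexs)
  expect_equal(ref$C_ref, 200)
  sh <- phrase_shift(c(a = 1, b = 3), ref, lexs, comparison = "X")
  expect_equal(sh$net, 100)
  expect_equal(sh$C_comp, 250)
  d <- stats::setNames(sh$terms$delta, sh$terms$lemma)
  expect_equal(d[["a"]], 50)
  expect_equal(d[["b"]], 50)
  ct <- sh$terms$category
  expect_equal(sh$terms$category[sh$terms$lemma == "a"], "-down")
  expect_equal(sh$terms$category[sh$terms$lemma == "b"], "+up")
  expect_equal(sum(sh$terms$delta), 100, tolerance = 1e-9)
  expect_equal(sum(sh$category_totals), sh$net, tolerance = 1e-9)

  # degenerate comparison rejected
  expect_error(phrase_shift(c(a = 1, b = 1), ref, lexs), "equal")
})

test_that("contribution categories follow the two sign definitions", {
  expect_equal(classify_contribution(300, 200, 0.75, 0.5), "+up")
  expect_equal(classify_contribution(100, 200, 0.25, 0.5), "-down")
  expect_equal(classify_contribution(300, 200, 0.25, 0.5), "+down")
  expect_equal(classify_contribution(100, 200, 0.75, 0.5), "-up")
  expect_error(classify_contribution(200, 200, 0.5, 0.5), "zero")
})

test_that("shift contributions always sum to the signed 100 percent", {
  set.seed(13)
  lemmas <- sprintf("L%02d", 1:6)
  lx <- lexicon(data.frame(phrase = paste0("p", 1:6), lemma = lemmas,
                           score = round(stats::runif(6, 20, 600), 1)),
                side = "input")
  for (i in 1:300) {
    nr <- sample(2:5, 1)
    cdf <- counts_df(region = rep(sprintf("R%d", 1:nr), each = 6),
                     lemma = rep(lemmas, nr),
                     count = stats::rpois(6 * nr, 8) + 1)
    ref <- pooled_reference(cdf, lx)
    comp <- stats::setNames(stats::rpois(6, 8) + 1, lemmas)
    C_comp <- caloric_score(comp, lx)
    if (C_comp == ref$C_ref) next
    sh <- phrase_shift(comp, ref, lx)
    expect_equal(sum(sh$terms$delta), sign(C_comp - ref$C_ref) * 100,
                 tolerance = 1e-9)
    expect_equal(sum(sh$category_totals), sh$net, tolerance = 1e-9)
    # terms sorted by decreasing magnitude
    expect_true(!is.unsorted(rev(abs(sh$terms$delta))))
    # category labels agree with the two signs
    for (r in seq_len(nrow(sh$terms))) {
      lm <- sh$terms$lemma[r]
      expect_equal(sh$terms$category[r],
                   classify_contribution(lemma_score(lx, lm), ref$C_ref,
                                         comp[[lm]] / sum(comp),
                                         ref$p_ref[[lm]]))
    }
  }
})

test_that("swapping comparison and reference flips the net sign", {
  ref_ab <- pooled_reference(counts_df("A", c("a", "b"), c(1, 1)), lexs)
  ref_x <- pooled_reference(counts_df("X", c("a", "b"), c(1, 3)), lexs)
  sh1 <- phrase_shift(c(a = 1, b = 3), ref_ab, lexs)
  sh2 <- phrase_shift(c(a = 1, b = 1), ref_x, lexs)
  expect_equal(sh1$net, 100)
  expect_equal(sh2$net, -100)
})

test_that("the unreferenced-score identity holds exactly", {
  # sum_s score(s) dp(s) = sum_s (score(s) - C_ref) dp(s), since dp sums to 0
  set.seed(17)
  lemmas <- c("a", "b", "c")
  lx <- lexicon(data.frame(phrase = lemmas, lemma = lemmas,
                           score = c(50, 250, 500)), side = "input")
  for (i in 1:50) {
    p1 <- prop.table(stats::runif(3)); names(p1) <- lemmas
    p2 <- prop.table(stats::runif(3)); names(p2) <- lemmas
    sc <- lemma_score(lx, lemmas)
    Cref <- sum(sc * p2)
    expect_equal(sum(sc * (p1 - p2)), sum((sc - Cref) * (p1 - p2)),
                 tolerance = 1e-12)
  }
})

test_that("distinguishing lemma is the largest aligned increased-usage term", {
  ref <- pooled_reference(counts_df(c("A", "B"), c("a", "b"), c(1, 1)), lexs)
  sh <- phrase_shift(c(a = 1, b = 3), ref, lexs)
  expect_equal(distinguishing_lemma(sh), "b") # only 'up' term aligned with net

  # all 'up' terms oppose the net -> explicit absence
  sh_dn <- phrase_shift(c(a = 3, b = 1), ref, lexs) # net -100, 'a' is -up
  expect_equal(sh_dn$net, -100)
  expect_equal(distinguishing_lemma(sh_dn), "a") # -up aligned with negative net
  # construct a shift whose only up term fights the net: comparison uses the
  # high-calorie lemma more, yet scores below reference through a third lemma
  lx3 <- lexicon(data.frame(phrase = c("a", "b", "c"),
                            lemma = c("a", "b", "c"),
                            score = c(100, 300, 10)), side = "input")
  refs <- pooled_reference(counts_df("A", c("a", "b", "c"), c(4, 4, 2)), lx3)
  shx <- phrase_shift(c(a = 1, b = 5, c = 14), refs, lx3)
  expect_equal(shx$net, -100)
  up_aligned <- grepl("up$", shx$terms$category) &
    sign(shx$terms$delta) == sign(shx$net)
  if (!any(up_aligned)) expect_true(is.na(distinguishing_lemma(shx)))
})

test_that("shift export round-trips through JSON and TSV", {
  ref <- pooled_reference(counts_df(c("A", "B"), c("a", "b"), c(1, 1)), lexs)
  sh <- phrase_shift(c(a = 1, b = 3), ref, lexs, comparison = "X")
  fj <- withr::local_tempfile(fileext = ".json")
  write_shift(sh, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$net, 100)
  expect_equal(sum(unlist(back$category_totals)), 100, tolerance = 1e-9)
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_shift(sh, ft)
  tab <- utils::read.delim(ft)
  expect_equal(nrow(tab), nrow(sh$terms))
})
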