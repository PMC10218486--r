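test_that("pair lookups follow the code table", {
  expect_equal(classify_pair("C", "C"), "wandering")
  expect_equal(classify_pair("P", "P"), "none")
  expect_equal(classify_pair("S", "P"), "bored")
  expect_equal(classify_pair("S", "C"), "nervous")
  expect_error(classify_pair("X", "C"), "invalid pose letter")
  expect_error(classify_pair("C", 1), "invalid pose letter")
})

test_that("edit distance handles the canonical examples", {
  expect_equal(damerau_levenshtein("CCSP", "CCSP"), 0L)
  expect_equal(damerau_levenshtein("CS", "SC"), 1L)
  expect_equal(damerau_levenshtein("CCSS", "PPSS"), 2L)
  expect_equal(damerau_levenshtein("", "CSP"), 3L)
  expect_equal(damerau_levenshtein("", ""), 0L)
})

test_that("edit distance agrees with the brute-force recurrence enumerator", {
  strs <- all_pose_strings(3)
  grid <- expand.grid(x = strs, y = strs, stringsAsFactors = FALSE)
  expect_equal(damerau_levenshtein(grid$x, grid$y),
               unname(mapply(dl_naive, grid$x, grid$y)))
})

test_that("edit distance is a symmetric premetric bounded by Levenshtein", {
  set.seed(23)
  rand_str <- function() {
    paste(sample(pose_letters(), sample(0:8, 1), replace = TRUE),
          collapse = "")
  }
  for (k in 1:200) {
    x <- rand_str(); y <- rand_str(); z <- rand_str()
    dxy <- damerau_levenshtein(x, y)
    expect_identical(dxy, damerau_levenshtein(y, x))
    expect_identical(dxy == 0L, x == y)
    # triangle inequality
    expect_lte(dxy, damerau_levenshtein(x, z) + damerau_levenshtein(z, y))
    # adding transpositions can only help relative to plain Levenshtein
    expect_lte(dxy, drop(utils::adist(x, y)))
    expect_gte(dxy, abs(nchar(x) - nchar(y)))
  }
})

test_that("canonical templates self-classify pair by pair", {
  for (len in c(4L, 5L, 9L)) {
    pats <- canonical_patterns(len)
    for (mood in names(pats)) {
      s <- pose_stream("t", seq_len(len), strsplit(pats[[mood]], "")[[1]])
      expect_true(all(classify_stream(s)$mood == mood))
    }
  }
})

test_that("stream classification slides over adjacent pairs", {
  s <- pose_stream("p", 1:3, c("C", "C", "C"))
  expect_equal(classify_stream(s)$mood, c("wandering", "wandering"))
  s2 <- pose_stream("p", 1:3, c("S", "P", "S"))
  expect_equal(classify_stream(s2)$mood, c("bored", "bored"))
  expect_error(classify_stream(pose_stream("p", 1, "C")),
               "insufficient data")
  # labels are stamped with the pair-completing event time
  expect_equal(classify_stream(s2)$t, c(2L, 3L))
})

test_that("stream classification yields n-1 labels overlapping, floor(n/2) disjoint", {
  set.seed(5)
  for (k in 1:20) {
    n <- sample(2:40, 1)
    s <- pose_stream("p", seq_len(n),
                     sample(pose_letters(), n, replace = TRUE))
    expect_equal(nrow(classify_stream(s)), n - 1L)
    expect_equal(nrow(classify_stream(s, step = "disjoint")), n %/% 2L)
  }
})

test_that("window classification finds the nearest template", {
  expect_equal(classify_window("CCCC")[c("mood", "distance")],
               list(mood = "wandering", distance = 0L))
  expect_equal(classify_window("SSSS")[c("mood", "distance")],
               list(mood = "depressed", distance = 0L))
  w <- classify_window("CCCS")
  expect_equal(w$mood, "wandering")
  expect_equal(w$distance, 1L)
  # every mood recovers its own template at distance zero
  for (len in c(4L, 7L, 12L)) {
    pats <- canonical_patterns(len)
    for (mood in names(pats)) {
      got <- classify_window(pats[[mood]], pats)
      expect_equal(got$mood, mood)
      expect_equal(got$distance, 0L)
      expect_equal(got$ties, mood)
    }
  }
})

test_that("window ties are reported and broken by the fixed priority order", {
  set.seed(31)
  for (k in 1:50) {
    w <- paste(sample(pose_letters(), sample(2:10, 1), replace = TRUE),
               collapse = "")
    got <- classify_window(w)
    expect_equal(got$ties, intersect(mood_levels(), got$ties))
    expect_equal(got$mood, got$ties[[1]])
    # reported distance really is the minimum over re-tiled templates
    pats <- canonical_patterns(nchar(w))
    expect_equal(got$distance,
                 min(damerau_levenshtein(rep(w, 6), unname(pats))))
  }
  expect_error(classify_window(""), "nonempty")
  expect_error(classify_window("CQ"), "invalid pose letter")
})
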