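test_that("wandering needs four consecutive walking observations", {
  s4 <- pose_stream("p", 1:4, rep("C", 4))
  expect_true("wandering" %in% apply_state_rules(s4)$asserted_states)
  s3 <- pose_stream("p", 1:3, rep("C", 3))
  expect_false("wandering" %in% apply_state_rules(s3)$asserted_states)
  # an interrupted run does not count under the consecutive reading
  s_broken <- pose_stream("p", 1:7, c("C", "C", "S", "C", "C", "C", "S"))
  expect_false("wandering" %in% apply_state_rules(s_broken)$asserted_states)
  # ... but does when consecutive = FALSE relaxes the run to a count
  s_spread <- pose_stream("p", 1:8, rep(c("C", "S"), 4))
  expect_false("wandering" %in% apply_state_rules(s_spread)$asserted_states)
  expect_true("wandering" %in%
                apply_state_rules(s_spread,
                                  consecutive = FALSE)$asserted_states)
})

test_that("an empty stream asserts nothing without erroring", {
  s <- pose_stream("p", integer(0), character(0))
  r <- apply_state_rules(s)
  expect_length(r$asserted_states, 0L)
  expect_true(is.na(r$primary))
  expect_equal(nrow(r$firings), 0L)
})

test_that("every default rule fires at its threshold and not below", {
  letter_of <- function(pattern) {
    names(pose_patterns())[match(pattern, unname(pose_patterns()))]
  }
  for (rule in default_state_rules()) {
    letter <- letter_of(rule$patterns[[1]])
    k <- rule$min_repetitions
    at <- pose_stream("p", seq_len(k), rep(letter, k))
    expect_true(rule$mood %in% apply_state_rules(at)$asserted_states)
    if (k > 1) {
      below <- pose_stream("p", seq_len(k - 1), rep(letter, k - 1))
      expect_false(rule$mood %in% apply_state_rules(below)$asserted_states)
    }
    expect_equal(min_trigger_run(rule$mood), k)
  }
})

test_that("minimal trigger runs match the rule thresholds", {
  expect_equal(min_trigger_run("wandering"), 4L)
  expect_equal(min_trigger_run("depressed"), 1L)
  expect_equal(min_trigger_run("nervous"), 1L)
  expect_error(min_trigger_run("none"), "not present")
})

test_that("rule firing is monotone under appended events", {
  set.seed(17)
  for (k in 1:25) {
    n <- sample(5:40, 1)
    poses <- sample(pose_letters(), n, replace = TRUE)
    prefix <- pose_stream("p", seq_len(n - 3), poses[seq_len(n - 3)])
    full <- pose_stream("p", seq_len(n), poses)
    before <- apply_state_rules(prefix)$asserted_states
    after <- apply_state_rules(full)$asserted_states
    expect_true(all(before %in% after))
  }
})

test_that("every firing records a supporting run at least as long as the threshold", {
  rules <- default_state_rules()
  mins <- vapply(rules, `[[`, integer(1), "min_repetitions")
  names(mins) <- vapply(rules, `[[`, character(1), "mood")
  set.seed(19)
  for (k in 1:20) {
    n <- sample(4:50, 1)
    s <- pose_stream("p", seq_len(n),
                     sample(pose_letters(), n, replace = TRUE))
    r <- apply_state_rules(s)
    if (nrow(r$firings)) {
      expect_true(all(r$firings$run_length >= mins[r$firings$mood]))
      expect_setequal(unique(r$firings$mood), r$asserted_states)
    }
  }
})

test_that("instance checking composes asserted typing with subsumption", {
  m <- build_taxonomy(alz_taxonomy("full"))
  m <- add_individuals(m, c("obs_1", "obs_2"), c("Walking", "Nervous"))
  expect_true(instance_check(m, "obs_1", "Patron"))
  expect_true(instance_check(m, "obs_1", "Walking"))
  expect_false(instance_check(m, "obs_1", "State of mind"))
  expect_true(instance_check(m, "obs_2", m$root))
  expect_error(instance_check(m, "ghost", "Patron"), "ghost")
  expect_error(instance_check(m, "obs_1", "NoSuch"), "NoSuch")
  # agreement with is_subclass_of on every (individual, class) combination
  for (i in m$individuals$name) {
    asserted <- m$individuals$class[m$individuals$name == i]
    for (cl in c(m$root, m$classes)) {
      expect_identical(instance_check(m, i, cl),
                       is_subclass_of(m, asserted, cl))
    }
  }
})

test_that("the audit flags the moods whose two pattern sources disagree", {
  rep <- audit_rule_consistency()
  expect_equal(nrow(rep), 6L)
  row <- function(m) rep[rep$mood == m, ]
  expect_false(row("nervous")$agree)
  expect_equal(row("nervous")$pair_patterns, "sitting+walking")
  expect_equal(row("nervous")$rule_patterns, "sitting+standing")
  expect_true(row("depressed")$agree)
  expect_true(row("wandering")$agree)
  expect_true(row("bored")$agree)
  expect_false(row("disoriented")$agree)
  expect_false(row("none")$agree)  # pair code PP has no state rule
})

test_that("an empty audit yields an empty report", {
  rep <- audit_rule_consistency(table = character(0), rules = list())
  expect_equal(nrow(rep), 0L)
})

test_that("state rules load from JSON configuration", {
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(rules = list(
    list(mood = "wandering", patterns = list("walking"),
         min_repetitions = 2))), auto_unbox = TRUE), f)
  rules <- read_state_rules(f)
  expect_equal(min_trigger_run("wandering", rules), 2L)
  writeLines(jsonlite::toJSON(list(rules = list(
    list(mood = "confused", patterns = list("walking"),
         min_repetitions = 1))), auto_unbox = TRUE), f)
  expect_error(read_state_rules(f), "unknown mood")
})
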