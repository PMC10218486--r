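#' Default state rules
#'
#' The run-length rules linking activity patterns to mood states: bored,
#' disoriented and nervous fire on sitting or standing; depressed on
#' sitting; wandering on walking, and only when the walking observation is
#' repeated at least 4 consecutive times. All other rules have a minimum
#' repetition count of 1.
#'
#' @return A list of rules, each a list with fields `mood`, `patterns`
#'   (subset of walking/sitting/standing) and `min_repetitions`.
#' @seealso [apply_state_rules()], [audit_rule_consistency()]
#' @export
default_state_rules <- function() {
  list(
    list(mood = "bored", patterns = c("sitting", "standing"),
         min_repetitions = 1L),
    list(mood = "disoriented", patterns = c("sitting", "standing"),
         min_repetitions = 1L),
    list(mood = "depressed", patterns = "sitting", min_repetitions = 1L),
    list(mood = "wandering", patterns = "walking", min_repetitions = 4L),
    list(mood = "nervous", patterns = c("sitting", "standing"),
         min_repetitions = 1L)
  )
}

validate_state_rules <- function(rules) {
  for (r in rules) {
    if (!all(c("mood", "patterns", "min_repetitions") %in% names(r))) {
      stop("each rule needs fields mood, patterns, min_repetitions",
           call. = FALSE)
    }
    if (!r$mood %in% mood_levels()) {
      stop("unknown mood in rule: ", r$mood, call. = FALSE)
    }
    if (!length(r$patterns) ||
        !all(r$patterns %in% unname(pose_patterns()))) {
      stop("rule for ", r$mood,
           ": patterns must be a nonempty subset of walking/sitting/standing",
           call. = FALSE)
    }
    if (r$min_repetitions < 1) {
      stop("rule for ", r$mood, ": min_repetitions must be >= 1",
           call. = FALSE)
    }
  }
  rules
}

#' Read state rules from a JSON configuration
#'
#' Expects `{"rules": [{"mood": ..., "patterns": [...],
#' "min_repetitions": ...}, ...]}` (or the bare array).
#'
#' @param path JSON file path.
#' @return A validated rule list.
#' @export
read_state_rules <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rules <- if (!is.null(cfg$rules)) cfg$rules else cfg
  rules <- lapply(rules, function(r) {
    r$patterns <- unlist(r$patterns)
    r$min_repetitions <- as.integer(r$min_repetitions)
    r
  })
  validate_state_rules(rules)
}

#' Infer patient-level mood states from a pose stream
#'
#' Forward-chaining rule application: a rule fires iff the stream contains
#' a maximal run of consecutive events whose activity patterns all lie in
#' the rule's allowed patterns, of length at least `min_repetitions`. The
#' asserted states are the moods of all fired rules; states are not
#' mutually exclusive, and the highest-priority asserted state is reported
#' as `primary`.
#'
#' With `consecutive = FALSE` the run requirement is relaxed to a total
#' count of qualifying events anywhere in the stream.
#'
#' @param stream A [pose_stream()] (an empty stream yields an empty
#'   result, not an error).
#' @param rules Rule list; default [default_state_rules()].
#' @param consecutive Require consecutive runs (default `TRUE`).
#' @return An object of class `inference_result`: list with `patient_id`,
#'   `asserted_states`, `primary`, and `firings` (data.frame `mood`,
#'   `start_t`, `end_t`, `run_length`).
#' @export
#' @examples
#' s <- pose_stream("P001", 1:4, rep("C", 4))
#' apply_state_rules(s)$asserted_states
apply_state_rules <- function(stream, rules = default_state_rules(),
                              consecutive = TRUE) {
  stopifnot(inherits(stream, "pose_stream"))
  rules <- validate_state_rules(rules)
  patterns <- unname(pose_patterns()[stream$events$pose])
  firings <- list()
  for (r in rules) {
    ok <- patterns %in% r$patterns
    if (!length(ok) || !any(ok)) next
    if (consecutive) {
      runs <- rle(ok)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      hit <- which(runs$values & runs$lengths >= r$min_repetitions)
      for (h in hit) {
        firings[[length(firings) + 1L]] <- data.frame(
          mood = r$mood,
          start_t = stream$events$t[starts[h]],
          end_t = stream$events$t[ends[h]],
          run_length = runs$lengths[h],
          stringsAsFactors = FALSE)
      }
    } else if (sum(ok) >= r$min_repetitions) {
      idx <- which(ok)
      firings[[length(firings) + 1L]] <- data.frame(
        mood = r$mood,
        start_t = stream$events$t[idx[1]],
        end_t = stream$events$t[idx[length(idx)]],
        run_length = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  firings <- if (length(firings)) do.call(rbind, firings) else
    data.frame(mood = character(0), start_t = integer(0),
               end_t = integer(0), run_length = integer(0),
               stringsAsFactors = FALSE)
  asserted <- intersect(mood_levels(), unique(firings$mood))
  structure(
    list(patient_id = stream$patient_id,
         asserted_states = asserted,
         primary = if (length(asserted)) asserted[[1]] else NA_character_,
         firings = firings),
    class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference_result> patient:", x$patient_id, "\n")
  if (length(x$asserted_states)) {
    cat("  asserted:", paste(x$asserted_states, collapse = ", "),
        "(primary:", paste0(x$primary, ")"), "\n")
    cat("  firings: ", nrow(x$firings), "\n", sep = "")
  } else {
    cat("  no states asserted\n")
  }
  invisible(x)
}

#' Minimal run length that triggers a mood
#'
#' Probes [apply_state_rules()] with synthetic runs of k = 1, 2, 3, ...
#' qualifying events until the mood is asserted, and returns that k. For
#' the default rules this is 4 for wandering and 1 for every other ruled
#' mood.
#'
#' @param mood A mood label present in `rules`.
#' @param rules Rule list.
#' @param max_k Probe ceiling (safety bound).
#' @return The smallest triggering run length, as an integer.
#' @export
#' @examples
#' min_trigger_run("wandering")
min_trigger_run <- function(mood, rules = default_state_rules(),
                            max_k = 1000L) {
  rules <- validate_state_rules(rules)
  moods <- vapply(rules, `[[`, character(1), "mood")
  if (!mood %in% moods) {
    stop("mood not present in rules: ", mood, call. = FALSE)
  }
  rule <- rules[[which(moods == mood)[1]]]
  letter <- names(pose_patterns())[match(rule$patterns[[1]],
                                         unname(pose_patterns()))]
  for (k in seq_len(max_k)) {
    s <- pose_stream("probe", seq_len(k), rep(letter, k))
    if (mood %in% apply_state_rules(s, rules)$asserted_states) {
      return(k)
    }
  }
  stop("mood ", mood, " not triggered by runs up to length ", max_k,
       call. = FALSE)
}

#' Instance checking against the class hierarchy
#'
#' Does the named individual belong to the queried class? True iff its
#' asserted class equals the queried class or is one of its descendants
#' (subsumption composed with the asserted typing).
#'
#' @param model An `ontology_model` containing the individual.
#' @param individual Individual name.
#' @param class Class name.
#' @return Logical scalar.
#' @export
instance_check <- function(model, individual, class) {
  stopifnot(inherits(model, "ontology_model"))
  hit <- match(individual, model$individuals$name)
  if (is.na(hit)) stop("unknown individual: ", individual, call. = FALSE)
  if (!class %in% all_class_names(model)) {
    stop("unknown class: ", class, call. = FALSE)
  }
  is_subclass_of(model, model$individuals$class[hit], class)
}

#' Audit the two mood-pattern sources against each other
#'
#' The package carries two independent statements of which activity
#' patterns accompany each mood: the pair-code table (each mood's pair
#' codes, decoded letter by letter to patterns) and the state rules
#' (`allowed_patterns`). This audit compares the two pattern sets per mood
#' and flags every mood where they differ; under the defaults, nervous,
#' disoriented and none disagree while wandering, depressed and bored
#' agree.
#'
#' @param table Pair-code table.
#' @param rules State rule list.
#' @param letter_patterns Letter-to-pattern-name mapping; default
#'   [pose_patterns()].
#' @return An object of class `conflict_report`: data.frame with one row
#'   per mood appearing in either source and columns `mood`,
#'   `pair_patterns`, `rule_patterns`, `agree`.
#' @export
#' @examples
#' audit_rule_consistency()
audit_rule_consistency <- function(table = pair_code_table(),
                                   rules = default_state_rules(),
                                   letter_patterns = pose_patterns()) {
  if (length(table)) table <- validate_pair_table(table)
  rules <- validate_state_rules(rules)
  rule_moods <- vapply(rules, `[[`, character(1), "mood")
  moods <- intersect(mood_levels(), unique(c(unname(table), rule_moods)))
  rows <- lapply(moods, function(m) {
    codes <- names(table)[table == m]
    pair_pat <- sort(unique(unname(
      letter_patterns[unlist(strsplit(codes, ""))])))
    rp <- rules[rule_moods == m]
    rule_pat <- if (length(rp)) sort(unique(rp[[1]]$patterns)) else character(0)
    data.frame(
      mood = m,
      pair_patterns = paste(pair_pat, collapse = "+"),
      rule_patterns = paste(rule_pat, collapse = "+"),
      agree = setequal(pair_pat, rule_pat) &&
        length(pair_pat) > 0 && length(rule_pat) > 0,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mood = character(0), pair_patterns = character(0),
               rule_patterns = character(0), agree = logical(0),
               stringsAsFactors = FALSE)
  class(out) <- c("conflict_report", class(out))
  out
}

#' @export
print.conflict_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<conflict_report> empty\n")
    return(invisible(x))
  }
  cat("<conflict_report>", sum(!x$agree), "of", nrow(x),
      "moods disagree between pair codes and state rules\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
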