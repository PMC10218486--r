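#' Mood labels
#'
#' The closed set of mood labels used throughout the package, in priority
#' order. `"none"` stands for the absence of an observable mood (the
#' "no observation" category). The order doubles as the deterministic
#' tie-break priority used by [classify_window()] and when reporting a
#' primary state: wandering > nervous > depressed > disoriented > bored >
#' none.
#'
#' @return Character vector of the six mood labels.
#' @export
#' @examples
#' mood_levels()
mood_levels <- function() {
  c("wandering", "nervous", "depressed", "disoriented", "bored", "none")
}

#' Pose letters and their activity patterns
#'
#' Pose observations are encoded as single letters: `C` = walking,
#' `S` = sitting, `P` = standing. `pose_letters()` returns the letters;
#' `pose_patterns()` returns the letter-to-pattern-name mapping.
#'
#' @return `pose_letters()`: character vector `c("C","S","P")`.
#'   `pose_patterns()`: named character vector mapping letter to pattern
#'   name.
#' @export
#' @examples
#' pose_patterns()[["C"]]
pose_letters <- function() c("C", "S", "P")

#' @rdname pose_letters
#' @export
pose_patterns <- function() {
  c(C = "walking", S = "sitting", P = "standing")
}

#' Default numeric pose-code map
#'
#' Tabular pose streams record poses as small integers; this map decodes
#' them to pose letters. The default is 1 = C (walking), 2 = S (sitting),
#' 3 = P (standing), matching the order in which the activity patterns are
#' introduced in the ontology schema. Override it when a source file uses a
#' different convention.
#'
#' @return Named character vector: names are the numeric codes as strings,
#'   values are pose letters.
#' @export
#' @examples
#' default_pose_code_map()
default_pose_code_map <- function() {
  map <- c(`1` = "C", `2` = "S", `3` = "P")
  validate_pose_code_map(map)
}

validate_pose_code_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("pose code map must be a named vector (code -> letter)", call. = FALSE)
  }
  if (anyDuplicated(names(map)) || anyDuplicated(map)) {
    stop("pose code map must be injective", call. = FALSE)
  }
  if (!setequal(unname(map), pose_letters())) {
    stop("pose code map must map onto the letters C, S, P", call. = FALSE)
  }
  map
}

#' The pose-pair code table
#'
#' Maps each of the nine ordered pairs of pose letters to a mood label:
#' CC = wandering; CS, SC = nervous; SS = depressed; CP, PC = disoriented;
#' PS, SP = bored; PP = none. This is the core lookup used by
#' [classify_pair()] and [classify_stream()].
#'
#' @return Named character vector with the nine ordered pairs as names and
#'   mood labels as values.
#' @export
#' @examples
#' pair_code_table()[["CC"]]
pair_code_table <- function() {
  c(
    CC = "wandering",
    CS = "nervous",
    SC = "nervous",
    SS = "depressed",
    CP = "disoriented",
    PC = "disoriented",
    PS = "bored",
    SP = "bored",
    PP = "none"
  )
}

validate_pair_table <- function(table) {
  pairs <- as.vector(outer(pose_letters(), pose_letters(), paste0))
  if (!setequal(names(table), pairs)) {
    stop("pair table must cover all 9 ordered pairs of C, S, P", call. = FALSE)
  }
  bad <- setdiff(unique(table), mood_levels())
  if (length(bad)) {
    stop("unknown mood label(s) in pair table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  table
}

# Representative pair per mood, used to build canonical templates and
# synthetic streams. Each pair must map to its mood under the pair table.
canonical_pairs <- function() {
  c(
    wandering   = "CC",
    nervous     = "CS",
    depressed   = "SS",
    disoriented = "CP",
    bored       = "SP",
    none        = "PP"
  )
}

#' Mood concept annotations
#'
#' Short textual definitions of the five observable moods, used to annotate
#' the corresponding state classes in the ontology. The wording restates,
#' in the package's own terms, how each mood manifests behaviourally in
#' elderly patients with Alzheimer's disease.
#'
#' @return Named character vector, one entry per observable mood.
#' @export
mood_annotations <- function() {
  c(
    disoriented = paste(
      "Loss of the ability to recognize places or familiar faces,",
      "or confusion about one's own position."),
    nervous = paste(
      "Repetitive acts such as asking the same questions, returning to",
      "the same topic, or redoing completed tasks; interruption of these",
      "acts produces worry and anxiousness."),
    bored = paste(
      "Demotivation and lack of interest in recreational or social",
      "activities the person traditionally carried out, such as reading,",
      "looking at images, or physical and creative activity."),
    wandering = paste(
      "Walking without direction, sense, or spatial orientation."),
    depressed = paste(
      "Loss of capacity for motor activities together with deteriorated",
      "memory for the execution of voluntary acts.")
  )
}

# Normalize a free-text mood/state label to one of the six mood labels,
# or NA if unrecognized. Covers the spelling variants that appear across
# the taxonomy ("Wander", "Wandered", "Boring", "highly strung", ...).
normalize_mood <- function(x) {
  key <- tolower(trimws(as.character(x)))
  lut <- c(
    wandering = "wandering", wander = "wandering", wandered = "wandering",
    wanders = "wandering",
    nervous = "nervous", `highly strung` = "nervous", anxious = "nervous",
    depressed = "depressed", sad = "depressed", depression = "depressed",
    disoriented = "disoriented", disorientated = "disoriented",
    bored = "bored", boring = "bored",
    none = "none", nothing = "none", `no observation` = "none"
  )
  out <- unname(lut[key])
  out[is.na(out) & key %in% mood_levels()] <- key[is.na(out) & key %in% mood_levels()]
  out
}

# Local, restorable RNG seeding: runs `expr`-free style, callers use
# with_seed(seed, { ... }). A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
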