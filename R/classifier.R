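#' Classify one ordered pose pair
#'
#' Exact lookup of an ordered pair of pose letters in the pair-code table:
#' e.g. walking followed by walking (`C`, `C`) is wandering; standing
#' followed by standing (`P`, `P`) is none.
#'
#' @param a,b Pose letters (first and second observation).
#' @param table Pair-code table; default [pair_code_table()].
#' @return A mood label.
#' @export
#' @examples
#' classify_pair("C", "C")
#' classify_pair("S", "P")
classify_pair <- function(a, b, table = pair_code_table()) {
  table <- validate_pair_table(table)
  for (x in c(a, b)) {
    if (!(is.character(x) && length(x) == 1L && x %in% pose_letters())) {
      stop("invalid pose letter: ", deparse(x), call. = FALSE)
    }
  }
  unname(table[[paste0(a, b)]])
}

#' Restricted Damerau-Levenshtein distance
#'
#' Minimum number of unit-cost insertions, deletions, substitutions and
#' adjacent transpositions transforming `x` into `y` (optimal string
#' alignment form: no substring is edited twice). Symmetric, zero iff the
#' strings are equal. Vectorized with recycling.
#'
#' @param x,y Character vectors.
#' @return Integer vector of distances.
#' @export
#' @examples
#' damerau_levenshtein("CS", "SC")   # one transposition
#' damerau_levenshtein("CCSS", "PPSS")
damerau_levenshtein <- function(x, y) {
  stopifnot(is.character(x), is.character(y))
  dl_distance_cpp(x, y)
}

#' Canonical mood templates
#'
#' Each mood's canonical pose-letter template is its representative pair
#' code tiled to the requested length: wandering `CCCC`, nervous `CSCS`,
#' depressed `SSSS`, disoriented `CPCP`, bored `SPSP`, none `PPPP` at the
#' default length 4 (chosen to align with the four-repetition wandering
#' rule). Every adjacent pair of a template classifies to the template's
#' own mood.
#'
#' @param length Template length in events (default 4).
#' @param table Pair-code table used to verify template consistency.
#' @return Named character vector: mood label -> template string.
#' @export
#' @examples
#' canonical_patterns()
#' canonical_patterns(6)[["nervous"]]
canonical_patterns <- function(length = 4L, table = pair_code_table()) {
  stopifnot(length >= 2L)
  table <- validate_pair_table(table)
  pairs <- canonical_pairs()
  bad <- names(pairs)[unname(table[pairs]) != names(pairs)]
  if (base::length(bad)) {
    stop("canonical pair inconsistent with pair table for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vapply(pairs, function(p) tile_template(p, length), character(1))
}

tile_template <- function(pair, length) {
  substr(strrep(pair, ceiling(length / 2)), 1L, length)
}

#' Classify a pose stream pair-by-pair
#'
#' Slides over the stream and classifies each ordered pose pair through the
#' pair-code table. With `step = "overlap"` (the default) pairs overlap
#' (events 1-2, 2-3, ...), giving one label per adjacent pair, `n - 1`
#' labels for `n` events, each stamped with the time of the pair's second
#' event. With `step = "disjoint"` consecutive non-overlapping pairs are
#' used (events 1-2, 3-4, ...).
#'
#' @param stream A [pose_stream()] with at least 2 events.
#' @param table Pair-code table.
#' @param step `"overlap"` or `"disjoint"`.
#' @return A data.frame with columns `t` and `mood`.
#' @export
#' @examples
#' s <- pose_stream("P001", 1:3, c("S", "P", "S"))
#' classify_stream(s)
classify_stream <- function(stream, table = pair_code_table(),
                            step = c("overlap", "disjoint")) {
  step <- match.arg(step)
  stopifnot(inherits(stream, "pose_stream"))
  table <- validate_pair_table(table)
  n <- nrow(stream$events)
  if (n < 2L) {
    stop("insufficient data: classify_stream needs at least 2 events",
         call. = FALSE)
  }
  i <- if (step == "overlap") seq_len(n - 1L) else seq(1L, n - 1L, by = 2L)
  pairs <- paste0(stream$events$pose[i], stream$events$pose[i + 1L])
  data.frame(t = stream$events$t[i + 1L],
             mood = unname(table[pairs]),
             stringsAsFactors = FALSE)
}

#' Classify a pose window by nearest canonical template
#'
#' Compares a pose-letter window against each mood's canonical template
#' (tiled or truncated to the window's length) under the restricted
#' Damerau-Levenshtein distance and returns the mood of the closest
#' template. Ties are broken deterministically by the fixed priority order
#' wandering > nervous > depressed > disoriented > bored > none; tying
#' moods are reported in the `ties` field.
#'
#' @param window Nonempty pose-letter string.
#' @param patterns Named character vector mood -> template, as from
#'   [canonical_patterns()]; templates are re-tiled to the window length.
#' @return A list with `mood`, `distance`, `ties` (all moods at the
#'   minimum distance, in priority order).
#' @export
#' @examples
#' classify_window("CCCC")
#' classify_window("CCCS")$distance
classify_window <- function(window, patterns = canonical_patterns()) {
  if (!(is.character(window) && length(window) == 1L && nzchar(window))) {
    stop("window must be a nonempty pose-letter string", call. = FALSE)
  }
  letters_in <- strsplit(window, "")[[1]]
  bad <- setdiff(unique(letters_in), pose_letters())
  if (length(bad)) {
    stop("invalid pose letter(s) in window: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(patterns)) || !length(patterns)) {
    stop("patterns must be a nonempty named vector (mood -> template)",
         call. = FALSE)
  }
  ord <- intersect(mood_levels(), names(patterns))
  ord <- c(ord, setdiff(names(patterns), ord))
  templates <- vapply(patterns[ord], function(tp) {
    base <- substr(tp, 1L, 2L)
    if (nchar(tp) >= nchar(window)) substr(tp, 1L, nchar(window))
    else tile_template(base, nchar(window))
  }, character(1))
  d <- damerau_levenshtein(rep(window, length(templates)),
                           unname(templates))
  dmin <- min(d)
  ties <- names(templates)[d == dmin]
  list(mood = ties[[1]], distance = dmin, ties = ties)
}
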