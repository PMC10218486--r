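#' Mood counts and percentages
#'
#' Tallies a vector of mood labels over the six-mood vocabulary; moods with
#' no occurrences are reported with count 0 so the category layout is
#' stable. Percentages always sum to 100.
#'
#' @param labels Nonempty character vector of mood labels.
#' @return An object of class `mood_summary`: list with integer `counts`
#'   and numeric `percentages`, both named by mood.
#' @export
#' @examples
#' mood_percentages(c("wandering", "wandering", "depressed", "depressed"))
mood_percentages <- function(labels) {
  if (!base::length(labels)) {
    stop("mood_percentages needs at least one label", call. = FALSE)
  }
  bad <- setdiff(unique(labels), mood_levels())
  if (base::length(bad)) {
    stop("unknown mood label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(labels, levels = mood_levels()))
  counts <- structure(as.integer(counts), names = names(counts))
  structure(
    list(counts = counts, percentages = 100 * counts / sum(counts)),
    class = "mood_summary")
}

#' @export
print.mood_summary <- function(x, digits = 1, ...) {
  cat("<mood_summary> n =", sum(x$counts), "\n")
  df <- data.frame(mood = names(x$counts), count = unname(x$counts),
                   percent = round(unname(x$percentages), digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mood_summary <- function(x, ...) {
  graphics::barplot(x$percentages, ylab = "percent of labeled pairs",
                    xlab = "mood", las = 2, ...)
  invisible(x)
}

#' Per-patient mood-frequency matrix
#'
#' Classifies every stream pair-by-pair ([classify_stream()]) and returns
#' the fraction of each patient's labeled pairs falling in each mood: one
#' row per patient, one column per mood, rows summing to 1. This matrix is
#' the input to [pca_summary()].
#'
#' @param streams A list of [pose_stream()] objects (each with >= 2
#'   events) or a `labeled_dataset`.
#' @param table Pair-code table.
#' @param step Pair stepping, as in [classify_stream()].
#' @return A numeric matrix, patients x moods, with patient ids as row
#'   names.
#' @export
#' @examples
#' d <- generate_dataset(generate_cohort(5, seed = 1), seed = 2)
#' mood_frequency_matrix(d)
mood_frequency_matrix <- function(streams, table = pair_code_table(),
                                  step = c("overlap", "disjoint")) {
  step <- match.arg(step)
  if (inherits(streams, "labeled_dataset")) streams <- streams$streams
  if (inherits(streams, "pose_stream")) streams <- list(streams)
  if (!base::length(streams)) {
    stop("no streams to summarize", call. = FALSE)
  }
  rows <- t(vapply(streams, function(s) {
    labs <- classify_stream(s, table = table, step = step)$mood
    p <- mood_percentages(labs)$percentages / 100
    unname(p)
  }, numeric(base::length(mood_levels()))))
  rownames(rows) <- unname(vapply(streams, `[[`, character(1),
                                  "patient_id"))
  colnames(rows) <- mood_levels()
  rows
}

#' Principal component analysis of mood frequencies
#'
#' Centered (unscaled) PCA of the patients x moods frequency matrix.
#' Alongside loadings, scores and per-component explained-variance ratios,
#' the summary reports the cumulative variance explained by the component
#' pairs (1,2), (2,3) and (1,3), the pairs conventionally shown in biplot
#' panels.
#'
#' @param x Numeric matrix (patients x moods), e.g. from
#'   [mood_frequency_matrix()].
#' @param n_components Number of components to keep; default all available
#'   (`min(nrow - 1, ncol)`).
#' @return An object of class `mood_pca`: list with `loadings` (moods x
#'   components, orthonormal columns), `scores` (patients x components),
#'   `explained_variance_ratio` (nonincreasing, sums to <= 1), `pair_variance`
#'   (named percentages for the three component pairs) and `center`.
#' @export
#' @examples
#' d <- generate_dataset(generate_cohort(20, seed = 1), noise_rate = 0.2,
#'                       seed = 2)
#' p <- pca_summary(mood_frequency_matrix(d))
#' p$explained_variance_ratio
pca_summary <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("pca_summary needs at least 2 rows (patients)", call. = FALSE)
  }
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components < 1L || n_components > min(dim(x))) {
    stop("n_components must be between 1 and ", min(dim(x)), call. = FALSE)
  }
  vars <- apply(x, 2, stats::var)
  if (all(vars < 1e-12)) {
    stop("degenerate input: all columns have zero variance", call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ratio <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$rotation))
  pair_variance <- c(NA_real_, NA_real_, NA_real_)
  names(pair_variance) <- c("PC1+PC2", "PC2+PC3", "PC1+PC3")
  if (base::length(ratio) >= 2) {
    pair_variance[["PC1+PC2"]] <- 100 * (ratio[1] + ratio[2])
  }
  if (base::length(ratio) >= 3) {
    pair_variance[["PC2+PC3"]] <- 100 * (ratio[2] + ratio[3])
    pair_variance[["PC1+PC3"]] <- 100 * (ratio[1] + ratio[3])
  }
  structure(
    list(loadings = fit$rotation[, seq_len(k), drop = FALSE],
         scores = fit$x[, seq_len(k), drop = FALSE],
         explained_variance_ratio = ratio[seq_len(k)],
         all_variance_ratio = ratio,
         pair_variance = pair_variance,
         center = fit$center),
    class = "mood_pca")
}

#' @export
print.mood_pca <- function(x, digits = 3, ...) {
  cat("<mood_pca>", ncol(x$loadings), "components\n")
  cat("  explained variance ratio:",
      paste(round(x$explained_variance_ratio, digits), collapse = ", "),
      "\n")
  pv <- x$pair_variance[!is.na(x$pair_variance)]
  if (base::length(pv)) {
    cat("  pair variance (%):",
        paste(names(pv), round(unname(pv), 1), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
plot.mood_pca <- function(x, choices = c(1, 2), ...) {
  stopifnot(base::length(choices) == 2, all(choices <= ncol(x$scores)))
  sc <- x$scores[, choices, drop = FALSE]
  ld <- x$loadings[, choices, drop = FALSE]
  graphics::plot(sc, pch = 16, col = "grey40",
                 xlab = colnames(sc)[1], ylab = colnames(sc)[2], ...)
  scale <- 0.8 * max(abs(sc)) / max(abs(ld))
  graphics::arrows(0, 0, ld[, 1] * scale, ld[, 2] * scale,
                   length = 0.08, col = "firebrick")
  graphics::text(ld * scale * 1.08, labels = rownames(ld),
                 col = "firebrick", cex = 0.8)
  invisible(x)
}

#' End-to-end cohort summary
#'
#' Runs the full pipeline on a labeled dataset: classify every stream
#' pair-by-pair, apply the state rules per patient, and summarize the
#' cohort with mood percentages and (when feasible) a PCA of the
#' mood-frequency matrix. The whole pipeline is deterministic given the
#' dataset.
#'
#' @param dataset A `labeled_dataset` (or plain list of streams).
#' @param table Pair-code table.
#' @param rules State rules.
#' @return A list with `summary` ([mood_percentages()] over all labeled
#'   pairs), `frequency_matrix`, `pca` (`NULL` if the matrix is degenerate),
#'   `inference` (data.frame `patient_id`, `primary`, `n_states`).
#' @export
summarize_cohort <- function(dataset, table = pair_code_table(),
                             rules = default_state_rules()) {
  streams <- if (inherits(dataset, "labeled_dataset")) dataset$streams
             else dataset
  labels <- unlist(lapply(streams, function(s) {
    classify_stream(s, table = table)$mood
  }), use.names = FALSE)
  freq <- mood_frequency_matrix(streams, table = table)
  pca <- tryCatch(pca_summary(freq), error = function(e) NULL)
  inf <- do.call(rbind, lapply(streams, function(s) {
    r <- apply_state_rules(s, rules)
    data.frame(patient_id = r$patient_id, primary = r$primary,
               n_states = base::length(r$asserted_states),
               stringsAsFactors = FALSE)
  }))
  rownames(inf) <- NULL
  list(summary = mood_percentages(labels), frequency_matrix = freq,
       pca = pca, inference = inf)
}
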