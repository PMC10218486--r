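#' Simulate a patient cohort
#'
#' Generates a cohort of patients with the study demographics: 147
#' individuals of both sexes diagnosed with Alzheimer's disease, men aged
#' 75 to 86 and women aged 75 to 89 (ranges inclusive, ages sampled
#' uniformly within the sex's range). A smaller preset of 45 patients — the
#' subset observed on video — is available as `n_patients = 45`.
#'
#' @param n_patients Number of patients (default 147).
#' @param sex_ratio Fraction of male patients (default 0.5).
#' @param age_range_male,age_range_female Inclusive integer age ranges.
#' @param seed Optional integer seed; the same seed yields an identical
#'   cohort. The global RNG state is left untouched.
#' @return A data.frame with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`) and `age`.
#' @export
#' @examples
#' head(generate_cohort(seed = 1))
generate_cohort <- function(n_patients = 147L, sex_ratio = 0.5,
                            age_range_male = c(75L, 86L),
                            age_range_female = c(75L, 89L),
                            seed = NULL) {
  stopifnot(n_patients >= 0, sex_ratio >= 0, sex_ratio <= 1)
  for (r in list(age_range_male, age_range_female)) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0) {
      stop("invalid age range: ", paste(r, collapse = "-"), call. = FALSE)
    }
  }
  if (n_patients == 0L) {
    return(data.frame(patient_id = character(0), sex = character(0),
                      age = integer(0), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    sex <- ifelse(stats::runif(n_patients) < sex_ratio, "male", "female")
    age <- integer(n_patients)
    male <- sex == "male"
    age[male] <- sample(seq(age_range_male[1], age_range_male[2]),
                        sum(male), replace = TRUE)
    age[!male] <- sample(seq(age_range_female[1], age_range_female[2]),
                         sum(!male), replace = TRUE)
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      sex = sex, age = age, stringsAsFactors = FALSE)
  })
}

#' Simulate a pose stream with known ground truth
#'
#' The base sequence is the true mood's canonical template tiled to the
#' requested length (wandering: walking runs `CCC...`; depressed: sitting
#' runs; none: standing runs; nervous: walking/sitting alternation;
#' disoriented: walking/standing alternation; bored: sitting/standing
#' alternation). Each event is then independently corrupted with
#' probability `noise_rate`, substituting a uniformly random *other* pose
#' letter; the observation grid is fixed-rate (one event per second), so
#' the noise model has no insertions or deletions.
#'
#' @param true_mood A mood label.
#' @param length Number of events (default 60, one per second over a
#'   one-minute observation); must be at least 2.
#' @param noise_rate Per-event substitution probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param patient_id Patient identifier for the stream.
#' @param record_status Write `true_mood` into the status column (default
#'   `TRUE`).
#' @return A [pose_stream()] with attribute `true_mood`.
#' @export
#' @examples
#' generate_stream("depressed", length = 10)
generate_stream <- function(true_mood, length = 60L, noise_rate = 0,
                            seed = NULL, patient_id = "P001",
                            record_status = TRUE) {
  if (!true_mood %in% mood_levels()) {
    stop("unknown mood: ", true_mood, call. = FALSE)
  }
  if (length < 2L) stop("stream length must be at least 2", call. = FALSE)
  stopifnot(noise_rate >= 0, noise_rate <= 1)
  base <- strsplit(tile_template(canonical_pairs()[[true_mood]], length),
                   "")[[1]]
  with_seed(seed, {
    flip <- stats::runif(length) < noise_rate
    if (any(flip)) {
      base[flip] <- vapply(base[flip], function(l) {
        sample(setdiff(pose_letters(), l), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    s <- pose_stream(patient_id, seq_len(length), base,
                     status = if (record_status) true_mood else NA_character_)
    attr(s, "true_mood") <- true_mood
    s
  })
}

#' Simulate a labeled multi-patient dataset
#'
#' Assigns each patient a true mood by multinomial sampling from
#' `mixing_proportions` and generates one pose stream per patient. The
#' result flows through the rest of the pipeline unchanged: write it with
#' [write_pose_table()] and read it back with [read_pose_table()].
#'
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param mixing_proportions Named numeric vector over mood labels summing
#'   to 1 (default: uniform over the six moods).
#' @param length,noise_rate Stream parameters passed to
#'   [generate_stream()].
#' @param seed Optional integer seed governing both the mood assignment
#'   and the streams.
#' @return An object of class `labeled_dataset`: list with `streams` (one
#'   [pose_stream()] per patient), `truth` (data.frame `patient_id`,
#'   `true_mood`) and `proportions`.
#' @export
#' @examples
#' d <- generate_dataset(generate_cohort(12, seed = 1), seed = 2)
#' table(d$truth$true_mood)
generate_dataset <- function(cohort,
                             mixing_proportions = NULL,
                             length = 60L, noise_rate = 0,
                             seed = NULL) {
  stopifnot(is.data.frame(cohort), "patient_id" %in% names(cohort))
  if (is.null(mixing_proportions)) {
    mixing_proportions <- structure(rep(1 / 6, 6), names = mood_levels())
  }
  bad <- setdiff(names(mixing_proportions), mood_levels())
  if (base::length(bad)) {
    stop("unknown mood in mixing proportions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(mixing_proportions) - 1) > 1e-9) {
    stop("mixing proportions must sum to 1", call. = FALSE)
  }
  n <- nrow(cohort)
  with_seed(seed, {
    moods <- if (n) sample(names(mixing_proportions), n, replace = TRUE,
                           prob = mixing_proportions) else character(0)
    streams <- lapply(seq_len(n), function(i) {
      generate_stream(moods[i], length = length, noise_rate = noise_rate,
                      patient_id = cohort$patient_id[i])
    })
    names(streams) <- cohort$patient_id
    structure(
      list(streams = streams,
           truth = data.frame(patient_id = cohort$patient_id,
                              true_mood = moods,
                              stringsAsFactors = FALSE),
           proportions = mixing_proportions),
      class = "labeled_dataset")
  })
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", base::length(x$streams), "streams\n")
  if (nrow(x$truth)) print(table(x$truth$true_mood))
  invisible(x)
}
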