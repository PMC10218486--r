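#' Construct a pose stream
#'
#' A `pose_stream` holds the time-ordered pose observations of one patient:
#' an integer time in seconds from stream start, a pose letter (C/S/P), an
#' optional recorded status (mood label as written in the source), and an
#' optional scene name. Event times must be strictly increasing.
#'
#' @param patient_id Patient identifier (scalar character).
#' @param t Integer vector of event times in seconds, strictly increasing,
#'   all `>= 0`.
#' @param pose Character vector of pose letters (`C`, `S`, `P`).
#' @param status Optional character vector of recorded statuses (`NA`
#'   allowed).
#' @param scene Optional character vector of scene names.
#' @return An object of class `pose_stream`.
#' @export
#' @examples
#' pose_stream("P001", t = 1:3, pose = c("C", "C", "S"))
pose_stream <- function(patient_id, t, pose, status = NA_character_,
                        scene = NA_character_) {
  stopifnot(length(patient_id) == 1L, nzchar(patient_id))
  t <- as.integer(t)
  if (any(is.na(t)) || any(t < 0)) {
    stop("event times must be non-negative integers", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("event times must be strictly increasing for patient ", patient_id,
         call. = FALSE)
  }
  bad <- setdiff(unique(pose), pose_letters())
  if (length(bad)) {
    stop("invalid pose letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  events <- data.frame(
    t = t,
    pose = as.character(pose),
    status = rep_len(as.character(status), length(t)),
    scene = rep_len(as.character(scene), length(t)),
    stringsAsFactors = FALSE)
  structure(list(patient_id = as.character(patient_id), events = events),
            class = "pose_stream")
}

#' @export
print.pose_stream <- function(x, ...) {
  cat("<pose_stream> patient:", x$patient_id, "-", nrow(x$events),
      "events\n")
  cat("  poses:", paste(x$events$pose, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.pose_stream <- function(x) nrow(x$events)

# Pose letters of a stream as one string ("CCSP...").
stream_letters <- function(stream) {
  paste(stream$events$pose, collapse = "")
}

#' Parse clock times to seconds
#'
#' Accepts `H:MM:SS` strings (fields need not be zero-padded; minute and
#' second fields above 59 are accepted and folded in, so `0:00:60` is 60
#' seconds) as well as bare non-negative integers.
#'
#' @param x Character or numeric vector.
#' @return Integer vector of seconds; unparseable entries are `NA`.
#' @export
#' @examples
#' parse_clock_time(c("0:00:1", "0:01:05", "42"))
parse_clock_time <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  bare <- grepl("^[0-9]+$", x)
  out[bare] <- as.integer(x[bare])
  hms <- grepl("^[0-9]+:[0-9]+:[0-9]+$", x)
  if (any(hms)) {
    parts <- do.call(rbind, strsplit(x[hms], ":", fixed = TRUE))
    out[hms] <- as.integer(parts[, 1]) * 3600L +
      as.integer(parts[, 2]) * 60L + as.integer(parts[, 3])
  }
  out
}

format_clock_time <- function(sec) {
  sec <- as.integer(sec)
  sprintf("%d:%02d:%02d", sec %/% 3600L, (sec %% 3600L) %/% 60L, sec %% 60L)
}

match_column <- function(cols, wanted) {
  hit <- which(tolower(cols) == tolower(wanted))
  if (length(hit)) hit[[1]] else NA_integer_
}

read_tabular <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(file, col_types = "text"))
  } else {
    df <- utils::read.csv(file, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  }
  df
}

#' Read a tabular pose-observation file into pose streams
#'
#' Reads a CSV or XLSX file with columns `time`, `pose`, `status` (and
#' optionally `scene` and `patient`; names case-insensitive, remappable via
#' `columns`), decodes numeric pose codes through `code_map`, and returns
#' one [pose_stream()] per patient with events ordered by time.
#'
#' Recorded status values are normalized to the package's mood labels where
#' recognized; unknown values are preserved verbatim with a warning. An
#' unmapped pose code or a duplicate timestamp within a patient is an
#' error naming the offending row.
#'
#' @param file Path to a CSV or XLSX file.
#' @param code_map Named vector mapping numeric pose codes to pose letters;
#'   default [default_pose_code_map()]. Pose letters appearing directly in
#'   the file are accepted as-is.
#' @param columns Optional named list/vector remapping logical column names
#'   to the file's column names, e.g.
#'   `list(time = "Time", pose = "Pose", status = "Status")`.
#' @param default_patient Patient id used when the file has no patient
#'   column.
#' @return A list of `pose_stream` objects, one per patient, ordered by
#'   patient id.
#' @export
read_pose_table <- function(file, code_map = default_pose_code_map(),
                            columns = NULL, default_patient = "patient_1") {
  code_map <- validate_pose_code_map(code_map)
  df <- read_tabular(file)
  logical_names <- c("time", "pose", "status", "scene", "patient")
  wanted <- structure(logical_names, names = logical_names)
  if (!is.null(columns)) {
    columns <- unlist(columns)
    wanted[names(columns)] <- columns
  }
  idx <- vapply(wanted, function(w) match_column(names(df), w), integer(1))
  for (req in c("time", "pose", "status")) {
    if (is.na(idx[[req]])) {
      stop("missing required column: ", wanted[[req]], call. = FALSE)
    }
  }
  if (nrow(df) == 0L) return(list())

  row_no <- seq_len(nrow(df)) + 1L  # file line numbers, counting the header
  t <- parse_clock_time(df[[idx[["time"]]]])
  if (anyNA(t)) {
    stop("unparseable time at row ", row_no[is.na(t)][1], call. = FALSE)
  }
  pose_raw <- trimws(df[[idx[["pose"]]]])
  pose <- ifelse(pose_raw %in% pose_letters(), pose_raw,
                 unname(code_map[pose_raw]))
  if (anyNA(pose)) {
    bad <- row_no[is.na(pose)][1]
    stop("unmapped pose code '", pose_raw[is.na(pose)][1], "' at row ", bad,
         call. = FALSE)
  }
  status_raw <- trimws(df[[idx[["status"]]]])
  status <- normalize_mood(status_raw)
  unknown <- !is.na(status_raw) & nzchar(status_raw) & is.na(status)
  if (any(unknown)) {
    warning("unknown status value(s) preserved verbatim: ",
            paste(unique(status_raw[unknown]), collapse = ", "),
            call. = FALSE)
    status[unknown] <- status_raw[unknown]
  }
  scene <- if (!is.na(idx[["scene"]])) trimws(df[[idx[["scene"]]]])
           else NA_character_
  scene[!is.na(scene) & !nzchar(scene)] <- NA_character_
  patient <- if (!is.na(idx[["patient"]])) trimws(df[[idx[["patient"]]]])
             else default_patient

  tab <- data.frame(row = row_no, t = t, pose = pose, status = status,
                    scene = rep_len(scene, nrow(df)),
                    patient = rep_len(patient, nrow(df)),
                    stringsAsFactors = FALSE)
  streams <- lapply(split(tab, tab$patient), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    dup <- duplicated(d$t)
    if (any(dup)) {
      stop("duplicate timestamp for patient ", d$patient[1], " at row ",
           d$row[dup][1], call. = FALSE)
    }
    pose_stream(d$patient[1], d$t, d$pose, d$status, d$scene)
  })
  streams[order(names(streams), method = "radix")]
}

#' Write pose streams in the tabular interchange schema
#'
#' Writes streams back to a CSV with columns `time`, `pose`, `status`,
#' `scene`, `patient`, encoding pose letters as numeric codes through the
#' inverse of `code_map` and times as `H:MM:SS`. Files written here read
#' back identically through [read_pose_table()].
#'
#' @param streams A `pose_stream` or list of them (a
#'   [generate_dataset()] result is also accepted).
#' @param path Output CSV path.
#' @param code_map Pose code map; its inverse encodes letters as codes.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(streams, path,
                             code_map = default_pose_code_map()) {
  code_map <- validate_pose_code_map(code_map)
  if (inherits(streams, "labeled_dataset")) streams <- streams$streams
  if (inherits(streams, "pose_stream")) streams <- list(streams)
  inv <- structure(names(code_map), names = unname(code_map))
  rows <- lapply(streams, function(s) {
    data.frame(
      time = format_clock_time(s$events$t),
      pose = unname(inv[s$events$pose]),
      status = ifelse(is.na(s$events$status), "", s$events$status),
      scene = ifelse(is.na(s$events$scene), "", s$events$scene),
      patient = s$patient_id,
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Attach pose streams to an ontology as individuals
#'
#' Adds one Patient individual per stream and one observation individual
#' per event, typed by the Pattern subclass matching its pose letter
#' (C = Walking, S = Sitting, P = Standing). The model must contain the
#' schema classes (`Patient` and the three pattern subclasses); a missing
#' class is an error naming it.
#'
#' @param model An `ontology_model`, typically [schema_ontology()].
#' @param streams A list of `pose_stream` objects.
#' @return The updated, validated model.
#' @export
#' @examples
#' m <- schema_ontology()
#' s <- generate_stream("depressed", length = 5, seed = 1)
#' m2 <- attach_individuals(m, list(s))
#' nrow(m2$individuals)
attach_individuals <- function(model, streams) {
  stopifnot(inherits(model, "ontology_model"))
  if (inherits(streams, "pose_stream")) streams <- list(streams)
  if (!length(streams)) return(model)
  if (!"Patient" %in% all_class_names(model)) {
    stop("schema class missing from ontology: Patient", call. = FALSE)
  }
  pat_class <- vapply(pose_patterns(), function(p) {
    hit <- all_class_names(model)[tolower(all_class_names(model)) == p]
    if (length(hit)) hit[[1]] else NA_character_
  }, character(1))
  missing <- names(pose_patterns())[is.na(pat_class)]
  if (length(missing)) {
    stop("schema class missing from ontology: ",
         paste(pose_patterns()[missing], collapse = ", "), call. = FALSE)
  }
  for (s in streams) {
    stopifnot(inherits(s, "pose_stream"))
    model <- add_individuals(model, paste0("patient_", s$patient_id),
                             "Patient")
    obs_names <- paste0("obs_", s$patient_id, "_t", s$events$t)
    model <- add_individuals(model, obs_names,
                             unname(pat_class[s$events$pose]))
  }
  model
}
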