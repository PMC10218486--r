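table4_file <- function() {
  system.file("extdata", "table4_poses.csv", package = "alzmood",
              mustWork = TRUE)
}

test_that("the printed pose table ingests as one stream with mapped letters", {
  streams <- read_pose_table(table4_file())
  expect_length(streams, 1L)
  s <- streams[[1]]
  expect_s3_class(s, "pose_stream")
  expect_equal(nrow(s$events), 11L)
  expect_equal(s$events$t, c(1:5, 55:60))
  expect_equal(paste(s$events$pose, collapse = ""), "CSPCCSSSCCC")
  # recorded statuses are normalized mood labels
  expect_equal(s$events$status[1:3], c("wandering", "wandering", "nervous"))
})

test_that("clock times parse in H:MM:SS and bare-second form", {
  expect_equal(parse_clock_time(c("0:00:1", "0:01:05", "1:00:00", "42")),
               c(1L, 65L, 3600L, 42L))
  expect_equal(parse_clock_time("0:00:60"), 60L)
  expect_true(is.na(parse_clock_time("abc")))
})

test_that("ingestion contract errors carry row numbers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time,pose,status", "0:00:1,1,Wander", "0:00:2,9,Wander"), f)
  expect_error(read_pose_table(f), "row 3")
  writeLines(c("time,pose,status", "0:00:1,1,", "0:00:1,2,"), f)
  expect_error(read_pose_table(f), "duplicate timestamp")
  writeLines("time,pose,status", f)
  expect_equal(read_pose_table(f), list())
})

test_that("unknown status values are preserved verbatim with a warning", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time,pose,status", "0:00:1,1,Perplexed", "0:00:2,2,Wander"),
             f)
  expect_warning(streams <- read_pose_table(f), "Perplexed")
  expect_equal(streams[[1]]$events$status, c("Perplexed", "wandering"))
})

test_that("ingestion is stable under row shuffling", {
  df <- utils::read.csv(table4_file(), colClasses = "character")
  ref <- read_pose_table(table4_file())
  set.seed(11)
  f <- tempfile(fileext = ".csv")
  for (k in 1:3) {
    utils::write.csv(df[sample(nrow(df)), ], f, row.names = FALSE)
    expect_equal(read_pose_table(f), ref)
  }
})

test_that("column names are case-insensitive and remappable", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Tiempo,POSE,Status,patient",
               "0:00:1,1,Wander,A", "0:00:2,2,Wander,B"), f)
  streams <- read_pose_table(f, columns = list(time = "Tiempo"))
  expect_length(streams, 2L)
  expect_equal(names(streams), c("A", "B"))
})

test_that("multi-patient CSV round-trips through write_pose_table", {
  d <- generate_dataset(generate_cohort(6, seed = 3), noise_rate = 0.2,
                        length = 20, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_pose_table(d, f)
  back <- read_pose_table(f)
  expect_length(back, length(d$streams))
  for (id in names(d$streams)) {
    expect_equal(back[[id]]$events$t, d$streams[[id]]$events$t)
    expect_equal(back[[id]]$events$pose, d$streams[[id]]$events$pose)
    expect_equal(back[[id]]$events$status, d$streams[[id]]$events$status)
  }
})

test_that("attach_individuals adds one patient plus one typed observation per event", {
  m <- schema_ontology()
  s <- pose_stream("P9", 1:3, c("C", "S", "P"))
  m2 <- attach_individuals(m, list(s))
  expect_equal(nrow(m2$individuals), nrow(m$individuals) + 4L)
  obs <- m2$individuals[grepl("^obs_", m2$individuals$name), ]
  obs <- obs[order(obs$name), ]
  expect_equal(obs$class, c("Walking", "Sitting", "Standing"))
  expect_true("patient_P9" %in% m2$individuals$name)
  # no streams: model unchanged
  expect_identical(attach_individuals(m, list()), m)
})

test_that("the printed pose table attaches with pattern types following the letters", {
  streams <- read_pose_table(table4_file())
  m <- attach_individuals(schema_ontology(), streams)
  s <- streams[[1]]
  want <- c(C = "Walking", S = "Sitting", P = "Standing")[s$events$pose]
  got <- m$individuals$class[match(paste0("obs_", s$patient_id, "_t",
                                          s$events$t),
                                   m$individuals$name)]
  expect_equal(unname(got), unname(want))
})

test_that("attach_individuals names the missing schema class", {
  # observational taxonomy has Patron/Stopped, not Pattern/Standing
  m <- build_taxonomy(alz_taxonomy("full"))
  s <- pose_stream("P1", 1:2, c("C", "S"))
  expect_error(attach_individuals(m, list(s)), "standing")
})

test_that("individuals survive an OWL export and re-parse", {
  streams <- read_pose_table(table4_file())
  m <- attach_individuals(schema_ontology(), streams)
  for (dialect in c("rdfxml", "turtle")) {
    back <- owl_parse(owl_serialize(m, dialect), dialect)
    expect_identical(back$individuals, m$individuals)
  }
})
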