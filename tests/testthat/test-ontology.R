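test_that("the observational taxonomy builds with 7 top classes and 36 leaves", {
  m <- build_taxonomy(alz_taxonomy("full"))
  counts <- ontology_counts(m)
  expect_equal(counts$n_top, 7L)
  expect_equal(counts$n_leaves, 36L)
  expect_equal(counts$n_classes, 43L)
  # the schema taxonomy carries 4 root classes and 24 subclasses
  s <- ontology_counts(build_taxonomy(alz_taxonomy("schema")))
  expect_equal(s$n_top, 4L)
  expect_equal(s$n_leaves, 24L)
})

test_that("mood state subclasses receive concept annotations", {
  m <- build_taxonomy(alz_taxonomy("full"))
  expect_setequal(names(m$annotations),
                  c("Disoriented", "Nervous", "Boring", "Wander", "Depressed"))
  expect_match(m$annotations[["Wander"]], "direction")
  s <- schema_ontology()
  expect_true("Wandered" %in% names(s$annotations))
})

test_that("an empty taxonomy yields a root-only model", {
  m <- build_taxonomy(data.frame(class = character(0),
                                 subclass = character(0)))
  expect_equal(length(m$classes), 0L)
  expect_equal(nrow(m$edges), 0L)
  expect_equal(ontology_counts(m)$n_top, 0L)
})

test_that("a subclass under two classes is rejected by name", {
  bad <- data.frame(class = c("A", "B"), subclass = c("X", "X"))
  expect_error(build_taxonomy(bad), "X")
  dup <- data.frame(class = c("A", "A"), subclass = c("X", "X"))
  expect_error(build_taxonomy(dup), "duplicate")
})

test_that("taxonomy building is order-independent and deterministic", {
  spec <- alz_taxonomy("full")
  m1 <- build_taxonomy(spec)
  set.seed(42)
  for (k in 1:5) {
    m2 <- build_taxonomy(spec[sample(nrow(spec)), , drop = FALSE])
    expect_identical(m1, m2)
  }
})

test_that("subsumption is reflexive and follows the hierarchy", {
  m <- build_taxonomy(alz_taxonomy("full"))
  expect_true(is_subclass_of(m, "Nervous", "State of mind"))
  expect_true(is_subclass_of(m, "Nervous", "Nervous"))
  expect_false(is_subclass_of(m, "Nervous", "Patron"))
  expect_true(is_subclass_of(m, "Walking", m$root))
  expect_false(is_subclass_of(m, "State of mind", "Nervous"))
  expect_error(is_subclass_of(m, "NoSuchClass", "Patron"), "NoSuchClass")
})

test_that("inferred hierarchy is the exact transitive closure", {
  # chain A < B < C: closure must contain the indirect (A, C) pair
  chain <- ontology_model("C")
  chain <- add_classes(chain, "B", "C")
  chain <- add_classes(chain, "A", "B")
  h <- inferred_hierarchy(chain)
  expect_true(any(h$child == "A" & h$ancestor == "C"))
  expect_equal(nrow(h), 3L)

  for (m in list(build_taxonomy(alz_taxonomy("full")), schema_ontology())) {
    expect_equal(inferred_hierarchy(m), closure_oracle(m$edges))
  }

  # flat model: closure equals the direct edges
  flat <- build_taxonomy(data.frame(class = c("A", "B"),
                                    subclass = c("", "")))
  h <- inferred_hierarchy(flat)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$ancestor, flat$root)
})

test_that("inferred hierarchy matches the closure oracle on random DAG-shaped models", {
  set.seed(7)
  for (k in 1:5) {
    m <- ontology_model()
    pool <- m$root
    for (i in 1:30) {
      cl <- paste0("C", k, "_", i)
      m <- add_classes(m, cl, parent = sample(pool, 1))
      pool <- c(pool, cl)
    }
    expect_equal(inferred_hierarchy(m), closure_oracle(m$edges))
  }
})

test_that("cycles and dangling references are always rejected", {
  m <- build_taxonomy(toy_taxonomy())
  broken <- m
  broken$edges <- rbind(broken$edges,
                        data.frame(child = "Patron", parent = "Walking"))
  expect_error(validate_ontology(broken), "cycle")
  orphan <- m
  orphan$individuals <- data.frame(name = "x", class = "NoSuch")
  expect_error(validate_ontology(orphan), "NoSuch")
})

test_that("OWL round-trip is the identity in both dialects", {
  models <- list(
    root_only = ontology_model("Thing"),
    taxonomy = build_taxonomy(alz_taxonomy("full")),
    schema = add_individuals(schema_ontology(),
                             c("patient_P001", "obs_P001_t1"),
                             c("Patient", "Walking")))
  for (dialect in c("rdfxml", "turtle")) {
    for (m in models) {
      doc <- owl_serialize(m, dialect)
      back <- owl_parse(doc, dialect)
      expect_identical(back$root, m$root)
      expect_identical(back$classes, m$classes)
      expect_identical(back$edges, m$edges)
      expect_identical(back$properties, m$properties)
      expect_identical(back$individuals, m$individuals)
      expect_identical(back$annotations, m$annotations)
    }
  }
})

test_that("file round-trip infers the dialect from the extension", {
  m <- schema_ontology()
  ttl <- file.path(tempdir(), "onto.ttl")
  owl <- file.path(tempdir(), "onto.owl")
  write_ontology(m, ttl, "turtle")
  write_ontology(m, owl, "rdfxml")
  expect_identical(read_ontology(ttl)$edges, m$edges)
  expect_identical(read_ontology(owl)$edges, m$edges)
})

test_that("malformed and cyclic documents are rejected on load", {
  expect_error(owl_parse("<rdf:RDF", "rdfxml"), "parse error")
  expect_error(owl_parse("not turtle at all", "turtle"), "line 1")
  cyclic <- paste(
    ":T a owl:Class .",
    ":A a owl:Class .",
    ":B a owl:Class .",
    ":A rdfs:subClassOf :B .",
    ":B rdfs:subClassOf :A .",
    sep = "\n")
  expect_error(owl_parse(cyclic, "turtle"))
})

test_that("labels with spaces and slashes survive the IRI mapping", {
  expect_equal(iri_fragment("State of mind"), "State_of_mind")
  expect_equal(iri_fragment("Sensation/Perception"), "Sensation_Perception")
  expect_equal(iri_fragment(c("a b", "a  b")), c("a_b", "a_b"))
  m <- build_taxonomy(alz_taxonomy("full"))
  back <- owl_parse(owl_serialize(m, "turtle"), "turtle")
  expect_true("Activity/Rest-Rest/Sleep" %in% back$classes)
})

test_that("schema ontology carries the at-least-one pattern restrictions", {
  m <- schema_ontology()
  p <- m$properties
  expect_true(all(p$name == "hasPattern"))
  expect_true(all(p$cardinality == "min1"))
  expect_setequal(p$range[p$domain == "Wandered"], "Walking")
  expect_setequal(p$range[p$domain == "Depressed"], "Sitting")
  expect_setequal(p$range[p$domain == "Bored"], c("Sitting", "Standing"))
})

test_that("DOT export lists every subclass edge", {
  m <- build_taxonomy(toy_taxonomy())
  dot <- export_dot(m)
  expect_match(dot, "digraph")
  expect_match(dot, "\"Walking\" -> \"Patron\"", fixed = TRUE)
})
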