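# OWL serialization of ontology_model objects.
#
# Two dialects are supported: RDF/XML (through xml2) and Turtle (written
# and parsed natively, one triple per line, restricted to the vocabulary
# this package emits: owl:Class, rdfs:subClassOf, rdfs:label,
# rdfs:comment, owl:ObjectProperty, owl:Restriction with
# owl:minQualifiedCardinality/owl:someValuesFrom, owl:NamedIndividual,
# rdf:type). Round-tripping either dialect reproduces the model's logical
# content exactly.

NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL <- "http://www.w3.org/2002/07/owl#"
NS_XSD <- "http://www.w3.org/2001/XMLSchema#"
ONTO_BASE <- "http://alzmood.org/onto#"

#' Deterministic label-to-IRI fragment mapping
#'
#' Class and individual labels may contain spaces, slashes and other
#' characters not allowed in IRI fragments; they are mapped to
#' underscore-safe fragments (runs of disallowed characters collapse to a
#' single `_`; a leading digit is prefixed with `n`). The original label is
#' preserved in `rdfs:label`, so the mapping never loses information on
#' round trip.
#'
#' @param label Character vector of labels.
#' @return Character vector of IRI fragments.
#' @export
#' @examples
#' iri_fragment("State of mind")
iri_fragment <- function(label) {
  x <- gsub("[^A-Za-z0-9_.-]+", "_", label)
  x <- gsub("^_+|_+$", "", x)
  x <- ifelse(grepl("^[0-9]", x), paste0("n", x), x)
  ifelse(nzchar(x), x, "_blank")
}

fragment_map <- function(labels) {
  frags <- iri_fragment(labels)
  if (anyDuplicated(frags)) {
    stop("label-to-IRI collision: ",
         paste(unique(labels[frags %in% frags[duplicated(frags)]]),
               collapse = ", "), call. = FALSE)
  }
  structure(frags, names = labels)
}

#' Serialize an ontology to OWL
#'
#' @param model An `ontology_model`.
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @return A single character string holding the document.
#' @seealso [owl_parse()], [write_ontology()]
#' @export
owl_serialize <- function(model, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  validate_ontology(model)
  switch(dialect,
         rdfxml = serialize_rdfxml(model),
         turtle = serialize_turtle(model))
}

#' Parse an OWL document produced by this package
#'
#' Reconstructs an `ontology_model` from RDF/XML or Turtle. The parsed
#' model is validated on load: documents declaring a cyclic subclass
#' hierarchy (or other invariant violations) are rejected. Malformed
#' documents raise a parse error carrying position information.
#'
#' @param text Document text (single string) or a file path.
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @return A validated `ontology_model`.
#' @export
owl_parse <- function(text, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  }
  model <- switch(dialect,
                  rdfxml = parse_rdfxml(text),
                  turtle = parse_turtle(text))
  model <- canonicalize_model(model)
  validate_ontology(model)
  model
}

#' Write / read an ontology file
#'
#' Convenience file wrappers around [owl_serialize()] and [owl_parse()].
#' `read_ontology()` infers the dialect from the extension (`.ttl` is
#' Turtle, anything else RDF/XML) unless given explicitly.
#'
#' @param model An `ontology_model`.
#' @param path File path.
#' @param dialect `"rdfxml"` or `"turtle"`; for `read_ontology()` `NULL`
#'   means infer from the extension.
#' @return `write_ontology()` returns `path` invisibly; `read_ontology()`
#'   the parsed model.
#' @export
write_ontology <- function(model, path, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  writeLines(owl_serialize(model, dialect), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ontology
#' @export
read_ontology <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.ttl$", path, ignore.case = TRUE)) "turtle"
               else "rdfxml"
  }
  owl_parse(path, dialect)
}

# ---- RDF/XML ---------------------------------------------------------------

serialize_rdfxml <- function(model) {
  labels <- unique(c(all_class_names(model), model$individuals$name))
  frag <- fragment_map(labels)
  uri <- function(lbl) paste0(ONTO_BASE, frag[[lbl]])

  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = NS_RDF, "xmlns:rdfs" = NS_RDFS,
    "xmlns:owl" = NS_OWL, "xmlns:xsd" = NS_XSD)
  xml2::xml_add_child(doc, "owl:Ontology",
                      "rdf:about" = sub("#$", "", ONTO_BASE))

  parents <- split(model$edges$parent, model$edges$child)
  props <- model$properties
  for (cl in c(model$root, model$classes)) {
    node <- xml2::xml_add_child(doc, "owl:Class", "rdf:about" = uri(cl))
    lab <- xml2::xml_add_child(node, "rdfs:label")
    xml2::xml_text(lab) <- cl
    for (p in sort(parents[[cl]] %||% character(0))) {
      xml2::xml_add_child(node, "rdfs:subClassOf", "rdf:resource" = uri(p))
    }
    if (cl %in% names(model$annotations)) {
      cm <- xml2::xml_add_child(node, "rdfs:comment")
      xml2::xml_text(cm) <- model$annotations[[cl]]
    }
    rows <- props[props$domain == cl, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      sc <- xml2::xml_add_child(node, "rdfs:subClassOf")
      re <- xml2::xml_add_child(sc, "owl:Restriction")
      xml2::xml_add_child(re, "owl:onProperty",
                          "rdf:resource" = paste0(ONTO_BASE,
                                                  iri_fragment(rows$name[i])))
      if (rows$cardinality[i] == "min1") {
        mc <- xml2::xml_add_child(
          re, "owl:minQualifiedCardinality",
          "rdf:datatype" = paste0(NS_XSD, "nonNegativeInteger"))
        xml2::xml_text(mc) <- "1"
        xml2::xml_add_child(re, "owl:onClass",
                            "rdf:resource" = uri(rows$range[i]))
      } else {
        xml2::xml_add_child(re, "owl:someValuesFrom",
                            "rdf:resource" = uri(rows$range[i]))
      }
    }
  }
  for (pn in unique(props$name)) {
    xml2::xml_add_child(doc, "owl:ObjectProperty",
                        "rdf:about" = paste0(ONTO_BASE, iri_fragment(pn)))
  }
  ind <- model$individuals
  for (i in seq_len(nrow(ind))) {
    node <- xml2::xml_add_child(doc, "owl:NamedIndividual",
                                "rdf:about" = uri(ind$name[i]))
    xml2::xml_add_child(node, "rdf:type", "rdf:resource" = uri(ind$class[i]))
    lab <- xml2::xml_add_child(node, "rdfs:label")
    xml2::xml_text(lab) <- ind$name[i]
  }
  as.character(doc)
}

parse_rdfxml <- function(text) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(text)),
                  error = function(e) {
                    stop("RDF/XML parse error: ", conditionMessage(e),
                         call. = FALSE)
                  })
  ns <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL)
  frag_of <- function(x) sub("^.*#", "", x)

  cls_nodes <- xml2::xml_find_all(doc, "./owl:Class", ns)
  iri_label <- character(0)
  edges_iri <- list()
  props <- list()
  annotations_iri <- character(0)
  for (node in cls_nodes) {
    iri <- frag_of(xml2::xml_attr(node, "about"))
    lab <- xml2::xml_find_first(node, "./rdfs:label", ns)
    iri_label[[iri]] <- if (inherits(lab, "xml_missing")) iri
                        else xml2::xml_text(lab)
    for (sc in xml2::xml_find_all(node, "./rdfs:subClassOf", ns)) {
      res <- xml2::xml_attr(sc, "resource")
      if (!is.na(res)) {
        edges_iri[[length(edges_iri) + 1L]] <- c(iri, frag_of(res))
        next
      }
      re <- xml2::xml_find_first(sc, "./owl:Restriction", ns)
      if (inherits(re, "xml_missing")) next
      onp <- xml2::xml_attr(
        xml2::xml_find_first(re, "./owl:onProperty", ns), "resource")
      onc <- xml2::xml_find_first(re, "./owl:onClass", ns)
      if (!inherits(onc, "xml_missing")) {
        props[[length(props) + 1L]] <-
          c(frag_of(onp), iri, frag_of(xml2::xml_attr(onc, "resource")),
            "min1")
      } else {
        sv <- xml2::xml_find_first(re, "./owl:someValuesFrom", ns)
        props[[length(props) + 1L]] <-
          c(frag_of(onp), iri, frag_of(xml2::xml_attr(sv, "resource")),
            "some")
      }
    }
    cm <- xml2::xml_find_first(node, "./rdfs:comment", ns)
    if (!inherits(cm, "xml_missing")) {
      annotations_iri[[iri]] <- xml2::xml_text(cm)
    }
  }
  prop_label <- character(0)
  for (node in xml2::xml_find_all(doc, "./owl:ObjectProperty", ns)) {
    iri <- frag_of(xml2::xml_attr(node, "about"))
    prop_label[[iri]] <- iri
  }
  ind <- list()
  for (node in xml2::xml_find_all(doc, "./owl:NamedIndividual", ns)) {
    iri <- frag_of(xml2::xml_attr(node, "about"))
    lab <- xml2::xml_find_first(node, "./rdfs:label", ns)
    name <- if (inherits(lab, "xml_missing")) iri else xml2::xml_text(lab)
    typ <- xml2::xml_attr(
      xml2::xml_find_first(node, "./rdf:type", ns), "resource")
    ind[[length(ind) + 1L]] <- c(name, frag_of(typ))
  }
  assemble_model(iri_label, edges_iri, props, annotations_iri, ind,
                 prop_label)
}

# ---- Turtle ----------------------------------------------------------------

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

serialize_turtle <- function(model) {
  labels <- unique(c(all_class_names(model), model$individuals$name))
  frag <- fragment_map(labels)
  t <- function(lbl) paste0(":", frag[[lbl]])
  lines <- c(
    paste0("@prefix rdf: <", NS_RDF, "> ."),
    paste0("@prefix rdfs: <", NS_RDFS, "> ."),
    paste0("@prefix owl: <", NS_OWL, "> ."),
    paste0("@prefix xsd: <", NS_XSD, "> ."),
    paste0("@prefix : <", ONTO_BASE, "> ."),
    "")
  for (cl in c(model$root, model$classes)) {
    lines <- c(lines,
               paste0(t(cl), " a owl:Class ."),
               paste0(t(cl), ' rdfs:label "', ttl_escape(cl), '" .'))
    if (cl %in% names(model$annotations)) {
      lines <- c(lines, paste0(t(cl), ' rdfs:comment "',
                               ttl_escape(model$annotations[[cl]]), '" .'))
    }
  }
  e <- model$edges
  lines <- c(lines, vapply(seq_len(nrow(e)), function(i) {
    paste0(t(e$child[i]), " rdfs:subClassOf ", t(e$parent[i]), " .")
  }, character(1)))
  p <- model$properties
  for (pn in unique(p$name)) {
    lines <- c(lines, paste0(":", iri_fragment(pn), " a owl:ObjectProperty ."))
  }
  lines <- c(lines, vapply(seq_len(nrow(p)), function(i) {
    inner <- if (p$cardinality[i] == "min1") {
      paste0('owl:minQualifiedCardinality "1"^^xsd:nonNegativeInteger ; ',
             "owl:onClass ", t(p$range[i]))
    } else {
      paste0("owl:someValuesFrom ", t(p$range[i]))
    }
    paste0(t(p$domain[i]), " rdfs:subClassOf [ a owl:Restriction ; ",
           "owl:onProperty :", iri_fragment(p$name[i]), " ; ", inner, " ] .")
  }, character(1)))
  ind <- model$individuals
  lines <- c(lines, unlist(lapply(seq_len(nrow(ind)), function(i) {
    c(paste0(t(ind$name[i]), " a owl:NamedIndividual ."),
      paste0(t(ind$name[i]), " rdf:type ", t(ind$class[i]), " ."),
      paste0(t(ind$name[i]), ' rdfs:label "', ttl_escape(ind$name[i]), '" .'))
  }), use.names = FALSE))
  paste(lines, collapse = "\n")
}

parse_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  iri_label <- character(0)
  ind_label <- character(0)
  class_iris <- character(0)
  ind_iris <- character(0)
  prop_label <- character(0)
  edges_iri <- list()
  props <- list()
  annotations_iri <- character(0)
  ind_type <- character(0)

  str_re <- '"((?:[^"\\\\]|\\\\.)*)"'
  for (k in seq_along(lines)) {
    ln <- trimws(lines[[k]])
    if (!nzchar(ln) || startsWith(ln, "@prefix") || startsWith(ln, "#")) next
    if (grepl("^:(\\S+) a owl:Class \\.$", ln)) {
      class_iris <- c(class_iris, sub("^:(\\S+) a owl:Class \\.$", "\\1", ln))
    } else if (grepl("^:(\\S+) a owl:ObjectProperty \\.$", ln)) {
      iri <- sub("^:(\\S+) a owl:ObjectProperty \\.$", "\\1", ln)
      prop_label[[iri]] <- iri
    } else if (grepl("^:(\\S+) a owl:NamedIndividual \\.$", ln)) {
      ind_iris <- c(ind_iris, sub("^:(\\S+) a owl:NamedIndividual \\.$",
                                  "\\1", ln))
    } else if (grepl(paste0("^:(\\S+) rdfs:label ", str_re, " \\.$"), ln)) {
      m <- regmatches(ln, regexec(paste0("^:(\\S+) rdfs:label ", str_re,
                                         " \\.$"), ln))[[1]]
      iri_label[[m[2]]] <- ttl_unescape(m[3])
    } else if (grepl(paste0("^:(\\S+) rdfs:comment ", str_re, " \\.$"), ln)) {
      m <- regmatches(ln, regexec(paste0("^:(\\S+) rdfs:comment ", str_re,
                                         " \\.$"), ln))[[1]]
      annotations_iri[[m[2]]] <- ttl_unescape(m[3])
    } else if (grepl("^:(\\S+) rdfs:subClassOf \\[", ln)) {
      m <- regmatches(ln, regexec(
        paste0("^:(\\S+) rdfs:subClassOf \\[ a owl:Restriction ; ",
               "owl:onProperty :(\\S+) ; (.*) \\] \\.$"), ln))[[1]]
      if (!length(m)) stop("Turtle parse error at line ", k, ": ", ln,
                           call. = FALSE)
      body <- m[4]
      if (grepl("minQualifiedCardinality", body)) {
        rng <- sub('^owl:minQualifiedCardinality "1"\\^\\^xsd:nonNegativeInteger ; owl:onClass :(\\S+)$',
                   "\\1", body)
        props[[length(props) + 1L]] <- c(m[3], m[2], rng, "min1")
      } else {
        rng <- sub("^owl:someValuesFrom :(\\S+)$", "\\1", body)
        props[[length(props) + 1L]] <- c(m[3], m[2], rng, "some")
      }
    } else if (grepl("^:(\\S+) rdfs:subClassOf :(\\S+) \\.$", ln)) {
      m <- regmatches(ln, regexec("^:(\\S+) rdfs:subClassOf :(\\S+) \\.$",
                                  ln))[[1]]
      edges_iri[[length(edges_iri) + 1L]] <- c(m[2], m[3])
    } else if (grepl("^:(\\S+) rdf:type :(\\S+) \\.$", ln)) {
      m <- regmatches(ln, regexec("^:(\\S+) rdf:type :(\\S+) \\.$", ln))[[1]]
      ind_type[[m[2]]] <- m[3]
    } else {
      stop("Turtle parse error at line ", k, ": ", ln, call. = FALSE)
    }
  }
  # the shared label map covers classes and individuals; split it
  class_labels <- structure(
    vapply(class_iris, function(iri) {
      if (iri %in% names(iri_label)) iri_label[[iri]] else iri
    }, character(1)),
    names = class_iris)
  ind <- lapply(ind_iris, function(iri) {
    nm <- if (iri %in% names(iri_label)) iri_label[[iri]] else iri
    if (!iri %in% names(ind_type)) {
      stop("individual without rdf:type: ", iri, call. = FALSE)
    }
    c(nm, ind_type[[iri]])
  })
  annotations_cls <- annotations_iri[names(annotations_iri) %in% class_iris]
  assemble_model(class_labels, edges_iri, props, annotations_cls, ind,
                 prop_label)
}

# Shared assembly: inputs keyed by IRI fragment, output keyed by label.
assemble_model <- function(iri_label, edges_iri, props, annotations_iri,
                           individuals, prop_label) {
  lbl <- function(iri) {
    out <- iri_label[iri]
    out[is.na(out)] <- iri[is.na(out)]
    unname(out)
  }
  children <- vapply(edges_iri, `[`, character(1), 1)
  roots <- setdiff(names(iri_label), children)
  if (length(iri_label) && length(roots) != 1L) {
    stop("document must declare exactly one parentless root class, found ",
         length(roots), call. = FALSE)
  }
  model <- ontology_model(root = if (length(iri_label)) lbl(roots) else "Thing")
  model$classes <- setdiff(lbl(names(iri_label)), model$root)
  if (length(edges_iri)) {
    model$edges <- data.frame(
      child = lbl(vapply(edges_iri, `[`, character(1), 1)),
      parent = lbl(vapply(edges_iri, `[`, character(1), 2)),
      stringsAsFactors = FALSE)
  }
  if (length(props)) {
    model$properties <- data.frame(
      name = vapply(props, `[`, character(1), 1),
      domain = lbl(vapply(props, `[`, character(1), 2)),
      range = lbl(vapply(props, `[`, character(1), 3)),
      cardinality = vapply(props, `[`, character(1), 4),
      stringsAsFactors = FALSE)
  }
  if (length(annotations_iri)) {
    model$annotations <- structure(unname(annotations_iri),
                                   names = lbl(names(annotations_iri)))
  }
  if (length(individuals)) {
    model$individuals <- data.frame(
      name = vapply(individuals, `[`, character(1), 1),
      class = lbl(vapply(individuals, `[`, character(1), 2)),
      stringsAsFactors = FALSE)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
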