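#' Create an empty ontology model
#'
#' An `ontology_model` is a lightweight in-memory OWL-style ontology: a set
#' of named classes arranged in an acyclic subclass hierarchy under a single
#' root concept (mirroring `owl:Thing`), object properties with
#' domain/range and a cardinality kind, per-class text annotations, and
#' typed individuals.
#'
#' @param root Name of the single top concept. Default `"Thing"`.
#' @return An object of class `ontology_model` with fields `root`,
#'   `classes` (character), `edges` (data.frame `child`, `parent`),
#'   `properties` (data.frame `name`, `domain`, `range`, `cardinality`),
#'   `annotations` (named character) and `individuals` (data.frame `name`,
#'   `class`).
#' @seealso [build_taxonomy()], [is_subclass_of()], [inferred_hierarchy()]
#' @export
ontology_model <- function(root = "Thing") {
  stopifnot(is.character(root), length(root) == 1L, nzchar(root))
  model <- structure(
    list(
      root = root,
      classes = character(0),
      edges = data.frame(child = character(0), parent = character(0),
                         stringsAsFactors = FALSE),
      properties = data.frame(name = character(0), domain = character(0),
                              range = character(0), cardinality = character(0),
                              stringsAsFactors = FALSE),
      annotations = character(0),
      individuals = data.frame(name = character(0), class = character(0),
                               stringsAsFactors = FALSE)
    ),
    class = "ontology_model"
  )
  model
}

all_class_names <- function(model) c(model$root, model$classes)

# Canonical ordering makes model construction order-independent: classes
# sorted, edges sorted by (parent, child), individuals by name.
canonicalize_model <- function(model) {
  model$classes <- sort(unique(model$classes), method = "radix")
  e <- unique(model$edges)
  model$edges <- e[order(e$parent, e$child, method = "radix"), , drop = FALSE]
  rownames(model$edges) <- NULL
  p <- unique(model$properties)
  model$properties <- p[order(p$name, p$domain, p$range, method = "radix"), ,
                        drop = FALSE]
  rownames(model$properties) <- NULL
  i <- model$individuals
  model$individuals <- i[order(i$name, method = "radix"), , drop = FALSE]
  rownames(model$individuals) <- NULL
  if (length(model$annotations)) {
    model$annotations <- model$annotations[
      order(names(model$annotations), method = "radix")]
  }
  model
}

#' Validate an ontology model
#'
#' Checks the structural invariants: the subclass graph is acyclic, every
#' class is reachable from the root, every individual's asserted class
#' exists, and every object property's domain and range exist. Called after
#' every mutation; violations are always errors.
#'
#' @param model An `ontology_model`.
#' @return The model, invisibly, if valid; otherwise an error.
#' @export
validate_ontology <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  known <- all_class_names(model)
  if (anyDuplicated(known)) {
    stop("duplicate class name: ",
         paste(unique(known[duplicated(known)]), collapse = ", "),
         call. = FALSE)
  }
  e <- model$edges
  bad <- setdiff(unique(c(e$child, e$parent)), known)
  if (length(bad)) {
    stop("subclass edge refers to unknown class: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (model$root %in% e$child) {
    stop("root concept cannot have a parent", call. = FALSE)
  }
  # acyclicity via Kahn-style peeling on the child -> parent graph
  if (nrow(e)) {
    remaining <- e
    repeat {
      leaves <- setdiff(remaining$child, remaining$parent)
      if (!length(leaves)) {
        if (nrow(remaining)) {
          stop("subclass hierarchy contains a cycle involving: ",
               paste(sort(unique(remaining$child)), collapse = ", "),
               call. = FALSE)
        }
        break
      }
      remaining <- remaining[!remaining$child %in% leaves, , drop = FALSE]
      if (!nrow(remaining)) break
    }
  }
  # reachability: every class must reach root via parent links
  if (length(model$classes)) {
    anc <- ancestors_table(model)
    unreachable <- model$classes[
      !vapply(model$classes, function(cl) model$root %in% anc[[cl]], logical(1))]
    if (length(unreachable)) {
      stop("class(es) not reachable from root: ",
           paste(unreachable, collapse = ", "), call. = FALSE)
    }
  }
  badp <- setdiff(unique(c(model$properties$domain, model$properties$range)), known)
  if (length(badp)) {
    stop("object property refers to unknown class: ",
         paste(badp, collapse = ", "), call. = FALSE)
  }
  badi <- setdiff(unique(model$individuals$class), known)
  if (length(badi)) {
    stop("individual asserted to unknown class: ",
         paste(badi, collapse = ", "), call. = FALSE)
  }
  bada <- setdiff(names(model$annotations), known)
  if (length(bada)) {
    stop("annotation attached to unknown class: ",
         paste(bada, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

# named list: class -> character vector of strict ancestors (BFS up the
# child -> parent edges)
ancestors_table <- function(model) {
  parents <- split(model$edges$parent, model$edges$child)
  out <- vector("list", length(all_class_names(model)))
  names(out) <- all_class_names(model)
  for (cl in names(out)) {
    seen <- character(0)
    frontier <- parents[[cl]]
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unique(unlist(parents[frontier], use.names = FALSE))
    }
    out[[cl]] <- seen
  }
  out
}

#' Add classes to an ontology model
#'
#' @param model An `ontology_model`.
#' @param classes Character vector of new class names.
#' @param parent Name of the parent class (default: the root).
#' @return The updated, validated model.
#' @export
add_classes <- function(model, classes, parent = model$root) {
  stopifnot(inherits(model, "ontology_model"), is.character(classes))
  classes <- classes[nzchar(classes)]
  dup <- intersect(classes, all_class_names(model))
  if (length(dup)) {
    stop("class already present: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!parent %in% all_class_names(model)) {
    stop("unknown parent class: ", parent, call. = FALSE)
  }
  model$classes <- c(model$classes, classes)
  model$edges <- rbind(model$edges,
                       data.frame(child = classes, parent = parent,
                                  stringsAsFactors = FALSE))
  model <- canonicalize_model(model)
  validate_ontology(model)
  model
}

#' Add an object property (with an optional cardinality restriction)
#'
#' Properties are stored per (name, domain, range) triple. A cardinality
#' kind of `"min1"` records an at-least-one restriction: every instance of
#' the domain class must relate to at least one instance of the range class
#' through the property.
#'
#' @param model An `ontology_model`.
#' @param name Property name.
#' @param domain,range Existing class names.
#' @param cardinality `"min1"` or `"some"`.
#' @return The updated, validated model.
#' @export
add_object_property <- function(model, name, domain, range,
                                cardinality = c("min1", "some")) {
  cardinality <- match.arg(cardinality)
  stopifnot(inherits(model, "ontology_model"), nzchar(name))
  model$properties <- rbind(
    model$properties,
    data.frame(name = name, domain = domain, range = range,
               cardinality = cardinality, stringsAsFactors = FALSE))
  model <- canonicalize_model(model)
  validate_ontology(model)
  model
}

#' Add typed individuals
#'
#' @param model An `ontology_model`.
#' @param names Character vector of individual names.
#' @param classes Asserted class for each individual (recycled if scalar).
#' @return The updated, validated model.
#' @export
add_individuals <- function(model, names, classes) {
  stopifnot(inherits(model, "ontology_model"))
  classes <- rep_len(classes, length(names))
  dup <- intersect(names, model$individuals$name)
  if (length(dup)) {
    stop("individual already present: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  model$individuals <- rbind(
    model$individuals,
    data.frame(name = names, class = classes, stringsAsFactors = FALSE))
  model <- canonicalize_model(model)
  validate_ontology(model)
  model
}

#' Read a two-column taxonomy table
#'
#' The taxonomy interchange format is a UTF-8 CSV with a header row and two
#' columns, `class` and `subclass`, one row per (class, subclass) pair in
#' document order.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `class` and `subclass`.
#' @seealso [alz_taxonomy()] for the taxonomies shipped with the package.
#' @export
read_taxonomy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  names(df) <- tolower(names(df))
  if (!all(c("class", "subclass") %in% names(df))) {
    stop("taxonomy CSV must have columns 'class' and 'subclass'",
         call. = FALSE)
  }
  df[, c("class", "subclass")]
}

#' Taxonomies shipped with the package
#'
#' Two fixtures are installed under `extdata/`:
#' \describe{
#'   \item{`"full"`}{the observational taxonomy: 7 classes (Patient, State
#'     of mind, Patron, Gerontological Centers, Reception/Cognition-
#'     Attention, Activity/Rest-Rest/Sleep, Nutrition) with 36 subclasses.}
#'   \item{`"schema"`}{the OWL schema taxonomy: 4 classes (Patient, Scene,
#'     Pattern, State) with 24 subclasses, the hierarchy that pose streams
#'     are attached to.}
#' }
#'
#' @param which `"full"` or `"schema"`.
#' @return A data.frame with columns `class` and `subclass`.
#' @export
#' @examples
#' nrow(alz_taxonomy("full"))
alz_taxonomy <- function(which = c("full", "schema")) {
  which <- match.arg(which)
  file <- c(full = "taxonomy_full.csv", schema = "schema_owl.csv")[[which]]
  read_taxonomy_csv(system.file("extdata", file, package = "alzmood",
                                mustWork = TRUE))
}

validate_taxonomy_table <- function(spec) {
  stopifnot(is.data.frame(spec))
  if (!all(c("class", "subclass") %in% names(spec))) {
    stop("taxonomy table needs columns 'class' and 'subclass'", call. = FALSE)
  }
  spec$class <- trimws(spec$class)
  spec$subclass <- trimws(spec$subclass)
  if (any(!nzchar(spec$class))) {
    stop("taxonomy table has an empty class name", call. = FALSE)
  }
  key <- paste(spec$class, spec$subclass, sep = "\r")
  if (anyDuplicated(key)) {
    d <- spec$subclass[duplicated(key)]
    stop("duplicate (class, subclass) pair: ", paste(d, collapse = ", "),
         call. = FALSE)
  }
  sub <- spec[nzchar(spec$subclass), , drop = FALSE]
  multi <- unique(sub$subclass[stats::ave(sub$class, sub$subclass,
                                          FUN = function(x) length(unique(x))) > 1])
  if (length(multi)) {
    stop("subclass listed under more than one class: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  spec
}

#' Build an ontology from a taxonomy table
#'
#' Each distinct `class` becomes a direct child of the root; each
#' `subclass` becomes a child of its class. Subclasses whose name denotes
#' one of the five observable moods (in any of the spelling variants used
#' across the taxonomies: Wander/Wandered, Boring/Bored, ...) receive the
#' corresponding concept annotation from [mood_annotations()].
#'
#' The build is deterministic: the same set of rows yields an identical
#' model regardless of row order.
#'
#' @param spec A data.frame with columns `class`, `subclass` (a row with an
#'   empty `subclass` declares a class with no subclasses).
#' @param annotate Attach mood concept annotations? Default `TRUE`.
#' @param root Name of the top concept.
#' @return A validated `ontology_model`.
#' @export
#' @examples
#' m <- build_taxonomy(alz_taxonomy("full"))
#' m
build_taxonomy <- function(spec, annotate = TRUE, root = "Thing") {
  spec <- validate_taxonomy_table(spec)
  model <- ontology_model(root = root)
  top <- unique(spec$class)
  sub <- spec[nzchar(spec$subclass), , drop = FALSE]
  clash <- intersect(sub$subclass, top)
  if (length(clash)) {
    stop("name used both as class and subclass: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  model$classes <- c(top, sub$subclass)
  if (length(top)) {
    model$edges <- rbind(
      data.frame(child = top, parent = root, stringsAsFactors = FALSE),
      data.frame(child = sub$subclass, parent = sub$class,
                 stringsAsFactors = FALSE))
  }
  if (annotate && nrow(sub)) {
    moods <- normalize_mood(sub$subclass)
    hit <- !is.na(moods) & moods %in% names(mood_annotations())
    if (any(hit)) {
      ann <- mood_annotations()[moods[hit]]
      names(ann) <- sub$subclass[hit]
      model$annotations <- ann
    }
  }
  model <- canonicalize_model(model)
  validate_ontology(model)
  model
}

#' Subsumption query
#'
#' Is class `a` subsumed by class `b`? True iff `b` is reachable from `a`
#' via subclass edges; the relation is reflexive (`a` is a subclass of
#' itself).
#'
#' @param model An `ontology_model`.
#' @param a,b Class names present in the model.
#' @return Logical scalar.
#' @export
#' @examples
#' m <- build_taxonomy(alz_taxonomy("full"))
#' is_subclass_of(m, "Nervous", "State of mind")
is_subclass_of <- function(model, a, b) {
  stopifnot(inherits(model, "ontology_model"))
  known <- all_class_names(model)
  for (x in c(a, b)) {
    if (!x %in% known) stop("unknown class: ", x, call. = FALSE)
  }
  if (a == b) return(TRUE)
  b %in% ancestors_table(model)[[a]]
}

#' Inferred subclass hierarchy
#'
#' The transitive closure of the subclass edges: every (child, ancestor)
#' pair with the ancestor reachable through one or more edges. Reflexive
#' pairs are not included.
#'
#' @param model An `ontology_model`.
#' @return A data.frame with columns `child` and `ancestor`, sorted.
#' @export
inferred_hierarchy <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  anc <- ancestors_table(model)
  anc <- anc[lengths(anc) > 0]
  out <- data.frame(
    child = rep(names(anc), lengths(anc)),
    ancestor = unlist(anc, use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- out[order(out$child, out$ancestor, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count top-level classes and leaf subclasses
#'
#' @param model An `ontology_model`.
#' @return List with `n_top` (direct children of the root), `n_leaves`
#'   (classes with no subclasses), and `n_classes` (all classes except the
#'   root).
#' @export
ontology_counts <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  list(
    n_top = sum(model$edges$parent == model$root),
    n_leaves = length(setdiff(model$classes, model$edges$parent)),
    n_classes = length(model$classes)
  )
}

#' @export
print.ontology_model <- function(x, ...) {
  n <- ontology_counts(x)
  cat("<ontology_model> root:", x$root, "\n")
  cat("  classes:     ", n$n_classes, " (", n$n_top, " top-level, ",
      n$n_leaves, " leaves)\n", sep = "")
  cat("  properties:  ", nrow(x$properties), "\n", sep = "")
  cat("  individuals: ", nrow(x$individuals), "\n", sep = "")
  cat("  annotations: ", length(x$annotations), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ontology_model <- function(object, ...) {
  top <- sort(object$edges$child[object$edges$parent == object$root])
  kids <- vapply(top, function(cl) sum(object$edges$parent == cl), integer(1))
  out <- list(counts = ontology_counts(object),
              top_classes = data.frame(class = top, n_subclasses = kids,
                                       row.names = NULL))
  class(out) <- "summary.ontology_model"
  out
}

#' @export
print.summary.ontology_model <- function(x, ...) {
  cat("Top-level classes (", x$counts$n_top, "), ",
      x$counts$n_classes, " classes in total:\n", sep = "")
  print(x$top_classes, row.names = FALSE)
  invisible(x)
}

#' Build the OWL schema ontology with state-pattern axioms
#'
#' Builds the schema taxonomy (Patient, Scene, Pattern, State) and adds the
#' at-least-one object property `hasPattern` from each State subclass to
#' its allowed Pattern subclasses, as minimum-cardinality-1 restrictions:
#' bored, disoriented and nervous with sitting and standing; depressed with
#' sitting; wandered with walking.
#'
#' @param rules State rules supplying the allowed patterns per mood;
#'   default [default_state_rules()].
#' @return A validated `ontology_model`.
#' @export
#' @examples
#' m <- schema_ontology()
#' subset(m$properties, domain == "Wandered")
schema_ontology <- function(rules = default_state_rules()) {
  model <- build_taxonomy(alz_taxonomy("schema"))
  states <- model$edges$child[model$edges$parent == "State"]
  patterns <- model$edges$child[model$edges$parent == "Pattern"]
  pat_by_name <- structure(patterns, names = tolower(patterns))
  for (st in states) {
    mood <- normalize_mood(st)
    rule <- Filter(function(r) r$mood == mood, rules)
    if (!length(rule)) next
    for (p in rule[[1]]$patterns) {
      model <- add_object_property(model, "hasPattern", st,
                                   pat_by_name[[p]], "min1")
    }
  }
  model
}

#' Export an ontology as a DOT graph
#'
#' Writes a Graphviz DOT rendering of the subclass hierarchy (solid edges)
#' and object properties (dashed, labelled edges) for static visualization.
#'
#' @param model An `ontology_model`.
#' @param path Output file; if `NULL`, the DOT text is returned invisibly
#'   without writing.
#' @return The DOT source, invisibly.
#' @export
export_dot <- function(model, path = NULL) {
  stopifnot(inherits(model, "ontology_model"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph ontology {", "  rankdir=BT;",
             paste0("  ", q(model$root), " [shape=box];"))
  if (nrow(model$edges)) {
    lines <- c(lines, paste0("  ", q(model$edges$child), " -> ",
                             q(model$edges$parent), ";"))
  }
  if (nrow(model$properties)) {
    lines <- c(lines, paste0("  ", q(model$properties$domain), " -> ",
                             q(model$properties$range),
                             " [style=dashed, label=",
                             q(model$properties$name), "];"))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
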