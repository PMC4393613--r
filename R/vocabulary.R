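#' Controlled-vocabulary term
#'
#' A term is the atomic unit of the controlled vocabulary from which
#' phenotyping schemes are built. Terms come in three kinds: `entity`
#' (the biological object scored, e.g. leaf, plot), `attribute` (the
#' trait measured, e.g. plant height) and `value` (one category of a
#' categorical attribute, e.g. a senescence stage). Entities are
#' typically cross-referenced to the Plant Ontology (PO) and attributes
#' to the Plant Trait Ontology (TO) via a CURIE, which keeps the link to
#' the original ontology source.
#'
#' @param term_id opaque stable identifier, unique within a registry.
#' @param kind one of `"entity"`, `"attribute"`, `"value"`.
#' @param labels named character vector of display labels, names are
#'   BCP-47 two-letter language codes; at least one entry.
#' @param ontology_ref optional CURIE string (e.g. `"PO:0025034"`).
#' @param definition optional free-text definition.
#' @param unit optional unit string; only meaningful for attributes.
#' @return An object of class `pheno_term`.
#' @examples
#' term("e.leaf", "entity", c(en = "leaf", de = "Blatt"), ontology_ref = "PO:0025034")
#' @export
term <- function(term_id, kind, labels, ontology_ref = NULL,
                 definition = NULL, unit = NULL) {
  pheno_assert(is.character(term_id) && length(term_id) == 1L && nzchar(term_id),
               "validation_error", "term_id must be a non-empty string")
  pheno_assert(kind %in% c("entity", "attribute", "value"),
               "validation_error", paste0("unknown term kind: ", kind))
  labels <- unlist(labels)
  pheno_assert(length(labels) >= 1L && !is.null(names(labels)) &&
                 all(nzchar(names(labels))) && all(nzchar(labels)),
               "validation_error", "labels must be a non-empty named character vector")
  if (!is.null(ontology_ref)) {
    pheno_assert(is_curie(ontology_ref), "validation_error",
                 paste0("malformed CURIE: ", ontology_ref))
  }
  if (!is.null(unit)) {
    pheno_assert(kind == "attribute", "validation_error",
                 "unit is only allowed on attribute terms")
  }
  structure(
    list(term_id = term_id, kind = kind,
         labels = labels[order(names(labels))],
         ontology_ref = ontology_ref, definition = definition, unit = unit),
    class = "pheno_term"
  )
}

#' @export
print.pheno_term <- function(x, ...) {
  cat(sprintf("<term %s [%s]%s> %s\n", x$term_id, x$kind,
              if (is.null(x$ontology_ref)) "" else paste0(" ", x$ontology_ref),
              paste(sprintf("%s:%s", names(x$labels), x$labels), collapse = ", ")))
  invisible(x)
}

#' Reference to an illustrating image
#'
#' Categorical value terms can carry an image that the capture layer may
#' display next to the value choice. The registry stores only a
#' reference (path or URI) plus a SHA-256 checksum of the referenced
#' bytes, so the link stays verifiable.
#'
#' @param href path or URI of the image.
#' @param checksum hex digest of the image bytes; computed from `href`
#'   when the file exists and `checksum` is omitted.
#' @return An object of class `image_ref`.
#' @export
image_ref <- function(href, checksum = NULL) {
  pheno_assert(is.character(href) && nzchar(href), "validation_error",
               "image href must be non-empty")
  if (is.null(checksum)) {
    pheno_assert(file.exists(href), "not_found_error",
                 "checksum omitted and image file not found")
    checksum <- sha256_file(href)
  }
  structure(list(href = href, checksum = checksum), class = "image_ref")
}

#' Create an empty term registry
#'
#' The registry is the single source of the controlled vocabulary:
#' terms, project-specific subsets (which restrict what a project's
#' schemes may use), and images illustrating categorical values.
#'
#' @param default_language language code used for label fallback
#'   (default `"en"`).
#' @return An object of class `term_registry`.
#' @seealso [add_term()], [define_subset()], [attach_image()], [mirror()]
#' @export
term_registry <- function(default_language = "en") {
  structure(
    list(terms = list(), subsets = list(), images = list(),
         default_language = default_language),
    class = "term_registry"
  )
}

#' @export
print.term_registry <- function(x, ...) {
  kinds <- vapply(x$terms, `[[`, "", "kind")
  cat(sprintf("<term_registry: %d terms (%d entity, %d attribute, %d value), %d subsets, default '%s'>\n",
              length(x$terms), sum(kinds == "entity"), sum(kinds == "attribute"),
              sum(kinds == "value"), length(x$subsets), x$default_language))
  invisible(x)
}

#' Add a new term to a registry
#'
#' @param registry a [term_registry()].
#' @param term a [term()]; its `term_id` must not be present yet
#'   (use [update_term()] to modify an existing term).
#' @return The updated registry.
#' @export
add_term <- function(registry, term) {
  stopifnot(inherits(registry, "term_registry"), inherits(term, "pheno_term"))
  pheno_assert(!term$term_id %in% names(registry$terms), "conflict_error",
               paste0("term already exists: ", term$term_id))
  registry$terms[[term$term_id]] <- term
  registry
}

#' Update labels, definition or unit of an existing term
#'
#' `kind` and `term_id` are immutable; labels, definition and unit may
#' change over a vocabulary's life.
#'
#' @inheritParams add_term
#' @param term replacement [term()] with the same `term_id` and `kind`.
#' @return The updated registry.
#' @export
update_term <- function(registry, term) {
  stopifnot(inherits(registry, "term_registry"), inherits(term, "pheno_term"))
  old <- registry$terms[[term$term_id]]
  pheno_assert(!is.null(old), "not_found_error",
               paste0("unknown term: ", term$term_id))
  pheno_assert(old$kind == term$kind, "validation_error",
               "term kind is immutable")
  registry$terms[[term$term_id]] <- term
  registry
}

get_term <- function(registry, term_id) {
  t <- registry$terms[[term_id]]
  pheno_assert(!is.null(t), "not_found_error", paste0("unknown term: ", term_id))
  t
}

#' Resolve a term label in a requested language
#'
#' Lookup order: requested language, then the registry default language,
#' then the first remaining language by sorted code — so resolution
#' always succeeds for any term with at least one label. This backs the
#' language-switch behaviour of composed schemes and exports.
#'
#' @param registry a [term_registry()].
#' @param term_id id of an existing term.
#' @param language BCP-47 two-letter code; defaults to the registry
#'   default language.
#' @return The display label (character scalar).
#' @export
resolve_label <- function(registry, term_id, language = registry$default_language) {
  t <- get_term(registry, term_id)
  for (lang in c(language, registry$default_language)) {
    if (lang %in% names(t$labels)) return(unname(t$labels[[lang]]))
  }
  unname(t$labels[[1L]])  # labels are stored sorted by language code
}

#' Define a project-specific vocabulary subset
#'
#' A subset restricts scheme composition for that project to the listed
#' terms, which keeps large institutional vocabularies manageable for
#' individual projects. An empty subset is valid and forbids any
#' composition for the project.
#'
#' @param registry a [term_registry()].
#' @param project_id project the subset applies to.
#' @param term_ids character vector of existing term ids (may be empty).
#' @return The updated registry.
#' @export
define_subset <- function(registry, project_id, term_ids) {
  stopifnot(inherits(registry, "term_registry"))
  term_ids <- unique(as.character(term_ids))
  missing <- setdiff(term_ids, names(registry$terms))
  pheno_assert(length(missing) == 0L, "not_found_error",
               paste0("unknown term(s) in subset: ", paste(missing, collapse = ", ")))
  registry$subsets[[project_id]] <- term_ids
  registry
}

#' Attach an illustrating image to a categorical value term
#'
#' Re-attaching replaces the previous reference (last write wins).
#' Exported schemes carry the reference so devices can display it.
#'
#' @param registry a [term_registry()].
#' @param value_term_id id of a `value`-kind term.
#' @param image an [image_ref()].
#' @return The updated registry.
#' @export
attach_image <- function(registry, value_term_id, image) {
  stopifnot(inherits(registry, "term_registry"), inherits(image, "image_ref"))
  t <- get_term(registry, value_term_id)
  pheno_assert(t$kind == "value", "kind_error",
               paste0("images attach only to value terms; '", value_term_id,
                      "' is of kind ", t$kind))
  registry$images[[value_term_id]] <- image
  registry
}

#' Mirror a registry
#'
#' Produces a value-equal, independent copy with identical term ids
#' (primary keys preserved), the operation used to replicate the
#' vocabulary from the scheme database into each results database so
#' results remain interpretable without access to the source.
#'
#' @param source a [term_registry()].
#' @return A new registry, value-equal to `source`.
#' @export
mirror <- function(source) {
  stopifnot(inherits(source, "term_registry"))
  structure(unserialize(serialize(source, NULL)), class = "term_registry")
}

# ---- persistence (vocabulary.xml) -----------------------------------------

#' Write a registry to its XML persistence format
#'
#' One document holds terms (with per-language labels), project subsets
#' and image references; see `docs/formats.md` for the layout.
#'
#' @param registry a [term_registry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
registry_to_xml <- function(registry, path) {
  stopifnot(inherits(registry, "term_registry"))
  doc <- xml2::xml_new_root("vocabulary",
                            default_language = registry$default_language)
  for (id in sort(names(registry$terms))) {
    t <- registry$terms[[id]]
    node <- xml2::xml_add_child(doc, "term", id = t$term_id, kind = t$kind)
    if (!is.null(t$ontology_ref)) xml2::xml_set_attr(node, "ontology_ref", t$ontology_ref)
    if (!is.null(t$unit)) xml2::xml_set_attr(node, "unit", t$unit)
    for (lang in names(t$labels)) {
      xml2::xml_add_child(node, "label", t$labels[[lang]], lang = lang)
    }
    if (!is.null(t$definition)) xml2::xml_add_child(node, "definition", t$definition)
    img <- registry$images[[id]]
    if (!is.null(img)) {
      xml2::xml_add_child(node, "image", href = img$href, checksum = img$checksum)
    }
  }
  for (pid in sort(names(registry$subsets))) {
    sub <- xml2::xml_add_child(doc, "subset", project = pid)
    for (tid in sort(registry$subsets[[pid]])) {
      xml2::xml_add_child(sub, "member", ref = tid)
    }
  }
  write_doc(doc, path)
  invisible(path)
}

#' Read a registry from its XML persistence format
#'
#' @param path path to a `vocabulary.xml` written by [registry_to_xml()].
#' @return A [term_registry()].
#' @export
registry_from_xml <- function(path) {
  pheno_assert(file.exists(path), "not_found_error", paste0("no such file: ", path))
  doc <- xml2::read_xml(path)
  reg <- term_registry(default_language = xml2::xml_attr(doc, "default_language"))
  for (node in xml2::xml_find_all(doc, "./term")) {
    labs <- xml2::xml_find_all(node, "./label")
    labels <- setNames(xml2::xml_text(labs), xml2::xml_attr(labs, "lang"))
    def <- xml2::xml_find_first(node, "./definition")
    reg <- add_term(reg, term(
      term_id = xml2::xml_attr(node, "id"),
      kind = xml2::xml_attr(node, "kind"),
      labels = labels,
      ontology_ref = xattr(node, "ontology_ref"),
      definition = if (inherits(def, "xml_missing")) NULL else xml2::xml_text(def),
      unit = xattr(node, "unit")
    ))
    img <- xml2::xml_find_first(node, "./image")
    if (!inherits(img, "xml_missing")) {
      reg <- attach_image(reg, xml2::xml_attr(node, "id"),
                          image_ref(xml2::xml_attr(img, "href"),
                                    xml2::xml_attr(img, "checksum")))
    }
  }
  for (sub in xml2::xml_find_all(doc, "./subset")) {
    members <- xml2::xml_attr(xml2::xml_find_all(sub, "./member"), "ref")
    reg <- define_subset(reg, xml2::xml_attr(sub, "project"), members)
  }
  reg
}
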