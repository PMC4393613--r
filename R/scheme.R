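#' Scheme parameter
#'
#' One measured variable inside an entity block: either numeric (free
#' value entry with an optional unit) or categorical (value chosen from
#' an ordered domain of value-term ids).
#'
#' @param attribute_id id of an `attribute`-kind term.
#' @param datatype `"numeric"` or `"categorical"`.
#' @param unit optional unit text; numeric parameters only. Defaults to
#'   the attribute term's unit at composition time when omitted.
#' @param domain ordered character vector of `value`-kind term ids;
#'   required (non-empty) for categorical, forbidden for numeric.
#' @param required whether the capture layer should treat the parameter
#'   as mandatory.
#' @return An object of class `pheno_parameter`.
#' @export
parameter <- function(attribute_id, datatype, unit = NULL, domain = NULL,
                      required = FALSE) {
  pheno_assert(is.character(attribute_id) && nzchar(attribute_id),
               "validation_error", "attribute_id must be non-empty")
  pheno_assert(datatype %in% c("numeric", "categorical"), "validation_error",
               paste0("unsupported datatype: ", datatype))
  if (datatype == "categorical") {
    pheno_assert(length(domain) >= 1L, "validation_error",
                 "categorical parameter needs a non-empty domain")
    pheno_assert(is.null(unit), "validation_error",
                 "unit is only allowed on numeric parameters")
    pheno_assert(!anyDuplicated(domain), "validation_error",
                 "duplicate value ids in domain")
  } else {
    pheno_assert(is.null(domain), "validation_error",
                 "numeric parameter must not carry a domain")
  }
  structure(list(attribute_id = attribute_id, datatype = datatype,
                 unit = unit, domain = if (is.null(domain)) NULL else as.character(domain),
                 required = isTRUE(required)),
            class = "pheno_parameter")
}

#' Entity block of a scheme
#'
#' Ordered group of parameters all scored on the same entity; on the
#' capture device each block becomes one input page.
#'
#' @param entity_id id of an `entity`-kind term.
#' @param parameters list of [parameter()]s (at least one); attribute
#'   ids must be unique within the block.
#' @return An object of class `entity_block`.
#' @export
entity_block <- function(entity_id, parameters) {
  pheno_assert(is.character(entity_id) && nzchar(entity_id),
               "validation_error", "entity_id must be non-empty")
  pheno_assert(length(parameters) >= 1L &&
                 all(vapply(parameters, inherits, TRUE, "pheno_parameter")),
               "validation_error", "parameters must be a non-empty list of parameter()")
  ids <- vapply(parameters, `[[`, "", "attribute_id")
  pheno_assert(!anyDuplicated(ids), "conflict_error",
               paste0("duplicate attribute in entity block: ",
                      paste(ids[duplicated(ids)], collapse = ", ")))
  structure(list(entity_id = entity_id, parameters = parameters),
            class = "entity_block")
}

snapshot_entry <- function(registry, term_id, language) {
  t <- get_term(registry, term_id)
  list(term_id = t$term_id, kind = t$kind,
       label = resolve_label(registry, term_id, language),
       ontology_ref = t$ontology_ref, unit = t$unit)
}

#' Compose a phenotyping scheme
#'
#' Builds a self-contained scheme from registry terms: ordered entity
#' blocks, each with ordered parameters, plus an embedded snapshot of
#' the labels, ontology CURIEs, units and value images of exactly the
#' referenced terms. The snapshot makes exported scheme files usable on
#' devices with no registry (or network) access. Labels are resolved in
#' the scheme language at composition time.
#'
#' When `project_id` is given and the registry defines a subset for that
#' project, every referenced term must lie in the subset.
#'
#' @param registry a [term_registry()].
#' @param name display name (duplicates allowed; `scheme_id` is the identity).
#' @param owner user id of the scheme owner.
#' @param blocks ordered list of [entity_block()]s.
#' @param project_id optional project whose vocabulary subset applies.
#' @param language scheme display language (default: registry default).
#' @param clock time source for the creation timestamp.
#' @return An object of class `pheno_scheme`.
#' @export
compose_scheme <- function(registry, name, owner, blocks, project_id = NULL,
                           language = registry$default_language,
                           clock = system_clock) {
  stopifnot(inherits(registry, "term_registry"))
  pheno_assert(length(blocks) >= 1L &&
                 all(vapply(blocks, inherits, TRUE, "entity_block")),
               "validation_error", "blocks must be a non-empty list of entity_block()")

  subset_ids <- NULL
  if (!is.null(project_id)) {
    subset_ids <- registry$subsets[[project_id]]
    pheno_assert(!is.null(subset_ids), "not_found_error",
                 paste0("no vocabulary subset defined for project: ", project_id))
  }
  check_subset <- function(id) {
    if (!is.null(subset_ids) && !id %in% subset_ids) {
      pheno_error("subset_violation_error",
                  paste0("term '", id, "' is not in the vocabulary subset of project '",
                         project_id, "'"))
    }
  }
  check_kind <- function(id, kind) {
    t <- get_term(registry, id)
    pheno_assert(t$kind == kind, "validation_error",
                 paste0("term '", id, "' has kind ", t$kind, ", expected ", kind))
  }

  snap_terms <- list()
  snap_images <- list()
  pairs <- character()
  blocks <- lapply(blocks, function(b) {
    check_kind(b$entity_id, "entity"); check_subset(b$entity_id)
    snap_terms[[b$entity_id]] <<- snapshot_entry(registry, b$entity_id, language)
    b$parameters <- lapply(b$parameters, function(p) {
      check_kind(p$attribute_id, "attribute"); check_subset(p$attribute_id)
      key <- paste0(b$entity_id, "\n", p$attribute_id)
      pheno_assert(!key %in% pairs, "conflict_error",
                   paste0("duplicate (entity, attribute) pair: ",
                          b$entity_id, " / ", p$attribute_id))
      pairs <<- c(pairs, key)
      entry <- snapshot_entry(registry, p$attribute_id, language)
      # numeric parameters inherit the attribute term's unit when none given;
      # the snapshot mirrors the parameter so scheme files stay self-consistent
      if (p$datatype == "numeric" && is.null(p$unit)) {
        p["unit"] <- list(entry$unit)   # keep the element even when NULL
      }
      entry["unit"] <- list(p$unit)
      snap_terms[[p$attribute_id]] <<- entry
      for (v in p$domain) {
        check_kind(v, "value"); check_subset(v)
        snap_terms[[v]] <<- snapshot_entry(registry, v, language)
        img <- registry$images[[v]]
        if (!is.null(img)) snap_images[[v]] <<- img
      }
      p
    })
    b
  })

  structure(
    list(scheme_id = new_id(), name = name, owner = owner,
         language = language, created = clock(), blocks = blocks,
         snapshot = list(terms = snap_terms, images = snap_images)),
    class = "pheno_scheme"
  )
}

#' @export
print.pheno_scheme <- function(x, ...) {
  np <- sum(vapply(x$blocks, function(b) length(b$parameters), 1L))
  cat(sprintf("<phenotyping scheme '%s' (%s)>\n  owner: %s, language: %s, created: %s\n  %d entities, %d parameters\n",
              x$name, x$scheme_id, x$owner, x$language, fmt_ts(x$created),
              length(x$blocks), np))
  invisible(x)
}

scheme_pairs <- function(scheme) {
  do.call(rbind, lapply(scheme$blocks, function(b) {
    data.frame(entity_id = b$entity_id,
               attribute_id = vapply(b$parameters, `[[`, "", "attribute_id"),
               stringsAsFactors = FALSE)
  }))
}

scheme_parameter <- function(scheme, entity_id, attribute_id) {
  for (b in scheme$blocks) {
    if (b$entity_id == entity_id) {
      for (p in b$parameters) if (p$attribute_id == attribute_id) return(p)
    }
  }
  NULL
}

#' Clone a scheme
#'
#' Deep copy with fresh id, name, owner and creation timestamp; blocks
#' and snapshot are value-equal to the source. Cloning is the supported
#' way to derive a modified scheme without touching another user's
#' original.
#'
#' @param scheme a [compose_scheme()] result.
#' @param new_name name for the clone.
#' @param new_owner owner for the clone.
#' @param clock time source for the clone's creation timestamp.
#' @return A new `pheno_scheme`.
#' @export
clone_scheme <- function(scheme, new_name, new_owner, clock = system_clock) {
  stopifnot(inherits(scheme, "pheno_scheme"))
  out <- unserialize(serialize(scheme, NULL))
  out$scheme_id <- new_id()
  out$name <- new_name
  out$owner <- new_owner
  out$created <- clock()
  out
}

# ---- XML interchange -------------------------------------------------------

scheme_xsd_path <- function() {
  system.file("xsd", "scheme.xsd", package = "phenotyper", mustWork = TRUE)
}
results_xsd_path <- function() {
  system.file("xsd", "results.xsd", package = "phenotyper", mustWork = TRUE)
}

#' Serialize a scheme to its XML interchange format
#'
#' The document is self-contained (labels, CURIEs, units, value domains
#' and image references are embedded), validates against the shipped
#' `scheme.xsd`, and is written canonically — serializing the same
#' scheme twice yields byte-identical output.
#'
#' @param scheme a `pheno_scheme`.
#' @param path optional output file; when omitted only the document is
#'   returned.
#' @return An `xml2::xml_document`, invisibly when `path` is given.
#' @export
scheme_to_xml <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "pheno_scheme"))
  snap <- scheme$snapshot$terms
  doc <- xml2::xml_new_root("phenotyping_scheme",
                            id = scheme$scheme_id, name = scheme$name,
                            owner = scheme$owner, language = scheme$language,
                            created = fmt_ts(scheme$created))
  for (b in scheme$blocks) {
    ent <- snap[[b$entity_id]]
    enode <- xml2::xml_add_child(doc, "entity", id = b$entity_id)
    if (!is.null(ent$ontology_ref)) xml2::xml_set_attr(enode, "ontology_ref", ent$ontology_ref)
    xml2::xml_add_child(enode, "label", ent$label)
    for (p in b$parameters) {
      att <- snap[[p$attribute_id]]
      pnode <- xml2::xml_add_child(enode, "parameter", id = p$attribute_id)
      if (!is.null(att$ontology_ref)) xml2::xml_set_attr(pnode, "ontology_ref", att$ontology_ref)
      xml2::xml_set_attr(pnode, "datatype", p$datatype)
      if (!is.null(p$unit)) xml2::xml_set_attr(pnode, "unit", p$unit)
      xml2::xml_set_attr(pnode, "required", tolower(as.character(p$required)))
      xml2::xml_add_child(pnode, "label", att$label)
      for (v in p$domain) {
        vnode <- xml2::xml_add_child(pnode, "value", id = v)
        img <- scheme$snapshot$images[[v]]
        if (!is.null(img)) {
          xml2::xml_set_attr(vnode, "image", img$href)
          xml2::xml_set_attr(vnode, "image_checksum", img$checksum)
        }
        xml2::xml_add_child(vnode, "label", snap[[v]]$label)
      }
    }
  }
  if (!is.null(path)) {
    write_doc(doc, path)
    return(invisible(doc))
  }
  doc
}

as_xml_input <- function(x) {
  if (inherits(x, "xml_node")) return(x)
  pheno_assert(is.character(x) && length(x) == 1L, "validation_error",
               "expected a file path or xml_document")
  pheno_assert(file.exists(x), "not_found_error", paste0("no such file: ", x))
  tryCatch(xml2::read_xml(x),
           error = function(e) pheno_error("validation_error",
                                           paste0("not well-formed XML: ", conditionMessage(e))))
}

finding <- function(severity, path, message) {
  data.frame(severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

empty_findings <- function() finding(character(), character(), character())[0, ]

validation_report <- function(findings) {
  structure(list(ok = !any(findings$severity == "error"), findings = findings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation report: %s, %d finding(s)>\n",
              if (x$ok) "ok" else "NOT ok", nrow(x$findings)))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s: %s\n", x$findings$severity[i],
                  x$findings$path[i], x$findings$message[i]))
    }
  }
  invisible(x)
}

xsd_findings <- function(doc, xsd_path) {
  if (!inherits(doc, "xml_document")) {
    doc <- xml2::read_xml(as.character(doc))  # detach embedded node
  }
  schema <- xml2::read_xml(xsd_path)
  ok <- xml2::xml_validate(doc, schema)
  if (isTRUE(ok)) return(empty_findings())
  msgs <- attr(ok, "errors")
  do.call(rbind, lapply(msgs, function(m) finding("error", "schema", m)))
}

#' Validate a scheme document
#'
#' Accepts arbitrary input and never raises: every problem becomes a
#' finding. The document is checked for well-formedness, conformance to
#' the shipped scheme XSD, and internal consistency (categorical
#' parameters carry a domain, numeric ones do not, no duplicate
#' (entity, attribute) pairs or domain value ids).
#'
#' @param x file path or `xml2::xml_document`.
#' @return A `validation_report` with fields `ok` and `findings`.
#' @export
validate_scheme_document <- function(x) {
  doc <- tryCatch(as_xml_input(x), error = function(e) e)
  if (inherits(doc, "error")) {
    return(validation_report(finding("error", "/", conditionMessage(doc))))
  }
  f <- xsd_findings(doc, scheme_xsd_path())
  if (!any(f$severity == "error")) {
    pairs <- character()
    for (enode in xml2::xml_find_all(doc, "./entity")) {
      eid <- xml2::xml_attr(enode, "id")
      for (pnode in xml2::xml_find_all(enode, "./parameter")) {
        aid <- xml2::xml_attr(pnode, "id")
        epath <- sprintf("/phenotyping_scheme/entity[@id='%s']/parameter[@id='%s']", eid, aid)
        key <- paste0(eid, "\n", aid)
        if (key %in% pairs) {
          f <- rbind(f, finding("error", epath, "duplicate (entity, attribute) pair"))
        }
        pairs <- c(pairs, key)
        dt <- xml2::xml_attr(pnode, "datatype")
        vals <- xml2::xml_attr(xml2::xml_find_all(pnode, "./value"), "id")
        if (dt == "categorical" && length(vals) == 0L) {
          f <- rbind(f, finding("error", epath,
                                "categorical parameter without domain values"))
        }
        if (dt == "numeric" && length(vals) > 0L) {
          f <- rbind(f, finding("error", epath,
                                "numeric parameter must not carry domain values"))
        }
        if (anyDuplicated(vals)) {
          f <- rbind(f, finding("error", epath, "duplicate value ids in domain"))
        }
      }
    }
  }
  validation_report(f)
}

#' Read a scheme from its XML interchange format
#'
#' The document must validate (see [validate_scheme_document()]);
#' blocks, order, datatypes, domains and the embedded term snapshot are
#' reconstructed exactly.
#'
#' @param x file path or `xml2::xml_document`.
#' @return A `pheno_scheme`.
#' @export
scheme_from_xml <- function(x) {
  doc <- as_xml_input(x)
  rep <- validate_scheme_document(doc)
  if (!rep$ok) {
    pheno_error("validation_error",
                paste0("invalid scheme document:\n",
                       paste(sprintf("  [%s] %s: %s", rep$findings$severity,
                                     rep$findings$path, rep$findings$message),
                             collapse = "\n")),
                report = rep)
  }

  snap_terms <- list()
  snap_images <- list()
  note <- function(id, kind, node, unit = NULL) {
    lab <- xml2::xml_text(xml2::xml_find_first(node, "./label"))
    snap_terms[[id]] <<- list(term_id = id, kind = kind, label = lab,
                              ontology_ref = xattr(node, "ontology_ref"),
                              unit = unit)
  }
  blocks <- lapply(xml2::xml_find_all(doc, "./entity"), function(enode) {
    eid <- xml2::xml_attr(enode, "id")
    note(eid, "entity", enode)
    params <- lapply(xml2::xml_find_all(enode, "./parameter"), function(pnode) {
      aid <- xml2::xml_attr(pnode, "id")
      unit <- xattr(pnode, "unit")
      note(aid, "attribute", pnode, unit = unit)
      vnodes <- xml2::xml_find_all(pnode, "./value")
      domain <- NULL
      if (length(vnodes)) {
        domain <- xml2::xml_attr(vnodes, "id")
        for (vnode in vnodes) {
          vid <- xml2::xml_attr(vnode, "id")
          note(vid, "value", vnode)
          href <- xattr(vnode, "image")
          if (!is.null(href)) {
            snap_images[[vid]] <<- image_ref(href, xml2::xml_attr(vnode, "image_checksum"))
          }
        }
      }
      parameter(aid, xml2::xml_attr(pnode, "datatype"), unit = unit,
                domain = domain,
                required = identical(xml2::xml_attr(pnode, "required"), "true"))
    })
    entity_block(eid, params)
  })

  structure(
    list(scheme_id = xml2::xml_attr(doc, "id"),
         name = xml2::xml_attr(doc, "name"),
         owner = xml2::xml_attr(doc, "owner"),
         language = xml2::xml_attr(doc, "language"),
         created = parse_ts(xml2::xml_attr(doc, "created")),
         blocks = blocks,
         snapshot = list(terms = snap_terms, images = snap_images)),
    class = "pheno_scheme"
  )
}
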