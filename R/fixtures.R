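# Deterministic generators for vocabularies, schemes and capture
# sessions. Everything is a pure function of its FixtureSpec: one seed
# drives separate, stably-derived sub-streams (vocabulary, scheme,
# session), so adding a generator never perturbs existing fixtures and
# identical specs yield byte-identical artifacts.

#' Fixture generation specification
#'
#' @param seed integer RNG seed; identical specs produce byte-identical
#'   fixtures.
#' @param n_entities,n_attributes number of entity and attribute terms.
#' @param n_values_per_categorical domain size of categorical parameters.
#' @param fraction_categorical proportion of attributes scored
#'   categorically, in `[0, 1]`.
#' @param n_objects number of base identifiers opened per session.
#' @param multiplication identifier multiplication factor.
#' @param missing_rate probability that an (identifier, parameter) cell
#'   stays unscored, in `[0, 1]`.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_entities = 3L, n_attributes = 6L,
                         n_values_per_categorical = 4L,
                         fraction_categorical = 0.4, n_objects = 4L,
                         multiplication = 1L, missing_rate = 0.1) {
  counts <- c(n_entities, n_attributes, n_values_per_categorical,
              n_objects, multiplication)
  pheno_assert(all(counts >= 1L), "validation_error", "all counts must be >= 1")
  pheno_assert(fraction_categorical >= 0 && fraction_categorical <= 1 &&
                 missing_rate >= 0 && missing_rate <= 1,
               "validation_error", "proportions must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_entities = as.integer(n_entities),
                 n_attributes = as.integer(n_attributes),
                 n_values_per_categorical = as.integer(n_values_per_categorical),
                 fraction_categorical = fraction_categorical,
                 n_objects = as.integer(n_objects),
                 multiplication = as.integer(multiplication),
                 missing_rate = missing_rate),
            class = "fixture_spec")
}

# stable stream splitting: sub-stream k of seed s (double arithmetic is
# exact here and avoids 32-bit integer overflow for large seeds)
sub_seed <- function(spec, k) {
  as.integer((as.numeric(spec$seed) * 131 + k) %% 2147483629)
}

syllables <- c("ba", "do", "fi", "ga", "ke", "lu", "mi", "no", "pa", "ra",
               "se", "ti", "vo", "wu", "za")

synth_word <- function() paste(sample(syllables, 3, replace = TRUE), collapse = "")

#' Generate a deterministic synthetic vocabulary
#'
#' Terms get synthetic two-language (en/de) labels; every other entity
#' and attribute carries a well-formed synthetic PO/TO CURIE drawn from
#' a reserved high-numbered id range, so fixtures never collide with
#' real ontology terms.
#'
#' @param spec a [fixture_spec()].
#' @return A [term_registry()] with `n_entities` entity terms,
#'   `n_attributes` attribute terms and one value set of size
#'   `n_values_per_categorical` per attribute.
#' @export
generate_vocabulary <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(sub_seed(spec, 1L), {
    reg <- term_registry("en")
    units <- c("cm", "mm", "g", "kg", "%", NA)
    for (i in seq_len(spec$n_entities)) {
      w <- synth_word()
      reg <- add_term(reg, term(
        sprintf("ent%02d", i), "entity",
        c(en = paste0(w, " organ"), de = paste0(w, "-Organ")),
        ontology_ref = if (i %% 2L == 0L) sprintf("PO:9%06d", i) else NULL))
    }
    for (i in seq_len(spec$n_attributes)) {
      w <- synth_word()
      u <- sample(units, 1)
      reg <- add_term(reg, term(
        sprintf("att%02d", i), "attribute",
        c(en = paste0(w, " trait"), de = paste0(w, "-Merkmal")),
        ontology_ref = if (i %% 2L == 0L) sprintf("TO:9%06d", i) else NULL,
        unit = if (is.na(u)) NULL else u))
      for (j in seq_len(spec$n_values_per_categorical)) {
        v <- synth_word()
        reg <- add_term(reg, term(
          sprintf("val%02d_%02d", i, j), "value",
          c(en = paste0(v, " class"), de = paste0(v, "-Klasse"))))
      }
    }
    reg
  })
}

#' Generate a deterministic scheme over a vocabulary
#'
#' Attributes are dealt round-robin over the entities; a deterministic
#' `fraction_categorical` share of them is scored categorically using
#' their generated value sets, the rest numerically.
#'
#' @param spec a [fixture_spec()].
#' @param registry registry from [generate_vocabulary()] (or any
#'   registry using the same id pattern and large enough for `spec`).
#' @param name,owner scheme metadata.
#' @param clock creation time source.
#' @return A valid `pheno_scheme`.
#' @export
generate_scheme <- function(spec, registry, name = "generated scheme",
                            owner = "fixture",
                            clock = manual_clock("2015-04-07T08:00:00+00:00")) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(registry, "term_registry"))
  kinds <- vapply(registry$terms, `[[`, "", "kind")
  ents <- names(kinds)[kinds == "entity"][seq_len(spec$n_entities)]
  atts <- names(kinds)[kinds == "attribute"][seq_len(spec$n_attributes)]
  pheno_assert(!anyNA(ents) && !anyNA(atts), "validation_error",
               "registry too small for spec")
  n_cat <- round(spec$fraction_categorical * spec$n_attributes)

  withr::with_seed(sub_seed(spec, 2L), {
    cat_idx <- if (n_cat > 0) sort(sample(seq_along(atts), n_cat)) else integer()
    params <- lapply(seq_along(atts), function(i) {
      aid <- atts[i]
      if (i %in% cat_idx) {
        dom <- sprintf("%s_%02d", sub("^att", "val", aid),
                       seq_len(spec$n_values_per_categorical))
        pheno_assert(all(dom %in% names(registry$terms)), "validation_error",
                     "registry too small for spec (missing value terms)")
        parameter(aid, "categorical", domain = dom)
      } else {
        parameter(aid, "numeric")
      }
    })
    split_idx <- rep(seq_along(ents), length.out = length(params))
    used <- sort(unique(split_idx))   # entities left empty are dropped
    blocks <- lapply(used, function(e) entity_block(ents[e], params[split_idx == e]))
    compose_scheme(registry, name = name, owner = owner, blocks = blocks,
                   clock = clock)
  })
}

#' Simulate a capture session
#'
#' Emulates field entry on a device: `n_objects` base identifiers are
#' opened with the spec's multiplication factor, and each
#' (identifier, parameter) cell is scored with probability
#' `1 - missing_rate`. Numeric values are drawn uniformly on
#' `[0, 100]` rounded to 0.1; categorical values uniformly from the
#' domain. Timestamps come from the injected clock and increase
#' strictly.
#'
#' @param spec a [fixture_spec()].
#' @param scheme a valid `pheno_scheme`.
#' @param clock time source for the session.
#' @param storage_dir device storage directory (default: fresh tempdir).
#' @param id_prefix prefix of the generated base identifiers.
#' @return A `capture_session`.
#' @export
simulate_session <- function(spec, scheme,
                             clock = manual_clock("2015-04-07T09:00:00+00:00"),
                             storage_dir = tempfile("device"),
                             id_prefix = "obj") {
  stopifnot(inherits(spec, "fixture_spec"), inherits(scheme, "pheno_scheme"))
  config <- device_config("simdev", storage_dir, clock = clock)
  session <- start_session(scheme, config)
  pairs <- scheme_pairs(scheme)
  withr::with_seed(sub_seed(spec, 3L), {
    for (o in seq_len(spec$n_objects)) {
      ids <- open_object(session, sprintf("%s%03d", id_prefix, o),
                         spec$multiplication)
      for (id in ids) {
        for (i in seq_len(nrow(pairs))) {
          if (runif(1) < spec$missing_rate) next
          p <- scheme_parameter(scheme, pairs$entity_id[i], pairs$attribute_id[i])
          raw <- if (p$datatype == "numeric") {
            fmt_num(round(runif(1, 0, 100), 1))
          } else {
            sample(p$domain, 1)
          }
          record_value(session, id, pairs$entity_id[i], pairs$attribute_id[i], raw)
        }
      }
    }
  })
  session
}

#' The sparse two-phase project scenario
#'
#' The textbook case for EAV storage of volatile phenotyping data: at
#' the start of a project 20 parameters are assessed on each plant;
#' after the first evaluations only the five most predictive parameters
#' plus one newly discovered parameter — six in total — are carried
#' forward. Both phases are returned as a scheme plus a fully scored
#' single-plant session, ready for QC and ingestion; ingesting them
#' yields 20 EAV rows per plant in phase 1 and 6 in phase 2, with no
#' placeholder rows and no table change in between.
#'
#' @param storage_dir device storage directory for the two sessions.
#' @param seed RNG seed (fixed default: the scenario is a deterministic
#'   fixture).
#' @return List with `registry`, `phase1_scheme`, `phase2_scheme`,
#'   `phase1_session`, `phase2_session`.
#' @export
sparse_project_scenario <- function(storage_dir = tempfile("sparse"), seed = 407L) {
  spec1 <- fixture_spec(seed = seed, n_entities = 1L, n_attributes = 21L,
                        n_values_per_categorical = 4L,
                        fraction_categorical = 0.25, n_objects = 1L,
                        multiplication = 1L, missing_rate = 0)
  registry <- generate_vocabulary(spec1)

  kinds <- vapply(registry$terms, `[[`, "", "kind")
  atts <- names(kinds)[kinds == "attribute"]
  phase1_atts <- atts[1:20]
  retained <- atts[1:5]           # the five most predictive parameters
  new_att <- atts[21]             # the newly discovered parameter

  mk_scheme <- function(att_ids, name) {
    spec_n <- fixture_spec(seed = seed, n_entities = 1L,
                           n_attributes = length(att_ids),
                           n_values_per_categorical = 4L,
                           fraction_categorical = 0, n_objects = 1L,
                           missing_rate = 0)
    withr::with_seed(sub_seed(spec_n, 2L), {
      params <- lapply(att_ids, function(aid) parameter(aid, "numeric"))
      compose_scheme(registry, name = name, owner = "fixture",
                     blocks = list(entity_block("ent01", params)),
                     clock = manual_clock("2015-03-01T08:00:00+00:00"))
    })
  }
  phase1_scheme <- mk_scheme(phase1_atts, "phase 1 screen")
  phase2_scheme <- mk_scheme(c(retained, new_att), "phase 2 follow-up")

  # each phase scores its own plant: the combined pivot then shows the
  # phase-2 row empty in the 15 columns measured only in phase 1
  sim <- function(scheme, n_attrs, start, prefix) {
    spec_s <- fixture_spec(seed = seed, n_entities = 1L, n_attributes = n_attrs,
                           n_values_per_categorical = 4L,
                           fraction_categorical = 0, n_objects = 1L,
                           missing_rate = 0)
    simulate_session(spec_s, scheme, clock = manual_clock(start),
                     storage_dir = file.path(storage_dir, scheme$name),
                     id_prefix = prefix)
  }
  list(registry = registry,
       phase1_scheme = phase1_scheme, phase2_scheme = phase2_scheme,
       phase1_session = sim(phase1_scheme, 20L, "2015-04-07T09:00:00+00:00",
                            "phase1-plant"),
       phase2_session = sim(phase2_scheme, 6L, "2015-06-15T09:00:00+00:00",
                            "phase2-plant"))
}
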