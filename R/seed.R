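#' Seed controlled vocabulary
#'
#' A small ready-made vocabulary for getting started and for examples:
#' common plant entities with Plant Ontology (PO) cross-references,
#' frequently scored attributes — some with Plant Trait Ontology (TO)
#' ids, some user-defined — and categorical value sets for the
#' categorical attributes. English and German labels throughout, so the
#' language-switch behaviour is exercised out of the box.
#'
#' Only widely established PO/TO ids are cross-referenced; everything
#' else is deliberately left as user-defined vocabulary, which the
#' scheme composer treats identically.
#'
#' @return A populated [term_registry()].
#' @examples
#' reg <- seed_vocabulary()
#' resolve_label(reg, "e.leaf", "de")
#' @export
seed_vocabulary <- function() {
  reg <- term_registry("en")
  ent <- list(
    list("e.plant",  c(en = "whole plant", de = "Gesamtpflanze"), "PO:0000003"),
    list("e.leaf",   c(en = "leaf", de = "Blatt"),                "PO:0025034"),
    list("e.root",   c(en = "root", de = "Wurzel"),               "PO:0009005"),
    list("e.stem",   c(en = "stem", de = "Spross"),               "PO:0009047"),
    list("e.flower", c(en = "flower", de = "Blüte"),         "PO:0009046"),
    list("e.fruit",  c(en = "fruit", de = "Frucht"),              "PO:0009001"),
    list("e.seed",   c(en = "seed", de = "Same"),                 "PO:0009010"),
    list("e.tuber",  c(en = "tuber", de = "Knolle"),              NULL),
    list("e.plot",   c(en = "plot", de = "Parzelle"),             NULL),
    list("e.canopy", c(en = "canopy", de = "Bestand"),            NULL)
  )
  for (e in ent) {
    reg <- add_term(reg, term(e[[1]], "entity", e[[2]], ontology_ref = e[[3]]))
  }

  att <- list(
    list("a.height",     c(en = "plant height", de = "Pflanzenhöhe"),  "TO:0000207", "cm"),
    list("a.length",     c(en = "length", de = "Länge"),               NULL, "cm"),
    list("a.width",      c(en = "width", de = "Breite"),                    NULL, "cm"),
    list("a.area",       c(en = "area", de = "Fläche"),                NULL, "cm2"),
    list("a.fresh_mass", c(en = "fresh mass", de = "Frischmasse"),          NULL, "g"),
    list("a.dry_mass",   c(en = "dry mass", de = "Trockenmasse"),           NULL, "g"),
    list("a.count",      c(en = "organ count", de = "Organzahl"),           NULL, NULL),
    list("a.spad",       c(en = "chlorophyll index", de = "Chlorophyllindex"), NULL, NULL),
    list("a.diameter",   c(en = "diameter", de = "Durchmesser"),            NULL, "mm"),
    list("a.moisture",   c(en = "soil moisture", de = "Bodenfeuchte"),      NULL, "%"),
    list("a.color",      c(en = "colour class", de = "Farbklasse"),         NULL, NULL),
    list("a.senescence", c(en = "senescence stage", de = "Seneszenzstufe"), NULL, NULL),
    list("a.damage",     c(en = "damage class", de = "Schadklasse"),        NULL, NULL),
    list("a.growth",     c(en = "growth stage", de = "Entwicklungsstadium"), NULL, NULL),
    list("a.vigor",      c(en = "vigour score", de = "Wuchskraft"),         NULL, NULL)
  )
  for (a in att) {
    reg <- add_term(reg, term(a[[1]], "attribute", a[[2]], ontology_ref = a[[3]],
                              unit = a[[4]]))
  }

  vals <- list(
    c("v.green",  "green",  "grün"),
    c("v.yellow", "yellow", "gelb"),
    c("v.brown",  "brown",  "braun"),
    c("v.red",    "red",    "rot"),
    c("v.sen1",   "senescence stage 1", "Seneszenz Stufe 1"),
    c("v.sen2",   "senescence stage 2", "Seneszenz Stufe 2"),
    c("v.sen3",   "senescence stage 3", "Seneszenz Stufe 3"),
    c("v.sen4",   "senescence stage 4", "Seneszenz Stufe 4"),
    c("v.dmg0",   "no damage",     "kein Schaden"),
    c("v.dmg1",   "light damage",  "leichter Schaden"),
    c("v.dmg2",   "medium damage", "mittlerer Schaden"),
    c("v.dmg3",   "severe damage", "starker Schaden"),
    c("v.veg",    "vegetative",  "vegetativ"),
    c("v.flower", "flowering",   "blühend"),
    c("v.ripe",   "ripening",    "reifend"),
    c("v.mature", "mature",      "reif"),
    c("v.low",    "low vigour",    "geringe Wuchskraft"),
    c("v.medium", "medium vigour", "mittlere Wuchskraft"),
    c("v.high",   "high vigour",   "hohe Wuchskraft"),
    c("v.dead",   "dead", "abgestorben")
  )
  for (v in vals) {
    reg <- add_term(reg, term(v[[1]], "value", c(en = v[[2]], de = v[[3]])))
  }
  reg
}

# categorical domains conventionally used with the seed attributes
seed_domains <- function() {
  list(
    a.color      = c("v.green", "v.yellow", "v.brown", "v.red"),
    a.senescence = c("v.sen1", "v.sen2", "v.sen3", "v.sen4"),
    a.damage     = c("v.dmg0", "v.dmg1", "v.dmg2", "v.dmg3"),
    a.growth     = c("v.veg", "v.flower", "v.ripe", "v.mature", "v.dead"),
    a.vigor      = c("v.low", "v.medium", "v.high")
  )
}
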