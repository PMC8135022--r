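# Closed type system: eight entity types and the derived relation/label sets.

#' Entity types recognized by the package
#'
#' The closed set of eight entity types: the drug name itself plus seven
#' prescription attributes.
#' @return Character vector of the eight entity type names.
#' @export
entity_types <- function() {
  c("Drug", "Strength", "Dosage", "Frequency", "Duration", "Route", "Form",
    "Reason")
}

#' Attribute types (all entity types except Drug)
#' @return Character vector of the seven attribute type names.
#' @export
attribute_types <- function() setdiff(entity_types(), "Drug")

#' Relation types
#'
#' One relation type per attribute, always directed attribute -> drug.
#' @return Character vector such as `"Strength-Drug"`.
#' @export
relation_types <- function() paste0(attribute_types(), "-Drug")

rtype_for <- function(attr_type) paste0(attr_type, "-Drug")

#' The BIOES label set
#'
#' `O` plus one of B/I/E/S per entity type: 33 labels in total.  Label order
#' is fixed (O first, then types in `entity_types()` order, B/I/E/S within a
#' type) so that model parameters are reproducible.
#' @return Character vector of the 33 BIOES labels.
#' @export
bioes_labels <- function() {
  c("O", as.vector(vapply(entity_types(), function(ty) {
    paste0(c("B-", "I-", "E-", "S-"), ty)
  }, character(4L))))
}

label_prefix <- function(labels) {
  ifelse(labels == "O", "O", substr(labels, 1L, 1L))
}

label_type <- function(labels) {
  ifelse(labels == "O", NA_character_, substring(labels, 3L))
}
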