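# BioPAX Level-3 parser for the Reactome RDF/XML export dialect.
# The fixed class subset (Protein, Rna, Dna, SmallMolecule,
# PhysicalEntity, Complex, BiochemicalReaction, Catalysis, Control,
# Pathway) is consumed directly from the RDF/XML serialization.

biopax_entity_classes <- c("Protein", "Rna", "Dna", "SmallMolecule",
                           "PhysicalEntity", "Complex")

biopax_db_prefixes <- c(
  "uniprot"            = "uniprot",
  "uniprot isoform"    = "uniprot",
  "chebi"              = "chebi",
  "ensembl"            = "ensembl",
  "entrez gene"        = "ncbigene",
  "ncbi gene"          = "ncbigene",
  "hgnc"               = "hgnc",
  "hgnc symbol"        = "hgnc",
  "mirbase"            = "mirbase",
  "pubchem compound"   = "pubchem.compound",
  "pubchem-compound"   = "pubchem.compound",
  "kegg compound"      = "kegg.compound",
  "reactome"           = "reactome",
  "reactome database id release" = "reactome")

biopax_xref_curie <- function(db, id, label = "") {
  if (!nzchar(trimws(id %||% ""))) return(NULL)
  id <- trimws(id)
  key <- tolower(trimws(db %||% ""))
  prefix <- biopax_db_prefixes[key]
  if (is.na(prefix)) prefix <- if (nzchar(key)) label_slug(key) else "reactome.local"
  if (prefix == "chebi") id <- sub("^chebi:", "", id, ignore.case = TRUE)
  curie(prefix, id, label)
}

rdf_id_of <- function(node) {
  id <- xml2::xml_attr(node, "ID")
  if (!is.na(id %||% NA)) return(id)
  about <- xml2::xml_attr(node, "about")
  if (!is.na(about %||% NA)) return(sub("^#", "", about))
  NA_character_
}

rdf_resource_refs <- function(node, property) {
  refs <- xml2::xml_attr(
    xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", property)),
    "resource")
  sub("^#", "", refs[!is.na(refs)])
}

bp_text <- function(node, property) {
  v <- xml2::xml_text(xml2::xml_find_first(
    node, sprintf("./*[local-name()='%s']", property)))
  if (is.na(v)) "" else trimws(v)
}

#' Parse a BioPAX Level-3 pathway document (Reactome dialect)
#'
#' Reads one BioPAX Level 3 OWL file in RDF/XML serialization. Physical
#' entities (Protein, Rna, Dna, SmallMolecule, PhysicalEntity, Complex)
#' become entities with cross-references collected from their
#' `entityReference` chain's UnificationXrefs (or direct `xref`s);
#' Complex `component` links populate group membership; entities
#' carrying `memberPhysicalEntity` links (Reactome's encoding of
#' families) become `EntitySet` groups. `BiochemicalReaction` instances
#' become reified reactions (left -> reactants, right -> products);
#' `Catalysis`/`Control` instances become interactions from the
#' controller to the controlled reaction with raw relation
#' `controlType` (`"ACTIVATION"` when absent, the BioPAX default).
#' Sub-pathways referenced through `pathwayComponent` become entities
#' of raw type `"Pathway"`; the hierarchy is not recursed — one file is
#' one pathway.
#'
#' @param x file path or RDF/XML text
#' @param pathway_iri optional `rdf:ID` of the pathway of interest;
#'   defaults to the first Pathway instance that is not a component of
#'   another (canonical-pathway filtering is the caller's allowlist)
#' @return a [source_pathway()] with `database = "reactome"`
#' @export
parse_biopax <- function(x, pathway_iri = NULL) {
  doc <- read_xml_input(x)
  root <- xml2::xml_root(doc)

  elems <- xml2::xml_find_all(root, "./*")
  by_id <- list()
  class_of <- character()
  for (el in elems) {
    id <- rdf_id_of(el)
    if (is.na(id) || !nzchar(id)) next
    by_id[[id]] <- el
    class_of[id] <- xml2::xml_name(el)
  }

  xrefs_of <- function(el, label) {
    out <- list()
    refs <- c(rdf_resource_refs(el, "entityReference"), rdf_id_of(el))
    xref_ids <- character()
    for (rid in refs[!is.na(refs)]) {
      tgt <- by_id[[rid]]
      if (!is.null(tgt)) xref_ids <- c(xref_ids, rdf_resource_refs(tgt, "xref"))
    }
    for (xid in unique(xref_ids)) {
      xr <- by_id[[xid]]
      if (is.null(xr) || class_of[xid] != "UnificationXref") next
      cu <- biopax_xref_curie(bp_text(xr, "db"), bp_text(xr, "id"), label)
      if (!is.null(cu)) out <- c(out, list(cu))
    }
    out
  }

  pathway_ids <- names(class_of)[class_of == "Pathway"]
  componented <- unlist(lapply(pathway_ids, function(pid)
    rdf_resource_refs(by_id[[pid]], "pathwayComponent")), use.names = FALSE)
  top <- pathway_iri %||% setdiff(pathway_ids, componented)[1] %||% NA_character_
  pid <- "unknown"; pname <- ""
  sub_pathways <- character()
  if (!is.na(top) && !is.null(by_id[[top]])) {
    pel <- by_id[[top]]
    pname <- bp_text(pel, "displayName")
    if (!nzchar(pname)) pname <- bp_text(pel, "name")
    pid <- top
    for (xid in rdf_resource_refs(pel, "xref")) {
      xr <- by_id[[xid]]
      if (!is.null(xr) && class_of[xid] == "UnificationXref" &&
          tolower(bp_text(xr, "db")) == "reactome") pid <- bp_text(xr, "id")
    }
    sub_pathways <- intersect(rdf_resource_refs(pel, "pathwayComponent"),
                              pathway_ids)
  }

  entities <- source_entities()
  add_entity <- function(local_id, raw_type, label, xrefs, members = character()) {
    entities <<- rbind(entities, tibble::tibble(
      local_id = local_id, raw_type = raw_type, label = label,
      xrefs = list(xrefs), member_ids = list(members)))
  }

  ids_sorted <- sort(names(class_of))   # fixed ordering policy
  for (id in ids_sorted) {
    cls <- class_of[id]
    if (!cls %in% biopax_entity_classes) next
    el <- by_id[[id]]
    label <- bp_text(el, "displayName")
    if (!nzchar(label)) label <- bp_text(el, "name")
    members <- rdf_resource_refs(el, "memberPhysicalEntity")
    if (length(members)) {
      add_entity(id, "EntitySet", label, xrefs_of(el, label), members)
    } else if (cls == "Complex") {
      add_entity(id, "Complex", label, xrefs_of(el, label),
                 rdf_resource_refs(el, "component"))
    } else {
      add_entity(id, cls, label, xrefs_of(el, label))
    }
  }
  for (id in sort(sub_pathways)) {
    el <- by_id[[id]]
    label <- bp_text(el, "displayName")
    if (!nzchar(label)) label <- bp_text(el, "name")
    add_entity(id, "Pathway", label, xrefs_of(el, label))
  }

  # drop group members that are not parsed entities (e.g. nested refs out
  # of the subset)
  if (nrow(entities)) {
    known <- entities$local_id
    entities$member_ids <- lapply(entities$member_ids, intersect, known)
  }

  reactions <- source_reactions()
  for (id in ids_sorted[class_of[ids_sorted] == "BiochemicalReaction"]) {
    el <- by_id[[id]]
    reactions <- rbind(reactions, tibble::tibble(
      reaction_id = id,
      reactant_ids = list(intersect(rdf_resource_refs(el, "left"),
                                    entities$local_id)),
      product_ids = list(intersect(rdf_resource_refs(el, "right"),
                                   entities$local_id)),
      reversible = identical(bp_text(el, "conversionDirection"), "REVERSIBLE"),
      modifier_ids = list(character())))
  }

  interactions <- source_interactions()
  for (id in ids_sorted[class_of[ids_sorted] %in% c("Catalysis", "Control")]) {
    el <- by_id[[id]]
    controllers <- intersect(rdf_resource_refs(el, "controller"),
                             entities$local_id)
    controlled <- rdf_resource_refs(el, "controlled")
    controlled <- controlled[controlled %in% c(entities$local_id,
                                               reactions$reaction_id)]
    if (!length(controllers) || !length(controlled)) {
      warn_beltway("BioPAX ", class_of[id], " ", id,
                   " has unresolvable controller/controlled; dropped")
      next
    }
    ctype <- bp_text(el, "controlType")
    if (!nzchar(ctype)) ctype <- "ACTIVATION"
    for (s in controllers) for (t in controlled)
      interactions <- rbind(interactions, tibble::tibble(
        source_id = s, target_id = t, raw_relations = list(ctype)))
  }

  source_pathway("reactome", pid, pname, entities, interactions, reactions)
}
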