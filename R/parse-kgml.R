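# KGML (KEGG Markup Language) parser: pathway/entry/relation/reaction
# schema -> source_pathway.

# Accept a file path or literal XML text.
read_xml_input <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  if (length(x) == 1 && !grepl("^[[:space:]]*<", x) && file.exists(x))
    return(xml2::read_xml(x))
  xml2::read_xml(paste(x, collapse = "\n"))
}

# Map a KEGG accession ("hsa:207", "cpd:C00008", "path:hsa04150") to a
# CURIE candidate. Organism-prefixed gene accessions keep the full token
# as identifier under the generic kegg prefix; typed accessions get a
# scoped prefix. Normalization to HGNC/ChEBI happens downstream.
kegg_accession_curie <- function(acc, label = "") {
  parts <- strsplit(acc, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(curie("kegg", acc, label))
  ns <- tolower(parts[1])
  local <- paste(parts[-1], collapse = ":")
  switch(ns,
    cpd  = curie("kegg.compound", local, label),
    gl   = curie("kegg.glycan", local, label),
    dr   = curie("kegg.drug", local, label),
    path = curie("kegg.pathway", local, label),
    ko   = curie("kegg.orthology", local, label),
    ec   = curie("eccode", local, label),
    rn   = curie("kegg.reaction", local, label),
    curie("kegg", acc, label))
}

#' Parse a KGML (KEGG) pathway document
#'
#' Reads one KEGG Markup Language file into the parser intermediate
#' representation. Each `entry` becomes one entity per accession in its
#' space-separated `name` attribute (multi-accession entries expand to
#' local ids `id#1` ... `id#k`, and every interaction, reaction or group
#' referencing the entry expands accordingly); each `relation` with its
#' `subtype` children becomes one interaction carrying all subtype
#' names; each `reaction` becomes a reified reaction whose catalysing
#' gene entries (matched through their `reaction` attribute) are
#' recorded as modifiers; `group` entries become group entities with
#' `member_ids` from their `component` children.
#'
#' Relations carrying a `compound` subtype (a gene-gene relation
#' mediated by a compound entry) are rewritten into two interactions,
#' source -> compound and compound -> target, labelled
#' `compound_mediated`, preserving the mediator as a node.
#'
#' @param x file path or KGML text
#' @return a [source_pathway()] with `database = "kegg"`
#' @examples
#' kgml <- '<pathway name="path:hsa00001" title="demo">
#'   <entry id="1" name="hsa:207" type="gene">
#'     <graphics name="AKT1"/></entry>
#'   <entry id="2" name="cpd:C00008" type="compound"/>
#'   <relation entry1="1" entry2="2" type="PPrel">
#'     <subtype name="activation" value="--&gt;"/></relation>
#' </pathway>'
#' parse_kgml(kgml)
#' @export
parse_kgml <- function(x) {
  doc <- read_xml_input(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway")
    stop_format("not a KGML document: root element is <",
                xml2::xml_name(root), ">, expected <pathway>")

  pid <- sub("^path:", "", xml2::xml_attr(root, "name") %||% "unknown")
  pname <- xml2::xml_attr(root, "title") %||% ""

  entities <- source_entities()
  expansion <- list()   # entry id -> entity local ids
  reaction_of_entry <- list()   # entry id -> reaction name(s)

  for (entry in xml2::xml_find_all(root, "./entry")) {
    eid <- xml2::xml_attr(entry, "id")
    etype <- xml2::xml_attr(entry, "type") %||% "gene"
    name_attr <- xml2::xml_attr(entry, "name")
    gname <- xml2::xml_attr(xml2::xml_find_first(entry, "./graphics"), "name")
    glabel <- if (!is.na(gname %||% NA)) trimws(strsplit(gname, ",")[[1]][1]) else ""
    rxn_attr <- xml2::xml_attr(entry, "reaction")
    if (!is.na(rxn_attr %||% NA))
      reaction_of_entry[[eid]] <- strsplit(trimws(rxn_attr), "[[:space:]]+")[[1]]

    if (etype == "group") {
      comp <- xml2::xml_attr(xml2::xml_find_all(entry, "./component"), "id")
      entities <- rbind(entities, tibble::tibble(
        local_id = eid, raw_type = "group",
        label = if (nzchar(glabel)) glabel else paste0("group:", eid),
        xrefs = list(list()), member_ids = list(comp)))
      expansion[[eid]] <- eid
      next
    }

    accs <- if (is.na(name_attr %||% NA) || !nzchar(trimws(name_attr %||% ""))) {
      warn_beltway("KGML entry ", eid, " has no name attribute; keeping label only")
      character()
    } else setdiff(strsplit(trimws(name_attr), "[[:space:]]+")[[1]], "undefined")

    if (!length(accs)) {
      entities <- rbind(entities, tibble::tibble(
        local_id = eid, raw_type = etype,
        label = if (nzchar(glabel)) glabel else paste0("entry:", eid),
        xrefs = list(list()), member_ids = list(character())))
      expansion[[eid]] <- eid
      next
    }

    ids <- if (length(accs) == 1) eid else paste0(eid, "#", seq_along(accs))
    for (k in seq_along(accs)) {
      entities <- rbind(entities, tibble::tibble(
        local_id = ids[k], raw_type = etype,
        label = if (nzchar(glabel)) glabel else accs[k],
        xrefs = list(list(kegg_accession_curie(accs[k], glabel))),
        member_ids = list(character())))
    }
    expansion[[eid]] <- ids
  }

  # group members expand to the entities behind each component entry
  if (nrow(entities)) {
    is_grp <- entities$raw_type == "group"
    entities$member_ids[is_grp] <- lapply(entities$member_ids[is_grp], function(m)
      unlist(expansion[m], use.names = FALSE) %||% character())
  }

  expand <- function(eid) expansion[[eid]] %||% character()

  interactions <- source_interactions()
  add_interaction <- function(src, tgt, labels) {
    for (s in expand(src)) for (t in expand(tgt))
      interactions <<- rbind(interactions, tibble::tibble(
        source_id = s, target_id = t, raw_relations = list(labels)))
  }

  for (rel in xml2::xml_find_all(root, "./relation")) {
    e1 <- xml2::xml_attr(rel, "entry1"); e2 <- xml2::xml_attr(rel, "entry2")
    subs <- xml2::xml_find_all(rel, "./subtype")
    snames <- xml2::xml_attr(subs, "name")
    svals <- xml2::xml_attr(subs, "value")
    if (!length(snames)) {
      warn_beltway("KGML relation ", e1, "->", e2, " has no subtype; dropped")
      next
    }
    mediators <- svals[snames == "compound"]
    direct <- snames[snames != "compound"]
    if (length(direct)) add_interaction(e1, e2, direct)
    for (m in mediators) {
      if (!length(expand(m))) {
        warn_beltway("KGML compound subtype references unknown entry ", m,
                     "; keeping direct relation")
        add_interaction(e1, e2, "compound_mediated")
      } else {
        add_interaction(e1, m, "compound_mediated")
        add_interaction(m, e2, "compound_mediated")
      }
    }
  }

  reactions <- source_reactions()
  rxns <- xml2::xml_find_all(root, "./reaction")
  if (length(rxns)) {
    modifier_of <- list()
    for (eid in names(reaction_of_entry))
      for (rname in reaction_of_entry[[eid]])
        modifier_of[[rname]] <- c(modifier_of[[rname]], eid)
    for (rx in rxns) {
      rname <- xml2::xml_attr(rx, "name") %||% xml2::xml_attr(rx, "id")
      subs <- unlist(lapply(xml2::xml_attr(
        xml2::xml_find_all(rx, "./substrate"), "id"), expand))
      prods <- unlist(lapply(xml2::xml_attr(
        xml2::xml_find_all(rx, "./product"), "id"), expand))
      mods <- unlist(lapply(modifier_of[[rname]] %||% character(), expand))
      reactions <- rbind(reactions, tibble::tibble(
        reaction_id = xml2::xml_attr(rx, "id") %||% rname,
        reactant_ids = list(subs %||% character()),
        product_ids = list(prods %||% character()),
        reversible = identical(xml2::xml_attr(rx, "type"), "reversible"),
        modifier_ids = list(mods %||% character())))
    }
  }

  source_pathway("kegg", pid, pname, entities, interactions, reactions)
}
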