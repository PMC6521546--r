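# GPML (WikiPathways 2013a) parser: Pathway/DataNode/Interaction/Group
# subset -> source_pathway.

# Display names used in GPML Xref Database attributes -> namespace prefixes.
gpml_database_prefixes <- c(
  "entrez gene"        = "ncbigene",
  "ensembl"            = "ensembl",
  "hgnc"               = "hgnc",
  "uniprot-trembl"     = "uniprot",
  "uniprot/trembl"     = "uniprot",
  "uniprot"            = "uniprot",
  "chebi"              = "chebi",
  "pubchem-compound"   = "pubchem.compound",
  "mirbase"            = "mirbase",
  "mirbase sequence"   = "mirbase",
  "mirbase mature sequence" = "mirbase",
  "kegg compound"      = "kegg.compound",
  "kegg genes"         = "kegg",
  "wikipathways"       = "wikipathways",
  "reactome"           = "reactome")

gpml_xref_curie <- function(database, id, label) {
  if (is.na(id %||% NA) || !nzchar(trimws(id %||% ""))) return(NULL)
  id <- trimws(id)
  prefix <- gpml_database_prefixes[tolower(trimws(database %||% ""))]
  if (is.na(prefix)) prefix <- "wikipathways.local"
  if (prefix == "chebi") id <- sub("^chebi:", "", id, ignore.case = TRUE)
  curie(prefix, id, label)
}

#' Parse a GPML (WikiPathways) pathway document
#'
#' Reads one Graphical Pathway Markup Language (2013a schema subset)
#' file. Every `DataNode` becomes an entity with raw type from its
#' `Type` attribute (absent -> `"DataNode"`, the abstract class for
#' unspecified physical entities) and one cross-reference candidate
#' from its `Xref`; every `Group` becomes a group entity whose members
#' are the DataNodes carrying the matching `GroupRef`; every
#' `Interaction` whose endpoints attach to DataNodes or Groups through
#' `GraphRef`s becomes an interaction whose raw relation is the
#' arrow-head type of its end point (`"Line"` when absent).
#'
#' An endpoint pointing at an `Anchor` drawn on another interaction
#' (catalysis onto a conversion arrow) is resolved one level, to the
#' anchored interaction's target node; deeper anchor chains and
#' endpoints that resolve to nothing are dropped with a warning.
#'
#' @param x file path or GPML text
#' @param pathway_id optional accession; defaults to a slug of the
#'   pathway `Name` attribute
#' @return a [source_pathway()] with `database = "wikipathways"`
#' @export
parse_gpml <- function(x, pathway_id = NULL) {
  doc <- read_xml_input(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Pathway")
    stop_format("not a GPML document: root element is <",
                xml2::xml_name(root), ">, expected <Pathway>")
  pname <- xml2::xml_attr(root, "Name") %||% ""
  pid <- pathway_id %||% label_slug(pname)

  entities <- source_entities()
  alias <- list()   # GraphId / GroupId -> entity local_id

  dn_nodes <- xml2::xml_find_all(root, ".//*[local-name()='DataNode']")
  group_ref <- character()
  for (k in seq_along(dn_nodes)) {
    dn <- dn_nodes[[k]]
    gid <- xml2::xml_attr(dn, "GraphId") %||% paste0("dn", k)
    label <- xml2::xml_attr(dn, "TextLabel") %||% ""
    raw_type <- xml2::xml_attr(dn, "Type") %||% "DataNode"
    xref <- xml2::xml_find_first(dn, "./*[local-name()='Xref']")
    cu <- if (!inherits(xref, "xml_missing"))
      gpml_xref_curie(xml2::xml_attr(xref, "Database"),
                      xml2::xml_attr(xref, "ID"), label) else NULL
    entities <- rbind(entities, tibble::tibble(
      local_id = gid, raw_type = raw_type, label = label,
      xrefs = list(if (is.null(cu)) list() else list(cu)),
      member_ids = list(character())))
    alias[[gid]] <- gid
    gr <- xml2::xml_attr(dn, "GroupRef")
    if (!is.na(gr %||% NA)) group_ref[gid] <- gr
  }

  for (grp in xml2::xml_find_all(root, ".//*[local-name()='Group']")) {
    group_id <- xml2::xml_attr(grp, "GroupId")
    graph_id <- xml2::xml_attr(grp, "GraphId")
    local <- graph_id %||% group_id %||% "group"
    style <- xml2::xml_attr(grp, "Style") %||% "Group"
    members <- names(group_ref)[group_ref == (group_id %||% "")]
    entities <- rbind(entities, tibble::tibble(
      local_id = local, raw_type = if (tolower(style) == "complex") "Complex" else "Group",
      label = paste0("group:", local),
      xrefs = list(list()), member_ids = list(members)))
    if (!is.na(group_id %||% NA)) alias[[group_id]] <- local
    if (!is.na(graph_id %||% NA)) alias[[graph_id]] <- local
  }

  # first pass over interactions: endpoints, arrow heads, anchors
  inter_nodes <- xml2::xml_find_all(root, ".//*[local-name()='Interaction']")
  raw <- vector("list", length(inter_nodes))
  anchor_of <- integer()
  for (k in seq_along(inter_nodes)) {
    pts <- xml2::xml_find_all(inter_nodes[[k]],
                              "./*[local-name()='Graphics']/*[local-name()='Point']")
    if (length(pts) < 2) { raw[[k]] <- NULL; next }
    first <- pts[[1]]; last <- pts[[length(pts)]]
    arrow <- xml2::xml_attr(last, "ArrowHead") %||%
      xml2::xml_attr(first, "ArrowHead") %||% "Line"
    raw[[k]] <- list(src = xml2::xml_attr(first, "GraphRef"),
                     tgt = xml2::xml_attr(last, "GraphRef"),
                     arrow = arrow)
    for (anc in xml2::xml_find_all(inter_nodes[[k]],
                                   "./*[local-name()='Graphics']/*[local-name()='Anchor']")) {
      aid <- xml2::xml_attr(anc, "GraphId")
      if (!is.na(aid %||% NA)) anchor_of[aid] <- k
    }
  }

  resolve_ref <- function(ref, depth = 1L) {
    if (is.na(ref %||% NA)) return(NULL)
    if (!is.null(alias[[ref]])) return(alias[[ref]])
    if (ref %in% names(anchor_of) && depth > 0) {
      anchored <- raw[[anchor_of[[ref]]]]
      if (!is.null(anchored)) return(resolve_ref(anchored$tgt, depth - 1L))
    }
    NULL
  }

  interactions <- source_interactions()
  for (r in raw) {
    if (is.null(r)) next
    s <- resolve_ref(r$src); t <- resolve_ref(r$tgt)
    if (is.null(s) || is.null(t)) {
      warn_beltway("GPML interaction endpoint unresolvable (",
                   r$src %||% "<none>", " -> ", r$tgt %||% "<none>", "); dropped")
      next
    }
    interactions <- rbind(interactions, tibble::tibble(
      source_id = s, target_id = t, raw_relations = list(r$arrow)))
  }

  source_pathway("wikipathways", pid, pname, entities, interactions)
}
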