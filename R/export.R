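# Graph serialization: BEL script (write-only), GraphML, and the
# canonical node-link JSON interchange dialect (lossless round-trip).
# All writers iterate in sorted order so output is byte-stable.

sorted_nodes <- function(g) g$nodes[order(g$nodes$key, method = "radix"), ]

sorted_edges <- function(g) {
  e <- g$edges
  e[order(e$subject, e$object, e$relation, e$database, e$pathway_id,
          e$source_relation, method = "radix"), ]
}

maybe_write <- function(text, path) {
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    invisible(text)
  } else text
}

bel_mod_term <- function(mod) {
  parts <- strsplit(mod, ":", fixed = TRUE)[[1]]
  detail <- paste(parts[-1], collapse = ":")
  switch(parts[1],
         protein_modification = sprintf('pmod("%s")', detail),
         fragment = sprintf('frag("%s")', detail),
         variant = sprintf('var("%s")', detail),
         sprintf('var("%s")', mod))
}

bel_term <- function(key, g) {
  i <- match(key, g$nodes$key)
  cls <- g$nodes$class[i]
  ns <- paste0(g$nodes$prefix[i], ":", g$nodes$identifier[i])
  mods <- g$nodes$mods[[i]]
  inner <- if (length(mods))
    paste0(ns, ", ", paste(vapply(mods, bel_mod_term, character(1)),
                           collapse = ", ")) else ns
  switch(cls,
    protein = sprintf("p(%s)", inner),
    rna = sprintf("r(%s)", inner),
    gene = sprintf("g(%s)", inner),
    mirna = sprintf("m(%s)", inner),
    abundance = sprintf("a(%s)", inner),
    bioprocess = sprintf("bp(%s)", inner),
    complex = sprintf("complex(%s)", inner),
    family = sprintf("complex(%s)", inner),
    reaction = {
      e <- g$edges
      reactants <- sort(e$object[e$subject == key & e$relation == "has_reactant"])
      products <- sort(e$object[e$subject == key & e$relation == "has_product"])
      sprintf("rxn(reactants(%s), products(%s))",
              paste(vapply(reactants, bel_term, character(1), g = g),
                    collapse = ", "),
              paste(vapply(products, bel_term, character(1), g = g),
                    collapse = ", "))
    })
}

bel_relation_keywords <- c(
  increases = "increases", decreases = "decreases",
  directly_increases = "directlyIncreases",
  directly_decreases = "directlyDecreases",
  regulates = "regulates", association = "association",
  has_component = "hasComponent", has_member = "hasMember",
  has_reactant = "hasReactant", has_product = "hasProduct",
  transcribed_to = "transcribedTo", translated_to = "translatedTo")

#' Write a graph as a BEL script
#'
#' Renders one BEL 2.0-style statement per edge, subjects and objects
#' as `p()`/`r()`/`g()`/`m()`/`a()`/`bp()`/`complex()`/`rxn()` terms
#' over `namespace:identifier`, with `SET` annotation blocks carrying
#' edge provenance. Statement order is deterministic (sorted by
#' provenance, subject, object, relation). Write-only: no BEL parser
#' is provided.
#'
#' @param g a [pathway_graph()]
#' @param path optional output file; when NULL the text is returned
#' @return the BEL script text (invisibly when written to `path`)
#' @export
write_bel_script <- function(g, path = NULL) {
  header <- c(
    "SET DOCUMENT Name = \"Harmonized pathway graph\"",
    "SET DOCUMENT Version = \"1.0\"",
    sprintf("SET DOCUMENT Description = \"%d nodes, %d edges from %s\"",
            nrow(g$nodes), nrow(g$edges),
            paste(sort(unique(g$metadata$database)) %||% "no source",
                  collapse = ", ")))
  e <- g$edges
  e <- e[order(e$database, e$pathway_id, e$subject, e$object, e$relation,
               e$source_relation, method = "radix"), ]
  lines <- header
  prev <- ""
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    tag <- paste(e$database[i], e$pathway_id[i])
    if (tag != prev) {
      lines <- c(lines, "",
                 sprintf("SET Database = \"%s\"", e$database[i]),
                 sprintf("SET Pathway = \"%s\"", e$pathway_id[i]),
                 sprintf("SET PathwayName = \"%s\"", e$pathway_name[i]))
      prev <- tag
    }
    lines <- c(lines,
               sprintf("SET SourceRelation = \"%s\"", e$source_relation[i]),
               paste(bel_term(e$subject[i], g),
                     bel_relation_keywords[[e$relation[i]]],
                     bel_term(e$object[i], g)))
  }
  maybe_write(paste0(paste(lines, collapse = "\n"), "\n"), path)
}

#' Write a graph as GraphML
#'
#' Serializes the multigraph with node class/namespace/label and edge
#' relation/provenance as typed GraphML attributes, for use in tools
#' such as Cytoscape. Nodes and edges are written in sorted order.
#'
#' @inheritParams write_bel_script
#' @return GraphML XML text (invisibly when written to `path`)
#' @export
write_graphml <- function(g, path = NULL) {
  nodes <- sorted_nodes(g)
  edges <- sorted_edges(g)
  vertices <- data.frame(name = nodes$key, class = nodes$class,
                         prefix = nodes$prefix, identifier = nodes$identifier,
                         label = nodes$label,
                         mods = vapply(nodes$mods, paste, character(1),
                                       collapse = ";"),
                         stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edf <- data.frame(from = edges$subject, to = edges$object,
                      relation = edges$relation, database = edges$database,
                      pathway_id = edges$pathway_id,
                      pathway_name = edges$pathway_name,
                      source_relation = edges$source_relation,
                      stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(from = character(), to = character())
  }
  ig <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vertices)
  tmp <- if (is.null(path)) tempfile(fileext = ".graphml") else path
  igraph::write_graph(ig, tmp, format = "graphml")
  if (is.null(path)) {
    on.exit(unlink(tmp))
    paste0(paste(readLines(tmp, warn = FALSE), collapse = "\n"), "\n")
  } else invisible(NULL)
}

#' Write a graph as node-link JSON
#'
#' The canonical on-disk interchange form:
#' `{"directed": true, "nodes": [...], "links": [...], "metadata":
#' [...]}` with node fields key/class/prefix/identifier/label/mods/
#' members and link fields source/target/relation/database/pathway_id/
#' pathway_name/source_relation. Sorted, so output is byte-stable, and
#' lossless: [read_node_link()] restores an identical node-key set and
#' edge multiset.
#'
#' @inheritParams write_bel_script
#' @return JSON text (invisibly when written to `path`)
#' @export
write_node_link <- function(g, path = NULL) {
  nodes <- sorted_nodes(g)
  edges <- sorted_edges(g)
  payload <- list(
    directed = TRUE,
    nodes = lapply(seq_len(nrow(nodes)), function(i) list(
      key = nodes$key[i], class = nodes$class[i], prefix = nodes$prefix[i],
      identifier = nodes$identifier[i], label = nodes$label[i],
      mods = I(as.character(nodes$mods[[i]])),
      members = I(as.character(nodes$members[[i]])))),
    links = lapply(seq_len(nrow(edges)), function(i) list(
      source = edges$subject[i], target = edges$object[i],
      relation = edges$relation[i], database = edges$database[i],
      pathway_id = edges$pathway_id[i], pathway_name = edges$pathway_name[i],
      source_relation = edges$source_relation[i])),
    metadata = lapply(seq_len(nrow(g$metadata)), function(i) list(
      database = g$metadata$database[i],
      pathway_id = g$metadata$pathway_id[i],
      pathway_name = g$metadata$pathway_name[i])))
  txt <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE))
  maybe_write(paste0(txt, "\n"), path)
}

#' Read a node-link JSON graph
#'
#' Inverse of [write_node_link()]. Malformed JSON or missing required
#' fields raise a format error.
#'
#' @param x file path or JSON text
#' @return a [pathway_graph()]
#' @export
read_node_link <- function(x) {
  txt <- if (length(x) == 1 && !grepl("^[[:space:]]*[\\{\\[]", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "\n") else paste(x, collapse = "\n")
  data <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                   error = function(e) stop_format("malformed node-link JSON: ",
                                                   conditionMessage(e)))
  for (field in c("nodes", "links"))
    if (is.null(data[[field]]))
      stop_format("node-link JSON missing required field '", field, "'")
  req_node <- c("key", "class", "prefix", "identifier")
  nodes <- empty_nodes()
  for (n in data$nodes) {
    if (!all(req_node %in% names(n)))
      stop_format("node-link JSON node missing field(s): ",
                  paste(setdiff(req_node, names(n)), collapse = ", "))
    nodes <- rbind(nodes, tibble::tibble(
      key = n$key, class = n$class, prefix = n$prefix,
      identifier = n$identifier, label = n$label %||% "",
      mods = list(as.character(unlist(n$mods))),
      members = list(as.character(unlist(n$members)))))
  }
  req_link <- c("source", "target", "relation", "database", "pathway_id")
  edges <- empty_edges()
  for (l in data$links) {
    if (!all(req_link %in% names(l)))
      stop_format("node-link JSON link missing field(s): ",
                  paste(setdiff(req_link, names(l)), collapse = ", "))
    edges <- rbind(edges, tibble::tibble(
      subject = l$source, object = l$target, relation = l$relation,
      database = l$database, pathway_id = l$pathway_id,
      pathway_name = l$pathway_name %||% "",
      source_relation = l$source_relation %||% ""))
  }
  metadata <- NULL
  if (!is.null(data$metadata) && length(data$metadata)) {
    metadata <- do.call(rbind, lapply(data$metadata, function(m)
      tibble::tibble(database = m$database, pathway_id = m$pathway_id,
                     pathway_name = m$pathway_name %||% "")))
  }
  pathway_graph(nodes, edges, metadata = metadata)
}
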