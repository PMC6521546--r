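# Format-agnostic intermediate representation emitted by the three
# parsers and consumed by the conversion layer.

source_entities <- function() {
  tibble::tibble(local_id = character(), raw_type = character(),
                 label = character(), xrefs = list(), member_ids = list())
}

source_interactions <- function() {
  tibble::tibble(source_id = character(), target_id = character(),
                 raw_relations = list())
}

source_reactions <- function() {
  tibble::tibble(reaction_id = character(), reactant_ids = list(),
                 product_ids = list(), reversible = logical(),
                 modifier_ids = list())
}

#' Construct a source pathway (parser intermediate representation)
#'
#' All three parsers emit this structure: entities with their raw source
#' type and candidate cross-references, pairwise interactions with raw
#' relation labels, and reified reactions with reactant/product/modifier
#' lists. Raw types and relations are mapped to the unified model later,
#' by [to_unified()].
#'
#' @param database one of "kegg", "reactome", "wikipathways"
#' @param pathway_id source accession of the pathway
#' @param pathway_name display name
#' @param entities,interactions,reactions tibbles (see the parsers)
#' @return object of class `source_pathway`
#' @export
source_pathway <- function(database, pathway_id, pathway_name = "",
                           entities = source_entities(),
                           interactions = source_interactions(),
                           reactions = source_reactions()) {
  database <- match.arg(database, c("kegg", "reactome", "wikipathways"))
  entities <- tibble::as_tibble(entities)
  interactions <- tibble::as_tibble(interactions)
  reactions <- tibble::as_tibble(reactions)
  if (nrow(entities) && anyDuplicated(entities$local_id))
    stop("duplicate local_id in source entities")
  if (nrow(interactions)) {
    # controls (e.g. BioPAX Catalysis) may point at a reified reaction
    known <- c(entities$local_id, reactions$reaction_id)
    ok <- interactions$source_id %in% known & interactions$target_id %in% known
    if (!all(ok)) stop("interaction endpoints reference unknown local_ids: ",
                       paste(utils::head(c(interactions$source_id[!ok],
                                           interactions$target_id[!ok]), 5),
                             collapse = ", "))
  }
  structure(list(database = database,
                 pathway_id = as.character(pathway_id),
                 pathway_name = as.character(pathway_name %||% ""),
                 entities = entities, interactions = interactions,
                 reactions = reactions),
            class = "source_pathway")
}

#' @export
print.source_pathway <- function(x, ...) {
  cat(sprintf("<source_pathway> %s:%s \"%s\" — %d entities, %d interactions, %d reactions\n",
              x$database, x$pathway_id, x$pathway_name,
              nrow(x$entities), nrow(x$interactions), nrow(x$reactions)))
  invisible(x)
}
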