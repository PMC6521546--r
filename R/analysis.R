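# Comparative analytics over harmonized graphs: provenance-aware
# merging, gene-level collapsing, the Szymkiewicz-Simpson overlap
# coefficient, the three-way pathway similarity index, per-modality
# shared/partial/exclusive ratios and consensus/contradiction
# detection.

#' Merge pathway graphs into one provenance-tagged network
#'
#' Unites node sets by node key and keeps all edges with their
#' provenance, so each source network's boundary remains queryable by
#' database/pathway in the merged graph (the basis of crosstalk
#' exploration). Idempotent on nodes: merging a graph with itself
#' leaves the node set unchanged.
#'
#' @param graphs list of [pathway_graph()] objects (length >= 1)
#' @return merged `pathway_graph`
#' @export
merge_graphs <- function(graphs) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1)
  nodes <- do.call(bind_nodes, lapply(graphs, function(g) g$nodes))
  edges <- do.call(rbind, lapply(graphs, function(g) g$edges))
  metadata <- unique(do.call(rbind, lapply(graphs, function(g) g$metadata)))
  pathway_graph(nodes, edges, metadata = metadata)
}

#' Collapse genes, RNAs and proteins into gene nodes
#'
#' Every `protein`, `rna` and `gene` node sharing one resolved
#' identifier (modifications stripped) becomes a single `gene` node;
#' incident edges are rewired and deduplicated. Databases use these
#' classes interchangeably, so collapsing is what makes cross-database
#' topology and entity-set comparisons fair. miRNA, abundance and
#' bioprocess nodes are untouched.
#'
#' @param g a [pathway_graph()]
#' @return collapsed `pathway_graph`
#' @export
collapse_to_genes <- function(g) {
  collapsible <- g$nodes$class %in% c("gene", "rna", "protein")
  if (!any(collapsible)) return(g)
  new_key <- stats::setNames(g$nodes$key, g$nodes$key)
  new_key[collapsible] <- node_key_vec("gene", g$nodes$prefix[collapsible],
                                       g$nodes$identifier[collapsible])
  nodes <- g$nodes
  nodes$key <- unname(new_key[nodes$key])
  nodes$class[collapsible] <- "gene"
  nodes$mods[collapsible] <- list(character())
  nodes <- nodes[!duplicated(nodes$key), ]
  nodes$members <- lapply(nodes$members, function(m) unique(unname(new_key[m])))
  edges <- g$edges
  if (nrow(edges)) {
    edges$subject <- unname(new_key[edges$subject])
    edges$object <- unname(new_key[edges$object])
  }
  pathway_graph(nodes, edges, metadata = g$metadata)
}

# vectorized node_key without per-element match.arg overhead
node_key_vec <- function(node_class, prefix, identifier) {
  paste0(node_class, "|", tolower(prefix), ":", identifier)
}

#' Szymkiewicz-Simpson overlap coefficient
#'
#' `|X intersect Y| / min(|X|, |Y|)`, the pairwise set-similarity
#' measure between two molecular-entity sets. Symmetric, in \[0, 1\].
#' By convention 0 when either set is empty (an empty set arises when a
#' source file holds no convertible content).
#'
#' @param x,y character vectors treated as sets (duplicates ignored)
#' @return numeric scalar in \[0, 1\]
#' @examples
#' overlap_coefficient(c("a", "b", "c"), c("b", "c", "d"))  # 2/3
#' @export
overlap_coefficient <- function(x, y) {
  x <- unique(x); y <- unique(y)
  m <- min(length(x), length(y))
  if (m == 0) return(0)
  length(intersect(x, y)) / m
}

#' Three-way pathway similarity index
#'
#' The mean of the three pairwise overlap coefficients between the
#' KEGG, Reactome and WikiPathways entity sets of one pathway:
#' `(S(K,R) + S(K,W) + S(R,W)) / 3`. Lies in \[0, 1\] — 0 when no pair
#' of sets overlaps, 1 when all three fully overlap — and is invariant
#' under permutation of its arguments.
#'
#' @param kegg,reactome,wikipathways character vectors treated as sets
#' @return numeric scalar in \[0, 1\]
#' @export
similarity_index <- function(kegg, reactome, wikipathways) {
  coeffs <- c(overlap_coefficient(kegg, reactome),
              overlap_coefficient(kegg, wikipathways),
              overlap_coefficient(reactome, wikipathways))
  # summing in sorted order makes the result exactly permutation invariant
  sum(sort(coeffs)) / 3
}

#' Shared / partial / exclusive overlap ratios of three sets
#'
#' Fractions of the three-set union present in all three sets
#' (`shared`), in exactly two (`partial`), and in exactly one
#' (`exclusive`). The three ratios sum to 1.
#'
#' @param a,b,c character vectors treated as sets
#' @return named numeric vector c(shared, partial, exclusive)
#' @export
modality_overlap <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  if (!length(u)) stop("modality_overlap: all three sets are empty")
  count <- (u %in% a) + (u %in% b) + (u %in% c)
  c(shared = sum(count == 3) / length(u),
    partial = sum(count == 2) / length(u),
    exclusive = sum(count == 1) / length(u))
}

#' Molecular entity sets of a graph, by modality
#'
#' Splits a graph's molecular entities into the four modalities:
#' `genes` (gene, RNA and protein nodes, pooled at the gene level with
#' modifications stripped), `mirnas`, `metabolites` (abundances) and
#' `biological_processes`. Group nodes (complex/family) and reaction
#' nodes are excluded everywhere — they aggregate rather than denote
#' individual molecular entities.
#'
#' @param g a [pathway_graph()]
#' @param collapse collapse gene/RNA/protein to gene level first
#'   (default TRUE; disable for sensitivity analysis)
#' @return named list of character vectors of node keys
#' @export
entity_sets_by_modality <- function(g, collapse = TRUE) {
  if (collapse) g <- collapse_to_genes(g)
  keys_of <- function(classes) g$nodes$key[g$nodes$class %in% classes]
  list(genes = keys_of(c("gene", "rna", "protein")),
       mirnas = keys_of("mirna"),
       metabolites = keys_of("abundance"),
       biological_processes = keys_of("bioprocess"))
}

#' All molecular entities of a graph (similarity set)
#'
#' The union of the four modality sets: every individual molecular
#' entity, excluding group and reaction nodes. This is the set the
#' similarity index is computed over; restrict with `modality`.
#'
#' @inheritParams entity_sets_by_modality
#' @param modality one of "all", "genes", "mirnas", "metabolites",
#'   "biological_processes"
#' @return character vector of node keys
#' @export
entity_set <- function(g, modality = "all", collapse = TRUE) {
  sets <- entity_sets_by_modality(g, collapse = collapse)
  if (modality == "all") unlist(sets, use.names = FALSE) else sets[[modality]]
}

#' Maximum achievable pairwise overlap between sets of given sizes
#'
#' When two databases hold very different numbers of entities of one
#' modality, the smaller set caps the possible consensus: at most
#' `min(n_x, n_y)` entities can be common, so the maximum overlap
#' fraction relative to the larger set is `min/max`.
#'
#' @param size_x,size_y non-negative set sizes, not both zero
#' @return numeric scalar in \[0, 1\]
#' @examples
#' max_pairwise_overlap_bound(4048, 655)  # 0.1618 = 16.18%
#' @export
max_pairwise_overlap_bound <- function(size_x, size_y) {
  stopifnot(size_x >= 0, size_y >= 0)
  if (max(size_x, size_y) == 0)
    stop("max_pairwise_overlap_bound: both sizes are zero")
  min(size_x, size_y) / max(size_x, size_y)
}

#' Detect consensus and contradictory relationships in a merged graph
#'
#' For every ordered node pair carrying two or more polar edges
#' (polarity != 0) from two or more distinct source pathways, reports
#' whether the sources agree (`consensus`: all polarities equal) or
#' disagree (`contradictory`: both signs occur — A increases B in one
#' pathway and decreases it in another). Non-polar relations are
#' ignored. By default `increases`/`directly_increases` (and their
#' negative counterparts) count as equivalent polarity; with
#' `relation_exact = TRUE` only identical relation types form a
#' consensus.
#'
#' @param g a merged [pathway_graph()]
#' @param relation_exact require identical relation types for consensus
#' @return tibble: subject, object, n_sources, polarities (list),
#'   verdict
#' @export
detect_consensus <- function(g, relation_exact = FALSE) {
  out <- tibble::tibble(subject = character(), object = character(),
                        n_sources = integer(), polarities = list(),
                        verdict = character())
  e <- g$edges
  if (!nrow(e)) return(out)
  pol <- relation_polarity(e$relation)
  e <- e[pol != 0, ]; pol <- pol[pol != 0]
  if (!nrow(e)) return(out)
  pair <- paste(e$subject, e$object, sep = "\r")
  for (p in unique(pair)) {
    idx <- which(pair == p)
    prov <- unique(paste(e$database[idx], e$pathway_id[idx]))
    if (length(idx) < 2 || length(prov) < 2) next
    if (relation_exact) {
      agree <- length(unique(e$relation[idx])) == 1
    } else {
      agree <- length(unique(pol[idx])) == 1
    }
    out <- rbind(out, tibble::tibble(
      subject = e$subject[idx[1]], object = e$object[idx[1]],
      n_sources = length(prov),
      polarities = list(stats::setNames(pol[idx], paste(e$database[idx],
                                                        e$pathway_id[idx]))),
      verdict = if (agree) "consensus" else "contradictory"))
  }
  out
}

#' Summarize a pathway graph
#'
#' Global statistics of the harmonized content: node and edge totals
#' plus per-class and per-relation breakdowns.
#'
#' @param g a [pathway_graph()]
#' @return list(nodes, edges, by_class, by_relation)
#' @export
summarize_graph <- function(g) {
  list(nodes = nrow(g$nodes), edges = nrow(g$edges),
       by_class = table(factor(g$nodes$class, levels = node_classes())),
       by_relation = table(factor(g$edges$relation, levels = relation_types())))
}

#' Pairwise coefficients and similarity index for a pathway triple
#'
#' Computes the three pairwise overlap coefficients and the similarity
#' index over the molecular entity sets of one pathway's KEGG,
#' Reactome and WikiPathways graphs, in the comparison-report layout
#' (one row per pathway triple).
#'
#' @param kegg,reactome,wikipathways [pathway_graph()] objects
#' @param modality entity-set restriction, see [entity_set()]
#' @param collapse collapse to gene level first (default TRUE)
#' @return one-row tibble: s_kegg_reactome, s_kegg_wikipathways,
#'   s_reactome_wikipathways, similarity_index
#' @export
compare_pathways <- function(kegg, reactome, wikipathways,
                             modality = "all", collapse = TRUE) {
  k <- entity_set(kegg, modality, collapse)
  r <- entity_set(reactome, modality, collapse)
  w <- entity_set(wikipathways, modality, collapse)
  tibble::tibble(
    s_kegg_reactome = overlap_coefficient(k, r),
    s_kegg_wikipathways = overlap_coefficient(k, w),
    s_reactome_wikipathways = overlap_coefficient(r, w),
    similarity_index = similarity_index(k, r, w))
}

#' Venn-region counts of three entity sets
#'
#' Counts per region of the three-set Venn partition, keyed
#' `kegg`, `reactome`, `wikipathways`, `kegg_reactome`, ...,
#' `kegg_reactome_wikipathways` (exclusive regions).
#'
#' @param k,r,w character vectors treated as sets
#' @return named integer vector of the 7 region sizes
#' @export
venn_counts <- function(k, r, w) {
  k <- unique(k); r <- unique(r); w <- unique(w)
  u <- union(union(k, r), w)
  ink <- u %in% k; inr <- u %in% r; inw <- u %in% w
  c(kegg = sum(ink & !inr & !inw),
    reactome = sum(!ink & inr & !inw),
    wikipathways = sum(!ink & !inr & inw),
    kegg_reactome = sum(ink & inr & !inw),
    kegg_wikipathways = sum(ink & !inr & inw),
    reactome_wikipathways = sum(!ink & inr & inw),
    kegg_reactome_wikipathways = sum(ink & inr & inw))
}
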