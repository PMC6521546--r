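# Identifier normalization: cross-reference mapping tables and the
# per-modality namespace priority cascade (HGNC on top for genes and
# gene products, ChEBI then PubChem for metabolites, miRBase for
# miRNAs; entities with no route to a prioritized namespace retain
# their database-specific identifier).

NATIVE_SENTINEL <- "<native>"

#' Load a cross-reference mapping table
#'
#' Reads a 4-column, tab-separated table of identifier equivalences
#' (header `source_prefix  source_id  target_prefix  target_id`,
#' `#`-comment lines allowed). Lookups are indexed by
#' (source_prefix, source_id); when two rows map the same source to the
#' same target namespace with different identifiers the first-loaded
#' row wins and the conflict is warned about.
#'
#' @param path TSV file path, or a data frame already in that shape
#' @return a `mapping_table` object
#' @export
load_mapping_table <- function(path) {
  if (is.data.frame(path)) {
    df <- tibble::as_tibble(path)
    if (!identical(names(df), c("source_prefix", "source_id",
                                "target_prefix", "target_id")))
      stop_format("mapping table needs columns source_prefix/source_id/",
                  "target_prefix/target_id")
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^[[:space:]]*(#|$)", lines)
    lines <- lines[keep]; line_no <- which(keep)
    if (!length(lines)) stop_format("empty mapping table file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 4))
      stop_format("mapping table ", path, ": expected 4 tab-separated columns, ",
                  "got ", nf[nf != 4][1], " at line ", line_no[nf != 4][1])
    m <- do.call(rbind, fields)
    header <- tolower(trimws(m[1, ]))
    if (!identical(header, c("source_prefix", "source_id",
                             "target_prefix", "target_id")))
      stop_format("mapping table ", path, ": bad header (",
                  paste(m[1, ], collapse = "/"), ")")
    m <- m[-1, , drop = FALSE]
    df <- tibble::tibble(source_prefix = tolower(trimws(m[, 1])),
                         source_id = trimws(m[, 2]),
                         target_prefix = tolower(trimws(m[, 3])),
                         target_id = trimws(m[, 4]))
  }
  self <- df$source_prefix == df$target_prefix & df$source_id == df$target_id
  if (any(self)) {
    warn_beltway("dropping ", sum(self), " self-mapping row(s)")
    df <- df[!self, ]
  }
  index <- new.env(parent = emptyenv())
  dup <- 0L
  if (nrow(df)) for (i in seq_len(nrow(df))) {
    key <- paste0(df$source_prefix[i], ":", df$source_id[i])
    tgt <- get0(key, envir = index, ifnotfound = character())
    if (df$target_prefix[i] %in% names(tgt)) {
      if (!identical(tgt[[df$target_prefix[i]]], df$target_id[i])) dup <- dup + 1L
      next   # first-loaded row wins
    }
    tgt[[df$target_prefix[i]]] <- df$target_id[i]
    assign(key, tgt, envir = index)
  }
  if (dup) warn_beltway(dup, " conflicting duplicate mapping row(s) ignored ",
                        "(first-loaded row wins)")
  structure(list(rows = df, index = index), class = "mapping_table")
}

#' An empty mapping table
#' @return a `mapping_table` with no rows
#' @export
empty_mapping_table <- function() {
  load_mapping_table(tibble::tibble(source_prefix = character(),
                                    source_id = character(),
                                    target_prefix = character(),
                                    target_id = character()))
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table> %d row(s)\n", nrow(x$rows)))
  invisible(x)
}

# Direct lookups of one (prefix, id): named character target_prefix -> id.
mapping_lookup <- function(table, prefix, id) {
  get0(paste0(tolower(prefix), ":", id), envir = table$index,
       ifnotfound = character())
}

#' Default namespace priority configuration
#'
#' Ordered namespace lists per modality, each terminated by the
#' native-fallback sentinel: genes and gene products resolve towards
#' HGNC (through UniProt, NCBI Gene or Ensembl intermediates),
#' metabolites towards ChEBI then PubChem, miRNAs towards miRBase.
#' Everything else (biological processes and unmapped entities) keeps
#' its database-native identifier.
#'
#' @return named list of character vectors, class `priority_config`
#' @export
default_priority_config <- function() {
  structure(list(
    genes       = c("hgnc", "uniprot", "ncbigene", "ensembl", NATIVE_SENTINEL),
    metabolites = c("chebi", "pubchem.compound", NATIVE_SENTINEL),
    mirnas      = c("mirbase", "hgnc", NATIVE_SENTINEL),
    bioprocess  = c(NATIVE_SENTINEL)
  ), class = "priority_config")
}

#' Load a priority configuration file
#'
#' Two-column tab-separated text: modality, then a comma-separated
#' ordered namespace list. A trailing native sentinel is appended when
#' missing. Modalities absent from the file keep the defaults.
#'
#' @param path file path
#' @return `priority_config`
#' @export
load_priority_config <- function(path) {
  cfg <- default_priority_config()
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop_format("priority config: expected 2 tab-separated columns in '", ln, "'")
    ns <- trimws(strsplit(parts[2], ",")[[1]])
    if (!length(ns)) stop_format("priority config: empty namespace list for ", parts[1])
    if (utils::tail(ns, 1) != NATIVE_SENTINEL) ns <- c(ns, NATIVE_SENTINEL)
    cfg[[trimws(parts[1])]] <- ns
  }
  cfg
}

# All (prefix -> identifier) pairs reachable from one xref through the
# mapping table in at most max_hops hops, cycle-safe. Nearer hops win a
# namespace; within a hop, insertion order is table order.
reachable_namespaces <- function(table, prefix, id, max_hops = 2L) {
  out <- stats::setNames(id, tolower(prefix))
  frontier <- list(c(tolower(prefix), id))
  visited <- paste0(tolower(prefix), ":", id)
  for (hop in seq_len(max_hops)) {
    nxt <- list()
    for (node in frontier) {
      hits <- mapping_lookup(table, node[1], node[2])
      for (ns in names(hits)) {
        key <- paste0(ns, ":", hits[[ns]])
        if (key %in% visited) next
        visited <- c(visited, key)
        if (!ns %in% names(out)) out[[ns]] <- hits[[ns]]
        nxt <- c(nxt, list(c(ns, hits[[ns]])))
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  out
}

#' Detect a miRNA entity
#'
#' GPML and KGML type miRNAs as generic gene products, so miRNA status
#' is inferred before modality assignment: either a miRBase
#' cross-reference or a label matching the lowercase `-mir-` / `-let-`
#' nomenclature pattern.
#'
#' @param xrefs list of [curie()] candidates
#' @param label entity display label
#' @return logical scalar
#' @export
is_mirna <- function(xrefs, label = "") {
  any(vapply(xrefs, function(x) identical(x$prefix, "mirbase"), logical(1))) ||
    grepl("(-mir-|-let-)", tolower(label %||% ""))
}

#' Resolve cross-references to a single prioritized identifier
#'
#' Walks the modality's namespace priority list and returns the first
#' achievable identifier: an xref already in a prioritized namespace,
#' or any xref that maps into one directly or transitively through at
#' most two hops (e.g. database-native -> UniProt -> HGNC). The highest
#' reachable namespace wins; ties between xrefs are broken by xref
#' order (a disagreement between xrefs on the target identifier is
#' warned about). With no route into a prioritized namespace the first
#' xref is returned unchanged; with no xrefs at all a synthetic
#' database-local identifier is minted from the label.
#'
#' @param xrefs list of [curie()] candidates (possibly empty)
#' @param modality one of names([default_priority_config()]); unknown
#'   modalities fall back to native identifiers
#' @param table a [load_mapping_table()] result
#' @param config a priority configuration
#' @param database source database token, used for the synthetic
#'   fallback prefix
#' @param label entity label, used for the synthetic fallback identifier
#' @return a single [curie()]
#' @export
resolve_xrefs <- function(xrefs, modality = "genes",
                          table = empty_mapping_table(),
                          config = default_priority_config(),
                          database = "kegg", label = "") {
  xrefs <- Filter(Negate(is.null), xrefs)
  if (!length(xrefs))
    return(curie(paste0(database, ".local"), label_slug(label), label))
  if (!nzchar(label)) {
    labels <- vapply(xrefs, function(x) x$label, character(1))
    label <- c(labels[nzchar(labels)], "")[1]
  }
  priorities <- setdiff(config[[modality]] %||% NATIVE_SENTINEL, NATIVE_SENTINEL)
  if (length(priorities)) {
    reach <- lapply(xrefs, function(x)
      reachable_namespaces(table, x$prefix, x$identifier))
    for (ns in priorities) {
      hits <- vapply(reach, function(r)
        if (ns %in% names(r)) r[[ns]] else NA_character_, character(1))
      found <- which(!is.na(hits))
      if (length(found)) {
        if (length(unique(hits[found])) > 1)
          warn_beltway("xrefs disagree on ", ns, " target (",
                       paste(unique(hits[found]), collapse = " vs "),
                       "); taking xref-order winner")
        return(curie(ns, hits[found[1]], label))
      }
    }
  }
  first <- xrefs[[1]]
  curie(first$prefix, first$identifier, label)
}
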