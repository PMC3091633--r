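# Ranked taxonomy: a data.frame (taxid, parent, rank, name) wrapped in an
# S3 class with an id -> row index for O(1) lookups. Exactly one root
# (parent == self); parent links must be acyclic and closed.

new_taxonomy <- function(nodes) {
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  nodes$rank <- tolower(as.character(nodes$rank))
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$taxid))
    stop("duplicate taxid: ", nodes$taxid[duplicated(nodes$taxid)][1L])
  idx <- seq_len(nrow(nodes))
  names(idx) <- nodes$taxid
  tax <- structure(list(nodes = nodes, index = idx), class = "taxonomy")
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  nodes <- tax$nodes
  roots <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root (parent == self); found ",
         length(roots))
  orphan <- !(nodes$parent %in% nodes$taxid)
  if (any(orphan))
    stop("orphan parent ", nodes$parent[orphan][1L], " for taxid ",
         nodes$taxid[orphan][1L])
  # acyclicity: walk every lineage; a walk longer than the node count
  # proves a cycle
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    id <- nodes$taxid[i]
    steps <- 0L
    while (id != nodes$parent[tax$index[[as.character(id)]]]) {
      id <- nodes$parent[tax$index[[as.character(id)]]]
      steps <- steps + 1L
      if (steps > n)
        stop("cycle detected in taxonomy involving taxid ", nodes$taxid[i])
    }
  }
  invisible(tax)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes; ranks: %s\n", nrow(x$nodes),
              paste(sort(unique(x$nodes$rank)), collapse = ", ")))
  invisible(x)
}

#' Load a taxonomy
#'
#' Two dialects are supported. \code{"tsv"}: a tab-separated file with
#' columns \code{taxid}, \code{parent}, \code{rank}, \code{name} (header
#' required). \code{"taxdump"}: the NCBI distribution layout — \code{path}
#' is a directory containing \code{nodes.dmp} and \code{names.dmp} with
#' pipe-tab (\code{\\t|\\t}) field delimiters; only names of class
#' \code{scientific name} are kept.
#'
#' @param path File (tsv) or directory (taxdump).
#' @param dialect \code{"tsv"} or \code{"taxdump"}.
#' @return A \code{taxonomy} object.
#' @export
load_taxonomy <- function(path, dialect = c("tsv", "taxdump")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    nodes <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c("integer", "integer",
                                              "character", "character"))
    need <- c("taxid", "parent", "rank", "name")
    if (!all(need %in% names(nodes)))
      stop("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
    return(new_taxonomy(nodes[need]))
  }
  nodes_file <- file.path(path, "nodes.dmp")
  names_file <- file.path(path, "names.dmp")
  if (!file.exists(nodes_file) || !file.exists(names_file))
    stop("taxdump directory must contain nodes.dmp and names.dmp: ", path)
  parse_dmp <- function(f) {
    lines <- readLines(f)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nd <- parse_dmp(nodes_file)
  bad <- which(vapply(nd, length, 0L) < 3L)
  if (length(bad))
    stop("malformed nodes.dmp line ", bad[1L])
  nodes <- data.frame(
    taxid = as.integer(vapply(nd, `[`, "", 1L)),
    parent = as.integer(vapply(nd, `[`, "", 2L)),
    rank = vapply(nd, `[`, "", 3L),
    stringsAsFactors = FALSE)
  nm <- parse_dmp(names_file)
  bad <- which(vapply(nm, length, 0L) < 4L)
  if (length(bad))
    stop("malformed names.dmp line ", bad[1L])
  cls <- vapply(nm, `[`, "", 4L)
  sci <- nm[cls == "scientific name"]
  name_map <- vapply(sci, `[`, "", 2L)
  names(name_map) <- vapply(sci, `[`, "", 1L)
  nodes$name <- unname(name_map[as.character(nodes$taxid)])
  nodes$name[is.na(nodes$name)] <- ""
  new_taxonomy(nodes)
}

#' Build a taxonomy from vectors
#'
#' Programmatic constructor used by the community generator and tests.
#'
#' @param taxid,parent Integer vectors; the root has \code{parent == taxid}.
#' @param rank,name Character vectors.
#' @return A \code{taxonomy} object.
#' @export
taxonomy <- function(taxid, parent, rank, name) {
  new_taxonomy(data.frame(taxid = taxid, parent = parent, rank = rank,
                          name = name, stringsAsFactors = FALSE))
}

#' Write a taxonomy as 4-column TSV
#' @param tax A taxonomy.
#' @param path Output file.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  utils::write.table(tax$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

taxon_row <- function(tax, taxid) {
  i <- tax$index[as.character(taxid)]
  if (is.na(i)) stop("unknown taxid: ", taxid)
  i
}

#' Lineage of a taxon
#'
#' @param tax A taxonomy.
#' @param taxid Node id.
#' @return Integer vector of taxids from the node (inclusive) up to the
#'   root (inclusive).
#' @export
lineage <- function(tax, taxid) {
  i <- taxon_row(tax, taxid)
  out <- integer()
  repeat {
    out <- c(out, tax$nodes$taxid[i])
    p <- tax$nodes$parent[i]
    if (p == tax$nodes$taxid[i]) break
    i <- taxon_row(tax, p)
  }
  out
}

#' Ancestor of a taxon at a given rank
#'
#' Walks parent links from the node (including the node itself) and
#' returns the first ancestor whose rank matches (case-insensitive exact
#' string match). Returns NA when the lineage carries no node of that
#' rank — e.g. a genus-level record queried at species rank — so that
#' clade-level annotations degrade gracefully.
#'
#' @param tax A taxonomy.
#' @param taxid Node id (errors if unknown).
#' @param rank Rank string, e.g. \code{"species"}, \code{"genus"},
#'   \code{"family"}.
#' @return The ancestor's taxid, or \code{NA_integer_}.
#' @export
ancestor_at_rank <- function(tax, taxid, rank) {
  rank <- tolower(rank)
  i <- taxon_row(tax, taxid)
  repeat {
    if (tax$nodes$rank[i] == rank) return(tax$nodes$taxid[i])
    p <- tax$nodes$parent[i]
    if (p == tax$nodes$taxid[i]) return(NA_integer_)
    i <- taxon_row(tax, p)
  }
}

# Vectorized convenience used by the amplifier and the indices.
ancestors_at_rank <- function(tax, taxids, rank) {
  vapply(taxids, function(id) {
    if (is.na(id) || !(as.character(id) %in% names(tax$index)))
      return(NA_integer_)
    ancestor_at_rank(tax, id, rank)
  }, NA_integer_)
}

taxon_name <- function(tax, taxid) {
  ifelse(is.na(taxid), "",
         tax$nodes$name[tax$index[as.character(taxid)]])
}
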