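## Interaction network container and interchange formats.
##
## An `interactome` is a light S3 container holding two data.frames:
##   nodes: protein, role ("bait", "prey", "pY-added"), sites (";"-joined)
##   edges: from, to, evidence ("TAP" or "database"), support
## TAP edges always have a bait endpoint in `from`; edges are undirected in
## meaning but stored once.

#' Construct an interaction network
#'
#' @param nodes data.frame with columns `protein`, `role` and optionally
#'   `sites`; one row per protein.
#' @param edges data.frame with columns `from`, `to`, `evidence`, `support`.
#' @return an object of class `interactome`
#' @export
interactome <- function(nodes = data.frame(protein = character(),
                                           role = character(),
                                           sites = character()),
                        edges = data.frame(from = character(),
                                           to = character(),
                                           evidence = character(),
                                           support = numeric())) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"sites" %in% names(nodes)) nodes$sites <- rep("", nrow(nodes))
  stopifnot(all(c("protein", "role") %in% names(nodes)))
  if (nrow(edges)) {
    stopifnot(all(c("from", "to", "evidence") %in% names(edges)))
    if (!"support" %in% names(edges)) edges$support <- NA_real_
    miss <- setdiff(c(edges$from, edges$to), nodes$protein)
    if (length(miss))
      stop("edge endpoints missing from node table: ",
           paste(miss, collapse = ", "))
  } else {
    edges <- data.frame(from = character(), to = character(),
                        evidence = character(), support = numeric())
  }
  if (anyDuplicated(nodes$protein)) stop("duplicated node identifiers")
  ## canonical edge orientation: TAP edges lead with a bait endpoint,
  ## database edges with the lexicographically smaller protein
  if (nrow(edges)) {
    role <- setNames(nodes$role, nodes$protein)
    swap <- ifelse(edges$evidence == "TAP",
                   role[edges$from] != "bait" & role[edges$to] == "bait",
                   edges$from > edges$to)
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  ## canonical order makes outputs independent of input row order
  nodes <- nodes[order(nodes$protein), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to, edges$evidence), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tab <- table(x$nodes$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  tab <- table(x$edges$evidence)
  if (length(tab))
    cat("  evidence:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert an interactome to an igraph graph
#'
#' Node roles, site annotations and edge evidence/support become igraph
#' attributes.
#'
#' @param net an `interactome`
#' @return an undirected `igraph` graph
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interactome"))
  v <- data.frame(name = net$nodes$protein, role = net$nodes$role,
                  sites = net$nodes$sites, stringsAsFactors = FALSE)
  e <- net$edges[, c("from", "to", "evidence", "support")]
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

.from_igraph <- function(g) {
  nodes <- data.frame(protein = igraph::V(g)$name,
                      role = igraph::V(g)$role,
                      sites = if (is.null(igraph::V(g)$sites)) "" else
                        igraph::V(g)$sites,
                      stringsAsFactors = FALSE)
  nodes$sites[is.na(nodes$sites)] <- ""
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(from = el$from, to = el$to,
                      evidence = el$evidence,
                      support = if (is.null(el$support)) NA_real_ else
                        as.numeric(el$support),
                      stringsAsFactors = FALSE)
  interactome(nodes, edges)
}

#' Write a network to GraphML or SIF
#'
#' GraphML round-trips all node and edge attributes; SIF is a lossy
#' Cytoscape edge list (`A tap B` / `A db B`, no node attributes).
#'
#' @param net an `interactome`
#' @param path output file
#' @param format `"graphml"` or `"sif"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "interactome"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    rel <- ifelse(net$edges$evidence == "TAP", "tap", "db")
    lines <- paste(net$edges$from, rel, net$edges$to)
    ## isolated nodes still get a line of their own so they survive export
    iso <- setdiff(net$nodes$protein, c(net$edges$from, net$edges$to))
    writeLines(c(lines, iso), path)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path GraphML file
#' @param format only `"graphml"` is supported for reading (SIF is lossy)
#' @return an `interactome`
#' @export
read_network <- function(path, format = "graphml") {
  if (format != "graphml") stop("only GraphML can be read back losslessly")
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("malformed GraphML in ", path, ": ",
                                         conditionMessage(e)))
  .from_igraph(g)
}

## PPI reference --------------------------------------------------------------

#' Construct a protein-protein interaction reference
#'
#' Edges are undirected and deduplicated; self-loops are dropped.
#'
#' @param a,b character vectors of interactor identifiers
#' @param source optional source tags
#' @return a `ppi_reference` (data.frame with columns a, b, source)
#' @export
ppi_reference <- function(a, b, source = "user") {
  keep <- a != b
  a2 <- pmin(a[keep], b[keep])
  b2 <- pmax(a[keep], b[keep])
  source <- rep_len(source, length(a))[keep]
  df <- data.frame(a = a2, b = b2, source = source,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$a, df$b)), , drop = FALSE]
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ppi_reference", "data.frame")
  df
}

#' Test whether two proteins interact in a PPI reference
#'
#' @param ppi a `ppi_reference`
#' @param x,y protein identifiers (vectorised over `x`)
#' @return logical
#' @export
ppi_has_edge <- function(ppi, x, y) {
  key <- paste(pmin(x, y), pmax(x, y))
  key %in% paste(ppi$a, ppi$b)
}

#' Neighbours of a protein in a PPI reference
#'
#' @param ppi a `ppi_reference`
#' @param x protein identifier
#' @return character vector of interaction partners
#' @export
ppi_neighbors <- function(ppi, x) {
  sort(unique(c(ppi$b[ppi$a == x], ppi$a[ppi$b == x])))
}

#' Read a PSI-MITAB 2.5 interaction file
#'
#' Only the first two columns (interactor identifiers) are used; a
#' `db:accession` prefix is stripped. Rows with fewer than 15 columns are
#' skipped with a single warning giving the count. Self-loops are dropped
#' and duplicate pairs (either orientation) are merged.
#'
#' @param path MITAB file; a leading `#` header line is allowed
#' @param source tag recorded for every edge
#' @return a `ppi_reference`
#' @export
read_mitab <- function(path, source = "mitab") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 15L
  if (any(!ok))
    warning(sum(!ok), " MITAB row(s) with fewer than 15 columns skipped")
  if (!any(ok)) return(ppi_reference(character(), character()))
  strip <- function(x) sub("^[^:]+:", "", x)
  a <- strip(vapply(fields[ok], `[[`, "", 1L))
  b <- strip(vapply(fields[ok], `[[`, "", 2L))
  ppi_reference(a, b, source = source)
}

#' Read a two-column TSV of interactions
#'
#' @param path TSV with at least two columns (header required)
#' @param source tag recorded for every edge
#' @return a `ppi_reference`
#' @export
read_ppi_tsv <- function(path, source = "tsv") {
  df <- read_table_file(path)
  if (ncol(df) < 2) stop("PPI TSV needs at least two columns: ", path)
  ppi_reference(as.character(df[[1]]), as.character(df[[2]]), source = source)
}

#' Write a PPI reference as a two-column TSV
#'
#' @param ppi a `ppi_reference`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ppi_tsv <- function(ppi, path) {
  write_table_file(data.frame(protein_a = ppi$a, protein_b = ppi$b,
                              source = ppi$source), path)
}
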