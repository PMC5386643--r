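#' Protein-protein interaction networks
#'
#' A `ppi_network` is an undirected simple graph over official gene symbols:
#' no self-loops, no duplicate edges, symbols non-empty and stored uppercase.
#' It is the substrate on which node neighborhoods — and hence per-node Gibbs
#' free energies — are defined.
#'
#' @param edges a data frame whose first two columns are the interacting gene
#'   symbols, or `NULL` for an edgeless network.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node symbols.
#' @param name free-text label for the network.
#'
#' @return An object of class `ppi_network`.
#'
#' @examples
#' net <- ppi_network(data.frame(a = c("TP53", "MDM2"), b = c("MDM2", "EGFR")))
#' net
#' ppi_nodes(net)
#' ppi_edges(net)
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, name = "ppi") {
  if (!is.null(edges)) {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2) abort("`edges` needs at least two columns.")
    a <- clean_symbol(edges[[1]])
    b <- clean_symbol(edges[[2]])
  } else {
    a <- b <- character()
  }
  nodes <- clean_symbol(nodes %||% character())
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = unique(c(a, b, nodes)))
  )
  new_ppi_network(g, name)
}

# wrap an igraph object, enforcing the class invariants
new_ppi_network <- function(g, name = "ppi") {
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  structure(list(graph = g, name = name), class = "ppi_network")
}

clean_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x) | is.na(x))) abort("Gene symbols must be non-empty.")
  x
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network '%s': %d nodes, %d edges>\n",
    x$name, n_nodes(x), n_edges(x)
  ))
  invisible(x)
}

#' Network accessors
#'
#' @param net a [ppi_network].
#' @return `ppi_nodes()` the character vector of gene symbols; `ppi_edges()`
#'   a tibble with columns `from`/`to`; `n_nodes()`/`n_edges()` counts;
#'   `as_igraph()` the underlying igraph object.
#' @export
ppi_nodes <- function(net) igraph::V(net$graph)$name

#' @rdname ppi_nodes
#' @export
ppi_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  tibble(from = as.character(el[, 1]), to = as.character(el[, 2]))
}

#' @rdname ppi_nodes
#' @export
n_nodes <- function(net) igraph::vcount(net$graph)

#' @rdname ppi_nodes
#' @export
n_edges <- function(net) igraph::ecount(net$graph)

#' @rdname ppi_nodes
#' @export
as_igraph <- function(net) net$graph

#' @export
glance.ppi_network <- function(x, ...) {
  tibble(
    name = x$name,
    n_nodes = n_nodes(x),
    n_edges = n_edges(x),
    n_components = if (n_nodes(x) == 0) 0L else igraph::components(x$graph)$no
  )
}

# ---- readers -----------------------------------------------------------

# normalize a header name for dialect-insensitive matching
squash_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

find_column <- function(nms, patterns, what) {
  squashed <- squash_name(nms)
  for (p in patterns) {
    hit <- which(squashed == p)
    if (length(hit)) return(hit[1])
  }
  abort(sprintf(
    "BioGrid file is missing a required column: %s (looked for %s).",
    what, paste(patterns, collapse = " / ")
  ))
}

#' Read a BioGrid TAB2/TAB3 interaction file
#'
#' Parses a tab-delimited BioGrid export into a [ppi_network]. One node per
#' distinct official symbol; one edge per distinct interacting pair.
#' Self-interactions are dropped, duplicate records (reversed order, repeated
#' evidence lines) are collapsed, and symbols are uppercased. The TAB2 and
#' TAB3 dialects are both accepted: required columns are detected by header
#' name ("Official Symbol Interactor A/B" and, when `organism_id` is given,
#' "Organism (ID) Interactor A/B").
#'
#' @param path path to the tab-delimited file. A leading `#` on the header
#'   line is tolerated.
#' @param organism_id optional NCBI taxonomy id (e.g. 9606 for human); when
#'   given, only rows where both interactors match are kept.
#' @param name label for the returned network.
#'
#' @return A [ppi_network].
#' @export
read_biogrid <- function(path, organism_id = NULL, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) abort("BioGrid file is empty.")
  header <- sub("^#", "", lines[[1]])
  nms <- strsplit(header, "\t", fixed = TRUE)[[1]]
  ia <- find_column(nms, "officialsymbolinteractora", "Official Symbol Interactor A")
  ib <- find_column(nms, "officialsymbolinteractorb", "Official Symbol Interactor B")
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (!is.null(organism_id)) {
    oa <- find_column(nms, c("organisminteractora", "organismidinteractora"),
                      "Organism Interactor A")
    ob <- find_column(nms, c("organisminteractorb", "organismidinteractorb"),
                      "Organism Interactor B")
    keep <- vapply(rows, function(r) {
      length(r) >= max(oa, ob) &&
        identical(r[[oa]], as.character(organism_id)) &&
        identical(r[[ob]], as.character(organism_id))
    }, logical(1))
    rows <- rows[keep]
  }
  pairs <- vapply(
    rows,
    function(r) c(r[[ia]], r[[ib]]),
    character(2)
  )
  if (length(pairs)) {
    a <- toupper(trimws(pairs[1, ]))
    b <- toupper(trimws(pairs[2, ]))
    ok <- nzchar(a) & nzchar(b) & a != b & a != "-" & b != "-"
    a <- a[ok]; b <- b[ok]
  } else {
    a <- b <- character()
  }
  if (length(a) == 0) {
    abort("No interactions left after filtering: the network would be empty.")
  }
  ppi_network(data.frame(a = a, b = b), name = name)
}

#' Read a plain edge list
#'
#' Two whitespace- or tab-separated gene symbols per line; lines beginning
#' with `#` and blank lines are ignored, except `# node SYMBOL` lines, which
#' declare isolated nodes (the form [write_edge_list()] emits). Self-loops
#' are dropped and duplicate edges (either orientation) collapsed.
#'
#' @param path path to the edge-list file.
#' @param name label for the returned network.
#' @return A [ppi_network].
#' @export
read_edge_list <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^\\s*#\\s*node\\s+", "", grep("^\\s*#\\s*node\\s+\\S+\\s*$", lines, value = TRUE))
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2)
  if (length(bad)) {
    abort(sprintf(
      "Line %d of '%s' has %d tokens (expected 2).",
      idx[bad[1]], path, lengths(toks)[bad[1]]
    ))
  }
  if (length(toks) == 0 && length(iso) == 0) {
    abort("Edge-list file contains no edges: the network would be empty.")
  }
  m <- if (length(toks)) do.call(rbind, toks) else matrix(character(), ncol = 2)
  net <- ppi_network(data.frame(a = m[, 1], b = m[, 2]), nodes = iso, name = name)
  if (n_nodes(net) == 0) abort("Edge-list file yields an empty network.")
  net
}

#' Write a network as a plain edge list
#'
#' Isolated nodes are written as comment lines (`# node SYMBOL`) so the file
#' round-trips through [read_edge_list()] plus [ppi_network()]'s `nodes`
#' argument; networks whose nodes all have degree >= 1 round-trip directly.
#'
#' @param net a [ppi_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  ed <- ppi_edges(net)
  iso <- setdiff(ppi_nodes(net), unique(c(ed$from, ed$to)))
  out <- c(
    sprintf("%s\t%s", ed$from, ed$to),
    if (length(iso)) sprintf("# node %s", iso)
  )
  writeLines(out, path)
  invisible(path)
}

#' Induced subnetwork
#'
#' Restricts a network to a set of kept symbols: the node set becomes exactly
#' `keep` (isolated kept nodes preserved) and the edges are those of `net`
#' with both endpoints in `keep`.
#'
#' @param net a [ppi_network].
#' @param keep character vector of symbols, a subset of `ppi_nodes(net)`.
#' @return A [ppi_network].
#' @export
induced_subnetwork <- function(net, keep) {
  keep <- unique(toupper(as.character(keep)))
  unknown <- setdiff(keep, ppi_nodes(net))
  if (length(unknown)) {
    abort(sprintf(
      "Symbols not in the network: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  g <- igraph::induced_subgraph(net$graph, keep)
  new_ppi_network(g, name = net$name)
}
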