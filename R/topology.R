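## GF(2) rank computations for boundary matrices.
##
## Two deliberately independent code paths:
##  * gf2_rank_sparse(): pivot-reduction over rows stored as sorted integer
##    index sets (symmetric differences) — used by betti_number().
##  * gf2_rank_dense(): plain Gaussian elimination on a dense 0/1 matrix —
##    used only by betti_oracle().

gf2_rank_sparse <- function(rows) {
  pivots <- new.env(parent = emptyenv())
  rank <- 0L
  for (row in rows) {
    repeat {
      if (length(row) == 0L) break
      p <- as.character(row[length(row)]) # pivot = largest index
      piv <- pivots[[p]]
      if (is.null(piv)) {
        pivots[[p]] <- row
        rank <- rank + 1L
        break
      }
      # row <- row XOR piv (symmetric difference of index sets)
      both <- c(row, piv)
      row <- sort(both[!(both %in% row[row %in% piv])])
    }
  }
  rank
}

gf2_rank_dense <- function(m) {
  m <- m %% 2L
  nr <- nrow(m); nc <- ncol(m)
  rank <- 0L
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(m[row:nr, col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) m[c(row, piv), ] <- m[c(piv, row), ]
    hits <- which(m[, col] == 1L)
    hits <- hits[hits != row]
    if (length(hits)) {
      m[hits, ] <- (m[hits, , drop = FALSE] +
                      matrix(m[row, ], length(hits), nc, byrow = TRUE)) %% 2L
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

# first Betti number of the dimension-2 flag complex of an igraph object
flag_betti1 <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0L) return(0L)
  comp <- igraph::components(g)$no
  cycle_rank <- m - n + comp
  if (cycle_rank <= 0L) return(0L)
  tri <- igraph::triangles(g)
  if (length(tri) == 0L) return(as.integer(cycle_rank))
  tri <- matrix(as.integer(tri), nrow = 3L)
  eid <- function(a, b) igraph::get_edge_ids(g, rbind(a, b))
  rows <- lapply(seq_len(ncol(tri)), function(k) {
    v <- tri[, k]
    sort(as.integer(c(
      eid(v[1L], v[2L]), eid(v[1L], v[3L]), eid(v[2L], v[3L])
    )))
  })
  as.integer(cycle_rank - gf2_rank_sparse(rows))
}

#' Betti number of the clique complex
#'
#' Counts the independent rings of four or more proteins in a network: the
#' first Betti number of its dimension-2 flag (clique) complex, in which
#' every edge is a 1-simplex and every triangle (3-clique) is a filled
#' 2-simplex. Triangles therefore do not count as rings, while chordless
#' cycles of length >= 4 do. Computed as
#' `b1 = (E - V + C) - rank(boundary_2)` with the triangle-boundary rank
#' taken over GF(2), so all rank decisions are exact.
#'
#' @param net a [ppi_network].
#' @return A one-row tibble of class `topology_summary` with columns
#'   `betti`, `components`, `n_nodes`, `n_edges`, `n_triangles`.
#' @examples
#' sq <- ppi_network(data.frame(a = c("A", "B", "C", "D"),
#'                              b = c("B", "C", "D", "A")))
#' betti_number(sq) # one square ring
#' @export
betti_number <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  structure(
    tibble(
      betti = flag_betti1(g),
      components = if (n == 0L) 0L else igraph::components(g)$no,
      n_nodes = n,
      n_edges = igraph::ecount(g),
      n_triangles = length(igraph::triangles(g)) %/% 3L
    ),
    class = c("topology_summary", class(tibble()))
  )
}

#' Brute-force Betti oracle
#'
#' Independent verification path for [betti_number()]: builds the full
#' vertex-edge and edge-triangle boundary matrices explicitly and evaluates
#' `b1 = dim ker(boundary_1) - rank(boundary_2)` by dense Gaussian
#' elimination over GF(2). Limited to small graphs; intended for testing.
#'
#' @param net a [ppi_network] with at most 25 nodes.
#' @return The first Betti number as an integer.
#' @export
betti_oracle <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n > 25L) abort("betti_oracle() is limited to networks with <= 25 nodes.")
  if (n == 0L) return(0L)
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  # boundary_1: vertices x edges
  d1 <- matrix(0L, n, max(m, 1L))
  if (m > 0L) {
    for (e in seq_len(m)) d1[el[e, ], e] <- 1L
  } else {
    d1 <- matrix(0L, n, 0L)
  }
  ker1 <- m - gf2_rank_dense(d1)
  tri <- igraph::triangles(g)
  if (length(tri) == 0L) return(as.integer(ker1))
  tri <- matrix(as.integer(tri), nrow = 3L)
  d2 <- matrix(0L, m, ncol(tri))
  for (k in seq_len(ncol(tri))) {
    v <- tri[, k]
    ids <- igraph::get_edge_ids(g, c(v[1], v[2], v[1], v[3], v[2], v[3]))
    d2[ids, k] <- 1L
  }
  as.integer(ker1 - gf2_rank_dense(d2))
}
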