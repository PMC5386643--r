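#' Per-node Gibbs free energy
#'
#' The Gibbs free energy of protein `i` on the interaction network is
#' \deqn{G_i = c_i \ln\left(\frac{c_i}{\sum_{j \in N[i]} c_j}\right)}
#' where `c_i` is the rescaled concentration and `N[i]` the closed
#' neighborhood (the node together with its interaction partners). Since
#' the denominator is at least `c_i`, the log ratio is at most 0 and every
#' `G_i <= 0`: deeper (more negative) values are deeper wells of the energy
#' landscape. By the continuity convention `0 * ln(0/x) = 0`, nodes with
#' zero concentration — including the mandatory minimum of the min-max
#' rescaling — contribute nothing, as do isolated nodes (ratio 1).
#'
#' `gibbs_energy()` evaluates all nodes at once and returns an `energy_map`;
#' `gibbs_node()` evaluates a single node.
#'
#' @param net a [ppi_network].
#' @param conc a `concentration_profile` aligned to `net` (see
#'   [align_to_network()]): one concentration in `[0,1]` per network node.
#' @param node a gene symbol in `net`.
#'
#' @return `gibbs_node()`: a single non-positive number. `gibbs_energy()`:
#'   a tibble of class `energy_map` with columns `gene`, `degree`, `conc`,
#'   `gibbs`, and the network total (the sum of all `G_i`) as attribute
#'   `total` (also reported by `glance()` and [total_energy()]).
#' @examples
#' net <- ppi_network(data.frame(a = "A", b = "B"))
#' prof <- expression_profile(
#'   data.frame(gene = c("A", "B", "LO", "HI"), value = c(5, 5, 0, 10)),
#'   patient_id = "p1", platform = "log2_values"
#' )
#' conc <- align_to_network(rescale(prof), net) # A and B both at c = 0.5
#' gibbs_node(net, conc, "A") # 0.5 * log(0.5) = -0.347
#' total_energy(gibbs_energy(net, conc))
#' @export
gibbs_energy <- function(net, conc) {
  check_alignment(net, conc)
  g <- net$graph
  nodes <- ppi_nodes(net)
  ci <- setNames(conc$conc, conc$gene)[nodes]
  deg <- if (length(nodes)) igraph::degree(g) else integer()
  if (length(nodes)) {
    adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    denom <- as.vector(adj %*% ci) + ci # closed neighborhood includes i
    gi <- ifelse(ci > 0, ci * log(ci / denom), 0)
  } else {
    gi <- numeric()
  }
  structure(
    tibble(
      gene = nodes,
      degree = as.integer(unname(deg)),
      conc = unname(ci),
      gibbs = unname(gi)
    ),
    patient_id = attr(conc, "patient_id"),
    total = sum(gi),
    class = c("energy_map", class(tibble()))
  )
}

#' @rdname gibbs_energy
#' @export
gibbs_node <- function(net, conc, node) {
  node <- toupper(node)
  if (!node %in% ppi_nodes(net)) {
    abort(sprintf("Node '%s' is not in the network.", node))
  }
  check_alignment(net, conc)
  lut <- setNames(conc$conc, conc$gene)
  ci <- lut[[node]]
  if (ci == 0) return(0)
  nb <- igraph::neighbors(net$graph, node)$name
  denom <- ci + sum(lut[nb])
  stopifnot(denom >= ci) # concentrations are non-negative
  ci * log(ci / denom)
}

check_alignment <- function(net, conc) {
  stopifnot(inherits(net, "ppi_network"), inherits(conc, "concentration_profile"))
  if (!setequal(conc$gene, ppi_nodes(net))) {
    abort("Concentration profile is not aligned to the network; run align_to_network().")
  }
  if (any(conc$conc < 0 | conc$conc > 1)) {
    abort("Concentrations must lie in [0, 1].")
  }
  invisible(TRUE)
}

#' Total energy of an energy map
#'
#' @param energy an `energy_map` from [gibbs_energy()].
#' @return The network total Gibbs free energy (sum over nodes).
#' @export
total_energy <- function(energy) {
  stopifnot(inherits(energy, "energy_map"))
  attr(energy, "total")
}

#' @export
glance.energy_map <- function(x, ...) {
  tibble(
    patient_id = attr(x, "patient_id"),
    n_nodes = nrow(x),
    total_gibbs = attr(x, "total"),
    min_gibbs = if (nrow(x)) min(x$gibbs) else NA_real_,
    n_zero = sum(x$gibbs == 0)
  )
}

#' Degree-distribution entropy
#'
#' Shannon entropy (natural log) of a network's degree distribution:
#' `H = -sum_k p(k) ln p(k)` with `p(k)` the fraction of nodes of degree
#' `k`, degree-0 nodes included. A summary of wiring heterogeneity: any
#' k-regular graph has `H = 0`; heavy-tailed PPI networks have `H` well
#' above 1.
#'
#' @param net a non-empty [ppi_network].
#' @return A single non-negative number.
#' @export
degree_entropy <- function(net) {
  if (n_nodes(net) == 0) abort("degree_entropy() needs a non-empty network.")
  p <- as.vector(table(igraph::degree(net$graph))) / n_nodes(net)
  -sum(p * log(p))
}
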