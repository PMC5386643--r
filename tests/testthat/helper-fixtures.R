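# Graph fixtures ---------------------------------------------------------

edge_net <- function(from, to, nodes = NULL) {
  ppi_network(data.frame(a = from, b = to), nodes = nodes)
}

ring_net <- function(n, prefix = "N") {
  v <- paste0(prefix, seq_len(n))
  edge_net(v, c(v[-1], v[1]))
}

path_net <- function(syms) edge_net(syms[-length(syms)], syms[-1])

star_net <- function(n_leaves) {
  edge_net(rep("HUB", n_leaves), paste0("L", seq_len(n_leaves)))
}

k4_net <- function() {
  v <- utils::combn(c("A", "B", "C", "D"), 2)
  edge_net(v[1, ], v[2, ])
}

# hub joined to every node of a 4-cycle
wheel_net <- function() {
  rim <- c("R1", "R2", "R3", "R4")
  edge_net(
    c(rim, rep("HUB", 4)),
    c(rim[-1], rim[1], rim)
  )
}

# two squares sharing the single node H: 7 nodes, 8 edges, betti 2
two_squares_net <- function() {
  edge_net(
    c("H", "A1", "A2", "A3", "H", "B1", "B2", "B3"),
    c("A1", "A2", "A3", "H", "B1", "B2", "B3", "H")
  )
}

random_net <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("V", seq_len(n))
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(ppi_network(nodes = paste0("V", seq_len(n))))
  ppi_network(data.frame(a = el[, 1], b = el[, 2]), nodes = paste0("V", seq_len(n)))
}

# Concentration fixtures --------------------------------------------------

# exact concentrations on a network through the public path: anchor genes
# pin the min to 0 and the max to 1, then alignment discards the anchors
make_conc <- function(net, values) {
  stopifnot(all(values >= 0), all(values <= 1))
  prof <- expression_profile(
    data.frame(
      gene = c(names(values), "ZZANCHOR0", "ZZANCHOR1"),
      value = c(values, 0, 1)
    ),
    patient_id = "fixture", platform = "log2_values"
  )
  align_to_network(rescale(prof), net)
}

fake_energy <- function(net, gibbs) {
  # energy map with prescribed per-node energies (concentrations unused)
  stopifnot(setequal(names(gibbs), ppi_nodes(net)))
  nodes <- ppi_nodes(net)
  structure(
    tibble::tibble(
      gene = nodes,
      degree = as.integer(igraph::degree(as_igraph(net))[nodes]),
      conc = NA_real_,
      gibbs = unname(gibbs[nodes])
    ),
    patient_id = "fixture",
    total = sum(gibbs),
    class = c("energy_map", class(tibble::tibble()))
  )
}

fake_report <- function(targets, patient = "p") {
  structure(
    list(
      patient_id = patient, threshold = 32, nominal_betti = 1L,
      nominal_gibbs = -1, homology_energy = -1, whole_network_energy = -10,
      subnetwork_entropy = 0, network_entropy = 0, n_edges_subnetwork = 1L,
      records = NULL, equivalent_targets = sort(targets),
      min_post_betti = 0L, n_equivalent = length(targets)
    ),
    class = "target_report"
  )
}

# Independent oracles -----------------------------------------------------

# naive per-node Gibbs energy by explicit loops over the edge table
naive_gibbs_total <- function(net, conc) {
  lut <- stats::setNames(conc$conc, conc$gene)
  ed <- ppi_edges(net)
  total <- 0
  for (v in ppi_nodes(net)) {
    ci <- lut[[v]]
    if (ci == 0) next
    nb <- c(ed$to[ed$from == v], ed$from[ed$to == v])
    denom <- ci + sum(lut[nb])
    total <- total + ci * log(ci / denom)
  }
  total
}

# exhaustive two-sided Mann-Whitney p-value via pair counting (a different
# statistic formulation from the implementation's rank sums)
mwu_perm_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_pairs <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mid <- n1 * length(y) / 2
  obs <- abs(u_pairs(x, y) - mid)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) u_pairs(pool[i], pool[-i]))
  mean(abs(us - mid) >= obs - 1e-9)
}
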