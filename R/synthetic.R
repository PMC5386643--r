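#' Specification for synthetic pipeline inputs
#'
#' Describes a seeded synthetic study: a sparse scale-free PPI-like network
#' (preferential attachment, heavy-tailed degrees), heavy-tailed nonnegative
#' expression counts, and optionally a *planted module* — two or more rings
#' of length >= 4 sharing a single hinge node, wired into the network and
#' over-expressed by a known boost factor. The hinge is recoverable ground
#' truth: its removal collapses the ring count of the planted module, which
#' is exactly the mechanism the knockout scan rewards.
#'
#' Identical specs (including the seed) generate byte-identical artifacts.
#'
#' @param n_nodes total number of genes/nodes (>= 10).
#' @param edges_per_node preferential-attachment edges added per node
#'   (default 2: mean degree about 4, comparable to curated human PPI).
#' @param meanlog,sdlog log-normal parameters of the count model (natural
#'   log scale). Defaults (6, 0.5) give a median count of about 400 with a
#'   right-skewed spread typical of expressed genes while letting the
#'   planted boost dominate gene-to-gene dispersion.
#' @param planted_rings integer vector of ring lengths (each >= 4) sharing
#'   one hinge, or `NULL` for no planted module.
#' @param boost multiplicative count boost applied to planted-module nodes.
#' @param seed integer random seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 300, edges_per_node = 2,
                           meanlog = 6, sdlog = 0.5,
                           planted_rings = c(6, 6), boost = 50,
                           seed = 1) {
  if (n_nodes < 10) abort("`n_nodes` must be at least 10.")
  if (!is.null(planted_rings)) {
    if (any(planted_rings < 4)) abort("Planted rings must have length >= 4.")
    if (length(planted_rings) < 2) abort("Plant at least two rings (they share the hinge).")
    if (sum(planted_rings - 1) + 1 > n_nodes) {
      abort("Planted module is larger than the whole network.")
    }
  }
  structure(
    list(
      n_nodes = as.integer(n_nodes),
      edges_per_node = as.integer(edges_per_node),
      meanlog = meanlog, sdlog = sdlog,
      planted_rings = planted_rings,
      boost = boost,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

planted_module_size <- function(spec) {
  if (is.null(spec$planted_rings)) 0L else as.integer(sum(spec$planted_rings - 1) + 1)
}

planted_node_names <- function(spec) {
  k <- planted_module_size(spec)
  if (k == 0L) character() else c("HINGE", sprintf("RING%03d", seq_len(k - 1L)))
}

#' Generate a synthetic PPI network
#'
#' Builds a preferential-attachment graph over synthetic gene symbols
#' (`GENE0001`, ...) and, if the spec has a planted module, wires in the
#' shared-hinge rings and attaches them to the main component by a single
#' edge from a ring node to a uniformly chosen background node.
#'
#' @param spec a [synthetic_spec].
#' @return A [ppi_network] with extra fields `hinge` (ground-truth target
#'   symbol or `NULL`) and `planted_nodes`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  npl <- planted_module_size(spec)
  nbg <- spec$n_nodes - npl
  if (nbg < 2) abort("Too few background nodes outside the planted module.")
  g <- igraph::sample_pa(nbg, m = spec$edges_per_node, directed = FALSE)
  igraph::V(g)$name <- sprintf("GENE%04d", seq_len(nbg))
  pl <- planted_node_names(spec)
  if (npl > 0L) {
    g <- igraph::add_vertices(g, npl, name = pl)
    offset <- 1L # first ring node after the hinge
    for (len in spec$planted_rings) {
      ring <- c("HINGE", pl[(offset + 1L):(offset + len - 1L)])
      cyc <- rbind(ring, c(ring[-1], ring[1]))
      g <- igraph::add_edges(g, match(as.vector(cyc), igraph::V(g)$name))
      offset <- offset + len - 1L
    }
    anchor <- sprintf("GENE%04d", sample.int(nbg, 1))
    g <- igraph::add_edges(g, match(c(pl[2], anchor), igraph::V(g)$name))
  }
  net <- new_ppi_network(g, name = sprintf("synthetic(seed=%d)", spec$seed))
  net$hinge <- if (npl > 0L) "HINGE" else NULL
  net$planted_nodes <- pl
  net
}

#' Generate a synthetic expression profile
#'
#' Draws integer counts from the spec's log-normal model, one per network
#' node, and multiplies planted-module counts by the boost factor so that
#' after `log2(count + 1)` and min-max rescaling the planted nodes hold the
#' top concentration ranks. If the draw degenerates to a constant vector
#' (e.g. `sdlog = 0` with no planted module) one count is perturbed so the
#' profile stays rescalable.
#'
#' @param net a network from [generate_network()].
#' @param spec the matching [synthetic_spec].
#' @param patient_id identifier for the profile.
#' @param count_shift optional named adjustment: counts of the top-decile-
#'   degree genes are multiplied by `2^count_shift` (used by
#'   [generate_cohort()] to separate histology groups energetically).
#' @param seed seed for this draw; defaults to `spec$seed + 1` so a
#'   standalone call is reproducible. [generate_cohort()] passes
#'   `spec$seed + i` for patient `i`.
#' @return An [expression_profile] with `platform = "rnaseq_counts"`.
#' @export
generate_expression <- function(net, spec, patient_id = "synthetic",
                                count_shift = 0, seed = spec$seed + 1L) {
  stopifnot(inherits(net, "ppi_network"), inherits(spec, "synthetic_spec"))
  set.seed(seed)
  nodes <- ppi_nodes(net)
  counts <- round(rlnorm(length(nodes), spec$meanlog, spec$sdlog))
  names(counts) <- nodes
  pl <- intersect(net$planted_nodes %||% character(), nodes)
  if (length(pl)) counts[pl] <- counts[pl] * spec$boost
  if (count_shift != 0) {
    deg <- igraph::degree(net$graph)
    hubs <- names(deg)[deg >= stats::quantile(deg, 0.9)]
    hubs <- setdiff(hubs, pl)
    counts[hubs] <- round(counts[hubs] * 2^count_shift)
  }
  if (length(unique(counts)) == 1L) counts[1] <- counts[1] + 1
  expression_profile(
    tibble(gene = nodes, value = as.numeric(counts)),
    patient_id = patient_id, platform = "rnaseq_counts"
  )
}

#' Generate a synthetic patient cohort
#'
#' Independent per-patient expression draws on one shared network. With
#' `histology_shift`, patients are assigned round-robin to the named groups
#' and each group's hub-gene counts are multiplied by `2^shift`, which
#' deepens (for positive shifts) that group's energy landscape detectably —
#' a stand-in for histology-linked expression differences.
#'
#' @param n_patients number of patients (>= 2).
#' @param spec a [synthetic_spec]; its seed drives the whole cohort.
#' @param histology_shift optional named numeric vector of per-group shifts,
#'   e.g. `c(astro = 0, oligo = 0, oligoastro = 2)`.
#' @return A list of class `synthetic_cohort`: `network`, `profiles` (list
#'   of [expression_profile]), `labels` (tibble `patient_id`, `group`; only
#'   when groups are given) and `hinge`.
#' @export
generate_cohort <- function(n_patients, spec, histology_shift = NULL) {
  if (n_patients < 2) abort("`n_patients` must be at least 2.")
  net <- generate_network(spec)
  groups <- names(histology_shift)
  ids <- sprintf("SYN-%03d", seq_len(n_patients))
  grp <- if (is.null(groups)) rep(NA_character_, n_patients) else
    groups[(seq_len(n_patients) - 1L) %% length(groups) + 1L]
  profiles <- purrr::map(seq_len(n_patients), function(i) {
    shift <- if (is.null(groups)) 0 else histology_shift[[grp[i]]]
    generate_expression(net, spec, patient_id = ids[i], count_shift = shift,
                        seed = spec$seed + i)
  })
  structure(
    list(
      network = net,
      profiles = profiles,
      labels = if (is.null(groups)) NULL else tibble(patient_id = ids, group = grp),
      hinge = net$hinge
    ),
    class = "synthetic_cohort"
  )
}

#' Write synthetic inputs in the formats the readers consume
#'
#' Writes the network as an edge list, each profile as a two-column
#' expression TSV, and a ground-truth JSON (hinge, planted nodes, labels).
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(cohort$network, file.path(dir, "network.tsv"))
  for (p in cohort$profiles) {
    readr::write_tsv(
      tibble(gene = p$gene, value = p$value),
      file.path(dir, paste0(attr(p, "patient_id"), ".tsv")),
      col_names = FALSE
    )
  }
  truth <- list(
    hinge = cohort$hinge,
    planted_nodes = cohort$network$planted_nodes,
    patients = vapply(cohort$profiles, attr, character(1), "patient_id")
  )
  if (!is.null(cohort$labels)) {
    readr::write_tsv(cohort$labels, file.path(dir, "labels.tsv"))
    truth$groups <- cohort$labels$group
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
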