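#' Gibbs-homology filtration
#'
#' Extracts the low-energy ("Gibbs homology") subnetwork: imagine the
#' per-node energies as wells of a landscape and a horizontal filtration
#' plane rising from the deepest well. At a given threshold the plane has
#' captured the deepest wells, whose induced subnetwork is the persistent
#' low-energy structure of the patient's network.
#'
#' The default threshold semantics (`mode = "count"`) capture the
#' `threshold` nodes with the most negative Gibbs energy, ties broken by
#' ascending lexicographic symbol; this matches the small dimensionless
#' thresholds (8...128) used in practice. `mode = "energy"` instead treats
#' `threshold` as an absolute energy level and captures every node with
#' `G_i <= threshold` — exposed for sensitivity analysis.
#'
#' @param net a [ppi_network].
#' @param energy an `energy_map` from [gibbs_energy()] over `net`'s nodes.
#' @param threshold for `mode = "count"` a positive integer number of wells;
#'   for `mode = "energy"` an energy cutoff (non-positive real).
#' @param mode `"count"` (default) or `"energy"`.
#'
#' @return An object of class `filtration_result`: a list with
#'   `threshold`, `mode`, `captured` (tibble of captured nodes, deepest
#'   first, with their `conc` and `gibbs`), `subnetwork` (the induced
#'   [ppi_network], isolated captured nodes retained), `homology_energy`
#'   (sum of captured `G_i`) and `whole_network_energy`.
#' @export
gibbs_homology <- function(net, energy, threshold, mode = c("count", "energy")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ppi_network"), inherits(energy, "energy_map"))
  if (!setequal(energy$gene, ppi_nodes(net))) {
    abort("Energy map does not cover the network's nodes.")
  }
  ord <- energy[order(energy$gibbs, energy$gene), ]
  if (mode == "count") {
    if (length(threshold) != 1 || is.na(threshold) || threshold < 1) {
      abort("`threshold` must be a single integer >= 1.")
    }
    threshold <- as.integer(threshold)
    if (threshold > nrow(ord)) {
      warn(sprintf(
        "Threshold %d exceeds the %d available nodes; capturing all of them.",
        threshold, nrow(ord)
      ))
      threshold <- nrow(ord)
    }
    captured <- ord[seq_len(threshold), ]
  } else {
    captured <- ord[ord$gibbs <= threshold, ]
  }
  sub <- induced_subnetwork(net, captured$gene)
  structure(
    list(
      patient_id = attr(energy, "patient_id"),
      threshold = threshold,
      mode = mode,
      captured = as_tibble(captured),
      subnetwork = sub,
      homology_energy = sum(captured$gibbs),
      whole_network_energy = attr(energy, "total")
    ),
    class = "filtration_result"
  )
}

#' @export
print.filtration_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<filtration_result: threshold %s (%s), %d captured nodes, ",
      "%d edges, homology energy %.4f (whole network %.4f)>\n"
    ),
    format(x$threshold), x$mode, nrow(x$captured), n_edges(x$subnetwork),
    x$homology_energy, x$whole_network_energy
  ))
  invisible(x)
}

#' @export
tidy.filtration_result <- function(x, ...) x$captured

#' @export
glance.filtration_result <- function(x, ...) {
  tibble(
    patient_id = x$patient_id %||% NA_character_,
    threshold = x$threshold,
    mode = x$mode,
    n_captured = nrow(x$captured),
    n_edges = n_edges(x$subnetwork),
    homology_energy = x$homology_energy,
    whole_network_energy = x$whole_network_energy,
    subnetwork_entropy = if (nrow(x$captured)) degree_entropy(x$subnetwork) else NA_real_
  )
}

#' Filtration threshold sweep
#'
#' Applies [gibbs_homology()] at each threshold. Because the capture order
#' is a fixed ranking of wells, captured sets at increasing thresholds are
#' nested — the defining persistence property of the filtration — and the
#' homology energy is non-increasing in the threshold.
#'
#' @inheritParams gibbs_homology
#' @param thresholds vector of positive integers (capture counts). Defaults
#'   to the standard sweep `c(8, 16, 32, 48, 64, 128)`.
#' @return A list of `filtration_result`, one per threshold, named by
#'   threshold.
#' @export
filtration_sweep <- function(net, energy, thresholds = c(8, 16, 32, 48, 64, 128)) {
  if (length(thresholds) == 0) abort("`thresholds` must be non-empty.")
  res <- lapply(thresholds, function(t) gibbs_homology(net, energy, t))
  names(res) <- as.character(thresholds)
  res
}
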