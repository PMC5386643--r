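#' Single-node knockout scan
#'
#' Sequentially removes (with replacement) each protein of the Gibbs-homology
#' subnetwork, recomputing after each removal the clique-complex Betti number
#' and the subnetwork Gibbs energy. A node whose removal produces a large
#' drop in Betti number holds together many independent rings — the paper's
#' criterion for a promising therapeutic target. The scan is side-effect
#' free: the filtration result is never modified.
#'
#' With `recompute_energy = TRUE` (default) the subnetwork energy is
#' re-evaluated from the concentrations on the reduced topology — removing a
#' protein changes its neighbors' chemical potential — and the nominal
#' energy uses the same convention (energy of the intact subnetwork
#' topology). With `recompute_energy = FALSE` energies are partial sums of
#' the full-network per-node values, so a knockout simply subtracts the
#' removed node's `G_i`.
#'
#' @param filt a `filtration_result` from [gibbs_homology()] with a
#'   non-empty subnetwork.
#' @param conc the patient's `concentration_profile` aligned to the full
#'   network (a superset of the subnetwork's nodes).
#' @param recompute_energy logical; see Details.
#'
#' @return A tibble of class `knockout_records`, one row per subnetwork
#'   node, with columns `node`, `post_betti`, `delta_betti`
#'   (nominal − post), `post_gibbs`, `delta_gibbs` (post − nominal; the
#'   undeclared-sign convention is also reported as `abs_delta_gibbs`).
#'   Attributes `nominal_betti`, `nominal_gibbs`, `patient_id`, `threshold`.
#' @export
knockout_scan <- function(filt, conc, recompute_energy = TRUE) {
  stopifnot(inherits(filt, "filtration_result"))
  nodes <- filt$captured$gene
  if (length(nodes) == 0) abort("Cannot scan an empty subnetwork.")
  sub <- filt$subnetwork
  nominal_betti <- flag_betti1(sub$graph)
  if (recompute_energy) {
    sub_conc <- restrict_conc(conc, nodes)
    nominal_gibbs <- total_energy(gibbs_energy(sub, sub_conc))
  } else {
    nominal_gibbs <- filt$homology_energy
  }
  gi <- setNames(filt$captured$gibbs, filt$captured$gene)
  rec <- purrr::map(nodes, function(v) {
    keep <- setdiff(nodes, v)
    reduced <- induced_subnetwork(sub, keep)
    post_betti <- flag_betti1(reduced$graph)
    post_gibbs <- if (recompute_energy) {
      if (length(keep)) {
        total_energy(gibbs_energy(reduced, restrict_conc(conc, keep)))
      } else 0
    } else {
      nominal_gibbs - gi[[v]]
    }
    tibble(node = v, post_betti = post_betti, post_gibbs = post_gibbs)
  })
  out <- bind_rows(rec) |>
    mutate(
      delta_betti = nominal_betti - .data$post_betti,
      delta_gibbs = .data$post_gibbs - nominal_gibbs,
      abs_delta_gibbs = abs(.data$delta_gibbs)
    ) |>
    select(
      "node", "post_betti", "delta_betti",
      "post_gibbs", "delta_gibbs", "abs_delta_gibbs"
    )
  structure(
    out,
    nominal_betti = nominal_betti,
    nominal_gibbs = nominal_gibbs,
    patient_id = filt$patient_id,
    threshold = filt$threshold,
    class = c("knockout_records", class(tibble()))
  )
}

restrict_conc <- function(conc, genes) {
  stopifnot(inherits(conc, "concentration_profile"))
  missing <- setdiff(genes, conc$gene)
  if (length(missing)) {
    abort(sprintf(
      "Concentration profile lacks subnetwork gene(s): %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  new_concentration(
    conc[match(genes, conc$gene), c("gene", "conc")],
    attr(conc, "patient_id"),
    attr(conc, "coverage")
  )
}

#' Equivalent best targets
#'
#' Identifies the knockout(s) achieving the minimal post-removal Betti
#' number — the biggest drop in network complexity. All ties are included:
#' such proteins are *equivalent targets*, reported in lexicographic order.
#'
#' @param records a `knockout_records` tibble from [knockout_scan()].
#' @return A list with `equivalent_targets` (sorted character vector),
#'   `min_post_betti` and `n_equivalent`.
#' @export
best_targets <- function(records) {
  stopifnot(inherits(records, "knockout_records"), nrow(records) > 0)
  mn <- min(records$post_betti)
  eq <- sort(records$node[records$post_betti == mn])
  list(
    equivalent_targets = eq,
    min_post_betti = as.integer(mn),
    n_equivalent = length(eq)
  )
}

#' Per-patient target report
#'
#' Bundles a patient's filtration, knockout scan and best-target call into a
#' single object. `tidy()` returns the knockout table; `glance()` a one-row
#' summary with the Table-style columns (entropies, energies, Betti numbers,
#' edge counts, targets).
#'
#' @param filt a `filtration_result`.
#' @param records the matching `knockout_records`.
#' @param net optionally, the full [ppi_network] (adds the whole-network
#'   degree entropy to `glance()`).
#' @return An object of class `target_report`.
#' @export
target_report <- function(filt, records, net = NULL) {
  bt <- best_targets(records)
  structure(
    list(
      patient_id = filt$patient_id %||% NA_character_,
      threshold = filt$threshold,
      nominal_betti = attr(records, "nominal_betti"),
      nominal_gibbs = attr(records, "nominal_gibbs"),
      homology_energy = filt$homology_energy,
      whole_network_energy = filt$whole_network_energy,
      subnetwork_entropy = degree_entropy(filt$subnetwork),
      network_entropy = if (is.null(net)) NA_real_ else degree_entropy(net),
      n_edges_subnetwork = n_edges(filt$subnetwork),
      records = records,
      equivalent_targets = bt$equivalent_targets,
      min_post_betti = bt$min_post_betti,
      n_equivalent = bt$n_equivalent
    ),
    class = "target_report"
  )
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<target_report: patient '%s', threshold %s>\n",
      "  nominal Betti %d, homology energy %.4f\n",
      "  %d equivalent target(s) at post-Betti %d: %s\n"
    ),
    x$patient_id, format(x$threshold), x$nominal_betti, x$homology_energy,
    x$n_equivalent, x$min_post_betti,
    paste(x$equivalent_targets, collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.target_report <- function(x, ...) as_tibble(x$records)

#' @export
glance.target_report <- function(x, ...) {
  tibble(
    patient_id = x$patient_id,
    threshold = x$threshold,
    subnetwork_entropy = x$subnetwork_entropy,
    network_entropy = x$network_entropy,
    nominal_betti = x$nominal_betti,
    homology_energy = x$homology_energy,
    whole_network_energy = x$whole_network_energy,
    n_edges_subnetwork = x$n_edges_subnetwork,
    min_post_betti = x$min_post_betti,
    n_equivalent = x$n_equivalent,
    equivalent_targets = paste(x$equivalent_targets, collapse = ";")
  )
}
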