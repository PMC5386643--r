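#' Run the full per-patient analysis
#'
#' Chains the whole method for one patient: count transform (if needed) →
#' min-max rescaling → network alignment → per-node Gibbs energy →
#' landscape filtration at the threshold → clique-complex Betti number →
#' knockout scan → equivalent best targets.
#'
#' @param net a [ppi_network].
#' @param profile the patient's [expression_profile].
#' @param threshold filtration threshold (number of captured wells;
#'   default 32).
#' @param missing_policy how to treat network nodes without a measurement;
#'   see [align_to_network()].
#' @param recompute_energy see [knockout_scan()].
#' @return A [target_report].
#' @examples
#' spec <- synthetic_spec(n_nodes = 120, seed = 7)
#' net <- generate_network(spec)
#' prof <- generate_expression(net, spec, "demo")
#' analyze_patient(net, prof, threshold = 19)
#' @export
analyze_patient <- function(net, profile, threshold = 32,
                            missing_policy = "zero", recompute_energy = TRUE) {
  pipeline_patient(net, profile, threshold, missing_policy, recompute_energy)$report
}

pipeline_patient <- function(net, profile, threshold = 32,
                             missing_policy = "zero", recompute_energy = TRUE) {
  prep <- prepare_patient(net, profile, missing_policy)
  energy <- gibbs_energy(prep$net, prep$conc)
  filt <- gibbs_homology(prep$net, energy, threshold)
  records <- knockout_scan(filt, prep$conc, recompute_energy = recompute_energy)
  list(
    net = prep$net, conc = prep$conc, energy = energy, filt = filt,
    records = records,
    report = target_report(filt, records, net = prep$net)
  )
}

default_config <- function() {
  list(
    ppi = NULL, ppi_format = "edgelist", organism_id = NULL,
    expression = character(), platform = "rnaseq_counts",
    threshold = 32, thresholds = NULL, missing_policy = "zero",
    recompute_energy = TRUE, labels = NULL, out_dir = ".",
    seed = 1, log_level = "info"
  )
}

load_network_from_config <- function(config) {
  if (is.null(config$ppi)) abort("[graph] `ppi` input path is required.")
  if (identical(config$ppi_format, "biogrid")) {
    read_biogrid(config$ppi, organism_id = config$organism_id)
  } else {
    read_edge_list(config$ppi)
  }
}

write_manifest <- function(config, inputs, path) {
  manifest <- list(
    package = "gibbsnet",
    version = as.character(utils::packageVersion("gibbsnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.null, logical(1))],
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

report_to_json <- function(report, conc) {
  list(
    patient_id = report$patient_id,
    threshold = report$threshold,
    coverage = attr(conc, "coverage"),
    nominal_betti = report$nominal_betti,
    nominal_gibbs = report$nominal_gibbs,
    homology_energy = report$homology_energy,
    whole_network_energy = report$whole_network_energy,
    subnetwork_entropy = report$subnetwork_entropy,
    network_entropy = report$network_entropy,
    n_edges_subnetwork = report$n_edges_subnetwork,
    min_post_betti = report$min_post_betti,
    n_equivalent = report$n_equivalent,
    equivalent_targets = report$equivalent_targets,
    knockouts = as.data.frame(report$records)
  )
}

#' Run the single-patient pipeline from a configuration
#'
#' Reads the network and one expression file, executes [analyze_patient()],
#' and writes into `out_dir`: the per-patient report JSON
#' (`<patient>_report.json`), the knockout table TSV
#' (`<patient>_knockouts.tsv`), the per-node energy table TSV
#' (`<patient>_energy.tsv`, with totals in a JSON sidecar) and a run
#' manifest (`manifest.json`) recording all configuration values and input
#' checksums. Any stage failure raises an error naming the stage.
#'
#' @param config a named list; recognised fields: `ppi`, `ppi_format`
#'   (`"edgelist"` or `"biogrid"`), `organism_id`, `expression` (one path),
#'   `platform`, `threshold`, `missing_policy`, `recompute_energy`,
#'   `out_dir`.
#' @return The [target_report], invisibly.
#' @export
run_patient <- function(config) {
  config <- utils::modifyList(default_config(), config)
  net <- with_stage("graph", load_network_from_config(config))
  if (length(config$expression) != 1) {
    abort("[expression] exactly one expression path is required.")
  }
  profile <- with_stage(
    "expression",
    read_expression(config$expression, platform = config$platform)
  )
  res <- with_stage(
    "analysis",
    pipeline_patient(net, profile, config$threshold,
                     config$missing_policy, config$recompute_energy)
  )
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pid <- res$report$patient_id
  with_stage("report", {
    jsonlite::write_json(
      report_to_json(res$report, res$conc),
      file.path(config$out_dir, paste0(pid, "_report.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    readr::write_tsv(
      as_tibble(res$records),
      file.path(config$out_dir, paste0(pid, "_knockouts.tsv"))
    )
    readr::write_tsv(
      as_tibble(res$energy),
      file.path(config$out_dir, paste0(pid, "_energy.tsv"))
    )
    jsonlite::write_json(
      list(patient_id = pid, total_gibbs = total_energy(res$energy),
           coverage = attr(res$conc, "coverage")),
      file.path(config$out_dir, paste0(pid, "_energy_totals.json")),
      auto_unbox = TRUE, digits = NA
    )
    write_manifest(
      config, c(config$ppi, config$expression),
      file.path(config$out_dir, "manifest.json")
    )
  })
  log_info(config, sprintf(
    "patient %s: %d nodes / %d edges, coverage %.2f, threshold %s, betti %d, %d equivalent target(s)",
    pid, n_nodes(net), n_edges(net), attr(res$conc, "coverage"),
    format(config$threshold), res$report$nominal_betti, res$report$n_equivalent
  ))
  invisible(res$report)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

log_info <- function(config, msg) {
  if (!identical(config$log_level, "quiet")) {
    message(sprintf("[gibbsnet] %s", msg))
  }
  invisible(NULL)
}

#' Run the cohort pipeline from a configuration
#'
#' Runs [analyze_patient()] for every expression file, then aggregates:
#' Pareto target counts, a cohort table with the per-patient summary
#' columns (patient, entropies, energies, Betti, edge count, targets), a
#' threshold-sweep table when `thresholds` is set, and group statistics
#' when a `labels` TSV (`patient_id<TAB>group`) is supplied. A failing
#' patient is reported with a warning and skipped; the run continues.
#'
#' @param config as for [run_patient()], with `expression` a vector of
#'   paths, plus optional `thresholds` (integer vector) and `labels`.
#' @return A list with `reports`, `summary` (a `cohort_summary`),
#'   `cohort_table`, and optionally `sweep` and `group_stats`; invisibly.
#' @export
run_cohort <- function(config) {
  config <- utils::modifyList(default_config(), config)
  net <- with_stage("graph", load_network_from_config(config))
  if (length(config$expression) < 1) {
    abort("[expression] at least one expression path is required.")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  for (path in config$expression) {
    res <- tryCatch(
      {
        profile <- read_expression(path, platform = config$platform)
        pipeline_patient(net, profile, config$threshold,
                         config$missing_policy, config$recompute_energy)
      },
      error = function(e) {
        warn(sprintf("Skipping patient file '%s': %s", path, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) runs[[length(runs) + 1L]] <- res
  }
  if (length(runs) == 0) abort("[cohort] every patient failed; nothing to aggregate.")
  reports <- purrr::map(runs, "report")
  summary <- pareto_counts(reports)
  cohort_table <- bind_rows(purrr::map(reports, glance))
  readr::write_tsv(summary$pareto, file.path(config$out_dir, "pareto.tsv"))
  readr::write_tsv(cohort_table, file.path(config$out_dir, "cohort.tsv"))
  for (res in runs) {
    jsonlite::write_json(
      report_to_json(res$report, res$conc),
      file.path(config$out_dir, paste0(res$report$patient_id, "_report.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out <- list(reports = reports, summary = summary, cohort_table = cohort_table)
  if (!is.null(config$thresholds)) {
    profiles <- purrr::map(config$expression, function(p) {
      tryCatch(read_expression(p, platform = config$platform), error = function(e) NULL)
    })
    profiles <- profiles[!vapply(profiles, is.null, logical(1))]
    out$sweep <- threshold_sweep_stats(
      net, profiles, config$thresholds,
      missing_policy = config$missing_policy,
      recompute_energy = config$recompute_energy
    )
    readr::write_tsv(out$sweep, file.path(config$out_dir, "threshold_sweep.tsv"))
  }
  if (!is.null(config$labels)) {
    labels <- readr::read_tsv(config$labels, show_col_types = FALSE)
    joined <- dplyr::inner_join(
      cohort_table, labels, by = "patient_id"
    )
    if (length(unique(joined$group)) >= 2) {
      out$group_stats <- group_energy_comparison(
        joined, group = "group", value = "homology_energy"
      )
      jsonlite::write_json(
        list(
          group_stats = as.data.frame(out$group_stats$group_stats),
          pairwise = as.data.frame(out$group_stats$pairwise)
        ),
        file.path(config$out_dir, "group_stats.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  write_manifest(
    config,
    c(config$ppi, config$expression,
      if (!is.null(config$labels)) config$labels),
    file.path(config$out_dir, "manifest.json")
  )
  log_info(config, sprintf(
    "cohort: %d/%d patients analysed, %d target instances, mean %.3f equivalent targets",
    length(reports), length(config$expression),
    summary$total_target_instances, summary$mean_equivalent_targets
  ))
  invisible(out)
}
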