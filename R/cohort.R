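#' Pareto ranking of targets across a cohort
#'
#' Counts, over a list of per-patient [target_report]s, how often each
#' protein appears among a patient's equivalent best targets. Every member
#' of a patient's equivalent set contributes one count, so the total number
#' of target instances can exceed the number of patients (ties are real
#' alternatives, not noise). Counts are sorted descending, ties by symbol.
#'
#' @param reports a non-empty list of [target_report] objects.
#' @return An object of class `cohort_summary`: a list with `n_patients`,
#'   `pareto` (tibble `target`, `count`), `total_target_instances`,
#'   `mean_equivalent_targets` and `sd_equivalent_targets` (sample SD).
#' @export
pareto_counts <- function(reports) {
  if (length(reports) == 0) abort("`reports` must be non-empty.")
  stopifnot(all(vapply(reports, inherits, logical(1), "target_report")))
  n_eq <- vapply(reports, function(r) r$n_equivalent, numeric(1))
  targets <- unlist(lapply(reports, function(r) r$equivalent_targets))
  pareto <- tibble(target = targets) |>
    count(.data$target, name = "count") |>
    arrange(desc(.data$count), .data$target)
  structure(
    list(
      n_patients = length(reports),
      pareto = pareto,
      total_target_instances = as.integer(sum(pareto$count)),
      mean_equivalent_targets = mean(n_eq),
      sd_equivalent_targets = if (length(n_eq) > 1) sd(n_eq) else 0
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_summary: %d patients, %d target instances, ",
      "mean %.3f (SD %.3f) equivalent targets>\n"
    ),
    x$n_patients, x$total_target_instances,
    x$mean_equivalent_targets, x$sd_equivalent_targets
  ))
  print(head(x$pareto, 10))
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$pareto

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    total_target_instances = x$total_target_instances,
    n_distinct_targets = nrow(x$pareto),
    mean_equivalent_targets = x$mean_equivalent_targets,
    sd_equivalent_targets = x$sd_equivalent_targets
  )
}

# Two-sided Mann-Whitney U. Exact by exhaustive enumeration of group
# assignments when feasible (handles ties correctly); normal approximation
# via stats::wilcox.test otherwise.
mann_whitney_u <- function(x, y, exact_limit = 20000) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= exact_limit) {
    pool <- c(x, y)
    rp <- rank(pool)
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(rp[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    p <- mean(abs(us - mid) >= abs(u - mid) - 1e-9)
    method <- "exact permutation"
  } else {
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    method <- "normal approximation"
  }
  list(u = u, p_value = p, method = method)
}

#' Compare homology energies between histology groups
#'
#' Per-group mean/SD of the homology energy and all pairwise two-sided
#' Mann-Whitney U comparisons. P-values are reported unadjusted. For small
#' groups the p-value is computed by exhaustive permutation of the group
#' assignment (exact even with ties); larger groups use the normal
#' approximation.
#'
#' @param data a data frame with one row per patient.
#' @param group name of the grouping column (histology).
#' @param value name of the numeric column (e.g. homology energy).
#' @return A list of class `group_comparison` with `group_stats` (tibble
#'   `group`, `n`, `mean`, `sd`) and `pairwise` (tibble `group1`, `group2`,
#'   `u`, `p_value`, `method`).
#' @export
group_energy_comparison <- function(data, group = "group", value = "energy") {
  data <- as.data.frame(data)
  g <- as.character(data[[group]])
  v <- as.numeric(data[[value]])
  split_v <- split(v, g)
  if (length(split_v) < 2) abort("Need at least two groups.")
  small <- names(split_v)[lengths(split_v) < 2]
  if (length(small)) {
    abort(sprintf(
      "Group(s) with fewer than 2 values: %s", paste(small, collapse = ", ")
    ))
  }
  stats_tb <- tibble(
    group = names(split_v),
    n = lengths(split_v),
    mean = vapply(split_v, mean, numeric(1)),
    sd = vapply(split_v, sd, numeric(1))
  )
  pairs <- utils::combn(names(split_v), 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    mw <- mann_whitney_u(split_v[[a]], split_v[[b]])
    tibble(
      group1 = a, group2 = b,
      u = mw$u, p_value = mw$p_value, method = mw$method
    )
  })
  structure(
    list(group_stats = stats_tb, pairwise = bind_rows(pw)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$group_stats)
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' Equivalent-target statistics across a threshold sweep
#'
#' Runs the full per-patient pipeline (energy, filtration, knockout scan,
#' best targets) at each filtration threshold and summarises how many
#' equivalent targets patients have. Low thresholds leave little subnetwork
#' complexity and tend to produce many tied targets; high thresholds
#' usually isolate one.
#'
#' @param net the shared [ppi_network].
#' @param profiles a list of [expression_profile] objects (one per patient).
#' @param thresholds integer vector of capture counts.
#' @param missing_policy,recompute_energy passed through the pipeline; see
#'   [align_to_network()] and [knockout_scan()].
#' @return A tibble with columns `threshold`, `mean_n_equivalent`,
#'   `sd_n_equivalent`, `n_patients`.
#' @export
threshold_sweep_stats <- function(net, profiles,
                                  thresholds = c(8, 16, 32, 48, 64, 128),
                                  missing_policy = "zero",
                                  recompute_energy = TRUE) {
  if (length(profiles) == 0) abort("`profiles` must be non-empty.")
  per_patient <- purrr::map(profiles, function(p) {
    prep <- prepare_patient(net, p, missing_policy)
    energy <- gibbs_energy(prep$net, prep$conc)
    vapply(thresholds, function(t) {
      filt <- suppressWarnings(gibbs_homology(prep$net, energy, t))
      rec <- knockout_scan(filt, prep$conc, recompute_energy = recompute_energy)
      best_targets(rec)$n_equivalent
    }, numeric(1))
  })
  m <- do.call(rbind, per_patient)
  tibble(
    threshold = as.integer(thresholds),
    mean_n_equivalent = apply(m, 2, mean),
    sd_n_equivalent = if (nrow(m) > 1) apply(m, 2, sd) else rep(0, ncol(m)),
    n_patients = nrow(m)
  )
}

# expression_profile -> working network + aligned concentration profile.
# Under missing_policy = "drop" the working network is restricted to the
# measured genes, per the alignment contract.
prepare_patient <- function(net, profile, missing_policy = "zero") {
  if (identical(attr(profile, "platform"), "rnaseq_counts")) {
    profile <- log2_transform(profile)
  }
  conc <- align_to_network(rescale(profile), net, missing_policy = missing_policy)
  if (missing_policy == "drop") {
    net <- induced_subnetwork(net, conc$gene)
  }
  list(net = net, conc = conc)
}
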