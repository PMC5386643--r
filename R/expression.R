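#' Per-patient expression profiles
#'
#' An `expression_profile` is a tibble with columns `gene` and `value`
#' holding one patient's transcription measurements: normalized RNA-seq
#' counts (`platform = "rnaseq_counts"`) or already log2-scale values such
#' as microarray intensities (`platform = "log2_values"`). Gene symbols are
#' uppercased and made unique; duplicate symbols are averaged (arithmetic
#' mean) with a message.
#'
#' @param data a data frame whose first two columns are gene symbol and value.
#' @param patient_id patient identifier string.
#' @param platform `"rnaseq_counts"` or `"log2_values"`.
#'
#' @return A tibble of class `expression_profile` with attributes
#'   `patient_id` and `platform`.
#' @export
expression_profile <- function(data, patient_id = "patient",
                               platform = c("rnaseq_counts", "log2_values")) {
  platform <- match.arg(platform)
  data <- as.data.frame(data)
  if (ncol(data) < 2) abort("Expression data needs gene and value columns.")
  gene <- clean_symbol(data[[1]])
  value <- as.numeric(data[[2]])
  if (anyNA(value)) abort("Expression values contain NA or are non-numeric.")
  tb <- tibble(gene = gene, value = value)
  if (anyDuplicated(tb$gene)) {
    dups <- unique(tb$gene[duplicated(tb$gene)])
    inform(sprintf(
      "Averaging %d duplicated gene symbol(s) (e.g. %s).",
      length(dups), paste(head(dups, 3), collapse = ", ")
    ))
    tb <- tb |>
      group_by(.data$gene) |>
      summarise(value = mean(.data$value), .groups = "drop")
  }
  new_profile(tb, patient_id, platform)
}

new_profile <- function(tb, patient_id, platform) {
  structure(
    as_tibble(tb),
    patient_id = patient_id,
    platform = platform,
    class = c("expression_profile", class(tibble()))
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf(
    "# expression_profile: patient '%s', platform %s, %d genes\n",
    attr(x, "patient_id"), attr(x, "platform"), nrow(x)
  ))
  NextMethod()
}

#' Read an expression TSV
#'
#' Expects two tab-separated columns, gene symbol and value. A header line is
#' auto-detected (first row whose second field is non-numeric is treated as a
#' header).
#'
#' @param path path to the TSV file.
#' @inheritParams expression_profile
#' @return An [expression_profile].
#' @export
read_expression <- function(path, patient_id = sub("\\.[^.]*$", "", basename(path)),
                            platform = c("rnaseq_counts", "log2_values")) {
  platform <- match.arg(platform)
  first <- readLines(path, n = 1, warn = FALSE)
  toks <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(toks) >= 2 && is.na(suppressWarnings(as.numeric(toks[[2]])))
  tb <- readr::read_tsv(
    path,
    col_names = c("gene", "value"),
    col_types = readr::cols(gene = "c", value = "d"),
    skip = if (has_header) 1 else 0,
    progress = FALSE
  )
  expression_profile(tb, patient_id = patient_id, platform = platform)
}

#' log2 transform of RNA-seq counts
#'
#' Replaces each normalized count by `log2(count + 1)`, putting RNA-seq data
#' on the same scale as log2 microarray values. Strictly monotone, so
#' expression ranks are preserved.
#'
#' @param profile an [expression_profile] with `platform = "rnaseq_counts"`
#'   and non-negative values.
#' @return An [expression_profile] with `platform = "log2_values"`.
#' @export
log2_transform <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  if (!identical(attr(profile, "platform"), "rnaseq_counts")) {
    abort("log2_transform() expects platform 'rnaseq_counts'.")
  }
  neg <- profile$gene[profile$value < 0]
  if (length(neg)) {
    abort(sprintf(
      "Negative count(s) for gene(s): %s", paste(head(neg, 5), collapse = ", ")
    ))
  }
  out <- profile
  out$value <- log2(out$value + 1)
  attr(out, "platform") <- "log2_values"
  out
}

#' Min-max rescaling to concentrations
#'
#' Converts log2-scale expression into dimensionless surrogate protein
#' concentrations `c = (e - e_min) / (e_max - e_min)`, with the minimum and
#' maximum taken over this patient's vector only: the most down-regulated
#' gene maps to 0 (no protein) and the most up-regulated to 1. The transform
#' is invariant under positive affine changes of the input scale.
#'
#' @param profile an [expression_profile] with `platform = "log2_values"`
#'   (apply [log2_transform()] first for counts) and at least two distinct
#'   values.
#' @return A tibble of class `concentration_profile` with columns `gene`,
#'   `conc` and attribute `patient_id`.
#' @export
rescale <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  if (!identical(attr(profile, "platform"), "log2_values")) {
    abort("rescale() expects platform 'log2_values'; run log2_transform() first.")
  }
  if (nrow(profile) == 0) abort("Cannot rescale an empty profile.")
  e <- profile$value
  rng <- range(e)
  if (rng[1] == rng[2]) {
    abort("Degenerate profile: all expression values are identical.")
  }
  new_concentration(
    tibble(gene = profile$gene, conc = (e - rng[1]) / (rng[2] - rng[1])),
    attr(profile, "patient_id")
  )
}

new_concentration <- function(tb, patient_id, coverage = NA_real_) {
  structure(
    as_tibble(tb),
    patient_id = patient_id,
    coverage = coverage,
    class = c("concentration_profile", class(tibble()))
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cov <- attr(x, "coverage")
  cat(sprintf(
    "# concentration_profile: patient '%s', %d genes%s\n",
    attr(x, "patient_id"), nrow(x),
    if (is.na(cov)) "" else sprintf(", network coverage %.1f%%", 100 * cov)
  ))
  NextMethod()
}

#' Align a concentration profile to a network
#'
#' Restricts a patient's concentrations to the genes of a PPI network.
#' Genes measured but absent from the network are discarded. Network nodes
#' without a measurement are assigned concentration 0 under
#' `missing_policy = "zero"` (no transcript implies no protein, and their
#' Gibbs energy is 0 by the continuity convention); under `"drop"` they are
#' omitted from the output, and the caller is expected to work on
#' `induced_subnetwork(net, genes-in-output)`.
#'
#' The fraction of network nodes with a measurement is recorded as the
#' `coverage` attribute.
#'
#' @param conc a `concentration_profile` (from [rescale()]).
#' @param net a [ppi_network].
#' @param missing_policy `"zero"` (default) or `"drop"`.
#' @return A `concentration_profile` keyed by network nodes.
#' @export
align_to_network <- function(conc, net, missing_policy = c("zero", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(conc, "concentration_profile"))
  nodes <- ppi_nodes(net)
  measured <- intersect(nodes, conc$gene)
  coverage <- if (length(nodes)) length(measured) / length(nodes) else NA_real_
  lut <- setNames(conc$conc, conc$gene)
  if (missing_policy == "zero") {
    out <- tibble(gene = nodes, conc = unname(lut[nodes]))
    out$conc[is.na(out$conc)] <- 0
  } else {
    out <- tibble(gene = measured, conc = unname(lut[measured]))
  }
  new_concentration(out, attr(conc, "patient_id"), coverage = coverage)
}

#' @export
glance.concentration_profile <- function(x, ...) {
  tibble(
    patient_id = attr(x, "patient_id"),
    n_genes = nrow(x),
    coverage = attr(x, "coverage"),
    min_conc = if (nrow(x)) min(x$conc) else NA_real_,
    max_conc = if (nrow(x)) max(x$conc) else NA_real_
  )
}
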