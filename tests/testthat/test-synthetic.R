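test_that("identical specs generate identical artifacts", {
  spec <- synthetic_spec(n_nodes = 50, seed = 1)
  n1 <- generate_network(spec)
  n2 <- generate_network(spec)
  expect_identical(ppi_edges(n1), ppi_edges(n2))
  p1 <- generate_expression(n1, spec, "p")
  p2 <- generate_expression(n2, spec, "p")
  expect_identical(p1$value, p2$value)

  c1 <- generate_cohort(4, spec)
  c2 <- generate_cohort(4, spec)
  expect_identical(
    lapply(c1$profiles, `[[`, "value"),
    lapply(c2$profiles, `[[`, "value")
  )
})

test_that("the planted module carries the advertised ring topology", {
  spec <- synthetic_spec(n_nodes = 60, planted_rings = c(5, 5), seed = 3)
  net <- generate_network(spec)
  expect_identical(net$hinge, "HINGE")
  planted <- net$planted_nodes
  expect_length(planted, 9) # two 5-rings sharing the hinge
  sub <- induced_subnetwork(net, planted)
  expect_equal(betti_number(sub)$betti, 2L)
  expect_equal(betti_oracle(sub), 2L)
  no_hinge <- induced_subnetwork(net, setdiff(planted, "HINGE"))
  expect_equal(betti_number(no_hinge)$betti, 0L)
})

test_that("without a planted module there is no ground-truth label", {
  spec <- synthetic_spec(n_nodes = 40, planted_rings = NULL, seed = 2)
  net <- generate_network(spec)
  expect_null(net$hinge)
  expect_length(net$planted_nodes, 0)
  expect_equal(n_nodes(net), 40L)
})

test_that("boosted planted nodes take the top concentration ranks", {
  spec <- synthetic_spec(n_nodes = 100, planted_rings = c(6, 6),
                         boost = 100, seed = 8)
  net <- generate_network(spec)
  prof <- generate_expression(net, spec, "p")
  conc <- align_to_network(rescale(log2_transform(prof)), net)
  top <- conc$gene[order(-conc$conc)][seq_along(net$planted_nodes)]
  expect_setequal(top, net$planted_nodes)
})

test_that("degenerate draws are perturbed so rescaling stays defined", {
  spec <- synthetic_spec(n_nodes = 20, planted_rings = NULL, sdlog = 0, seed = 1)
  net <- generate_network(spec)
  prof <- generate_expression(net, spec, "p")
  expect_gt(length(unique(prof$value)), 1)
  expect_silent(rescale(log2_transform(prof)))
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(n_nodes = 10, planted_rings = c(8, 8)), "larger")
  expect_error(synthetic_spec(n_nodes = 5), "at least 10")
  expect_error(synthetic_spec(n_nodes = 50, planted_rings = c(3, 5)), ">= 4")
})

test_that("generated artifacts satisfy the network and expression invariants", {
  spec <- synthetic_spec(n_nodes = 80, seed = 12)
  net <- generate_network(spec)
  ed <- ppi_edges(net)
  expect_true(all(ed$from != ed$to))
  expect_false(any(duplicated(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))))
  prof <- generate_expression(net, spec, "p")
  expect_true(all(prof$value >= 0))
  expect_true(all(prof$value == round(prof$value))) # integer counts
  expect_false(any(duplicated(prof$gene)))
})

test_that("histology shifts separate group energies in the expected direction", {
  spec <- synthetic_spec(n_nodes = 150, seed = 6)
  cohort <- generate_cohort(
    12, spec, histology_shift = c(astro = 0, oligo = 0, oligoastro = 3)
  )
  expect_s3_class(cohort$labels, "tbl_df")
  energies <- vapply(seq_along(cohort$profiles), function(i) {
    glance(analyze_patient(cohort$network, cohort$profiles[[i]],
                           threshold = 15))$homology_energy
  }, numeric(1))
  df <- data.frame(group = cohort$labels$group, energy = energies)
  means <- tapply(df$energy, df$group, mean)
  expect_lt(means[["oligoastro"]], means[["astro"]])
  expect_lt(means[["oligoastro"]], means[["oligo"]])
})

test_that("a minimal two-patient cohort is valid", {
  spec <- synthetic_spec(n_nodes = 50, seed = 10)
  cohort <- generate_cohort(2, spec)
  expect_length(cohort$profiles, 2)
  expect_error(generate_cohort(1, spec), "at least 2")
})
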