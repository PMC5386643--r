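test_that("per-node energy matches hand-evaluated closed forms", {
  iso <- ppi_network(data.frame(a = "B", b = "C"), nodes = "A")
  conc <- make_conc(iso, c(A = 0.7, B = 0, C = 0))
  expect_equal(gibbs_node(iso, conc, "A"), 0) # isolated: ratio 1

  tri <- ppi_network(data.frame(a = c("A", "A"), b = c("B", "C")))
  conc2 <- make_conc(tri, c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(gibbs_node(tri, conc2, "A"), -0.3465735903, tolerance = 1e-9)

  conc3 <- make_conc(tri, c(A = 0, B = 0.3, C = 0.2))
  expect_equal(gibbs_node(tri, conc3, "A"), 0) # continuity convention

  expect_error(gibbs_node(tri, conc2, "NOPE"), "not in the network")
})

test_that("network totals sum per-node energies and add over components", {
  ab <- ppi_network(data.frame(a = "A", b = "B"))
  conc <- make_conc(ab, c(A = 0.5, B = 0.5))
  em <- gibbs_energy(ab, conc)
  expect_equal(em$gibbs, rep(0.5 * log(0.5), 2))
  expect_equal(total_energy(em), log(0.5), tolerance = 1e-12)

  zeros <- make_conc(ab, c(A = 0, B = 0))
  expect_equal(total_energy(gibbs_energy(ab, zeros)), 0)

  # disjoint union: totals add exactly
  two <- ppi_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  conc4 <- make_conc(two, c(A = 0.5, B = 0.5, C = 0.9, D = 0.1))
  cd <- ppi_network(data.frame(a = "C", b = "D"))
  expect_equal(
    total_energy(gibbs_energy(two, conc4)),
    total_energy(gibbs_energy(ab, conc)) +
      total_energy(gibbs_energy(cd, make_conc(cd, c(C = 0.9, D = 0.1)))),
    tolerance = 1e-12
  )
})

test_that("energy maps are non-positive, consistent, and zero exactly when expected", {
  set.seed(21)
  for (i in 1:10) {
    net <- random_net(12, 0.3, 100 + i)
    vals <- round(runif(12), 3)
    vals[sample(12, 3)] <- 0
    names(vals) <- ppi_nodes(net)
    conc <- make_conc(net, vals)
    em <- gibbs_energy(net, conc)
    expect_true(all(em$gibbs <= 0))
    expect_equal(sum(em$gibbs), total_energy(em), tolerance = 1e-9)
    # G_i = 0 iff c_i = 0, node isolated, or all neighbors at 0
    g <- as_igraph(net)
    for (k in seq_len(nrow(em))) {
      nb <- igraph::neighbors(g, em$gene[k])$name
      expected_zero <- em$conc[k] == 0 || length(nb) == 0 ||
        all(conc$conc[match(nb, conc$gene)] == 0)
      expect_identical(em$gibbs[k] == 0, expected_zero)
    }
  }
})

test_that("totals agree with a naive double-loop oracle", {
  for (i in 1:8) {
    net <- random_net(10, 0.35, 200 + i)
    vals <- round(runif(10), 3)
    names(vals) <- ppi_nodes(net)
    conc <- make_conc(net, vals)
    expect_equal(
      total_energy(gibbs_energy(net, conc)),
      naive_gibbs_total(net, conc),
      tolerance = 1e-12
    )
  }
})

test_that("adding a concentrated neighbor deepens a node's well", {
  ab <- ppi_network(data.frame(a = "A", b = "B"))
  abc <- ppi_network(data.frame(a = c("A", "A"), b = c("B", "C")))
  g_before <- gibbs_node(ab, make_conc(ab, c(A = 0.5, B = 0.3)), "A")
  g_after <- gibbs_node(abc, make_conc(abc, c(A = 0.5, B = 0.3, C = 0.2)), "A")
  expect_lt(g_after, g_before)
})

test_that("scaling all concentrations scales the prefactor, not the log ratio", {
  net <- random_net(8, 0.4, 33)
  vals <- seq(0.1, 0.8, 0.1)
  names(vals) <- ppi_nodes(net)
  alpha <- 0.4
  em1 <- gibbs_energy(net, make_conc(net, vals))
  em2 <- gibbs_energy(net, make_conc(net, alpha * vals))
  # G_i(alpha * c) = alpha * c_i * ln(c_i / sum) = alpha * G_i(c)
  expect_equal(em2$gibbs, alpha * em1$gibbs, tolerance = 1e-12)
})

test_that("degree entropy matches hand evaluations", {
  expect_equal(degree_entropy(ring_net(6)), 0) # 2-regular
  expect_equal(degree_entropy(star_net(3)), 0.5623351446, tolerance = 1e-9)
  expect_equal(degree_entropy(path_net(c("A", "B", "C"))), 0.6365141683,
               tolerance = 1e-9)
  expect_error(degree_entropy(ppi_network()), "non-empty")
})
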