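# run a knockout scan on a hand-built subnetwork captured in full
scan_whole <- function(net, conc_values, recompute_energy = TRUE) {
  conc <- make_conc(net, conc_values)
  em <- gibbs_energy(net, conc)
  filt <- gibbs_homology(net, em, n_nodes(net))
  knockout_scan(filt, conc, recompute_energy = recompute_energy)
}

uniform_conc <- function(net, c = 0.5) {
  stats::setNames(rep(c, n_nodes(net)), ppi_nodes(net))
}

test_that("every node of a plain square is an equivalent target", {
  sq <- ppi_network(data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "A")))
  rec <- scan_whole(sq, uniform_conc(sq))
  expect_equal(attr(rec, "nominal_betti"), 1L)
  expect_true(all(rec$post_betti == 0L))
  expect_true(all(rec$delta_betti == 1L))
  bt <- best_targets(rec)
  expect_identical(bt$equivalent_targets, c("A", "B", "C", "D"))
  expect_equal(bt$n_equivalent, 4L)
})

test_that("the shared hinge of two squares is the unique best target", {
  net <- two_squares_net()
  rec <- scan_whole(net, uniform_conc(net))
  expect_equal(attr(rec, "nominal_betti"), 2L)
  expect_equal(rec$post_betti[rec$node == "H"], 0L)
  expect_true(all(rec$post_betti[rec$node != "H"] == 1L))
  expect_identical(best_targets(rec)$equivalent_targets, "H")
})

test_that("removing the wheel hub raises complexity: negative delta is representable", {
  wheel <- wheel_net()
  rec <- scan_whole(wheel, uniform_conc(wheel))
  expect_equal(attr(rec, "nominal_betti"), 0L)
  hub <- rec[rec$node == "HUB", ]
  expect_equal(hub$post_betti, 1L)
  expect_equal(hub$delta_betti, -1L)
})

test_that("the scan is side-effect free and deterministic", {
  net <- two_squares_net()
  conc <- make_conc(net, uniform_conc(net))
  em <- gibbs_energy(net, conc)
  filt <- gibbs_homology(net, em, 7)
  snapshot <- list(filt$captured, ppi_edges(filt$subnetwork))
  rec1 <- knockout_scan(filt, conc)
  rec2 <- knockout_scan(filt, conc)
  expect_identical(list(filt$captured, ppi_edges(filt$subnetwork)), snapshot)
  expect_identical(as.data.frame(rec1), as.data.frame(rec2))
})

test_that("energy bookkeeping follows the declared conventions", {
  net <- two_squares_net()
  conc <- make_conc(net, uniform_conc(net))
  em <- gibbs_energy(net, conc)
  filt <- gibbs_homology(net, em, 7)

  # without recomputation a knockout just subtracts the node's energy
  fixed <- knockout_scan(filt, conc, recompute_energy = FALSE)
  gi <- stats::setNames(filt$captured$gibbs, filt$captured$gene)
  expect_equal(fixed$post_gibbs, attr(fixed, "nominal_gibbs") - unname(gi[fixed$node]),
               tolerance = 1e-12)
  expect_equal(attr(fixed, "nominal_gibbs"), filt$homology_energy)

  # with recomputation the reduced topology is re-evaluated: removing a
  # well typically leaves post - nominal > 0 (the subnetwork loses depth)
  rec <- knockout_scan(filt, conc, recompute_energy = TRUE)
  expect_equal(
    rec$post_gibbs[rec$node == "H"],
    total_energy(gibbs_energy(
      induced_subnetwork(net, setdiff(ppi_nodes(net), "H")),
      make_conc(induced_subnetwork(net, setdiff(ppi_nodes(net), "H")),
                uniform_conc(net)[setdiff(ppi_nodes(net), "H")])
    )),
    tolerance = 1e-12
  )
  expect_equal(rec$delta_gibbs, rec$post_gibbs - attr(rec, "nominal_gibbs"))
  expect_equal(rec$abs_delta_gibbs, abs(rec$delta_gibbs))
})

test_that("a strict minimizer yields a singleton target set", {
  net <- two_squares_net()
  rec <- scan_whole(net, uniform_conc(net))
  expect_equal(best_targets(rec)$n_equivalent, 1L)
  report <- target_report(
    gibbs_homology(net, gibbs_energy(net, make_conc(net, uniform_conc(net))), 7),
    rec, net = net
  )
  expect_identical(report$equivalent_targets, "H")
  expect_equal(report$min_post_betti, 0L)
  expect_s3_class(tidy(report), "tbl_df")
  expect_equal(glance(report)$n_equivalent, 1L)
})

test_that("empty subnetworks are rejected", {
  net <- two_squares_net()
  conc <- make_conc(net, uniform_conc(net))
  em <- gibbs_energy(net, conc)
  filt <- gibbs_homology(net, em, 1)
  filt$captured <- filt$captured[0, ]
  expect_error(knockout_scan(filt, conc), "empty")
})
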