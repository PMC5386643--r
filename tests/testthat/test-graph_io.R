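biogrid_file <- function(rows, tab3 = FALSE, drop_cols = character()) {
  org <- if (tab3) "Organism ID Interactor" else "Organism Interactor"
  cols <- c(
    "#BioGRID Interaction ID",
    "Official Symbol Interactor A", "Official Symbol Interactor B",
    paste(org, "A"), paste(org, "B"),
    "Experimental System"
  )
  keep <- !cols %in% drop_cols
  lines <- c(
    paste(cols[keep], collapse = "\t"),
    vapply(rows, function(r) paste(c("1", r)[keep], collapse = "\t"), character(1))
  )
  path <- withr::local_tempfile(fileext = ".tab2.txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("BioGrid parsing collapses duplicates and drops self-interactions", {
  path <- biogrid_file(list(
    c("TP53", "MDM2", "9606", "9606", "Two-hybrid"),
    c("MDM2", "TP53", "9606", "9606", "Affinity Capture-MS"),
    c("EGFR", "EGFR", "9606", "9606", "Two-hybrid")
  ))
  net <- read_biogrid(path)
  expect_setequal(ppi_nodes(net), c("TP53", "MDM2"))
  expect_equal(n_edges(net), 1L)
})

test_that("BioGrid organism filter keeps rows where both interactors match", {
  path <- biogrid_file(list(
    c("TP53", "MDM2", "9606", "9606", "x"),
    c("TRP53", "MDM2", "10090", "9606", "x"),
    c("TRP53", "MDM2", "10090", "10090", "x")
  ))
  net <- read_biogrid(path, organism_id = 9606)
  expect_setequal(ppi_nodes(net), c("TP53", "MDM2"))
  expect_equal(n_edges(net), 1L)
  # without the filter, all symbols survive
  expect_setequal(ppi_nodes(read_biogrid(path)), c("TP53", "MDM2", "TRP53"))
})

test_that("TAB3-style organism headers are detected too", {
  path <- biogrid_file(list(c("A", "B", "9606", "9606", "x")), tab3 = TRUE)
  net <- read_biogrid(path, organism_id = 9606)
  expect_equal(n_edges(net), 1L)
})

test_that("BioGrid reader fails informatively", {
  path <- biogrid_file(list(c("A", "B", "9606", "9606", "x")),
                       drop_cols = "Official Symbol Interactor B")
  expect_error(read_biogrid(path), "Official Symbol Interactor B")
  only_mouse <- biogrid_file(list(c("A", "B", "10090", "10090", "x")))
  expect_error(read_biogrid(only_mouse, organism_id = 9606), "empty")
})

test_that("edge lists parse with comments, dedup and line-numbered errors", {
  path <- withr::local_tempfile()
  writeLines(c("# a comment", "A B", "B\tC", "B A"), path)
  net <- read_edge_list(path)
  expect_setequal(ppi_nodes(net), c("A", "B", "C"))
  expect_equal(n_edges(net), 2L)

  bad <- withr::local_tempfile()
  writeLines(c("A B", "A B C"), bad)
  expect_error(read_edge_list(bad), "Line 2")

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_error(read_edge_list(empty), "empty")
})

test_that("networks round-trip through the edge-list format", {
  for (seed in 1:5) {
    net <- random_net(12, 0.25, seed)
    path <- withr::local_tempfile()
    write_edge_list(net, path)
    back <- read_edge_list(path)
    expect_setequal(ppi_nodes(back), ppi_nodes(net))
    canon <- function(x) {
      ed <- ppi_edges(x)
      sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))
    }
    expect_identical(canon(back), canon(net))
  }
})

test_that("constructed networks always satisfy the class invariants", {
  set.seed(42)
  for (i in 1:20) {
    syms <- sample(c("tp53", "MDM2", "egfr", "KRAS", "BRAF"), 8, replace = TRUE)
    net <- suppressWarnings(ppi_network(data.frame(a = syms[1:4], b = syms[5:8])))
    ed <- ppi_edges(net)
    expect_true(all(ed$from != ed$to)) # no self-loops
    expect_true(all(ppi_nodes(net) == toupper(ppi_nodes(net))))
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    expect_false(any(duplicated(key))) # no duplicate edges either way round
    expect_true(all(c(ed$from, ed$to) %in% ppi_nodes(net)))
  }
})

test_that("induced_subnetwork restricts exactly and keeps isolated nodes", {
  pabc <- path_net(c("A", "B", "C"))
  sub <- induced_subnetwork(pabc, c("A", "C"))
  expect_setequal(ppi_nodes(sub), c("A", "C"))
  expect_equal(n_edges(sub), 0L)

  sq <- ring_net(4, "S")
  same <- induced_subnetwork(sq, ppi_nodes(sq))
  expect_setequal(ppi_nodes(same), ppi_nodes(sq))
  expect_equal(n_edges(same), n_edges(sq))

  empty <- induced_subnetwork(sq, character())
  expect_equal(n_nodes(empty), 0L)

  expect_error(induced_subnetwork(sq, c("S1", "NOPE")), "NOPE")
})
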