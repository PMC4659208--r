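mirror_id <- function(id) {
  chartr("RL", "LR", id)
}

test_that("the complete circle wires 18 segments between 3 inlets and 6 outlets", {
  net <- build_complete_cow()
  expect_s3_class(net, "cow_network")
  expect_equal(nrow(net$segments), 18)
  expect_setequal(net$segments$id, willisflow:::COW_SEGMENT_IDS)
  expect_equal(sum(net$nodes$role == "inlet"), 3)
  expect_equal(sum(net$nodes$role == "outlet"), 6)
  expect_length(net$flags, 0)

  # each ICA terminus joins {ICA, A1, MCA, PCoA}
  touching <- function(node) {
    s <- net$segments
    sort(s$id[s$from == node | s$to == node])
  }
  expect_setequal(touching("R_ICA_term"), c("RICA", "RA1", "RMCA", "RPCoA"))
  expect_setequal(touching("BA_top"), c("BA", "RP1", "LP1"))
  expect_setequal(touching("L_ant"), c("LA1", "ACoA", "LA2"))
})

test_that("a left-right mirrored dimension table leaves the graph automorphic", {
  dims <- nominal_geometry()
  net <- build_complete_cow(dims)
  edges <- net$segments[, c("id", "length_mm", "diameter_mm")]
  mirrored <- edges
  mirrored$id <- mirror_id(mirrored$id)
  merged <- merge(edges, mirrored, by = "id")
  expect_equal(merged$length_mm.x, merged$length_mm.y)
  expect_equal(merged$diameter_mm.x, merged$diameter_mm.y)
})

test_that("dimension-table defects are rejected by name", {
  dims <- nominal_geometry()
  expect_error(build_complete_cow(dims[dims$id != "ACoA", ]), "ACoA")
  dims$diameter_mm[dims$id == "BA"] <- 0
  expect_error(build_complete_cow(dims), "BA")
})

test_that("variants remove exactly one named segment and never touch dimensions", {
  net <- build_complete_cow()
  expect_identical(apply_variant(net, "COMPLETE"), net)
  for (v in setdiff(COW_VARIANTS, "COMPLETE")) {
    out <- apply_variant(net, v)
    expect_equal(nrow(out$segments), 17)
    gone <- setdiff(net$segments$id, out$segments$id)
    expect_length(gone, 1)
    kept <- merge(out$segments, net$segments, by = "id")
    expect_equal(kept$length_mm.x, kept$length_mm.y)
    expect_equal(kept$diameter_mm.x, kept$diameter_mm.y)
  }
})

test_that("with LA1 absent the left ACA territory hangs on the ACoA alone", {
  net <- apply_variant(build_complete_cow(), "LA1_ABSENT")
  g <- willisflow:::as_igraph(net)
  # still reachable through the ACoA ...
  expect_true(igraph::distances(g, "LICA_root", "LACA_out") < Inf)
  # ... and unreachable once the ACoA goes too
  sliced <- apply_variant(net, "ACOA_ABSENT")
  expect_match(paste(sliced$flags, collapse = " "), "LACA_out")
  g2 <- willisflow:::as_igraph(sliced)
  expect_true(is.infinite(igraph::distances(g2, "LICA_root", "LACA_out")))
})

test_that("NASCET degree arithmetic and its guards", {
  expect_equal(stenosis_degree(3, 3), 0)
  expect_equal(stenosis_degree(0, 3), 100)
  expect_equal(stenosis_degree(1.5, 3), 50)
  expect_error(stenosis_degree(4, 3), "narrow_diameter")
  expect_error(stenosis_degree(1, 0), "positive")
})

test_that("stenosis application splits, occludes or leaves the segment alone", {
  net <- build_complete_cow()
  expect_identical(apply_stenosis(net, 0), net)

  occluded <- apply_stenosis(net, 100)
  expect_false("RICA" %in% occluded$segments$id)

  half <- apply_stenosis(net, 50)
  sten <- half$segments[half$segments$id == "RICA_sten", ]
  d_n <- net$segments$diameter_mm[net$segments$id == "RICA"]
  expect_equal(sten$diameter_mm, d_n / 2)
  expect_equal(sten$length_mm, 10)
  remainder <- half$segments[half$segments$id == "RICA", ]
  expect_equal(remainder$length_mm + sten$length_mm,
               net$segments$length_mm[net$segments$id == "RICA"])

  expect_error(apply_stenosis(net, 150), "\\[0, 100\\]")
  expect_error(apply_stenosis(half, 25), "already stenosed")
  expect_error(apply_stenosis(net, 50, stenotic_length = 500), "shorter")
})

test_that("stenosis degree round-trips through the stenotic sub-segment", {
  net <- build_complete_cow()
  d_n <- net$segments$diameter_mm[net$segments$id == "RICA"]
  set.seed(3)
  for (deg in runif(10, 1, 99)) {
    sten <- apply_stenosis(net, deg)
    d_s <- sten$segments$diameter_mm[sten$segments$id == "RICA_sten"]
    expect_equal(stenosis_degree(d_s, d_n), deg, tolerance = 1e-12)
  }
})

test_that("synthetic geometry is seeded, bounded and symmetric at zero jitter", {
  expect_identical(synthetic_geometry(1, 0), synthetic_geometry(1, 0))
  expect_identical(synthetic_geometry(1, 0), nominal_geometry())
  a <- synthetic_geometry(1, 0.1)
  b <- synthetic_geometry(1, 0.1)
  c <- synthetic_geometry(2, 0.1)
  expect_identical(a, b)
  expect_false(identical(a, c))
  nom <- nominal_geometry()
  expect_true(all(abs(a$length_mm / nom$length_mm - 1) <= 0.1))
  expect_true(all(abs(a$diameter_mm / nom$diameter_mm - 1) <= 0.1))
  expect_error(synthetic_geometry(1, 0.5), "0.3")
  # global RNG state untouched
  set.seed(99)
  before <- .Random.seed
  invisible(synthetic_geometry(5, 0.2))
  expect_identical(before, .Random.seed)
})

test_that("segment tables round-trip through CSV", {
  net <- build_complete_cow()
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(net$segments, path)
  back <- read_segments(path)
  expect_equal(as.data.frame(back), as.data.frame(net$segments))
})
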