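test_that("TLS detection enforces the 40-cell minimum on dense clusters", {
  # 10 um spacing packs far above the density threshold
  expect_equal(n_patches(detect_tls(hex_cluster(39, 10, c(500, 500)))), 0L)
  p45 <- detect_tls(hex_cluster(45, 10, c(500, 500)))
  expect_equal(n_patches(p45), 1L)
  expect_length(p45$patches[[1]]$members, 45L)
})

test_that("uniform fields below the density threshold yield no patch", {
  for (lam in c(500, 1000, 2000)) {
    pp <- generate_point_pattern("grid", c(0, 0, 600, 600),
                                 spacing_um = 1000 / sqrt(lam))
    expect_gte(nrow(pp$points), 100L)
    expect_equal(n_patches(detect_tls(pp$points)), 0L)
  }
  pp4 <- generate_point_pattern("grid", c(0, 0, 600, 600),
                                spacing_um = 1000 / sqrt(4000))
  expect_gte(n_patches(detect_tls(pp4$points)), 1L)
})

test_that("Poisson fields: dense intensities always trigger, sparse never", {
  hits_dense <- hits_sparse <- logical(100)
  for (k in 1:100) {
    dense <- generate_point_pattern("csr", c(0, 0, 500, 500), seed = 1000 + k,
                                    intensity_per_mm2 = 4000)
    hits_dense[k] <- n_patches(detect_tls(dense$points)) >= 1
    sparse <- generate_point_pattern("csr", c(0, 0, 500, 500), seed = 2000 + k,
                                     intensity_per_mm2 = 500)
    hits_sparse[k] <- n_patches(detect_tls(sparse$points)) >= 1
  }
  expect_true(all(hits_dense))
  expect_false(any(hits_sparse))
})

test_that("fewer than three density-passing points give an empty patch set", {
  expect_equal(n_patches(detect_tls(data.frame(x_um = c(0, 1),
                                               y_um = c(0, 0)))), 0L)
  expect_equal(n_patches(detect_tls(data.frame(x_um = numeric(0),
                                               y_um = numeric(0)))), 0L)
})

test_that("graph patches require 25 connected member cells", {
  for (n in c(24, 25)) {
    tbl <- chain_table(n)
    g <- path_graph(tbl$cell_id)
    ps <- detect_patches(tbl, g, "B", min_cells = 25, expand_um = 0,
                         kind = "CD20")
    expect_equal(n_patches(ps), if (n >= 25) 1L else 0L)
  }
  # membership mixes B and BnT when both are member types
  tbl <- chain_table(30)
  tbl$phenotype[15] <- "BnT"
  g <- path_graph(tbl$cell_id)
  ps <- detect_patches(tbl, g, c("B", "BnT"), 25, 0, "CD20")
  expect_equal(n_patches(ps), 1L)
  expect_true("b15" %in% ps$patches[[1]]$core)
})

test_that("patch expansion is boundary-inclusive and monotone", {
  base <- chain_table(30)
  probe <- function(d, expand, kind, types) {
    tbl <- cell_table(rbind(base, data.frame(
      image_id = "img", cell_id = "probe", x_um = 30 * 8 + d, y_um = 0,
      area_um2 = 1, phenotype = "other")))
    tbl$phenotype[seq_len(30)] <- types
    g <- path_graph(base$cell_id)
    ps <- detect_patches(tbl, g, types, 25, expand, kind)
    "probe" %in% ps$patches[[1]]$members
  }
  # CD20 patches expand by 10 um: in at 9 and 10, out at 11
  expect_true(probe(9, 10, "CD20", "B"))
  expect_true(probe(10, 10, "CD20", "B"))
  expect_false(probe(11, 10, "CD20", "B"))
  # tumour patches expand by 25 um, inclusive at exactly 25
  expect_true(probe(25, 25, "tumor", "Tumor"))
  expect_false(probe(26, 25, "tumor", "Tumor"))

  # monotone: members at a smaller radius are a subset of a larger one
  set.seed(8)
  tbl <- cell_table(data.frame(
    image_id = "img", cell_id = as.character(1:80),
    x_um = c(seq_len(30) * 8, runif(50, 0, 400)),
    y_um = c(rep(0, 30), runif(50, 0, 200)), area_um2 = 1,
    phenotype = c(rep("B", 30), rep("other", 50))))
  g <- path_graph(as.character(1:30))
  g <- cell_graph(tbl$cell_id, graph_edges(g))
  m1 <- detect_patches(tbl, g, "B", 25, 5, "CD20")$patches[[1]]$members
  m2 <- detect_patches(tbl, g, "B", 25, 20, "CD20")$patches[[1]]$members
  expect_true(all(m1 %in% m2))
})

test_that("alpha shapes outline clusters and report sensible areas", {
  # a filled 10x10 grid of spacing 10: area ~ 90x90 square
  g <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  sh <- alpha_shape(g$x, g$y, alpha_um = 15)
  expect_length(sh, 1L)
  expect_equal(sh[[1]]$area_um2, 8100, tolerance = 1e-9)
  expect_length(sh[[1]]$members, 100L)
  # two distant clusters -> two components
  sh2 <- alpha_shape(c(g$x, g$x + 500), c(g$y, g$y), alpha_um = 15)
  expect_length(sh2, 2L)
  # degenerate: collinear points fall back without error
  sh3 <- alpha_shape(c(0, 10, 20, 30), rep(0, 4), alpha_um = 15)
  expect_length(sh3, 1L)
  expect_equal(sh3[[1]]$area_um2, 0)
})
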