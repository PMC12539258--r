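test_that("similarity transforms are recovered exactly from landmarks", {
  set.seed(5)
  src <- matrix(runif(8, 0, 100), 4, 2)
  # identity
  tr0 <- estimate_similarity_transform(src, src)
  expect_equal(tr0$scale, 1, tolerance = 1e-12)
  expect_equal(tr0$rmse, 0, tolerance = 1e-12)
  # rotation 30 deg, scale 1.5, translation (10, -5)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  dst <- t(1.5 * R %*% t(src)) + matrix(c(10, -5), 4, 2, byrow = TRUE)
  tr <- estimate_similarity_transform(src, dst)
  expect_equal(tr$scale, 1.5, tolerance = 1e-9)
  expect_equal(tr$theta, th, tolerance = 1e-9)
  expect_equal(c(tr$tx, tr$ty), c(10, -5), tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(tr, src) - dst)), 1e-9)
  # apply then invert returns the input
  back <- apply_transform(invert_transform(tr), apply_transform(tr, src))
  expect_lt(max(abs(back - src)), 1e-9)
})

test_that("noisy landmarks give RMSE at the noise scale", {
  set.seed(6)
  rmses <- replicate(100, {
    src <- matrix(runif(12, 0, 500), 6, 2)
    dst <- src + matrix(rnorm(12, 0, 1), 6, 2)
    estimate_similarity_transform(src, dst)$rmse
  })
  expect_gt(mean(rmses), 0.5)
  expect_lt(mean(rmses), 1.5)
})

test_that("degenerate landmark configurations are rejected", {
  expect_error(estimate_similarity_transform(matrix(1, 1, 2),
                                             matrix(1, 1, 2)), "at least 2")
  same <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(estimate_similarity_transform(same, same), "duplicate")
  col3 <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(estimate_similarity_transform(col3, col3, type = "affine"),
               "collinear")
})

test_that("reflected configurations need allow_reflection", {
  set.seed(7)
  src <- matrix(runif(10, 0, 100), 5, 2)
  dst <- src %*% diag(c(1, -1))          # pure reflection
  tr <- estimate_similarity_transform(src, dst)
  expect_gt(tr$rmse, 1)                  # rigid fit cannot reach it
  trr <- estimate_similarity_transform(src, dst, allow_reflection = TRUE)
  expect_lt(trr$rmse, 1e-9)
  expect_true(trr$reflection)
})

test_that("kcross equals the naive double sum and spatstat's estimator", {
  set.seed(7)
  w <- c(0, 0, 400, 300)
  pts <- data.frame(x_um = runif(120, 0, 400), y_um = runif(120, 0, 300),
                    mark = rep(c("a", "b"), 60))
  pp <- point_pattern(pts, w)
  radii <- default_radii(w, 64)
  cur <- kcross(pp, "a", "b", radii)
  a <- pts[pts$mark == "a", ]; b <- pts[pts$mark == "b", ]
  A <- 400 * 300
  k_naive <- vapply(radii, function(r) {
    s <- 0
    for (i in seq_len(nrow(a))) {
      dx <- a$x_um[i] - b$x_um; dy <- a$y_um[i] - b$y_um
      d <- sqrt(dx^2 + dy^2)
      keep <- d <= r
      s <- s + sum(A / ((400 - abs(dx[keep])) * (300 - abs(dy[keep]))))
    }
    A / (nrow(a) * nrow(b)) * s
  }, numeric(1))
  expect_lt(max(abs(cur$k - k_naive)), 1e-9)

  ss <- spatstat.explore::Kcross(
    spatstat.geom::ppp(pts$x_um, pts$y_um,
                       window = spatstat.geom::owin(c(0, 400), c(0, 300)),
                       marks = factor(pts$mark)),
    "a", "b", r = radii, correction = "translate")
  expect_lt(max(abs(cur$k - ss$trans)), 1e-8)

  # translation-corrected L is symmetric in (i, j)
  cur_ba <- kcross(pp, "b", "a", radii)
  expect_equal(cur$l, cur_ba$l, tolerance = 1e-12)
  expect_equal(cur$l[1], 0)
  expect_error(kcross(pp, "a", "zz", radii), "zz")
})

test_that("a single cross pair jumps K at exactly its distance", {
  w <- c(0, 0, 400, 400)
  pp <- point_pattern(data.frame(x_um = c(100, 130), y_um = c(200, 200),
                                 mark = c("a", "b")), w)
  radii <- seq(0, 100, by = 1)
  cur <- kcross(pp, "a", "b", radii)
  A <- 400 * 400
  e <- A / ((400 - 30) * 400)
  expect_true(all(cur$k[radii < 30] == 0))
  expect_equal(cur$k[radii >= 30], rep(A * e, sum(radii >= 30)))
})

test_that("the L-area score integrates L - r with sign", {
  curve <- structure(list(r = seq(0, 10, length.out = 101),
                          l = seq(0, 10, length.out = 101)),
                     class = "spatial_curve")
  expect_equal(l_area_score(curve), 0)
  curve$l <- curve$r + 1
  expect_equal(l_area_score(curve), 10)
  curve$l <- curve$r - 2
  expect_equal(l_area_score(curve), -20)
})

test_that("the L-area score is centred at zero under CSR", {
  set.seed(12)
  areas <- replicate(100, {
    pat <- csr_pattern(50, 50)
    l_area_score(kcross(pat, "i", "j", default_radii(pat$window, 64)))
  })
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas)), 2 * se)
})

test_that("MAD test: co-clustered types reach the minimal p-value", {
  pat <- clustered_bivariate(seed = 3)
  mt <- mad_test(pat, "i", "j", nsim = 99,
                 radii = default_radii(pat$window, 128), seed = 11)
  expect_equal(mt$p_value, 0.01)
  expect_equal(mt$p_value, 1 / (mt$nsim + 1))
  # seeded reproducibility
  mt2 <- mad_test(pat, "i", "j", nsim = 99,
                  radii = default_radii(pat$window, 128), seed = 11)
  expect_identical(mt$sim_statistics, mt2$sim_statistics)
})

test_that("MAD p-values follow the rank formula on the achievable grid", {
  set.seed(30)
  pat <- csr_pattern(20, 20)
  radii <- default_radii(pat$window, 32)
  mt <- mad_test(pat, "i", "j", nsim = 1, seed = 2, radii = radii)
  expect_true(mt$p_value %in% c(0.5, 1))
  expect_equal(mt$p_value,
               (1 + sum(mt$sim_statistics >= mt$statistic)) / 2)
})

test_that("MAD p-values are uniform under CSR", {
  # Kolmogorov distance to uniform over seeded CSR replicates
  ps <- vapply(1:500, function(k) {
    set.seed(5000 + k)
    pat <- csr_pattern(15, 15)
    mad_test(pat, "i", "j", nsim = 19, seed = 9000 + k,
             radii = default_radii(pat$window, 24))$p_value
  }, numeric(1))
  grid <- seq(0.05, 1, by = 0.05)
  ks <- max(abs(vapply(grid, function(q) mean(ps <= q), numeric(1)) - grid))
  expect_lt(ks, 0.1)
})

test_that("co-localization calls follow the two printed bounds", {
  expect_equal(colocalization_call(5, 0.01), "colocalized")
  expect_equal(colocalization_call(-1, 0.01), "not_colocalized")
  expect_equal(colocalization_call(5, 0.02), "not_colocalized")
  expect_equal(colocalization_call(0, 0.001), "not_colocalized")
})

test_that("modality pairing aligns, windows and restores co-location", {
  set.seed(9)
  cells <- data.frame(x_um = runif(80, 0, 300), y_um = runif(80, 0, 300),
                      phenotype = "T")
  ident <- similarity_transform()
  pat <- pair_modalities(cells, cells, ident, cell_type = "T")
  expect_equal(sum(pat$points$mark == "IMC"),
               sum(pat$points$mark == "mIF"))
  # shifted mIF restored by the matching transform
  shift <- transform(cells, x_um = x_um + 40, y_um = y_um - 15)
  tr <- similarity_transform(tx = -40, ty = 15)
  pat2 <- pair_modalities(cells, shift, tr, cell_type = "T")
  imc <- pat2$points[pat2$points$mark == "IMC", ]
  mif <- pat2$points[pat2$points$mark == "mIF", ]
  expect_equal(nrow(imc), nrow(mif))
  expect_lt(max(abs(sort(imc$x_um) - sort(mif$x_um))), 1e-9)
  # disjoint windows error
  far <- transform(cells, x_um = x_um + 5000)
  expect_error(pair_modalities(cells, far, ident), "empty intersection")
})
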