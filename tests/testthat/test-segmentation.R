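test_that("two disjoint bright disks segment into exactly the disks", {
  m <- disk_mask(rbind(c(20, 30), c(45, 30)), c(6, 6), c(60, 60))
  img <- matrix(0, 60, 60); img[m$labels > 0] <- 100
  seg <- segment_nuclei(img, 1)
  expect_equal(length(mask_labels(seg)), 2L)
  # same pixel sets (labels may be permuted)
  expect_equal(seg$labels > 0, m$labels > 0)
  for (l in 1:2) {
    got <- unique(seg$labels[m$labels == l])
    expect_length(got, 1L)
  }
})

test_that("overlapping disks are split at the neck", {
  cc <- expand.grid(r = 1:60, c = 1:60)
  d1 <- sqrt((cc$r - 30)^2 + (cc$c - 22)^2)
  d2 <- sqrt((cc$r - 30)^2 + (cc$c - 38)^2)
  img <- matrix(0, 60, 60)
  img[d1 <= 10 | d2 <= 10] <- 100
  seg <- segment_nuclei(img, 1)
  expect_equal(length(mask_labels(seg)), 2L)
  # compare with the nearest-disk-centre assignment on the synthetic geometry
  fg <- img > 0
  oracle <- matrix(ifelse(d1 < d2, 1L, 2L), 60, 60)[fg]
  got <- seg$labels[fg]
  agree <- max(mean(got == oracle), mean(got == 3L - oracle))
  expect_gt(agree, 0.95)
})

test_that("degenerate inputs give empty masks or parameter errors", {
  expect_equal(length(mask_labels(segment_nuclei(matrix(0, 30, 30), 1))), 0L)
  expect_equal(length(mask_labels(segment_nuclei(matrix(7, 30, 30), 1))), 0L)
  expect_error(segment_nuclei(matrix(1, 5, 5), 1, window_um = 0),
               "window_um")
})

test_that("small objects below the area floor are removed", {
  img <- matrix(0, 40, 40)
  img[20:26, 20:26] <- 100        # 49 px
  img[5, 5] <- 100                # 1 px, below 8 um^2 at 1 um/px
  seg <- segment_nuclei(img, 1)
  expect_equal(length(mask_labels(seg)), 1L)
})

test_that("cell expansion matches the brute-force nearest-nucleus oracle", {
  # two nuclei 4 um apart: expansion halts at the equidistant line
  m <- disk_mask(rbind(c(14, 20), c(26, 20)), c(4, 4), c(40, 40))
  seg <- expand_cells(m, 5)
  expect_identical(seg$cells$labels, expand_oracle(m, 5))
  expect_setequal(mask_labels(seg$cells), c(1L, 2L))

  # random droplet fields, exact equality on <= 128^2 images
  for (seed in 1:3) {
    set.seed(seed)
    n <- 6
    ctr <- cbind(runif(n, 12, 108), runif(n, 12, 108))
    m2 <- disk_mask(ctr, runif(n, 2, 5), c(120, 120))
    seg2 <- expand_cells(m2, 5)
    expect_identical(seg2$cells$labels, expand_oracle(m2, 5))
    # structural invariants: cells contain nuclei, cytoplasm is difference
    nn <- m2$labels > 0
    expect_true(all(seg2$cells$labels[nn] == m2$labels[nn]))
    expect_true(all(seg2$cytoplasm$labels[nn] == 0L))
  }
})

test_that("isolated nucleus expands by at most 5 um", {
  m <- disk_mask(rbind(c(100, 100)), 4, c(400, 400), pixel_size_um = 0.5)
  seg <- expand_cells(m, 5)
  d <- EBImage::distmap(matrix(as.numeric(m$labels == 0), 400)) * 0.5
  reach <- max(d[seg$cells$labels > 0 & m$labels == 0])
  expect_lte(reach, 5)
  expect_gt(reach, 5 - 2 * 0.5)   # within one pixel of the full 5 um
})

test_that("zero expansion returns cells equal to nuclei", {
  m <- disk_mask(rbind(c(10, 10)), 4, c(24, 24))
  seg <- expand_cells(m, 0)
  expect_identical(seg$cells$labels, m$labels)
  expect_equal(sum(seg$cytoplasm$labels), 0)
})

test_that("mask matching applies the strict overlap threshold", {
  # |A| = |B| = 1000, intersection 500 -> coefficient exactly 0.5, excluded
  a <- matrix(0L, 10, 300); a[1:10, 1:100] <- 1L
  b <- matrix(0L, 10, 300); b[1:10, 51:150] <- 1L
  r <- match_masks(label_mask(a, 1, validate = FALSE),
                   label_mask(b, 1, validate = FALSE))
  expect_equal(r$pairs$overlap, 0.5)
  expect_false(r$pairs$retained)
  expect_equal(unname(r$class_counts[c("1 - missing", "missing - 1")]),
               c(1L, 1L))
  # one pixel more -> retained as 1 - 1
  b2 <- matrix(0L, 10, 300); b2[1:10, 51:150] <- 1L; b2[1, 50] <- 1L
  r2 <- match_masks(label_mask(a, 1, validate = FALSE),
                    label_mask(b2, 1, validate = FALSE))
  expect_true(r2$pairs$retained)
  expect_equal(unname(r2$class_counts["1 - 1"]), 1L)
})

test_that("identical masks match perfectly; split nuclei are 1 - many", {
  m <- disk_mask(rbind(c(15, 15), c(40, 40)), c(6, 6), c(60, 60))
  r <- match_masks(m, m)
  expect_equal(unname(r$class_counts["1 - 1"]), 2L)
  expect_true(all(r$pairs$overlap == 1))

  # one A-nucleus covering two disjoint B-nuclei fully inside it
  a <- matrix(0L, 30, 30); a[5:25, 5:25] <- 1L
  b <- matrix(0L, 30, 30); b[7:12, 7:12] <- 1L; b[18:23, 18:23] <- 2L
  r2 <- match_masks(label_mask(a, 1, validate = FALSE),
                    label_mask(b, 1, validate = FALSE))
  expect_equal(unname(r2$class_counts["1 - many"]), 1L)
  expect_equal(sum(r2$class_counts), 1L)
})

test_that("mask matching is permutation invariant and symmetric", {
  set.seed(11)
  m <- disk_mask(cbind(runif(8, 10, 110), runif(8, 10, 110)),
                 rep(5, 8), c(120, 120))
  shuf <- m
  perm <- sample(8)
  shuf$labels[m$labels > 0] <- perm[m$labels[m$labels > 0]]
  mb <- disk_mask(cbind(runif(8, 10, 110), runif(8, 10, 110)),
                  rep(5, 8), c(120, 120))
  r1 <- match_masks(m, mb)
  r2 <- match_masks(shuf, mb)
  expect_equal(r1$class_counts, r2$class_counts)
  r3 <- match_masks(mb, m)
  swap <- c("1 - 1", "many - 1", "1 - many", "many - many",
            "missing - 1", "1 - missing")
  expect_equal(unname(r3$class_counts[swap]), unname(r1$class_counts))
  expect_error(match_masks(m, disk_mask(rbind(c(5, 5)), 3, c(50, 50))),
               "shapes differ")
})
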