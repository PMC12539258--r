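mk_seg_stack <- function() {
  # one 3x3 nucleus inside a 5x5 cell, plus an isolated 2x2 nucleus whose
  # cell equals the nucleus (zero cytoplasm via max_dist 0 on that side)
  nuc <- matrix(0L, 20, 20)
  nuc[6:8, 6:8] <- 1L
  cells <- matrix(0L, 20, 20)
  cells[5:9, 5:9] <- 1L
  cyto <- ifelse(nuc > 0L, 0L, cells); storage.mode(cyto) <- "integer"
  seg <- segmentation_result(label_mask(nuc, 1, validate = FALSE),
                             label_mask(cells, 1, validate = FALSE),
                             label_mask(cyto, 1, validate = FALSE))
  px <- array(0, c(20, 20, 1))
  man <- data.frame(channel_id = 1, marker = "CD3", fluorophore = "F1")
  list(seg = seg, man = man, px = px)
}

test_that("constant channels yield the constant for every statistic", {
  f <- mk_seg_stack()
  f$px[] <- 7
  tbl <- quantify_cells(image_stack(f$px, f$man, 1), f$seg)
  for (col in grep("CD3_", names(tbl), value = TRUE))
    expect_equal(tbl[[col]], 7)
  expect_equal(tbl$area_um2, 25)
  # centroid of the 5x5 block starting at row/col 5 (um, corner origin)
  expect_equal(tbl$x_um, 6.5)
  expect_equal(tbl$y_um, 6.5)
})

test_that("statistics match hand-computed values on known pixels", {
  f <- mk_seg_stack()
  vals <- matrix(0, 20, 20)
  nucv <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  vals[6:8, 6:8] <- matrix(nucv, 3, 3)
  cellv <- seq_len(25)
  vals[5:9, 5:9] <- matrix(cellv, 5, 5)
  vals[6:8, 6:8] <- matrix(nucv, 3, 3)   # nucleus values override
  f$px[, , 1] <- vals
  tbl <- quantify_cells(image_stack(f$px, f$man, 1), f$seg)
  nuc_px <- vals[6:8, 6:8]
  cell_px <- vals[5:9, 5:9]
  cyto_px <- cell_px[-(as.vector(matrix(1:25, 5, 5)[2:4, 2:4]))]
  expect_equal(tbl$CD3_nucleus_mean, mean(nuc_px))
  expect_equal(tbl$CD3_nucleus_median, median(as.numeric(nuc_px)))
  expect_equal(tbl$CD3_cell_p75,
               unname(quantile(as.numeric(cell_px), 0.75)))
  expect_equal(tbl$CD3_cytoplasm_mean, mean(cyto_px))
  expect_equal(tbl$CD3_cell_p90,
               unname(quantile(as.numeric(cell_px), 0.9)))
})

test_that("empty cytoplasm yields missing values, not zeros", {
  nuc <- matrix(0L, 10, 10); nuc[3:5, 3:5] <- 1L
  seg <- segmentation_result(label_mask(nuc, 1, validate = FALSE),
                             label_mask(nuc, 1, validate = FALSE),
                             label_mask(matrix(0L, 10, 10), 1,
                                        validate = FALSE))
  px <- array(5, c(10, 10, 1))
  man <- data.frame(channel_id = 1, marker = "CD3", fluorophore = "F1")
  tbl <- quantify_cells(image_stack(px, man, 1), seg)
  expect_true(is.na(tbl$CD3_cytoplasm_mean))
  expect_equal(tbl$CD3_cell_mean, 5)
})

test_that("cells without nuclei are a consistency error", {
  nuc <- matrix(0L, 10, 10); nuc[3:4, 3:4] <- 1L
  cells <- nuc; cells[8:9, 8:9] <- 2L
  cyto <- matrix(0L, 10, 10); cyto[8:9, 8:9] <- 2L
  seg <- segmentation_result(label_mask(nuc, 1, validate = FALSE),
                             label_mask(cells, 1, validate = FALSE),
                             label_mask(cyto, 1, validate = FALSE))
  px <- array(1, c(10, 10, 1))
  man <- data.frame(channel_id = 1, marker = "CD3", fluorophore = "F1")
  expect_error(quantify_cells(image_stack(px, man, 1), seg),
               "not in nuclei")
})

test_that("thresholding is strict, idempotent and matches the oracle", {
  set.seed(2)
  tbl <- cell_table(data.frame(
    image_id = "i", cell_id = 1:50, x_um = 1, y_um = 1, area_um2 = 1,
    CD3_cell_mean = c(50, 49.999, 50.001, runif(47, 0, 100))))
  thr <- threshold_set(data.frame(marker = "CD3", region = "cell",
                                  statistic = "mean", threshold = 50))
  out <- apply_thresholds(tbl, thr)
  expect_false(out$pos_CD3[1])            # score == threshold is negative
  expect_false(out$pos_CD3[2])
  expect_true(out$pos_CD3[3])
  expect_identical(out$pos_CD3, tbl$CD3_cell_mean > 50)  # elementwise oracle
  # idempotent
  expect_identical(apply_thresholds(out, thr)$pos_CD3, out$pos_CD3)
  # -Inf threshold -> everything positive
  thr2 <- threshold_set(transform(thr, threshold = -.Machine$double.xmax))
  expect_true(all(apply_thresholds(tbl, thr2)$pos_CD3))
  # missing score column names the marker
  thr3 <- threshold_set(data.frame(marker = "CD20", region = "cell",
                                   statistic = "mean", threshold = 1))
  expect_error(apply_thresholds(tbl, thr3), "CD20")
})

test_that("phenotype assignment reproduces the priority example and the
           exhaustive rule scan", {
  key <- phenotype_key(
    data.frame(CD3 = c("+", "-"), CD163 = c("any", "+"),
               phenotype = c("T", "Mac")),
    priority = c("CD3", "CD163"))
  tbl <- cell_table(data.frame(
    image_id = "i", cell_id = 1:4, x_um = 1, y_um = 1, area_um2 = 1,
    pos_CD3 = c(TRUE, TRUE, FALSE, FALSE),
    pos_CD163 = c(TRUE, FALSE, TRUE, FALSE)))
  out <- assign_phenotypes(tbl, key)
  # CD3+CD163+ resolves to T because CD3 is prioritized
  expect_equal(out$phenotype, c("T", "T", "Mac", "other"))

  # exhaustive: every combination of 4 markers against a brute-force scan
  mk <- paste0("m", 1:4)
  rules <- data.frame(m1 = c("+", "-", "-"), m2 = c("any", "+", "-"),
                      m3 = c("any", "any", "+"), m4 = "any",
                      phenotype = c("A", "B", "C"))
  key4 <- phenotype_key(rules, priority = mk)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  names(combos) <- paste0("pos_", mk)
  tbl4 <- cell_table(cbind(
    data.frame(image_id = "i", cell_id = seq_len(16), x_um = 1, y_um = 1,
               area_um2 = 1), combos))
  out4 <- assign_phenotypes(tbl4, key4)
  brute <- apply(as.matrix(combos), 1L, function(fl) {
    for (ri in seq_len(nrow(rules))) {
      p <- unlist(rules[ri, mk])
      if (all(p == "any" | (p == "+" & fl) | (p == "-" & !fl)))
        return(rules$phenotype[ri])
    }
    "other"
  })
  expect_equal(out4$phenotype, unname(brute))

  # invariant to cell ordering
  perm <- sample(16)
  out_perm <- assign_phenotypes(tbl4[perm, ], key4)
  expect_equal(out_perm$phenotype, out4$phenotype[perm])
})
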