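# Shared fixtures, built in code at test time.

# rasterized disk label mask: centres (x, y) in um, radii in um
disk_mask <- function(centres, radii, dim_px, pixel_size_um = 1,
                      validate = FALSE) {
  lab <- matrix(0L, dim_px[1], dim_px[2])
  xc <- (seq_len(dim_px[2]) - 0.5) * pixel_size_um
  yc <- (seq_len(dim_px[1]) - 0.5) * pixel_size_um
  for (i in seq_len(nrow(centres))) {
    for (r in which(abs(yc - centres[i, 2]) <= radii[i])) {
      hit <- which((xc - centres[i, 1])^2 + (yc[r] - centres[i, 2])^2 <=
                     radii[i]^2)
      lab[r, hit] <- i
    }
  }
  label_mask(lab, pixel_size_um, validate = validate)
}

# brute-force per-pixel nearest-nucleus-within-radius expansion oracle
expand_oracle <- function(nuclei, max_dist_um) {
  lab <- nuclei$labels
  s <- nuclei$pixel_size_um
  H <- nrow(lab); W <- ncol(lab)
  pix <- which(lab > 0L)
  pr <- (pix - 1L) %% H + 1L
  pc <- (pix - 1L) %/% H + 1L
  bl <- lab[pix]
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    d <- sqrt(((pr - r) * s)^2 + ((pc - c) * s)^2)
    dm <- min(d)
    if (dm <= max_dist_um) out[r, c] <- min(bl[d == dm])
  }
  out
}

# chain-of-cells table and path graph (IMC-style neighbourhood fixtures)
chain_table <- function(n, phenotype = "B", prefix = "b", y_um = 0,
                        spacing = 8) {
  cell_table(data.frame(
    image_id = "img", cell_id = paste0(prefix, seq_len(n)),
    x_um = seq_len(n) * spacing, y_um = y_um, area_um2 = 1,
    phenotype = phenotype))
}

path_graph <- function(ids, extra_edges = NULL) {
  e <- cbind(ids[-length(ids)], ids[-1])
  if (!is.null(extra_edges)) e <- rbind(e, extra_edges)
  cell_graph(ids, e)
}

# tumour blob of size n_t with an attached stroma chain of size n_s
island_fixture <- function(n_t, n_s) {
  tum <- paste0("t", seq_len(n_t)); str <- paste0("s", seq_len(n_s))
  nodes <- c(tum, str)
  edges <- cbind(tum[-n_t], tum[-1])
  if (n_s > 1L) edges <- rbind(edges, cbind(str[-n_s], str[-1]))
  edges <- rbind(edges, c(tum[1], str[1]))
  tbl <- cell_table(data.frame(
    image_id = "img", cell_id = nodes, x_um = seq_along(nodes), y_um = 1,
    area_um2 = 1, pos_CK = c(rep(TRUE, n_t), rep(FALSE, n_s))))
  list(table = tbl, graph = cell_graph(nodes, edges),
       stroma = str, tumor = tum)
}

# two-marker demo key: CK+ -> Tumor, CD3+ -> T (CD3 prioritized), else other
demo_key <- function() {
  phenotype_key(
    data.frame(CK = c("+", "any"), CD3 = c("any", "+"),
               phenotype = c("Tumor", "T")),
    priority = c("CD3", "CK"))
}

demo_thresholds <- function() {
  threshold_set(data.frame(
    marker = c("CK", "CD3"), region = "cell", statistic = "mean",
    threshold = 50))
}

# bivariate clustered pattern sharing cluster centres (strong co-location)
clustered_bivariate <- function(n_per_type = 200, n_centres = 5,
                                window = c(0, 0, 1000, 1000), seed = 3,
                                sigma = 20) {
  set.seed(seed)
  cx <- runif(n_centres, window[1] + 200, window[3] - 200)
  cy <- runif(n_centres, window[2] + 200, window[4] - 200)
  per <- n_per_type / n_centres
  mk <- function(m) data.frame(
    x_um = pmin(pmax(rep(cx, each = per) + rnorm(n_per_type, 0, sigma),
                     window[1]), window[3]),
    y_um = pmin(pmax(rep(cy, each = per) + rnorm(n_per_type, 0, sigma),
                     window[2]), window[4]),
    mark = m)
  point_pattern(rbind(mk("i"), mk("j")), window)
}

csr_pattern <- function(n_i, n_j, window = c(0, 0, 500, 500)) {
  point_pattern(data.frame(
    x_um = runif(n_i + n_j, window[1], window[3]),
    y_um = runif(n_i + n_j, window[2], window[4]),
    mark = rep(c("i", "j"), c(n_i, n_j))), window)
}
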