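test_that("bin edges are equal-width over the value range", {
  e <- bin_edges(c(0, 32), nbins = 32)
  expect_equal(e, 0:32)
  expect_false(is.unsorted(bin_edges(rnorm(50)), strictly = TRUE))
  # constant vector: degenerate unit-width span, all mass in one bin
  ec <- bin_edges(rep(4, 10))
  h <- joint_histogram(rep(4, 10), rep(4, 10), ec, ec)
  expect_equal(sum(h), 10)
  expect_equal(sum(h > 0), 1L)
  expect_error(bin_edges(numeric()), "empty")
})

test_that("joint histogram counts cells per bin with half-open bins", {
  # 2x2 example: four cells, one per quadrant
  e <- c(0, 0.5, 1)
  h <- joint_histogram(c(0, 0, 1, 1), c(0, 1, 0, 1), e, e)
  expect_equal(as.vector(h), rep(1L, 4))
  expect_error(joint_histogram(1:3, 1:4, e, e), "length")
})

test_that("histogram mass equals the number of cells for random inputs", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    x <- rexp(n); y <- rexp(n)
    h <- joint_histogram(x, y, bin_edges(x), bin_edges(y))
    expect_identical(sum(h), n)
  }
})

test_that("self-images place all mass on the diagonal", {
  set.seed(22)
  for (i in 1:10) {
    v <- rpois(100, 3) + runif(100)
    e <- bin_edges(v)
    h <- joint_histogram(v, v, e, e)
    expect_equal(sum(h) - sum(diag(h)), 0)
  }
})

test_that("log-normalization maps counts into [0, log10(11)] monotonically", {
  h <- matrix(0, 3, 3); h[2, 2] <- 50
  out <- lognorm_histogram(h)
  expect_equal(out[2, 2], log10(11))           # all mass in one bin
  expect_equal(sum(out) - out[2, 2], 0)        # zeros stay zero
  # uniform mass over k bins
  k <- 4
  hu <- matrix(c(rep(5, k), rep(0, 5)), 3, 3)
  expect_equal(unique(lognorm_histogram(hu)[hu > 0]), log10(1 + 10 / k))
  # monotone in the counts
  set.seed(23)
  hr <- matrix(rpois(9, 4), 3, 3)
  lr <- lognorm_histogram(hr)
  ord <- order(hr)
  expect_false(is.unsorted(lr[ord]))
  expect_error(lognorm_histogram(matrix(0, 2, 2)), "no mass")
})

test_that("image stacks follow the 2n+3 layout contract", {
  ds <- simulate_dataset(synthetic_spec(n_genes = 15, n_cells = 60,
                                        n_tfs = 2, targets_per_tf = 2))
  pm <- suppressWarnings(preprocess_expression(ds$matrix))
  st3 <- build_image_stack(ds$tfs[1], "G001", pm, n = 3)
  expect_equal(dim(st3$images), c(32, 32, 9))  # 2*3 + 3
  st0 <- build_image_stack(ds$tfs[1], "G001", pm, n = 0)
  expect_equal(dim(st0$images), c(32, 32, 3))  # primary + two self-images
  expect_identical(st3$layout$role[1:3], c("primary", "self_x", "self_y"))
  expect_error(build_image_stack("NOPE", "G001", pm, 1), "unknown gene")
})

test_that("swapping the pair transposes the primary image and swaps blocks", {
  ds <- simulate_dataset(synthetic_spec(n_genes = 15, n_cells = 60,
                                        n_tfs = 2, targets_per_tf = 2))
  pm <- suppressWarnings(preprocess_expression(ds$matrix))
  a <- build_image_stack("TF01", "G001", pm, n = 2)
  b <- build_image_stack("G001", "TF01", pm, n = 2)
  expect_equal(b$images[, , 1], t(a$images[, , 1]))
  expect_equal(b$images[, , 2], a$images[, , 3])   # self images swapped
  expect_equal(b$images[, , 3], a$images[, , 2])
  expect_equal(b$images[, , 4:5], a$images[, , 6:7])  # neighbor blocks swap
  expect_equal(b$images[, , 6:7], a$images[, , 4:5])
})

test_that("images are invariant to cell-order permutation", {
  ds <- simulate_dataset(synthetic_spec(n_genes = 15, n_cells = 60,
                                        n_tfs = 2, targets_per_tf = 2))
  pm <- suppressWarnings(preprocess_expression(ds$matrix))
  set.seed(4)
  perm <- sample(ncol(pm$values))
  pm2 <- pm
  pm2$values <- pm$values[, perm]
  pm2$cell_ids <- pm$cell_ids[perm]
  a <- build_image_stack("TF01", "G002", pm, n = 2)
  b <- build_image_stack("TF01", "G002", pm2, n = 2)
  expect_equal(a$images, b$images)
})

test_that("missing neighbors are zero-padded and flagged", {
  pm <- five_gene_pm()
  # gene C has no positive-covariance neighbor among A/B/D (all negative)
  st <- build_image_stack("C", "D", pm, n = 3, within = c("A", "B", "C", "D"))
  padded <- st$layout$padded[st$layout$role == "neighbor_x"]
  expect_true(any(padded))
  for (slot in st$layout$slot[st$layout$padded]) {
    expect_equal(sum(st$images[, , slot]), 0)
  }
})
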