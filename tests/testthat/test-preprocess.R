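test_that("per-cell normalization scales every column to the size factor", {
  m <- cbind(c(2, 198), c(50, 50))
  out <- normalize_per_cell(m, size_factor = 1e4)
  expect_equal(out[, 1], c(100, 9900))
  expect_lt(max(abs(colSums(out) - 1e4)) / 1e4, 1e-6)
  # fixed point: column already summing to the size factor
  m2 <- cbind(c(9999, 1))
  expect_equal(normalize_per_cell(m2, 1e4), m2)
  # all-zero column dropped with a warning
  m3 <- cbind(c(1, 1), c(0, 0))
  expect_warning(out3 <- normalize_per_cell(m3), "all-zero")
  expect_equal(ncol(out3), 1L)
  expect_error(normalize_per_cell(m, size_factor = 0), "size_factor")
})

test_that("log transform is log1p with domain checking", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(100), log(101))
  v <- sort(runif(20, 0, 50))
  expect_false(is.unsorted(log_transform(v)))   # monotone
  expect_error(log_transform(-1), "non-negative")
})

test_that("HVG selection finds planted high-dispersion genes", {
  # three mean levels with ten genes each; one gene per level gets ~20x
  # inflated dispersion at its level's mean (gamma shape 0.25 vs 5 at the
  # same expectation)
  set.seed(42)
  n <- 300
  mu <- rep(c(5, 15, 40), each = 10)
  hot <- c(2, 12, 22)
  base <- t(sapply(seq_len(30), function(g) {
    shape <- if (g %in% hot) 0.25 else 5
    rgamma(n, shape = shape, rate = shape / mu[g])
  }))
  rownames(base) <- sprintf("g%02d", 1:30)
  colnames(base) <- paste0("c", 1:n)
  lg <- log_transform(base)
  picked <- select_hvgs(lg, k = 3, n_bins = 3)
  # brute-force oracle: dispersion var/mean of the de-logged values,
  # z-scored within equal-width mean bins
  x <- expm1(lg)
  mu <- rowMeans(x); v <- apply(x, 1, var)
  disp <- v / mu
  z <- ave(disp, cut(mu, 3, include.lowest = TRUE), FUN = function(d) {
    s <- sd(d); if (!is.finite(s) || s == 0) rep(0, length(d)) else
      (d - mean(d)) / s
  })
  oracle <- rownames(base)[order(-z, rownames(base))[1:3]]
  expect_setequal(picked, oracle)
  expect_setequal(picked, rownames(base)[hot])
})

test_that("HVG selection is deterministic and ignores degenerate genes", {
  em <- toy_counts(8, 30)
  lg <- log_transform(normalize_per_cell(em$values))
  lg <- rbind(lg, FLAT = rep(1, ncol(lg)))     # zero-variance gene
  expect_warning(all_ranked <- select_hvgs(lg, k = 50), "nonzero variance")
  expect_false("FLAT" %in% all_ranked)
  # invariance to cell permutation
  set.seed(3)
  perm <- sample(ncol(lg))
  expect_identical(select_hvgs(lg, k = 4), select_hvgs(lg[, perm], k = 4))
})

test_that("winsorization matches the sort-based rule", {
  v <- 1:100
  out <- clip_top_values(v, 0.05)
  expect_equal(max(out), 96)
  expect_equal(sum(out != v), 4L)              # 96 maps to itself
  expect_equal(out[96:100], rep(96, 5))
  # N = 10 -> k = 1, maximum maps to itself
  expect_equal(clip_top_values(1:10, 0.05), 1:10)
  expect_equal(clip_top_values(rep(3, 7)), rep(3, 7))
  expect_error(clip_top_values(1:5, 0), "fraction")
  expect_error(clip_top_values(1:5, 1), "fraction")
  # properties: never increases entries; zero set untouched when the top
  # set stays within the positive entries
  set.seed(5)
  for (i in 1:20) {
    x <- rpois(50, 2)
    y <- clip_top_values(x, 0.05)
    expect_true(all(y <= x))
    if (sum(x > 0) > ceiling(0.05 * 50)) {
      expect_identical(y == 0, x == 0)
    }
  }
})

test_that("neighbor ranking reproduces the covariance matrix ordering", {
  pm <- five_gene_pm()
  r <- rank_neighbors(pm, "A", n = 4, warn = FALSE)
  cv <- cov(t(pm$values))                       # direct covariance oracle
  pos <- cv["A", setdiff(colnames(cv), "A")]
  pos <- pos[pos > 0]
  oracle <- names(sort(pos, decreasing = TRUE))
  expect_identical(r$neighbors$gene_id, oracle)
  expect_equal(r$neighbors$covariance, unname(sort(pos, decreasing = TRUE)))
  # identical gene ranks first, anti-correlated gene excluded
  expect_identical(r$neighbors$gene_id[1], "B")
  expect_false("C" %in% r$neighbors$gene_id)
  expect_false("A" %in% r$neighbors$gene_id)
  # shorter list + warning when fewer positive-covariance genes than n
  expect_warning(rank_neighbors(pm, "C", n = 4), "positive-covariance")
  expect_error(rank_neighbors(pm, "ZZZ", n = 2), "unknown gene")
})

test_that("neighbor ranking is invariant to cell order", {
  pm <- five_gene_pm()
  set.seed(8)
  perm <- sample(ncol(pm$values))
  pm2 <- pm
  pm2$values <- pm$values[, perm]
  r1 <- rank_neighbors(pm, "D", n = 3, warn = FALSE)
  r2 <- rank_neighbors(pm2, "D", n = 3, warn = FALSE)
  expect_identical(r1$neighbors$gene_id, r2$neighbors$gene_id)
  expect_equal(r1$neighbors$covariance, r2$neighbors$covariance)
})

test_that("preprocessing pipeline composes and stamps a manifest", {
  em <- toy_counts(10, 40)
  expect_warning(pm <- preprocess_expression(em, hvg_count = 5), NA)
  expect_true(all(is.finite(pm$values)) && all(pm$values >= 0))
  expect_length(pm$hvg_ids, 5L)
  expect_true(all(pm$hvg_ids %in% pm$gene_ids))
  pm2 <- suppressWarnings(preprocess_expression(em, hvg_count = 5))
  expect_identical(pm$manifest, pm2$manifest)
  pm3 <- suppressWarnings(preprocess_expression(em, hvg_count = 5,
                                                clip_fraction = 0.1))
  expect_false(identical(pm$manifest, pm3$manifest))
})
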