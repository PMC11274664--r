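test_that("AUROC matches its defining examples", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUROC equals the pairwise comparison oracle to 1e-12", {
  brute <- function(s, y) {
    p <- s[y == 1]; n <- s[y == 0]
    tot <- 0
    for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(p) * length(n))
  }
  set.seed(14)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)                   # coarse scores force ties
    expect_equal(auroc(s, y), brute(s, y), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(15)
  for (i in 1:10) {
    y <- c(1, 0, rbinom(18, 1, 0.5))
    s <- rnorm(20)
    a <- auroc(s, y)
    expect_equal(auroc(exp(s), y), a)
    expect_equal(auroc(qlogis(plogis(s)), y), a, tolerance = 1e-12)
    expect_equal(auroc(rank(s, ties.method = "average"), y), a)
  }
})

test_that("ROC curves are monotone and integrate to the AUROC", {
  set.seed(16)
  y <- c(1, 0, rbinom(28, 1, 0.4))
  s <- round(rnorm(30), 1)
  rc <- roc_curve(s, y)
  expect_false(is.unsorted(rc$fpr))
  expect_false(is.unsorted(rc$tpr))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_equal(attr(rc, "auroc"), auroc(s, y), tolerance = 1e-12)
  # independent cross-check against pROC
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(s, y), ref, tolerance = 1e-10)
})

test_that("dropout injection zeroes exactly the prescribed entries", {
  set.seed(17)
  vals <- matrix(rpois(20 * 10, 30), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("c", 1:10)))
  vals[1:4, 1:10] <- 500                       # above the threshold
  em <- expression_matrix(vals)
  eligible <- sum(vals > 0 & vals < 200)
  out <- inject_dropout(em, pct = 10, count_threshold = 200, seed = 3)
  changed <- which(out$values != em$values)
  expect_length(changed, round(0.10 * eligible))
  expect_true(all(out$values[changed] == 0))
  # entries >= threshold and existing zeros never change
  expect_equal(out$values[vals >= 200], vals[vals >= 200])
  expect_true(all(out$values[vals == 0] == 0))
  # determinism
  out2 <- inject_dropout(em, pct = 10, count_threshold = 200, seed = 3)
  expect_identical(out$values, out2$values)
  # nothing eligible -> unchanged with a warning
  hi <- expression_matrix(matrix(300, 2, 2,
                                 dimnames = list(c("a", "b"), c("x", "y"))))
  expect_warning(same <- inject_dropout(hi, 50), "eligible")
  expect_identical(same$values, hi$values)
})

test_that("counting example: 40 eligible entries at 10% zeroes 4", {
  vals <- matrix(0, 8, 10, dimnames = list(sprintf("g%d", 1:8),
                                           sprintf("c%d", 1:10)))
  vals[1:4, ] <- 50                            # exactly 40 eligible
  em <- expression_matrix(vals)
  out <- inject_dropout(em, 10, 200, seed = 1)
  expect_equal(sum(out$values == 0) - sum(vals == 0), 4L)
})

test_that("repeated runs summarize per-seed AUROCs", {
  with_seed_local <- function(seed) {
    set.seed(seed)
    auroc(rnorm(20), rep(c(1, 0), 10))
  }
  rr <- repeated_runs(with_seed_local, seeds = 1:10)
  expect_equal(nrow(rr$runs), 10L)
  expect_true(all(is.finite(rr$runs$auroc)))
  rr2 <- repeated_runs(with_seed_local, seeds = 1:10)
  expect_identical(rr$runs$auroc, rr2$runs$auroc)
  expect_error(repeated_runs(with_seed_local, c(1, 1, 2)), "distinct")
})
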