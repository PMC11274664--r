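gn <- asNamespace("grnimage")

rand_stack <- function(n, seed) {
  set.seed(seed)
  s <- 2L * n + 3L
  structure(list(pair = c(tf = "a", target = "b"), n = as.integer(n),
                 images = array(runif(32 * 32 * s), c(32, 32, s)),
                 layout = NULL),
            class = "image_stack")
}

test_that("towers map one image to one embedding of the configured length", {
  set.seed(1)
  tiny <- gn$build_tower_arch(tower_config("tiny"), "t.")
  x <- array(runif(32 * 32), c(1, 32, 32, 1))
  emb <- gn$tower_forward(tiny, tiny$par, new.env(), x, train = FALSE,
                          keep = FALSE)$out
  expect_equal(dim(emb), c(32L, 1L))
  # full-size default: 512-dimensional embedding
  set.seed(2)
  full <- gn$build_tower_arch(tower_config(), "f.")
  embf <- gn$tower_forward(full, full$par, new.env(), x, train = FALSE,
                           keep = FALSE)$out
  expect_equal(dim(embf), c(512L, 1L))
})

test_that("evaluation-mode scoring is deterministic and batch invariant", {
  set.seed(3)
  model <- gn$build_classifier(1L, tower_config("mini"), head_config("tiny"))
  model$par[["h.fc3.W"]][] <- rnorm(length(model$par[["h.fc3.W"]])) * 0.3
  stacks <- lapply(1:3, function(i) rand_stack(1, 100 + i))
  s_all <- score_stacks(model, stacks)
  s_one <- vapply(stacks, function(s) score_stacks(model, list(s)),
                  numeric(1))
  expect_equal(s_all, s_one, tolerance = 1e-6)
  expect_equal(s_all, score_stacks(model, stacks))
  expect_true(all(s_all > 0 & s_all < 1))
})

test_that("a freshly built classifier scores exactly 0.5", {
  set.seed(4)
  model <- gn$build_classifier(1L, tower_config("mini"), head_config("tiny"))
  expect_equal(score_stacks(model, list(rand_stack(1, 9))), 0.5)
})

test_that("stack layout order is part of the scoring contract", {
  set.seed(5)
  model <- gn$build_classifier(2L, tower_config("mini"), head_config("tiny"))
  model$par[["h.fc3.W"]][] <- rnorm(length(model$par[["h.fc3.W"]])) * 0.3
  st <- rand_stack(2, 55)
  base <- score_stacks(model, list(st))
  swapped <- st
  swapped$images[, , c(4, 5)] <- st$images[, , c(5, 4)]  # permute x-neighbors
  expect_false(isTRUE(all.equal(base, score_stacks(model, list(swapped)))))
  wrong <- rand_stack(1, 56)
  expect_error(score_stacks(model, list(wrong)), "expects")
})

test_that("stack-size mismatch with the model's n is refused", {
  set.seed(6)
  model <- gn$build_classifier(3L, tower_config("mini"), head_config("tiny"))
  expect_error(gn$classifier_forward(model, list(rand_stack(2, 7))),
               "expects 9")
})

test_that("parameter counting is exact and monotone", {
  sp <- gn$conv_spec(c(8, 8), 3L, 5L, 3L, 1L, 1L, "c", bias = TRUE)
  par <- gn$conv_init(sp)
  expect_equal(sum(lengths(par)), 3 * 3 * 3 * 5 + 5)  # k*k*cin*cout + cout
  set.seed(7)
  m1 <- gn$build_classifier(1L, tower_config("mini"), head_config("tiny"))
  set.seed(7)
  m2 <- gn$build_classifier(1L, tower_config("mini"), head_config("tiny"))
  expect_identical(count_parameters(m1), count_parameters(m2))
  bigger <- tower_config("mini")
  bigger$embedding_dim <- 2L * bigger$embedding_dim
  set.seed(7)
  m3 <- gn$build_classifier(1L, bigger, head_config("tiny"))
  expect_gt(count_parameters(m3), count_parameters(m1))
})

test_that("identity blocks reduce to a ReLU passthrough when zeroed", {
  set.seed(8)
  cfg <- tower_config(stem_channels = 2, stage_blocks = c(2, 1, 1, 1),
                      stage_widths = c(2, 4, 8, 16), embedding_dim = 8)
  arch <- gn$build_tower_arch(cfg, "z.")
  par <- arch$par
  # second block of stage 1 is an identity block: zero its branch convs
  for (nm in grep("^z\\.s1b2\\.c[123]\\.W$", names(par), value = TRUE)) {
    par[[nm]][] <- 0
  }
  blk <- NULL
  for (u in arch$units) if (identical(u$kind, "block") &&
                            grepl("s1b2", u$conv1$wname)) blk <- u
  # block input: 8 channels (stage-1 width 2 x expansion 4), 8x8 maps
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  out <- gn$block_forward(blk, par, new.env(), x, train = TRUE,
                          keep = FALSE)$out
  expect_equal(out, x * (x > 0))
})

test_that("gradients reach every trainable tensor", {
  set.seed(9)
  model <- gn$build_classifier(1L, tower_config("mini"), head_config("tiny"))
  model$par[["h.fc3.W"]][] <- rnorm(length(model$par[["h.fc3.W"]])) * 0.3
  stacks <- lapply(1:4, function(i) rand_stack(1, 200 + i))
  fw <- gn$classifier_forward(model, stacks, train = TRUE, keep = TRUE)
  grads <- gn$classifier_backward(model, fw$caches,
                                  (fw$prob - c(1, 0, 1, 0)) / 4)
  expect_setequal(names(grads), names(model$par))
  dead <- names(grads)[!vapply(grads, function(g) any(g != 0), logical(1))]
  expect_identical(dead, character(0))
})

test_that("compiled kernels agree with finite differences", {
  set.seed(10)
  # convolution
  sp <- gn$conv_spec(c(8, 8), 3L, 5L, 3L, 2L, 1L, "cv")
  par <- gn$conv_init(sp)
  X <- array(rnorm(3 * 8 * 8 * 3), c(3, 8, 8, 3))
  fw <- gn$conv_forward(sp, par, X, keep = TRUE)
  dOut <- array(rnorm(length(fw$out)), dim(fw$out))
  bw <- gn$conv_backward(sp, par, fw$cache, dOut)
  eps <- 1e-6
  obj <- function(p, x) sum(gn$conv_forward(sp, p, x, FALSE)$out * dOut)
  for (i in sample(length(par[[1]]), 12)) {
    p2 <- par; p2[[1]][i] <- p2[[1]][i] + eps
    p3 <- par; p3[[1]][i] <- p3[[1]][i] - eps
    num <- (obj(p2, X) - obj(p3, X)) / (2 * eps)
    expect_equal(bw$grads[[sp$wname]][i], num, tolerance = 1e-5)
  }
  for (i in sample(length(X), 12)) {
    X2 <- X; X2[i] <- X[i] + eps
    X3 <- X; X3[i] <- X[i] - eps
    num <- (obj(par, X2) - obj(par, X3)) / (2 * eps)
    expect_equal(bw$dX[i], num, tolerance = 1e-5)
  }
  # pooling
  ps <- gn$pool_spec(c(8, 8), 3L, 3L, 2L, 1L, "mp")
  Xp <- array(rnorm(3 * 8 * 8 * 2), c(3, 8, 8, 2))
  fp <- gn$maxpool_forward(ps, Xp, keep = TRUE)
  dP <- array(rnorm(length(fp$out)), dim(fp$out))
  dXp <- gn$maxpool_backward(ps, fp$cache, dP)
  for (i in sample(length(Xp), 10)) {
    X2 <- Xp; X2[i] <- Xp[i] + eps
    X3 <- Xp; X3[i] <- Xp[i] - eps
    num <- (sum(gn$maxpool_forward(ps, X2, FALSE)$out * dP) -
              sum(gn$maxpool_forward(ps, X3, FALSE)$out * dP)) / (2 * eps)
    expect_equal(dXp[i], num, tolerance = 1e-5)
  }
  av <- gn$pool_spec(c(8, 8), 4L, 2L, 2L, 0L, "ap", kind = "avgpool")
  Xa <- array(rnorm(4 * 8 * 8 * 2), c(4, 8, 8, 2))
  fa <- gn$avgpool_forward(av, Xa, keep = TRUE)
  dA <- array(rnorm(length(fa$out)), dim(fa$out))
  dXa <- gn$avgpool_backward(av, fa$cache, dA)
  for (i in sample(length(Xa), 8)) {
    X2 <- Xa; X2[i] <- Xa[i] + eps
    X3 <- Xa; X3[i] <- Xa[i] - eps
    num <- (sum(gn$avgpool_forward(av, X2, FALSE)$out * dA) -
              sum(gn$avgpool_forward(av, X3, FALSE)$out * dA)) / (2 * eps)
    expect_equal(dXa[i], num, tolerance = 1e-5)
  }
})

test_that("a whole tower backpropagates exactly", {
  set.seed(11)
  cfg <- tower_config("mini")
  cfg$dropout_rate <- 0
  arch <- gn$build_tower_arch(cfg, "t.")
  par <- arch$par
  X <- array(runif(1 * 32 * 32 * 4), c(1, 32, 32, 4))
  Rw <- matrix(rnorm(cfg$embedding_dim * 4), cfg$embedding_dim, 4)
  obj <- function(p) {
    sum(gn$tower_forward(arch, p, new.env(), X, train = TRUE,
                         keep = FALSE)$out * Rw)
  }
  fw <- gn$tower_forward(arch, par, new.env(), X, train = TRUE, keep = TRUE)
  bw <- gn$tower_backward(arch, par, fw$caches, Rw)
  set.seed(12)
  eps <- 1e-6
  for (nm in sample(names(par), 15)) {
    i <- sample(length(par[[nm]]), 1)
    p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + eps
    p3 <- par; p3[[nm]][i] <- p3[[nm]][i] - eps
    num <- (obj(p2) - obj(p3)) / (2 * eps)
    ana <- bw$grads[[nm]][i]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
  }
})
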