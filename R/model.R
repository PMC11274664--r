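# The twin residual-network classifier: two structurally identical
# convolutional towers (independent weights) embed the primary image and the
# context images into fixed-length vectors; the concatenated embeddings pass
# through a dropout-regularized fully connected head ending in a sigmoid.

#' Tower configuration
#'
#' Describes one residual convolutional tower: a stem of three 3x3
#' convolutions (the first with stride 2) followed by 3x3/stride-2 max
#' pooling, four stages of bottleneck residual blocks, global average
#' pooling with dropout, and a fully connected layer to the embedding.
#' Downsampling blocks use the average-pool shortcut variant (2x2 average
#' pool followed by a 1x1 convolution). The default configuration mirrors a
#' 50-layer residual network and emits 512-dimensional embeddings; the
#' `"tiny"` preset keeps the identical structure at a fraction of the width
#' so the full pipeline trains on one CPU in minutes.
#'
#' @param preset `NULL` (defaults below), `"tiny"` (stem 8, widths
#'   8/16/32/64, 32-d embedding) or `"mini"` (stem 2, widths 2/4/8/16,
#'   8-d embedding). The presets change capacity, not structure; `"mini"`
#'   is the capacity the package's reference fixture trains in about a
#'   minute per fold on one CPU.
#' @param stem_channels Channels of the stem convolutions.
#' @param stage_blocks Integer vector of 4 block counts; default `c(3,4,6,3)`.
#' @param stage_widths Integer vector of 4 bottleneck widths; default
#'   `c(64,128,256,512)`. A block's output has `width * bottleneck_expansion`
#'   channels.
#' @param bottleneck_expansion Channel expansion of the third bottleneck
#'   convolution; default 4.
#' @param embedding_dim Length of the per-image embedding; default 512.
#' @param bottleneck `"standard"` (1x1, 3x3, 1x1) or `"conv3"` (all 3x3).
#' @param batchnorm Batch-normalize after every convolution; default `TRUE`.
#' @param dropout_rate Dropout after global average pooling; default 0.5.
#' @return A list of class `"tower_config"`.
#' @export
tower_config <- function(preset = NULL, stem_channels = 64,
                         stage_blocks = c(3L, 4L, 6L, 3L),
                         stage_widths = c(64L, 128L, 256L, 512L),
                         bottleneck_expansion = 4L, embedding_dim = 512L,
                         bottleneck = c("standard", "conv3"),
                         batchnorm = TRUE, dropout_rate = 0.5) {
  bottleneck <- match.arg(bottleneck)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny", "mini"))
    stage_blocks <- c(1L, 1L, 1L, 1L)
    if (preset == "tiny") {
      stem_channels <- 8L
      stage_widths <- c(8L, 16L, 32L, 64L)
      embedding_dim <- 32L
    } else {
      stem_channels <- 2L
      stage_widths <- c(2L, 4L, 8L, 16L)
      embedding_dim <- 8L
    }
  }
  if (length(stage_blocks) != 4L || length(stage_widths) != 4L) {
    stop_grn("stage_blocks and stage_widths must each have length 4")
  }
  check_scalar_num(embedding_dim, "embedding_dim", lower = 1)
  check_scalar_num(dropout_rate, "dropout_rate", lower = 0, upper = 1,
                   open_upper = TRUE)
  structure(list(stem_channels = as.integer(stem_channels),
                 stage_blocks = as.integer(stage_blocks),
                 stage_widths = as.integer(stage_widths),
                 bottleneck_expansion = as.integer(bottleneck_expansion),
                 embedding_dim = as.integer(embedding_dim),
                 bottleneck = bottleneck, batchnorm = batchnorm,
                 dropout_rate = dropout_rate, input_channels = 1L),
            class = "tower_config")
}

#' Head configuration
#'
#' The fully connected head applied to the concatenated embeddings: two
#' hidden layers by default, each followed by ReLU and dropout, then a
#' single sigmoid output unit.
#'
#' @param preset `NULL` (defaults below) or `"tiny"` (hidden widths 32, 8 —
#'   pairs with `tower_config("tiny")` so that the head cannot simply
#'   memorize small training sets through sheer width).
#' @param hidden_dims Widths of the hidden layers; default `c(512, 128)`.
#' @param dropout_rate Dropout after each hidden layer; default 0.5.
#' @return A list of class `"head_config"`.
#' @export
head_config <- function(preset = NULL, hidden_dims = c(512L, 128L),
                        dropout_rate = 0.5) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "tiny")
    hidden_dims <- c(32L, 8L)
  }
  check_scalar_num(dropout_rate, "dropout_rate", lower = 0, upper = 1,
                   open_upper = TRUE)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 dropout_rate = dropout_rate),
            class = "head_config")
}

# Build the ordered unit list of one tower under a parameter-name prefix.
# Returns list(units, par, hw_out, ch_out).
build_tower_arch <- function(cfg, prefix, input_hw = c(32L, 32L)) {
  units <- list()
  par <- list()
  hw <- as.integer(input_hw)
  ch <- cfg$input_channels
  nm <- function(...) paste0(prefix, paste0(...))
  add_conv <- function(cin, cout, k, s, p, name) {
    sp <- conv_spec(hw, cin, cout, k, s, p, name, bias = !cfg$batchnorm)
    ini <- conv_init(sp)
    par[names(ini)] <<- ini
    hw <<- c(sp$Ho, sp$Wo)
    sp
  }
  add_bn <- function(C, name, fused = FALSE) {
    sp <- if (fused) bnrelu_spec(C, name) else bn_spec(C, name)
    ini <- bn_init(sp)
    par[names(ini)] <<- ini
    sp
  }
  # stem: three 3x3 convolutions (first stride 2) + 3x3 stride-2 max pool
  stem <- list()
  strides <- c(2L, 1L, 1L)
  cin <- ch
  for (i in 1:3) {
    cv <- add_conv(cin, cfg$stem_channels, 3L, strides[i], 1L, nm("stem", i))
    stem[[length(stem) + 1L]] <- cv
    if (cfg$batchnorm) {
      stem[[length(stem) + 1L]] <- add_bn(cfg$stem_channels,
                                          nm("stem", i, ".bn"), fused = TRUE)
    } else {
      stem[[length(stem) + 1L]] <- list(kind = "relu")
    }
    cin <- cfg$stem_channels
  }
  mp <- pool_spec(hw, cfg$stem_channels, 3L, 2L, 1L, nm("stem.pool"))
  hw <- c(mp$Ho, mp$Wo)
  stem[[length(stem) + 1L]] <- mp
  units <- c(units, stem)
  ch <- cfg$stem_channels
  # four stages of bottleneck blocks
  for (st in 1:4) {
    w <- cfg$stage_widths[st]
    cout <- w * cfg$bottleneck_expansion
    for (b in seq_len(cfg$stage_blocks[st])) {
      stride <- if (b == 1L && st > 1L) 2L else 1L
      project <- (b == 1L)
      bname <- nm("s", st, "b", b)
      blk <- list(kind = "block", stride = stride)
      in_hw <- hw; cin_b <- ch
      ks <- if (cfg$bottleneck == "standard") c(1L, 3L, 1L) else c(3L, 3L, 3L)
      ps <- ifelse(ks == 3L, 1L, 0L)
      blk$conv1 <- add_conv(cin_b, w, ks[1L], 1L, ps[1L], paste0(bname, ".c1"))
      if (cfg$batchnorm) blk$bn1 <- add_bn(w, paste0(bname, ".c1.bn"),
                                           fused = TRUE)
      blk$conv2 <- add_conv(w, w, ks[2L], stride, ps[2L], paste0(bname, ".c2"))
      if (cfg$batchnorm) blk$bn2 <- add_bn(w, paste0(bname, ".c2.bn"),
                                           fused = TRUE)
      blk$conv3 <- add_conv(w, cout, ks[3L], 1L, ps[3L], paste0(bname, ".c3"))
      if (cfg$batchnorm) blk$bn3 <- add_bn(cout, paste0(bname, ".c3.bn"))
      if (project) {
        sc <- list()
        sc_hw <- in_hw
        if (stride == 2L) {
          sc$pool <- pool_spec(sc_hw, cin_b, 2L, 2L, 0L,
                               paste0(bname, ".sc.pool"), kind = "avgpool")
          sc_hw <- c(sc$pool$Ho, sc$pool$Wo)
        }
        sp <- conv_spec(sc_hw, cin_b, cout, 1L, 1L, 0L, paste0(bname, ".sc"),
                        bias = !cfg$batchnorm)
        ini <- conv_init(sp)
        par[names(ini)] <- ini
        sc$conv <- sp
        if (cfg$batchnorm) {
          bsp <- bn_spec(cout, paste0(bname, ".sc.bn"))
          inib <- bn_init(bsp)
          par[names(inib)] <- inib
          sc$bn <- bsp
        }
        blk$shortcut <- sc
      }
      units[[length(units) + 1L]] <- blk
      ch <- cout
    }
  }
  # global average pool -> dropout -> fully connected embedding
  units[[length(units) + 1L]] <- list(kind = "gap")
  units[[length(units) + 1L]] <- list(kind = "dropout",
                                      rate = cfg$dropout_rate)
  fc <- dense_spec(ch, cfg$embedding_dim, nm("fc"))
  inif <- dense_init(fc)
  par[names(inif)] <- inif
  units[[length(units) + 1L]] <- fc
  list(units = units, par = par, hw_out = hw, ch_out = ch)
}

block_forward <- function(blk, par, bn_env, X, train, keep) {
  caches <- list()
  run <- function(tag, res) {
    caches[[tag]] <<- res$cache
    res$out
  }
  h <- run("c1", conv_forward(blk$conv1, par, X, keep))
  h <- if (!is.null(blk$bn1)) {
    run("b1", bnrelu_forward(blk$bn1, par, bn_env, h, train, keep))
  } else run("r1", relu_forward(h, keep))
  h <- run("c2", conv_forward(blk$conv2, par, h, keep))
  h <- if (!is.null(blk$bn2)) {
    run("b2", bnrelu_forward(blk$bn2, par, bn_env, h, train, keep))
  } else run("r2", relu_forward(h, keep))
  h <- run("c3", conv_forward(blk$conv3, par, h, keep))
  if (!is.null(blk$bn3)) h <- run("b3", bn_forward(blk$bn3, par, bn_env, h, train, keep))
  if (is.null(blk$shortcut)) {
    sc <- X
  } else {
    sc <- X
    if (!is.null(blk$shortcut$pool)) {
      sc <- run("scp", avgpool_forward(blk$shortcut$pool, sc, keep))
    }
    sc <- run("scc", conv_forward(blk$shortcut$conv, par, sc, keep))
    if (!is.null(blk$shortcut$bn)) {
      sc <- run("scb", bn_forward(blk$shortcut$bn, par, bn_env, sc, train, keep))
    }
  }
  out <- nn_addrelu_fwd(h, sc)
  if (keep) caches[["rout"]] <- out
  list(out = out, cache = caches)
}

block_backward <- function(blk, par, cache, dOut, grads) {
  d <- nn_addrelu_bwd(dOut, cache$rout)
  dsc <- d
  if (!is.null(blk$shortcut)) {
    if (!is.null(blk$shortcut$bn)) {
      r <- bn_backward(blk$shortcut$bn, par, cache$scb, dsc)
      grads[names(r$grads)] <- r$grads
      dsc <- r$dX
    }
    r <- conv_backward(blk$shortcut$conv, par, cache$scc, dsc)
    grads[names(r$grads)] <- r$grads
    dsc <- r$dX
    if (!is.null(blk$shortcut$pool)) {
      dsc <- avgpool_backward(blk$shortcut$pool, cache$scp, dsc)
    }
  }
  if (!is.null(blk$bn3)) {
    r <- bn_backward(blk$bn3, par, cache$b3, d)
    grads[names(r$grads)] <- r$grads
    d <- r$dX
  }
  r <- conv_backward(blk$conv3, par, cache$c3, d)
  grads[names(r$grads)] <- r$grads
  d <- r$dX
  if (!is.null(blk$bn2)) {
    r <- bnrelu_backward(blk$bn2, par, cache$b2, d)
    grads[names(r$grads)] <- r$grads
    d <- r$dX
  } else {
    d <- relu_backward(cache$r2, d)
  }
  r <- conv_backward(blk$conv2, par, cache$c2, d)
  grads[names(r$grads)] <- r$grads
  d <- r$dX
  if (!is.null(blk$bn1)) {
    r <- bnrelu_backward(blk$bn1, par, cache$b1, d)
    grads[names(r$grads)] <- r$grads
    d <- r$dX
  } else {
    d <- relu_backward(cache$r1, d)
  }
  r <- conv_backward(blk$conv1, par, cache$c1, d)
  grads[names(r$grads)] <- r$grads
  list(dX = r$dX + dsc, grads = grads)
}

tower_forward <- function(arch, par, bn_env, X, train = FALSE, keep = TRUE) {
  caches <- vector("list", length(arch$units))
  h <- X
  for (i in seq_along(arch$units)) {
    u <- arch$units[[i]]
    res <- switch(u$kind,
      conv = conv_forward(u, par, h, keep),
      bn = bn_forward(u, par, bn_env, h, train, keep),
      bnrelu = bnrelu_forward(u, par, bn_env, h, train, keep),
      relu = relu_forward(h, keep),
      maxpool = maxpool_forward(u, h, keep),
      block = block_forward(u, par, bn_env, h, train, keep),
      gap = gap_forward(h),
      dropout = dropout_forward(h, u$rate, train, keep),
      dense = dense_forward(u, par, h, keep))
    h <- res$out
    caches[[i]] <- res$cache
  }
  list(out = h, caches = caches)
}

tower_backward <- function(arch, par, caches, dOut, grads = list()) {
  d <- dOut
  for (i in rev(seq_along(arch$units))) {
    u <- arch$units[[i]]
    if (u$kind == "conv") {
      r <- conv_backward(u, par, caches[[i]], d)
      grads[names(r$grads)] <- r$grads
      d <- r$dX
    } else if (u$kind == "bn") {
      r <- bn_backward(u, par, caches[[i]], d)
      grads[names(r$grads)] <- r$grads
      d <- r$dX
    } else if (u$kind == "bnrelu") {
      r <- bnrelu_backward(u, par, caches[[i]], d)
      grads[names(r$grads)] <- r$grads
      d <- r$dX
    } else if (u$kind == "relu") {
      d <- relu_backward(caches[[i]], d)
    } else if (u$kind == "maxpool") {
      d <- maxpool_backward(u, caches[[i]], d)
    } else if (u$kind == "block") {
      r <- block_backward(u, par, caches[[i]], d, grads)
      grads <- r$grads
      d <- r$dX
    } else if (u$kind == "gap") {
      d <- gap_backward(caches[[i]], d)
    } else if (u$kind == "dropout") {
      d <- dropout_backward(caches[[i]], d)
    } else if (u$kind == "dense") {
      r <- dense_backward(u, par, caches[[i]], d)
      grads[names(r$grads)] <- r$grads
      d <- r$dX
    }
  }
  list(dX = d, grads = grads)
}

#' Build the twin-tower classifier
#'
#' Constructs tower X (primary image), tower Y (context images, one set of
#' weights shared across all `2n + 2` of them), and the fully connected
#' head. Weights are drawn from the He-uniform fan-in distribution using the
#' current RNG state, so wrap calls in `set.seed()` for reproducibility.
#'
#' @param n Neighbor count the model accepts; stacks must have `2n + 3`
#'   images.
#' @param tower A [tower_config()].
#' @param head A [head_config()].
#' @param manifest Optional preprocessing manifest hash to pin.
#' @return Object of class `"grn_classifier"`.
#' @export
build_classifier <- function(n, tower = tower_config(), head = head_config(),
                             manifest = NULL) {
  check_scalar_num(n, "n", lower = 0)
  n <- as.integer(n)
  arch_x <- build_tower_arch(tower, "x.")
  arch_y <- build_tower_arch(tower, "y.")
  d <- tower$embedding_dim
  s <- 2L * n + 3L
  dims <- c(d * s, head$hidden_dims, 1L)
  hspecs <- list()
  hpar <- list()
  for (i in seq_len(length(dims) - 1L)) {
    sp <- dense_spec(dims[i], dims[i + 1L], paste0("h.fc", i))
    ini <- dense_init(sp)
    # zero-initialize the sigmoid output layer so training starts from
    # p = 0.5 rather than from arbitrarily confident logits
    if (i == length(dims) - 1L) ini[[sp$wname]][] <- 0
    hpar[names(ini)] <- ini
    hspecs[[i]] <- sp
  }
  structure(list(n = n, stack_size = s,
                 tower_cfg = tower, head_cfg = head,
                 arch_x = arch_x, arch_y = arch_y, head = hspecs,
                 par = c(arch_x$par, arch_y$par, hpar),
                 bn = new.env(parent = emptyenv()),
                 manifest = manifest),
            class = "grn_classifier")
}

#' @export
print.grn_classifier <- function(x, ...) {
  cat(sprintf(
    "grn_classifier: n = %d (stacks of %d images), embedding %d-d, %s parameters\n",
    x$n, x$stack_size, x$tower_cfg$embedding_dim,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A [build_classifier()] model.
#' @return Integer count of all trainable weights (convolution and dense
#'   weights and biases, batch-norm scales and shifts).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$par, length, integer(1L)))
}

# Stack list -> channel-first arrays consumed by the towers: primary
# (1,32,32,B) and context (1,32,32,B*(S-1)), context images ordered
# stack-major (all context images of stack 1, then stack 2, ...).
stacks_to_arrays <- function(stacks, stack_size) {
  B <- length(stacks)
  nb <- dim(stacks[[1L]]$images)[1L]
  prim <- array(0, c(1L, nb, nb, B))
  ctx <- array(0, c(1L, nb, nb, B * (stack_size - 1L)))
  for (b in seq_len(B)) {
    im <- stacks[[b]]$images
    if (dim(im)[3L] != stack_size) {
      stop_grn("stack %d has %d images; model expects %d",
               b, dim(im)[3L], stack_size)
    }
    prim[1L, , , b] <- im[, , 1L]
    ctx[1L, , , (b - 1L) * (stack_size - 1L) + seq_len(stack_size - 1L)] <-
      im[, , -1L]
  }
  list(primary = prim, context = ctx)
}

# Full forward pass over a batch of stacks. Returns scores in (0,1) and,
# when keep = TRUE, every cache needed for the backward pass.
classifier_forward <- function(model, stacks, train = FALSE, keep = FALSE) {
  arr <- stacks_to_arrays(stacks, model$stack_size)
  B <- length(stacks)
  S <- model$stack_size
  d <- model$tower_cfg$embedding_dim
  fx <- tower_forward(model$arch_x, model$par, model$bn, arr$primary,
                      train, keep)
  fy <- tower_forward(model$arch_y, model$par, model$bn, arr$context,
                      train, keep)
  # concatenate in stack-layout order: primary embedding first, then the
  # 2n+2 context embeddings of that stack
  Z <- rbind(fx$out, matrix(fy$out, d * (S - 1L), B))
  hcaches <- list()
  h <- Z
  for (i in seq_along(model$head)) {
    r <- dense_forward(model$head[[i]], model$par, h, keep)
    hcaches[[paste0("fc", i)]] <- r$cache
    h <- r$out
    if (i < length(model$head)) {
      r <- relu_forward(h, keep)
      hcaches[[paste0("relu", i)]] <- r$cache
      h <- r$out
      r <- dropout_forward(h, model$head_cfg$dropout_rate, train, keep)
      hcaches[[paste0("drop", i)]] <- r$cache
      h <- r$out
    }
  }
  logit <- as.vector(h)
  list(prob = stats::plogis(logit), logit = logit,
       caches = if (keep) list(x = fx$caches, y = fy$caches,
                               head = hcaches, B = B) else NULL)
}

# Backward pass from d(loss)/d(logit); returns the named gradient list.
classifier_backward <- function(model, caches, dlogit) {
  B <- caches$B
  S <- model$stack_size
  d <- model$tower_cfg$embedding_dim
  grads <- list()
  dh <- matrix(dlogit, 1L, B)
  for (i in rev(seq_along(model$head))) {
    if (i < length(model$head)) {
      dh <- dropout_backward(caches$head[[paste0("drop", i)]], dh)
      dh <- relu_backward(caches$head[[paste0("relu", i)]], dh)
    }
    r <- dense_backward(model$head[[i]], model$par,
                        caches$head[[paste0("fc", i)]], dh)
    grads[names(r$grads)] <- r$grads
    dh <- r$dX
  }
  dZx <- dh[seq_len(d), , drop = FALSE]
  dZy <- matrix(dh[-seq_len(d), , drop = FALSE], d, (S - 1L) * B)
  rx <- tower_backward(model$arch_x, model$par, caches$x, dZx, grads)
  ry <- tower_backward(model$arch_y, model$par, caches$y, dZy, rx$grads)
  ry$grads
}

#' Score image stacks with a trained classifier
#'
#' Evaluation-mode forward pass (dropout off, batch-norm running statistics):
#' deterministic and batch-size invariant.
#'
#' @param model A `"grn_classifier"`.
#' @param stacks List of [build_image_stack()] objects of matching size.
#' @return Numeric vector of scores in (0, 1).
#' @export
score_stacks <- function(model, stacks) {
  classifier_forward(model, stacks, train = FALSE, keep = FALSE)$prob
}
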