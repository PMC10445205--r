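#' Registration network configuration
#'
#' Configuration of the weakly supervised registration networks.  Three
#' variants are supported, differing only in their inputs and loss:
#' \describe{
#'   \item{`sc`}{fixed + moving scans (2 channels), NMI + smoothness.}
#'   \item{`msk`}{fixed + moving label images (2 channels), one-hot L1 +
#'     smoothness.}
#'   \item{`sc_msk`}{scans and label images (4 channels), NMI + one-hot L1 +
#'     smoothness.}
#' }
#' Label inputs are the single-channel integer-coded images (codes 0–4)
#' scaled to `[0, 1]` by division by 4; the L1 loss itself operates on
#' one-hot indicators.  Default loss weights are `alpha = 1, lambda = 4`
#' (`sc`), `alpha = 2, lambda = 4` (`msk`) and
#' `alpha = 1, beta = 2, lambda = 4` (`sc_msk`).
#'
#' The network is a 3D U-Net: four stride-2 encoder convolutions, a mirror
#' decoder with skip connections, and a flow head predicting the three
#' displacement components at half resolution, trilinearly upsampled to the
#' full grid (displacements are predicted in voxels internally and
#' converted to mm at the interface).  Grid dimensions must be divisible by
#' 16.  There is no diffeomorphic integration layer: smoothness is
#' encouraged by the diffusion regulariser only, and folding is measured
#' downstream rather than prevented.
#'
#' Training uses Adam with a stepped learning-rate schedule
#' (`lr_init * lr_gamma^floor(epoch / lr_step)`), batch size one volume
#' pair.
#'
#' @param variant `"sc"`, `"msk"` or `"sc_msk"`.
#' @param enc Encoder channel widths (4 values).
#' @param refine Channels of the pre-flow refinement convolution.
#' @param alpha,beta,lambda Loss weights (variant defaults if `NULL`).
#' @param nmi_bins NMI histogram bins.
#' @param lr_init,lr_gamma,lr_step Learning-rate schedule parameters.
#' @param epochs Training epochs.
#' @param seed Seed controlling weight init and shuffling.
#' @return An object of class `regnet_config`.
#' @export
regnet_config <- function(variant = c("sc", "msk", "sc_msk"),
                          enc = c(16, 32, 32, 32), refine = 16,
                          alpha = NULL, beta = NULL, lambda = NULL,
                          nmi_bins = 32,
                          lr_init = 5e-4, lr_gamma = 0.7, lr_step = 10,
                          epochs = 150, seed = 1) {
  variant <- match.arg(variant)
  w <- default_loss_weights(variant)
  if (!is.null(alpha)) w[["alpha"]] <- alpha
  if (!is.null(beta)) w[["beta"]] <- beta
  if (!is.null(lambda)) w[["lambda"]] <- lambda
  stopifnot(length(enc) == 4, all(enc >= 1), refine >= 1, nmi_bins >= 8)
  structure(list(variant = variant, enc = as.integer(enc),
                 refine = as.integer(refine), weights = w,
                 in_channels = if (variant == "sc_msk") 4L else 2L,
                 nmi_bins = as.integer(nmi_bins),
                 lr_init = lr_init, lr_gamma = lr_gamma,
                 lr_step = as.integer(lr_step),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "regnet_config")
}

#' Stepped learning-rate schedule
#' @param epoch 0-based epoch index.
#' @param lr_init,gamma,step Schedule parameters.
#' @return Learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, lr_init = 5e-4, gamma = 0.7, step = 10) {
  lr_init * gamma^floor(epoch / step)
}

#' Build an untrained registration network
#'
#' He-initialised convolution weights; the flow head is initialised near
#' zero so the untrained network starts from (almost) the identity
#' transform.  Deterministic given `cfg$seed`.
#'
#' @param cfg A [regnet_config()].
#' @return An object of class `regnet` (list of parameter tensors).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "regnet_config"))
  e <- cfg$enc
  shapes <- list(
    e1 = c(cfg$in_channels, e[1]), e2 = c(e[1], e[2]),
    e3 = c(e[2], e[3]), e4 = c(e[3], e[4]),
    d4 = c(e[4], e[4]), d3 = c(e[4] + e[3], e[3]),
    d2 = c(e[3] + e[2], e[2]), d1 = c(e[2] + e[1], e[1]),
    r1 = c(e[1], cfg$refine), flow = c(cfg$refine, 3L))
  params <- with_seed(cfg$seed, lapply(names(shapes), function(nm) {
    cin <- shapes[[nm]][1]; cout <- shapes[[nm]][2]
    sd <- if (nm == "flow") 1e-5 else sqrt(2 / (27 * cin))
    list(W = matrix(stats::rnorm(cout * 27 * cin, 0, sd), cout, 27 * cin),
         b = rep(0, cout), cin = cin, cout = cout)
  }))
  names(params) <- names(shapes)
  structure(list(params = params, cfg = cfg), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("<regnet> variant '%s', %d input channels, %d parameters\n",
              x$cfg$variant, x$cfg$in_channels, np))
  invisible(x)
}

check_net_grid <- function(shape) {
  if (any(shape %% 16L != 0L)) {
    pad <- (16L - shape %% 16L) %% 16L
    stop("configuration error: grid dimensions must be divisible by 16; ",
         "pad by (", paste(pad, collapse = ", "), ") voxels")
  }
}

lrelu_fw <- function(x) pmax(x, 0) + 0.2 * pmin(x, 0)
lrelu_bw <- function(x, g) g * (0.2 + 0.8 * (x > 0))

conv_fw <- function(x, p, stride) {
  cpp_conv3d_fw(x, dim(x)[1:3], p$cin, p$W, p$b, stride)
}

# Forward keeping the im2col matrix for the backward pass (training mode).
conv_fwc <- function(x, p, stride) {
  cpp_conv3d_fwc(x, dim(x)[1:3], p$cin, p$W, p$b, stride)
}

cat4 <- function(a, b) {
  d <- dim(a)[1:3]
  out <- array(0, c(d, dim(a)[4] + dim(b)[4]))
  out[, , , seq_len(dim(a)[4])] <- a
  out[, , , dim(a)[4] + seq_len(dim(b)[4])] <- b
  out
}

# Forward pass: x is (nx, ny, nz, C); returns the full-resolution flow
# (voxel units) and the cache for backprop.  In training mode the im2col
# matrices are kept so the backward pass can reuse them.
net_forward <- function(net, x, train = FALSE) {
  p <- net$params
  cache <- list(x0 = x)
  cfw <- function(x, prm, stride, nm) {
    if (!train) return(conv_fw(x, prm, stride))
    res <- conv_fwc(x, prm, stride)
    cache[[paste0("col_", nm)]] <<- res$col
    res$y
  }
  z1 <- cfw(x, p$e1, 2L, "e1");  a1 <- lrelu_fw(z1)
  z2 <- cfw(a1, p$e2, 2L, "e2"); a2 <- lrelu_fw(z2)
  z3 <- cfw(a2, p$e3, 2L, "e3"); a3 <- lrelu_fw(z3)
  z4 <- cfw(a3, p$e4, 2L, "e4"); a4 <- lrelu_fw(z4)
  zd4 <- cfw(a4, p$d4, 1L, "d4"); h4 <- lrelu_fw(zd4)
  u4 <- cpp_upsample2_fw(h4, dim(h4)[1:3], dim(h4)[4]); c3 <- cat4(u4, a3)
  zd3 <- cfw(c3, p$d3, 1L, "d3"); h3 <- lrelu_fw(zd3)
  u3 <- cpp_upsample2_fw(h3, dim(h3)[1:3], dim(h3)[4]); c2 <- cat4(u3, a2)
  zd2 <- cfw(c2, p$d2, 1L, "d2"); h2 <- lrelu_fw(zd2)
  u2 <- cpp_upsample2_fw(h2, dim(h2)[1:3], dim(h2)[4]); c1 <- cat4(u2, a1)
  zd1 <- cfw(c1, p$d1, 1L, "d1"); h1 <- lrelu_fw(zd1)
  zr <- cfw(h1, p$r1, 1L, "r1"); r <- lrelu_fw(zr)
  flow_half <- cfw(r, p$flow, 1L, "flow")
  flow_full <- 2 * cpp_upsample2_lin_fw(flow_half, dim(flow_half)[1:3], 3L)
  cache <- c(cache, list(z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3,
                         a3 = a3, z4 = z4, a4 = a4, zd4 = zd4, c3 = c3,
                         zd3 = zd3, c2 = c2, zd2 = zd2, c1 = c1, zd1 = zd1,
                         h1 = h1, zr = zr, r = r, flow_half = flow_half))
  list(flow = flow_full, cache = cache)
}

conv_bw <- function(x, p, gy, stride, need_gx = TRUE, col = NULL) {
  if (is.null(col))
    cpp_conv3d_bw(x, dim(x)[1:3], p$cin, p$W, gy, stride, need_gx)
  else
    cpp_conv3d_bwc(col, dim(x)[1:3], p$cin, p$W, gy, stride, need_gx)
}

split4 <- function(g, n_first) {
  list(a = g[, , , seq_len(n_first), drop = FALSE],
       b = g[, , , setdiff(seq_len(dim(g)[4]), seq_len(n_first)),
             drop = FALSE])
}

# Backward pass: gflow is the gradient wrt the full-resolution voxel flow.
# Returns a named list of parameter gradients matching net$params.
net_backward <- function(net, cache, gflow) {
  p <- net$params
  g <- list()
  gh <- 2 * cpp_upsample2_lin_bw(gflow, dim(gflow)[1:3], 3L)
  bw <- conv_bw(cache$r, p$flow, gh, 1L, col = cache$col_flow)
  g$flow <- bw
  gr <- lrelu_bw(cache$zr, bw$gx)
  bw <- conv_bw(cache$h1, p$r1, gr, 1L, col = cache$col_r1); g$r1 <- bw
  gh1 <- lrelu_bw(cache$zd1, bw$gx)
  bw <- conv_bw(cache$c1, p$d1, gh1, 1L, col = cache$col_d1); g$d1 <- bw
  sp <- split4(bw$gx, dim(bw$gx)[4] - dim(cache$a1)[4])
  ga1 <- sp$b
  gh2 <- cpp_upsample2_bw(sp$a, dim(sp$a)[1:3], dim(sp$a)[4])
  gh2 <- lrelu_bw(cache$zd2, gh2)
  bw <- conv_bw(cache$c2, p$d2, gh2, 1L, col = cache$col_d2); g$d2 <- bw
  sp <- split4(bw$gx, dim(bw$gx)[4] - dim(cache$a2)[4])
  ga2 <- sp$b
  gh3 <- cpp_upsample2_bw(sp$a, dim(sp$a)[1:3], dim(sp$a)[4])
  gh3 <- lrelu_bw(cache$zd3, gh3)
  bw <- conv_bw(cache$c3, p$d3, gh3, 1L, col = cache$col_d3); g$d3 <- bw
  sp <- split4(bw$gx, dim(bw$gx)[4] - dim(cache$a3)[4])
  ga3 <- sp$b
  gh4 <- cpp_upsample2_bw(sp$a, dim(sp$a)[1:3], dim(sp$a)[4])
  gh4 <- lrelu_bw(cache$zd4, gh4)
  bw <- conv_bw(cache$a4, p$d4, gh4, 1L, col = cache$col_d4); g$d4 <- bw
  ga4 <- bw$gx
  gz4 <- lrelu_bw(cache$z4, ga4)
  bw <- conv_bw(cache$a3, p$e4, gz4, 2L, col = cache$col_e4); g$e4 <- bw
  gz3 <- lrelu_bw(cache$z3, bw$gx + ga3)
  bw <- conv_bw(cache$a2, p$e3, gz3, 2L, col = cache$col_e3); g$e3 <- bw
  gz2 <- lrelu_bw(cache$z2, bw$gx + ga2)
  bw <- conv_bw(cache$a1, p$e2, gz2, 2L, col = cache$col_e2); g$e2 <- bw
  gz1 <- lrelu_bw(cache$z1, bw$gx + ga1)
  bw <- conv_bw(cache$x0, p$e1, gz1, 2L, need_gx = FALSE,
                col = cache$col_e1); g$e1 <- bw
  g
}

# Assemble the network input channels for a pair (normalised scans in
# [0,1]; label images are integer-coded, scaled by /4).
net_input <- function(cfg, fixed, moving, fixed_labels, moving_labels) {
  chans <- switch(cfg$variant,
    sc = list(fixed$data, moving$data),
    msk = list(fixed_labels$data / 4, moving_labels$data / 4),
    sc_msk = list(fixed$data, moving$data,
                  fixed_labels$data / 4, moving_labels$data / 4))
  d <- dim(chans[[1]])
  x <- array(0, c(d, length(chans)))
  for (i in seq_along(chans)) x[, , , i] <- chans[[i]]
  x
}

#' Predict a deformation field with a registration network
#'
#' Runs the network on a fixed/moving pair and returns the dense
#' displacement field on the fixed grid in mm (pull-back convention).
#' Deterministic: two calls with the same weights and inputs give identical
#' output.
#'
#' @param net A `regnet` from [build_network()] or [train_network()].
#' @param fixed,moving Normalised `image_volume`s (ignored by `msk`).
#' @param fixed_labels,moving_labels `label_volume`s (required by
#'   `msk`/`sc_msk`).
#' @return A [deformation_field()] on the fixed grid.
#' @export
predict_field <- function(net, fixed = NULL, moving = NULL,
                          fixed_labels = NULL, moving_labels = NULL) {
  cfg <- net$cfg
  if (cfg$variant %in% c("msk", "sc_msk") &&
      (is.null(fixed_labels) || is.null(moving_labels)))
    stop("input error: variant '", cfg$variant, "' needs label volumes")
  if (cfg$variant %in% c("sc", "sc_msk") &&
      (is.null(fixed) || is.null(moving)))
    stop("input error: variant '", cfg$variant, "' needs scan volumes")
  ref <- if (is.null(fixed)) fixed_labels else fixed
  check_net_grid(dim(ref$data))
  x <- net_input(cfg, fixed, moving, fixed_labels, moving_labels)
  flow <- net_forward(net, x)$flow
  u <- flow
  for (dcomp in 1:3) u[, , , dcomp] <- flow[, , , dcomp] * ref$spacing[dcomp]
  deformation_field(u, ref$spacing, ref$origin, ref$frame_id)
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    gW <- grads[[nm]]$gW; gb <- grads[[nm]]$gb
    s <- state[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * gW
    s$vW <- b2 * s$vW + (1 - b2) * gW^2
    s$mb <- b1 * s$mb + (1 - b1) * gb
    s$vb <- b2 * s$vb + (1 - b2) * gb^2
    mhW <- s$mW / (1 - b1^t); vhW <- s$vW / (1 - b2^t)
    mhb <- s$mb / (1 - b1^t); vhb <- s$vb / (1 - b2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# One training step on a pair: forward, loss and gradients, Adam update.
# Returns the updated net/state and the loss components.
train_step <- function(net, pair, state, lr, t) {
  cfg <- net$cfg
  w <- cfg$weights
  x <- net_input(cfg, pair$fixed, pair$moving, pair$fixed_labels,
                 pair$moving_labels)
  fw <- net_forward(net, x, train = TRUE)
  flow <- fw$flow
  d <- dim(flow)[1:3]
  use_nmi <- cfg$variant %in% c("sc", "sc_msk")
  use_l1 <- cfg$variant %in% c("msk", "sc_msk")
  mov <- NULL
  if (use_nmi) mov <- array(pair$moving$data, c(d, 1))
  if (use_l1) {
    oh <- one_hot_organs(pair$moving_labels$data)
    mov <- if (is.null(mov)) oh else cat4(mov, oh)
  }
  nc <- dim(mov)[4]
  warped <- cpp_warp_linear(mov, d, nc, flow)
  if (nc == 1) warped <- array(warped, c(d, 1))
  gwarped <- array(0, dim(warped))
  loss_nmi <- 0; loss_l1 <- 0
  ch <- 1
  if (use_nmi) {
    res <- cpp_nmi_soft(as.numeric(pair$fixed$data),
                        as.numeric(warped[, , , 1]), cfg$nmi_bins, TRUE)
    loss_nmi <- -res$nmi
    gwarped[, , , 1] <- -w[["alpha"]] * array(res$grad_b, d)
    ch <- 2
  }
  if (use_l1) {
    foh <- one_hot_organs(pair$fixed_labels$data)
    diffs <- warped[, , , ch:(ch + 3), drop = FALSE] - foh
    loss_l1 <- sum(abs(diffs)) / prod(d)
    wl1 <- if (cfg$variant == "msk") w[["alpha"]] else w[["beta"]]
    gwarped[, , , ch:(ch + 3)] <- wl1 * sign(diffs) / prod(d)
  }
  # diffusion regulariser in the reference normalisation (mean over
  # voxels, directions and components): smoothness_loss sums the nine
  # direction/component mean-squares, so divide by 9
  loss_sm <- smoothness_loss(flow) / 9
  gflow <- cpp_warp_linear_bw(mov, d, nc, flow, gwarped) +
    (w[["lambda"]] / 9) * smoothness_grad(flow)
  total <- if (cfg$variant == "sc") {
    w[["alpha"]] * loss_nmi + w[["lambda"]] * loss_sm
  } else if (cfg$variant == "msk") {
    w[["alpha"]] * loss_l1 + w[["lambda"]] * loss_sm
  } else {
    w[["alpha"]] * loss_nmi + w[["beta"]] * loss_l1 + w[["lambda"]] * loss_sm
  }
  if (!is.finite(total))
    stop("training diverged: non-finite loss at step ", t)
  grads <- net_backward(net, fw$cache, gflow)
  upd <- adam_step(net$params, grads, state, lr, t)
  net$params <- upd$params
  list(net = net, state = upd$state,
       loss = c(total = total, nmi = loss_nmi, l1 = loss_l1,
                smooth = loss_sm))
}

val_metric <- function(net, val) {
  cfg <- net$cfg
  if (cfg$variant == "sc") {
    # no labels at validation time for the intensity-only variant: use the
    # negated total loss so that higher is better
    losses <- vapply(val, function(p) {
      f <- predict_field(net, p$fixed, p$moving)
      as.numeric(total_loss("sc", p$fixed, p$moving, field = f,
                            weights = as.list(cfg$weights),
                            bins = cfg$nmi_bins))
    }, 0)
    -mean(losses)
  } else {
    dscs <- vapply(val, function(p) {
      f <- predict_field(net, p$fixed, p$moving, p$fixed_labels,
                         p$moving_labels)
      wl <- warp(p$moving_labels, f)
      mean(vapply(2:4, function(code)
        dsc(p$fixed_labels$data == code, wl$data == code), 0))
    }, 0)
    mean(dscs)
  }
}

#' Train a registration network
#'
#' Adam, batch size one pair, stepped learning-rate schedule, with the
#' checkpoint achieving the best validation measure retained as the final
#' model (mean organ Dice for the label-aware variants; negated validation
#' loss for `sc`).  The history records per-epoch mean losses, the learning
#' rate, and the validation measure.
#'
#' @param cfg A [regnet_config()].
#' @param pairs Training pairs: list of lists with fields `fixed`, `moving`
#'   (normalised `image_volume`s) and `fixed_labels`, `moving_labels`
#'   (`label_volume`s, required by label-aware variants).
#' @param val Validation pairs, same structure; must be non-empty.
#' @return List with `net` (best checkpoint), `history` (data frame),
#'   `best_epoch` (0-based).
#' @export
train_network <- function(cfg, pairs, val) {
  stopifnot(length(pairs) > 0, length(val) > 0)
  net <- build_network(cfg)
  ref <- if (cfg$variant == "msk") pairs[[1]]$fixed_labels else pairs[[1]]$fixed
  check_net_grid(dim(ref$data))
  state <- adam_init(net$params)
  history <- NULL
  best <- list(metric = -Inf, epoch = NA_integer_, params = net$params)
  t <- 0
  order_seed <- cfg$seed + 77L
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_schedule(epoch, cfg$lr_init, cfg$lr_gamma, cfg$lr_step)
    ord <- with_seed(order_seed + epoch, sample.int(length(pairs)))
    losses <- matrix(0, length(pairs), 4)
    for (i in seq_along(ord)) {
      t <- t + 1
      st <- train_step(net, pairs[[ord[i]]], state, lr, t)
      net <- st$net; state <- st$state
      losses[i, ] <- st$loss
    }
    vm <- val_metric(net, val)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss = mean(losses[, 1]),
      loss_nmi = mean(losses[, 2]), loss_l1 = mean(losses[, 3]),
      loss_smooth = mean(losses[, 4]), val_metric = vm))
    if (vm > best$metric)
      best <- list(metric = vm, epoch = epoch, params = net$params)
  }
  net$params <- best$params
  list(net = net, history = history, best_epoch = best$epoch)
}

#' Subject-level stratified train/validation/test splits
#'
#' Assigns subjects to 70/15/15 train/validation/test partitions for each
#' of `n_folds` independent random folds.  All images of a subject follow
#' the subject's partition; stratification (any extra columns of
#' `subjects`, e.g. an images-per-subject class and a scanner class) is
#' preserved as closely as integer counts allow via largest-remainder
#' rounding within each stratum.
#'
#' @param subjects Data frame with a column `id` and optional stratum
#'   columns.
#' @param seed Seed; the same seed reproduces the plan.
#' @param n_folds Number of folds.
#' @param fractions Partition fractions (train, validation, test).
#' @return A data frame (class `split_plan`) with columns `fold`, `id`,
#'   `partition`.
#' @export
make_splits <- function(subjects, seed = 1, n_folds = 3,
                        fractions = c(0.70, 0.15, 0.15)) {
  if (is.vector(subjects)) subjects <- data.frame(id = subjects)
  if (!"id" %in% names(subjects)) stop("subjects needs an 'id' column")
  if (nrow(subjects) < 3) stop("need at least 3 subjects")
  strata_cols <- setdiff(names(subjects), "id")
  strata <- if (length(strata_cols))
    interaction(subjects[strata_cols], drop = TRUE)
  else factor(rep(1, nrow(subjects)))
  if (any(table(strata) < 3))
    warning("some strata have fewer than 3 subjects; ",
            "stratification will be approximate")
  plan <- with_seed(seed, {
    out <- NULL
    lev <- levels(strata)
    n_by <- vapply(lev, function(s) sum(strata == s), 0L)
    # per-stratum validation/test counts by cumulative rounding, so the
    # totals hit round(fraction * n) even when strata tie at .5
    cum_cnt <- function(f) diff(c(0L, round(cumsum(n_by * f) + 1e-9)))
    n_val <- cum_cnt(fractions[2])
    n_test <- cum_cnt(fractions[3])
    for (fold in seq_len(n_folds)) {
      for (si in seq_along(lev)) {
        ids <- subjects$id[strata == lev[si]]
        ids <- ids[sample.int(length(ids))]
        n <- length(ids)
        cnt <- c(n - n_val[si] - n_test[si], n_val[si], n_test[si])
        if (any(cnt < 0)) stop("fractions incompatible with stratum sizes")
        part <- rep(c("train", "validation", "test"), times = cnt)
        out <- rbind(out, data.frame(fold = fold, id = ids,
                                     partition = part))
      }
    }
    out
  })
  class(plan) <- c("split_plan", class(plan))
  plan
}
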