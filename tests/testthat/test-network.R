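test_that("variant configurations wire the documented defaults", {
  expect_equal(regnet_config("sc")$in_channels, 2L)
  expect_equal(regnet_config("msk")$in_channels, 2L)
  expect_equal(regnet_config("sc_msk")$in_channels, 4L)
  w <- regnet_config("sc")$weights
  expect_equal(unname(w[c("alpha", "lambda")]), c(1, 4))
  w <- regnet_config("msk")$weights
  expect_equal(unname(w[c("alpha", "lambda")]), c(2, 4))
})

test_that("the learning-rate schedule steps by 0.7 every 10 epochs", {
  expect_equal(lr_schedule(0), 5e-4)
  expect_equal(lr_schedule(9), 5e-4)
  expect_equal(lr_schedule(10), 0.00035)
  expect_equal(lr_schedule(35), 5e-4 * 0.7^3)
})

test_that("an untrained network emits a finite field of the right shape", {
  cfg <- regnet_config("sc_msk", enc = c(2, 3, 3, 3), refine = 2, seed = 2)
  net <- build_network(cfg)
  g <- grid_spec(c(32, 16, 16), c(3, 3, 3), c(0, 0, 0))
  set.seed(1)
  mk <- function() image_volume(array(runif(prod(g$shape)), g$shape),
                                g$spacing, g$origin, "planning")
  mkl <- function() label_volume(array(sample(0:4, prod(g$shape), TRUE),
                                       g$shape), g$spacing, g$origin,
                                 "planning")
  fx <- mk(); mv <- mk(); fl <- mkl(); ml <- mkl()
  f1 <- predict_field(net, fx, mv, fl, ml)
  expect_equal(dim(f1$u), c(g$shape, 3))
  expect_true(all(is.finite(f1$u)))
  # deterministic in eval mode
  f2 <- predict_field(net, fx, mv, fl, ml)
  expect_identical(f1$u, f2$u)
  # same seed, fresh build: identical weights
  net2 <- build_network(cfg)
  expect_identical(net$params$e1$W, net2$params$e1$W)
})

test_that("grids not divisible by the downsampling factor are refused", {
  cfg <- regnet_config("sc", enc = c(2, 2, 2, 2), refine = 2)
  net <- build_network(cfg)
  g <- grid_spec(c(30, 16, 16), c(3, 3, 3), c(0, 0, 0))
  v <- image_volume(array(0.5, g$shape), g$spacing, g$origin)
  expect_error(predict_field(net, v, v), "divisible")
  expect_error(predict_field(net, fixed_labels = NULL), "scan")
  cfgm <- regnet_config("msk", enc = c(2, 2, 2, 2), refine = 2)
  expect_error(predict_field(build_network(cfgm), v, v), "label")
})

test_that("a few supervised steps reduce the msk training loss", {
  pair <- as_train_pair(fx_pair())
  cfg <- regnet_config("msk", enc = c(4, 6, 6, 6), refine = 4, seed = 3,
                       lr_init = 2e-3)
  net <- build_network(cfg)
  state <- dosewarp:::adam_init(net$params)
  losses <- numeric(12)
  for (t in 1:12) {
    st <- dosewarp:::train_step(net, pair, state, cfg$lr_init, t)
    net <- st$net; state <- st$state
    losses[t] <- st$loss[["total"]]
  }
  expect_lt(mean(losses[9:12]), mean(losses[1:4]))
  expect_true(all(is.finite(losses)))
})

test_that("train_network keeps the best-validation checkpoint", {
  pair <- as_train_pair(fx_pair())
  cfg <- regnet_config("msk", enc = c(2, 3, 3, 3), refine = 2, seed = 3,
                       epochs = 3, lr_init = 2e-3)
  fit <- train_network(cfg, list(pair), list(pair))
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$best_epoch,
               fit$history$epoch[which.max(fit$history$val_metric)])
  expect_equal(fit$history$lr, rep(cfg$lr_init, 3))
})

test_that("subject splits are 70/15/15, disjoint, and reproducible", {
  subjects <- data.frame(id = sprintf("s%02d", 1:20),
                         scanner = rep(c("A", "B"), each = 10))
  plan <- suppressWarnings(make_splits(subjects, seed = 4))
  sizes <- table(plan$partition[plan$fold == 1])
  expect_equal(as.integer(sizes[c("train", "validation", "test")]),
               c(14L, 3L, 3L))
  for (fold in 1:3) {
    sub <- plan[plan$fold == fold, ]
    expect_equal(sort(sub$id), sort(subjects$id))  # each subject once
  }
  plan2 <- suppressWarnings(make_splits(subjects, seed = 4))
  expect_identical(plan, plan2)
  expect_error(make_splits(data.frame(id = "a")), "3 subjects")
})

test_that("backpropagation matches finite differences through the warp", {
  d <- c(16, 16, 16)
  sp <- c(3, 3, 3)
  mk <- function(fill) {
    arr <- array(0L, d); arr[4:12, 4:12, 4:12] <- 1L
    arr[fill[1]:fill[2], 6:9, 6:9] <- 4L
    label_volume(arr, sp, c(0, 0, 0), "f")
  }
  fx <- mk(c(6, 9)); mv <- mk(c(7, 10))
  cfg <- regnet_config("msk", enc = c(2, 3, 3, 3), refine = 2, seed = 5,
                       nmi_bins = 16)
  net <- build_network(cfg)
  loss_of <- function(net) {
    x <- dosewarp:::net_input(net$cfg, NULL, NULL, fx, mv)
    flow <- dosewarp:::net_forward(net, x)$flow
    oh <- dosewarp:::one_hot_organs(mv$data)
    warped <- dosewarp:::cpp_warp_linear(oh, d, 4L, flow)
    2 * sum(abs(warped - dosewarp:::one_hot_organs(fx$data))) / prod(d) +
      (4 / 9) * smoothness_loss(flow)
  }
  x <- dosewarp:::net_input(cfg, NULL, NULL, fx, mv)
  fw <- dosewarp:::net_forward(net, x, train = TRUE)
  oh <- dosewarp:::one_hot_organs(mv$data)
  warped <- dosewarp:::cpp_warp_linear(oh, d, 4L, fw$flow)
  gw <- 2 * sign(warped - dosewarp:::one_hot_organs(fx$data)) / prod(d)
  gflow <- dosewarp:::cpp_warp_linear_bw(oh, d, 4L, fw$flow, gw) +
    (4 / 9) * dosewarp:::smoothness_grad(fw$flow)
  grads <- dosewarp:::net_backward(net, fw$cache, gflow)
  set.seed(2)
  for (nm in c("e1", "e3", "d2", "r1")) {
    W <- net$params[[nm]]$W
    for (i in sample(length(W), 2)) {
      eps <- 1e-5
      n2 <- net; n2$params[[nm]]$W[i] <- W[i] + eps
      lp <- loss_of(n2)
      n2$params[[nm]]$W[i] <- W[i] - eps
      lm <- loss_of(n2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]]$gW[i], num, tolerance = 1e-3)
    }
  }
})
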