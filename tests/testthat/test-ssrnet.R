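test_that("quartiles follow the linear-interpolation convention", {
  expect_equal(compute_quartiles(rep(120, 30)),
               c(Q1 = 120, Q2 = 120, Q3 = 120))
  x <- 1:8
  expect_equal(unname(compute_quartiles(x)),
               c(oracle_quantile(x, 0.25), oracle_quantile(x, 0.5),
                 oracle_quantile(x, 0.75)))
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(4:50, 1), 120, 5)
    q <- compute_quartiles(v)
    expect_equal(unname(q), c(oracle_quantile(v, 0.25),
                              oracle_quantile(v, 0.5),
                              oracle_quantile(v, 0.75)),
                 tolerance = 1e-12)
    expect_identical(compute_quartiles(rev(v)), q)
    expect_true(q[1] <= q[2] && q[2] <= q[3])
  }
  expect_error(compute_quartiles(c(1, 2, 3)), "insufficient data")
})

test_that("penalty loss reproduces the worked branch substitutions", {
  sp <- loss_spec(alpha = 3, Q1 = 115, Q3 = 124)
  expect_equal(penalty_loss(120, 120, sp), 0)
  expect_equal(penalty_loss(135, 135, sp), 0)      # zero error, any branch
  expect_equal(penalty_loss(125, 120, sp), 5)      # cuff inside [Q1, Q3]
  expect_equal(penalty_loss(125, 130, sp), 15)     # cuff above Q3: |-5| * 3
  expect_equal(penalty_loss(110, 114, sp), 12)     # cuff below Q1
})

test_that("boundary references take the unweighted branch", {
  sp <- loss_spec(alpha = 3, Q1 = 115, Q3 = 124)
  expect_equal(penalty_loss(117, 115, sp), 2)
  expect_equal(penalty_loss(120, 124, sp), 4)
})

test_that("alpha = 1 collapses the penalty loss to plain MAE", {
  set.seed(2)
  pred <- rnorm(50, 120, 6)
  cuff <- rnorm(50, 120, 6)
  sp <- loss_spec_from_refs(cuff, alpha = 1)
  expect_equal(penalty_loss(pred, cuff, sp), mean(abs(pred - cuff)),
               tolerance = 1e-14)
})

test_that("penalty loss dominates the plain absolute error", {
  set.seed(3)
  for (i in 1:10) {
    pred <- rnorm(30, 120, 8)
    cuff <- rnorm(30, 120, 8)
    sp <- loss_spec_from_refs(cuff, alpha = 3)
    per <- penalty_loss(pred, cuff, sp, reduce = FALSE)
    expect_true(all(per >= abs(pred - cuff) - 1e-12))
    inside <- cuff >= sp$Q1 & cuff <= sp$Q3
    expect_equal(per[inside], abs(pred - cuff)[inside])
  }
})

test_that("penalty loss slope is +/- alpha outside and +/- 1 inside the band", {
  sp <- loss_spec(alpha = 3, Q1 = 115, Q3 = 124)
  h <- 1e-6
  fd <- function(pred, cuff) {
    (penalty_loss(pred + h, cuff, sp) - penalty_loss(pred - h, cuff, sp)) /
      (2 * h)
  }
  expect_equal(fd(125, 120), 1, tolerance = 1e-6)    # inside, pred > cuff
  expect_equal(fd(115, 120), -1, tolerance = 1e-6)   # inside, pred < cuff
  expect_equal(fd(125, 130), -3, tolerance = 1e-6)   # above Q3
  expect_equal(fd(120, 110), 3, tolerance = 1e-6)    # below Q1
})

test_that("convergence detection matches a brute-force definition scan", {
  expect_equal(convergence_epoch(rep(5, 50)), 1)            # flat
  expect_true(is.na(convergence_epoch(5 * 0.5^(1:50))))     # always improving
  expect_error(convergence_epoch(c(3, 2, 1)), "undefined convergence")
  set.seed(4)
  for (i in 1:50) {
    hist <- abs(cumprod(c(10, runif(39, 0.85, 1.05)))) + 0.5
    expect_identical(convergence_epoch(hist), oracle_convergence(hist))
  }
})

test_that("default network respects the 0.04 M parameter budget", {
  net <- build_ssrnet(ssrnet_config(), seed = 0)
  expect_lte(net$n_params, 40000)
  expect_identical(ssrnet_n_params(net), net$n_params)
})

test_that("over-budget configurations are rejected with the count", {
  cfg <- ssrnet_config(max_params = 100)
  expect_error(build_ssrnet(cfg, seed = 0), "parameter budget")
  err <- tryCatch(build_ssrnet(cfg, seed = 0), error = conditionMessage)
  expect_match(err, "[0-9]+")
})

test_that("predictions are always inside the configured range", {
  cfg <- tiny_net_config(bp_range = c(80, 180))
  set.seed(5)
  for (s in 1:3) {
    net <- build_ssrnet(cfg, seed = s)
    # exaggerate the weights to push the stagewise expectation to extremes
    net$params <- lapply(net$params, function(w) w * 40)
    X <- array(runif(16 * 16 * 6), dim = c(16, 16, 6))
    y <- predict_bp(net, X)
    expect_length(y, 6)
    expect_true(all(is.finite(y)))
    expect_true(all(y >= 80 & y <= 180))
  }
})

test_that("prediction is deterministic and validates input shape", {
  net <- build_ssrnet(tiny_net_config(), seed = 1)
  X <- matrix(runif(16 * 16), 16)
  expect_identical(predict_bp(net, X), predict_bp(net, X))
  expect_error(predict_bp(net, matrix(0, 8, 8)), "input error")
})

test_that("zeroed heads give the hand-computed stagewise expectation", {
  cfg <- ssrnet_config(bp_range = c(80, 180))
  net <- build_ssrnet(cfg, seed = 2)
  for (k in 1:3) {
    for (suf in c("Wp", "bp", "Wd", "bd", "We", "be")) {
      nm <- paste0("st", k, "_", suf)
      net$params[[nm]] <- net$params[[nm]] * 0
    }
  }
  # uniform bin probabilities, zero shifts/refinements:
  # y_norm = sum_k mean(0:(s_k - 1)) / prod_{j<=k} s_j = 1/3 + 1/9 + 1/27
  expected <- 80 + 100 * (1 / 3 + 1 / 9 + 1 / 27)
  y <- predict_bp(net, array(0, dim = c(32, 32, 1)))
  expect_equal(y, expected, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_net_config(bp_range = c(80, 180))
  net <- build_ssrnet(cfg, seed = 3)
  set.seed(6)
  # jitter away from the exact ReLU kinks created by zero-initialized biases
  net$params <- lapply(net$params, function(w) w + rnorm(length(w), 0, 0.05))
  N <- 3
  X <- array(runif(16 * 16 * N), dim = c(16, 16, N))
  y <- c(100, 125, 140)
  sp <- loss_spec(alpha = 3, Q1 = 110, Q3 = 130)
  lossfun <- function(m) penalty_loss(ipgbp:::ssr_forward(m, X)$yhat, y, sp)
  fw <- ipgbp:::ssr_forward(net, X, keep_cache = TRUE)
  dyhat <- ipgbp:::penalty_weights(y, sp) * sign(fw$yhat - y) / N
  gr <- ipgbp:::ssr_backward(net, X, fw, dyhat)
  eps <- 1e-5
  for (nm in names(net$params)) {
    n_w <- length(net$params[[nm]])
    for (ii in unique(c(1, sample(n_w, min(3, n_w))))) {
      m2 <- net; m2$params[[nm]][ii] <- m2$params[[nm]][ii] + eps
      m3 <- net; m3$params[[nm]][ii] <- m3$params[[nm]][ii] - eps
      fd <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_equal(gr[[nm]][ii], fd, tolerance = 1e-3,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("input shapes must be divisible by the pooling factor", {
  expect_error(ssrnet_config(input_shape = c(30, 30)), "divisible")
})

test_that("training is deterministic and reduces the loss", {
  set.seed(7)
  N <- 24
  X <- array(runif(16 * 16 * N), dim = c(16, 16, N))
  refs <- runif(N, 110, 130)
  cfg <- tiny_net_config(bp_range = c(80, 180))
  f1 <- train_personalized(X, refs, cfg, epochs = 12, seed = 5)
  f2 <- train_personalized(X, refs, cfg, epochs = 12, seed = 5)
  expect_identical(f1$report$loss_history, f2$report$loss_history)
  expect_lte(f1$report$loss_history[12], f1$report$loss_history[1])
  expect_equal(f1$report$alpha_used, 3)
  expect_error(train_personalized(array(0, c(16, 16, 0)), numeric(0), cfg),
               "empty")
})
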