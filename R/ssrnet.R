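# Ultra-lightweight two-stream soft stagewise regression network.
#
# The network predicts a bounded continuous value (one BP target) from a
# scale-time scalogram image by soft, stagewise assignment to progressively
# refined bins. Two parallel convolutional trunks with complementary
# pooling/activation (average pooling + ReLU vs max pooling + tanh) feed a
# small fusion head at every stage; each head emits soft bin probabilities,
# a bin-width refinement and per-bin shifts. The stagewise expectation
#
#   y_norm = sum_k [ sum_i p_i^(k) (i + eta_i^(k)) ] / prod_{j<=k} s_j (1 + 0.5 delta_j)
#
# mapped onto [y_min, y_max] gives the prediction. All forward/backward
# passes are hand-written vectorized R; parameter tensors are small enough
# (tens of thousands of weights) that BLAS matrix products dominate.

#' Configuration of the stagewise regression network
#'
#' @param input_shape `c(H, W)` of the input image; both divisible by
#'   `2^n_stages`.
#' @param n_stages Number of refinement stages.
#' @param bins Bins per stage (recycled to `n_stages`).
#' @param widths Convolution channels per stage (recycled).
#' @param head_channels Channels of the per-stage 1x1 fusion head.
#' @param bp_range `c(y_min, y_max)` regression span, mmHg. Defaults cover
#'   resting adult systolic pressure with margin; use `c(40, 120)` for a
#'   diastolic model.
#' @param max_params Trainable-parameter budget (default 40 000, i.e.
#'   0.04 M).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Default training epochs.
#' @param alpha Default penalty-loss weight.
#' @return Object of class `ssrnet_config`.
#' @export
ssrnet_config <- function(input_shape = c(32, 32), n_stages = 3,
                          bins = 3, widths = 8, head_channels = 4,
                          bp_range = c(80, 180), max_params = 40000,
                          lr = 1e-3, batch_size = 16, max_epochs = 100,
                          alpha = 3) {
  bins <- rep_len(bins, n_stages)
  widths <- rep_len(widths, n_stages)
  if (any(input_shape %% 2^n_stages != 0)) {
    stop("input_shape must be divisible by 2^n_stages", call. = FALSE)
  }
  if (bp_range[1] >= bp_range[2]) stop("bp_range must be increasing", call. = FALSE)
  structure(list(input_shape = input_shape, n_stages = n_stages, bins = bins,
                 widths = widths, head_channels = head_channels,
                 bp_range = bp_range, max_params = max_params, lr = lr,
                 batch_size = batch_size, max_epochs = max_epochs,
                 alpha = alpha),
            class = "ssrnet_config")
}

# Spatial size of the trunk output at each stage, and the head pooling
# target (4x4, or smaller if the trunk map is already smaller).
ssr_stage_geometry <- function(config) {
  H <- config$input_shape[1]; W <- config$input_shape[2]
  lapply(seq_len(config$n_stages), function(k) {
    h <- H / 2^k; w <- W / 2^k
    th <- min(4, h); tw <- min(4, w)
    list(h = h, w = w, pool_h = h / th, pool_w = w / tw,
         feat_dim = th * tw * config$head_channels)
  })
}

#' Build (initialize) a stagewise regression network
#'
#' Initializes all weights (He initialization on the ReLU stream, Xavier
#' on the tanh stream and heads), deterministically for a given seed, and
#' enforces the trainable-parameter budget.
#'
#' @param config An [ssrnet_config()].
#' @param seed Integer seed for the weight draw.
#' @return Object of class `ssrnet`.
#' @examples
#' net <- build_ssrnet(ssrnet_config(), seed = 1)
#' net$n_params
#' @export
build_ssrnet <- function(config = ssrnet_config(), seed = 0) {
  stopifnot(inherits(config, "ssrnet_config"))
  geom <- ssr_stage_geometry(config)
  hc <- config$head_channels
  params <- with_local_seed(seed, {
    p <- list()
    for (stream in c("A", "B")) {
      cin <- 1L
      for (k in seq_len(config$n_stages)) {
        cout <- config$widths[k]
        fan_in <- 9 * cin
        sdv <- if (stream == "A") sqrt(2 / fan_in) else sqrt(1 / fan_in)
        p[[paste0(stream, k, "_convW")]] <-
          array(stats::rnorm(9 * cin * cout, 0, sdv), dim = c(3, 3, cin, cout))
        p[[paste0(stream, k, "_convb")]] <- numeric(cout)
        p[[paste0(stream, k, "_headW")]] <-
          matrix(stats::rnorm(cout * hc, 0, sqrt(1 / cout)), cout, hc)
        p[[paste0(stream, k, "_headb")]] <- numeric(hc)
        cin <- cout
      }
    }
    for (k in seq_len(config$n_stages)) {
      D <- geom[[k]]$feat_dim
      s <- config$bins[k]
      sdv <- sqrt(1 / D)
      p[[paste0("st", k, "_Wp")]] <- matrix(stats::rnorm(D * s, 0, sdv), D, s)
      p[[paste0("st", k, "_bp")]] <- numeric(s)
      p[[paste0("st", k, "_Wd")]] <- matrix(stats::rnorm(D, 0, 0.1 * sdv), D, 1)
      p[[paste0("st", k, "_bd")]] <- numeric(1)
      p[[paste0("st", k, "_We")]] <- matrix(stats::rnorm(D * s, 0, 0.1 * sdv), D, s)
      p[[paste0("st", k, "_be")]] <- numeric(s)
    }
    p
  })
  n_params <- sum(vapply(params, length, 0L))
  if (n_params > config$max_params) {
    stop("parameter budget exceeded: configuration instantiates ", n_params,
         " trainable parameters but max_params = ", config$max_params,
         call. = FALSE)
  }
  structure(list(config = config, params = params, n_params = n_params,
                 geom = geom, seed = as.integer(seed),
                 idx_cache = new.env(parent = emptyenv())),
            class = "ssrnet")
}

#' @export
print.ssrnet <- function(x, ...) {
  cfg <- x$config
  cat("Soft stagewise regression network\n")
  cat(sprintf("  input %dx%d, %d stages, bins %s, widths %s\n",
              cfg$input_shape[1], cfg$input_shape[2], cfg$n_stages,
              paste(cfg$bins, collapse = "/"),
              paste(cfg$widths, collapse = "/")))
  cat(sprintf("  %d trainable parameters (%.4f M, budget %.2f M)\n",
              x$n_params, x$n_params / 1e6, cfg$max_params / 1e6))
  cat(sprintf("  output range [%g, %g] mmHg\n",
              cfg$bp_range[1], cfg$bp_range[2]))
  invisible(x)
}

#' Trainable parameter count
#' @param model An [build_ssrnet()] model.
#' @return Integer parameter count.
#' @export
ssrnet_n_params <- function(model) model$n_params

## ---- low-level tensor ops (arrays are H x W x C x N) ----------------------

# Linear gather indices mapping a zero-padded (H+2, W+2, C, N) array onto
# the im2col matrix of shape (H*W*N, 9*C): row order (h, w, n), column
# order (ky, kx, cin) to match the column-major layout of the weight
# array. Cached per layer geometry in `env` (index construction costs as
# much as the gather itself).
im2col_idx <- function(H, W, C, N, env = NULL) {
  key <- paste0("i", H, "_", W, "_", C, "_", N)
  if (!is.null(env) && !is.null(env[[key]])) return(env[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  hh <- rep.int(seq_len(H), W)                 # padded row of output pixel
  ww <- rep(seq_len(W), each = H)
  base_hw <- hh + Hp * (ww - 1L)               # offset (ky=1, kx=1) position
  off_k <- as.vector(outer(0:2, Hp * (0:2), "+"))            # 9 offsets
  off_n <- Hp * Wp * C * (seq_len(N) - 1L)
  off_c <- Hp * Wp * (seq_len(C) - 1L)
  # index[(hw, n), (k, c)]
  idx <- outer(as.vector(outer(base_hw, off_n, "+")),
               as.vector(outer(off_k, off_c, "+")), "+")
  if (!is.null(env)) env[[key]] <- idx
  idx
}

conv3x3_forward <- function(x, W, b, env = NULL) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  cout <- dim(W)[4]
  xp <- array(0, dim = c(H + 2, Wd + 2, C, N))
  xp[2:(H + 1), 2:(Wd + 1), , ] <- x
  colm <- xp[im2col_idx(H, Wd, C, N, env)]
  dim(colm) <- c(H * Wd * N, 9L * C)
  y <- colm %*% matrix(W, nrow = 9 * C)
  y <- sweep(y, 2, b, "+")
  ya <- aperm(array(y, dim = c(H * Wd, N, cout)), c(1, 3, 2))
  dim(ya) <- c(H, Wd, cout, N)
  list(out = ya, cols = colm, in_dim = d)
}

conv3x3_backward <- function(dY, cache, W, env = NULL) {
  d <- cache$in_dim; H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  cout <- dim(W)[4]
  dYm <- matrix(aperm(array(dY, dim = c(H * Wd, cout, N)), c(1, 3, 2)),
                nrow = H * Wd * N)
  dWm <- crossprod(cache$cols, dYm)
  db <- colSums(dYm)
  # input gradient = convolution of dY with the spatially flipped kernel,
  # input/output channels swapped; reuses the fast gather-based forward
  Wflip <- aperm(W[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  dX <- conv3x3_forward(dY, Wflip, numeric(C), env)$out
  list(dX = dX, dW = array(dWm, dim = dim(W)), db = db)
}

avgpool_forward <- function(x, f) {
  if (f == 1L) return(list(out = x, f = 1L, in_dim = dim(x)))
  d <- dim(x); H <- d[1]; W <- d[2]
  out <- array(0, dim = c(H / f, W / f, d[3], d[4]))
  for (i in seq_len(f)) for (j in seq_len(f)) {
    out <- out + x[seq(i, H, by = f), seq(j, W, by = f), , , drop = FALSE]
  }
  list(out = out / f^2, f = f, in_dim = d)
}

avgpool_backward <- function(dY, cache) {
  f <- cache$f
  if (f == 1L) return(dY)
  d <- cache$in_dim
  dX <- array(0, dim = d)
  g <- dY / f^2
  for (i in seq_len(f)) for (j in seq_len(f)) {
    dX[seq(i, d[1], by = f), seq(j, d[2], by = f), , ] <- g
  }
  dX
}

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  ro <- seq(1, H, by = 2); re <- seq(2, H, by = 2)
  co <- seq(1, W, by = 2); ce <- seq(2, W, by = 2)
  s <- list(x[ro, co, , , drop = FALSE], x[re, co, , , drop = FALSE],
            x[ro, ce, , , drop = FALSE], x[re, ce, , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim = dim(m))
  which4 <- array(0L, dim = dim(m))
  for (i in 1:4) {
    hit <- (s[[i]] == m) & !taken   # ties -> earliest slot, deterministic
    which4[hit] <- i
    taken <- taken | hit
  }
  list(out = m, which4 = which4, in_dim = d)
}

maxpool2_backward <- function(dY, cache) {
  d <- cache$in_dim
  dX <- array(0, dim = d)
  ro <- seq(1, d[1], by = 2); re <- seq(2, d[1], by = 2)
  co <- seq(1, d[2], by = 2); ce <- seq(2, d[2], by = 2)
  idx <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (i in 1:4) {
    g <- dY * (cache$which4 == i)
    dX[idx[[i]][[1]], idx[[i]][[2]], , ] <-
      dX[idx[[i]][[1]], idx[[i]][[2]], , , drop = FALSE] + g
  }
  dX
}

conv1x1_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  y <- sweep(xm %*% W, 2, b, "+")
  ya <- aperm(array(y, dim = c(d[1], d[2], d[4], ncol(W))), c(1, 2, 4, 3))
  list(out = ya, xm = xm, in_dim = d)
}

conv1x1_backward <- function(dY, cache, W) {
  d <- cache$in_dim
  dYm <- matrix(aperm(dY, c(1, 2, 4, 3)), ncol = ncol(W))
  dW <- crossprod(cache$xm, dYm)
  db <- colSums(dYm)
  dxm <- dYm %*% t(W)
  dX <- aperm(array(dxm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dX = dX, dW = dW, db = db)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

## ---- forward / backward ----------------------------------------------------

# Forward pass. X: array H x W x N (single channel) or H x W x 1 x N.
# Returns yhat (mmHg) and, when keep_cache, everything backward needs.
ssr_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$config
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  if (length(dim(X)) == 3L) X <- array(X, dim = c(dim(X)[1], dim(X)[2], 1L, dim(X)[3]))
  d <- dim(X)
  if (d[1] != cfg$input_shape[1] || d[2] != cfg$input_shape[2]) {
    stop("input error: image shape ", d[1], "x", d[2],
         " does not match the configured input shape ",
         cfg$input_shape[1], "x", cfg$input_shape[2], call. = FALSE)
  }
  N <- d[4]
  p <- model$params
  cache <- list(N = N)
  stage_feats <- vector("list", cfg$n_stages)

  for (stream in c("A", "B")) {
    x <- X
    for (k in seq_len(cfg$n_stages)) {
      id <- paste0(stream, k)
      cv <- conv3x3_forward(x, p[[paste0(id, "_convW")]], p[[paste0(id, "_convb")]],
                            model$idx_cache)
      a <- if (stream == "A") pmax(cv$out, 0) else tanh(cv$out)
      pl <- if (stream == "A") avgpool_forward(a, 2L) else maxpool2_forward(a)
      x <- pl$out
      hd <- conv1x1_forward(x, p[[paste0(id, "_headW")]], p[[paste0(id, "_headb")]])
      ha <- if (stream == "A") pmax(hd$out, 0) else tanh(hd$out)
      hp <- avgpool_forward(ha, model$geom[[k]]$pool_h)
      u <- matrix(hp$out, nrow = model$geom[[k]]$feat_dim)  # D x N
      stage_feats[[k]][[stream]] <- u
      if (keep_cache) {
        cache[[id]] <- list(conv = cv, act = a, pool = pl, head = hd,
                            head_act = ha, head_pool = hp)
      }
    }
  }

  s_bins <- cfg$bins
  e_k <- matrix(0, cfg$n_stages, N)
  sbar <- matrix(0, cfg$n_stages, N)
  stage_cache <- vector("list", cfg$n_stages)
  for (k in seq_len(cfg$n_stages)) {
    uA <- stage_feats[[k]][["A"]]; uB <- stage_feats[[k]][["B"]]
    z <- uA * uB                                        # fusion, D x N
    logits <- crossprod(p[[paste0("st", k, "_Wp")]], z) + p[[paste0("st", k, "_bp")]]
    prob <- softmax_cols(logits)                        # bins x N
    delta <- tanh(crossprod(p[[paste0("st", k, "_Wd")]], z) + p[[paste0("st", k, "_bd")]])
    eta <- tanh(crossprod(p[[paste0("st", k, "_We")]], z) + p[[paste0("st", k, "_be")]])
    idxv <- seq_len(s_bins[k]) - 1
    e_k[k, ] <- colSums(prob * (idxv + eta))
    # bin-width refinement bounded to +/- 50% so a stage can never
    # collapse its effective bin count to zero
    sbar[k, ] <- s_bins[k] * (1 + 0.5 * as.numeric(delta))
    stage_cache[[k]] <- list(uA = uA, uB = uB, z = z, prob = prob,
                             delta = as.numeric(delta), eta = eta, idxv = idxv)
  }
  Fk <- apply(sbar, 2, cumprod)
  if (cfg$n_stages == 1L) Fk <- matrix(Fk, nrow = 1)
  ynorm <- colSums(e_k / Fk)
  yclip <- pmin(pmax(ynorm, 0), 1)
  yhat <- cfg$bp_range[1] + diff(cfg$bp_range) * yclip
  if (keep_cache) {
    cache$stage <- stage_cache
    cache$e_k <- e_k; cache$sbar <- sbar; cache$Fk <- Fk; cache$ynorm <- ynorm
  }
  list(yhat = as.numeric(yhat), cache = cache)
}

# Backward pass: gradient of the scalar loss wrt every parameter, given
# dL/dyhat (length N). Returns list of gradients matching model$params.
ssr_backward <- function(model, X, fw, dyhat) {
  cfg <- model$config
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  if (length(dim(X)) == 3L) X <- array(X, dim = c(dim(X)[1], dim(X)[2], 1L, dim(X)[3]))
  p <- model$params
  cache <- fw$cache
  N <- cache$N
  grads <- lapply(p, function(w) w * 0)

  interior <- cache$ynorm > 0 & cache$ynorm < 1
  dynorm <- dyhat * diff(cfg$bp_range) * interior

  n_st <- cfg$n_stages
  e_k <- cache$e_k; Fk <- cache$Fk; sbar <- cache$sbar
  de <- sweep(1 / Fk, 2, dynorm, "*")                    # n_st x N
  # dsbar_j = -(1/sbar_j) * sum_{k >= j} e_k / F_k * dynorm
  tail_sum <- apply((e_k / Fk)[n_st:1, , drop = FALSE], 2, cumsum)
  if (n_st == 1L) tail_sum <- matrix(tail_sum, nrow = 1)
  tail_sum <- tail_sum[n_st:1, , drop = FALSE]
  dsbar <- sweep(-tail_sum / sbar, 2, dynorm, "*")

  du <- vector("list", n_st)  # gradients wrt fused-head inputs per stream
  for (k in seq_len(n_st)) {
    st <- cache$stage[[k]]
    s_k <- cfg$bins[k]
    dprob <- sweep(st$idxv + st$eta, 2, de[k, ], "*")    # bins x N
    deta <- sweep(st$prob, 2, de[k, ], "*")
    ddelta <- dsbar[k, ] * s_k * 0.5
    # softmax backward
    dlog <- st$prob * sweep(dprob, 2, colSums(st$prob * dprob), "-")
    # tanh backward
    deta_pre <- deta * (1 - st$eta^2)
    ddelta_pre <- ddelta * (1 - st$delta^2)
    z <- st$z
    grads[[paste0("st", k, "_Wp")]] <- z %*% t(dlog)
    grads[[paste0("st", k, "_bp")]] <- rowSums(dlog)
    grads[[paste0("st", k, "_We")]] <- z %*% t(deta_pre)
    grads[[paste0("st", k, "_be")]] <- rowSums(deta_pre)
    grads[[paste0("st", k, "_Wd")]] <- z %*% matrix(ddelta_pre, ncol = 1)
    grads[[paste0("st", k, "_bd")]] <- sum(ddelta_pre)
    dz <- p[[paste0("st", k, "_Wp")]] %*% dlog +
          p[[paste0("st", k, "_We")]] %*% deta_pre +
          p[[paste0("st", k, "_Wd")]] %*% matrix(ddelta_pre, nrow = 1)
    du[[k]] <- list(A = dz * st$uB, B = dz * st$uA)
  }

  for (stream in c("A", "B")) {
    dtrunk <- NULL  # gradient flowing into the trunk output of stage k
    for (k in n_st:1) {
      id <- paste0(stream, k)
      cc <- cache[[id]]
      geomk <- model$geom[[k]]
      dU <- du[[k]][[stream]]
      dhp <- array(dU, dim = dim(cc$head_pool$out))
      dha <- avgpool_backward(dhp, cc$head_pool)
      dhd <- if (stream == "A") dha * (cc$head$out > 0)
             else dha * (1 - cc$head_act^2)
      hb <- conv1x1_backward(dhd, cc$head, p[[paste0(id, "_headW")]])
      grads[[paste0(id, "_headW")]] <- grads[[paste0(id, "_headW")]] + hb$dW
      grads[[paste0(id, "_headb")]] <- grads[[paste0(id, "_headb")]] + hb$db
      dpool_out <- hb$dX
      if (!is.null(dtrunk)) dpool_out <- dpool_out + dtrunk
      da <- if (stream == "A") avgpool_backward(dpool_out, cc$pool)
            else maxpool2_backward(dpool_out, cc$pool)
      dc <- if (stream == "A") da * (cc$conv$out > 0) else da * (1 - cc$act^2)
      cb <- conv3x3_backward(dc, cc$conv, p[[paste0(id, "_convW")]],
                             model$idx_cache)
      grads[[paste0(id, "_convW")]] <- grads[[paste0(id, "_convW")]] + cb$dW
      grads[[paste0(id, "_convb")]] <- grads[[paste0(id, "_convb")]] + cb$db
      dtrunk <- cb$dX
    }
  }
  grads
}

#' Predict blood pressure from scalogram images
#'
#' @param model A trained (or freshly built) [build_ssrnet()] model.
#' @param images `H x W` matrix (one image) or `H x W x N` array.
#' @return Numeric vector of predictions, mmHg, guaranteed inside the
#'   configured `bp_range`.
#' @export
predict_bp <- function(model, images) {
  stopifnot(inherits(model, "ssrnet"))
  ssr_forward(model, images)$yhat
}
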