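#' Network configuration
#'
#' @param depth Number of contracting stages (filters double per stage;
#'   2x2 max-pooling between stages).
#' @param baseFilters Filters at the first stage.
#' @param inSize Input side length; must be divisible by `2^depth`.
#' @return A [NetConfig-class].
#' @export
netConfig <- function(depth = 3, baseFilters = 8, inSize = 128) {
  new("NetConfig", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters), inSize = as.integer(inSize))
}

#' Filter counts per stage
#'
#' Stage `k` (1-based) of the contracting path holds
#' `baseFilters * 2^(k - 1)` filters; the spatial side there is
#' `inSize / 2^(k - 1)`.
#'
#' @param config A [NetConfig-class].
#' @return Data frame with `stage`, `filters`, `side`.
#' @export
unetStagePlan <- function(config) {
  k <- seq_len(config@depth)
  data.frame(stage = k,
             filters = config@baseFilters * 2^(k - 1),
             side = config@inSize / 2^(k - 1))
}

.heInit <- function(nr, nc, fanIn) matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)

#' Build an untrained UNet
#'
#' Contracting path: `depth` stages of two 3x3 convolutions + ReLU, with 2x2
#' max-pooling (stride 2) after each stage but the deepest; filter counts
#' double per stage. Expanding path: 2x2 up-convolutions halving the channel
#' count, concatenation with the matching contracting feature map, then two
#' 3x3 convolutions + ReLU. A final 1x1 convolution with a sigmoid yields a
#' per-pixel opacity probability. Weights are He-initialized from the current
#' RNG stream (or `seed`, when given); biases start at zero.
#'
#' @param config A [NetConfig-class].
#' @param seed Optional integer seed for initialization.
#' @return An untrained [UNetModel-class].
#' @export
buildUnet <- function(config, seed = NULL) {
  init <- function() {
    p <- list()
    d <- config@depth; f0 <- config@baseFilters
    cin <- 1L
    for (k in seq_len(d)) {
      f <- f0 * 2^(k - 1)
      p[[sprintf("enc%d.c1.w", k)]] <- .heInit(9 * cin, f, 9 * cin)
      p[[sprintf("enc%d.c1.b", k)]] <- numeric(f)
      p[[sprintf("enc%d.c2.w", k)]] <- .heInit(9 * f, f, 9 * f)
      p[[sprintf("enc%d.c2.b", k)]] <- numeric(f)
      cin <- f
    }
    if (d > 1) {
      for (k in seq(d - 1, 1)) {
        fa <- f0 * 2^k        # channels arriving from below
        f <- f0 * 2^(k - 1)   # channels at this stage
        p[[sprintf("dec%d.up.w", k)]] <- .heInit(fa, 4 * f, fa)
        p[[sprintf("dec%d.up.b", k)]] <- numeric(f)
        p[[sprintf("dec%d.c1.w", k)]] <- .heInit(9 * 2 * f, f, 9 * 2 * f)
        p[[sprintf("dec%d.c1.b", k)]] <- numeric(f)
        p[[sprintf("dec%d.c2.w", k)]] <- .heInit(9 * f, f, 9 * f)
        p[[sprintf("dec%d.c2.b", k)]] <- numeric(f)
      }
    }
    p[["head.w"]] <- matrix(rnorm(f0, sd = sqrt(1 / f0)), f0, 1)
    p[["head.b"]] <- 0
    p
  }
  params <- if (is.null(seed)) init() else withSeed(seed, init())
  new("UNetModel", params = params, netConfig = config,
      provenance = list(), lossTrace = numeric())
}

# -- cube helpers (H, W, C * B layout, image-major slices) --------------------

catChannels <- function(a, b, nimg) {
  ca <- dim(a)[3] / nimg; cb <- dim(b)[3] / nimg
  out <- array(0, c(dim(a)[1], dim(a)[2], (ca + cb) * nimg))
  for (i in seq_len(nimg)) {
    o <- (i - 1) * (ca + cb)
    out[, , (o + 1):(o + ca)] <- a[, , ((i - 1) * ca + 1):(i * ca)]
    out[, , (o + ca + 1):(o + ca + cb)] <- b[, , ((i - 1) * cb + 1):(i * cb)]
  }
  out
}

splitChannels <- function(x, ca, cb, nimg) {
  a <- array(0, c(dim(x)[1], dim(x)[2], ca * nimg))
  b <- array(0, c(dim(x)[1], dim(x)[2], cb * nimg))
  for (i in seq_len(nimg)) {
    o <- (i - 1) * (ca + cb)
    a[, , ((i - 1) * ca + 1):(i * ca)] <- x[, , (o + 1):(o + ca)]
    b[, , ((i - 1) * cb + 1):(i * cb)] <- x[, , (o + ca + 1):(o + ca + cb)]
  }
  list(a = a, b = b)
}

conv1x1Fw <- function(x, w, b, nimg) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3] / nimg
  out <- array(0, c(H, W, nimg))
  for (i in seq_len(nimg)) {
    X <- matrix(x[, , ((i - 1) * cin + 1):(i * cin)], H * W, cin)
    out[, , i] <- matrix(X %*% w + b, H, W)
  }
  out
}

conv1x1Bw <- function(x, w, gy, nimg) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3] / nimg
  gx <- array(0, dim(x))
  gw <- matrix(0, nrow(w), ncol(w))
  gb <- 0
  for (i in seq_len(nimg)) {
    X <- matrix(x[, , ((i - 1) * cin + 1):(i * cin)], H * W, cin)
    G <- matrix(gy[, , i], H * W, 1)
    gw <- gw + t(X) %*% G
    gb <- gb + sum(G)
    gx[, , ((i - 1) * cin + 1):(i * cin)] <- array(G %*% t(w), c(H, W, cin))
  }
  list(gx = gx, gw = gw, gb = gb)
}

relu <- function(z) { z[z < 0] <- 0; z }

# forward pass; x is a cube (inSize, inSize, nimg) of single-channel images
unetForward <- function(model, x, nimg, keepCache = FALSE) {
  p <- model@params
  d <- model@netConfig@depth
  cache <- list()
  cur <- x
  for (k in seq_len(d)) {
    z1 <- .conv3x3Fw(cur, p[[sprintf("enc%d.c1.w", k)]], p[[sprintf("enc%d.c1.b", k)]], nimg)
    a1 <- relu(z1)
    z2 <- .conv3x3Fw(a1, p[[sprintf("enc%d.c2.w", k)]], p[[sprintf("enc%d.c2.b", k)]], nimg)
    a2 <- relu(z2)
    cache[[sprintf("enc%d", k)]] <- list(in1 = cur, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
    if (k < d) {
      pl <- .maxpool2Fw(a2)
      cache[[sprintf("pool%d", k)]] <- pl$idx
      cur <- pl$y
    } else cur <- a2
  }
  if (d > 1) {
    for (k in seq(d - 1, 1)) {
      up <- .upconv2Fw(cur, p[[sprintf("dec%d.up.w", k)]], p[[sprintf("dec%d.up.b", k)]], nimg)
      cat <- catChannels(cache[[sprintf("enc%d", k)]]$a2, up, nimg)
      z1 <- .conv3x3Fw(cat, p[[sprintf("dec%d.c1.w", k)]], p[[sprintf("dec%d.c1.b", k)]], nimg)
      a1 <- relu(z1)
      z2 <- .conv3x3Fw(a1, p[[sprintf("dec%d.c2.w", k)]], p[[sprintf("dec%d.c2.b", k)]], nimg)
      a2 <- relu(z2)
      cache[[sprintf("dec%d", k)]] <- list(inBelow = cur, cat = cat,
                                           z1 = z1, a1 = a1, z2 = z2)
      cur <- a2
    }
  }
  cache$headIn <- cur
  logits <- conv1x1Fw(cur, p[["head.w"]], p[["head.b"]], nimg)
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits, cache = if (keepCache) cache else NULL)
}

# backward pass from dL/dlogits; returns named gradient list matching params
unetBackward <- function(model, cache, gLogits, nimg) {
  p <- model@params
  d <- model@netConfig@depth
  f0 <- model@netConfig@baseFilters
  g <- list()
  hb <- conv1x1Bw(cache$headIn, p[["head.w"]], gLogits, nimg)
  g[["head.w"]] <- hb$gw; g[["head.b"]] <- hb$gb
  gcur <- hb$gx  # gradient at the output of the last-run block
  gSkip <- vector("list", d)
  if (d > 1) {
    # decoder ran k = d-1 .. 1, so backprop visits k = 1 .. d-1
    for (k in seq(1, d - 1)) {
      dc <- cache[[sprintf("dec%d", k)]]
      gz2 <- gcur * (dc$z2 > 0)
      b2 <- .conv3x3Bw(dc$a1, p[[sprintf("dec%d.c2.w", k)]], gz2, nimg)
      g[[sprintf("dec%d.c2.w", k)]] <- b2$gw; g[[sprintf("dec%d.c2.b", k)]] <- as.numeric(b2$gb)
      gz1 <- b2$gx * (dc$z1 > 0)
      b1 <- .conv3x3Bw(dc$cat, p[[sprintf("dec%d.c1.w", k)]], gz1, nimg)
      g[[sprintf("dec%d.c1.w", k)]] <- b1$gw; g[[sprintf("dec%d.c1.b", k)]] <- as.numeric(b1$gb)
      f <- f0 * 2^(k - 1)
      sp <- splitChannels(b1$gx, f, f, nimg)
      gSkip[[k]] <- sp$a
      bu <- .upconv2Bw(dc$inBelow, p[[sprintf("dec%d.up.w", k)]], sp$b, nimg)
      g[[sprintf("dec%d.up.w", k)]] <- bu$gw; g[[sprintf("dec%d.up.b", k)]] <- as.numeric(bu$gb)
      gcur <- bu$gx  # gradient at the output of dec(k+1) (or enc d)
    }
  }
  # encoder gradients, deepest stage first
  ga2 <- gcur
  gIn <- NULL
  for (k in seq(d, 1)) {
    ec <- cache[[sprintf("enc%d", k)]]
    if (k < d)
      ga2 <- .maxpool2Bw(cache[[sprintf("pool%d", k)]], gIn) + gSkip[[k]]
    gz2 <- ga2 * (ec$z2 > 0)
    b2 <- .conv3x3Bw(ec$a1, p[[sprintf("enc%d.c2.w", k)]], gz2, nimg)
    g[[sprintf("enc%d.c2.w", k)]] <- b2$gw; g[[sprintf("enc%d.c2.b", k)]] <- as.numeric(b2$gb)
    gz1 <- b2$gx * (ec$z1 > 0)
    b1 <- .conv3x3Bw(ec$in1, p[[sprintf("enc%d.c1.w", k)]], gz1, nimg)
    g[[sprintf("enc%d.c1.w", k)]] <- b1$gw; g[[sprintf("enc%d.c1.b", k)]] <- as.numeric(b1$gb)
    gIn <- b1$gx
  }
  g
}
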