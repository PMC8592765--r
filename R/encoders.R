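# Encoder trunks. Each builder returns taps (node ids), channels and strides
# of the five-level feature pyramid.
#
# - plain: the classic double-conv/max-pool contracting path at strides
#   1,2,4,8,16 with channel doubling from baseWidth.
# - efficientnet_b0: stem + MBConv stages (expansion, depthwise conv,
#   squeeze-excitation, linear projection, residual), swish activations,
#   taps at strides 2..32 with channels 16,24,40,112,320.
# - xception: depthwise-separable trunk with residual shortcuts
#   (entry/middle/exit flow), taps at strides 2..32 with channels
#   64,128,256,728,2048.

encPlain <- function(g, x, base, act, bn) {
  chans <- as.integer(base * 2^(0:4))
  taps <- integer(5)
  n <- x
  cin <- nodeChannels(g, x)
  if (is.na(cin)) cin <- 3L
  for (i in 1:5) {
    if (i > 1) n <- gMaxPool(g, n, cin)
    n <- gConvBlock(g, n, cin, chans[i], act, bn)
    n <- gConvBlock(g, n, chans[i], chans[i], act, bn)
    taps[i] <- n
    cin <- chans[i]
  }
  list(taps = taps, channels = chans, strides = c(1L, 2L, 4L, 8L, 16L))
}

# One MBConv block: 1x1 expansion (skipped when expand == 1), depthwise
# k x k, squeeze-excitation gated on the block input channels, linear 1x1
# projection; identity shortcut when the stride is 1 and channels match.
mbconv <- function(g, x, cin, cout, expand, k, stride) {
  mid <- cin * expand
  n <- x
  if (expand != 1L) {
    n <- gConv(g, n, cin, mid, k = 1L, bias = FALSE)
    n <- gBN(g, n, mid)
    n <- gAct(g, n, mid, "swish")
  }
  n <- gDWConv(g, n, mid, k = k, stride = stride)
  n <- gBN(g, n, mid)
  n <- gAct(g, n, mid, "swish")
  se <- max(1L, cin %/% 4L)
  s <- gGAP(g, n, mid)
  s <- gConv(g, s, mid, se, k = 1L, bias = TRUE)
  s <- gAct(g, s, se, "swish")
  s <- gConv(g, s, se, mid, k = 1L, bias = TRUE)
  s <- gSigmoid(g, s, mid)
  n <- gMul(g, n, s, mid)
  n <- gConv(g, n, mid, cout, k = 1L, bias = FALSE)
  n <- gBN(g, n, cout)
  if (stride == 1L && cin == cout) n <- gAdd(g, n, x, cout)
  n
}

encEfficientNetB0 <- function(g, x) {
  n <- gConv(g, x, 3L, 32L, k = 3L, stride = 2L, bias = FALSE)
  n <- gBN(g, n, 32L)
  n <- gAct(g, n, 32L, "swish")
  # stage table: expand, kernel, out channels, repeats, first stride
  cfg <- list(c(1L, 3L, 16L, 1L, 1L), c(6L, 3L, 24L, 2L, 2L),
              c(6L, 5L, 40L, 2L, 2L), c(6L, 3L, 80L, 3L, 2L),
              c(6L, 5L, 112L, 3L, 1L), c(6L, 5L, 192L, 4L, 2L),
              c(6L, 3L, 320L, 1L, 1L))
  tapAfter <- c(1L, 2L, 3L, 5L, 7L)  # stages whose output feeds the pyramid
  taps <- integer(5)
  cin <- 32L
  for (si in seq_along(cfg)) {
    p <- cfg[[si]]
    for (r in seq_len(p[4])) {
      n <- mbconv(g, n, cin, p[3], p[1], p[2], if (r == 1L) p[5] else 1L)
      cin <- p[3]
    }
    hit <- which(tapAfter == si)
    if (length(hit)) taps[hit] <- n
  }
  list(taps = taps, channels = c(16L, 24L, 40L, 112L, 320L),
       strides = c(2L, 4L, 8L, 16L, 32L))
}

# Separable conv: depthwise 3x3 then pointwise 1x1, batch-normalised.
sepconv <- function(g, x, cin, cout) {
  n <- gDWConv(g, x, cin, k = 3L, stride = 1L)
  n <- gConv(g, n, cin, cout, k = 1L, bias = FALSE)
  gBN(g, n, cout)
}

# Downsampling residual block of the entry/exit flow.
xceptionBlock <- function(g, x, cin, cout1, cout2, preRelu = TRUE) {
  n <- x
  if (preRelu) n <- gAct(g, n, cin, "relu")
  n <- sepconv(g, n, cin, cout1)
  n <- gAct(g, n, cout1, "relu")
  n <- sepconv(g, n, cout1, cout2)
  n <- gMaxPool(g, n, cout2, k = 3L, stride = 2L, pad = 1L)
  sc <- gConv(g, x, cin, cout2, k = 1L, stride = 2L, pad = 0L, bias = FALSE)
  sc <- gBN(g, sc, cout2)
  gAdd(g, n, sc, cout2)
}

encXception <- function(g, x) {
  n <- gConv(g, x, 3L, 32L, k = 3L, stride = 2L, pad = 1L, bias = FALSE)
  n <- gBN(g, n, 32L)
  n <- gAct(g, n, 32L, "relu")
  n <- gConv(g, n, 32L, 64L, k = 3L, bias = FALSE)
  n <- gBN(g, n, 64L)
  t1 <- n <- gAct(g, n, 64L, "relu")
  t2 <- n <- xceptionBlock(g, n, 64L, 128L, 128L, preRelu = FALSE)
  t3 <- n <- xceptionBlock(g, n, 128L, 256L, 256L)
  n <- xceptionBlock(g, n, 256L, 728L, 728L)
  for (b in 1:8) {  # middle flow
    m <- n
    for (r in 1:3) {
      m <- gAct(g, m, 728L, "relu")
      m <- sepconv(g, m, 728L, 728L)
    }
    n <- gAdd(g, m, n, 728L)
  }
  t4 <- n
  n <- xceptionBlock(g, n, 728L, 728L, 1024L)
  n <- sepconv(g, n, 1024L, 1536L)
  n <- gAct(g, n, 1536L, "relu")
  n <- sepconv(g, n, 1536L, 2048L)
  t5 <- gAct(g, n, 2048L, "relu")
  list(taps = c(t1, t2, t3, t4, t5),
       channels = c(64L, 128L, 256L, 728L, 2048L),
       strides = c(2L, 4L, 8L, 16L, 32L))
}

buildEncoder <- function(g, x, spec) {
  switch(spec@encoder,
         plain = encPlain(g, x, spec@baseWidth, spec@activation,
                          spec@batchNorm),
         efficientnet_b0 = encEfficientNetB0(g, x),
         xception = encXception(g, x),
         configError(sprintf("unknown encoder '%s'", spec@encoder)))
}
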