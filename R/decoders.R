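# Decoders.
#
# - unet: the classic expanding path. Each step upsamples with a 2x2
#   transposed convolution (bias, no batch norm), concatenates the
#   same-level encoder tap, and applies two 3x3 conv blocks.
# - unetpp_dense: the nested UNet++ grid. Node X(i,j) (level i, column
#   j >= 1) receives ALL same-level predecessors X(i, 0..j-1) plus the
#   upsampled X(i+1, j-1).
# - unetpp_improved: the pruned grid: X(i,j) receives ONLY X(i, j-1) plus
#   the upsampled X(i+1, j-1); node internals are identical, so its
#   parameter count is strictly below the dense variant's.
#
# Nested-grid upsampling is bilinear x2 followed by a 3x3 conv block; when
# the encoder pyramid starts at stride 2 (backbone encoders), a final
# bilinear x2 precedes the 1x1 head so logits match the input resolution.

decUnet <- function(g, enc, spec) {
  E <- enc$channels
  w <- if (spec@encoder == "plain") E else spec@decoderWidths
  n <- enc$taps[5]
  cin <- E[5]
  for (i in 4:1) {
    n <- gConvT2(g, n, cin, w[i])
    n <- gConcat(g, c(enc$taps[i], n))
    n <- gConvBlock(g, n, E[i] + w[i], w[i], spec@activation, spec@batchNorm)
    n <- gConvBlock(g, n, w[i], w[i], spec@activation, spec@batchNorm)
    n <- gDropout(g, n, w[i], spec@dropoutRate)
    cin <- w[i]
  }
  if (enc$strides[1] == 2L) n <- gUp2(g, n, cin)
  head <- gConv(g, n, cin, spec@outChannels, k = 1L, bias = TRUE)
  head
}

decUnetpp <- function(g, enc, spec, dense) {
  E <- enc$channels
  w <- spec@decoderWidths
  act <- spec@activation
  bn <- spec@batchNorm
  # X[[i]][[j + 1]] is node X(i-1, j); column 0 holds the encoder taps.
  X <- lapply(1:5, function(i) list(enc$taps[i]))
  chanOf <- function(i, j) if (j == 0L) E[i] else w[i]
  for (j in 1:4) {
    for (i in 1:(5 - j)) {
      upc <- chanOf(i + 1L, j - 1L)
      up <- gUp2(g, X[[i + 1L]][[j]], upc)
      up <- gConvBlock(g, up, upc, w[i], act, bn)
      preds <- if (dense) seq_len(j) else j
      ins <- c(vapply(preds, function(q) X[[i]][[q]], integer(1)), up)
      n <- gConcat(g, ins)
      cat_ch <- sum(vapply(preds, function(q) chanOf(i, q - 1L),
                           numeric(1))) + w[i]
      n <- gConvBlock(g, n, cat_ch, w[i], act, bn)
      n <- gConvBlock(g, n, w[i], w[i], act, bn)
      n <- gDropout(g, n, w[i], spec@dropoutRate)
      X[[i]][[j + 1L]] <- n
    }
  }
  headAt <- function(node) {
    n <- node
    if (enc$strides[1] == 2L) n <- gUp2(g, n, w[1])
    gConv(g, n, w[1], spec@outChannels, k = 1L, bias = TRUE)
  }
  cols <- if (spec@deepSupervision) 2:5 else 5L
  vapply(cols, function(j) headAt(X[[1]][[j]]), integer(1))
}

buildDecoder <- function(g, enc, spec) {
  switch(spec@architecture,
         unet = decUnet(g, enc, spec),
         unetpp_dense = decUnetpp(g, enc, spec, dense = TRUE),
         unetpp_improved = decUnetpp(g, enc, spec, dense = FALSE),
         configError(sprintf("unknown architecture '%s'",
                             spec@architecture)))
}
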