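# Graph-construction helpers over the native engine. A graph is built as a
# flat list of layer specs plus node wiring (node 1 is the input
# placeholder); channel counts are tracked per node on the R side.

newGraph <- function() {
  g <- new.env(parent = emptyenv())
  g$layers <- list()
  g$nodeInputs <- list(integer())   # node 1 = input
  g$nodeLayer <- -1L
  g$channels <- c(NA_integer_)
  g
}

addNode <- function(g, spec, inputs, outChannels) {
  # force node-creating arguments before touching the graph state, so that
  # nested constructor calls append their nodes first
  inputs <- as.integer(inputs)
  force(spec)
  force(outChannels)
  g$layers[[length(g$layers) + 1L]] <- spec
  g$nodeLayer <- c(g$nodeLayer, length(g$layers) - 1L)
  g$nodeInputs[[length(g$nodeInputs) + 1L]] <- as.integer(inputs - 1L)
  g$channels <- c(g$channels, as.integer(outChannels))
  length(g$nodeInputs)
}

nodeChannels <- function(g, node) g$channels[node]

gConv <- function(g, x, cin, cout, k = 3L, stride = 1L,
                  pad = as.integer(k %/% 2), bias = TRUE) {
  addNode(g, list(type = "conv", cin = as.integer(cin),
                  cout = as.integer(cout), k = as.integer(k),
                  stride = as.integer(stride), pad = as.integer(pad),
                  bias = bias), x, cout)
}

gDWConv <- function(g, x, c, k = 3L, stride = 1L) {
  addNode(g, list(type = "dwconv", c = as.integer(c), k = as.integer(k),
                  stride = as.integer(stride)), x, c)
}

gConvT2 <- function(g, x, cin, cout) {
  addNode(g, list(type = "convT2", cin = as.integer(cin),
                  cout = as.integer(cout)), x, cout)
}

gBN <- function(g, x, c) {
  addNode(g, list(type = "bn", c = as.integer(c)), x, c)
}

gAct <- function(g, x, c, kind) {
  if (kind == "prelu")
    addNode(g, list(type = "prelu", c = as.integer(c)), x, c)
  else
    addNode(g, list(type = "act", kind = kind), x, c)
}

gMaxPool <- function(g, x, c, k = 2L, stride = 2L, pad = 0L) {
  addNode(g, list(type = "maxpool", k = as.integer(k),
                  stride = as.integer(stride), pad = as.integer(pad)), x, c)
}

gGAP <- function(g, x, c) addNode(g, list(type = "gap"), x, c)
gSigmoid <- function(g, x, c) addNode(g, list(type = "sigmoid"), x, c)
gMul <- function(g, x, s, c) addNode(g, list(type = "mul"), c(x, s), c)
gAdd <- function(g, a, b, c) addNode(g, list(type = "add"), c(a, b), c)
gUp2 <- function(g, x, c) addNode(g, list(type = "up2"), x, c)

gConcat <- function(g, xs) {
  ctot <- sum(g$channels[xs])
  addNode(g, list(type = "concat"), xs, ctot)
}

gDropout <- function(g, x, c, rate) {
  if (rate <= 0) return(x)
  addNode(g, list(type = "dropout", rate = rate), x, c)
}

# conv -> [BN] -> activation, the standard block of plain encoder and all
# decoders. 3x3 convolutions carry a bias even under batch norm.
gConvBlock <- function(g, x, cin, cout, act, bn, k = 3L, stride = 1L,
                       bias = TRUE) {
  n <- gConv(g, x, cin, cout, k = k, stride = stride, bias = bias)
  if (bn) n <- gBN(g, n, cout)
  gAct(g, n, cout, act)
}

buildEngine <- function(g, outputNodes) {
  eng_build(g$layers, g$nodeInputs, g$nodeLayer,
            as.integer(outputNodes - 1L))
}
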