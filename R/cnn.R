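## Compact 3D convolutional network for 5 x 5 x B sub-volume classification.
##
## Layer sequence: six 3D convolutional hidden layers with down-sampling
## along the spectral axis (two of them collapse the spatial window 5->3->1),
## one fully connected hidden layer, and a K-neuron linear output producing
## per-class scores. With the default (window 5, 100 bands, 7 classes)
## configuration the network has exactly 32,628 trainable parameters.
##
## Implementation: activations are stored as feature x batch matrices;
## convolutions are gather (im2col) + dense matrix product, with gathers
## precomputed as integer index vectors so forward is a single row-subset
## plus one BLAS product per layer, and the backward scatter is rowsum().
## Feature flattening order is fixed throughout: channel fastest, then
## spectral depth, then spatial position (window row-major).

convOutDim <- function(D, k, stride, pad, dil) {
  (D + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
}

## gather index vector for one conv layer.
## input layout: flat = ((s-1)*Din + d - 1)*Cin + c  (c fastest, d, then s)
## output columns: p = (sOut-1)*Dout + dOut (d fastest); taps within a
## position: c fastest, then kernel depth, then kernel spatial (row-major).
## Padding positions map to index CDS+1 (a zero row appended to the input).
buildGather <- function(Cin, Din, hIn, wIn, kd, stride, pad, dil, kSpat) {
  Dout <- convOutDim(Din, kd, stride, pad, dil)
  hOut <- hIn - kSpat + 1L; wOut <- wIn - kSpat + 1L
  if (Dout < 1L || hOut < 1L || wOut < 1L)
    stop(sprintf("layer arithmetic gives a nonpositive dimension (depth %d, spatial %d x %d)",
                 Dout, hOut, wOut))
  CDS <- Cin * Din * hIn * wIn
  padIdx <- CDS + 1L

  taps <- expand.grid(c = seq_len(Cin), kdd = seq_len(kd),
                      kc = seq_len(kSpat), kr = seq_len(kSpat))
  # tap order: c fastest, then kernel depth, then spatial row-major (kr outer)
  taps <- taps[order(taps$kr, taps$kc, taps$kdd, taps$c), ]
  TT <- nrow(taps)

  pos <- expand.grid(d = seq_len(Dout), oc = seq_len(wOut), or = seq_len(hOut))
  pos <- pos[order(pos$or, pos$oc, pos$d), ]   # p = (sOut-1)*Dout + d, s row-major
  P <- nrow(pos)

  gidx <- integer(P * TT)
  for (p in seq_len(P)) {
    dIn0 <- (pos$d[p] - 1L) * stride - pad
    r0 <- pos$or[p]; c0 <- pos$oc[p]
    din <- dIn0 + (taps$kdd - 1L) * dil + 1L
    rin <- r0 + taps$kr - 1L
    cin <- c0 + taps$kc - 1L
    sIn <- (rin - 1L) * wIn + cin
    flat <- ((sIn - 1L) * Din + din - 1L) * Cin + taps$c
    flat[din < 1L | din > Din] <- padIdx
    gidx[((p - 1L) * TT + 1L):(p * TT)] <- flat
  }
  list(gidx = gidx, TT = TT, P = P, Dout = Dout, hOut = hOut, wOut = wOut,
       CDS = CDS)
}

#' CNN architecture descriptor
#'
#' Builds the layer descriptors (including precomputed convolution gather
#' indices) for the compact 3D CNN. Channel widths and the hidden
#' fully-connected width are fixed so that the default configuration
#' (window 5, 100 bands, 7 classes) has exactly 32,628 trainable parameters.
#'
#' @param window odd spatial window (>= 5 for this layer sequence).
#' @param bands spectral bands.
#' @param nClasses number of output classes.
#' @return list with per-layer descriptors and a `nParams` count.
#' @export
cnnArchitecture <- function(window = 5L, bands = 100L, nClasses = 7L) {
  if (window %% 2L == 0L) stop("window must be odd")
  c1 <- 22L; c2 <- 31L; fcH <- 15L
  layers <- list()
  g1 <- buildGather(1L, bands, window, window, kd = 3L, stride = 1L, pad = 1L,
                    dil = 1L, kSpat = 3L)
  layers$conv1 <- c(g1, list(Cin = 1L, Cout = c1, type = "conv"))
  g2 <- buildGather(c1, g1$Dout, g1$hOut, g1$wOut, kd = 3L, stride = 2L,
                    pad = 1L, dil = 3L, kSpat = 1L)
  layers$down1 <- c(g2, list(Cin = c1, Cout = c1, type = "conv"))
  g3 <- buildGather(c1, g2$Dout, g2$hOut, g2$wOut, kd = 3L, stride = 1L,
                    pad = 1L, dil = 1L, kSpat = 3L)
  layers$conv2 <- c(g3, list(Cin = c1, Cout = c2, type = "conv"))
  g4 <- buildGather(c2, g3$Dout, g3$hOut, g3$wOut, kd = 3L, stride = 2L,
                    pad = 1L, dil = 3L, kSpat = 1L)
  layers$down2 <- c(g4, list(Cin = c2, Cout = c2, type = "conv"))
  g5 <- buildGather(c2, g4$Dout, g4$hOut, g4$wOut, kd = 3L, stride = 1L,
                    pad = 1L, dil = 3L, kSpat = 1L)
  layers$conv3 <- c(g5, list(Cin = c2, Cout = c2, type = "conv"))
  g6 <- buildGather(c2, g5$Dout, g5$hOut, g5$wOut, kd = 2L, stride = 2L,
                    pad = 1L, dil = 2L, kSpat = 1L)
  layers$conv4 <- c(g6, list(Cin = c2, Cout = c2, type = "conv"))
  flat <- c2 * g6$Dout * g6$hOut * g6$wOut
  layers$fc1 <- list(type = "fc", Fin = flat, Fout = fcH)
  layers$out <- list(type = "fc", Fin = fcH, Fout = as.integer(nClasses))

  nParams <- 0L
  for (l in layers) {
    nParams <- nParams + if (l$type == "conv") l$Cout * l$TT + l$Cout
                         else l$Fin * l$Fout + l$Fout
  }
  list(window = as.integer(window), bands = as.integer(bands),
       nClasses = as.integer(nClasses), layers = layers, nParams = nParams)
}

initParams <- function(arch) {
  lapply(arch$layers, function(l) {
    fanIn <- if (l$type == "conv") l$TT else l$Fin
    nOut <- if (l$type == "conv") l$Cout else l$Fout
    bound <- 1 / sqrt(fanIn)
    list(W = matrix(runif(nOut * fanIn, -bound, bound), nOut, fanIn),
         b = runif(nOut, -bound, bound))
  })
}

#' Build the (untrained) CNN classifier
#'
#' Constructs the network and initializes parameters with uniform fan-in
#' scaling, seeded for reproducibility.
#'
#' @param window,bands spatial window and band count of the expected input.
#' @param classSet class set to predict over.
#' @param normalization spectral preprocessing the model expects ("none" or
#'   "snv"); enforced at inference.
#' @param seed initialization seed.
#' @return an untrained [CNNModel-class].
#' @export
buildCNN <- function(window = 5L, bands = 100L, classSet = tissueClasses(),
                     normalization = c("none", "snv"), seed = 1L) {
  normalization <- match.arg(normalization)
  arch <- cnnArchitecture(window, bands, length(classSet@codes))
  set.seed(seed)
  params <- initParams(arch)
  new("CNNModel", classSet = classSet, normalization = normalization,
      trainSubjects = character(), arch = arch, params = params,
      trained = FALSE, log = data.frame(epoch = integer(), loss = numeric()))
}

#' Count trainable parameters
#'
#' @param model a [CNNModel-class].
#' @return integer total of all weight and bias elements.
#' @export
countParameters <- function(model) {
  sum(vapply(model@params, function(p) length(p$W) + length(p$b), numeric(1)))
}

## forward pass; X: (w*w*B) x m feature-major batch.
## returns logits (K x m) and, if keepActs, per-layer caches for backprop.
cnnForward <- function(arch, params, X, keepActs = FALSE) {
  m <- ncol(X)
  acts <- if (keepActs) vector("list", length(arch$layers))
  cur <- X
  nl <- length(arch$layers)
  for (li in seq_len(nl)) {
    l <- arch$layers[[li]]; pr <- params[[li]]
    if (l$type == "conv") {
      curPad <- rbind(cur, 0)                       # zero row for padded taps
      cols <- curPad[l$gidx, , drop = FALSE]        # (P*TT) x m
      dim(cols) <- c(l$TT, l$P * m)
      Z <- pr$W %*% cols + pr$b                     # Cout x (P*m)
      A <- Z * (Z > 0)                              # ReLU (all hidden layers)
      if (keepActs) acts[[li]] <- list(cols = cols, mask = Z > 0)
      dim(A) <- c(l$Cout * l$P, m)
      cur <- A
    } else {
      Z <- pr$W %*% cur + pr$b
      isOutput <- li == nl
      A <- if (isOutput) Z else Z * (Z > 0)
      if (keepActs) acts[[li]] <- list(input = cur, mask = if (!isOutput) Z > 0)
      cur <- A
    }
  }
  list(logits = cur, acts = acts)
}

## backward pass from dLogits (K x m); returns list of gradients per layer.
cnnBackward <- function(arch, params, X, acts, dLogits) {
  m <- ncol(dLogits)
  nl <- length(arch$layers)
  grads <- vector("list", nl)
  dCur <- dLogits
  for (li in rev(seq_len(nl))) {
    l <- arch$layers[[li]]; pr <- params[[li]]; ac <- acts[[li]]
    if (l$type == "fc") {
      if (!is.null(ac$mask)) dCur <- dCur * ac$mask
      grads[[li]] <- list(W = tcrossprod(dCur, ac$input), b = rowSums(dCur))
      dCur <- crossprod(pr$W, dCur)
    } else {
      dim(dCur) <- c(l$Cout, l$P * m)
      dCur <- dCur * ac$mask
      grads[[li]] <- list(W = tcrossprod(dCur, ac$cols), b = rowSums(dCur))
      dCols <- crossprod(pr$W, dCur)                # TT x (P*m)
      dim(dCols) <- c(l$P * l$TT, m)
      rs <- rowsum(dCols, l$gidx)                   # scatter-add by source row
      dX <- matrix(0, l$CDS + 1L, m)
      dX[as.integer(rownames(rs)), ] <- rs
      dCur <- dX[seq_len(l$CDS), , drop = FALSE]
    }
  }
  grads
}

## class-weighted softmax cross-entropy; logits K x m, y integer 1..K,
## w per-class weights. Returns loss and dLogits.
weightedCrossEntropy <- function(logits, y, w) {
  m <- ncol(logits)
  z <- logits - rep(apply(logits, 2L, max), each = nrow(logits))
  ez <- exp(z)
  p <- ez / rep(colSums(ez), each = nrow(ez))
  wi <- w[y]
  sw <- sum(wi)
  pTrue <- p[cbind(y, seq_len(m))]
  loss <- sum(wi * -log(pmax(pTrue, 1e-300))) / sw
  dLogits <- p * rep(wi / sw, each = nrow(p))
  dLogits[cbind(y, seq_len(m))] <- dLogits[cbind(y, seq_len(m))] - wi / sw
  list(loss = loss, dLogits = dLogits)
}

#' Class weights inversely proportional to training counts
#'
#' `w_c = (1/n_c)`, normalized so the weights sum to the number of classes
#' (equal counts give all weights 1). Every class must be present: a class
#' with zero training samples indicates a fold-construction bug.
#'
#' @param counts named per-class sample counts, all >= 1.
#' @return named numeric weights summing to `length(counts)`.
#' @export
computeClassWeights <- function(counts) {
  if (any(counts < 1L))
    stop(sprintf("class(es) absent from the training set: %s",
                 paste(names(counts)[counts < 1L], collapse = ", ")))
  w <- 1 / counts
  w * length(counts) / sum(w)
}

#' Train the CNN with Adam and class-weighted cross-entropy
#'
#' Minimizes the class-weighted softmax cross-entropy (weights inversely
#' proportional to per-class training counts) with Adam at the configured
#' learning rate, fixed-epoch stopping, seeded shuffling. Deterministic
#' given (model, dataset, seed).
#'
#' @param model an untrained (or partially trained) [CNNModel-class].
#' @param dataset a [SubVolumeDataset-class]; every class must be present
#'   and its normalization must match the model's.
#' @param epochs full passes over the data (0 leaves parameters unchanged).
#' @param batchSize minibatch size.
#' @param learningRate Adam step size (default 0.001).
#' @param seed shuffling seed.
#' @param engine "single" runs the compiled single-precision kernels;
#'   "reference" runs the pure-R double-precision implementation (slower;
#'   used as the independent numerical reference).
#' @return the trained model, with a (epoch, loss) log.
#' @export
trainCNN <- function(model, dataset, epochs = 12L, batchSize = 32L,
                     learningRate = 0.001, seed = 1L,
                     engine = c("single", "reference")) {
  engine <- match.arg(engine)
  stopifnot(is(model, "CNNModel"), is(dataset, "SubVolumeDataset"))
  if (dataset@normalization != model@normalization)
    stop(sprintf("model expects '%s' normalization but dataset carries '%s'",
                 model@normalization, dataset@normalization))
  cls <- model@classSet
  counts <- classCounts(dataset)
  if (any(counts == 0L))
    stop(sprintf("class(es) missing from the training dataset: %s",
                 paste(names(counts)[counts == 0L], collapse = ", ")))
  w <- computeClassWeights(counts)[cls@labels]
  arch <- model@arch
  params <- model@params
  n <- nrow(dataset@volumes)
  y <- match(dataset@labels, cls@codes)

  if (engine == "single" && epochs > 0L) {
    set.seed(seed)
    perms <- vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
    res <- .cnnTrainCpp(arch$layers, params, t(dataset@volumes), y,
                        unname(w), perms, as.integer(batchSize), learningRate)
    model@params <- lapply(res$params, function(p) list(W = p$W, b = as.numeric(p$b)))
    names(model@params) <- names(params)
    model@trained <- TRUE
    model@trainSubjects <- unique(dataset@subjects)
    model@log <- rbind(model@log,
                       data.frame(epoch = seq_len(epochs), loss = res$losses))
    return(model)
  }

  # Adam state
  mState <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  vState <- mState
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  logRows <- list()

  set.seed(seed)
  Xall <- t(dataset@volumes)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      X <- Xall[, idx, drop = FALSE]
      fw <- cnnForward(arch, params, X, keepActs = TRUE)
      ce <- weightedCrossEntropy(fw$logits, y[idx], w)
      grads <- cnnBackward(arch, params, X, fw$acts, ce$dLogits)
      step <- step + 1L
      c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
      for (li in seq_along(params)) {
        for (nm in c("W", "b")) {
          g <- grads[[li]][[nm]]
          mState[[li]][[nm]] <- beta1 * mState[[li]][[nm]] + (1 - beta1) * g
          vState[[li]][[nm]] <- beta2 * vState[[li]][[nm]] + (1 - beta2) * g^2
          params[[li]][[nm]] <- params[[li]][[nm]] -
            learningRate * (mState[[li]][[nm]] / c1) /
            (sqrt(vState[[li]][[nm]] / c2) + eps)
        }
      }
      epochLoss <- epochLoss + ce$loss; nb <- nb + 1L
    }
    logRows[[ep]] <- data.frame(epoch = ep, loss = epochLoss / max(nb, 1L))
  }
  model@params <- params
  model@trained <- epochs > 0L || model@trained
  model@trainSubjects <- unique(dataset@subjects)
  model@log <- rbind(model@log, if (length(logRows)) do.call(rbind, logRows))
  model
}
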