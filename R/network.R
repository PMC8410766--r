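#' Network architecture configuration
#'
#' The default architecture stacks seven length-preserving 1D
#' convolutional layers with ReLU activations and one depth-preserving
#' max-pooling layer (window 3, stride 1), followed by two parallel 1x1
#' convolutional heads: a 3-channel softmax classifier (Class 0
#' non-peak, Class 1 dominated/shoulder peak, Class 2 main peak) and an
#' 8-channel linear regressor (two 4-channel blocks -- Class 2 first,
#' then Class 1 -- each holding sub-pixel offset, amplitude, FWHH and
#' Lorentzian fraction).  With the defaults the network has exactly 8037
#' trainable parameters and a receptive field of 33 points.
#'
#' @param depths Integer vector of hidden-layer depths.
#' @param kernels Integer vector of kernel sizes (odd).
#' @param kinds Character vector over \code{"conv"} / \code{"maxpool"}.
#' @param classifierChannels,regressorChannels Head widths.
#' @return Validated architecture list.
#' @export
archConfig <- function(depths = c(40, 20, 10, 20, 10, 30, 18, 18),
                       kernels = c(11, 1, 11, 1, 1, 11, 1, 3),
                       kinds = c(rep("conv", 7), "maxpool"),
                       classifierChannels = 3L,
                       regressorChannels = 8L) {
  if (length(depths) != length(kernels) || length(depths) != length(kinds))
    stop("depths, kernels and kinds must have the same length")
  if (any(kernels %% 2 == 0)) stop("kernels must be odd (same padding)")
  if (!all(kinds %in% c("conv", "maxpool"))) stop("unknown layer kind")
  din <- 1L
  for (l in seq_along(depths)) {
    if (kinds[l] == "maxpool" && depths[l] != din)
      stop("maxpool layer ", l, " must preserve depth (", din, ")")
    din <- depths[l]
  }
  list(depths = as.integer(depths), kernels = as.integer(kernels),
       kinds = kinds, classifierChannels = as.integer(classifierChannels),
       regressorChannels = as.integer(regressorChannels))
}

#' Receptive field of an architecture (points)
#'
#' @param arch An \code{\link{archConfig}}.
#' @return Integer receptive field (33 for the default).
#' @export
receptiveField <- function(arch = archConfig()) {
  as.integer(1 + sum(arch$kernels - 1))
}

#' Build a network with seeded random initialization
#'
#' Convolution weights use He-normal initialization (suited to ReLU);
#' the linear heads use Glorot-normal.  Biases start at zero.  Two
#' builds with the same seed are identical.
#'
#' @param arch An \code{\link{archConfig}}.
#' @param seed Integer seed.
#' @return An untrained \linkS4class{PickerNet}.
#' @export
buildNetwork <- function(arch = archConfig(), seed = 1L) {
  layers <- .withSeed(seed, {
    din <- 1L
    out <- vector("list", length(arch$depths))
    for (l in seq_along(arch$depths)) {
      k <- arch$kernels[l]
      if (arch$kinds[l] == "maxpool") {
        out[[l]] <- list(kind = "maxpool", kernel = k)
      } else {
        dout <- arch$depths[l]
        fanIn <- din * k
        out[[l]] <- list(kind = "conv", kernel = k,
                         W = matrix(rnorm(dout * fanIn, sd = sqrt(2 / fanIn)),
                                    dout, fanIn),
                         b = numeric(dout))
      }
      din <- arch$depths[l]
    }
    mkHead <- function(chan) {
      list(W = matrix(rnorm(chan * din, sd = sqrt(2 / (din + chan))), chan, din),
           b = numeric(chan))
    }
    list(layers = out, classifier = mkHead(arch$classifierChannels),
         regressor = mkHead(arch$regressorChannels))
  })
  new("PickerNet", arch = arch, weights = layers, trained = FALSE,
      provenance = list(initSeed = as.integer(seed)))
}

#' Count trainable parameters
#'
#' Sum over convolutional layers (including both heads) of
#' \code{in_depth * kernel * out_depth + out_depth}; pooling layers
#' contribute nothing.
#'
#' @param object A \linkS4class{PickerNet} or an \code{\link{archConfig}}.
#' @return Integer parameter count (8037 for the default architecture).
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "PickerNet", function(object) {
  countParameters(object@arch)
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "list", function(object) {
  arch <- object
  din <- 1L
  total <- 0L
  for (l in seq_along(arch$depths)) {
    if (arch$kinds[l] == "conv")
      total <- total + din * arch$kernels[l] * arch$depths[l] + arch$depths[l]
    din <- arch$depths[l]
  }
  total <- total + din * arch$classifierChannels + arch$classifierChannels
  total <- total + din * arch$regressorChannels + arch$regressorChannels
  as.integer(total)
})

#' Forward pass
#'
#' Runs the point-wise prediction over one spectrum (numeric vector) or a
#' batch (matrix, one spectrum per column; all the same length).  Class
#' scores are softmax-normalized per point.
#'
#' @param net A \linkS4class{PickerNet}.
#' @param x Numeric vector of length N >= the receptive field, or an
#'   N x B matrix.
#' @return For a vector input, a list with \code{classScores} (N x 3) and
#'   \code{regressor} (N x 8); for a matrix input the fields gain a third
#'   batch dimension.
#' @export
forwardNetwork <- function(net, x) {
  stopifnot(is(net, "PickerNet"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  if (nrow(X) < receptiveField(net@arch))
    stop("input length ", nrow(X), " is below the receptive field (",
         receptiveField(net@arch), " points)")
  out <- .cnn_forward(net@weights, X)
  if (vec)
    list(classScores = out$classScores[, , 1], regressor = out$regressor[, , 1])
  else out
}

#' Loss weights
#'
#' Class weights for the per-point cross-entropy (Class 0, 1, 2) and
#' per-class weights for the masked regressor MSE (Class 2 block, Class 1
#' block).  Labeled peak points are a small minority of each spectrum, so
#' the peak classes are up-weighted; the Class-1 weight trades shoulder
#' sensitivity against false shoulder calls on peak tails, and 1.5 is the
#' package's validated operating point.
#'
#' @param classWeights Numeric length-3 (Class 0, 1, 2).
#' @param regressorWeights Numeric length-2 (Class 2, Class 1).
#' @return Validated list.
#' @export
lossWeights <- function(classWeights = c(1, 1.5, 2),
                        regressorWeights = c(1, 1)) {
  stopifnot(length(classWeights) == 3, length(regressorWeights) == 2,
            all(classWeights >= 0), all(regressorWeights >= 0),
            any(classWeights > 0) || any(regressorWeights > 0))
  list(classWeights = as.numeric(classWeights),
       regressorWeights = as.numeric(regressorWeights))
}

#' Training configuration
#'
#' Full-batch Adam.  The documented full-scale settings are a learning
#' rate of 0.002 for 4000 epochs on the whole corpus in a single batch;
#' test and example workflows use fewer epochs and smaller corpora.
#'
#' @param learningRate Adam learning rate.
#' @param epochs Number of full-batch epochs.
#' @param retain "best" keeps the weights with the lowest validation
#'   loss; "final" keeps the last epoch's weights.
#' @param seed Unused by the (deterministic) optimizer itself; recorded
#'   in provenance.
#' @return Validated list.
#' @export
trainConfig <- function(learningRate = 0.002, epochs = 4000,
                        retain = c("best", "final"), seed = 1L) {
  stopifnot(learningRate > 0, epochs >= 1)
  list(learningRate = learningRate, epochs = as.integer(epochs),
       retain = match.arg(retain), seed = as.integer(seed))
}

#' Weighted classifier/regressor loss of a network output
#'
#' Reference implementation of the training target: the class-weighted
#' cross-entropy averaged over all points plus the per-class masked
#' regressor MSE (each class's block compared only at points labeled with
#' that class, averaged per element, then weighted).  Regressor errors
#' are divided by fixed per-channel characteristic scales (1 point
#' offset, 1 normalized-intensity unit, 10 points of FWHH, 1 unit of
#' Lorentzian fraction) so that no channel dominates the training
#' gradient.  The compiled trainer computes the identical quantity.
#'
#' @param output A \code{\link{forwardNetwork}} result (vector input
#'   form).
#' @param example A training example (see \code{\link{assembleExample}}).
#' @param weights A \code{\link{lossWeights}}.
#' @return Scalar loss with components as attributes.
#' @export
networkLoss <- function(output, example, weights = lossWeights()) {
  p <- output$classScores
  n <- nrow(p)
  stopifnot(length(example$classLabels) == n)
  y <- example$classLabels
  w <- weights$classWeights[y + 1]
  ce <- mean(w * -log(pmax(p[cbind(seq_len(n), y + 1)], 1e-12)))
  mse <- 0
  chScale <- c(1, 1, 10, 1)   # offset, amplitude, fwhh (points), eta
  for (cls in c(2L, 1L)) {
    idx <- which(y == cls & example$mask)
    if (!length(idx)) next
    block <- if (cls == 2L) 1:4 else 5:8
    err <- sweep(output$regressor[idx, block, drop = FALSE] -
                   example$targets[idx, , drop = FALSE], 2, chScale, "/")
    mse <- mse + weights$regressorWeights[3 - cls] * sum(err^2) / (4 * length(idx))
  }
  structure(ce + mse, ce = ce, mse = mse)
}

#' Train a network on a corpus
#'
#' Full-batch Adam for \code{config$epochs} epochs; the training and
#' validation losses are recorded each epoch and the weights achieving
#' the lowest validation loss are retained by default.  Training is
#' deterministic given the initial weights and corpus.
#'
#' @param net An (untrained) \linkS4class{PickerNet}.
#' @param corpus A \linkS4class{TrainingCorpus}.
#' @param config A \code{\link{trainConfig}}.
#' @param weights A \code{\link{lossWeights}}.
#' @return The trained \linkS4class{PickerNet} with history.
#' @export
trainNetwork <- function(net, corpus, config = trainConfig(),
                         weights = lossWeights()) {
  stopifnot(is(net, "PickerNet"), is(corpus, "TrainingCorpus"),
            length(corpus@train) > 0)
  tr <- .corpusTensors(corpus@train)
  if (length(corpus@val)) {
    va <- .corpusTensors(corpus@val)
  } else {
    va <- list(X = matrix(0, 0, 0), labels = matrix(0L, 0, 0),
               targets = matrix(0, 0, 0))
  }
  res <- .cnn_train(net@weights, tr$X, tr$labels, tr$targets,
                    va$X, va$labels, va$targets,
                    list(learningRate = config$learningRate,
                         epochs = config$epochs,
                         classWeights = weights$classWeights,
                         regressorWeights = weights$regressorWeights))
  keep <- if (config$retain == "best") res$best else res$final
  new("PickerNet", arch = net@arch, weights = keep, trained = TRUE,
      history = list(trainLoss = res$trainLoss, valLoss = res$valLoss,
                     trainCE = res$trainCE, trainMSE = res$trainMSE,
                     bestEpoch = res$bestEpoch, retained = config$retain),
      provenance = c(net@provenance,
                     list(corpusSeed = corpus@config$seed,
                          trainConfig = config,
                          lossWeights = weights)))
}

#' Save / load network weights
#'
#' Single-file checkpoint embedding the architecture manifest and
#' provenance; loading verifies the manifest and reproduces forward
#' outputs bitwise.
#'
#' @param net A \linkS4class{PickerNet}.
#' @param path Checkpoint path.
#' @param arch Optional expected architecture; load fails on mismatch.
#' @return \code{loadWeights} returns the \linkS4class{PickerNet}.
#' @export
saveWeights <- function(net, path) {
  stopifnot(is(net, "PickerNet"))
  saveRDS(list(format = "VoigtPicker-weights-1", arch = net@arch,
               weights = net@weights, trained = net@trained,
               history = net@history, provenance = net@provenance),
          path, version = 2)
  invisible(path)
}

#' @rdname saveWeights
#' @export
loadWeights <- function(path, arch = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "VoigtPicker-weights-1"))
    stop("not a VoigtPicker weight checkpoint: ", path)
  manifest <- do.call(archConfig, obj$arch[c("depths", "kernels", "kinds",
                                             "classifierChannels",
                                             "regressorChannels")])
  if (!is.null(arch) && !identical(manifest, do.call(archConfig, arch[
        c("depths", "kernels", "kinds", "classifierChannels",
          "regressorChannels")])))
    stop("architecture manifest in ", path, " does not match the requested ",
         "architecture")
  din <- 1L
  for (l in seq_along(manifest$depths)) {
    if (manifest$kinds[l] == "conv") {
      W <- obj$weights$layers[[l]]$W
      if (!all(dim(W) == c(manifest$depths[l], din * manifest$kernels[l])))
        stop("weight shapes do not match the architecture manifest in ", path)
    }
    din <- manifest$depths[l]
  }
  new("PickerNet", arch = manifest, weights = obj$weights,
      trained = isTRUE(obj$trained), history = obj$history,
      provenance = obj$provenance)
}
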