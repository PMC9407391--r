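# Trainable segmentation backend. The pre-installed stack has no deep
# learning runtime, so instead of a full encoder-decoder this is a compact
# convolutional segmenter: a fixed multiscale convolutional feature encoder
# (Gaussian pyramid + Hessian ridge channels, the same receptive-field idea
# as the first U-Net level) feeding a small trained nonlinear per-pixel
# decoder (one-hidden-layer network). It is trained by minibatch SGD on a
# pixelwise cross-entropy plus soft-Dice overlap loss, is deterministic
# given a seed, trains in seconds on CPU, and emits calibrated probability
# maps; `segment_classical` remains the training-free alternative.

model_feature_sigmas <- function() {
  list(gauss = c(1, 2, 4), ridge = c(1, 1.5, 2.5), bg = 16)
}

# per-pixel feature stack: n_px x n_feat matrix, robust-normalized intensity;
# `idx` restricts the stack to a subset of (linear) pixel indices
model_features <- function(image, sigmas = model_feature_sigmas(), idx = NULL) {
  med <- stats::median(image)
  # contrast scale: brightest structure quantile, floored at 6x the robust
  # noise level so near-empty fields do not amplify background noise
  sc <- max(stats::quantile(image, 0.9995, names = FALSE) - med,
            6 * stats::mad(image), 1e-6)
  z <- (image - med) / sc
  fz <- stats::fft(z)
  feats <- list(z)
  for (s in sigmas$gauss) feats[[length(feats) + 1]] <- gauss_blur(z, s, fm = fz)
  for (s in sigmas$ridge) {
    h <- hessian_responses(z, s, fm = fz)
    tr <- h$xx + h$yy
    disc <- sqrt(pmax((h$xx - h$yy)^2 + 4 * h$xy^2, 0))
    lam_min <- (tr - disc) / 2
    lam_max <- (tr + disc) / 2
    # ridge channel: elongated bright structures; blob channel: compact
    # bright spots (debris) where both eigenvalues are negative
    feats[[length(feats) + 1]] <- pmax(-lam_min, 0)
    feats[[length(feats) + 1]] <- pmax(-lam_max, 0)
  }
  # fine-scale local contrast: positive on ridge crests, negative in the
  # blur halo flanking a branch; lets the decoder emit tight centerline masks
  feats[[length(feats) + 1]] <- z - gauss_blur(z, 1.5, fm = fz)
  feats[[length(feats) + 1]] <- pmax(z - gauss_blur(z, sigmas$bg, fm = fz), 0)
  if (is.null(idx)) return(do.call(cbind, lapply(feats, as.vector)))
  do.call(cbind, lapply(feats, function(f) f[idx]))
}

# conservative candidate mask: smoothed normalized intensity above a small
# threshold; everything else is scored 0 without running the decoder
model_candidates <- function(image) {
  med <- stats::median(image)
  sc <- max(stats::quantile(image, 0.9995, names = FALSE) - med,
            6 * stats::mad(image), 1e-6)
  z1 <- gauss_blur((image - med) / sc, 1)
  which(z1 > 0.05)
}

#' Training configuration for the trainable segmenter
#' @param hidden hidden-layer width.
#' @param epochs passes over the sampled pixel set; 0 returns the untrained
#'   (near-uniform) model.
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param batch minibatch size (pixels).
#' @param pixels_per_image pixels sampled per training image.
#' @param dice_weight weight of the soft-Dice overlap term added to the
#'   pixelwise cross-entropy.
#' @param l2 weight decay.
#' @param seed integer seed controlling init and sampling.
#' @export
segmenter_config <- function(hidden = 12L, epochs = 8L, lr = 0.5,
                             momentum = 0.9, batch = 512L,
                             pixels_per_image = 4000L, dice_weight = 0.5,
                             l2 = 1e-5, seed = 1L) {
  list(hidden = as.integer(hidden), epochs = as.integer(epochs), lr = lr,
       momentum = momentum, batch = as.integer(batch),
       pixels_per_image = as.integer(pixels_per_image),
       dice_weight = dice_weight, l2 = l2, seed = as.integer(seed))
}

#' Train the dendrite segmentation model
#'
#' @param manifest a manifest data.frame or path to a manifest CSV produced
#'   by [make_dataset()] (unpaired: columns `image`, `mask`); at least 8
#'   image/mask pairs are required.
#' @param cfg a [segmenter_config()].
#' @param data_dir directory holding the files named in the manifest
#'   (defaults to the manifest's directory when a path is given).
#' @return object of class `dendrite_segmenter` with the trained weights,
#'   the config, and the final epoch loss.
#' @export
train_segmenter <- function(manifest, cfg = segmenter_config(),
                            data_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(data_dir)) data_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  if (!all(c("image", "mask") %in% names(manifest))) {
    stop("manifest must have 'image' and 'mask' columns (unpaired dataset)")
  }
  if (nrow(manifest) < 8) stop("need at least 8 image/mask pairs to train")
  pathify <- function(f) if (is.null(data_dir)) f else file.path(data_dir, f)

  with_seed(cfg$seed, {
    X <- NULL; Y <- NULL
    for (i in seq_len(nrow(manifest))) {
      img <- read_pgm(pathify(manifest$image[i]))
      msk <- read_pgm(pathify(manifest$mask[i])) > 0.5
      fg <- which(msk); bg <- which(!msk)
      n_fg <- min(length(fg), cfg$pixels_per_image %/% 3)
      # negatives: ring around the structure, the brightest background
      # pixels (hard negatives: debris and noise spikes), and uniform draws
      near <- which(dilate_disk(msk, 4) & !msk)
      n_near <- min(length(near), cfg$pixels_per_image %/% 4)
      n_hard <- cfg$pixels_per_image %/% 8
      far <- setdiff(bg, near)
      hard <- far[order(img[far], decreasing = TRUE)[seq_len(min(n_hard * 4, length(far)))]]
      n_far <- cfg$pixels_per_image - n_fg - n_near - n_hard
      sel <- c(sample(fg, n_fg), sample(near, n_near),
               sample(hard, min(n_hard, length(hard))),
               sample(far, min(length(far), n_far)))
      X <- rbind(X, model_features(img, idx = sel))
      Y <- c(Y, as.numeric(msk[sel]))
    }
    nf <- ncol(X)
    h <- cfg$hidden
    W1 <- matrix(stats::runif(nf * h, -0.3, 0.3), nf, h)
    b1 <- numeric(h)
    W2 <- matrix(stats::runif(h, -0.3, 0.3), h, 1)
    b2 <- 0
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
    n <- nrow(X)
    final_loss <- NA_real_
    if (cfg$epochs > 0) {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample(n)
        ep_loss <- 0; nb <- 0
        for (start in seq(1, n, by = cfg$batch)) {
          ii <- ord[start:min(n, start + cfg$batch - 1)]
          xb <- X[ii, , drop = FALSE]; yb <- Y[ii]
          a1 <- xb %*% W1
          a1 <- sweep(a1, 2, b1, `+`)
          h1 <- tanh(a1)
          z <- drop(h1 %*% W2) + b2
          p <- 1 / (1 + exp(-z))
          eps <- 1e-7
          bce <- -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))
          inter <- sum(p * yb); den <- sum(p) + sum(yb)
          dice_soft <- (2 * inter + 1) / (den + 1)
          loss <- bce + cfg$dice_weight * (1 - dice_soft)
          ep_loss <- ep_loss + loss; nb <- nb + 1
          # gradients: d(bce)/dz = (p - y)/m ; d(1-dice)/dz via quotient rule
          m <- length(yb)
          dz <- (p - yb) / m +
            cfg$dice_weight * (-(2 * yb * den - (2 * inter + 1)) / (den + 1)^2) *
            p * (1 - p)
          gW2 <- t(h1) %*% dz + cfg$l2 * W2
          gb2 <- sum(dz)
          dh1 <- (dz %*% t(W2)) * (1 - h1^2)
          gW1 <- t(xb) %*% dh1 + cfg$l2 * W1
          gb1 <- colSums(dh1)
          vW1 <- cfg$momentum * vW1 - cfg$lr * gW1; W1 <- W1 + vW1
          vb1 <- cfg$momentum * vb1 - cfg$lr * gb1; b1 <- b1 + vb1
          vW2 <- cfg$momentum * vW2 - cfg$lr * gW2; W2 <- W2 + vW2
          vb2 <- cfg$momentum * vb2 - cfg$lr * gb2; b2 <- b2 + vb2
        }
        final_loss <- ep_loss / nb
      }
    }
    model <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, cfg = cfg,
                  sigmas = model_feature_sigmas(), n_features = nf,
                  final_loss = final_loss, n_train_images = nrow(manifest))
    class(model) <- "dendrite_segmenter"
    model
  })
}

#' @export
print.dendrite_segmenter <- function(x, ...) {
  cat(sprintf(
    "<dendrite_segmenter> %d features -> %d hidden, %d epochs, final loss %.4f\n",
    x$n_features, x$cfg$hidden, x$cfg$epochs, x$final_loss))
  invisible(x)
}

#' Segment an image with a trained model
#'
#' @param image numeric image matrix.
#' @param model a `dendrite_segmenter` from [train_segmenter()].
#' @return probability-map matrix, same shape as `image`.
#' @export
segment_trained <- function(image, model) {
  stopifnot(inherits(model, "dendrite_segmenter"))
  cand <- model_candidates(image)
  p <- matrix(0, nrow(image), ncol(image))
  if (length(cand)) {
    F <- model_features(image, model$sigmas, idx = cand)
    if (ncol(F) != model$n_features) stop("feature/model mismatch")
    h1 <- tanh(sweep(F %*% model$W1, 2, model$b1, `+`))
    z <- drop(h1 %*% model$W2) + model$b2
    p[cand] <- 1 / (1 + exp(-z))
  }
  attr(p, "backend") <- "trained"
  p
}

#' Unified segmentation front end
#' @param image numeric image matrix.
#' @param backend "classical" or "trained".
#' @param model required for the trained backend.
#' @param ... passed to [segment_classical()].
#' @return probability map.
#' @export
segment_image <- function(image, backend = c("classical", "trained"),
                          model = NULL, ...) {
  backend <- match.arg(backend)
  if (backend == "classical") return(segment_classical(image, ...))
  if (is.null(model)) {
    stop("trained backend requested but no model supplied; ",
         "train one with train_segmenter() or pass backend = 'classical'")
  }
  segment_trained(image, model)
}

#' Save / load a trained segmenter as JSON
#' @param model a `dendrite_segmenter`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  obj <- model
  obj$W1 <- as.vector(obj$W1); obj$W2 <- as.vector(obj$W2)
  jsonlite::write_json(unclass(obj), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$cfg$hidden
  obj$W1 <- matrix(obj$W1, obj$n_features, h)
  obj$W2 <- matrix(obj$W2, h, 1)
  obj$sigmas <- lapply(obj$sigmas, unlist)
  class(obj) <- "dendrite_segmenter"
  obj
}
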