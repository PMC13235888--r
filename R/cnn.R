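# Compact convolutional classifier for encoded waveform images, written
# in vectorised base R: three 3x3 convolution blocks (ReLU, 2x2 max
# pooling after the first two), global average pooling and a single
# logistic output. Convolutions run as im2col matrix products with
# precomputed gather indices; training uses Adam, class-weighted binary
# cross-entropy and early stopping on validation loss with best-epoch
# checkpoint restoration. Grad-CAM saliency is computed from the same
# backward pass machinery.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param early_stop_patience Stop after this many epochs without
#'   validation-loss improvement; the best-epoch weights are restored.
#' @param class_weighting Weight the loss inversely to class frequency.
#' @param augmentation List with `horizontal_flip` (logical),
#'   `rotation_degrees` (max absolute rotation) and
#'   `color_jitter_strength` (brightness/contrast range); all-off means
#'   augmentation is the identity.
#' @param architecture Only `"small_cnn"` is implemented; the deeper
#'   published architectures are outside this package's scope.
#' @param channels Filters per convolution block (length 3).
#' @param seed RNG seed for initialization, shuffling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 50,
                         batch_size = 32, early_stop_patience = 10,
                         class_weighting = TRUE,
                         augmentation = list(horizontal_flip = TRUE,
                                             rotation_degrees = 15,
                                             color_jitter_strength = 0.1),
                         architecture = "small_cnn",
                         channels = c(8, 16, 16), seed = 1) {
  stopifnot(learning_rate > 0, early_stop_patience >= 1, max_epochs >= 1,
            length(channels) == 3)
  if (!identical(architecture, "small_cnn"))
    stop("architecture not implemented: ", architecture)
  structure(list(learning_rate = learning_rate, max_epochs = max_epochs,
                 batch_size = batch_size,
                 early_stop_patience = early_stop_patience,
                 class_weighting = class_weighting,
                 augmentation = augmentation, architecture = architecture,
                 channels = channels, seed = as.integer(seed)),
            class = "train_config")
}

#' Inverse-class-frequency weights
#'
#' `w_c = n / (2 * n_c)`, so a 2:1 imbalanced set gives the minority
#' class exactly twice the majority weight.
#'
#' @param labels 0/1 vector.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_weights <- function(labels) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  stopifnot(n0 > 0, n1 > 0)
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

# ---- geometry: precomputed gather indices ------------------------------

conv_index <- function(H, W, Cin, k = 3L) {
  Ho <- H - k + 1L; Wo <- W - k + 1L
  og <- expand.grid(ho = seq_len(Ho), wo = seq_len(Wo))
  pg <- expand.grid(c = seq_len(Cin), kh = 0:(k - 1L), kw = 0:(k - 1L))
  h_in <- outer(pg$kh, og$ho, "+")
  w_in <- outer(pg$kw, og$wo, "+")
  sp <- h_in + (w_in - 1L) * H
  idx <- (sp - 1L) * Cin + pg$c
  list(idx = idx, Ho = Ho, Wo = Wo, R = nrow(pg), S = Ho * Wo)
}

pool_index <- function(Ho, Wo) {
  Hp <- Ho %/% 2L; Wp <- Wo %/% 2L
  pg <- expand.grid(hp = seq_len(Hp), wp = seq_len(Wp))
  idx <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                function(d) {
                  (2L * pg$hp - 1L + d[1]) +
                    (2L * pg$wp - 1L + d[2] - 1L) * Ho
                })
  list(idx = idx, Hp = Hp, Wp = Wp, S = Hp * Wp)
}

small_cnn_geometry <- function(input_size, channels) {
  g1 <- conv_index(input_size, input_size, 1L)
  p1 <- pool_index(g1$Ho, g1$Wo)
  g2 <- conv_index(p1$Hp, p1$Wp, channels[1])
  p2 <- pool_index(g2$Ho, g2$Wo)
  g3 <- conv_index(p2$Hp, p2$Wp, channels[2])
  # precomputed sparse scatter operators for the backward im2col
  scatter <- function(g, n_in)
    Matrix::sparseMatrix(i = as.vector(g$idx),
                         j = seq_along(g$idx), x = 1,
                         dims = c(n_in, length(g$idx)))
  list(g1 = g1, p1 = p1, g2 = g2, p2 = p2, g3 = g3,
       sc2 = scatter(g2, channels[1] * p1$S),
       sc3 = scatter(g3, channels[2] * p2$S))
}

small_cnn_init <- function(input_size, channels, seed) {
  geom <- small_cnn_geometry(input_size, channels)
  with_seed(seed, {
    he <- function(cout, fanin)
      matrix(stats::rnorm(cout * fanin, 0, sqrt(2 / fanin)), cout, fanin)
    params <- list(
      W1 = he(channels[1], geom$g1$R), b1 = numeric(channels[1]),
      W2 = he(channels[2], geom$g2$R), b2 = numeric(channels[2]),
      W3 = he(channels[3], geom$g3$R), b3 = numeric(channels[3]),
      wd = stats::rnorm(channels[3], 0, sqrt(1 / channels[3])), bd = 0
    )
    structure(list(input_size = input_size, channels = channels,
                   params = params, geom = geom),
              class = "cnn_model")
  })
}

conv_fwd <- function(a_vec, g, Wm, b) {
  P <- matrix(a_vec[g$idx], nrow = g$R)
  Z <- Wm %*% P + b
  list(P = P, Z = Z)
}

pool_fwd <- function(A, p) {
  a1 <- A[, p$idx[[1]], drop = FALSE]; a2 <- A[, p$idx[[2]], drop = FALSE]
  a3 <- A[, p$idx[[3]], drop = FALSE]; a4 <- A[, p$idx[[4]], drop = FALSE]
  O <- pmax(a1, a2, a3, a4)
  arg <- 1L * (O == a1)
  arg[arg == 0 & O == a2] <- 2L
  arg[arg == 0 & O == a3] <- 3L
  arg[arg == 0 & O == a4] <- 4L
  list(O = O, arg = arg)
}

cnn_forward <- function(model, img, keep = FALSE) {
  gm <- model$geom; pr <- model$params
  a0 <- as.numeric(img)
  c1 <- conv_fwd(a0, gm$g1, pr$W1, pr$b1)
  A1 <- pmax(c1$Z, 0)
  p1 <- pool_fwd(A1, gm$p1)
  c2 <- conv_fwd(as.numeric(p1$O), gm$g2, pr$W2, pr$b2)
  A2 <- pmax(c2$Z, 0)
  p2 <- pool_fwd(A2, gm$p2)
  c3 <- conv_fwd(as.numeric(p2$O), gm$g3, pr$W3, pr$b3)
  A3 <- pmax(c3$Z, 0)
  g <- rowMeans(A3)
  logit <- sum(pr$wd * g) + pr$bd
  out <- list(logit = logit, prob = 1 / (1 + exp(-logit)))
  if (keep) out$cache <- list(c1 = c1, A1 = A1, p1 = p1, c2 = c2, A2 = A2,
                              p2 = p2, c3 = c3, A3 = A3, g = g)
  out
}

# scatter-add of patch gradients back onto the input activation vector
col2im <- function(dP, scat) {
  as.numeric(scat %*% as.vector(dP))
}

pool_bwd <- function(dO, pool, p, Cin, S_in) {
  dA <- matrix(0, Cin, S_in)
  for (k in 1:4) {
    dA[, p$idx[[k]]] <- dA[, p$idx[[k]]] + dO * (pool$arg == k)
  }
  dA
}

# Backward pass from d(logit). Returns parameter gradients and, when
# `want_act` names a stage ("A2" or "A3"), the gradient at that
# post-ReLU activation map.
cnn_backward <- function(model, cache, dlogit = 1, want_act = NULL) {
  gm <- model$geom; pr <- model$params
  S3 <- gm$g3$S
  dg <- dlogit * pr$wd
  dA3 <- matrix(dg / S3, nrow = model$channels[3], ncol = S3)
  out_act <- NULL
  if (identical(want_act, "A3")) out_act <- dA3
  dZ3 <- dA3 * (cache$c3$Z > 0)
  dW3 <- dZ3 %*% t(cache$c3$P)
  db3 <- rowSums(dZ3)
  dP3 <- t(pr$W3) %*% dZ3
  dp2 <- matrix(col2im(dP3, gm$sc3), nrow = model$channels[2])
  dA2 <- pool_bwd(dp2, cache$p2, gm$p2, model$channels[2], gm$g2$S)
  if (identical(want_act, "A2")) out_act <- dA2
  dZ2 <- dA2 * (cache$c2$Z > 0)
  dW2 <- dZ2 %*% t(cache$c2$P)
  db2 <- rowSums(dZ2)
  dP2 <- t(pr$W2) %*% dZ2
  dp1 <- matrix(col2im(dP2, gm$sc2), nrow = model$channels[1])
  dA1 <- pool_bwd(dp1, cache$p1, gm$p1, model$channels[1], gm$g1$S)
  dZ1 <- dA1 * (cache$c1$Z > 0)
  dW1 <- dZ1 %*% t(cache$c1$P)
  db1 <- rowSums(dZ1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3,
                    wd = dlogit * cache$g, bd = dlogit),
       act_grad = out_act)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- augmentation ------------------------------------------------------

#' Horizontal flip of an image matrix
#'
#' Deterministic involution: applying it twice restores the original.
#'
#' @param img Numeric matrix.
#' @return Column-mirrored matrix.
#' @export
flip_horizontal <- function(img) img[, ncol(img):1, drop = FALSE]

#' Rotate an image about its center
#'
#' Nearest-neighbour inverse mapping; pixels sampled from outside the
#' source are 0. A rotation of 0 degrees is the exact identity.
#'
#' @param img Numeric matrix.
#' @param degrees Rotation angle (counter-clockwise).
#' @return Rotated matrix, same dimensions.
#' @export
rotate_image <- function(img, degrees) {
  if (degrees == 0) return(img)
  th <- degrees * pi / 180
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- rr - cy; dx <- cc - cx
  sy <- round(cy + cos(th) * dy + sin(th) * dx)
  sx <- round(cx - sin(th) * dy + cos(th) * dx)
  ok <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  out <- matrix(0, H, W)
  out[ok] <- img[cbind(sy[ok], sx[ok])]
  out
}

#' Stochastic training-time augmentation
#'
#' Applies, in order: random horizontal flip (probability 0.5), random
#' rotation within `rotation_degrees`, and brightness/contrast jitter
#' scaled by `color_jitter_strength`. With every component disabled the
#' output is identical to the input. Randomness comes from the current
#' RNG stream (seeded by the training loop).
#'
#' @param img Numeric matrix.
#' @param aug Augmentation list as in [train_config()].
#' @return Augmented matrix.
#' @export
augment_image <- function(img, aug) {
  if (isTRUE(aug$horizontal_flip) && stats::runif(1) < 0.5)
    img <- flip_horizontal(img)
  if (!is.null(aug$rotation_degrees) && aug$rotation_degrees > 0)
    img <- rotate_image(img, stats::runif(1, -aug$rotation_degrees,
                                          aug$rotation_degrees))
  s <- aug$color_jitter_strength
  if (!is.null(s) && s > 0)
    img <- img * (1 + stats::runif(1, -s, s)) + stats::runif(1, -s, s)
  img
}

# ---- training ----------------------------------------------------------

weighted_bce <- function(probs, labels, w) {
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  wi <- ifelse(labels == 1, w["1"], w["0"])
  -mean(wi * (labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Train the compact CNN
#'
#' Trains on the images whose patients fall in the plan's training set
#' (validation set used for early stopping). Training halts when the
#' validation loss has not improved for `early_stop_patience` epochs or
#' at `max_epochs`; the returned model carries the weights of the
#' best-validation-loss epoch.
#'
#' @param images List of equal-sized square numeric matrices.
#' @param labels 0/1 vector, one per image.
#' @param patient_ids Character vector, one per image.
#' @param plan A `split_plan` from [make_splits()]; may be `NULL` if
#'   `train_idx`/`val_idx` are given.
#' @param repeat_idx Which repeat of the plan to use.
#' @param cfg A [train_config()].
#' @param train_idx,val_idx Optional explicit image-index splits
#'   (override the plan).
#' @return A `cnn_model` with `history` (data frame of epoch,
#'   train_loss, val_loss), `best_epoch`, and the training config.
#' @export
train_cnn <- function(images, labels, patient_ids, plan = NULL,
                      repeat_idx = 1, cfg = train_config(),
                      train_idx = NULL, val_idx = NULL) {
  stopifnot(length(images) == length(labels),
            length(images) == length(patient_ids))
  if (is.null(train_idx)) {
    stopifnot(inherits(plan, "split_plan"))
    asg <- plan$assignments[[repeat_idx]]
    set_of <- asg$set[match(patient_ids, asg$patient_id)]
    train_idx <- which(set_of == "train")
    val_idx <- which(set_of == "val")
  }
  if (!length(train_idx) || !length(val_idx))
    stop("empty train or validation split")
  if (length(unique(labels[train_idx])) < 2)
    stop("training split must contain both classes")
  sz <- nrow(images[[1]])
  w <- if (cfg$class_weighting) class_weights(labels[train_idx])
       else c("0" = 1, "1" = 1)
  model <- small_cnn_init(sz, cfg$channels, cfg$seed)
  opt <- adam_init(model$params)
  aug_on <- isTRUE(cfg$augmentation$horizontal_flip) ||
    (!is.null(cfg$augmentation$rotation_degrees) &&
       cfg$augmentation$rotation_degrees > 0) ||
    (!is.null(cfg$augmentation$color_jitter_strength) &&
       cfg$augmentation$color_jitter_strength > 0)
  val_probs <- function(m, idx) vapply(idx, function(i)
    cnn_forward(m, images[[i]])$prob, numeric(1))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L
  wait <- 0L
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0
      nb <- 0
      for (bs in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[bs:min(bs + cfg$batch_size - 1, length(ord))]
        gsum <- NULL
        for (i in bidx) {
          img <- images[[i]]
          if (aug_on) img <- augment_image(img, cfg$augmentation)
          fw <- cnn_forward(model, img, keep = TRUE)
          y <- labels[i]
          wi <- unname(w[as.character(y)])
          p <- min(max(fw$prob, 1e-12), 1 - 1e-12)
          ep_loss <- ep_loss - wi * (y * log(p) + (1 - y) * log(1 - p))
          dlogit <- wi * (fw$prob - y) / length(bidx)
          bw <- cnn_backward(model, fw$cache, dlogit)
          gsum <- if (is.null(gsum)) bw$grads
                  else Map(`+`, gsum, bw$grads)
        }
        st <- adam_step(model$params, gsum, opt, cfg$learning_rate)
        model$params <- st$params; opt <- st$state
        nb <- nb + 1
      }
      vl <- weighted_bce(val_probs(model, val_idx), labels[val_idx], w)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / length(ord), val_loss = vl))
      if (vl < best_val - 1e-12) {
        best_val <- vl; best_params <- model$params
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- history
  model$best_epoch <- best_epoch
  model$config <- cfg
  model$class_weights <- w
  model
}

#' Predict event probabilities for images
#'
#' Deterministic inference (no augmentation).
#'
#' @param model A trained `cnn_model`.
#' @param images List of image matrices (or a single matrix).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.matrix(images)) images <- list(images)
  if (nrow(images[[1]]) != model$input_size)
    stop("image size does not match the model input size")
  vapply(images, function(im) cnn_forward(model, im)$prob, numeric(1))
}

# bilinear upsampling of a small map to target dimensions
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == 1) m <- rbind(m, m)
  if (w == 1) m <- cbind(m, m)
  h <- nrow(m); w <- ncol(m)
  rows <- apply(m, 2, function(col)
    stats::approx(seq_len(h), col, xout = seq(1, h, length.out = H))$y)
  t(apply(rows, 1, function(rw)
    stats::approx(seq_len(w), rw, xout = seq(1, w, length.out = W))$y))
}

#' Grad-CAM saliency map
#'
#' Channel weights are the spatial means of the event-logit gradient at
#' the chosen convolutional stage; the map is the rectified weighted sum
#' of that stage's activations, bilinearly upsampled to the input extent
#' and max-normalized.
#'
#' @param model A trained `cnn_model`.
#' @param image Input image matrix.
#' @param layer_tag `"penultimate_conv"` (second conv block, the stage
#'   before the final one) or `"final_conv"` (third conv block).
#' @param target Class whose score is explained: `"predicted"` (default),
#'   `"event"` or `"nonevent"`.
#' @return A `saliency_map` list: `grid` (matrix, input extent, values in
#'   [0, 1]), `layer_tag`, `predicted_prob`.
#' @export
gradcam <- function(model, image, layer_tag = "penultimate_conv",
                    target = "predicted") {
  stopifnot(inherits(model, "cnn_model"))
  stage <- switch(layer_tag,
                  penultimate_conv = "A2", final_conv = "A3",
                  stop("unknown layer_tag: ", layer_tag))
  target <- match.arg(target, c("predicted", "event", "nonevent"))
  fw <- cnn_forward(model, image, keep = TRUE)
  dlogit <- switch(target,
                   event = 1,
                   nonevent = -1,
                   predicted = if (fw$prob >= 0.5) 1 else -1)
  bw <- cnn_backward(model, fw$cache, dlogit = dlogit, want_act = stage)
  A <- if (stage == "A2") fw$cache$A2 else fw$cache$A3
  geom <- if (stage == "A2") model$geom$g2 else model$geom$g3
  alpha <- rowMeans(bw$act_grad)
  map <- pmax(0, colSums(A * alpha))
  grid <- matrix(map, geom$Ho, geom$Wo)
  up <- upsample_bilinear(grid, nrow(image), ncol(image))
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(grid = up, layer_tag = layer_tag,
                 predicted_prob = fw$prob),
            class = "saliency_map")
}
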