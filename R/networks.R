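# Architectures: Siamese encoders (two-branch CNN variant, convolutional
# autoencoder variant) and the staging model (two-branch CNN feature block,
# sequence residual block with bi-LSTMs and a fully-connected shortcut,
# shared softmax head). Weight sharing across the two Siamese branches is
# structural: there is exactly one parameter set and "both branches" are two
# calls of the same function on it.

# ---- layer-stack plumbing -------------------------------------------------

# A stack is a list of layer specs; params is a parallel list. Shapes are
# tracked as list(L =, C =) for (batch, length, channel) arrays or
# list(D =) for dense matrices.

init_stack <- function(spec, in_shape) {
  params <- vector("list", length(spec))
  shp <- in_shape
  for (i in seq_along(spec)) {
    ly <- spec[[i]]
    params[i] <- list(switch(ly$type,
      conv = {
        fan_in <- ly$k * shp$C
        p <- list(W = he_init(ly$k * shp$C, ly$out_ch, fan_in),
                  b = numeric(ly$out_ch))
        shp <- list(L = conv_out_len(shp$L, ly$k, ly$stride, ly$pad),
                    C = ly$out_ch)
        p
      },
      deconv = {
        p <- list(W = array(stats::rnorm(ly$k * shp$C * ly$out_ch,
                                         sd = sqrt(2 / (ly$k * shp$C))),
                            c(ly$k, shp$C, ly$out_ch)),
                  b = numeric(ly$out_ch))
        shp <- list(L = (shp$L - 1L) * ly$stride + ly$k, C = ly$out_ch)
        p
      },
      bn = {
        nc <- if (!is.null(shp$C)) shp$C else shp$D
        list(gamma = rep(1, nc), beta = numeric(nc),
             rm = numeric(nc), rv = rep(1, nc))
      },
      relu = NULL,
      pool = {
        shp$L <- (shp$L - ly$size) %/% ly$stride + 1L
        NULL
      },
      dropout = NULL,
      flatten = {
        shp <- list(D = shp$L * shp$C)
        NULL
      },
      unflatten = {
        shp <- list(L = ly$L, C = ly$C)
        NULL
      },
      fitlen = {
        shp$L <- ly$target
        NULL
      },
      linear = {
        p <- list(W = he_init(shp$D, ly$out, shp$D), b = numeric(ly$out))
        shp <- list(D = ly$out)
        p
      },
      stop("unknown layer type: ", ly$type)))
  }
  list(params = params, out_shape = shp)
}

stack_fwd <- function(spec, params, X, train) {
  caches <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    ly <- spec[[i]]; p <- params[[i]]
    r <- switch(ly$type,
      conv = conv1d_fwd(X, p$W, p$b, ly$stride, ly$pad),
      deconv = deconv1d_fwd(X, p$W, p$b, ly$stride),
      bn = {
        rr <- bn_fwd(X, p$gamma, p$beta, p$rm, p$rv, train)
        params[[i]]$rm <- rr$run_mean; params[[i]]$rv <- rr$run_var
        rr
      },
      relu = relu_fwd(X),
      pool = maxpool1d_fwd(X, ly$size, ly$stride),
      dropout = dropout_fwd(X, ly$p, train),
      flatten = {
        d <- dim(X); Xf <- X; dim(Xf) <- c(d[1], d[2] * d[3])
        list(out = Xf, cache = d)
      },
      unflatten = {
        Xa <- X; dim(Xa) <- c(nrow(X), ly$L, ly$C)
        list(out = Xa, cache = dim(X))
      },
      fitlen = {
        d <- dim(X)
        if (d[2] >= ly$target) {
          list(out = X[, seq_len(ly$target), , drop = FALSE], cache = d)
        } else {
          Y <- array(0, c(d[1], ly$target, d[3]))
          Y[, seq_len(d[2]), ] <- X
          list(out = Y, cache = d)
        }
      },
      linear = linear_fwd(X, p$W, p$b))
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches, params = params)
}

stack_bwd <- function(spec, params, caches, dOut) {
  grads <- vector("list", length(spec))
  for (i in rev(seq_along(spec))) {
    ly <- spec[[i]]
    dOut <- switch(ly$type,
      conv = {
        g <- conv1d_bwd(caches[[i]], dOut)
        grads[[i]] <- list(W = g$dW, b = g$db)
        g$dX
      },
      deconv = {
        g <- deconv1d_bwd(caches[[i]], dOut)
        grads[[i]] <- list(W = g$dW, b = g$db)
        g$dX
      },
      bn = {
        g <- bn_bwd(caches[[i]], dOut)
        grads[[i]] <- list(gamma = g$dgamma, beta = g$dbeta,
                           rm = NULL, rv = NULL)
        g$dX
      },
      relu = relu_bwd(caches[[i]], dOut),
      pool = maxpool1d_bwd(caches[[i]], dOut),
      dropout = dropout_bwd(caches[[i]], dOut),
      flatten = { d <- caches[[i]]; dim(dOut) <- d; dOut },
      unflatten = { d <- caches[[i]]; dim(dOut) <- d; dOut },
      fitlen = {
        d <- caches[[i]]
        if (d[2] >= ly$target) {
          dX <- array(0, d)
          dX[, seq_len(ly$target), ] <- dOut
          dX
        } else {
          dOut[, seq_len(d[2]), , drop = FALSE]
        }
      },
      linear = {
        g <- linear_bwd(caches[[i]], dOut)
        grads[[i]] <- list(W = g$dW, b = g$db)
        g$dX
      })
  }
  list(dX = dOut, grads = grads)
}

# ---- architecture specs ---------------------------------------------------

# One CNN branch of the two-branch feature extractor (DeepSleepNet-style
# geometry: a wide-stride first convolution whose kernel sets the temporal
# scale, then three padded kernel-8 convolutions and pooling).
cnn_branch_spec <- function(first_k, first_stride, pool1, pool2,
                            f1, f2, dropout_p) {
  c(list(list(type = "conv", k = first_k, stride = first_stride, pad = 0L,
              out_ch = f1),
         list(type = "bn"), list(type = "relu"),
         list(type = "pool", size = pool1, stride = pool1),
         list(type = "dropout", p = dropout_p)),
    unlist(lapply(1:3, function(i) {
      list(list(type = "conv", k = 8L, stride = 1L, pad = 4L, out_ch = f2),
           list(type = "bn"), list(type = "relu"))
    }), recursive = FALSE),
    list(list(type = "pool", size = pool2, stride = pool2),
         list(type = "flatten")))
}

two_branch_specs <- function(fs, f1, f2, dropout_p = 0.5) {
  list(small = cnn_branch_spec(first_k = max(3L, round(fs / 2)),
                               first_stride = max(1L, round(fs / 16)),
                               pool1 = 8L, pool2 = 4L,
                               f1 = f1, f2 = f2, dropout_p = dropout_p),
       large = cnn_branch_spec(first_k = max(4L, round(fs * 4)),
                               first_stride = max(1L, round(fs / 2)),
                               pool1 = 4L, pool2 = 2L,
                               f1 = f1, f2 = f2, dropout_p = dropout_p))
}

ae_encoder_spec <- function(filters, latent_dim, L) {
  sp <- list()
  for (f in filters) {
    sp <- c(sp, list(list(type = "conv", k = 8L, stride = 2L, pad = 0L,
                          out_ch = f),
                     list(type = "bn"), list(type = "relu")))
  }
  c(sp, list(list(type = "flatten"),
             list(type = "linear", out = latent_dim)))
}

ae_decoder_spec <- function(filters, latent_dim, enc_L3, L_target) {
  f <- rev(filters)
  sp <- list(list(type = "linear", out = enc_L3 * f[1]),
             list(type = "unflatten", L = enc_L3, C = f[1]))
  for (i in seq_along(f)) {
    out_ch <- if (i < length(f)) f[i + 1] else 1L
    sp <- c(sp, list(list(type = "deconv", k = 8L, stride = 2L,
                          out_ch = out_ch)))
    if (i < length(f)) sp <- c(sp, list(list(type = "bn"),
                                        list(type = "relu")))
  }
  c(sp, list(list(type = "fitlen", target = L_target)))
}

# ---- Siamese model --------------------------------------------------------

#' Construct a Siamese encoder model
#'
#' Both Siamese branches are one parameter set; encoding an epoch through
#' "either branch" runs literally the same computation. The `"cnn"` variant
#' encodes with a two-branch convolutional stack (small-filter branch for
#' temporal detail, large-filter branch for frequency content) projected to
#' `latent_dim`; the `"ae"` variant is a three-stage convolutional encoder
#' with a mirrored transposed-convolution decoder that reconstructs the
#' input epoch.
#'
#' @param variant `"ae"` or `"cnn"`.
#' @param fs sampling rate of the epochs to encode (Hz).
#' @param latent_dim dimensionality of the latent feature.
#' @param filters integer vector of encoder filter counts; for `"ae"` the
#'   three conv stages (default 32, 64, 64), for `"cnn"` the two-branch
#'   `c(first_conv, inner_conv)` counts (default 64, 128).
#' @param dropout_p dropout probability in the CNN branches.
#' @param seed RNG seed for parameter initialization.
#' @return An object of class `"siamese_model"`.
#' @export
siamese_model <- function(variant = c("ae", "cnn"), fs = 100,
                          latent_dim = 128L, filters = NULL,
                          dropout_p = 0.5, seed = 1L) {
  variant <- match.arg(variant)
  L <- round(fs * 30)
  with_seed(seed, {
    if (variant == "ae") {
      if (is.null(filters)) filters <- c(32L, 64L, 64L)
      enc_spec <- ae_encoder_spec(filters, latent_dim, L)
      enc <- init_stack(enc_spec, list(L = L, C = 1L))
      # length after the three stride-2 convs
      L3 <- L
      for (i in 1:3) L3 <- conv_out_len(L3, 8L, 2L)
      dec_spec <- ae_decoder_spec(filters, latent_dim, L3, L)
      dec <- init_stack(dec_spec, list(D = latent_dim))
      model <- list(variant = "ae", fs = fs, L = L, latent_dim = latent_dim,
                    filters = filters,
                    enc_spec = enc_spec, dec_spec = dec_spec,
                    params = list(encoder = enc$params,
                                  decoder = dec$params))
    } else {
      if (is.null(filters)) filters <- c(64L, 128L)
      specs <- two_branch_specs(fs, filters[1], filters[2], dropout_p)
      b1 <- init_stack(specs$small, list(L = L, C = 1L))
      b2 <- init_stack(specs$large, list(L = L, C = 1L))
      feat_dim <- b1$out_shape$D + b2$out_shape$D
      proj_spec <- list(list(type = "linear", out = latent_dim))
      proj <- init_stack(proj_spec, list(D = feat_dim))
      model <- list(variant = "cnn", fs = fs, L = L, latent_dim = latent_dim,
                    filters = filters, branch_specs = specs,
                    proj_spec = proj_spec, feat_dim = feat_dim,
                    params = list(branch1 = b1$params, branch2 = b2$params,
                                  proj = proj$params))
    }
    structure(model, class = "siamese_model")
  })
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf("<siamese_model> variant %s, fs %g Hz, latent dim %d, %d parameters\n",
              toupper(x$variant), x$fs, x$latent_dim, n_parameters(x$params)))
  invisible(x)
}

n_parameters <- function(params) {
  tot <- 0L
  walk <- function(p) {
    for (el in p) {
      if (is.list(el)) walk(el)
      else if (is.numeric(el)) tot <<- tot + length(el)
    }
  }
  walk(params)
  tot
}

# Forward the encoder on a batch matrix (B x L); returns latents (B x latent)
# and caches needed for backprop.
encoder_fwd <- function(model, X, train = FALSE) {
  B <- nrow(X)
  Xa <- array(X, c(B, ncol(X), 1L))
  if (model$variant == "ae") {
    r <- stack_fwd(model$enc_spec, model$params$encoder, Xa, train)
    list(latent = r$out, caches = r$caches, params = r$params)
  } else {
    r1 <- stack_fwd(model$branch_specs$small, model$params$branch1, Xa, train)
    r2 <- stack_fwd(model$branch_specs$large, model$params$branch2, Xa, train)
    feat <- cbind(r1$out, r2$out)
    rp <- stack_fwd(model$proj_spec, model$params$proj, feat, train)
    list(latent = rp$out,
         caches = list(b1 = r1$caches, b2 = r2$caches, proj = rp$caches,
                       d1 = ncol(r1$out)),
         params = list(branch1 = r1$params, branch2 = r2$params,
                       proj = rp$params))
  }
}

encoder_bwd <- function(model, caches, dLatent) {
  if (model$variant == "ae") {
    g <- stack_bwd(model$enc_spec, model$params$encoder, caches, dLatent)
    list(grads = list(encoder = g$grads), dX = g$dX)
  } else {
    gp <- stack_bwd(model$proj_spec, model$params$proj, caches$proj, dLatent)
    d1 <- caches$d1
    g1 <- stack_bwd(model$branch_specs$small, model$params$branch1,
                    caches$b1, gp$dX[, seq_len(d1), drop = FALSE])
    g2 <- stack_bwd(model$branch_specs$large, model$params$branch2,
                    caches$b2, gp$dX[, -seq_len(d1), drop = FALSE])
    list(grads = list(branch1 = g1$grads, branch2 = g2$grads,
                      proj = gp$grads),
         dX = g1$dX + g2$dX)
  }
}

decoder_fwd <- function(model, latent, train = FALSE) {
  if (model$variant != "ae") stop("decoder exists only for the AE variant")
  r <- stack_fwd(model$dec_spec, model$params$decoder, latent, train)
  out <- r$out
  dim(out) <- c(nrow(latent), model$L)
  list(recon = out, caches = r$caches, params = r$params)
}

decoder_bwd <- function(model, caches, dRecon) {
  dR <- array(dRecon, c(nrow(dRecon), ncol(dRecon), 1L))
  g <- stack_bwd(model$dec_spec, model$params$decoder, caches, dR)
  list(grads = list(decoder = g$grads), dLatent = g$dX)
}

#' Encode one epoch to its latent feature
#'
#' Runs the (single, shared) encoder branch in evaluation mode; identical
#' inputs always give identical latents.
#'
#' @param model a `siamese_model`.
#' @param epoch an `epoch_record`, or a numeric vector of length `fs * 30`.
#' @return Numeric latent vector of length `model$latent_dim`.
#' @export
encode_epoch <- function(model, epoch) {
  x <- if (inherits(epoch, "epoch_record")) epoch$samples else as.numeric(epoch)
  if (length(x) != model$L) {
    stop("epoch length ", length(x), " does not match model input length ",
         model$L)
  }
  drop(encoder_fwd(model, matrix(x, 1L), train = FALSE)$latent)
}

#' Reconstruct an epoch from a latent feature (AE variant only)
#'
#' @param model a `siamese_model` with `variant == "ae"`.
#' @param latent numeric vector of length `model$latent_dim`.
#' @return Numeric vector of length `fs * 30` (the reconstruction).
#' @export
decode_latent <- function(model, latent) {
  if (model$variant != "ae") stop("decode_latent: model has no decoder (CNN variant)")
  if (length(latent) != model$latent_dim) stop("latent has wrong dimensionality")
  drop(decoder_fwd(model, matrix(as.numeric(latent), 1L),
                   train = FALSE)$recon)
}

#' Concatenate an epoch with its latent feature
#'
#' The augmented staging input: the raw samples first, then the latent
#' vector (fixed documented order).
#'
#' @param epoch an `epoch_record` or numeric vector.
#' @param latent numeric latent vector.
#' @return Numeric vector of length `length(epoch) + length(latent)`.
#' @export
concat_features <- function(epoch, latent) {
  x <- if (inherits(epoch, "epoch_record")) epoch$samples else as.numeric(epoch)
  c(x, as.numeric(latent))
}

# ---- staging model --------------------------------------------------------

#' Construct the sleep staging model
#'
#' A two-branch CNN feature block over the augmented (epoch + latent) input,
#' a sequence residual block (two bidirectional LSTM layers plus a
#' fully-connected shortcut, summed), and a shared linear softmax head over
#' the five stages. During pretraining only CNN block + head are used;
#' finetuning inserts the sequence block before the head.
#'
#' @param fs sampling rate (Hz).
#' @param latent_dim latent dimensionality of the paired Siamese encoder.
#' @param filters `c(first_conv, inner_conv)` filter counts
#'   (default 64, 128).
#' @param hidden bi-LSTM hidden size per direction (default 512).
#' @param dropout_p dropout probability.
#' @param seed RNG seed for initialization.
#' @return An object of class `"staging_model"`.
#' @export
staging_model <- function(fs = 100, latent_dim = 128L,
                          filters = c(64L, 128L), hidden = 512L,
                          dropout_p = 0.5, seed = 1L) {
  L_aug <- round(fs * 30) + latent_dim
  with_seed(seed, {
    specs <- two_branch_specs(fs, filters[1], filters[2], dropout_p)
    b1 <- init_stack(specs$small, list(L = L_aug, C = 1L))
    b2 <- init_stack(specs$large, list(L = L_aug, C = 1L))
    feat_dim <- b1$out_shape$D + b2$out_shape$D
    head <- init_stack(list(list(type = "linear", out = 5L)),
                       list(D = feat_dim))
    l1 <- lstm_init(feat_dim, hidden); l1b <- lstm_init(feat_dim, hidden)
    l2 <- lstm_init(2L * hidden, hidden); l2b <- lstm_init(2L * hidden, hidden)
    seq_params <- list(
      lstm1f = l1, lstm1b = l1b, lstm2f = l2, lstm2b = l2b,
      proj = list(W = he_init(2L * hidden, feat_dim, 2L * hidden),
                  b = numeric(feat_dim)),
      shortcut = list(W = he_init(feat_dim, feat_dim, feat_dim),
                      b = numeric(feat_dim)))
    structure(list(fs = fs, latent_dim = latent_dim, L_aug = L_aug,
                   feat_dim = feat_dim, hidden = hidden,
                   dropout_p = dropout_p, branch_specs = specs,
                   params = list(branch1 = b1$params, branch2 = b2$params,
                                 head = head$params, seq = seq_params)),
              class = "staging_model")
  })
}

#' @export
print.staging_model <- function(x, ...) {
  cat(sprintf(
    "<staging_model> fs %g Hz, augmented input %d, CNN features %d, bi-LSTM hidden %d, %d parameters\n",
    x$fs, x$L_aug, x$feat_dim, x$hidden, n_parameters(x$params)))
  invisible(x)
}

# CNN block forward on augmented batch matrix (B x L_aug) -> features.
cnn_block_fwd <- function(sm, X, train = FALSE) {
  Xa <- array(X, c(nrow(X), ncol(X), 1L))
  r1 <- stack_fwd(sm$branch_specs$small, sm$params$branch1, Xa, train)
  r2 <- stack_fwd(sm$branch_specs$large, sm$params$branch2, Xa, train)
  feat <- cbind(r1$out, r2$out)
  dr <- dropout_fwd(feat, sm$dropout_p, train)
  list(feat = dr$out,
       caches = list(b1 = r1$caches, b2 = r2$caches, drop = dr$cache,
                     d1 = ncol(r1$out)),
       params = list(branch1 = r1$params, branch2 = r2$params))
}

cnn_block_bwd <- function(sm, caches, dFeat) {
  dFeat <- dropout_bwd(caches$drop, dFeat)
  d1 <- caches$d1
  g1 <- stack_bwd(sm$branch_specs$small, sm$params$branch1, caches$b1,
                  dFeat[, seq_len(d1), drop = FALSE])
  g2 <- stack_bwd(sm$branch_specs$large, sm$params$branch2, caches$b2,
                  dFeat[, -seq_len(d1), drop = FALSE])
  list(grads = list(branch1 = g1$grads, branch2 = g2$grads),
       dX = g1$dX + g2$dX)
}

# Sequence residual block: features (B, T, F) -> residual sum (B, T, F).
seq_block_fwd <- function(sm, Feat3, train = FALSE) {
  p <- sm$params$seq
  r1 <- bilstm_fwd(Feat3, p$lstm1f$W, p$lstm1f$b, p$lstm1b$W, p$lstm1b$b)
  r2 <- bilstm_fwd(r1$out, p$lstm2f$W, p$lstm2f$b, p$lstm2b$W, p$lstm2b$b)
  d <- dim(r2$out)
  H2 <- r2$out; dim(H2) <- c(d[1] * d[2], d[3])
  pr <- linear_fwd(H2, p$proj$W, p$proj$b)
  dF <- dim(Feat3)
  Fm <- Feat3; dim(Fm) <- c(dF[1] * dF[2], dF[3])
  sc <- linear_fwd(Fm, p$shortcut$W, p$shortcut$b)
  scr <- relu_fwd(sc$out)
  out <- pr$out + scr$out
  dim(out) <- dF
  list(out = out,
       caches = list(r1 = r1$cache, r2 = r2$cache, pr = pr$cache,
                     sc = sc$cache, scr = scr$cache, dF = dF, d2 = d))
}

seq_block_bwd <- function(sm, caches, dOut) {
  dF <- caches$dF
  dm <- dOut; dim(dm) <- c(dF[1] * dF[2], dF[3])
  gpr <- linear_bwd(caches$pr, dm)
  gscr <- relu_bwd(caches$scr, dm)
  gsc <- linear_bwd(caches$sc, gscr)
  dH2 <- gpr$dX; dim(dH2) <- caches$d2
  g2 <- bilstm_bwd(caches$r2, dH2)
  g1 <- bilstm_bwd(caches$r1, g2$dX)
  dFeat3 <- g1$dX + array(gsc$dX, dF)
  list(grads = list(
         lstm1f = list(W = g1$dWf, b = g1$dbf),
         lstm1b = list(W = g1$dWb, b = g1$dbb),
         lstm2f = list(W = g2$dWf, b = g2$dbf),
         lstm2b = list(W = g2$dWb, b = g2$dbb),
         proj = list(W = gpr$dW, b = gpr$db),
         shortcut = list(W = gsc$dW, b = gsc$db)),
       dFeat3 = dFeat3)
}

head_fwd <- function(sm, feat) {
  linear_fwd(feat, sm$params$head[[1]]$W, sm$params$head[[1]]$b)
}

#' Forward pass of the staging model
#'
#' In `"pretrain"` mode each augmented input is classified independently by
#' the CNN block and head (no temporal coupling). In `"finetune"` mode the
#' input must be a sequence of `seq_len` augmented epochs; CNN features pass
#' through the sequence residual block (bi-LSTM branch plus fully-connected
#' shortcut, summed) before the head.
#'
#' @param sm a `staging_model`.
#' @param inputs numeric matrix of augmented inputs, one epoch per row
#'   (`ncol == fs*30 + latent_dim`). In finetune mode the rows are one
#'   ordered sequence.
#' @param mode `"pretrain"` or `"finetune"`.
#' @param seq_len required sequence length in finetune mode.
#' @return Numeric matrix of per-epoch class probabilities (rows sum to 1).
#' @export
forward_staging <- function(sm, inputs, mode = c("pretrain", "finetune"),
                            seq_len = 25L) {
  mode <- match.arg(mode)
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != sm$L_aug) {
    stop("augmented input length ", ncol(inputs), " does not match model (",
         sm$L_aug, ")")
  }
  cb <- cnn_block_fwd(sm, inputs, train = FALSE)
  if (mode == "finetune") {
    if (nrow(inputs) != seq_len) {
      stop("finetune mode needs exactly seq_len = ", seq_len,
           " epochs, got ", nrow(inputs))
    }
    F3 <- array(cb$feat, c(1L, nrow(inputs), sm$feat_dim))
    sq <- seq_block_fwd(sm, F3, train = FALSE)
    feat <- sq$out; dim(feat) <- c(nrow(inputs), sm$feat_dim)
  } else {
    feat <- cb$feat
  }
  softmax_rows(head_fwd(sm, feat)$out)
}
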