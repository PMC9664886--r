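# Conditional GAN: modified U-Net generator (long encoder-decoder skips,
# short residual skips within levels), three-layer leaky-ReLU patch
# discriminator with spectral normalisation, LSGAN + L1 objective, history
# buffer of previously generated pairs, and the training loop.

concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0

#' Build the U-Net generator
#'
#' A modified U-Net: stem convolution, `levels` stride-2 encoder stages
#' each followed by a residual block (the short skip connections), and a
#' mirrored decoder with nearest-neighbour upsampling whose stages
#' concatenate the corresponding encoder feature (the long skip
#' connections). The head convolution maps back to 3 channels through a
#' tanh, so output spatial size equals input size. Weights are initialised
#' from N(0, 0.02^2) under the seed.
#'
#' @param size Input/output spatial size; a power of two >= 32.
#' @param base_channels Channel count at the top level; doubles per level
#'   (capped at 8x).
#' @param levels Number of resolution levels; default `log2(size) - 2`
#'   (6 at 256, 4 at 64).
#' @param seed Integer seed for the weight initialisation.
#' @param short_skips,long_skips Toggle the residual and encoder-decoder
#'   skips.
#' @param norm `"none"` (default) or `"instance"`. Instance normalisation
#'   is conventional in image-to-image GANs but discards per-channel
#'   absolute intensity, which here carries the reflectance signal itself,
#'   so the default preserves radiometry.
#' @param spectral_norm Apply spectral normalisation to generator weights
#'   (off by default; the discriminator always uses it).
#' @return A `ganpop_generator`.
#' @export
build_generator <- function(size = 256, base_channels = 16, levels = NULL,
                            seed = 1L, short_skips = TRUE, long_skips = TRUE,
                            norm = c("none", "instance"),
                            spectral_norm = FALSE) {
  norm <- match.arg(norm)
  if (!is_pow2(size) || size < 32) {
    stop("`size` must be a power of two >= 32", call. = FALSE)
  }
  if (is.null(levels)) levels <- max(1L, as.integer(log2(size)) - 2L)
  rng <- local_rng(seed)
  ch <- base_channels * 2^pmin(0:levels, 3)
  layers <- list()
  add_unit <- function(layers, name, k, cin, cout, stride = 1) {
    layers[[name]] <- new_conv_layer(name, k, cin, cout, stride = stride,
                                     rng = rng,
                                     spectral_norm = spectral_norm)
    if (norm == "instance") {
      layers[[paste0("in_", name)]] <- new_in_layer(paste0("in_", name), cout)
    }
    layers
  }
  layers <- add_unit(layers, "stem", 3, 3, ch[1])
  for (l in seq_len(levels)) {
    layers <- add_unit(layers, paste0("down_", l), 3, ch[l], ch[l + 1],
                       stride = 2)
    layers <- add_unit(layers, paste0("res1_", l), 3, ch[l + 1], ch[l + 1])
    layers <- add_unit(layers, paste0("res2_", l), 3, ch[l + 1], ch[l + 1])
    layers <- add_unit(layers, paste0("up_", l), 3, ch[l + 1], ch[l])
    layers <- add_unit(layers, paste0("fuse_", l), 3,
                       if (long_skips) 2 * ch[l] else ch[l], ch[l])
  }
  layers$head <- new_conv_layer("head", 3, ch[1], 3, rng = rng,
                                spectral_norm = spectral_norm)
  structure(list(size = size, levels = levels, channels = ch,
                 layers = layers, short_skips = short_skips,
                 long_skips = long_skips, norm = norm,
                 seed = as.integer(seed)),
            class = "ganpop_generator")
}

# conv followed by optional instance norm; cache carries both stages
unit_forward <- function(gen, name, x) {
  cv <- conv_forward(gen$layers[[name]], x)
  inl <- gen$layers[[paste0("in_", name)]]
  if (is.null(inl)) list(y = cv$y, cv = cv, nc = NULL)
  else { nc <- in_forward(inl, cv$y); list(y = nc$y, cv = cv, nc = nc) }
}

unit_backward <- function(gen, name, cache, dy, grads) {
  inl <- gen$layers[[paste0("in_", name)]]
  if (!is.null(inl)) {
    bn <- in_backward(inl, cache$nc, dy)
    grads[[paste0("in_", name)]] <- bn
    dy <- bn$dx
  }
  g <- conv_backward(gen$layers[[name]], cache$cv, dy)
  grads[[name]] <- g
  list(dx = g$dx, grads = grads)
}

res_forward <- function(gen, l, f) {
  u1 <- unit_forward(gen, paste0("res1_", l), f)
  a1 <- lrelu_forward(u1$y)
  u2 <- unit_forward(gen, paste0("res2_", l), a1$y)
  s <- if (gen$short_skips) f + u2$y else u2$y
  a2 <- lrelu_forward(s)
  list(y = a2$y, u1 = u1, a1 = a1, u2 = u2, a2 = a2)
}

res_backward <- function(gen, l, rc, dy, grads) {
  d_s <- lrelu_backward(rc$a2, dy)
  b2 <- unit_backward(gen, paste0("res2_", l), rc$u2, d_s, grads)
  d_a1 <- lrelu_backward(rc$a1, b2$dx)
  b1 <- unit_backward(gen, paste0("res1_", l), rc$u1, d_a1, b2$grads)
  d_f <- b1$dx
  if (gen$short_skips) d_f <- d_f + d_s
  list(d_f = d_f, grads = b1$grads)
}

generator_forward <- function(gen, x, keep = FALSE) {
  L <- gen$levels; ly <- gen$layers
  st <- unit_forward(gen, "stem", x)
  ast <- lrelu_forward(st$y)
  enc_feats <- vector("list", L + 1)
  enc_feats[[1]] <- ast$y
  dn <- adn <- rb <- vector("list", L)
  f <- ast$y
  for (l in seq_len(L)) {
    dn[[l]] <- unit_forward(gen, paste0("down_", l), f)
    adn[[l]] <- lrelu_forward(dn[[l]]$y)
    rb[[l]] <- res_forward(gen, l, adn[[l]]$y)
    f <- rb[[l]]$y
    enc_feats[[l + 1]] <- f
  }
  cu <- au <- cf <- af <- vector("list", L)
  for (l in rev(seq_len(L))) {
    upin <- upsample2_forward(f)
    cu[[l]] <- unit_forward(gen, paste0("up_", l), upin)
    au[[l]] <- lrelu_forward(cu[[l]]$y)
    cat_in <- if (gen$long_skips) concat3(au[[l]]$y, enc_feats[[l]]) else au[[l]]$y
    cf[[l]] <- unit_forward(gen, paste0("fuse_", l), cat_in)
    af[[l]] <- lrelu_forward(cf[[l]]$y)
    f <- af[[l]]$y
  }
  hd <- conv_forward(ly$head, f)
  th <- tanh_forward(hd$y)
  out <- list(out = th$y)
  if (keep) {
    out$cache <- list(st = st, ast = ast, dn = dn, adn = adn, rb = rb,
                      cu = cu, au = au, cf = cf, af = af, hd = hd, th = th,
                      enc = enc_feats)
  }
  out
}

generator_backward <- function(gen, cache, d_out) {
  L <- gen$levels; ly <- gen$layers
  grads <- list()
  dh <- tanh_backward(cache$th, d_out)
  g_head <- conv_backward(ly$head, cache$hd, dh)
  grads$head <- g_head
  d_f <- g_head$dx
  d_enc <- vector("list", L + 1)  # long-skip gradients into encoder features
  for (l in seq_len(L)) {  # reverse of the decoding order (which ran L..1)
    d_afy <- lrelu_backward(cache$af[[l]], d_f)
    bf <- unit_backward(gen, paste0("fuse_", l), cache$cf[[l]], d_afy, grads)
    grads <- bf$grads
    chl <- gen$channels[l]
    if (gen$long_skips) {
      d_au <- bf$dx[, , seq_len(chl), drop = FALSE]
      d_enc[[l]] <- bf$dx[, , chl + seq_len(chl), drop = FALSE]
    } else {
      d_au <- bf$dx
    }
    d_cuy <- lrelu_backward(cache$au[[l]], d_au)
    bu <- unit_backward(gen, paste0("up_", l), cache$cu[[l]], d_cuy, grads)
    grads <- bu$grads
    d_f <- upsample2_backward(bu$dx)
  }
  d_feat <- d_f  # gradient wrt the deepest encoder feature
  for (l in rev(seq_len(L))) {
    rbk <- res_backward(gen, l, cache$rb[[l]], d_feat, grads)
    grads <- rbk$grads
    d_dny <- lrelu_backward(cache$adn[[l]], rbk$d_f)
    bd <- unit_backward(gen, paste0("down_", l), cache$dn[[l]], d_dny, grads)
    grads <- bd$grads
    d_feat <- bd$dx
    if (!is.null(d_enc[[l]])) d_feat <- d_feat + d_enc[[l]]
  }
  d_sty <- lrelu_backward(cache$ast, d_feat)
  bs <- unit_backward(gen, "stem", cache$st, d_sty, grads)
  grads <- bs$grads
  grads
}

#' Build the patch discriminator
#'
#' Three stacked convolution-classifier layers with leaky ReLUs
#' (slope 0.2): two stride-2 stages then a 1-channel score head, producing
#' a patch score map for a concatenated (input, candidate map) 6-channel
#' pair. All layers are spectrally normalised (one power iteration per
#' forward pass); weights are N(0, 0.02^2) under the seed.
#'
#' @param size Input spatial size; power of two >= 32.
#' @param base_channels First-layer channel count.
#' @param seed Integer seed.
#' @param lrelu_slope Leaky-ReLU negative slope.
#' @param spectral_norm Toggle spectral normalisation.
#' @return A `ganpop_discriminator`.
#' @export
build_discriminator <- function(size = 256, base_channels = 16, seed = 1L,
                                lrelu_slope = 0.2, spectral_norm = TRUE) {
  if (!is_pow2(size) || size < 32) {
    stop("`size` must be a power of two >= 32", call. = FALSE)
  }
  rng <- local_rng(seed)
  layers <- list(
    d1 = new_conv_layer("d1", 4, 6, base_channels, stride = 2, pad = 1,
                        rng = rng, spectral_norm = spectral_norm),
    d2 = new_conv_layer("d2", 4, base_channels, 2 * base_channels,
                        stride = 2, pad = 1, rng = rng,
                        spectral_norm = spectral_norm),
    d3 = new_conv_layer("d3", 4, 2 * base_channels, 1, stride = 1, pad = 1,
                        rng = rng, spectral_norm = spectral_norm)
  )
  structure(list(size = size, layers = layers, slope = lrelu_slope,
                 seed = as.integer(seed)),
            class = "ganpop_discriminator")
}

disc_forward <- function(disc, xy, keep = FALSE) {
  ly <- disc$layers
  c1 <- conv_forward(ly$d1, xy); a1 <- lrelu_forward(c1$y, disc$slope)
  c2 <- conv_forward(ly$d2, a1$y); a2 <- lrelu_forward(c2$y, disc$slope)
  c3 <- conv_forward(ly$d3, a2$y)
  out <- list(scores = c3$y)
  if (keep) out$cache <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3)
  out
}

disc_backward <- function(disc, cache, d_scores) {
  ly <- disc$layers
  g3 <- conv_backward(ly$d3, cache$c3, d_scores)
  d_a2 <- lrelu_backward(cache$a2, g3$dx)
  g2 <- conv_backward(ly$d2, cache$c2, d_a2)
  d_a1 <- lrelu_backward(cache$a1, g2$dx)
  g1 <- conv_backward(ly$d1, cache$c1, d_a1)
  list(grads = list(d1 = g1, d2 = g2, d3 = g3), d_input = g1$dx)
}

apply_grads <- function(net, grads, lr) {
  for (nm in names(grads)) {
    net$layers[[nm]] <- adam_step(net$layers[[nm]], grads[[nm]]$dw,
                                  grads[[nm]]$db, lr)
    if (isTRUE(net$layers[[nm]]$sn)) {
      # persist the power iteration so u tracks the leading singular vector
      net$layers[[nm]]$u <- sn_weight(net$layers[[nm]])$u
    }
  }
  net
}

# ---- losses ----------------------------------------------------------------

#' Least-squares adversarial loss
#'
#' LSGAN objective with real label 1 and fake label 0:
#' discriminator side `mean((d_real - 1)^2) + mean(d_fake^2)`, generator
#' side `mean((d_fake - 1)^2)`.
#'
#' @param d_real_scores,d_fake_scores Discriminator patch score maps
#'   (numeric arrays); `d_real_scores` is ignored on the generator side.
#' @param side `"discriminator"` or `"generator"`.
#' @return A non-negative scalar.
#' @export
adversarial_loss <- function(d_real_scores, d_fake_scores,
                             side = c("discriminator", "generator")) {
  side <- match.arg(side)
  if ((side == "discriminator" && any(!is.finite(d_real_scores))) ||
      any(!is.finite(d_fake_scores))) {
    stop("non-finite discriminator scores", call. = FALSE)
  }
  if (side == "discriminator") {
    mean((d_real_scores - 1)^2) + mean(d_fake_scores^2)
  } else {
    mean((d_fake_scores - 1)^2)
  }
}

#' Mean absolute (L1) image distance
#'
#' @param truth,generated Numeric arrays of identical shape.
#' @return Mean absolute pixel difference; 0 iff identical.
#' @export
l1_loss <- function(truth, generated) {
  if (!identical(dim(truth), dim(generated))) {
    stop("image shapes differ", call. = FALSE)
  }
  mean(abs(truth - generated))
}

#' Total generator objective
#'
#' `adv + lambda_l1 * l1`: the adversarial term plus the L1 regulariser
#' weighted by lambda (60 in all experiments by default).
#'
#' @param adv,l1 Loss components (finite scalars).
#' @param lambda_l1 Non-negative regularisation weight.
#' @return The combined scalar loss.
#' @export
total_generator_loss <- function(adv, l1, lambda_l1 = 60) {
  stopifnot(is.finite(adv), is.finite(l1), lambda_l1 >= 0)
  adv + lambda_l1 * l1
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference protocol: 200 epochs, Adam at learning
#' rate 1e-4 held constant for the first half of training then linearly
#' decayed to zero, L1 weight lambda = 60, N(0, 0.02^2) weight
#' initialisation, history buffer of 64 generated pairs, batch size 1.
#'
#' @param epochs Total epochs (must be even, for the half-way decay).
#' @param lr Adam learning rate.
#' @param lambda_l1 L1 regularisation weight.
#' @param base_channels Generator/discriminator base channel count.
#' @param seed Master seed: weight init, data order, history sampling.
#' @param history_capacity History buffer capacity.
#' @param sn_generator Spectrally normalise the generator too.
#' @param normalise_input Stretch input images by one dataset-level
#'   constant (the training split's maximum intensity) so the fringe
#'   signal uses the full network input range; the constant is stored in
#'   the fit and re-applied at prediction. Images are normalised to a
#'   consistent representation on the 8-bit scale, as is conventional for
#'   convolutional networks.
#' @param val_every Compute validation L1 every this many epochs.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200, lr = 1e-4, lambda_l1 = 60,
                         base_channels = 16, seed = 1L,
                         history_capacity = 64, sn_generator = FALSE,
                         normalise_input = TRUE, val_every = 1) {
  stopifnot(epochs >= 2, epochs %% 2 == 0, lr > 0, lambda_l1 >= 0,
            history_capacity >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 lambda_l1 = lambda_l1, base_channels = base_channels,
                 seed = as.integer(seed),
                 history_capacity = as.integer(history_capacity),
                 sn_generator = isTRUE(sn_generator),
                 normalise_input = isTRUE(normalise_input),
                 val_every = as.integer(val_every)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Constant at `lr` for the first half of training, then linear decay
#' reaching 0 at the final epoch.
#'
#' @param epoch Epoch number (1-based).
#' @param config A `train_config`.
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  E <- config$epochs
  config$lr * min(1, (E - epoch) / (E - E / 2))
}

sample_to_xy <- function(sample, input_scale = 1) {
  halves <- unpair_sample(sample)
  x <- pmin(halves$input / 255 / input_scale, 1)
  list(x = x * 2 - 1, y = halves$truth / 255 * 2 - 1)
}

#' Train the conditional GAN
#'
#' Alternating discriminator/generator updates with the least-squares
#' adversarial objective plus lambda-weighted L1. Each discriminator step
#' sees the current (input, truth) and (input, generated) pairs plus a
#' pair sampled uniformly from the history buffer of previously generated
#' pairs (capacity 64; a random slot is replaced once full). Fully
#' reproducible from the config seed.
#'
#' @param samples List of `paired_sample`s (e.g. from [render_dataset()]).
#' @param manifest Manifest with a filled `split` column
#'   (see [split_dataset()]); rows align with `samples`.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A `ganpop_fit`: generator, discriminator, config, per-epoch
#'   loss history tibble (`epoch`, `lr`, `d_loss`, `g_adv`, `g_l1`,
#'   `g_total`, `val_l1`) and a `diverged` flag.
#' @export
train_ganpop <- function(samples, manifest, config = train_config(),
                         verbose = FALSE) {
  stopifnot(length(samples) == nrow(manifest))
  idx_train <- which(manifest$split == "train")
  idx_val <- which(manifest$split == "val")
  if (length(idx_train) == 0) stop("empty training split", call. = FALSE)
  size <- dim(samples[[1]]$pixels)[1]
  input_scale <- 1
  if (isTRUE(config$normalise_input)) {
    input_scale <- max(vapply(idx_train, function(i) {
      max(unpair_sample(samples[[i]])$input)
    }, numeric(1))) / 255
    if (input_scale <= 0) input_scale <- 1
  }
  gen <- build_generator(size, config$base_channels,
                         seed = config$seed * 2L + 1L,
                         spectral_norm = config$sn_generator)
  disc <- build_discriminator(size, config$base_channels,
                              seed = config$seed * 2L + 2L)
  rng <- local_rng(config$seed)
  history <- vector("list", 0)
  hist_rows <- vector("list", config$epochs)
  lam <- config$lambda_l1
  diverged <- FALSE
  val_l1 <- function() {
    if (length(idx_val) == 0) return(NA_real_)
    mean(vapply(idx_val, function(i) {
      xy <- sample_to_xy(samples[[i]], input_scale)
      l1_loss(xy$y, generator_forward(gen, xy$x)$out)
    }, numeric(1)))
  }
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    order <- rng$sample(idx_train, length(idx_train))
    dl <- ga <- gl <- numeric(length(order))
    for (k in seq_along(order)) {
      xy <- sample_to_xy(samples[[order[k]]], input_scale)
      gf <- generator_forward(gen, xy$x, keep = TRUE)
      fake <- gf$out
      # --- discriminator step ---
      f_real <- disc_forward(disc, concat3(xy$x, xy$y), keep = TRUE)
      f_fake <- disc_forward(disc, concat3(xy$x, fake), keep = TRUE)
      use_hist <- length(history) > 0
      if (use_hist) {
        h <- history[[rng$sample(length(history), 1)]]
        f_hist <- disc_forward(disc, concat3(h$x, h$fake), keep = TRUE)
        d_loss <- mean((f_real$scores - 1)^2) +
          0.5 * (mean(f_fake$scores^2) + mean(f_hist$scores^2))
        if (!is.finite(d_loss)) stop("non-finite discriminator scores",
                                     call. = FALSE)
      } else {
        d_loss <- adversarial_loss(f_real$scores, f_fake$scores,
                                   side = "discriminator")
      }
      n_s <- length(f_real$scores)
      w_fake <- if (use_hist) 0.5 else 1
      b_real <- disc_backward(disc, f_real$cache,
                              2 * (f_real$scores - 1) / n_s)
      b_fake <- disc_backward(disc, f_fake$cache,
                              2 * w_fake * f_fake$scores / n_s)
      g_d <- purrr::map2(b_real$grads, b_fake$grads, function(a, b) {
        list(dw = a$dw + b$dw, db = a$db + b$db)
      })
      if (use_hist) {
        b_hist <- disc_backward(disc, f_hist$cache,
                                2 * w_fake * f_hist$scores / n_s)
        g_d <- purrr::map2(g_d, b_hist$grads, function(a, b) {
          list(dw = a$dw + b$dw, db = a$db + b$db)
        })
      }
      disc <- apply_grads(disc, g_d, lr)
      # update the history buffer with the detached fake
      entry <- list(x = xy$x, fake = fake)
      if (length(history) < config$history_capacity) {
        history[[length(history) + 1]] <- entry
      } else {
        history[[rng$sample(config$history_capacity, 1)]] <- entry
      }
      # --- generator step ---
      f_fake2 <- disc_forward(disc, concat3(xy$x, fake), keep = TRUE)
      adv <- adversarial_loss(NULL, f_fake2$scores, side = "generator")
      l1 <- l1_loss(xy$y, fake)
      b_adv <- disc_backward(disc, f_fake2$cache,
                             2 * (f_fake2$scores - 1) / length(f_fake2$scores))
      d_fake <- b_adv$d_input[, , 4:6, drop = FALSE] +
        lam * sign(fake - xy$y) / length(fake)
      g_g <- generator_backward(gen, gf$cache, d_fake)
      gen <- apply_grads(gen, g_g, lr)
      dl[k] <- d_loss; ga[k] <- adv; gl[k] <- l1
      if (!all(is.finite(c(d_loss, adv, l1)))) {
        warning("divergent loss at epoch ", epoch,
                "; aborting with last stable state")
        diverged <- TRUE
        break
      }
    }
    v <- if (epoch %% config$val_every == 0 || epoch == 1 ||
             epoch == config$epochs) val_l1() else NA_real_
    hist_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, d_loss = mean(dl), g_adv = mean(ga),
      g_l1 = mean(gl), g_total = mean(ga) + lam * mean(gl), val_l1 = v)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  D %.4f  G_adv %.4f  L1 %.4f  val %.4f",
                      epoch, lr, mean(dl), mean(ga), mean(gl), v))
    }
    if (diverged) break
  }
  structure(list(generator = gen, discriminator = disc, config = config,
                 input_scale = input_scale,
                 loss_history = dplyr::bind_rows(hist_rows),
                 n_train = length(idx_train), n_val = length(idx_val),
                 diverged = diverged),
            class = "ganpop_fit")
}

#' Predict an optical-property map from a fringe image
#'
#' Runs the trained generator on a single fringe-illuminated image and
#' returns the 8-bit 3-channel map (R = absorption colour, G = scattering
#' colour). Deterministic: no stochastic layers at inference.
#'
#' @param object A `ganpop_fit`.
#' @param input An `sfdi_image`, a `paired_sample` (its left half is
#'   used), or an 8-bit integer array `H x W x 3`.
#' @param ... Unused.
#' @return An integer array `H x W x 3` of 8-bit values.
#' @export
predict.ganpop_fit <- function(object, input, ...) {
  x8 <- if (inherits(input, "sfdi_image")) {
    floor(pmin(pmax(input$pixels, 0), 1) * 255 + 0.5)
  } else if (inherits(input, "paired_sample")) {
    unpair_sample(input)$input
  } else input
  d <- dim(x8)
  if (length(d) != 3 || d[3] != 3 || d[1] != object$generator$size) {
    stop("input size does not match the generator (", object$generator$size,
         ")", call. = FALSE)
  }
  sc <- object$input_scale %||% 1
  x <- pmin(x8 / 255 / sc, 1) * 2 - 1
  out <- generator_forward(object$generator, x)$out
  array(as.integer(floor((out + 1) / 2 * 255 + 0.5)), dim = d)
}
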