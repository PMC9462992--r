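# Two-stage optimization. Stage 1 trains the shared encoder and the
# segmentation + heatmap decoders on standard-plane images with the
# uncertainty-weighted total loss; stage 2 loads the encoder from the
# stage-1 checkpoint (frozen by default) and trains the classification head
# with cross-entropy on standard + nonstandard images.

#' Training configuration
#'
#' @param lr0 initial learning rate of the adaptive-moment optimizer (1e-4).
#' @param step_size,gamma step scheduler: the rate decays by `gamma` every
#'   `step_size` epochs.
#' @param epochs training epochs (200 clinically; reducible).
#' @param batch_size images per step (2).
#' @param seed master seed; every stochastic draw in a run derives from it.
#' @param augment apply random rotation/scaling during stage 1.
#' @param sigma heatmap Gaussian width, px.
#' @param n_triplets Monte-Carlo triplets per step for the shape loss.
#' @param slf_class mask class constrained to be convex (2 = fetal head).
#' @param w1 fixed mixing weight of the total loss.
#' @param delta per-heatmap MSE weights.
#' @param learn_uncertainty optimize the log-variance scalings of the total
#'   loss (else frozen at 0).
#' @param freeze_encoder_stage2 keep the shared encoder fixed in stage 2.
#' @export
train_config <- function(lr0 = 1e-4, step_size = 20, gamma = 0.1,
                         epochs = 200, batch_size = 2, seed = 1L,
                         augment = TRUE, sigma = 6, n_triplets = 128L,
                         slf_class = 2L, w1 = 0.5, delta = c(1.0, 0.8, 0.6),
                         learn_uncertainty = TRUE,
                         freeze_encoder_stage2 = TRUE) {
  stopifnot(lr0 > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr0 = lr0, step_size = step_size, gamma = gamma,
                 epochs = epochs, batch_size = batch_size,
                 seed = as.integer(seed), augment = augment, sigma = sigma,
                 n_triplets = as.integer(n_triplets),
                 slf_class = as.integer(slf_class), w1 = w1, delta = delta,
                 learn_uncertainty = learn_uncertainty,
                 freeze_encoder_stage2 = freeze_encoder_stage2),
            class = "train_config")
}

#' Step learning-rate schedule
#'
#' Closed form \eqn{lr_0 \cdot \gamma^{\lfloor (epoch-1)/step \rfloor}}
#' (epochs are 1-based): epochs 1-20 run at 1e-4, 21-40 at 1e-5, and so on
#' with the defaults.
#'
#' @param epoch 1-based epoch index.
#' @param config a [train_config()].
#' @export
lr_schedule <- function(epoch, config) {
  config$lr0 * config$gamma^((epoch - 1) %/% config$step_size)
}

# One Adam update over all trainable parameters with pending gradients.
adam_step <- function(params, lr, t, include = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in ls(params)) {
    p <- params[[nm]]
    if (!p$trainable || is.null(p$grad)) next
    if (!is.null(include) && !any(startsWith(nm, include))) {
      p$grad <- NULL; params[[nm]] <- p; next
    }
    if (is.null(p$m)) { p$m <- p$value * 0; p$v <- p$value * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
    params[[nm]] <- p
  }
  invisible(params)
}

# Assemble a batch from sample lists (optionally augmented in-place).
assemble_batch <- function(samples, do_augment = FALSE) {
  if (do_augment) samples <- lapply(samples, augment)
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  B <- length(samples)
  x <- array(0, c(H, W, 1, B))
  masks <- array(0L, c(H, W, B))
  y1h <- array(0, c(H, W, 3, B))
  hm <- array(0, c(H, W, 3, B))
  labels <- integer(B)
  for (b in seq_len(B)) {
    s <- samples[[b]]
    x[, , 1, b] <- s$image
    labels[b] <- s$class_label
    if (!is.null(s$mask)) {
      masks[, , b] <- s$mask
      for (k in 0:2) y1h[, , k + 1, b] <- (s$mask == k)
    }
    if (!is.null(s$endpoints)) {
      hm[, , , b] <- if (!is.null(s$heatmaps)) s$heatmaps else
        make_heatmaps(s$endpoints$left, s$endpoints$right, c(H, W), s$sigma)
    }
  }
  list(x = x, masks = masks, y1h = y1h, heatmaps = hm, labels = labels)
}

stage1_losses_numeric <- function(out, batch, cfg, seed) {
  fg <- c(2, 3)
  ld <- dice_loss(batch$y1h[, , fg, , drop = FALSE],
                  out$seg_probs[, , fg, , drop = FALSE])
  lsc <- 0; n_used <- 0
  if (cfg$n_triplets >= 1) for (b in seq_len(dim(batch$x)[4])) {
    v <- shape_constrained_loss(batch$masks[, , b],
                                out$seg_probs[, , cfg$slf_class + 1, b],
                                class_id = cfg$slf_class,
                                n_triplets = cfg$n_triplets,
                                seed = derive_seed(seed, b))
    if (sum(batch$masks[, , b] == cfg$slf_class) >= 2) {
      lsc <- lsc + v; n_used <- n_used + 1
    }
  }
  lsc <- if (n_used) lsc / n_used else 0
  lmse <- mse_heatmap_loss(out$heatmaps, batch$heatmaps, cfg$delta)
  c(dice = ld, slf = lsc, mse = lmse)
}

#' Stage-1 training: encoder + segmentation + heatmap decoders
#'
#' Optimizes the total loss on standard-plane samples with Adam and the
#' step schedule; the best-validation-loss parameters are kept and
#' optionally checkpointed with the RNG state.
#'
#' @param model an [mtunet()].
#' @param train_samples,val_samples sample lists from standard-plane images
#'   (see the manifest loader); training aborts if a nonstandard sample is
#'   present.
#' @param config a [train_config()].
#' @param checkpoint_path optional path for the best checkpoint.
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `log` (tibble: epoch, lr,
#'   per-loss components, validation loss) and `best_epoch`.
#' @export
train_stage1 <- function(model, train_samples, val_samples, config,
                         checkpoint_path = NULL, verbose = FALSE) {
  if (!length(train_samples)) stop("empty training set")
  if (any(vapply(train_samples, function(s) s$class_label, 0L) != 1L))
    stop("stage 1 uses standard-plane samples only")
  n <- length(train_samples)
  logs <- vector("list", config$epochs)
  best <- Inf; best_model <- mtunet_clone(model); best_epoch <- NA_integer_
  for (nm in c("loss.s1", "loss.s2")) {
    p <- model$params[[nm]]; p$trainable <- config$learn_uncertainty
    model$params[[nm]] <- p
  }
  t_adam <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    set.seed(derive_seed(config$seed, epoch))
    ord <- sample.int(n)
    comp <- c(dice = 0, slf = 0, mse = 0); tot <- 0; nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      batch <- assemble_batch(train_samples[idx], do_augment = config$augment)
      fw <- mtunet_forward(model, batch$x, train = TRUE,
                           tasks = c("task2", "task3"))
      tp <- fw$tape
      ld <- op_dice_loss(tp, fw$ids$seg_probs, batch$y1h)
      lsc <- op_slf(tp, fw$ids$seg_probs, batch$masks,
                    class_id = config$slf_class, channel = config$slf_class + 1,
                    n_triplets = config$n_triplets)
      lmse <- op_mse_heatmap(tp, fw$ids$heatmaps, batch$heatmaps, config$delta)
      ltot <- op_total_loss(tp, ld, lsc, lmse, w1 = config$w1)
      val <- tp_value(tp, ltot)
      if (!is.finite(val))
        stop(sprintf("non-finite loss at epoch %d (dice=%.4g slf=%.4g mse=%.4g)",
                     epoch, tp_value(tp, ld), tp_value(tp, lsc), tp_value(tp, lmse)))
      tape_backward(tp, ltot)
      t_adam <- t_adam + 1L
      adam_step(model$params, lr, t_adam)
      comp <- comp + c(tp_value(tp, ld), tp_value(tp, lsc), tp_value(tp, lmse))
      tot <- tot + val; nb <- nb + 1
    }
    vl <- validate_stage1(model, val_samples, config, epoch)
    logs[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss_total = tot / nb,
      loss_dice = comp[1] / nb, loss_slf = comp[2] / nb,
      loss_mse = comp[3] / nb, val_total = vl)
    if (verbose)
      message(sprintf("epoch %3d  lr %.1e  train %.4f  val %.4f",
                      epoch, lr, tot / nb, vl))
    if (vl < best) {
      best <- vl; best_model <- mtunet_clone(model); best_epoch <- epoch
    }
  }
  if (!is.null(checkpoint_path)) mtunet_save(best_model, checkpoint_path)
  list(model = best_model, log = dplyr::bind_rows(logs), best_epoch = best_epoch)
}

validate_stage1 <- function(model, val_samples, config, epoch) {
  if (!length(val_samples)) return(NA_real_)
  tot <- 0; nb <- 0
  for (start in seq(1, length(val_samples), by = config$batch_size)) {
    idx <- start:min(start + config$batch_size - 1, length(val_samples))
    batch <- assemble_batch(val_samples[idx])
    fw <- mtunet_forward(model, batch$x, train = FALSE,
                         tasks = c("task2", "task3"))
    comp <- stage1_losses_numeric(fw, batch, config,
                                  seed = derive_seed(config$seed, 100000 + epoch))
    w <- loss_weights(config$w1,
                      model$params[["loss.s1"]]$value,
                      model$params[["loss.s2"]]$value, config$delta)
    tot <- tot + total_loss(comp["dice"], comp["slf"], comp["mse"], w)
    nb <- nb + 1
  }
  tot / nb
}

#' Stage-2 training: classification head on the pretrained encoder
#'
#' Loads (or reuses) the stage-1 model, freezes the shared encoder by
#' default, and trains the classification decoder with cross-entropy on
#' standard and nonstandard samples. With a frozen encoder the bottleneck
#' features are precomputed once, so only the head is iterated.
#'
#' @param model an `mtunet` from stage 1, or a checkpoint path.
#' @param train_samples,val_samples sample lists (both strata).
#' @param config a [train_config()].
#' @inheritParams train_stage1
#' @return list with `model`, `log` (epoch, lr, loss, train/val accuracy)
#'   and `best_epoch` (by validation accuracy).
#' @export
train_stage2 <- function(model, train_samples, val_samples, config,
                         checkpoint_path = NULL, verbose = FALSE) {
  if (is.character(model)) {
    if (!file.exists(model)) stop("missing stage-1 checkpoint: ", model)
    model <- mtunet_load(model)
  }
  if (!length(train_samples)) stop("empty training set")
  n <- length(train_samples)
  labels <- vapply(train_samples, function(s) s$class_label, 0L)
  frozen <- config$freeze_encoder_stage2
  include <- if (frozen) "t1." else c("t1.", "enc", "eca")
  enc_feats <- NULL
  if (frozen) {
    enc_feats <- precompute_bottlenecks(model, train_samples)
    val_feats <- precompute_bottlenecks(model, val_samples)
  }
  logs <- vector("list", config$epochs)
  best <- -Inf; best_model <- mtunet_clone(model); best_epoch <- NA_integer_
  t_adam <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    set.seed(derive_seed(config$seed, 200000 + epoch))
    ord <- sample.int(n)
    tot <- 0; nb <- 0; correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      if (frozen) {
        xb <- abind4(enc_feats[idx])
        fw <- mtunet_forward_task1(model, xb, train = TRUE)
      } else {
        batch <- assemble_batch(train_samples[idx])
        fw <- mtunet_forward(model, batch$x, train = TRUE, tasks = "task1")
      }
      tp <- fw$tape
      lce <- op_ce(tp, fw$ids$class_probs, labels[idx])
      val <- tp_value(tp, lce)
      if (!is.finite(val)) stop("non-finite classification loss at epoch ", epoch)
      tape_backward(tp, lce)
      t_adam <- t_adam + 1L
      adam_step(model$params, lr, t_adam, include = include)
      pred <- apply(fw$class_probs, 2, which.max) - 1L
      correct <- correct + sum(pred == labels[idx])
      tot <- tot + val; nb <- nb + 1
    }
    vacc <- if (frozen) stage2_accuracy_cached(model, val_feats, val_samples)
            else stage2_accuracy(model, val_samples, config)
    logs[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                    loss_ce = tot / nb,
                                    train_acc = correct / n, val_acc = vacc)
    if (verbose)
      message(sprintf("epoch %3d  ce %.4f  train acc %.3f  val acc %.3f",
                      epoch, tot / nb, correct / n, vacc))
    if (is.finite(vacc) && vacc > best) {
      best <- vacc; best_model <- mtunet_clone(model); best_epoch <- epoch
    }
  }
  if (!is.finite(best)) best_model <- mtunet_clone(model)
  if (!is.null(checkpoint_path)) mtunet_save(best_model, checkpoint_path)
  list(model = best_model, log = dplyr::bind_rows(logs), best_epoch = best_epoch)
}

abind4 <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

precompute_bottlenecks <- function(model, samples, chunk = 8L) {
  if (!length(samples)) return(list())
  out <- vector("list", length(samples))
  for (start in seq(1, length(samples), by = chunk)) {
    idx <- start:min(start + chunk - 1, length(samples))
    batch <- assemble_batch(samples[idx])
    fw <- mtunet_forward(model, batch$x, train = FALSE, tasks = character(0))
    bv <- tp_value(fw$tape, fw$ids$bottleneck)
    for (k in seq_along(idx))
      out[[idx[k]]] <- bv[, , , k, drop = FALSE]
  }
  out
}

stage2_accuracy_cached <- function(model, feats, samples) {
  if (!length(samples)) return(NA_real_)
  labels <- vapply(samples, function(s) s$class_label, 0L)
  fw <- mtunet_forward_task1(model, abind4(feats), train = FALSE)
  mean((apply(fw$class_probs, 2, which.max) - 1L) == labels)
}

stage2_accuracy <- function(model, samples, config) {
  if (!length(samples)) return(NA_real_)
  labels <- vapply(samples, function(s) s$class_label, 0L)
  correct <- 0
  for (start in seq(1, length(samples), by = 8L)) {
    idx <- start:min(start + 7L, length(samples))
    batch <- assemble_batch(samples[idx])
    fw <- mtunet_forward(model, batch$x, train = FALSE, tasks = "task1")
    correct <- correct + sum((apply(fw$class_probs, 2, which.max) - 1L) == labels[idx])
  }
  correct / length(samples)
}

#' Run the full inference path on one raw image
#'
#' Classifies the plane; on a standard plane, segments, decodes the PS
#' endpoints from the heatmaps, maps everything back to original pixel
#' coordinates and measures the AoP from the fitted fetal-head ellipse. On
#' a nonstandard prediction the measurement is skipped and flagged.
#'
#' @param model a trained `mtunet`.
#' @param image_raw grayscale matrix in [0, 255].
#' @param target_size network input size (defaults to the model config).
#' @param rule tangent selection rule.
#' @return list with `is_standard`, `class_probs`, `seg_mask` (network
#'   resolution), `endpoints` (original coordinates), `spatial_map` and
#'   `aop` (an `aop_result`, or NULL when skipped).
#' @export
predict_aop <- function(model, image_raw, target_size = NULL,
                        rule = "max-angle") {
  if (is.null(target_size)) target_size <- model$config$input_size
  pp <- preprocess(image_raw, target_size)
  x <- array(pp$image, c(dim(pp$image), 1, 1))
  fw <- mtunet_forward(model, x, train = FALSE)
  probs <- fw$class_probs[, 1]
  is_std <- which.max(probs) == 2L
  seg <- apply(fw$seg_probs[, , , 1], c(1, 2), which.max) - 1L
  ep <- tryCatch(extract_endpoints(fw$heatmaps[, , , 1], pp$spatial_map),
                 error = function(e) NULL)
  aop <- NULL
  if (is_std) {
    aop <- if (is.null(ep)) {
      structure(list(left_endpoint = NULL, right_endpoint = NULL,
                     tangent_point = NULL, aop_deg = NA_real_, ellipse = NULL,
                     valid = FALSE, reason = "endpoint detection failed"),
                class = "aop_result")
    } else {
      measure_aop_mapped(seg, ep$left, ep$right, pp$spatial_map, rule)
    }
  }
  list(is_standard = is_std, class_probs = probs, seg_mask = seg,
       endpoints = ep, spatial_map = pp$spatial_map, aop = aop)
}

# Measure with the mask at network resolution but the geometry (fit,
# tangent, angle) carried out in original-image coordinates.
measure_aop_mapped <- function(seg_mask, left, right, map, rule = "max-angle") {
  fail <- function(reason) structure(
    list(left_endpoint = left, right_endpoint = right, tangent_point = NULL,
         aop_deg = NA_real_, ellipse = NULL, valid = FALSE, reason = reason),
    class = "aop_result")
  bnd <- tryCatch(mask_boundary(seg_mask, 2), error = function(e) NULL)
  if (is.null(bnd)) return(fail("no FH region"))
  bnd <- sm_apply(map, bnd, inverse = TRUE)
  e <- tryCatch(fit_ellipse_raster(bnd), error = function(e) NULL)
  if (is.null(e)) return(fail("ellipse fit failed"))
  tps <- tryCatch(tangent_points(e, right), error = function(e) NULL)
  if (is.null(tps)) return(fail("no tangent"))
  res <- tryCatch({
    tp <- select_tangent(tps, left, right, rule)
    list(tp = tp, aop = compute_aop(left, right, tp))
  }, error = function(e) NULL)
  if (is.null(res)) return(fail("degenerate key points"))
  structure(
    list(left_endpoint = as.numeric(left), right_endpoint = as.numeric(right),
         tangent_point = res$tp, aop_deg = res$aop,
         ellipse = e, valid = TRUE, reason = NA_character_),
    class = "aop_result")
}
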