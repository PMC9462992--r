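# Training objectives: binary cross-entropy, pooled foreground Dice loss,
# the convex shape-constrained loss (exhaustive and seeded Monte-Carlo
# forms), weighted heatmap MSE, and the uncertainty-weighted total loss.
#
# The public functions here are plain numeric; op_* counterparts at the
# bottom build the same quantities on the autodiff tape for training.

#' Loss weights for the total objective
#'
#' @param w1 fixed mixing weight between the segmentation pair and the
#'   heatmap loss (0.5).
#' @param s1,s2 log-variance parameters of the homoscedastic-uncertainty
#'   weighting; the effective scalings are `theta_i = exp(-s_i)` and each
#'   learnable `s_i` contributes a `s_i/2` regularizer. Frozen at 0 the
#'   total reduces to `w1 (L_D + L_SC) + (1 - w1) L_MSE`.
#' @param delta per-heatmap MSE weights (right endpoint, left endpoint,
#'   midpoint) in order of importance.
#' @export
loss_weights <- function(w1 = 0.5, s1 = 0, s2 = 0, delta = c(1.0, 0.8, 0.6)) {
  stopifnot(w1 >= 0, w1 <= 1, all(delta > 0))
  list(w1 = w1, s1 = s1, s2 = s2, delta = delta)
}

#' Binary cross-entropy
#'
#' \eqn{-y\log\hat y - (1-y)\log(1-\hat y)}, averaged over the batch, with
#' predictions clamped at 1e-7.
#'
#' @param y 0/1 labels.
#' @param yhat predicted probabilities of class 1.
#' @export
cross_entropy <- function(y, yhat) {
  eps <- 1e-7
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  mean(-y * log(yhat) - (1 - y) * log(1 - yhat))
}

#' Pooled Dice loss
#'
#' \eqn{1 - 2\sum y p / (\sum y + \sum p)} with the sums pooled over pixels
#' and the supplied (foreground) class maps. Pass only foreground channels;
#' the background is excluded by construction. The empty-empty case is 0.
#'
#' @param y one-hot ground truth array/vector.
#' @param p predicted probabilities, same shape.
#' @export
dice_loss <- function(y, p) {
  stopifnot(length(y) == length(p))
  denom <- sum(y) + sum(p)
  if (denom == 0) return(0)
  1 - 2 * sum(y * p) / denom
}

#' Weighted heatmap mean-squared-error loss
#'
#' \eqn{\sum_k \delta_k \,\mathrm{mean}_{ij}(H_k - \hat H_k)^2}; the mean
#' over pixels (and batch) makes the magnitude resolution-independent.
#'
#' @param h_pred,h_true arrays (H, W, K) or (H, W, K, N).
#' @param delta per-map weights.
#' @export
mse_heatmap_loss <- function(h_pred, h_true, delta = c(1.0, 0.8, 0.6)) {
  if (!all(dim(h_pred) == dim(h_true))) stop("heatmap shape mismatch")
  d <- dim(h_pred)
  if (length(d) == 3) { dim(h_pred) <- c(d, 1); dim(h_true) <- c(d, 1); d <- dim(h_pred) }
  stopifnot(d[3] == length(delta))
  sq <- (h_pred - h_true)^2
  per_map <- apply(sq, 3, mean)
  sum(delta * per_map)
}

# Rasterize the segment between two pixels (0-based x,y); returns the
# lattice points at t = 0..L steps, L = Chebyshev distance, incl. endpoints.
segment_pixels <- function(p, q) {
  L <- max(abs(q[1] - p[1]), abs(q[2] - p[2]))
  t <- 0:L
  cbind(round(p[1] + (q[1] - p[1]) * t / L), round(p[2] + (q[2] - p[2]) * t / L))
}

#' Convex shape-constrained segmentation loss
#'
#' For pixel pairs (p, q) inside the ground-truth region and points r on the
#' rasterized segment between them, accumulates
#' \eqn{B\,(y_p - p_p)(y_q - p_q)(p_p + p_q - 2 p_r)} where B = 1 when all
#' three ground-truth labels equal the class. A convex predicted region
#' makes the interior term small; a concave notch (depressed r between two
#' confident endpoints) is penalized. The exhaustive value is the mean over
#' ordered foreground pairs of the mean over segment points, which is
#' exactly what the seeded Monte-Carlo estimator (uniform pair, uniform
#' lattice point on the segment) estimates.
#'
#' @param y label matrix (rows = y) or binary matrix of the class.
#' @param p predicted probability map of the class, same shape.
#' @param class_id foreground class value in `y` (ignored when `y` is 0/1).
#' @param n_triplets Monte-Carlo sample size.
#' @param seed optional seed for the triplet draw.
#' @param exhaustive if TRUE, enumerate every pair (feasible only on tiny
#'   masks).
#' @return the loss estimate; with `exhaustive = TRUE` the attribute
#'   `"sum"` carries the unnormalized triple sum.
#' @export
shape_constrained_loss <- function(y, p, class_id = 1, n_triplets = 128L,
                                   seed = NULL, exhaustive = FALSE) {
  stopifnot(all(dim(y) == dim(p)))
  fg <- which(y == class_id)
  if (length(fg) < 2) return(0)
  H <- nrow(y)
  xs <- (fg - 1) %/% H; ys <- (fg - 1) %% H  # 0-based coords
  yb <- (y == class_id)
  if (exhaustive) {
    tot_mean <- 0; tot_sum <- 0; n_pairs <- 0L
    for (i in seq_along(fg)) for (j in seq_along(fg)) {
      if (i == j) next
      seg <- segment_pixels(c(xs[i], ys[i]), c(xs[j], ys[j]))
      ridx <- seg[, 2] + 1 + H * seg[, 1]
      B <- yb[ridx]
      a <- 1 - p[fg[i]]; b <- 1 - p[fg[j]]
      terms <- B * a * b * (p[fg[i]] + p[fg[j]] - 2 * p[ridx])
      tot_mean <- tot_mean + mean(terms)
      tot_sum <- tot_sum + sum(terms)
      n_pairs <- n_pairs + 1L
    }
    out <- tot_mean / n_pairs
    attr(out, "sum") <- tot_sum
    return(out)
  }
  draw <- function() {
    i <- sample.int(length(fg), n_triplets, replace = TRUE)
    j <- sample.int(length(fg), n_triplets, replace = TRUE)
    fix <- i == j
    while (any(fix)) {
      j[fix] <- sample.int(length(fg), sum(fix), replace = TRUE)
      fix <- i == j
    }
    L <- pmax(abs(xs[i] - xs[j]), abs(ys[i] - ys[j]))
    t <- floor(stats::runif(n_triplets) * (L + 1))
    t <- pmin(t, L)
    rx <- round(xs[i] + (xs[j] - xs[i]) * t / L)
    ry <- round(ys[i] + (ys[j] - ys[i]) * t / L)
    list(i = i, j = j, ridx = ry + 1 + H * rx)
  }
  tr <- if (is.null(seed)) draw() else with_seed_(seed, draw())
  B <- yb[tr$ridx]
  a <- 1 - p[fg[tr$i]]; b <- 1 - p[fg[tr$j]]
  terms <- B * a * b * (p[fg[tr$i]] + p[fg[tr$j]] - 2 * p[tr$ridx])
  out <- mean(terms)
  attr(out, "se") <- stats::sd(terms) / sqrt(length(terms))
  out
}

#' Uncertainty-weighted total loss
#'
#' \eqn{w_1(\theta_1 L_D + \theta_2 L_{SC}) + (1-w_1) L_{MSE}} with
#' \eqn{\theta_i = e^{-s_i}} plus an \eqn{s_i/2} regularizer per learnable
#' log-variance.
#'
#' @param l_d,l_sc,l_mse component losses.
#' @param weights a [loss_weights()] list.
#' @export
total_loss <- function(l_d, l_sc, l_mse, weights = loss_weights()) {
  stopifnot(is.finite(l_d), is.finite(l_sc), is.finite(l_mse))
  weights$w1 * (exp(-weights$s1) * l_d + exp(-weights$s2) * l_sc) +
    (1 - weights$w1) * l_mse + weights$s1 / 2 + weights$s2 / 2
}

# --- tape counterparts ------------------------------------------------------

# Dice loss over the foreground channels of seg probs (H,W,C,N).
op_dice_loss <- function(tp, p, y_onehot, fg_channels = c(2, 3)) {
  pv <- tp_value(tp, p)
  yf <- y_onehot[, , fg_channels, , drop = FALSE]
  pf <- pv[, , fg_channels, , drop = FALSE]
  P <- sum(yf * pf); Q <- sum(yf) + sum(pf)
  val <- if (Q == 0) 0 else 1 - 2 * P / Q
  tp_push(tp, val, parents = p, backfn = function(dy) {
    dp <- array(0, dim(pv))
    if (Q > 0) dp[, , fg_channels, ] <- -2 * (yf * Q - P) / Q^2
    list(dy * dp)
  })
}

# Monte-Carlo shape-constrained loss on one foreground channel of seg probs.
# Triplets are drawn from the current RNG stream (seed the epoch loop).
# The training form keeps only the concavity-violating (positive) triplet
# terms: the signed form rewards inflating interior predictions and, under
# optimization, degrades the segmentation it is meant to regularize. The
# exhaustive/metric form in shape_constrained_loss() stays signed.
op_slf <- function(tp, p, mask, class_id = 2, channel = 3, n_triplets = 128L) {
  if (n_triplets < 1) return(tp_push(tp, 0, parents = p,
                                     backfn = function(dy) list(NULL)))
  pv <- tp_value(tp, p)
  d <- dim(pv); H <- d[1]; Wd <- d[2]; N <- d[4]
  total <- 0; contribs <- list(); n_used <- 0L
  for (n in seq_len(N)) {
    m <- mask[, , n]
    fg <- which(m == class_id)
    if (length(fg) < 2) next
    xs <- (fg - 1) %/% H; ys <- (fg - 1) %% H
    i <- sample.int(length(fg), n_triplets, replace = TRUE)
    j <- sample.int(length(fg), n_triplets, replace = TRUE)
    fix <- i == j
    while (any(fix)) {
      j[fix] <- sample.int(length(fg), sum(fix), replace = TRUE)
      fix <- i == j
    }
    L <- pmax(abs(xs[i] - xs[j]), abs(ys[i] - ys[j]))
    t <- pmin(floor(stats::runif(n_triplets) * (L + 1)), L)
    rx <- round(xs[i] + (xs[j] - xs[i]) * t / L)
    ry <- round(ys[i] + (ys[j] - ys[i]) * t / L)
    ridx <- ry + 1 + H * rx
    B <- (m[ridx] == class_id)
    pc <- pv[, , channel, n]
    pp <- pc[fg[i]]; pq <- pc[fg[j]]; pr <- pc[ridx]
    a <- 1 - pp; b <- 1 - pq; cc <- pp + pq - 2 * pr
    B <- B & (cc > 0)  # concave-notch terms only
    total <- total + mean(B * a * b * cc)
    n_used <- n_used + 1L
    contribs[[n_used]] <- list(n = n, pidx = fg[i], qidx = fg[j], ridx = ridx,
                               B = B, a = a, b = b, cc = cc)
  }
  val <- if (n_used == 0) 0 else total / n_used
  nt <- n_triplets
  tp_push(tp, val, parents = p, backfn = function(dy) {
    dp <- array(0, dim(pv))
    if (n_used > 0) {
      sc <- dy / (n_used * nt)
      for (ct in contribs) {
        w <- sc * ct$B
        dpp <- w * (-ct$b * ct$cc + ct$a * ct$b)
        dpq <- w * (-ct$a * ct$cc + ct$a * ct$b)
        dpr <- w * (-2 * ct$a * ct$b)
        base <- (ct$n - 1) * H * Wd * d[3] + (channel - 1) * H * Wd
        for (upd in list(list(ct$pidx, dpp), list(ct$qidx, dpq),
                         list(ct$ridx, dpr))) {
          o <- rowsum(upd[[2]], upd[[1]])
          ii <- base + as.integer(rownames(o))
          dp[ii] <- dp[ii] + o[, 1]
        }
      }
    }
    list(dp)
  })
}

op_mse_heatmap <- function(tp, p, h_true, delta = c(1.0, 0.8, 0.6)) {
  pv <- tp_value(tp, p)
  d <- dim(pv)
  diff <- pv - h_true
  per_map <- apply(diff^2, 3, mean)
  val <- sum(delta * per_map)
  tp_push(tp, val, parents = p, backfn = function(dy) {
    w <- array(rep(delta, each = d[1] * d[2]), d)
    list(dy * 2 * w * diff / (d[1] * d[2] * d[4]))
  })
}

# Cross-entropy on class probabilities (2,N); row 2 = "standard".
op_ce <- function(tp, probs, labels) {
  pv <- tp_value(tp, probs)
  eps <- 1e-7
  yhat <- pmin(pmax(pv[2, ], eps), 1 - eps)
  N <- length(labels)
  val <- mean(-labels * log(yhat) - (1 - labels) * log(1 - yhat))
  tp_push(tp, val, parents = probs, backfn = function(dy) {
    dp <- matrix(0, 2, N)
    live <- pv[2, ] > eps & pv[2, ] < 1 - eps
    dp[2, live] <- dy * (-labels[live] / yhat[live] +
                           (1 - labels[live]) / (1 - yhat[live])) / N
    list(dp)
  })
}

# Total loss with learnable log-variances s1, s2 held in the param store.
op_total_loss <- function(tp, ld, lsc, lmse, w1 = 0.5,
                          s1name = "loss.s1", s2name = "loss.s2") {
  s1id <- op_param(tp, s1name); s2id <- op_param(tp, s2name)
  ldv <- tp_value(tp, ld); lscv <- tp_value(tp, lsc); lmsev <- tp_value(tp, lmse)
  s1 <- tp_value(tp, s1id); s2 <- tp_value(tp, s2id)
  val <- w1 * (exp(-s1) * ldv + exp(-s2) * lscv) + (1 - w1) * lmsev +
    s1 / 2 + s2 / 2
  tp_push(tp, val, parents = c(ld, lsc, lmse, s1id, s2id),
          backfn = function(dy) list(
            dy * w1 * exp(-s1), dy * w1 * exp(-s2), dy * (1 - w1),
            dy * (-w1 * exp(-s1) * ldv + 0.5),
            dy * (-w1 * exp(-s2) * lscv + 0.5)))
}
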