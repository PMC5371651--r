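# Shared fixtures and independent oracles.

# Dense random network in the model's operating regime (positive weights,
# no degenerate rows).
random_dim_network <- function(n, m, epsilon2 = 1e-2) {
  dim_network(matrix(runif(n * m), n, m) + 1e-3, epsilon2)
}

# Random input rescaled to fill [0, 1], as the preprocessing contract
# guarantees for real inputs.
random_x <- function(m) {
  x <- runif(m)
  x / max(x)
}

# Independent oracle: minimize the generalized KL divergence KL(x || V y)
# over y >= 0 with multi-start L-BFGS-B (no shared code with dim_solve).
oracle_kl_minimizer <- function(net, x, starts = 20L) {
  obj <- function(y) {
    r <- drop(net$V %*% pmax(y, 0))
    rf <- pmax(r, net$epsilon2)
    sum(ifelse(x > 0, x * log(x / rf), 0) - x + r)
  }
  n <- nrow(net$W)
  best <- NULL
  for (s in seq_len(starts)) {
    y0 <- runif(n, 0, 2)
    fit <- optim(y0, obj, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = 1000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pmax(best$par, 0)
}

# Independent oracle: plain-R matrix-form PC/BC-DIM iteration on dense
# block-structured weights (used to validate the convolutional solver).
oracle_matrix_iterate <- function(W, V, x, eps1, eps2, n_iter) {
  y <- rep(0, nrow(W))
  for (t in seq_len(n_iter)) {
    r <- drop(V %*% y)
    e <- x / pmax(eps2, r)
    y <- pmax(eps1, y) * drop(W %*% e)
  }
  y
}

# Dense block feedforward weights equivalent to a conv_network applied to
# an h x w image: one prediction neuron per (class, pixel), zero padding.
conv_block_W <- function(net, h, w) {
  npix <- h * w
  W <- matrix(0, net$p * npix, net$k * npix)
  for (j in seq_len(net$p)) {
    wk <- net$kernels_w[[j]]
    for (r in seq_len(h)) {       # prediction pixel
      for (cc in seq_len(w)) {
        out_idx <- (j - 1L) * npix + (cc - 1L) * h + r
        for (u in seq_len(net$kh)) {
          for (v in seq_len(net$kw)) {
            r2 <- r + u - 1L - net$anchor[1L]
            c2 <- cc + v - 1L - net$anchor[2L]
            if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w) {
              for (i in seq_len(net$k)) {
                W[out_idx, (i - 1L) * npix + (c2 - 1L) * h + r2] <- wk[u, v, i]
              }
            }
          }
        }
      }
    }
  }
  W
}

# Matching dense feedback weights, built directly from the feedback
# kernels the same way the solver applies them (R_i = sum_j v_ji * Y_j
# with the mirrored anchor).
conv_block_V <- function(net, h, w) {
  npix <- h * w
  V <- matrix(0, net$k * npix, net$p * npix)
  for (j in seq_len(net$p)) {
    vk <- net$kernels_v[[j]]
    for (r in seq_len(h)) {       # reconstruction pixel
      for (cc in seq_len(w)) {
        for (u in seq_len(net$kh)) {
          for (v in seq_len(net$kw)) {
            r2 <- r + u - 1L - net$anchor_v[1L]
            c2 <- cc + v - 1L - net$anchor_v[2L]
            if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w) {
              for (i in seq_len(net$k)) {
                V[(i - 1L) * npix + (cc - 1L) * h + r,
                  (j - 1L) * npix + (c2 - 1L) * h + r2] <- vk[u, v, i]
              }
            }
          }
        }
      }
    }
  }
  V
}

# Smooth random test patch (low-frequency, non-constant).
random_smooth_patch <- function(side, sigma = 1.5) {
  gaussian_smooth(matrix(runif(side * side), side, side), sigma)
}

# A small trained glyph classifier shared across recognizer tests (cached
# per session).
tiny_classifier <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gs <- glyph_spec(n_classes = 4L, seed = 401L)
      ds <- make_glyph_dataset(gs, 40L, 20L)
      cache <<- list(
        hierarchy = pcbc_train_classifier(ds$train$images, ds$train$labels,
                                          sigma = 4),
        data = ds)
    }
    cache
  }
})
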