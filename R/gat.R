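# Graph attention network for pKa-shift regression, implemented in R.
#
# Architecture (the "paper preset"): 3 single-head graph-attention
# convolution layers with 42 channels and ELU activations, global average
# pooling, then a dense head of 32 and 16 units (ReLU, dropout 0.2) and a
# linear output that predicts the pKa shift of the central residue. A
# single model serves acids and bases; the acid/base identity enters as a
# node feature. Forward pass, analytic backpropagation and Adam are
# written out explicitly (verified against finite differences in the test
# suite); training is seed-deterministic.

#' GAT configuration
#'
#' @param channels attention-convolution channels (42 in the preset).
#' @param conv_layers number of attention layers (3).
#' @param heads attention heads per layer (1).
#' @param hidden dense head widths (32, 16).
#' @param dropout dropout rate on the dense hidden layers during training.
#' @param leaky_slope negative slope of the attention LeakyReLU.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); ignored when no validation set is used.
#' @param tol_mse without a validation set, training stops early once the
#'   training MSE falls below this tolerance (0 = never).
#' @return object of class `gat_config`.
#' @export
gat_config <- function(channels = 42L, conv_layers = 3L, heads = 1L,
                       hidden = c(32L, 16L), dropout = 0.2,
                       leaky_slope = 0.2, lr = 1e-3, epochs = 200L,
                       patience = 20L, tol_mse = 0) {
  stopifnot(heads == 1L, conv_layers >= 1L, length(hidden) == 2L,
            dropout >= 0, dropout < 1)
  structure(list(channels = as.integer(channels),
                 conv_layers = as.integer(conv_layers), heads = 1L,
                 hidden = as.integer(hidden), dropout = dropout,
                 leaky_slope = leaky_slope, lr = lr,
                 epochs = as.integer(epochs),
                 patience = as.integer(patience), tol_mse = tol_mse),
            class = "gat_config")
}

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

gat_init_params <- function(width, config) {
  C <- config$channels
  conv <- list()
  fin <- width
  for (l in seq_len(config$conv_layers)) {
    conv[[l]] <- list(W = glorot(fin, C),
                      a_src = stats::runif(C, -sqrt(6 / (C + 1)), sqrt(6 / (C + 1))),
                      a_dst = stats::runif(C, -sqrt(6 / (C + 1)), sqrt(6 / (C + 1))),
                      b = numeric(C))
    fin <- C
  }
  h <- config$hidden
  list(conv = conv,
       mlp = list(W1 = glorot(C, h[1]), b1 = numeric(h[1]),
                  W2 = glorot(h[1], h[2]), b2 = numeric(h[2]),
                  W3 = glorot(h[2], 1L), b3 = 0))
}

# directed edge arrays with self-loops plus dense incidence matrices for
# BLAS-backed segment sums; cached on the graph by the training loop
gat_edge_index <- function(graph) {
  if (!is.null(graph$ei)) return(graph$ei)
  n <- nrow(graph$x)
  e <- graph$edges
  tgt <- c(e[, 1], e[, 2], seq_len(n))
  src <- c(e[, 2], e[, 1], seq_len(n))
  m <- length(tgt)
  Tm <- matrix(0, n, m)
  Tm[cbind(tgt, seq_len(m))] <- 1
  Sm <- matrix(0, n, m)
  Sm[cbind(src, seq_len(m))] <- 1
  list(tgt = tgt, src = src, n = n, Tm = Tm, Sm = Sm)
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1
  out[!pos] <- exp(x[!pos])
  out
}

# forward pass; returns prediction and (optionally) the cache needed for
# backprop. drop_masks: list of two 0/1-scaled masks or NULL (eval mode).
gat_forward <- function(graph, params, config, drop_masks = NULL,
                        keep_cache = FALSE) {
  ei <- gat_edge_index(graph)
  H <- graph$x
  cache <- list(layers = list(), ei = ei)
  for (l in seq_along(params$conv)) {
    p <- params$conv[[l]]
    Z <- H %*% p$W
    s <- as.numeric(Z %*% p$a_src)
    t <- as.numeric(Z %*% p$a_dst)
    e <- s[ei$tgt] + t[ei$src]
    g <- e
    gneg <- e < 0
    g[gneg] <- config$leaky_slope * e[gneg]
    w <- exp(g - max(g))
    alpha <- w / as.numeric(ei$Tm %*% w)[ei$tgt]
    agg <- ei$Tm %*% (Z[ei$src, , drop = FALSE] * alpha)
    U <- sweep(agg, 2, p$b, "+")
    Hout <- elu(U)
    if (keep_cache)
      cache$layers[[l]] <- list(H = H, Z = Z, e = e, alpha = alpha, U = U)
    H <- Hout
  }
  gvec <- colMeans(H)
  m <- params$mlp
  z1 <- as.numeric(gvec %*% m$W1) + m$b1
  h1 <- pmax(z1, 0)
  h1d <- if (is.null(drop_masks)) h1 else h1 * drop_masks[[1]]
  z2 <- as.numeric(h1d %*% m$W2) + m$b2
  h2 <- pmax(z2, 0)
  h2d <- if (is.null(drop_masks)) h2 else h2 * drop_masks[[2]]
  y <- as.numeric(h2d %*% m$W3) + m$b3
  if (keep_cache) {
    cache$Hlast <- H
    cache$mlp <- list(g = gvec, z1 = z1, h1d = h1d, z2 = z2, h2d = h2d)
    cache$drop_masks <- drop_masks
  }
  list(y = y, cache = cache)
}

# analytic gradients for one graph given dL/dy
gat_backward <- function(graph, params, config, cache, dy) {
  ei <- cache$ei
  m <- params$mlp
  mc <- cache$mlp
  dh2d <- dy * as.numeric(m$W3)
  dW3 <- matrix(mc$h2d * dy, ncol = 1)
  db3 <- dy
  dh2 <- if (is.null(cache$drop_masks)) dh2d else dh2d * cache$drop_masks[[2]]
  dz2 <- dh2 * (mc$z2 > 0)
  dW2 <- outer(mc$h1d, dz2)
  db2 <- dz2
  dh1d <- as.numeric(m$W2 %*% dz2)
  dh1 <- if (is.null(cache$drop_masks)) dh1d else dh1d * cache$drop_masks[[1]]
  dz1 <- dh1 * (mc$z1 > 0)
  dW1 <- outer(mc$g, dz1)
  db1 <- dz1
  dg <- as.numeric(m$W1 %*% dz1)

  n <- ei$n
  dH <- matrix(dg / n, n, length(dg), byrow = TRUE)
  grads_conv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    p <- params$conv[[l]]
    cl <- cache$layers[[l]]
    dU <- dH * elu_grad(cl$U)
    db <- colSums(dU)
    # aggregation backward
    dUt <- dU[ei$tgt, , drop = FALSE]
    dalpha <- rowSums(dUt * cl$Z[ei$src, , drop = FALSE])
    dZ <- ei$Sm %*% (dUt * cl$alpha)
    # softmax backward (per receiver segment)
    Ssum <- as.numeric(ei$Tm %*% (cl$alpha * dalpha))
    dgatt <- cl$alpha * (dalpha - Ssum[ei$tgt])
    lg <- rep(1, length(cl$e))
    lg[cl$e < 0] <- config$leaky_slope
    de <- dgatt * lg
    ds <- as.numeric(ei$Tm %*% de)
    dt <- as.numeric(ei$Sm %*% de)
    dZ <- dZ + outer(ds, p$a_src) + outer(dt, p$a_dst)
    da_src <- as.numeric(crossprod(cl$Z, ds))
    da_dst <- as.numeric(crossprod(cl$Z, dt))
    dW <- crossprod(cl$H, dZ)
    dH <- dZ %*% t(p$W)
    grads_conv[[l]] <- list(W = dW, a_src = da_src, a_dst = da_dst, b = db)
  }
  list(conv = grads_conv,
       mlp = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3))
}

# element-wise Adam over the nested parameter list
adam_step <- function(params, grads, state, lr, t, frozen_layers = 0L,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(params$conv)) {
    if (l <= frozen_layers) next
    for (nm in names(params$conv[[l]])) {
      r <- upd(params$conv[[l]][[nm]], grads$conv[[l]][[nm]],
               state$conv[[l]][[nm]]$m, state$conv[[l]][[nm]]$v)
      params$conv[[l]][[nm]] <- r$p
      state$conv[[l]][[nm]] <- list(m = r$m, v = r$v)
    }
  }
  for (nm in names(params$mlp)) {
    r <- upd(params$mlp[[nm]], grads$mlp[[nm]],
             state$mlp[[nm]]$m, state$mlp[[nm]]$v)
    params$mlp[[nm]] <- r$p
    state$mlp[[nm]] <- list(m = r$m, v = r$v)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zero_like <- function(p) list(m = p * 0, v = p * 0)
  list(conv = lapply(params$conv, function(l) lapply(l, zero_like)),
       mlp = lapply(params$mlp, zero_like))
}

gat_mse <- function(graphs, params, config) {
  if (length(graphs) == 0L) return(NA_real_)
  p <- vapply(graphs, function(g) gat_forward(g, params, config)$y, numeric(1))
  l <- vapply(graphs, function(g) g$label, numeric(1))
  mean((p - l)^2)
}

#' Train a pKa-shift GAT
#'
#' Minimizes MSE on the graph labels (pKa shifts) with Adam, one graph per
#' step, with optional early stopping on a held-out validation slice.
#' Fully deterministic given the seed.
#'
#' @param graphs list of labelled `residue_graph`s (consistent node
#'   feature width; acids and bases go into one model).
#' @param config a [gat_config()].
#' @param seed RNG seed (initialization, shuffling, dropout, validation
#'   split).
#' @param validation explicit validation graphs; overrides
#'   `validation_frac`.
#' @param validation_frac fraction of `graphs` held out for early
#'   stopping; 0 disables early stopping and trains for all epochs.
#' @param frozen_layers number of leading attention layers (0-2) whose
#'   parameters are held fixed (used when fine-tuning a pretrained model).
#' @param init_params optional parameter list to start from (transfer
#'   learning); defaults to fresh Glorot initialization.
#' @return object of class `gat_model` with fields `params`, `config`,
#'   `width`, `history` (per-epoch train/validation MSE), `best_epoch`.
#' @export
train_gat <- function(graphs, config = gat_config(), seed = 1L,
                      validation = NULL, validation_frac = 0.1,
                      frozen_layers = 0L, init_params = NULL) {
  if (length(graphs) < 4L) stop("need at least 4 graphs")
  if (!(frozen_layers %in% 0:2)) stop("frozen_layers must be 0, 1 or 2")
  widths <- vapply(graphs, function(g) ncol(g$x), integer(1))
  if (length(unique(widths)) != 1L)
    stop("inconsistent node feature widths: ",
         paste(unique(widths), collapse = ", "))
  labs <- vapply(graphs, function(g) g$label, numeric(1))
  if (any(!is.finite(labs))) stop("non-finite graph labels")
  width <- widths[1]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  if (is.null(validation) && validation_frac > 0) {
    nv <- max(1L, round(validation_frac * length(graphs)))
    vi <- sample(length(graphs), nv)
    validation <- graphs[vi]
    graphs <- graphs[-vi]
  }
  use_val <- length(validation) > 0
  graphs <- lapply(graphs, function(g) { g$ei <- gat_edge_index(g); g })
  if (use_val)
    validation <- lapply(validation, function(g) { g$ei <- gat_edge_index(g); g })

  params <- if (is.null(init_params)) gat_init_params(width, config)
            else init_params
  state <- adam_init(params)
  t_step <- 0L
  h <- config$hidden
  best <- list(params = params, val = Inf, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  wait <- 0L
  if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
    for (gi in sample(length(graphs))) {
      g <- graphs[[gi]]
      masks <- if (config$dropout > 0)
        list((stats::runif(h[1]) > config$dropout) / (1 - config$dropout),
             (stats::runif(h[2]) > config$dropout) / (1 - config$dropout))
      else NULL
      fw <- gat_forward(g, params, config, drop_masks = masks,
                        keep_cache = TRUE)
      dy <- 2 * (fw$y - g$label)
      gr <- gat_backward(g, params, config, fw$cache, dy)
      t_step <- t_step + 1L
      r <- adam_step(params, gr, state, config$lr, t_step, frozen_layers)
      params <- r$params
      state <- r$state
    }
    tr_mse <- gat_mse(graphs, params, config)
    va_mse <- if (use_val) gat_mse(validation, params, config) else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_mse = tr_mse,
                                         val_mse = va_mse))
    if (use_val) {
      if (va_mse < best$val - 1e-9) {
        best <- list(params = params, val = va_mse, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    } else {
      best <- list(params = params, val = tr_mse, epoch = ep)
      if (!is.null(config$tol_mse) && config$tol_mse > 0 &&
          tr_mse < config$tol_mse) break
    }
  }
  structure(list(params = best$params, config = config, width = width,
                 history = history, best_epoch = best$epoch, seed = seed,
                 frozen_layers = frozen_layers),
            class = "gat_model")
}

#' @export
print.gat_model <- function(x, ...) {
  cat(sprintf("<gat_model: %d conv x %d ch, head %s, width %d, best epoch %d>\n",
              x$config$conv_layers, x$config$channels,
              paste(x$config$hidden, collapse = "/"), x$width, x$best_epoch))
  invisible(x)
}

#' Predict pKa shifts with a trained GAT
#'
#' @param object a `gat_model`.
#' @param graphs a `residue_graph` or list of them.
#' @param ... unused.
#' @return numeric vector of predicted shifts (eval mode, no dropout).
#' @export
predict.gat_model <- function(object, graphs, ...) {
  if (inherits(graphs, "residue_graph")) graphs <- list(graphs)
  w <- vapply(graphs, function(g) ncol(g$x), integer(1))
  if (any(w != object$width))
    stop("node feature width mismatch: model ", object$width, ", graphs ",
         paste(unique(w), collapse = ", "))
  vapply(graphs, function(g)
    gat_forward(g, object$params, object$config)$y, numeric(1))
}

#' Train an ensemble of GATs on rotating train:validation splits
#'
#' `k` members are trained on `k` distinct 9:1 train:validation splits
#' (rotating validation folds of a seeded shuffle); the ensemble predicts
#' the arithmetic mean member shift.
#'
#' @param graphs labelled training graphs.
#' @param k ensemble size (default 10).
#' @param config a [gat_config()].
#' @param seed master seed; member seeds are derived from it.
#' @return object of class `gat_ensemble`.
#' @export
train_ensemble <- function(graphs, k = 10L, config = gat_config(),
                           seed = 1L) {
  stopifnot(k >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n <- length(graphs)
  ord <- sample(n)
  nfold <- 10L
  fold <- rep_len(seq_len(nfold), n)[order(ord)]
  member_seeds <- sample.int(.Machine$integer.max, k)
  members <- lapply(seq_len(k), function(m) {
    vf <- (m - 1L) %% nfold + 1L
    train_gat(graphs[fold != vf], config, seed = member_seeds[m],
              validation = graphs[fold == vf])
  })
  structure(list(members = members, config = config, k = k, seed = seed,
                 folds = fold),
            class = "gat_ensemble")
}

#' Predict pKa values with a GAT ensemble
#'
#' The prediction for a site is the model pKa of its residue type plus the
#' mean predicted shift over the members.
#'
#' @param ensemble a `gat_ensemble`.
#' @param graphs a `residue_graph` or list of them.
#' @param n_members use only the first `n_members` members (for
#'   ensemble-size curves); default all.
#' @return numeric vector of predicted pKa values.
#' @export
predict_ensemble <- function(ensemble, graphs, n_members = NULL) {
  if (length(ensemble$members) == 0L) stop("empty ensemble")
  if (inherits(graphs, "residue_graph")) graphs <- list(graphs)
  mem <- ensemble$members
  if (!is.null(n_members)) mem <- mem[seq_len(n_members)]
  shifts <- vapply(mem, function(m) predict.gat_model(m, graphs),
                   numeric(length(graphs)))
  shifts <- matrix(shifts, nrow = length(graphs))
  aa <- vapply(graphs, function(g) g$aa, character(1))
  model_pka(aa) + rowMeans(shifts)
}

#' Pretrain on theoretical labels, then fine-tune with frozen layers
#'
#' Two-phase transfer: the model is first trained on a large set of graphs
#' with theoretical pKa-shift labels, then fine-tuning continues from
#' those parameters on experimental graphs with the first `frozen_layers`
#' attention layers held fixed (bitwise).
#'
#' @param pretrain_graphs graphs with theoretical labels.
#' @param finetune_graphs graphs with experimental labels.
#' @param config a [gat_config()] shared by both phases.
#' @param frozen_layers 0, 1 or 2 leading attention layers to freeze
#'   during fine-tuning.
#' @param seed master seed.
#' @param pre_config,fine_config optional per-phase config overrides
#'   (e.g. different epoch budgets).
#' @return list of class `gat_transfer` with `pretrained` and `finetuned`
#'   `gat_model`s.
#' @export
pretrain_finetune <- function(pretrain_graphs, finetune_graphs,
                              config = gat_config(), frozen_layers = 0L,
                              seed = 1L, pre_config = NULL,
                              fine_config = NULL) {
  if (!(frozen_layers %in% 0:2)) stop("frozen_layers must be 0, 1 or 2")
  pre <- train_gat(pretrain_graphs, if (is.null(pre_config)) config
                   else pre_config, seed = seed)
  fine <- train_gat(finetune_graphs, if (is.null(fine_config)) config
                    else fine_config, seed = seed + 1L,
                    frozen_layers = frozen_layers,
                    init_params = pre$params)
  structure(list(pretrained = pre, finetuned = fine,
                 frozen_layers = frozen_layers),
            class = "gat_transfer")
}
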