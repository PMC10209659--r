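# Message-passing neural network mapping an attributed molecular graph to a
# 996-bin EI spectrum.
#
# Architecture (all sizes configurable through model_config()):
#   node embed   h_v = tanh(Wn x_v + bn)            x_v: one-hot element (11)
#   edge embed   g_e = tanh(We e + be)              e: bond features (5)
#   T rounds of edge-conditioned messages with a gated update:
#     m_v  = sum_{u ~ v} relu(Wm [h_u ; g_uv] + bm)
#     z_v  = sigmoid(Wz [h_v ; m_v] + bz)
#     h_v <- (1 - z_v) * h_v + z_v * tanh(Wu m_v + bu)
#   readout      r = sum_v h_v  (sum pooling: invariant to atom order)
#   spectrum     y = softplus(W2 relu(W1 r + b1) + b2)  length 996, >= 0
#
# The output rectifier is the smooth softplus rather than the hard relu: a
# hard rectifier lets whole spectrum bins die (zero gradient) during the
# large early Adam steps, which stalls memorization; softplus keeps every
# bin trainable while still guaranteeing nonnegative intensities.
#
# Training minimizes the weighted squared-error spectrum loss (see
# training_loss()) with Adam; gradients are computed by hand-written
# reverse-mode differentiation (backpropagation through the message rounds),
# verified against finite differences in the test suite. Pure R keeps runs
# bit-reproducible for a fixed seed.

#' Model and training configuration
#'
#' @param node_embed_dim Node state width (default 64).
#' @param edge_embed_dim Edge embedding width (default 32).
#' @param message_rounds Number of message-passing rounds (default 3).
#' @param readout_hidden Hidden width of the readout perceptron (default 128).
#' @param learning_rate Adam step size (default 3e-3, sized for desk-scale
#'   training sets; large-corpus runs may prefer smaller steps).
#' @param batch_size Minibatch size (default 16).
#' @param max_epochs Epoch cap (default 300).
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without a new validation-loss minimum (default 20).
#' @param loss_weighting Weight profile for the spectrum loss, see
#'   [training_loss()].
#' @param seed Integer seed controlling initialization and minibatch order.
#' @return A `model_config` list.
#' @export
model_config <- function(node_embed_dim = 64L, edge_embed_dim = 32L,
                         message_rounds = 3L, readout_hidden = 128L,
                         learning_rate = 3e-3, batch_size = 16L,
                         max_epochs = 300L, patience = 20L,
                         loss_weighting = c("uniform", "sqrt_mz"),
                         seed = 1L) {
  cfg <- list(
    node_embed_dim = as.integer(node_embed_dim),
    edge_embed_dim = as.integer(edge_embed_dim),
    message_rounds = as.integer(message_rounds),
    readout_hidden = as.integer(readout_hidden),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    loss_weighting = match.arg(loss_weighting),
    seed = as.integer(seed)
  )
  counts <- cfg[c("node_embed_dim", "edge_embed_dim", "message_rounds",
                  "readout_hidden", "batch_size", "max_epochs", "patience")]
  if (any(unlist(counts) < 1L)) {
    stop("all model size/count parameters must be >= 1", call. = FALSE)
  }
  if (!is.finite(cfg$learning_rate) || cfg$learning_rate <= 0) {
    stop("learning_rate must be positive", call. = FALSE)
  }
  class(cfg) <- "model_config"
  cfg
}

.glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize an untrained spectrum-prediction model
#'
#' Weights are drawn from scaled normal distributions seeded by
#' `config$seed`; the output bias starts negative so the softplus floor of
#' an untrained model is small relative to a normalized base peak.
#'
#' @param config A [model_config()].
#' @return An `mpnn_model` object (weights plus configuration).
#' @export
mpnn_init <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  d <- config$node_embed_dim
  de <- config$edge_embed_dim
  h1 <- config$readout_hidden
  set.seed(config$seed)
  params <- list(
    Wn = .glorot(length(ALLOWED_ELEMENTS), d), bn = numeric(d),
    We = .glorot(5L, de),                      be = numeric(de),
    Wm = .glorot(d + de, d),                   bm = numeric(d),
    Wz = .glorot(2L * d, d),                   bz = numeric(d),
    Wu = .glorot(d, d),                        bu = numeric(d),
    W1 = .glorot(d, h1),                       b1 = numeric(h1),
    W2 = .glorot(h1, SPECTRUM_LENGTH),
    b2 = rep(-2, SPECTRUM_LENGTH)  # start with a low softplus floor
  )
  structure(list(params = params, config = config, trained = FALSE),
            class = "mpnn_model")
}

#' @export
print.mpnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<mpnn_model> %s, %d message rounds, %d parameters, dims %d/%d/%d\n",
              if (isTRUE(x$trained)) "trained" else "untrained",
              x$config$message_rounds, n_par, x$config$node_embed_dim,
              x$config$edge_embed_dim, x$config$readout_hidden))
  invisible(x)
}

# Precompute per-graph tensors: feature matrices and the directed edge
# index (each undirected bond contributes messages in both directions).
.graph_tensors <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  m <- graph$n_edges
  ends <- if (m) {
    t(apply(graph$incidence, 1L, function(r) which(r == 1L)))
  } else matrix(0L, 0L, 2L)
  list(
    X = graph$node_features + 0,            # n x 11
    E = graph$edge_features + 0,            # m x 5
    n = graph$n_nodes, m = m,
    src = c(ends[, 1L], ends[, 2L]),        # 2m directed edges
    dst = c(ends[, 2L], ends[, 1L])
  )
}

# scatter-add rows of `values` (grouped by `index`) into an n-row zero matrix
.scatter_rows <- function(values, index, n, d) {
  out <- matrix(0, n, d)
  if (length(index)) {
    agg <- rowsum(values, index)
    out[as.integer(rownames(agg)), ] <- agg
  }
  out
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Forward pass; with cache = TRUE also returns every intermediate needed
# for the backward pass.
.mpnn_forward <- function(params, gt, rounds, cache = FALSE) {
  n <- gt$n; m <- gt$m
  d <- ncol(params$Wn); de <- ncol(params$We)
  H <- tanh(gt$X %*% params$Wn + rep(params$bn, each = n))
  H0 <- H
  if (m) {
    G <- tanh(gt$E %*% params$We + rep(params$be, each = m))
    Gd <- rbind(G, G)
  } else {
    G <- matrix(0, 0L, de); Gd <- matrix(0, 0L, de)
  }
  steps <- vector("list", rounds)
  for (t in seq_len(rounds)) {
    if (m) {
      Hs <- H[gt$src, , drop = FALSE]
      P <- cbind(Hs, Gd) %*% params$Wm + rep(params$bm, each = 2L * m)
      M <- pmax(P, 0)
      Mv <- .scatter_rows(M, gt$dst, n, d)
    } else {
      Hs <- NULL; P <- NULL; M <- NULL
      Mv <- matrix(0, n, d)
    }
    Zp <- cbind(H, Mv) %*% params$Wz + rep(params$bz, each = n)
    Z <- .sigmoid(Zp)
    C <- tanh(Mv %*% params$Wu + rep(params$bu, each = n))
    Hnew <- (1 - Z) * H + Z * C
    if (cache) steps[[t]] <- list(H = H, Hs = Hs, P = P, M = M, Mv = Mv,
                                  Z = Z, C = C)
    H <- Hnew
  }
  r <- matrix(colSums(H), 1L, d)
  h1p <- r %*% params$W1 + matrix(params$b1, 1L)
  h1 <- pmax(h1p, 0)
  yp <- h1 %*% params$W2 + matrix(params$b2, 1L)
  y <- .softplus(drop(yp))
  if (!cache) return(y)
  list(y = y, yp = drop(yp), h1 = h1, h1p = h1p, r = r, H = H,
       H0 = H0, G = G, Gd = Gd, steps = steps)
}

# Reverse-mode gradients of loss = sum(w * (y - A)^2) w.r.t. every parameter.
.mpnn_backward <- function(params, gt, fw, A, w, rounds) {
  n <- gt$n; m <- gt$m
  d <- ncol(params$Wn); de <- ncol(params$We)
  g <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))

  dyp <- matrix(2 * w * (fw$y - A) * .sigmoid(fw$yp), 1L)
  g$W2 <- t(fw$h1) %*% dyp
  g$b2 <- drop(dyp)
  dh1p <- (dyp %*% t(params$W2)) * (fw$h1p > 0)
  g$W1 <- t(fw$r) %*% dh1p
  g$b1 <- drop(dh1p)
  dr <- dh1p %*% t(params$W1)
  dH <- matrix(dr, n, d, byrow = TRUE)
  dGd <- matrix(0, 2L * m, de)

  for (t in rev(seq_len(rounds))) {
    st <- fw$steps[[t]]
    dZ <- dH * (st$C - st$H)
    dC <- dH * st$Z
    dHprev <- dH * (1 - st$Z)

    dCp <- dC * (1 - st$C^2)
    g$Wu <- g$Wu + t(st$Mv) %*% dCp
    g$bu <- g$bu + colSums(dCp)
    dMv <- dCp %*% t(params$Wu)

    dZp <- dZ * st$Z * (1 - st$Z)
    g$Wz <- g$Wz + t(cbind(st$H, st$Mv)) %*% dZp
    g$bz <- g$bz + colSums(dZp)
    dHM <- dZp %*% t(params$Wz)
    dHprev <- dHprev + dHM[, seq_len(d), drop = FALSE]
    dMv <- dMv + dHM[, d + seq_len(d), drop = FALSE]

    if (m) {
      dM <- dMv[gt$dst, , drop = FALSE]
      dP <- dM * (st$P > 0)
      g$Wm <- g$Wm + t(cbind(st$Hs, fw$Gd)) %*% dP
      g$bm <- g$bm + colSums(dP)
      dHsGd <- dP %*% t(params$Wm)
      dHprev <- dHprev +
        .scatter_rows(dHsGd[, seq_len(d), drop = FALSE], gt$src, n, d)
      dGd <- dGd + dHsGd[, d + seq_len(de), drop = FALSE]
    }
    dH <- dHprev
  }

  dH0p <- dH * (1 - fw$H0^2)
  g$Wn <- g$Wn + t(gt$X) %*% dH0p
  g$bn <- g$bn + colSums(dH0p)
  if (m) {
    dG <- dGd[seq_len(m), , drop = FALSE] +
      dGd[m + seq_len(m), , drop = FALSE]
    dGp <- dG * (1 - fw$G^2)
    g$We <- g$We + t(gt$E) %*% dGp
    g$be <- g$be + colSums(dGp)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the EI spectrum of a molecular graph
#'
#' Deterministic for fixed weights; the sum-pooling readout makes the
#' output invariant to atom reindexing of the same molecule.
#'
#' @param model An [mpnn_init()] or [train_mpnn()] model.
#' @param graph A [to_graph()] result.
#' @param normalize Scale to base peak 1.0 (default); the softplus output
#'   is strictly positive, so the base peak is always well defined.
#' @return An `ei_spectrum` length-996 vector.
#' @export
predict_spectrum <- function(model, graph, normalize = TRUE) {
  stopifnot(inherits(model, "mpnn_model"))
  gt <- .graph_tensors(graph)
  if (ncol(gt$X) != nrow(model$params$Wn)) {
    stop("node feature dimension ", ncol(gt$X),
         " does not match model input width ", nrow(model$params$Wn),
         call. = FALSE)
  }
  y <- .mpnn_forward(model$params, gt, model$config$message_rounds)
  spectrum_vector(y, normalize = normalize)
}

.adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(params = params, state = state)
}

#' Train the spectrum-prediction model
#'
#' Minibatch Adam on the weighted squared-error spectrum loss. After every
#' epoch the loss is evaluated on the validation set; the returned model
#' carries the weights from the epoch with minimum validation loss, and
#' training stops early once `patience` epochs pass without improvement.
#' Runs are bit-reproducible for a fixed `config$seed`.
#'
#' @param train_set,val_set Lists of `list(graph = <mol_graph>,
#'   spectrum = <ei_spectrum>)` pairs. Target spectra are normalized to
#'   base peak 1.0 before fitting.
#' @param config A [model_config()]; `NULL` uses `model$config` when a
#'   `model` is supplied.
#' @param model Optionally a pre-initialized [mpnn_init()] model to
#'   continue from.
#' @param verbose Print one line per 25 epochs.
#' @return List with `model` (best-validation weights, `trained = TRUE`)
#'   and `history`, a data frame of per-epoch `epoch`, `train_loss`,
#'   `val_loss`, `best_val_loss`.
#' @export
train_mpnn <- function(train_set, val_set = train_set, config = NULL,
                       model = NULL, verbose = FALSE) {
  if (!length(train_set)) stop("empty training set", call. = FALSE)
  if (is.null(model)) {
    config <- config %||% model_config()
    model <- mpnn_init(config)
  } else {
    config <- config %||% model$config
  }
  rounds <- config$message_rounds
  w <- loss_weights(config$loss_weighting)

  prep <- function(set) lapply(set, function(pair) {
    list(gt = .graph_tensors(pair$graph),
         A = .as_spectrum(spectrum_vector(.as_spectrum(pair$spectrum))))
  })
  tr <- prep(train_set)
  va <- prep(val_set)

  params <- model$params
  adam <- .adam_state(params)
  set.seed(config$seed)

  set_loss <- function(set, params) {
    mean(vapply(set, function(s) {
      y <- .mpnn_forward(params, s$gt, rounds)
      sum(w * (y - s$A)^2)
    }, 0))
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), best_val_loss = numeric(0))
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    order <- sample.int(length(tr))
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      grads <- NULL
      batch_loss <- 0
      for (i in batch) {
        s <- tr[[i]]
        fw <- .mpnn_forward(params, s$gt, rounds, cache = TRUE)
        batch_loss <- batch_loss + sum(w * (fw$y - s$A)^2)
        g <- .mpnn_backward(params, s$gt, fw, s$A, w, rounds)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads <- lapply(grads, `/`, length(batch))
      upd <- .adam_step(params, grads, adam, config$learning_rate)
      params <- upd$params
      adam <- upd$state
      epoch_loss <- epoch_loss + batch_loss
    }
    train_loss <- epoch_loss / length(tr)
    val_loss <- set_loss(va, params)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      best_val_loss = best_val))
    if (verbose && epoch %% 25L == 0L) {
      message(sprintf("epoch %4d  train %.5f  val %.5f  best %.5f",
                      epoch, train_loss, val_loss, best_val))
    }
    if (epoch - best_epoch >= config$patience) break
  }

  model$params <- best_params
  model$config <- config
  model$trained <- TRUE
  list(model = model, history = history)
}

#' Split paired data into train/validation/test partitions
#'
#' @param pairs List of items to partition.
#' @param fractions Length-3 positive fractions (train, validation, test)
#'   summing to at most 1; partition sizes are within one item of
#'   `fractions * length(pairs)`.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with `train`, `val`, `test` (disjoint sublists of `pairs`).
#' @export
split_dataset <- function(pairs, fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions <= 0) || sum(fractions) > 1 + 1e-9) {
    stop("fractions must be positive and sum to at most 1", call. = FALSE)
  }
  n <- length(pairs)
  sizes <- floor(fractions * n)
  if (sum(fractions) >= 1 - 1e-9) {
    # exhaustive partition: hand leftover items to the largest remainders
    rem <- fractions * n - sizes
    left <- n - sum(sizes)
    if (left > 0) {
      bump <- order(rem, decreasing = TRUE)[seq_len(left)]
      sizes[bump] <- sizes[bump] + 1L
    }
  }
  if (any(sizes < 1L)) {
    stop("dataset of size ", n, " is too small for fractions ",
         paste(signif(fractions, 3), collapse = "/"), call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  idx_train <- perm[seq_len(sizes[1])]
  idx_val <- perm[sizes[1] + seq_len(sizes[2])]
  idx_test <- perm[sizes[1] + sizes[2] + seq_len(sizes[3])]
  list(train = pairs[idx_train], val = pairs[idx_val],
       test = pairs[idx_test])
}
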