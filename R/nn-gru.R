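# Internal GRU machinery ------------------------------------------------------
#
# A compact CPU implementation of the sequence model: embedding -> stacked GRU
# layers -> linear readout, with manual backprop-through-time and an Adam
# optimizer. Parameters live in a flat named list of matrices/vectors so the
# optimizer can treat them uniformly. Row convention: activations are
# batch x dim; weight matrices are d_in x d_out.

sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias (row) vector to every row of a matrix
addb <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

gate_names <- c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wn", "Un", "bnx", "bnh")

gru_param_names <- function(n_layers) {
  c("E",
    unlist(lapply(seq_len(n_layers), function(l) paste0(gate_names, l))),
    "Wo", "bo")
}

# uniform init scaled by fan-in; caller controls the RNG state
gru_init_params <- function(vocab_size, embedding_dim, hidden_units, n_layers) {
  rmat <- function(nr, nc) {
    s <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  p <- list(E = rmat(vocab_size, embedding_dim))
  d_in <- embedding_dim
  for (l in seq_len(n_layers)) {
    p[[paste0("Wz", l)]] <- rmat(d_in, hidden_units)
    p[[paste0("Uz", l)]] <- rmat(hidden_units, hidden_units)
    p[[paste0("bz", l)]] <- numeric(hidden_units)
    p[[paste0("Wr", l)]] <- rmat(d_in, hidden_units)
    p[[paste0("Ur", l)]] <- rmat(hidden_units, hidden_units)
    p[[paste0("br", l)]] <- numeric(hidden_units)
    p[[paste0("Wn", l)]] <- rmat(d_in, hidden_units)
    p[[paste0("Un", l)]] <- rmat(hidden_units, hidden_units)
    p[[paste0("bnx", l)]] <- numeric(hidden_units)
    p[[paste0("bnh", l)]] <- numeric(hidden_units)
    d_in <- hidden_units
  }
  p$Wo <- rmat(hidden_units, vocab_size)
  p$bo <- numeric(vocab_size)
  p
}

# one GRU cell step for a single layer; returns h plus the quantities the
# backward pass needs
gru_cell_forward <- function(p, l, x, hprev) {
  z <- sigmoid(addb(x %*% p[[paste0("Wz", l)]] + hprev %*% p[[paste0("Uz", l)]],
                    p[[paste0("bz", l)]]))
  r <- sigmoid(addb(x %*% p[[paste0("Wr", l)]] + hprev %*% p[[paste0("Ur", l)]],
                    p[[paste0("br", l)]]))
  un_h <- addb(hprev %*% p[[paste0("Un", l)]], p[[paste0("bnh", l)]])
  n <- tanh(addb(x %*% p[[paste0("Wn", l)]], p[[paste0("bnx", l)]]) + r * un_h)
  h <- (1 - z) * n + z * hprev
  list(h = h, z = z, r = r, n = n, un_h = un_h, hprev = hprev, x = x)
}

# single autoregressive step used at sampling time: token ids + hidden states
# in, logits + updated hidden states out
gru_step <- function(params, n_layers, ids, hs) {
  x <- params$E[ids, , drop = FALSE]
  for (l in seq_len(n_layers)) {
    cell <- gru_cell_forward(params, l, x, hs[[l]])
    hs[[l]] <- cell$h
    x <- cell$h
  }
  list(logits = addb(x %*% params$Wo, params$bo), hs = hs)
}

# row-wise stable softmax
softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# accumulate dx rows into the embedding gradient, aggregating duplicate ids
accumulate_embedding <- function(dE, ids, dx) {
  agg <- rowsum(dx, group = ids)
  rows <- as.integer(rownames(agg))
  dE[rows, ] <- dE[rows, , drop = FALSE] + agg
  dE
}

# Weighted teacher-forced cross-entropy and its gradient.
#
# inputs, targets: B x T integer matrices of token ids; weights: B x T
# nonnegative multipliers applied per position to the CE terms. Returns the
# weighted loss sum and gradients for every parameter. Supervised training
# uses weights = mask / n_mask (a per-position mean); REINFORCE reuses the
# same routine with weights = reward_b / B so that minimizing the weighted CE
# is gradient ascent on the expected return.
gru_backprop <- function(params, n_layers, inputs, targets, weights,
                         eps = 1e-12) {
  bsz <- nrow(inputs)
  len <- ncol(inputs)
  hdim <- ncol(params$Wo)  # vocab
  hu <- nrow(params$Wo)    # hidden units

  hs <- rep(list(matrix(0, bsz, hu)), n_layers)
  caches <- vector("list", len)
  probs <- vector("list", len)
  loss <- 0
  for (t in seq_len(len)) {
    x <- params$E[inputs[, t], , drop = FALSE]
    layer_cache <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      cell <- gru_cell_forward(params, l, x, hs[[l]])
      layer_cache[[l]] <- cell
      hs[[l]] <- cell$h
      x <- cell$h
    }
    p_t <- softmax_rows(addb(x %*% params$Wo, params$bo))
    probs[[t]] <- p_t
    caches[[t]] <- layer_cache
    idx <- cbind(seq_len(bsz), targets[, t])
    loss <- loss + sum(-log(pmax(p_t[idx], eps)) * weights[, t])
  }

  grads <- lapply(params, function(m) {
    if (is.matrix(m)) matrix(0, nrow(m), ncol(m)) else numeric(length(m))
  })
  dh_carry <- rep(list(matrix(0, bsz, hu)), n_layers)
  for (t in rev(seq_len(len))) {
    p_t <- probs[[t]]
    dlogits <- p_t
    idx <- cbind(seq_len(bsz), targets[, t])
    dlogits[idx] <- dlogits[idx] - 1
    dlogits <- dlogits * weights[, t]

    h_top <- caches[[t]][[n_layers]]$h
    grads$Wo <- grads$Wo + crossprod(h_top, dlogits)
    grads$bo <- grads$bo + colSums(dlogits)
    d_from_above <- dlogits %*% t(params$Wo)

    for (l in rev(seq_len(n_layers))) {
      cell <- caches[[t]][[l]]
      dh <- d_from_above + dh_carry[[l]]
      dz <- dh * (cell$hprev - cell$n) * cell$z * (1 - cell$z)
      dn <- dh * (1 - cell$z) * (1 - cell$n^2)
      dr <- dn * cell$un_h * cell$r * (1 - cell$r)
      dnr <- dn * cell$r

      wz <- paste0("Wz", l); uz <- paste0("Uz", l); bz <- paste0("bz", l)
      wr <- paste0("Wr", l); ur <- paste0("Ur", l); br <- paste0("br", l)
      wn <- paste0("Wn", l); un <- paste0("Un", l)
      bnx <- paste0("bnx", l); bnh <- paste0("bnh", l)

      grads[[wz]] <- grads[[wz]] + crossprod(cell$x, dz)
      grads[[uz]] <- grads[[uz]] + crossprod(cell$hprev, dz)
      grads[[bz]] <- grads[[bz]] + colSums(dz)
      grads[[wr]] <- grads[[wr]] + crossprod(cell$x, dr)
      grads[[ur]] <- grads[[ur]] + crossprod(cell$hprev, dr)
      grads[[br]] <- grads[[br]] + colSums(dr)
      grads[[wn]] <- grads[[wn]] + crossprod(cell$x, dn)
      grads[[un]] <- grads[[un]] + crossprod(cell$hprev, dnr)
      grads[[bnx]] <- grads[[bnx]] + colSums(dn)
      grads[[bnh]] <- grads[[bnh]] + colSums(dnr)

      d_from_above <- dz %*% t(params[[wz]]) + dr %*% t(params[[wr]]) +
        dn %*% t(params[[wn]])
      dh_carry[[l]] <- dh * cell$z + dz %*% t(params[[uz]]) +
        dr %*% t(params[[ur]]) + dnr %*% t(params[[un]])
    }
    grads$E <- accumulate_embedding(grads$E, inputs[, t], d_from_above)
  }
  list(loss = loss, grads = grads)
}

# Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(m) {
    if (is.matrix(m)) matrix(0, nrow(m), ncol(m)) else numeric(length(m))
  })
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

params_l2_delta <- function(a, b) {
  sqrt(sum(vapply(names(a), function(nm) sum((a[[nm]] - b[[nm]])^2),
                  numeric(1))))
}
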