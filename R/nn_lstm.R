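# Batched LSTM with masking: the recurrent workhorse behind the sequence
# tagger (bidirectional over tokens, and over characters within tokens)
# and the relation classifier (unidirectional over candidate scopes).
#
# Sequences are right-padded within a batch; `mask` (B x T, 1 = real
# token) freezes the hidden and cell state across padded steps, so the
# state after the last processed step is the state at each sequence's last
# real element regardless of padding.  The backward pass is the exact
# reverse-mode differential of the forward recurrence, including the mask
# carry; it is verified against finite differences in the test suite.
#
# Gate layout in all 4H-wide matrices: [input, forget, candidate, output].

glorot_init <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# Parameters of one LSTM direction.  Forget-gate bias starts at 1 (the
# usual remedy against early vanishing of the cell state).
lstm_params <- function(input_dim, hidden) {
  list(Wx = glorot_init(input_dim, 4L * hidden),
       Wh = glorot_init(hidden, 4L * hidden),
       b = c(rep(0, hidden), rep(1, hidden), rep(0, 2L * hidden)),
       hidden = hidden, input_dim = input_dim)
}

lstm_zero_grads <- function(params) {
  list(Wx = params$Wx * 0, Wh = params$Wh * 0, b = params$b * 0)
}

# X: list over t of B x D input matrices; mask: B x T.
# Returns per-step outputs H (list of B x H), the final state, and the
# cache needed for the backward pass.  `reverse = TRUE` processes t = T..1
# (the backward direction of a BiLSTM); outputs stay indexed by true t.
lstm_forward <- function(X, mask, params, reverse = FALSE) {
  Tlen <- length(X)
  B <- nrow(mask)
  H <- params$hidden
  ord <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  h <- matrix(0, B, H)
  c_state <- matrix(0, B, H)
  Hs <- vector("list", Tlen)
  cache <- vector("list", Tlen)
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  for (t in ord) {
    z <- X[[t]] %*% params$Wx + h %*% params$Wh
    z <- sweep(z, 2L, params$b, "+")
    i_g <- sigmoid(z[, ii, drop = FALSE])
    f_g <- sigmoid(z[, fi, drop = FALSE])
    g_g <- tanh(z[, gi, drop = FALSE])
    o_g <- sigmoid(z[, oi, drop = FALSE])
    c_hat <- f_g * c_state + i_g * g_g
    tc <- tanh(c_hat)
    h_hat <- o_g * tc
    m <- mask[, t]
    h_new <- m * h_hat + (1 - m) * h
    c_new <- m * c_hat + (1 - m) * c_state
    cache[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g, tc = tc,
                       c_prev = c_state, h_prev = h, m = m)
    h <- h_new
    c_state <- c_new
    Hs[[t]] <- h
  }
  list(H = Hs, final_h = h, cache = cache, ord = ord, X = X)
}

# dH: list over t of B x H gradients w.r.t. the per-step outputs (NULL
# entries allowed); dfinal: B x H gradient w.r.t. the final state.
lstm_backward <- function(fwd, params, dH = NULL, dfinal = NULL) {
  cache <- fwd$cache
  X <- fwd$X
  Tlen <- length(X)
  B <- nrow(cache[[fwd$ord[1L]]]$h_prev)
  H <- params$hidden
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  grads <- lstm_zero_grads(params)
  dX <- vector("list", Tlen)
  dh_c <- if (is.null(dfinal)) matrix(0, B, H) else dfinal
  dc_c <- matrix(0, B, H)
  for (t in rev(fwd$ord)) {
    cc <- cache[[t]]
    m <- cc$m
    dh_tot <- dh_c
    if (!is.null(dH) && !is.null(dH[[t]])) dh_tot <- dh_tot + dH[[t]]
    dc_tot <- dc_c
    dh_hat <- m * dh_tot
    dc_hat <- m * dc_tot + dh_hat * cc$o * (1 - cc$tc^2)
    do_g <- dh_hat * cc$tc
    di_g <- dc_hat * cc$g
    df_g <- dc_hat * cc$c_prev
    dg_g <- dc_hat * cc$i
    dz <- cbind(di_g * cc$i * (1 - cc$i),
                df_g * cc$f * (1 - cc$f),
                dg_g * (1 - cc$g^2),
                do_g * cc$o * (1 - cc$o))
    grads$Wx <- grads$Wx + crossprod(X[[t]], dz)
    grads$Wh <- grads$Wh + crossprod(cc$h_prev, dz)
    grads$b <- grads$b + colSums(dz)
    dX[[t]] <- dz %*% t(params$Wx)
    dh_c <- dz %*% t(params$Wh) + (1 - m) * dh_tot
    dc_c <- (1 - m) * dc_tot + dc_hat * cc$f
  }
  list(dX = dX, grads = grads)
}

# Bidirectional wrapper: concatenated per-step outputs [fwd | bwd].
bilstm_forward <- function(X, mask, params_fwd, params_bwd) {
  fwd <- lstm_forward(X, mask, params_fwd, reverse = FALSE)
  bwd <- lstm_forward(X, mask, params_bwd, reverse = TRUE)
  H <- Map(cbind, fwd$H, bwd$H)
  list(H = H, fwd = fwd, bwd = bwd)
}

# dH on the concatenated outputs; returns dX (summed over directions) and
# per-direction parameter gradients.
bilstm_backward <- function(bi, params_fwd, params_bwd, dH) {
  Hf <- params_fwd$hidden
  dHf <- lapply(dH, function(d) if (is.null(d)) NULL else d[, seq_len(Hf), drop = FALSE])
  dHb <- lapply(dH, function(d) if (is.null(d)) NULL else d[, Hf + seq_len(params_bwd$hidden), drop = FALSE])
  bf <- lstm_backward(bi$fwd, params_fwd, dH = dHf)
  bb <- lstm_backward(bi$bwd, params_bwd, dH = dHb)
  dX <- Map(`+`, bf$dX, bb$dX)
  list(dX = dX, grads_fwd = bf$grads, grads_bwd = bb$grads)
}

# In-place-style SGD update: params - lr * grads for matching fields.
sgd_update <- function(params, grads, lr) {
  for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}
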