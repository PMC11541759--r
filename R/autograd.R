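# Minimal reverse-mode automatic differentiation on a per-forward tape.
#
# Every op follows the same contract: it computes its value eagerly; if no
# tape is active, or none of its arguments is a node, it returns the plain
# numeric value.  Otherwise it returns a node recorded on the active tape
# whose backward closure accumulates gradients into its node arguments.
# Plain numeric arguments flow through as constants, so the same forward
# code serves both evaluation (no tape) and training (tape active).
#
# Hot-path operations (spatial attention scoring, LSTM/GRU steps, temporal
# attention) are fused into single nodes with hand-derived backward passes;
# every backward pass is checked against finite differences in the tests.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

tape_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  .ag$tape <- t
  invisible(t)
}

tape_end <- function() {
  t <- .ag$tape
  .ag$tape <- NULL
  invisible(t)
}

tape_active <- function() !is.null(.ag$tape)

# nodes are the only environments that flow through op arguments, so the
# primitive environment check suffices (and is much faster than inherits)
is_node <- function(x) is.environment(x)

# value of a node or plain numeric
vof <- function(x) if (is_node(x)) x$v else x

# leaf node (parameter): holds a value and accumulates gradient; not taped
ag_leaf <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  class(nd) <- "ag_node"
  nd
}

new_node <- function(value, bw) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bw <- bw
  class(nd) <- "ag_node"
  t <- .ag$tape
  t$n <- t$n + 1L
  if (t$n > length(t$nodes)) length(t$nodes) <- 2L * t$n
  t$nodes[[t$n]] <- nd
  nd
}

accum <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

# Run the backward sweep from `loss` (a scalar node) over the active tape.
# Leaf gradients are left in place; read them with `$g`.
ag_backward <- function(loss) {
  stopifnot(is_node(loss), tape_active())
  loss$g <- 1
  t <- .ag$tape
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
  }
  invisible(NULL)
}

ag_zero_grad <- function(leaves) {
  for (l in leaves) l$g <- NULL
  invisible(NULL)
}

node_args <- function(...) {
  for (a in list(...)) if (is.environment(a)) return(TRUE)
  FALSE
}

# fast row-vector broadcast add (sweep is slow on small matrices)
add_rowvec <- function(M, v) M + rep(v, each = nrow(M))

# ---- primitive ops ---------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  out <- av %*% bv
  if (!tape_active() || !node_args(a, b)) return(out)
  new_node(out, function(g) {
    if (is_node(a)) accum(a, g %*% t(bv))
    if (is_node(b)) accum(b, crossprod(av, g))
  })
}

ag_add <- function(a, b) {
  out <- vof(a) + vof(b)
  if (!tape_active() || !node_args(a, b)) return(out)
  new_node(out, function(g) {
    if (is_node(a)) accum(a, g)
    if (is_node(b)) accum(b, g)
  })
}

ag_sub <- function(a, b) {
  out <- vof(a) - vof(b)
  if (!tape_active() || !node_args(a, b)) return(out)
  new_node(out, function(g) {
    if (is_node(a)) accum(a, g)
    if (is_node(b)) accum(b, -g)
  })
}

ag_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  out <- av * bv
  if (!tape_active() || !node_args(a, b)) return(out)
  new_node(out, function(g) {
    if (is_node(a)) accum(a, g * bv)
    if (is_node(b)) accum(b, g * av)
  })
}

# multiply by a plain scalar constant
ag_scale <- function(a, k) {
  out <- vof(a) * k
  if (!tape_active() || !is_node(a)) return(out)
  new_node(out, function(g) accum(a, g * k))
}

# scalar a / scalar b (either may be node)
ag_div <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  out <- av / bv
  if (!tape_active() || !node_args(a, b)) return(out)
  new_node(out, function(g) {
    if (is_node(a)) accum(a, g / bv)
    if (is_node(b)) accum(b, -g * av / (bv * bv))
  })
}

# add a row vector to every row of a matrix
ag_add_rowvec <- function(A, v) {
  Av <- vof(A); vv <- vof(v)
  out <- add_rowvec(Av, vv)
  if (!tape_active() || !node_args(A, v)) return(out)
  new_node(out, function(g) {
    if (is_node(A)) accum(A, g)
    if (is_node(v)) accum(v, colSums(g))
  })
}

ag_relu <- function(a) {
  av <- vof(a)
  out <- av * (av > 0)
  if (!tape_active() || !is_node(a)) return(out)
  new_node(out, function(g) accum(a, g * (av > 0)))
}

ag_sigmoid <- function(a) {
  out <- 1 / (1 + exp(-vof(a)))
  if (!tape_active() || !is_node(a)) return(out)
  new_node(out, function(g) accum(a, g * out * (1 - out)))
}

ag_tanh <- function(a) {
  out <- tanh(vof(a))
  if (!tape_active() || !is_node(a)) return(out)
  new_node(out, function(g) accum(a, g * (1 - out * out)))
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

ag_softmax <- function(a) {
  out <- softmax_vec(vof(a))
  if (!tape_active() || !is_node(a)) return(out)
  new_node(out, function(g) accum(a, out * (g - sum(g * out))))
}

# row-wise softmax of a matrix
ag_softmax_rows <- function(A) {
  Av <- vof(A)
  m <- apply(Av, 1L, max)
  e <- exp(Av - m)
  out <- e / rowSums(e)
  if (!tape_active() || !is_node(A)) return(out)
  new_node(out, function(g) {
    accum(A, out * (g - rowSums(g * out)))
  })
}

ag_sum <- function(a) {
  av <- vof(a)
  out <- sum(av)
  if (!tape_active() || !is_node(a)) return(out)
  d <- dim(av)
  new_node(out, function(g) {
    gg <- array(g, dim = if (is.null(d)) length(av) else d)
    accum(a, gg)
  })
}

ag_mean <- function(a) ag_scale(ag_sum(a), 1 / length(vof(a)))

# sum of elementwise product (inner product for vectors or matrices)
ag_dot <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  out <- sum(av * bv)
  if (!tape_active() || !node_args(a, b)) return(out)
  new_node(out, function(g) {
    if (is_node(a)) accum(a, g * bv)
    if (is_node(b)) accum(b, g * av)
  })
}

ag_slice <- function(a, idx) {
  av <- vof(a)
  out <- av[idx]
  if (!tape_active() || !is_node(a)) return(out)
  n <- length(av)
  new_node(out, function(g) {
    gg <- numeric(n)
    gg[idx] <- g
    accum(a, gg)
  })
}

ag_row <- function(A, i) {
  Av <- vof(A)
  out <- Av[i, ]
  if (!tape_active() || !is_node(A)) return(out)
  d <- dim(Av)
  new_node(out, function(g) {
    gg <- matrix(0, d[1], d[2])
    gg[i, ] <- g
    accum(A, gg)
  })
}

ag_slice_cols <- function(A, idx) {
  Av <- vof(A)
  out <- Av[, idx, drop = FALSE]
  if (!tape_active() || !is_node(A)) return(out)
  d <- dim(Av)
  new_node(out, function(g) {
    gg <- matrix(0, d[1], d[2])
    gg[, idx] <- g
    accum(A, gg)
  })
}

ag_t <- function(A) {
  out <- t(vof(A))
  if (!tape_active() || !is_node(A)) return(out)
  new_node(out, function(g) accum(A, t(g)))
}

# stack a list of row vectors (or scalars) into a matrix / vector
ag_rbind <- function(rows) {
  vals <- lapply(rows, vof)
  out <- do.call(rbind, vals)
  if (!tape_active() || !any(vapply(rows, is_node, logical(1)))) return(out)
  new_node(out, function(g) {
    for (i in seq_along(rows)) {
      if (is_node(rows[[i]])) accum(rows[[i]], g[i, ])
    }
  })
}

ag_cbind <- function(cols) {
  vals <- lapply(cols, vof)
  out <- do.call(cbind, vals)
  if (!tape_active() || !any(vapply(cols, is_node, logical(1)))) return(out)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_node(out, function(g) {
    for (i in seq_along(cols)) {
      if (is_node(cols[[i]])) accum(cols[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# bijective element re-indexing: out_flat[i] = in_flat[idx[i]]
ag_reindex <- function(a, idx, dim_out = NULL) {
  av <- vof(a)
  out <- av[idx]
  if (!is.null(dim_out)) dim(out) <- dim_out
  if (!tape_active() || !is_node(a)) return(out)
  d <- dim(av)
  new_node(out, function(g) {
    gg <- numeric(length(av))
    gg[idx] <- as.vector(g)
    if (!is.null(d)) dim(gg) <- d
    accum(a, gg)
  })
}

# Dense layer on row-major stacked inputs: act(X W + b), X: n x d_in.
ag_dense <- function(X, W, b, activation = c("none", "relu", "tanh")) {
  activation <- match.arg(activation)
  Xv <- vof(X); Wv <- vof(W); bv <- vof(b)
  pre <- add_rowvec(Xv %*% Wv, bv)
  out <- switch(activation, none = pre, relu = pre * (pre > 0), tanh = tanh(pre))
  if (!tape_active() || !node_args(X, W, b)) return(out)
  new_node(out, function(g) {
    gp <- switch(activation,
      none = g,
      relu = g * (pre > 0),
      tanh = g * (1 - out * out)
    )
    if (is_node(W)) accum(W, crossprod(Xv, gp))
    if (is_node(b)) accum(b, colSums(gp))
    if (is_node(X)) accum(X, gp %*% t(Wv))
  })
}

# Row-wise layer normalization with learned gain/bias.
ag_layernorm <- function(X, gain, bias, eps = 1e-5) {
  Xv <- vof(X); gv <- vof(gain); bv <- vof(bias)
  n <- ncol(Xv)
  mu <- rowMeans(Xv)
  xc <- Xv - mu
  varr <- rowMeans(xc * xc)
  inv <- 1 / sqrt(varr + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  if (!tape_active() || !node_args(X, gain, bias)) return(out)
  new_node(out, function(g) {
    if (is_node(gain)) accum(gain, colSums(g * xhat))
    if (is_node(bias)) accum(bias, colSums(g))
    if (is_node(X)) {
      gx_hat <- sweep(g, 2L, gv, "*")
      # d/dX of row-wise normalization
      gX <- inv * (gx_hat - rowMeans(gx_hat) - xhat * rowMeans(gx_hat * xhat))
      accum(X, gX)
    }
  })
}

# Numerically stable binary cross-entropy from a logit (scalar).
ag_bce_logit <- function(logit, y) {
  s <- vof(logit)
  out <- max(s, 0) - s * y + log1p(exp(-abs(s)))
  if (!tape_active() || !is_node(logit)) return(out)
  p <- 1 / (1 + exp(-s))
  new_node(out, function(g) accum(logit, g * (p - y)))
}

ag_mse <- function(pred, target) {
  pv <- vof(pred); tv <- vof(target)
  d <- pv - tv
  out <- mean(d * d)
  if (!tape_active() || !node_args(pred, target)) return(out)
  n <- length(pv)
  new_node(out, function(g) {
    if (is_node(pred)) accum(pred, g * 2 * d / n)
    if (is_node(target)) accum(target, -g * 2 * d / n)
  })
}

# ---- fused model ops -------------------------------------------------------

# Deferred parameter-gradient buffers.  With only small matrices in play,
# per-step outer products and gradient-matrix additions dominate the
# backward cost; instead, the fused recurrent ops write their per-step
# gate/score gradients into preallocated buffers and `defer_flush()`
# computes each parameter gradient as one batched crossprod per clip.
defer_create <- function(N, cells, C_att, C_e, C_h, gate_width, leaves) {
  d <- new.env(parent = emptyenv())
  d$N <- N; d$cells <- cells
  d$leaves <- leaves
  # per-frame slabs are kept in lists (no copy on write) and bound into
  # one matrix per parameter at flush time
  if (!is.null(leaves$Ma)) {
    d$P <- vector("list", N)
    d$GPRE <- vector("list", N)
    if (!is.null(leaves$Ms)) {
      d$GFSP <- vector("list", N)
      d$HPREV_ATT <- vector("list", N)
    }
  }
  if (!is.null(leaves$W)) {
    d$GA <- vector("list", N)
    d$X <- vector("list", N)
    d$HPREV <- vector("list", N)
    if (!is.null(leaves$bh)) d$GAH <- vector("list", N)  # gru
  }
  d
}

defer_flush <- function(d) {
  lv <- d$leaves
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  if (!is.null(lv$Ma)) {
    gpre <- drop_null(d$GPRE)
    if (length(gpre) > 0) {
      Pstack <- if (!is.null(d$Pstack) && length(gpre) == d$N) d$Pstack else {
        do.call(rbind, drop_null(d$P))
      }
      accum(lv$Ma, crossprod(Pstack, do.call(rbind, gpre)))
      if (!is.null(lv$Ms)) {
        accum(lv$Ms, crossprod(do.call(rbind, drop_null(d$HPREV_ATT)),
                               do.call(rbind, drop_null(d$GFSP))))
      }
    }
  }
  if (!is.null(lv$W)) {
    ga <- drop_null(d$GA)
    if (length(ga) > 0) {
      GA <- do.call(rbind, ga)
      X <- do.call(rbind, drop_null(d$X))
      HP <- do.call(rbind, drop_null(d$HPREV))
      accum(lv$W, crossprod(X, GA))
      if (is.null(lv$bh)) {
        accum(lv$U, crossprod(HP, GA))
        if (!is.null(lv$b)) accum(lv$b, colSums(GA))
      } else {
        GAH <- do.call(rbind, drop_null(d$GAH))
        accum(lv$U, crossprod(HP, GAH))
        accum(lv$bx, colSums(GA))
        accum(lv$bh, colSums(GAH))
      }
    }
  }
  invisible(NULL)
}

# Spatial attention scoring for one frame (fused).
# P: cells x C_e feature grid; h_prev: C_h vector or NULL; Ma: C_e x C_att;
# Ms: C_h x C_att; Mo: C_att vector.  Returns softmax-normalized weights
# over the cells.  With `defer`, the Ma/Ms gradients are buffered for one
# batched flush per clip.
ag_attention_step <- function(P, h_prev, Ma, Ms, Mo, defer = NULL,
                              frame = NA_integer_, f_app = NULL) {
  force(frame)
  Pv <- vof(P); Mav <- vof(Ma); Mov <- vof(Mo)
  # f_app = Pv %*% Mav may be precomputed for a whole clip in one matmul
  # (it does not depend on the hidden state); the hand-written backward
  # is unaffected
  pre <- if (is.null(f_app)) Pv %*% Mav else f_app
  if (!is.null(h_prev)) {
    hv <- vof(h_prev); Msv <- vof(Ms)
    fsp <- as.vector(hv %*% Msv)
    pre <- add_rowvec(pre, fsp)
  }
  Z <- pre * (pre > 0)
  scores <- as.vector(Z %*% Mov)
  att <- softmax_vec(scores)
  if (!tape_active() || !node_args(P, h_prev, Ma, Ms, Mo)) return(att)
  new_node(att, function(g) {
    gs <- att * (g - sum(g * att))          # softmax backward
    gZ <- gs %o% Mov                         # scores = Z Mo
    if (is_node(Mo)) accum(Mo, as.vector(crossprod(Z, gs)))
    gpre <- gZ * (pre > 0)
    gfsp <- if (!is.null(h_prev)) colSums(gpre)
    if (!is.null(defer)) {
      if (is.null(defer$Pstack)) defer$P[[frame]] <- Pv
      defer$GPRE[[frame]] <- gpre
      if (!is.null(h_prev) && !is.null(defer$GFSP)) {
        defer$GFSP[[frame]] <- gfsp
        defer$HPREV_ATT[[frame]] <- vof(h_prev)
      }
    } else {
      if (is_node(Ma)) accum(Ma, crossprod(Pv, gpre))
      if (!is.null(h_prev) && is_node(Ms)) accum(Ms, vof(h_prev) %o% gfsp)
    }
    if (is_node(P)) accum(P, gpre %*% t(Mav))
    if (!is.null(h_prev) && is_node(h_prev)) {
      accum(h_prev, as.vector(vof(Ms) %*% gfsp))
    }
  })
}

# Attention-weighted sum of cell features: t(P) %*% att  (fused).
ag_attend_aggregate <- function(att, P) {
  av <- vof(att); Pv <- vof(P)
  out <- as.vector(crossprod(Pv, av))
  if (!tape_active() || !node_args(att, P)) return(out)
  new_node(out, function(g) {
    if (is_node(att)) accum(att, as.vector(Pv %*% g))
    if (is_node(P)) accum(P, av %o% g)
  })
}

# One LSTM step (fused).  State is the concatenated vector c(h, c) of
# length 2*C_h.  Gate order i, f, g, o.  W: C_in x 4C_h, U: C_h x 4C_h.
ag_lstm_step <- function(x, hc, W, U, b, defer = NULL,
                         frame = NA_integer_) {
  force(frame)
  xv <- vof(x); hcv <- vof(hc)
  Wv <- vof(W); Uv <- vof(U); bv <- vof(b)
  ch <- length(hcv) %/% 2L
  h <- hcv[seq_len(ch)]
  c_prev <- hcv[(ch + 1L):(2L * ch)]
  a <- as.vector(xv %*% Wv) + as.vector(h %*% Uv) + bv
  ii <- 1 / (1 + exp(-a[seq_len(ch)]))
  ff <- 1 / (1 + exp(-a[(ch + 1L):(2L * ch)]))
  gg <- tanh(a[(2L * ch + 1L):(3L * ch)])
  oo <- 1 / (1 + exp(-a[(3L * ch + 1L):(4L * ch)]))
  c_new <- ff * c_prev + ii * gg
  tc <- tanh(c_new)
  h_new <- oo * tc
  out <- c(h_new, c_new)
  if (!tape_active() || !node_args(x, hc, W, U, b)) return(out)
  new_node(out, function(gr) {
    gh <- gr[seq_len(ch)]
    gc <- gr[(ch + 1L):(2L * ch)] + gh * oo * (1 - tc * tc)
    go <- gh * tc
    gf <- gc * c_prev
    gi <- gc * gg
    gg_ <- gc * ii
    ga <- c(gi * ii * (1 - ii),
            gf * ff * (1 - ff),
            gg_ * (1 - gg * gg),
            go * oo * (1 - oo))
    if (!is.null(defer)) {
      defer$GA[[frame]] <- ga
      defer$X[[frame]] <- xv
      defer$HPREV[[frame]] <- h
    } else {
      if (is_node(W)) accum(W, xv %o% ga)
      if (is_node(U)) accum(U, h %o% ga)
      if (is_node(b)) accum(b, ga)
    }
    if (is_node(x)) accum(x, as.vector(Wv %*% ga))
    if (is_node(hc)) accum(hc, c(as.vector(Uv %*% ga), gc * ff))
  })
}

# One GRU step (fused).  Gate order r, z, n.  Two bias vectors as in the
# standard gated-recurrent-unit formulation (the candidate's recurrent
# term is gated by r before the nonlinearity).
ag_gru_step <- function(x, h, W, U, bx, bh, defer = NULL,
                        frame = NA_integer_) {
  force(frame)
  xv <- vof(x); hv <- vof(h)
  Wv <- vof(W); Uv <- vof(U); bxv <- vof(bx); bhv <- vof(bh)
  ch <- length(hv)
  ax <- as.vector(xv %*% Wv) + bxv
  ah <- as.vector(hv %*% Uv) + bhv
  i1 <- seq_len(ch); i2 <- (ch + 1L):(2L * ch); i3 <- (2L * ch + 1L):(3L * ch)
  r <- 1 / (1 + exp(-(ax[i1] + ah[i1])))
  z <- 1 / (1 + exp(-(ax[i2] + ah[i2])))
  n <- tanh(ax[i3] + r * ah[i3])
  h_new <- (1 - z) * n + z * hv
  if (!tape_active() || !node_args(x, h, W, U, bx, bh)) return(h_new)
  new_node(h_new, function(g) {
    gz <- g * (hv - n)
    gn <- g * (1 - z)
    gan <- gn * (1 - n * n)
    gr <- gan * ah[i3]
    gahn <- gan * r
    gaz <- gz * z * (1 - z)
    gar <- gr * r * (1 - r)
    gax <- c(gar, gaz, gan)
    gah <- c(gar, gaz, gahn)
    if (!is.null(defer)) {
      defer$GA[[frame]] <- gax
      defer$GAH[[frame]] <- gah
      defer$X[[frame]] <- xv
      defer$HPREV[[frame]] <- hv
    } else {
      if (is_node(W)) accum(W, xv %o% gax)
      if (is_node(U)) accum(U, hv %o% gah)
      if (is_node(bx)) accum(bx, gax)
      if (is_node(bh)) accum(bh, gah)
    }
    if (is_node(x)) accum(x, as.vector(Wv %*% gax))
    if (is_node(h)) accum(h, as.vector(Uv %*% gah) + g * z)
  })
}

# Temporal attention over hidden states (fused): beta = H h_N,
# a = softmax(beta), h_f = t(H) a.  Returns h_f.
ag_temporal_attend <- function(H) {
  Hv <- vof(H)
  n <- nrow(Hv)
  hN <- Hv[n, ]
  beta <- as.vector(Hv %*% hN)
  a <- softmax_vec(beta)
  hf <- as.vector(crossprod(Hv, a))
  if (!tape_active() || !is_node(H)) return(hf)
  new_node(hf, function(g) {
    ga <- as.vector(Hv %*% g)                  # from h_f = t(H) a
    gbeta <- a * (ga - sum(ga * a))            # softmax backward
    gH <- a %o% g + gbeta %o% hN               # h_f term + beta = H hN term
    ghN <- as.vector(crossprod(Hv, gbeta))
    gH[n, ] <- gH[n, ] + ghN
    accum(H, gH)
  })
}
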