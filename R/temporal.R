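# Temporal sequence models (LSTM, GRU, transformer encoder), unsupervised
# temporal attention over hidden states, and the no-attention pathway.

#' Unsupervised temporal attention over hidden states
#'
#' Computes dot-product alignment of every hidden state with the final
#' hidden state, `beta_i = <h_i, h_N>`, softmax-normalizes it into weights
#' `A_temp`, and returns the attended summary `h_f = sum_i A_temp_i h_i`.
#'
#' @param H `N x C_h` matrix of hidden states (rows `h_1 ... h_N`).
#' @return list with `weights` (length `N`, summing to 1) and `h_f`
#'   (length `C_h`).
#' @export
temporal_attention <- function(H) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  if (nrow(H) < 1L) stop("empty hidden-state sequence")
  beta <- as.vector(H %*% H[nrow(H), ])
  w <- softmax_vec(beta)
  list(weights = w, h_f = as.vector(crossprod(H, w)))
}

#' Create temporal-model parameters
#'
#' @param kind one of `"lstm"`, `"gru"`, `"transformer"`.
#' @param C_in input feature length (the attended feature, `C_e`).
#' @param C_h hidden-state length (reference 1024).
#' @param n_layers,n_heads transformer depth and head count (ignored for
#'   recurrent kinds).
#' @param seed integer seed for initialization.
#' @return parameter list with class `"temporal_params"`.
#' @export
make_temporal_params <- function(kind = c("lstm", "gru", "transformer"),
                                 C_in, C_h, n_layers = 2L, n_heads = 4L,
                                 seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  rmat <- function(a, b, sd = sqrt(1 / a)) matrix(stats::rnorm(a * b, sd = sd), a, b)
  p <- switch(kind,
    lstm = {
      b <- numeric(4L * C_h)
      b[(C_h + 1L):(2L * C_h)] <- 1  # forget-gate bias
      list(W = rmat(C_in, 4L * C_h), U = rmat(C_h, 4L * C_h), b = b)
    },
    gru = list(W = rmat(C_in, 3L * C_h), U = rmat(C_h, 3L * C_h),
               bx = numeric(3L * C_h), bh = numeric(3L * C_h)),
    transformer = {
      if (C_h %% n_heads != 0L) stop("C_h must be divisible by n_heads")
      layer <- function() list(
        Wq = rmat(C_h, C_h), Wk = rmat(C_h, C_h), Wv = rmat(C_h, C_h),
        Wo = rmat(C_h, C_h), bo = numeric(C_h),
        ln1_g = rep(1, C_h), ln1_b = numeric(C_h),
        W1 = rmat(C_h, 2L * C_h, sd = sqrt(2 / C_h)), b1 = numeric(2L * C_h),
        W2 = rmat(2L * C_h, C_h), b2 = numeric(C_h),
        ln2_g = rep(1, C_h), ln2_b = numeric(C_h)
      )
      list(proj_W = rmat(C_in, C_h, sd = sqrt(2 / C_in)), proj_b = numeric(C_h),
           layers = replicate(n_layers, layer(), simplify = FALSE),
           n_heads = n_heads)
    }
  )
  structure(c(list(kind = kind, C_in = C_in, C_h = C_h), p),
            class = "temporal_params")
}

#' One step of a recurrent temporal model
#'
#' Advances an LSTM or GRU by one input frame.  The state of an LSTM is the
#' concatenation `c(h, c)` (length `2*C_h`); the state of a GRU is `h`.
#' Stepwise execution with state carried between calls is exactly
#' equivalent to [run_temporal_model()] on the whole sequence.
#'
#' @param params from [make_temporal_params()] (`lstm` or `gru`).
#' @param x input vector (length `C_in`).
#' @param state previous state; `NULL` means the zero initial state.
#' @return list with `h` (hidden state) and `state` (carry to next step).
#' @export
recurrent_step <- function(params, x, state = NULL) {
  C_h <- params$C_h
  if (params$kind == "lstm") {
    if (is.null(state)) state <- numeric(2L * C_h)
    hc <- ag_lstm_step(x, state, params$W, params$U, params$b)
    list(h = vof(hc)[seq_len(C_h)], state = hc)
  } else if (params$kind == "gru") {
    if (is.null(state)) state <- numeric(C_h)
    h <- ag_gru_step(x, state, params$W, params$U, params$bx, params$bh)
    list(h = vof(h), state = h)
  } else {
    stop("recurrent_step applies to lstm/gru only")
  }
}

# sinusoidal positional encoding, N x C (constant)
positional_encoding <- function(N, C) {
  pos <- seq_len(N) - 1
  pe <- matrix(0, N, C)
  half <- seq_len(C %/% 2)
  freq <- 1 / 10000^((2 * (half - 1)) / C)
  ang <- outer(pos, freq)
  pe[, 2 * half - 1] <- sin(ang)
  pe[, 2 * half] <- cos(ang)
  pe
}

# transformer encoder forward on autograd-compatible parameter entries.
# X: N x C_in (constant or node); pars: named list access function.
transformer_forward <- function(X, pars, n_heads, n_layers) {
  Xp <- ag_dense(X, pars("proj_W"), pars("proj_b"))
  N <- nrow(vof(Xp)); C <- ncol(vof(Xp))
  Z <- ag_add(Xp, positional_encoding(N, C))
  dh <- C %/% n_heads
  for (l in seq_len(n_layers)) {
    nm <- function(s) pars(paste0("l", l, ".", s))
    Q <- ag_matmul(Z, nm("Wq"))
    K <- ag_matmul(Z, nm("Wk"))
    V <- ag_matmul(Z, nm("Wv"))
    heads <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- ag_slice_cols(Q, idx)
      Kh <- ag_slice_cols(K, idx)
      Vh <- ag_slice_cols(V, idx)
      A <- ag_softmax_rows(ag_scale(ag_matmul(Qh, ag_t(Kh)), 1 / sqrt(dh)))
      heads[[h]] <- ag_matmul(A, Vh)
    }
    att <- ag_dense(ag_cbind(heads), nm("Wo"), nm("bo"))
    Z <- ag_layernorm(ag_add(Z, att), nm("ln1_g"), nm("ln1_b"))
    ff <- ag_dense(ag_dense(Z, nm("W1"), nm("b1"), "relu"), nm("W2"), nm("b2"))
    Z <- ag_layernorm(ag_add(Z, ff), nm("ln2_g"), nm("ln2_b"))
  }
  Z
}

#' Run a temporal model over a sequence of attended features
#'
#' For `lstm`/`gru`, runs the recurrence from the zero state and returns
#' the `N x C_h` matrix of per-step hidden states.  For `transformer`,
#' returns the per-position outputs of a standard (non-causal) encoder with
#' sinusoidal positional encoding.
#'
#' @param x `N x C_in` matrix of per-frame inputs.
#' @param params from [make_temporal_params()].
#' @return `N x C_h` matrix of per-step representations.
#' @export
run_temporal_model <- function(x, params) {
  if (!inherits(params, "temporal_params")) stop("params must be temporal_params")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$C_in) stop("input width does not match C_in")
  N <- nrow(x)
  if (params$kind %in% c("lstm", "gru")) {
    H <- matrix(0, N, params$C_h)
    st <- NULL
    for (i in seq_len(N)) {
      s <- recurrent_step(params, x[i, ], st)
      H[i, ] <- s$h
      st <- s$state
    }
    H
  } else {
    pars <- function(nm) {
      if (nm == "proj_W") return(params$proj_W)
      if (nm == "proj_b") return(params$proj_b)
      m <- regmatches(nm, regexec("^l([0-9]+)\\.(.*)$", nm))[[1]]
      params$layers[[as.integer(m[2])]][[m[3]]]
    }
    vof(transformer_forward(x, pars, params$n_heads, length(params$layers)))
  }
}

#' Create the final linear classifier
#'
#' @param C_h input width (hidden-state length).
#' @param seed integer seed.
#' @return list with weight vector `w` (length `C_h`) and scalar bias `b`.
#' @export
make_classifier_params <- function(C_h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(w = stats::rnorm(C_h, sd = sqrt(1 / C_h)), b = 0)
}

#' Classify a summary feature into an expert probability
#'
#' Sigmoid of an affine map of the final feature (`h_f` with temporal
#' attention, `h_N` without).  The hard label uses threshold 0.5.
#'
#' @param h feature vector of length `C_h`.
#' @param params from [make_classifier_params()].
#' @return probability in (0, 1).
#' @export
classify <- function(h, params) {
  if (length(h) != length(params$w)) stop("input width does not match classifier")
  1 / (1 + exp(-(sum(h * params$w) + params$b)))
}

#' Forward pass of the no-attention pathway
#'
#' The spatial attention module is replaced with average pooling over the
#' feature grid, the temporal model is run over the pooled features, and
#' the last frame's hidden state is classified (no temporal attention).
#'
#' @param features list of per-frame `H x W x C_e` arrays (or cell
#'   matrices).
#' @param temporal_params from [make_temporal_params()].
#' @param classifier_params from [make_classifier_params()].
#' @return probability in (0, 1).
#' @export
no_attention_forward <- function(features, temporal_params, classifier_params) {
  pooled <- t(vapply(features, function(f) {
    P <- if (length(dim(f)) == 3L) grid_to_cells(f) else f
    colMeans(P)
  }, numeric(temporal_params$C_in)))
  H <- run_temporal_model(pooled, temporal_params)
  classify(H[nrow(H), ], classifier_params)
}
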