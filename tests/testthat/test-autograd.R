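# The reverse-mode tape: analytic gradients of every fused operation are
# compared against central finite differences, and the taped forward value
# must equal the plain numeric forward.

test_that("attention-LSTM-Dice composite gradients match finite differences", {
  set.seed(101)
  Ce <- 6; Catt <- 5; Ch <- 4; cells <- 9; N <- 5
  P <- lapply(seq_len(N), function(i) matrix(rnorm(cells * Ce), cells, Ce))
  B <- matrix(rbinom(N * cells, 1, 0.2), N, cells)
  leaves <- leafify(list(
    Ma = matrix(rnorm(Ce * Catt), Ce, Catt),
    Ms = matrix(rnorm(Ch * Catt), Ch, Catt),
    Mo = rnorm(Catt),
    W = matrix(rnorm(Ce * 4 * Ch, sd = 0.3), Ce, 4 * Ch),
    U = matrix(rnorm(Ch * 4 * Ch, sd = 0.3), Ch, 4 * Ch),
    b = rnorm(4 * Ch),
    w = rnorm(Ch),
    b2 = 0.1
  ))
  fwd <- function() {
    st <- numeric(2 * Ch); hprev <- numeric(Ch)
    atts <- list(); hs <- list()
    for (i in seq_len(N)) {
      att <- surgskill:::ag_attention_step(P[[i]], hprev, leaves$Ma,
                                           leaves$Ms, leaves$Mo)
      atts[[i]] <- att
      xatt <- surgskill:::ag_attend_aggregate(att, P[[i]])
      st <- surgskill:::ag_lstm_step(xatt, st, leaves$W, leaves$U, leaves$b)
      h <- surgskill:::ag_slice(st, seq_len(Ch))
      hs[[i]] <- h
      hprev <- h
    }
    hf <- surgskill:::ag_temporal_attend(surgskill:::ag_rbind(hs))
    logit <- surgskill:::ag_add(surgskill:::ag_dot(hf, leaves$w), leaves$b2)
    bce <- surgskill:::ag_bce_logit(logit, 1)
    A <- surgskill:::ag_rbind(atts)
    inter <- surgskill:::ag_dot(A, B)
    num <- surgskill:::ag_add(surgskill:::ag_scale(inter, 2), 1)
    den <- surgskill:::ag_add(surgskill:::ag_sum(A), sum(B) + 1)
    dice <- surgskill:::ag_sub(1, surgskill:::ag_div(num, den))
    surgskill:::ag_add(bce, surgskill:::ag_scale(dice, 0.5))
  }
  v_plain <- surgskill:::vof(fwd())
  surgskill:::tape_begin()
  v_taped <- surgskill:::vof(fwd())
  surgskill:::tape_end()
  expect_identical(v_plain, v_taped)
  expect_fd_grads(fwd, leaves)
})

test_that("GRU chain gradients match finite differences", {
  set.seed(102)
  Ch <- 4; Cin <- 5; N <- 6
  X <- matrix(rnorm(N * Cin), N, Cin)
  leaves <- leafify(list(
    W = matrix(rnorm(Cin * 3 * Ch, sd = 0.4), Cin, 3 * Ch),
    U = matrix(rnorm(Ch * 3 * Ch, sd = 0.4), Ch, 3 * Ch),
    bx = rnorm(3 * Ch), bh = rnorm(3 * Ch), w = rnorm(Ch)
  ))
  fwd <- function() {
    h <- numeric(Ch); hs <- list()
    for (i in seq_len(N)) {
      h <- surgskill:::ag_gru_step(X[i, ], h, leaves$W, leaves$U,
                                   leaves$bx, leaves$bh)
      hs[[i]] <- h
    }
    hf <- surgskill:::ag_temporal_attend(surgskill:::ag_rbind(hs))
    surgskill:::ag_bce_logit(surgskill:::ag_dot(hf, leaves$w), 0)
  }
  expect_fd_grads(fwd, leaves)
})

test_that("transformer encoder gradients match finite differences", {
  set.seed(103)
  tp <- make_temporal_params("transformer", C_in = 5, C_h = 8,
                             n_layers = 2, n_heads = 4, seed = 3)
  flat <- list(proj_W = tp$proj_W, proj_b = tp$proj_b)
  for (l in seq_along(tp$layers)) {
    for (nm in names(tp$layers[[l]])) {
      flat[[paste0("l", l, ".", nm)]] <- tp$layers[[l]][[nm]]
    }
  }
  # nudge biases off the ReLU kink at exactly zero
  flat <- lapply(flat, function(v) {
    if (is.null(dim(v))) v + rnorm(length(v), sd = 0.05) else v
  })
  leaves <- leafify(flat)
  X <- matrix(rnorm(6 * 5), 6, 5)
  wcls <- rnorm(8)
  fwd <- function() {
    Z <- surgskill:::transformer_forward(X, function(nm) leaves[[nm]], 4, 2)
    hm <- surgskill:::ag_scale(
      surgskill:::ag_matmul(surgskill:::ag_t(Z), matrix(1, 6, 1)), 1 / 6)
    hv <- surgskill:::ag_reindex(hm, 1:8, NULL)
    surgskill:::ag_bce_logit(surgskill:::ag_dot(hv, wcls), 1)
  }
  expect_fd_grads(fwd, leaves, n_checks = 3, tol = 2e-3)
})

test_that("transposed-convolution decoder gradients match finite differences", {
  set.seed(104)
  dec <- make_decoder_params(6, n_layers = 3, channels = c(8, 4, 1),
                             seed = 4)
  flat <- list()
  for (l in 1:3) {
    flat[[paste0("dec.l", l, ".K")]] <- dec$layers[[l]]$K
    # random biases keep pre-activations off the ReLU kink
    flat[[paste0("dec.l", l, ".b")]] <- rnorm(length(dec$layers[[l]]$b),
                                              sd = 0.1)
  }
  leaves <- leafify(flat)
  Fm <- matrix(rnorm(4 * 6), 4, 6)
  tgt <- matrix(runif((2^3 * 2)^2), ncol = 1)
  fwd <- function() {
    res <- surgskill:::decoder_run(Fm, dec, 2, 2, function(nm) leaves[[nm]])
    surgskill:::ag_mse(res$X, tgt)
  }
  expect_fd_grads(fwd, leaves)
})

test_that("gradients of the combined loss w.r.t. attention parameters are finite and nonzero", {
  set.seed(105)
  cells <- 16; Ce <- 8; Catt <- 6; Ch <- 4
  P <- matrix(rnorm(cells * Ce), cells, Ce)
  hprev <- rnorm(Ch)
  Bv <- numeric(cells); Bv[5] <- 1
  leaves <- leafify(make_attention_params(Ce, Catt, Ch, seed = 9))
  w <- rnorm(Ce)
  fwd <- function() {
    att <- surgskill:::ag_attention_step(P, hprev, leaves$Ma, leaves$Ms,
                                         leaves$Mo)
    xatt <- surgskill:::ag_attend_aggregate(att, P)
    bce <- surgskill:::ag_bce_logit(surgskill:::ag_dot(xatt, w), 1)
    inter <- surgskill:::ag_dot(att, Bv)
    num <- surgskill:::ag_add(surgskill:::ag_scale(inter, 2), 1e-6)
    den <- surgskill:::ag_add(surgskill:::ag_sum(att), sum(Bv) + 1e-6)
    dice <- surgskill:::ag_sub(1, surgskill:::ag_div(num, den))
    surgskill:::ag_add(bce, surgskill:::ag_scale(dice, 0.5))
  }
  surgskill:::tape_begin()
  loss <- fwd()
  surgskill:::ag_backward(loss)
  surgskill:::tape_end()
  for (nm in names(leaves)) {
    g <- leaves[[nm]]$g
    expect_true(all(is.finite(g)), label = paste("finite grad for", nm))
    expect_gt(sum(abs(g)), 0)
  }
  expect_fd_grads(fwd, leaves)
})

test_that("batched (deferred) parameter gradients equal the direct per-step gradients", {
  set.seed(106)
  for (tm in c("lstm", "gru")) {
    cfg <- model_config(tm, TRUE, "supervised", "aggregation",
                        C_att = 6, C_h = 5)
    m <- build_model(cfg, seed = 3)
    N <- 4; cells <- 64
    feats <- lapply(seq_len(N), function(i) matrix(rnorm(cells * 32),
                                                   cells, 32))
    B <- matrix(0, N, cells); B[cbind(1:N, sample(cells, N))] <- 1
    run <- function(defer_on) {
      withr::local_options(surgskill.defer = defer_on)
      leaves <- lapply(m$params[m$trainable], surgskill:::ag_leaf)
      surgskill:::tape_begin()
      bnd <- surgskill:::model_forward(m, feats, label = 1, B = B,
                                       pget = function(nm) leaves[[nm]])
      loss <- surgskill:::bundle_loss(bnd, m$config)
      surgskill:::ag_backward(loss)
      if (!is.null(bnd$.defer)) surgskill:::defer_flush(bnd$.defer)
      surgskill:::tape_end()
      lapply(leaves, function(l) l$g)
    }
    ga <- run(TRUE); gb <- run(FALSE)
    for (nm in names(ga)) {
      expect_equal(ga[[nm]], gb[[nm]], tolerance = 1e-12,
                   label = paste(tm, nm))
    }
  }
})

test_that("the compiled fused training step equals the R tape path", {
  set.seed(107)
  for (tm in c("lstm", "gru")) {
    for (scheme in c("aggregation", "selection")) {
      for (sup in c(TRUE, FALSE)) {
        cfg <- model_config(tm, TRUE,
                            if (sup) "supervised" else "unsupervised",
                            scheme, C_att = 7, C_h = 6)
        m <- build_model(cfg, seed = 4)
        N <- 5; cells <- 64
        penult <- lapply(seq_len(N), function(i) {
          matrix(rnorm(cells * 32), cells, 32)
        })
        B <- matrix(0, N, cells); B[cbind(1:N, sample(cells, N))] <- 1
        # R reference gradients (direct per-step accumulation)
        leaves <- lapply(m$params[m$trainable], surgskill:::ag_leaf)
        withr::local_options(surgskill.defer = FALSE)
        surgskill:::tape_begin()
        bnd <- surgskill:::model_forward(m, penult, label = 1,
                                         B = if (sup) B,
                                         pget = function(nm) leaves[[nm]])
        loss <- surgskill:::bundle_loss(bnd, m$config)
        surgskill:::ag_backward(loss)
        surgskill:::tape_end()
        # compiled path consumes final features (aggregation) or the
        # penultimate stage with the trainable last block (selection)
        if (identical(scheme, "selection")) {
          feats <- penult
        } else {
          feats <- lapply(penult, function(P) {
            surgskill:::vof(surgskill:::encoder_last_block(
              P, m$encoder$last$W, m$encoder$last$b))
          })
          attr(feats, "stage") <- "final"
        }
        leaves2 <- lapply(m$params[m$trainable], surgskill:::ag_leaf)
        res <- surgskill:::fast_train_step(
          m, leaves2, list(feats = feats, B = if (sup) B, label = 1), cfg)
        expect_equal(res$loss, surgskill:::vof(loss), tolerance = 1e-10,
                     label = paste(tm, scheme, sup))
        for (nm in names(leaves)) {
          ga <- leaves[[nm]]$g
          gb <- leaves2[[nm]]$g
          if (is.null(ga)) ga <- leaves[[nm]]$v * 0
          if (is.null(gb)) gb <- leaves2[[nm]]$v * 0
          expect_lt(max(abs(ga - gb)), 1e-9)
        }
      }
    }
  }
})
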