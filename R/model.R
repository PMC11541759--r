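# Assembly of the spatial-temporal attention models: a frame encoder, the
# spatial attention core with its two attending schemes, a temporal model
# (LSTM / GRU / transformer), optional unsupervised temporal attention,
# and an optional multi-task keypoint decoder.

#' Model configuration
#'
#' Validates the combination rules of the model family:
#' * `spatial_attention = "none"` replaces attention with average pooling
#'   (the attending `scheme` is ignored);
#' * `multitask = TRUE` requires the aggregation scheme (the keypoint
#'   decoder consumes the attention-weighted feature map);
#' * `temporal_module = "transformer"` drops temporal attention (a
#'   transformer is already a temporal attention model) and removes the
#'   hidden-state input to the spatial attention scorer.
#'
#' The supervision weight `lambda` is forced to 0 unless
#' `spatial_attention = "supervised"`.  The selection scheme unfreezes the
#' encoder's last block during training (applied uniformly to all
#' selection-scheme configurations).
#'
#' @param temporal_module `"lstm"`, `"gru"`, or `"transformer"`.
#' @param temporal_attention attend over hidden states (`TRUE`) or use the
#'   last hidden state (`FALSE`).
#' @param spatial_attention `"none"`, `"unsupervised"`, or `"supervised"`.
#' @param scheme attending scheme, `"aggregation"` or `"selection"`.
#' @param multitask add the keypoint-localization decoder branch.
#' @param encoder `"tiny"`, `"deep"`, or a [frame_encoder()] object.
#' @param C_att,C_h attention hidden width and temporal hidden size
#'   (defaults scale with the encoder: 1024 for `"deep"`, 128 for
#'   `"tiny"`).
#' @param lambda Dice supervision weight (reference 0.5).
#' @param mu multitask MSE weight (default 1).
#' @param sigma_kp Gaussian target scale in pixels (default 6 at 224-px
#'   frames, scaled with frame size).
#' @param n_layers,n_heads transformer depth and heads.
#' @return a validated `model_config`.
#' @export
model_config <- function(temporal_module = c("lstm", "gru", "transformer"),
                         temporal_attention = TRUE,
                         spatial_attention = c("supervised", "unsupervised",
                                               "none"),
                         scheme = c("aggregation", "selection"),
                         multitask = FALSE,
                         encoder = "tiny",
                         C_att = NULL, C_h = NULL,
                         lambda = 0.5, mu = 1, sigma_kp = NULL,
                         n_layers = 2L, n_heads = 4L) {
  temporal_module <- match.arg(temporal_module)
  spatial_attention <- match.arg(spatial_attention)
  scheme <- match.arg(scheme)
  enc_type <- if (inherits(encoder, "frame_encoder")) encoder$type else encoder
  if (is.character(enc_type)) {
    enc_type <- match.arg(enc_type, c("tiny", "deep", "custom"))
  }
  if (spatial_attention == "none") {
    scheme <- NA_character_
    if (multitask) {
      stop("configuration error: multitask requires spatial attention ",
           "(the decoder consumes the attention-weighted feature map)")
    }
  }
  if (multitask && !identical(scheme, "aggregation")) {
    stop("configuration error: multitask = TRUE requires scheme = ",
         "\"aggregation\"")
  }
  if (temporal_module == "transformer" && temporal_attention) {
    stop("configuration error: temporal_module = \"transformer\" requires ",
         "temporal_attention = FALSE (the transformer is itself a temporal ",
         "attention model)")
  }
  if (spatial_attention != "supervised") lambda <- 0
  if (lambda < 0) stop("lambda must be nonnegative")
  deep_like <- enc_type == "deep"
  if (is.null(C_att)) C_att <- if (deep_like) 1024L else 128L
  if (is.null(C_h)) C_h <- if (deep_like) 1024L else 128L
  structure(list(temporal_module = temporal_module,
                 temporal_attention = temporal_attention,
                 spatial_attention = spatial_attention,
                 scheme = scheme, multitask = multitask,
                 encoder = encoder, C_att = as.integer(C_att),
                 C_h = as.integer(C_h), lambda = lambda, mu = mu,
                 sigma_kp = sigma_kp, n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads)),
            class = "model_config")
}

#' The standard model matrix
#'
#' The 14 evaluated variants: LSTM backbones with unsupervised/supervised
#' attention under both attending schemes, with and without temporal
#' attention and spatial attention, the multitask baseline, and GRU /
#' transformer backbones.
#'
#' @param encoder encoder type or object passed to every config.
#' @return named list of [model_config()] objects.
#' @export
model_variants <- function(encoder = "tiny") {
  mc <- function(...) model_config(..., encoder = encoder)
  list(
    lstm_agg = mc("lstm", TRUE, "unsupervised", "aggregation"),
    lstm_mul_agg = mc("lstm", TRUE, "unsupervised", "aggregation",
                      multitask = TRUE),
    lstm_agg_sup = mc("lstm", TRUE, "supervised", "aggregation"),
    lstm_sel_sup = mc("lstm", TRUE, "supervised", "selection"),
    lstm_agg_sup_not = mc("lstm", FALSE, "supervised", "aggregation"),
    lstm_sel_sup_not = mc("lstm", FALSE, "supervised", "selection"),
    lstm_no_spatial = mc("lstm", TRUE, "none"),
    lstm_no_spatial_not = mc("lstm", FALSE, "none"),
    gru_agg = mc("gru", TRUE, "unsupervised", "aggregation"),
    gru_agg_sup = mc("gru", TRUE, "supervised", "aggregation"),
    gru_sel_sup = mc("gru", TRUE, "supervised", "selection"),
    transformer_agg = mc("transformer", FALSE, "unsupervised",
                         "aggregation"),
    transformer_agg_sup = mc("transformer", FALSE, "supervised",
                             "aggregation"),
    transformer_sel_sup = mc("transformer", FALSE, "supervised",
                             "selection")
  )
}

#' Build a model from a configuration
#'
#' Initializes the encoder and all parameter groups and records which
#' parameters are trainable: the encoder's convolutional stack is frozen;
#' its last block becomes trainable under the selection scheme; the
#' attending stage itself is parameter-free (both schemes reuse the
#' attention scorer's weights).
#'
#' @param cfg a [model_config()].
#' @param seed integer initialization seed.
#' @return a `surgskill_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  encoder <- if (inherits(cfg$encoder, "frame_encoder")) cfg$encoder else {
    frame_encoder(cfg$encoder, seed = seed)
  }
  set.seed(seed + 1L)
  params <- list()
  trainable <- character()
  C_e <- encoder$C_e
  if (cfg$spatial_attention != "none") {
    C_h_att <- if (cfg$temporal_module == "transformer") NULL else cfg$C_h
    ap <- make_attention_params(C_e, cfg$C_att, C_h_att)
    params[["att.Ma"]] <- ap$Ma
    if (!is.null(ap$Ms)) params[["att.Ms"]] <- ap$Ms
    params[["att.Mo"]] <- ap$Mo
    trainable <- c(trainable, grep("^att\\.", names(params), value = TRUE))
  }
  tp <- make_temporal_params(cfg$temporal_module, C_in = C_e, C_h = cfg$C_h,
                             n_layers = cfg$n_layers, n_heads = cfg$n_heads)
  if (cfg$temporal_module == "lstm") {
    params[c("tmp.W", "tmp.U", "tmp.b")] <- tp[c("W", "U", "b")]
  } else if (cfg$temporal_module == "gru") {
    params[c("tmp.W", "tmp.U", "tmp.bx", "tmp.bh")] <-
      tp[c("W", "U", "bx", "bh")]
  } else {
    params[["tmp.proj_W"]] <- tp$proj_W
    params[["tmp.proj_b"]] <- tp$proj_b
    for (l in seq_along(tp$layers)) {
      for (nm in names(tp$layers[[l]])) {
        params[[paste0("tmp.l", l, ".", nm)]] <- tp$layers[[l]][[nm]]
      }
    }
  }
  trainable <- c(trainable, grep("^tmp\\.", names(params), value = TRUE))
  cp <- make_classifier_params(cfg$C_h)
  params[["cls.w"]] <- cp$w
  params[["cls.b"]] <- cp$b
  trainable <- c(trainable, "cls.w", "cls.b")
  decoder <- NULL
  if (cfg$multitask) {
    n_up <- round(log2(encoder$frame_size / encoder$H))
    decoder <- make_decoder_params(C_e, n_layers = n_up)
    for (l in seq_len(decoder$n_layers)) {
      params[[paste0("dec.l", l, ".K")]] <- decoder$layers[[l]]$K
      params[[paste0("dec.l", l, ".b")]] <- decoder$layers[[l]]$b
    }
    trainable <- c(trainable, grep("^dec\\.", names(params), value = TRUE))
  }
  if (identical(cfg$scheme, "selection")) {
    params[["enc.last.W"]] <- encoder$last$W
    params[["enc.last.b"]] <- encoder$last$b
    trainable <- c(trainable, "enc.last.W", "enc.last.b")
  }
  sigma_kp <- cfg$sigma_kp
  if (is.null(sigma_kp)) sigma_kp <- 6 * encoder$frame_size / 224
  structure(list(config = cfg, encoder = encoder, params = params,
                 trainable = trainable, decoder = decoder,
                 sigma_kp = sigma_kp, tp_meta = tp),
            class = "surgskill_model")
}

#' @export
print.surgskill_model <- function(x, ...) {
  cfg <- x$config
  cat("<surgskill_model> ", cfg$temporal_module,
      if (isTRUE(cfg$temporal_attention)) "+temporal-attention" else "",
      " | spatial: ", cfg$spatial_attention,
      if (!is.na(cfg$scheme)) paste0(" (", cfg$scheme, ")") else "",
      if (cfg$multitask) " | multitask" else "",
      "\n  encoder: ", x$encoder$type, " (", x$encoder$H, "x", x$encoder$W,
      "x", x$encoder$C_e, "), C_h = ", cfg$C_h,
      ", lambda = ", cfg$lambda, "\n", sep = "")
  cat("  trainable parameters: ",
      sum(vapply(x$params[x$trainable], length, numeric(1))), " in ",
      length(x$trainable), " arrays\n", sep = "")
  invisible(x)
}

# Apply the frozen last encoder block numerically, or defer to the
# trainable node via pget when the selection policy unfroze it.
final_features <- function(model, penult, pget = NULL) {
  if (is.null(model$encoder$last)) return(penult)  # custom encoder
  W <- if (!is.null(pget)) pget("enc.last.W") else NULL
  b <- if (!is.null(pget)) pget("enc.last.b") else NULL
  if (is.null(W)) W <- model$params[["enc.last.W"]]
  if (is.null(W)) W <- model$encoder$last$W
  if (is.null(b)) b <- model$params[["enc.last.b"]]
  if (is.null(b)) b <- model$encoder$last$b
  encoder_last_block(penult, W, b)
}

# Core forward pass over a clip's penultimate feature list.
#
# penult_list: list of N (cells x C_penult) matrices (constants).
# pget(name): returns the autograd leaf for a trainable parameter during
#   training, else NULL; plain arrays are used for everything else.
# B: optional N x cells binary heat-map matrix (row-major cells).
# kp_targets: optional list of per-frame target heat maps (multitask).
# label: optional 0/1 for the BCE loss.
#
# Returns values (probabilities, attention maps) plus loss nodes when a
# tape is active.
model_forward <- function(model, penult_list, label = NULL, B = NULL,
                          kp_targets = NULL, pget = NULL) {
  cfg <- model$config
  pv <- function(nm) {
    if (!is.null(pget)) {
      nd <- pget(nm)
      if (!is.null(nd)) return(nd)
    }
    model$params[[nm]]
  }
  N <- length(penult_list)
  pre_final <- identical(attr(penult_list, "stage"), "final")
  H <- model$encoder$H; W <- model$encoder$W
  cells <- H * W
  # batched parameter-gradient buffers for the per-frame fused ops
  defer <- NULL
  if (tape_active() && !is.null(pget) &&
      isTRUE(getOption("surgskill.defer", TRUE)) &&
      cfg$temporal_module %in% c("lstm", "gru")) {
    lv <- list(Ma = pget("att.Ma"), Ms = pget("att.Ms"),
               W = pget("tmp.W"), U = pget("tmp.U"), b = pget("tmp.b"),
               bx = pget("tmp.bx"), bh = pget("tmp.bh"))
    lv <- Filter(is_node, lv)
    if (length(lv) > 0) {
      gate_width <- if (cfg$temporal_module == "lstm") 4L * cfg$C_h else {
        3L * cfg$C_h
      }
      defer <- defer_create(N, cells, cfg$C_att, model$encoder$C_e,
                            cfg$C_h, gate_width, lv)
    }
  }
  use_hidden <- cfg$spatial_attention != "none" &&
    cfg$temporal_module %in% c("lstm", "gru")
  atts <- vector("list", N)
  x_atts <- vector("list", N)
  P_list <- vector("list", N)
  # precompute the appearance term of the attention scores for the whole
  # clip in one matrix product when the features are plain values
  f_app_list <- NULL
  if (cfg$spatial_attention != "none") {
    if (pre_final && !any(vapply(penult_list, is_node, logical(1)))) {
      Pstack <- do.call(rbind, penult_list)
      FAPP <- Pstack %*% vof(pv("att.Ma"))
      f_app_list <- lapply(seq_len(N), function(i) {
        FAPP[((i - 1L) * cells + 1L):(i * cells), , drop = FALSE]
      })
      if (!is.null(defer)) defer$Pstack <- Pstack
    }
  }
  hs <- vector("list", N)
  pred_kp <- if (cfg$multitask) vector("list", N) else NULL
  recurrent <- cfg$temporal_module %in% c("lstm", "gru")
  state <- if (cfg$temporal_module == "lstm") numeric(2L * cfg$C_h) else {
    numeric(cfg$C_h)
  }
  h_prev <- numeric(cfg$C_h)
  for (i in seq_len(N)) {
    P <- if (pre_final) penult_list[[i]] else {
      final_features(model, penult_list[[i]], pget)
    }
    P_list[[i]] <- P
    if (cfg$spatial_attention != "none") {
      att <- ag_attention_step(P, if (use_hidden) h_prev,
                               pv("att.Ma"),
                               if (use_hidden) pv("att.Ms"),
                               pv("att.Mo"), defer = defer, frame = i,
                               f_app = f_app_list[[i]])
      atts[[i]] <- att
      if (identical(cfg$scheme, "selection")) {
        x_att <- ag_row(P, which.max(vof(att)))
      } else {
        x_att <- ag_attend_aggregate(att, P)
      }
      if (cfg$multitask) {
        xt <- ag_rowscale(P, att)
        pred_kp[[i]] <- decoder_run(xt, model$decoder, H, W, pget)$X
      }
    } else {
      x_att <- if (is_node(P)) {
        ag_scale(ag_attend_aggregate(rep(1, cells), P), 1 / cells)
      } else {
        colMeans(vof(P))
      }
    }
    x_atts[[i]] <- x_att
    if (recurrent) {
      if (cfg$temporal_module == "lstm") {
        state <- ag_lstm_step(x_att, state, pv("tmp.W"), pv("tmp.U"),
                              pv("tmp.b"), defer = defer, frame = i)
        h <- ag_slice(state, seq_len(cfg$C_h))
      } else {
        state <- ag_gru_step(x_att, state, pv("tmp.W"), pv("tmp.U"),
                             pv("tmp.bx"), pv("tmp.bh"), defer = defer,
                             frame = i)
        h <- state
      }
      hs[[i]] <- h
      h_prev <- h
    }
  }
  if (!recurrent) {
    X <- ag_rbind(x_atts)
    Z <- transformer_forward(X, function(nm) pv(paste0("tmp.", nm)),
                             cfg$n_heads, cfg$n_layers)
    # classifier input: mean over position outputs
    h_final <- ag_scale(ag_matmul(ag_t(Z), matrix(1, N, 1)), 1 / N)
    h_final <- ag_reindex(h_final, seq_len(cfg$C_h), NULL)
    temporal_w <- NULL
  } else if (cfg$temporal_attention) {
    Hm <- ag_rbind(hs)
    h_final <- ag_temporal_attend(Hm)
    temporal_w <- {
      Hv <- vof(Hm)
      softmax_vec(as.vector(Hv %*% Hv[N, ]))
    }
  } else {
    h_final <- hs[[N]]
    temporal_w <- NULL
  }
  logit <- ag_add(ag_dot(h_final, pv("cls.w")), pv("cls.b"))
  prob <- 1 / (1 + exp(-vof(logit)))
  out <- list(prob = prob, .defer = defer,
              spatial_attention = if (cfg$spatial_attention != "none") {
                lapply(atts, vof)
              },
              temporal_attention = temporal_w)
  if (!is.null(label)) out$bce <- ag_bce_logit(logit, label)
  if (!is.null(B) && cfg$spatial_attention != "none") {
    A <- ag_rbind(atts)
    inter <- ag_dot(A, B)
    eps <- 1
    num <- ag_add(ag_scale(inter, 2), eps)
    den <- ag_add(ag_sum(A), sum(B) + eps)
    out$dice <- ag_sub(1, ag_div(num, den))
  }
  if (cfg$multitask && !is.null(kp_targets)) {
    mses <- lapply(seq_len(N), function(i) {
      ag_mse(pred_kp[[i]], kp_targets[[i]])
    })
    acc <- mses[[1]]
    if (N > 1) for (i in 2:N) acc <- ag_add(acc, mses[[i]])
    out$mse <- ag_scale(acc, 1 / N)
  }
  if (cfg$multitask) {
    out$pred_heatmaps <- lapply(pred_kp, function(p) {
      v <- vof(p)
      cells_to_grid(as.vector(v), H * 2L^model$decoder$n_layers,
                    W * 2L^model$decoder$n_layers)
    })
  }
  out
}

# total training loss node from a forward bundle
bundle_loss <- function(bundle, cfg) {
  loss <- bundle$bce
  if (!is.null(bundle$dice) && cfg$lambda > 0) {
    loss <- ag_add(loss, ag_scale(bundle$dice, cfg$lambda))
  }
  if (!is.null(bundle$mse)) loss <- ag_add(loss, ag_scale(bundle$mse, cfg$mu))
  loss
}

#' Forward pass of a model on one clip
#'
#' Runs the encoder (or consumes precomputed features), the spatial
#' attention core, the temporal model, and the classifier in evaluation
#' mode.  Deterministic given weights and clip.
#'
#' @param model a `surgskill_model` (method dispatch allows substituting
#'   other objects implementing this generic).
#' @param clip a `clip_sample`, or `NULL` when `feats` is supplied.
#' @param heatmaps optional `N x cells` binary heat-map matrix; when the
#'   model is supervised its per-clip soft Dice loss is returned as
#'   `dice`.
#' @param feats optional list of per-frame penultimate cell matrices
#'   (bypasses the encoder).
#' @param ... passed to methods.
#' @return list with `prob`, `spatial_attention` (per-frame cell weight
#'   vectors or `NULL`), `temporal_attention`, and loss components when
#'   targets were supplied.
#' @export
forward_clip <- function(model, clip, ...) UseMethod("forward_clip")

#' @rdname forward_clip
#' @export
forward_clip.surgskill_model <- function(model, clip, heatmaps = NULL,
                                         feats = NULL, ...) {
  if (is.null(feats)) {
    if (is.null(clip)) stop("either clip or feats must be supplied")
    d <- dim(clip$frames[[1]])
    if (d[1] != model$encoder$frame_size) {
      stop("frame size ", d[1], " does not match encoder input size ",
           model$encoder$frame_size)
    }
    feats <- lapply(clip$frames, function(f) {
      encode_frame(model$encoder, f, "penult")
    })
  }
  if (is.null(heatmaps) && !is.null(clip) &&
      model$config$spatial_attention == "supervised") {
    heatmaps <- clip_heatmaps(clip, model$encoder)
  }
  label <- if (!is.null(clip)) clip$label
  model_forward(model, feats, label = label, B = heatmaps)
}

# Binary trajectory heat maps for all frames of a clip, as an
# N x cells matrix in the model's grid geometry (row-major cells).
clip_heatmaps <- function(clip, encoder, frame_size = NULL) {
  fs <- if (!is.null(frame_size)) frame_size else {
    if (length(clip$frames) > 0L) dim(clip$frames[[1]])[1] else {
      encoder$frame_size
    }
  }
  t(vapply(clip$keypoints, function(kp) {
    as.vector(t(build_trajectory_heatmap(kp, fs, c(encoder$H, encoder$W))))
  }, numeric(encoder$H * encoder$W)))
}
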