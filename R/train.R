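# Training protocol, cross-validation and internal/external validation.

#' Training protocol settings
#'
#' Reference protocol: Adam with initial learning rate 1e-3, reduced by a
#' factor of 10 when the validation loss plateaus (patience 5 epochs,
#' floor 1e-6); batch size 2 (1 for the multitask model); one fresh clip
#' sampled per video per epoch; the checkpoint with the lowest validation
#' loss is retained.  Test-time prediction averages the probabilities of
#' `n_test_clips` independently sampled clips.
#'
#' @param epochs training epochs (reference 50; desk-scale profile 20).
#' @param lr initial learning rate.
#' @param batch_size clips per optimizer step.
#' @param clip_len,stride clip sampling parameters (reference 256 / 8).
#' @param annotation_interval keypoint annotation spacing.
#' @param patience epochs without validation improvement before the
#'   learning rate is divided by 10.
#' @param min_lr learning-rate floor.
#' @param n_val_clips validation clips per video (sampled once, reused
#'   each epoch so the plateau signal is comparable across epochs).
#' @param n_test_clips clips averaged at test time (default 3).
#' @param augment apply clip augmentation during training (requires
#'   frame-level access; incompatible with a precomputed feature cache).
#' @param aug_params ranges from [augmentation_params()].
#' @param clip_grad global gradient-norm clipping threshold (stabilizes
#'   recurrent training near convergence); `Inf` disables.
#' @param seed integer seed for clip sampling and batching.
#' @param verbose print per-epoch losses.
#' @return a `training_protocol` list.
#' @export
training_protocol <- function(epochs = 20, lr = 1e-3, batch_size = 2,
                              clip_len = 256, stride = 8,
                              annotation_interval = 12, patience = 5,
                              min_lr = 1e-6, n_val_clips = 1,
                              n_test_clips = 3, augment = FALSE,
                              aug_params = augmentation_params(),
                              clip_grad = 5, seed = 1L, verbose = FALSE) {
  structure(as.list(environment()), class = "training_protocol")
}

# per-video keypoint tables, read once
keypoint_cache <- function(records) {
  env <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(records))) {
    env[[records$video_id[r]]] <- read_keypoints(records$keypoint_file[r])
  }
  env
}

# Assemble the forward inputs for one sampled clip of one video.
# Returns list(feats, B, kp_targets, label).  `final_cache`, when given,
# holds per-video features with the frozen last encoder block already
# applied (reused across epochs); `heat_env` caches per-annotated-frame
# heat-map rows per video.
clip_inputs <- function(record, indices, model, protocol, features = NULL,
                        kp_env = NULL, need_heatmaps = FALSE,
                        need_kp_targets = FALSE, final_cache = NULL,
                        heat_env = NULL) {
  enc <- model$encoder
  kp_tab <- if (!is.null(kp_env)) kp_env[[record$video_id]] else {
    read_keypoints(record$keypoint_file)
  }
  if (!is.null(features) && !is.null(features[[record$video_id]])) {
    if (!is.null(final_cache)) {
      frames_list <- final_cache[[record$video_id]]
      if (is.null(frames_list)) {
        arr <- features[[record$video_id]]
        d <- dim(arr)
        flat <- matrix(aperm(arr, c(2L, 1L, 3L)), d[1] * d[2], d[3])
        fin <- vof(encoder_last_block(flat, model$params[["enc.last.W"]] %||%
                                        enc$last$W,
                                      model$params[["enc.last.b"]] %||%
                                        enc$last$b))
        # one matrix per frame so clip assembly is a plain list lookup
        frames_list <- lapply(seq_len(d[1]), function(i) {
          fin[((i - 1L) * d[2] + 1L):(i * d[2]), , drop = FALSE]
        })
        final_cache[[record$video_id]] <- frames_list
      }
      feats <- frames_list[indices + 1L]
      attr(feats, "stage") <- "final"
    } else {
      arr <- features[[record$video_id]]
      feats <- lapply(indices + 1L, function(i) arr[i, , ])
    }
    kps <- NULL
    fs <- enc$frame_size
  } else {
    clip <- load_clip(record, indices,
                      annotation_interval = protocol$annotation_interval)
    if (isTRUE(protocol$augment)) clip <- augment_clip(clip, protocol$aug_params)
    feats <- lapply(clip$frames, function(f) encode_frame(enc, f, "penult"))
    kps <- clip$keypoints
    fs <- dim(clip$frames[[1]])[1]
  }
  if (is.null(kps) && (need_heatmaps || need_kp_targets)) {
    kps <- assign_keypoints_to_frames(indices, kp_tab,
                                      protocol$annotation_interval)
  }
  B <- NULL
  if (need_heatmaps) {
    if (!is.null(heat_env)) {
      hc <- heat_env[[record$video_id]]
      if (is.null(hc)) {
        ann <- sort(unique(kp_tab$frame_index))
        mat <- if (length(ann) == 0L) NULL else {
          t(vapply(ann, function(a) {
            kp <- kp_tab[kp_tab$frame_index == a, , drop = FALSE]
            as.vector(t(build_trajectory_heatmap(kp, fs, c(enc$H, enc$W))))
          }, numeric(enc$H * enc$W)))
        }
        hc <- list(ann = ann, mat = mat)
        heat_env[[record$video_id]] <- hc
      }
      if (is.null(hc$mat)) {
        B <- matrix(0, length(indices), enc$H * enc$W)
      } else {
        k <- protocol$annotation_interval
        lower <- k * (indices %/% k)
        donor <- ifelse(indices - lower <= lower + k - indices, lower,
                        lower + k)
        donor <- pmin(donor, max(hc$ann))
        B <- hc$mat[match(donor, hc$ann), , drop = FALSE]
        B[is.na(B)] <- 0
      }
    } else {
      B <- t(vapply(kps, function(kp) {
        as.vector(t(build_trajectory_heatmap(kp, fs, c(enc$H, enc$W))))
      }, numeric(enc$H * enc$W)))
    }
  }
  kp_targets <- NULL
  if (need_kp_targets) {
    out_res <- enc$H * 2L^model$decoder$n_layers
    kp_targets <- lapply(kps, function(kp) {
      g <- gaussian_target_heatmap(kp, out_res, model$sigma_kp)
      matrix(as.vector(t(g)), ncol = 1L)
    })
  }
  list(feats = feats, B = B, kp_targets = kp_targets,
       label = record$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Whether a configuration can use the native fused clip-gradient routine
fast_eligible <- function(cfg) {
  cfg$temporal_module %in% c("lstm", "gru") && !cfg$multitask &&
    cfg$spatial_attention != "none" &&
    isTRUE(getOption("surgskill.fastclip", TRUE))
}

# One training clip through the native fused forward/backward; gradients
# are accumulated into the leaves.  Numerically equivalent to the R tape
# (asserted in the tests).
fast_train_step <- function(model, leaves, inp, cfg, accumulate = TRUE) {
  feats <- inp$feats
  featstack <- do.call(rbind, feats)
  train_last <- !is.null(leaves[["enc.last.W"]])
  lv <- function(nm) {
    l <- leaves[[nm]]
    if (!is.null(l)) l$v else model$params[[nm]]
  }
  gru <- cfg$temporal_module == "gru"
  res <- fast_clip_grad(
    featstack, lv("att.Ma"), lv("att.Ms"), lv("att.Mo"),
    lv("tmp.W"), lv("tmp.U"),
    if (gru) lv("tmp.bx") else lv("tmp.b"),
    if (gru) lv("tmp.bh") else numeric(0),
    lv("cls.w"), lv("cls.b"),
    if (!is.null(inp$B)) inp$B else matrix(0, 0, 0),
    if (train_last) lv("enc.last.W") else matrix(0, 0, 0),
    if (train_last) lv("enc.last.b") else numeric(0),
    length(feats), nrow(feats[[1]]), inp$label, cfg$lambda, 1,
    TRUE, identical(cfg$scheme, "selection"), gru,
    isTRUE(cfg$temporal_attention), train_last, FALSE)
  if (!accumulate) return(res)
  gmap <- c(att.Ma = "gMa", att.Ms = "gMs", att.Mo = "gMo",
            tmp.W = "gW", tmp.U = "gU", cls.w = "gcls_w",
            cls.b = "gcls_b", enc.last.W = "glastW",
            enc.last.b = "glastb")
  if (gru) {
    gmap <- c(gmap, tmp.bx = "gb", tmp.bh = "gbh")
  } else {
    gmap <- c(gmap, tmp.b = "gb")
  }
  for (nm in names(gmap)) {
    l <- leaves[[nm]]
    if (is.null(l) || is.null(res[[gmap[[nm]]]])) next
    g <- res[[gmap[[nm]]]]
    if (is.null(dim(l$v)) && !is.null(dim(g))) g <- as.vector(g)
    accum(l, g)
  }
  res
}

# Adam optimizer state and update
adam_init <- function(leaves) {
  list(m = lapply(leaves, function(l) l$v * 0),
       v = lapply(leaves, function(l) l$v * 0),
       t = 0L)
}

adam_step <- function(state, leaves, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(leaves)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    leaves[[nm]]$v <- leaves[[nm]]$v -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  state
}

#' Train a model
#'
#' One fresh clip is sampled from each training video per epoch; the
#' validation loss is tracked on fixed validation clips and the parameter
#' set with the lowest validation loss is retained.  The training loss
#' decomposition (binary cross-entropy, Dice supervision, multitask MSE)
#' is logged per epoch.
#'
#' @param model a `surgskill_model` from [build_model()].
#' @param train_records,val_records disjoint manifest subsets.
#' @param protocol a [training_protocol()].
#' @param features optional feature cache from [encode_videos()].
#' @return the model with trained parameters, plus `log` (per-epoch data
#'   frame) and `best_val_loss`.
#' @export
train_model <- function(model, train_records, val_records,
                        protocol = training_protocol(), features = NULL) {
  stopifnot(inherits(model, "surgskill_model"))
  if (nrow(train_records) == 0L) stop("empty training set")
  if (length(intersect(train_records$video_id, val_records$video_id)) > 0L) {
    stop("train and validation video sets overlap")
  }
  cfg <- model$config
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  batch_size <- if (cfg$multitask) 1L else protocol$batch_size
  need_B <- cfg$lambda > 0
  need_kp <- cfg$multitask
  kp_env <- keypoint_cache(rbind(train_records, val_records))
  final_cache <- if (!"enc.last.W" %in% model$trainable && !is.null(features)) {
    new.env(parent = emptyenv())
  }
  heat_env <- if (need_B) new.env(parent = emptyenv())
  # fixed validation clips
  val_sets <- lapply(seq_len(nrow(val_records)), function(r) {
    lapply(seq_len(protocol$n_val_clips), function(j) {
      sample_clip_indices(val_records$n_frames[r], protocol$clip_len,
                          protocol$stride)
    })
  })
  leaves <- lapply(model$params[model$trainable], ag_leaf)
  pget <- function(nm) leaves[[nm]]
  use_fast <- fast_eligible(cfg)
  opt <- adam_init(leaves)
  lr <- protocol$lr
  best_val <- Inf
  best_params <- NULL
  wait <- 0L
  log <- vector("list", protocol$epochs)
  val_loss_of <- function() {
    tot <- 0; cnt <- 0L
    for (r in seq_len(nrow(val_records))) {
      for (idx in val_sets[[r]]) {
        inp <- clip_inputs(val_records[r, ], idx, model, protocol, features,
                           kp_env, need_B, need_kp, final_cache, heat_env)
        if (use_fast && !is.null(attr(inp$feats, "stage")) ||
            use_fast && "enc.last.W" %in% names(leaves)) {
          loss <- fast_train_step(model, leaves, inp, cfg,
                                  accumulate = FALSE)$loss
        } else {
          # evaluate with current leaf values
          pg <- function(nm) {
            l <- leaves[[nm]]
            if (!is.null(l)) l$v else NULL
          }
          bnd <- model_forward(model, inp$feats, inp$label, inp$B,
                               inp$kp_targets, pget = pg)
          loss <- bnd$bce
          if (!is.null(bnd$dice)) loss <- loss + cfg$lambda * bnd$dice
          if (!is.null(bnd$mse)) loss <- loss + cfg$mu * bnd$mse
        }
        tot <- tot + loss
        cnt <- cnt + 1L
      }
    }
    if (cnt == 0L) NA_real_ else tot / cnt
  }
  n_train <- nrow(train_records)
  for (ep in seq_len(protocol$epochs)) {
    ord <- sample.int(n_train)
    ep_loss <- ep_bce <- ep_dice <- ep_mse <- 0
    nb <- 0L
    b <- 1L
    while (b <= n_train) {
      ids <- ord[b:min(b + batch_size - 1L, n_train)]
      ag_zero_grad(leaves)
      for (r in ids) {
        rec <- train_records[r, ]
        idx <- sample_clip_indices(rec$n_frames, protocol$clip_len,
                                   protocol$stride)
        inp <- clip_inputs(rec, idx, model, protocol, features, kp_env,
                           need_B, need_kp, final_cache, heat_env)
        if (use_fast) {
          res <- fast_train_step(model, leaves, inp, cfg)
          ep_loss <- ep_loss + res$loss
          ep_bce <- ep_bce + res$bce
          if (!is.na(res$dice)) ep_dice <- ep_dice + res$dice
        } else {
          tape_begin()
          bnd <- model_forward(model, inp$feats, inp$label, inp$B,
                               inp$kp_targets, pget = pget)
          loss <- bundle_loss(bnd, cfg)
          ag_backward(loss)
          if (!is.null(bnd$.defer)) defer_flush(bnd$.defer)
          tape_end()
          ep_loss <- ep_loss + vof(loss)
          ep_bce <- ep_bce + vof(bnd$bce)
          if (!is.null(bnd$dice)) ep_dice <- ep_dice + vof(bnd$dice)
          if (!is.null(bnd$mse)) ep_mse <- ep_mse + vof(bnd$mse)
        }
        nb <- nb + 1L
      }
      grads <- lapply(leaves, function(l) {
        if (is.null(l$g)) NULL else l$g / length(ids)
      })
      if (is.finite(protocol$clip_grad)) {
        gn <- sqrt(sum(vapply(grads, function(g) {
          if (is.null(g)) 0 else sum(g * g)
        }, numeric(1))))
        if (gn > protocol$clip_grad) {
          sc <- protocol$clip_grad / gn
          grads <- lapply(grads, function(g) if (is.null(g)) NULL else g * sc)
        }
      }
      opt <- adam_step(opt, leaves, grads, lr)
      b <- b + batch_size
    }
    vl <- val_loss_of()
    improved <- !is.na(vl) && vl < best_val - 1e-8
    if (improved) {
      best_val <- vl
      best_params <- lapply(leaves, function(l) l$v)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= protocol$patience && lr > protocol$min_lr) {
        lr <- max(lr * 0.1, protocol$min_lr)
        wait <- 0L
      }
    }
    log[[ep]] <- data.frame(epoch = ep, lr = lr,
                            train_loss = ep_loss / nb,
                            train_bce = ep_bce / nb,
                            train_dice = ep_dice / nb,
                            train_mse = ep_mse / nb,
                            val_loss = vl)
    if (isTRUE(protocol$verbose)) {
      message(sprintf("epoch %d: train %.4f, val %.4f, lr %.2g", ep,
                      ep_loss / nb, vl, lr))
    }
  }
  if (is.null(best_params)) best_params <- lapply(leaves, function(l) l$v)
  model$params[names(best_params)] <- best_params
  model$log <- do.call(rbind, log)
  model$best_val_loss <- best_val
  model
}

#' Predict the expert probability of one video
#'
#' Samples `n_clips` clips, runs the model on each, and averages the clip
#' probabilities (the hard label applies threshold 0.5 to the average).
#'
#' @param model a model implementing [forward_clip()].
#' @param record one manifest row.
#' @param n_clips number of clips to average (default 3).
#' @param protocol a [training_protocol()] (clip geometry).
#' @param features optional feature cache.
#' @param seed optional seed making the sampled evaluation clips
#'   reproducible.
#' @return averaged probability, with attribute `clip_probs`.
#' @export
predict_video <- function(model, record, n_clips = 3,
                          protocol = training_protocol(), features = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- vapply(seq_len(n_clips), function(j) {
    idx <- sample_clip_indices(record$n_frames, protocol$clip_len,
                               protocol$stride)
    if (inherits(model, "surgskill_model") && !is.null(features) &&
        !is.null(features[[record$video_id]])) {
      inp <- clip_inputs(record, idx, model, protocol, features)
      forward_clip(model, NULL, feats = inp$feats)$prob
    } else {
      clip <- load_clip(record, idx,
                        annotation_interval = protocol$annotation_interval)
      forward_clip(model, clip)$prob
    }
  }, numeric(1))
  out <- mean(probs)
  attr(out, "clip_probs") <- probs
  out
}

# mean soft-Dice overlap (1 - soft Dice loss) between a model's attention
# and ground-truth heat maps over sampled clips of the given videos
attention_dice_overlap <- function(model, records, protocol, features = NULL,
                                   n_clips = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kp_env <- keypoint_cache(records)
  vals <- c()
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    for (j in seq_len(n_clips)) {
      idx <- sample_clip_indices(rec$n_frames, protocol$clip_len,
                                 protocol$stride)
      inp <- clip_inputs(rec, idx, model, protocol, features, kp_env,
                         need_heatmaps = TRUE)
      bnd <- model_forward(model, inp$feats, inp$label, inp$B)
      if (!is.null(bnd$dice)) vals <- c(vals, 1 - vof(bnd$dice))
    }
  }
  mean(vals)
}

#' Five-fold cross-validation (internal validation arm)
#'
#' Stratified folds; in each round one fold is the test set, the next fold
#' is the validation set, and the rest train.  Every video is tested
#' exactly once; pooled test predictions give the internal metrics.  The
#' fold model with the lowest validation loss is marked `best_fold` (used
#' for external validation).
#'
#' @param records source-domain manifest.
#' @param cfg a [model_config()].
#' @param protocol a [training_protocol()].
#' @param k number of folds (default 5).
#' @param features optional feature cache.
#' @param seed integer seed controlling folds, initialization and
#'   training streams.
#' @return list with `predictions` (pooled data frame), `metrics`
#'   (internal `metrics_report`), `models`, `best_fold`, `fold` (the
#'   assignment).
#' @export
cross_validate <- function(records, cfg, protocol = training_protocol(),
                           k = 5, features = NULL, seed = 1L) {
  set.seed(seed)
  fold <- stratified_folds(records$label, k)
  models <- vector("list", k)
  preds <- vector("list", k)
  val_losses <- numeric(k)
  for (f in seq_len(k)) {
    test_rec <- records[fold == f, ]
    val_f <- f %% k + 1L
    val_rec <- records[fold == val_f, ]
    train_rec <- records[!(fold %in% c(f, val_f)), ]
    model <- build_model(cfg, seed = seed * 100L + f)
    prot <- protocol
    prot$seed <- seed * 1000L + f
    model <- train_model(model, train_rec, val_rec, prot, features)
    models[[f]] <- model
    val_losses[f] <- model$best_val_loss
    p <- vapply(seq_len(nrow(test_rec)), function(r) {
      as.numeric(predict_video(model, test_rec[r, ], protocol$n_test_clips,
                               protocol, features,
                               seed = seed * 10000L + f * 100L + r))
    }, numeric(1))
    preds[[f]] <- data.frame(video_id = test_rec$video_id,
                             label = test_rec$label, prob = p, fold = f)
  }
  predictions <- do.call(rbind, preds)
  list(predictions = predictions,
       metrics = compute_metrics(predictions$label, predictions$prob,
                                 arm = "internal"),
       models = models,
       best_fold = which.min(val_losses),
       val_losses = val_losses,
       fold = fold)
}

#' External validation on a target-domain dataset
#'
#' Evaluates the best cross-validation model (lowest validation loss) on
#' every target video.  Target videos must be disjoint from the source
#' videos and may lack keypoint annotations entirely: attention
#' supervision is a training-time signal only.
#'
#' @param cv result of [cross_validate()], or a single trained model.
#' @param target_records target-domain manifest.
#' @param source_ids source video ids (overlap check); taken from `cv`
#'   when available.
#' @param protocol a [training_protocol()].
#' @param features optional feature cache for the target videos.
#' @param seed evaluation clip seed.
#' @return list with `metrics` (external `metrics_report`) and
#'   `predictions`.
#' @export
external_validate <- function(cv, target_records, source_ids = NULL,
                              protocol = training_protocol(),
                              features = NULL, seed = 1L) {
  if (inherits(cv, "surgskill_model")) {
    model <- cv
  } else {
    model <- cv$models[[cv$best_fold]]
    if (is.null(source_ids)) source_ids <- cv$predictions$video_id
  }
  if (!is.null(source_ids) &&
      length(intersect(source_ids, target_records$video_id)) > 0L) {
    stop("configuration error: source and target video ids overlap")
  }
  p <- vapply(seq_len(nrow(target_records)), function(r) {
    as.numeric(predict_video(model, target_records[r, ],
                             protocol$n_test_clips, protocol, features,
                             seed = seed * 1000L + r))
  }, numeric(1))
  predictions <- data.frame(video_id = target_records$video_id,
                            label = target_records$label, prob = p)
  list(metrics = compute_metrics(predictions$label, predictions$prob,
                                 arm = "external"),
       predictions = predictions)
}
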