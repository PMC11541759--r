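# Desk-scale synthetic study: the package's end-to-end experiment at a
# size that runs on one CPU in minutes.  It generates a source and a
# shifted target domain with the desk generator profile, trains three
# model variants with five-fold cross-validation, and measures internal
# metrics, attention/heat-map alignment, and external (domain-shifted)
# performance.

#' Run the desk-scale synthetic study
#'
#' Generates a synthetic dataset with [synthetic_profile_desk()] (40
#' source videos, 20 target videos with 3x length and strong novice skew,
#' 64-px frames), precomputes tiny-encoder features, and trains three
#' LSTM variants under five-fold cross-validation with clip length 32 at
#' stride 4:
#' * supervised aggregation (Dice-supervised spatial attention),
#' * unsupervised aggregation (identical but supervision weight 0),
#' * supervised selection.
#'
#' It reports the pooled internal metrics of the supervised-aggregation
#' model, the mean attention/heat-map soft-Dice overlap of the supervised
#' versus unsupervised model (each fold model measured on its own test
#' fold), and the external AUC of the supervised-selection versus
#' unsupervised-aggregation models (best fold model on the full target
#' set).
#'
#' @param seed integer seed driving data generation, initialization and
#'   every sampling stream.
#' @param dir scratch directory for the generated dataset (removed
#'   afterwards unless `keep_data`).
#' @param epochs training epochs per fold (default 20).
#' @param clip_len,stride clip geometry (defaults 32 / 4).
#' @param keep_data keep the generated frames on disk.
#' @param verbose print progress.
#' @return list with `internal` (supervised-aggregation
#'   `metrics_report`), `dice_supervised`, `dice_unsupervised`,
#'   `external_auc_selection`, `external_auc_aggregation`, `external`
#'   (both external `metrics_report`s), and the per-model CV objects.
#' @export
desk_study <- function(seed = 1L, dir = tempfile("deskstudy"),
                       epochs = 20L, clip_len = 32L, stride = 4L,
                       keep_data = FALSE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  cfg_data <- synthetic_profile_desk(rng_seed = seed)
  say("generating synthetic dataset ...")
  manifest <- generate_dataset(cfg_data, dir)
  source_rec <- manifest[manifest$domain == "source", ]
  target_rec <- manifest[manifest$domain == "target", ]
  encoder <- frame_encoder("tiny", seed = seed)
  say("precomputing encoder features ...")
  feats_src <- encode_videos(source_rec, encoder)
  feats_tgt <- encode_videos(target_rec, encoder)
  protocol <- training_protocol(epochs = epochs, clip_len = clip_len,
                                stride = stride, verbose = verbose)
  variants <- list(
    supervised_aggregation = model_config("lstm", TRUE, "supervised",
                                          "aggregation", encoder = encoder),
    unsupervised_aggregation = model_config("lstm", TRUE, "unsupervised",
                                            "aggregation", encoder = encoder),
    supervised_selection = model_config("lstm", TRUE, "supervised",
                                        "selection", encoder = encoder)
  )
  cvs <- list()
  for (nm in names(variants)) {
    say("cross-validating ", nm, " ...")
    cvs[[nm]] <- cross_validate(source_rec, variants[[nm]], protocol,
                                k = 5, features = feats_src, seed = seed)
  }
  # attention / heat-map alignment, each fold model on its own test fold
  fold_dice <- function(cv) {
    vals <- vapply(seq_along(cv$models), function(f) {
      test_rec <- source_rec[cv$fold == f, ]
      attention_dice_overlap(cv$models[[f]], test_rec, protocol,
                             features = feats_src, n_clips = 1,
                             seed = seed + f)
    }, numeric(1))
    mean(vals)
  }
  dice_sup <- fold_dice(cvs$supervised_aggregation)
  dice_unsup <- fold_dice(cvs$unsupervised_aggregation)
  say("external validation ...")
  ext_sel <- external_validate(cvs$supervised_selection, target_rec,
                               protocol = protocol, features = feats_tgt,
                               seed = seed)
  ext_agg <- external_validate(cvs$unsupervised_aggregation, target_rec,
                               protocol = protocol, features = feats_tgt,
                               seed = seed)
  if (!keep_data) unlink(dir, recursive = TRUE)
  list(internal = cvs$supervised_aggregation$metrics,
       dice_supervised = dice_sup,
       dice_unsupervised = dice_unsup,
       external_auc_selection = unname(ext_sel$metrics$auc["estimate"]),
       external_auc_aggregation = unname(ext_agg$metrics$auc["estimate"]),
       external = list(supervised_selection = ext_sel$metrics,
                       unsupervised_aggregation = ext_agg$metrics),
       cv = cvs)
}
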