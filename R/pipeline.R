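#' Default pipeline configuration
#'
#' Every tunable of the pipeline in one nested list, mirroring the
#' YAML configuration files accepted by \code{\link{run_pipeline}}.
#' Phantom defaults here use a 64-pixel frame so that the desk-scale
#' \code{tiny_cnn} consumes them without resizing.
#'
#' @return Nested named list.
#' @export
aort_default_config <- function() {
  list(seed = 1L,
       phantom = list(n_frames = 200L, image_size = 64L,
                      jitter_sd = 0.01, pixel_noise_sd = 6, pt_prob = 0.9),
       backbone = list(name = "tiny_cnn", fine_tune = NULL,
                       input_size = NULL, feature_dim = NULL),
       head = list(hidden_width = 256L, coord_activation = "sigmoid"),
       loss = list(w1 = 1, w2 = 10),
       training = list(learning_rate = NULL, batch_size = NULL,
                       max_epochs = NULL, es_min_delta = 0.005,
                       es_patience = 5L, optimizer = "rectified_adam",
                       paper_scale = FALSE),
       split = list(train_fraction = 0.8, by_series = FALSE),
       metrics = list(threshold = 0.5))
}

# Recursive merge of configuration lists (right wins).
.merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], extra[[nm]])
    } else {
      base[[nm]] <- extra[[nm]]
    }
  }
  base
}

.resolve_config <- function(config = NULL, overrides = list()) {
  cfg <- aort_default_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- .merge_config(cfg, yaml::read_yaml(config))
  } else if (is.list(config)) {
    cfg <- .merge_config(cfg, config)
  }
  .merge_config(cfg, overrides)
}

.cfg_backbone <- function(cfg) {
  backbone_spec(cfg$backbone$name,
                fine_tune = cfg$backbone$fine_tune,
                input_size = cfg$backbone$input_size,
                feature_dim = cfg$backbone$feature_dim)
}

.cfg_training <- function(cfg) {
  tr <- cfg$training
  training_config(learning_rate = tr$learning_rate,
                  batch_size = tr$batch_size, max_epochs = tr$max_epochs,
                  es_min_delta = tr$es_min_delta,
                  es_patience = tr$es_patience, optimizer = tr$optimizer,
                  seed = cfg$seed,
                  weights = loss_weights(cfg$loss$w1, cfg$loss$w2),
                  paper_scale = isTRUE(tr$paper_scale))
}

.write_manifest <- function(dir, command, cfg) {
  yaml::write_yaml(list(command = command,
                        package = "aortrack",
                        version = as.character(utils::packageVersion("aortrack")),
                        seed = cfg$seed,
                        config = cfg),
                   file.path(dir, "manifest.yaml"))
}

# Run `writer(tmp)` against a scratch directory, then atomically move
# it into place so interrupted runs never leave partial outputs.
.atomic_dir <- function(out_dir, writer) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L) {
    stop("output directory exists and is not empty: ", out_dir)
  }
  tmp <- paste0(out_dir, ".tmp-", Sys.getpid())
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  writer(tmp)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  file.rename(tmp, out_dir)
  ok <- TRUE
  invisible(out_dir)
}

.load_dataset <- function(data_dir, with_images = TRUE) {
  path <- file.path(data_dir, "annotations.json")
  if (!file.exists(path)) {
    stop("no annotations.json found under ", data_dir)
  }
  read_annotations(path, image_dir = if (with_images)
    file.path(data_dir, "images") else NULL)
}

#' Run a pipeline command
#'
#' Reproducible entry points tying the modules together. Commands:
#' \describe{
#'   \item{simulate}{Generate a phantom dataset (PNG images +
#'     annotation JSON) under \code{out_dir}.}
#'   \item{summarize}{Exploratory summaries of an annotated dataset:
#'     per-frame count histogram, per-label totals, coordinate
#'     scatter, as CSV.}
#'   \item{train}{Fit the multi-task model on a dataset; writes
#'     \code{checkpoint.rds} and \code{history.csv}.}
#'   \item{evaluate}{Evaluate a checkpoint on the dataset's train and
#'     validation splits; writes \code{metrics.csv}.}
#'   \item{track}{Stream per-frame keypoints through the guidance
#'     geometry; writes JSON-lines (and CSV).}
#' }
#' Every command writes a \code{manifest.yaml} echoing the resolved
#' configuration and seed, and fills its output directory atomically.
#'
#' @param command One of \code{simulate}, \code{summarize},
#'   \code{train}, \code{evaluate}, \code{track}.
#' @param data_dir Input dataset directory (all commands except
#'   \code{simulate}).
#' @param out_dir Output directory.
#' @param config Path to a YAML configuration file, or a nested list;
#'   \code{NULL} for defaults.
#' @param overrides Nested list merged over the configuration (e.g.
#'   \code{list(seed = 7, phantom = list(n_frames = 50))}).
#' @param checkpoint Checkpoint path for \code{evaluate}; defaults to
#'   \code{<data_dir>/checkpoint.rds} if present.
#' @return Invisibly, the command's primary result.
#' @export
run_pipeline <- function(command = c("simulate", "summarize", "train",
                                     "evaluate", "track"),
                         data_dir = NULL, out_dir = NULL, config = NULL,
                         overrides = list(), checkpoint = NULL) {
  command <- match.arg(command)
  cfg <- .resolve_config(config, overrides)
  if (is.null(out_dir)) stop("out_dir is required")
  switch(command,
    simulate = {
      ph <- cfg$phantom
      pc <- phantom_config(n_frames = ph$n_frames,
                           image_size = ph$image_size,
                           jitter_sd = ph$jitter_sd,
                           pixel_noise_sd = ph$pixel_noise_sd,
                           pt_prob = ph$pt_prob, seed = cfg$seed)
      frames <- generate_phantom(pc)
      .atomic_dir(out_dir, function(tmp) {
        write_annotations(frames, tmp)
        .write_manifest(tmp, command, cfg)
      })
      invisible(frames)
    },
    summarize = {
      frames <- .load_dataset(data_dir, with_images = FALSE)
      s <- summarize_dataset(frames)
      .atomic_dir(out_dir, function(tmp) {
        write_summary_csv(s, tmp)
        .write_manifest(tmp, command, cfg)
      })
      invisible(s)
    },
    train = {
      frames <- .load_dataset(data_dir, with_images = TRUE)
      sp <- split_dataset(frames, cfg$split$train_fraction,
                          seed = cfg$seed, by_series = cfg$split$by_series)
      fit <- mtk_fit(sp$train, sp$valid, spec = .cfg_backbone(cfg),
                     config = .cfg_training(cfg),
                     head_hidden = cfg$head$hidden_width,
                     coord_activation = cfg$head$coord_activation)
      .atomic_dir(out_dir, function(tmp) {
        save_checkpoint(fit$model, file.path(tmp, "checkpoint.rds"))
        write_history_csv(fit, file.path(tmp, "history.csv"))
        .write_manifest(tmp, command, cfg)
      })
      invisible(fit)
    },
    evaluate = {
      frames <- .load_dataset(data_dir, with_images = TRUE)
      if (is.null(checkpoint)) {
        checkpoint <- file.path(data_dir, "checkpoint.rds")
      }
      if (!file.exists(checkpoint)) {
        stop("checkpoint not found: ", checkpoint)
      }
      model <- load_checkpoint(checkpoint)
      sp <- split_dataset(frames, cfg$split$train_fraction,
                          seed = cfg$seed, by_series = cfg$split$by_series)
      reports <- list(
        train = evaluate_model(model, sp$train, cfg$metrics$threshold),
        valid = evaluate_model(model, sp$valid, cfg$metrics$threshold))
      .atomic_dir(out_dir, function(tmp) {
        write_metrics_csv(reports, file.path(tmp, "metrics.csv"),
                          model = model$spec$name)
        .write_manifest(tmp, command, cfg)
      })
      invisible(reports)
    },
    track = {
      frames <- .load_dataset(data_dir, with_images = FALSE)
      tr <- track_frames(frames)
      .atomic_dir(out_dir, function(tmp) {
        con <- file(file.path(tmp, "guidance.jsonl"), "w")
        for (i in seq_len(nrow(tr))) {
          writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE,
                                      digits = NA, na = "null"), con)
        }
        close(con)
        utils::write.csv(tr, file.path(tmp, "guidance.csv"),
                         row.names = FALSE)
        .write_manifest(tmp, command, cfg)
      })
      invisible(tr)
    })
}
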