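#' Default experiment configuration
#'
#' A nested configuration for [run_experiment()]: phantom cohort, split,
#' optional augmentation, the model cells to train (2D/3D, with/without
#' augmentation, optionally deeper), training, and statistics. Any part can
#' be overridden by the corresponding argument of the module configs; the
#' whole structure round-trips through YAML.
#'
#' @param n_subjects Cohort size.
#' @param grid_shape Phantom grid.
#' @param split Either `list(type = "holdout", n_train = ...)` or
#'   `list(type = "kfold", k = ...)`.
#' @param cells List of model cells, each
#'   `list(name, dims, augment, deeper = FALSE)`.
#' @param iterations,channels,window,batch_size,num_samples Training scale.
#' @param n_augment Augmented-set size when a cell requests augmentation.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_subjects = 24,
                              grid_shape = c(64, 64, 12),
                              split = list(type = "holdout", n_train = 16),
                              cells = list(list(name = "2d_noaug", dims = 2,
                                                augment = FALSE)),
                              iterations = 2000,
                              channels = c(8, 16, 32, 64),
                              window = NULL,
                              batch_size = 8,
                              num_samples = 4,
                              n_augment = 1000,
                              seed = 0L) {
  structure(list(n_subjects = n_subjects, grid_shape = grid_shape,
                 split = split, cells = cells, iterations = iterations,
                 channels = channels, window = window,
                 batch_size = batch_size, num_samples = num_samples,
                 n_augment = n_augment, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Record run provenance
#'
#' Writes package version, a digest of the canonical YAML form of the
#' configuration, and the seed into `provenance.json` in the results
#' directory, so every results directory is reproducible from its embedded
#' configuration and seed alone.
#'
#' @param cfg Any configuration list.
#' @param out_dir Results directory.
#' @return The provenance list, invisibly.
#' @export
version_and_provenance <- function(cfg, out_dir) {
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  prov <- list(package = "paraseg",
               version = as.character(packageVersion("paraseg")),
               config_hash = hash,
               seed = cfg$seed %||% NA,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(prov)
}

#' Run a phantom-to-statistics experiment
#'
#' Executes the full pipeline at the configured scale: generate a phantom
#' cohort, split it, optionally augment the training set, train each model
#' cell, predict the held-out volumes, compute the seven-metric accuracy
#' report, and run the reliability/comparison statistics (per-muscle volume
#' ICC(2,1) and Bland-Altman for each cell; repeated-measures ANOVA over
#' cell x muscle when more than one cell is trained). All artifacts are
#' written under `out_dir`; a machine-readable `summary.json` collects the
#' headline numbers.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Output directory.
#' @param verbose Print stage progress.
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_experiment <- function(cfg, out_dir, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  version_and_provenance(cfg, out_dir)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "phantom"
  res <- tryCatch({
    pcfg <- phantom_config(grid_shape = cfg$grid_shape, seed = cfg$seed)
    say("generating %d phantoms at %s", cfg$n_subjects,
        paste(cfg$grid_shape, collapse = "x"))
    manifest <- generate_cohort(cfg$n_subjects, pcfg,
                                file.path(out_dir, "phantoms"), seed = cfg$seed)
    pairs <- load_cohort(manifest)

    stage <- "split"
    ids <- manifest$id
    splits <- if (identical(cfg$split$type, "kfold")) {
      kfold_split(ids, cfg$split$k, seed = cfg$seed)
    } else {
      ntr <- cfg$split$n_train
      perm <- with_seed(derive_seed(cfg$seed, 1L), sample(length(ids)))
      list(structure(list(fold_index = 1L,
                          train_ids = ids[perm[seq_len(ntr)]],
                          test_ids = ids[perm[-seq_len(ntr)]]),
                     class = "fold_split"))
    }

    all_metrics <- list()
    cell_stats <- list()
    for (cell in cfg$cells) {
      stage <- paste0("train:", cell$name)
      deeper <- isTRUE(cell$deeper)
      ucfg <- unet_config(dims = cell$dims, channels = cfg$channels,
                          deeper = deeper, seed = cfg$seed)
      win <- cfg$window %||%
        (if (cell$dims == 2) c(cfg$grid_shape[1], cfg$grid_shape[2], 1)
         else c(cfg$grid_shape[1], cfg$grid_shape[2],
                2^(length(cfg$channels) - 1 + isTRUE(deeper))))
      tcfg <- train_config(dims = cell$dims, iterations = cfg$iterations,
                           window = win, batch_size = cfg$batch_size,
                           num_samples = cfg$num_samples, seed = cfg$seed)
      for (fold in splits) {
        say("cell %s fold %d: training %d iterations",
            cell$name, fold$fold_index, tcfg$iterations)
        train_pairs <- pairs[fold$train_ids]
        if (isTRUE(cell$augment)) {
          stage <- paste0("augment:", cell$name)
          acfg <- augment_config(n_out = cfg$n_augment,
                                 seed = derive_seed(cfg$seed, 100 + fold$fold_index))
          adir <- file.path(out_dir, sprintf("aug_%s_f%d", cell$name, fold$fold_index))
          amf <- augment_dataset(manifest[manifest$id %in% fold$train_ids, ],
                                 acfg, adir)
          train_pairs <- load_cohort(amf)
          stage <- paste0("train:", cell$name)
        }
        ckpt <- train_model(train_pairs, ucfg, tcfg, verbose = verbose)
        save_checkpoint(ckpt, file.path(out_dir, sprintf("ckpt_%s_f%d.rds",
                                                         cell$name, fold$fold_index)))
        stage <- paste0("evaluate:", cell$name)
        mrep <- evaluate_cohort(ckpt, pairs[fold$test_ids])
        mrep$cell <- cell$name
        mrep$fold <- fold$fold_index
        all_metrics[[paste(cell$name, fold$fold_index)]] <- mrep
      }
    }
    metrics <- do.call(rbind, all_metrics)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

    stage <- "stats"
    for (cn in unique(metrics$cell)) {
      mm <- metrics[metrics$cell == cn, ]
      icc <- icc_2_1(mm$volume_sm_ml, mm$volume_gt_ml)
      ba <- bland_altman(mm$volume_sm_ml, mm$volume_gt_ml)
      cell_stats[[cn]] <- list(
        mean_dice = mean(mm$dice),
        mean_dice_by_muscle = tapply(mm$dice, mm$muscle, mean),
        volume_icc = icc$icc, volume_icc_ci = c(icc$ci_low, icc$ci_high),
        ba_bias_ml = ba$bias, ba_loa_ml = c(ba$loa_low, ba$loa_high))
    }
    anova_tab <- NULL
    if (length(unique(metrics$cell)) > 1) {
      anova_tab <- rm_anova(metrics, dv = "dice", subject = "subject",
                            factors = c("cell", "muscle"))
      write.csv(anova_tab, file.path(out_dir, "anova.csv"), row.names = FALSE)
    }
    summary <- list(cells = cell_stats,
                    anova = if (is.null(anova_tab)) NULL else anova_tab,
                    n_test = length(unique(metrics$subject)))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    summary
  }, error = function(e) {
    stopf("experiment failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
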