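#' Default pipeline configuration
#'
#' Returns the full nested configuration consumed by [run_pipeline()],
#' optionally merged with overrides (e.g. a YAML file read with
#' `yaml::read_yaml()`). Precedence: overrides > defaults. All artifact
#' paths are relative to `workdir` unless absolute.
#'
#' @param overrides nested list of overrides.
#' @return nested configuration list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    workdir = ".",
    num_classes = 4L,
    paths = list(image = "volume.nii.gz", mask = "mask.nii.gz",
                 scheme = "scheme.json", checkpoint = "model.rds",
                 prediction = "segmentation.nii.gz", metrics = "metrics.json",
                 phantom_report = "phantom.json"),
    phantom = list(shape = c(16L, 64L, 64L),
                   class_fractions = c(rea = 0.61, srf = 0.007, ped = 0.0003),
                   intensity_means = c(background = 30, rea = 110, srf = 190, ped = 240),
                   speckle_looks = 16, boundary_waviness = 2),
    discretize = list(mode = "per_slice", alpha = 0.5, beta = 0.5,
                      population_size = 50L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      tournament_size = 2L, elitism = 1L, fitness_target = NULL,
                      fcm_epsilon = 1e-5, fcm_max_iter = 300L),
    network = list(base_channels = 16L, max_channels = 128L, depth = 4L,
                   patch_size = c(64L, 64L, 64L),
                   use_dual_attention = TRUE, use_attention_refinement = TRUE,
                   use_deep_supervision = TRUE, attention_feature_maps = 16L),
    train = list(lr = 1e-3, momentum = 0.9, weight_decay = 1e-4,
                 grad_clip = 0.005, lr_drop_points = c(1000L, 2500L),
                 batch_size = 1L, iterations = 3000L),
    loss = list(kappa = 1, gamma = 1, lambda = 0.5, epsilon = 1e-5),
    evaluate = list(hd95_mode = "paper")
  )
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

resolve_path <- function(cfg, key) {
  p <- cfg$paths[[key]]
  if (is.null(p)) stop_validation("no path configured for '", key, "'")
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(cfg$workdir, p)
}

require_artifact <- function(cfg, key, producer) {
  p <- resolve_path(cfg, key)
  if (!file.exists(p))
    stop_validation("missing artifact '", p, "': run stage `", producer, "` first")
  p
}

#' Run the segmentation pipeline
#'
#' Executes the requested stages in the fixed order phantom -> discretize ->
#' train -> predict -> evaluate, reading and writing the artifacts named in
#' the configuration. All randomness is derived from the single global
#' `seed`, so a rerun with an identical configuration reproduces every
#' artifact.
#'
#' @param config nested configuration from [default_config()].
#' @param stages character subset of
#'   `c("phantom", "discretize", "train", "predict", "evaluate")`.
#' @return named list of artifact paths written, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("phantom", "discretize", "train",
                                    "predict", "evaluate")) {
  order_all <- c("phantom", "discretize", "train", "predict", "evaluate")
  stages <- order_all[order_all %in% match.arg(stages, order_all, several.ok = TRUE)]
  if (!dir.exists(config$workdir)) dir.create(config$workdir, recursive = TRUE)
  arts <- list()

  if ("phantom" %in% stages) {
    pc <- config$phantom
    sp <- phantom_spec(shape = pc$shape,
                       class_fractions = unlist(pc$class_fractions),
                       intensity_means = unlist(pc$intensity_means),
                       speckle_looks = pc$speckle_looks,
                       boundary_waviness = pc$boundary_waviness,
                       seed = derive_seed(config$seed, "phantom"))
    ph <- generate_phantom(sp)
    write_volume(ph$volume, arts$image <- resolve_path(config, "image"))
    write_volume(ph$mask, arts$mask <- resolve_path(config, "mask"))
    jsonlite::write_json(list(realized_fractions = as.list(ph$realized_fractions),
                              shape = sp$shape, seed = sp$seed),
                         arts$phantom_report <- resolve_path(config, "phantom_report"),
                         auto_unbox = TRUE, digits = NA)
  }

  tab <- NULL
  load_table <- function() {
    img <- read_volume(require_artifact(config, "image", "phantom"))
    msk <- read_volume(require_artifact(config, "mask", "phantom"))
    mode <- if (length(dim(img)) == 2L || config$discretize$mode == "whole_volume")
      "whole_volume" else "per_slice"
    build_decision_table(img, round(msk), config$num_classes, mode = mode)
  }

  if ("discretize" %in% stages) {
    dc <- config$discretize
    tab <- load_table()
    u <- run_fcm(tab, fcm_config(epsilon = dc$fcm_epsilon,
                                 max_iter = dc$fcm_max_iter))
    ga <- ga_discretize(tab, u, config = ga_config(
      alpha = dc$alpha, beta = dc$beta,
      population_size = dc$population_size, generations = dc$generations,
      crossover_rate = dc$crossover_rate, mutation_rate = dc$mutation_rate,
      tournament_size = dc$tournament_size, elitism = dc$elitism,
      fitness_target = dc$fitness_target,
      seed = derive_seed(config$seed, "discretize")))
    write_scheme(ga, arts$scheme <- resolve_path(config, "scheme"), table = tab)
    message(sprintf("discretize: fitness %.4f, eta_bar %.4f, %d/%d breakpoints",
                    ga$best_fitness, ga$eta_bar,
                    sum(ga$best_scheme$selected), ga$best_scheme$candidates$n))
  }

  net_cfg <- function() {
    nc <- config$network
    network_config(num_classes = config$num_classes,
                   base_channels = nc$base_channels, max_channels = nc$max_channels,
                   depth = nc$depth, patch_size = nc$patch_size,
                   use_dual_attention = nc$use_dual_attention,
                   use_attention_refinement = nc$use_attention_refinement,
                   use_deep_supervision = nc$use_deep_supervision,
                   attention_feature_maps = nc$attention_feature_maps)
  }

  if ("train" %in% stages) {
    if (is.null(tab)) tab <- load_table()
    scheme <- read_scheme(require_artifact(config, "scheme", "discretize"))
    img <- read_volume(resolve_path(config, "image"))
    msk <- round(read_volume(resolve_path(config, "mask")))
    tc <- config$train
    model <- build_network(net_cfg(), seed = derive_seed(config$seed, "init"))
    run <- train_network(model, img, msk, scheme = scheme, table = tab,
                         tc = train_config(lr = tc$lr, momentum = tc$momentum,
                                           weight_decay = tc$weight_decay,
                                           grad_clip = tc$grad_clip,
                                           lr_drop_points = tc$lr_drop_points,
                                           batch_size = tc$batch_size,
                                           iterations = tc$iterations,
                                           seed = derive_seed(config$seed, "train")),
                         lw = loss_weights(kappa = config$loss$kappa,
                                           gamma = config$loss$gamma,
                                           lambda = config$loss$lambda,
                                           epsilon = config$loss$epsilon))
    saveRDS(list(config = model$config, params = as.list(model$params),
                 seed = model$seed, history = run$history,
                 pipeline_seed = config$seed),
            arts$checkpoint <- resolve_path(config, "checkpoint"))
    message(sprintf("train: %d iterations, final loss %.4f",
                    nrow(run$history), run$history$loss[nrow(run$history)]))
  }

  if ("predict" %in% stages) {
    if (is.null(tab)) tab <- load_table()
    scheme <- read_scheme(require_artifact(config, "scheme", "discretize"))
    ck <- readRDS(require_artifact(config, "checkpoint", "train"))
    model <- structure(list(config = ck$config,
                            params = list2env(ck$params, parent = emptyenv()),
                            geom = new.env(parent = emptyenv()), seed = ck$seed),
                       class = "rfdseg_network")
    img <- read_volume(require_artifact(config, "image", "phantom"))
    pred <- predict_volume(model, img, scheme = scheme, table = tab)
    write_volume(pred$label, arts$prediction <- resolve_path(config, "prediction"))
  }

  if ("evaluate" %in% stages) {
    pred <- round(read_volume(require_artifact(config, "prediction", "predict")))
    truth <- round(read_volume(require_artifact(config, "mask", "phantom")))
    rep <- evaluate_segmentation(pred, truth, config$num_classes,
                                 hd95_mode = config$evaluate$hd95_mode)
    out <- list(per_class = rep$per_class, macro = rep$macro,
                hd95_mode = rep$hd95_mode, seed = config$seed)
    jsonlite::write_json(out, arts$metrics <- resolve_path(config, "metrics"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    message(sprintf("evaluate: macro DSC %.4f", rep$macro$dsc))
  }

  invisible(arts)
}
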