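# End-to-end orchestration: phantom -> train (4 architectures) -> ensemble
# predict -> en-face quantification -> evaluation, driven by one config with
# a single global seed expanded into fixed per-stage seeds, and recorded in a
# JSON run manifest so a rerun with the same config reproduces all
# deterministic outputs bit-identically.

.stage_seed <- function(seed, stage) {
  offs <- c(phantom = 101L, split = 211L, train = 307L, predict = 401L,
            evaluate = 503L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Default pipeline configuration
#'
#' A toy-scale but complete configuration: small phantom volumes, the four
#' U-shaped architectures at depth 3 / base 8 with 64-px crops, en-face
#' quantification and ETDRS evaluation. Any element can be overridden before
#' passing the config to [run_pipeline()], or supplied from YAML via
#' [load_run_config()].
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param seed global seed; expanded into fixed per-stage seeds.
#' @param n_volumes number of phantom volumes.
#' @param geometry an [oct_geometry()] for the phantoms.
#' @param fractions train/val/test split fractions.
#' @return a `run_config` list.
#' @export
default_run_config <- function(out_dir = tempfile("prlrun"), seed = 0L,
                               n_volumes = 10L,
                               geometry = oct_geometry(n_bscans = 8L,
                                                       n_depth = 160L,
                                                       n_ascans = 128L),
                               fractions = c(0.6, 0.2, 0.2)) {
  archs <- c("unet", "all_dropout", "bru_net", "u2net")
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    geometry = geometry,
    phantom = list(n_volumes = as.integer(n_volumes),
                   band_center_row = round(geometry$n_depth * 0.6),
                   band_thickness_px = 10,
                   thickness_amplitude = 2.5,
                   center_amplitude = round(geometry$n_depth * 0.075),
                   speckle_sigma = 0.15),
    split = list(fractions = fractions),
    models = lapply(archs, function(a)
      model_config(a, depth = 3L, base_channels = 8L, max_epochs = 6L,
                   patience = 3L, crop_size = 64L, crops_per_epoch = 50L)),
    enface = list(dz_um = 1, df_factor = 1 / 6),
    evaluate = list(n_thresholds = 101L)
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys override the defaults of
#' [default_run_config()] (nested keys merge shallowly; `models` entries are
#' passed to [model_config()]).
#'
#' @param path YAML file.
#' @param out_dir,seed overrides applied after the file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (!is.null(y$geometry))
    cfg$geometry <- do.call(oct_geometry, y$geometry)
  for (k in intersect(names(y), c("out_dir", "seed")))
    cfg[[k]] <- y[[k]]
  for (k in intersect(names(y), c("phantom", "split", "enface", "evaluate")))
    cfg[[k]] <- utils::modifyList(cfg[[k]], y[[k]])
  if (!is.null(y$models))
    cfg$models <- lapply(y$models, function(m) do.call(model_config, m))
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

.phantom_spec_from_config <- function(config, index, seed) {
  g <- config$geometry
  p <- config$phantom
  # vary pathology load across volumes deterministically: alternating
  # disruption / shadow / cyst burden acts as a stratification class
  cls <- index %% 2L
  nd <- if (cls == 0L) 1L else 2L
  .with_seed(seed + index, {
    disr <- lapply(seq_len(nd), function(i)
      list(b = stats::runif(1, 0.15, 0.85) * (g$n_bscans - 1),
           x = stats::runif(1, 0.15, 0.85) * (g$n_ascans - 1),
           rb = max(1, 0.06 * g$n_bscans), rx = 0.06 * g$n_ascans))
    shx <- round(stats::runif(1, 0.2, 0.8) * g$n_ascans)
    phantom_spec(
      geometry = g,
      band_center_row = p$band_center_row,
      band_thickness_px = p$band_thickness_px,
      thickness_amplitude = p$thickness_amplitude,
      center_amplitude = p$center_amplitude,
      disruptions = disr,
      shadows = list(list(x0 = shx, x1 = shx + round(0.02 * g$n_ascans),
                          factor = 0.5)),
      cysts = list(list(b = stats::runif(1, 0.2, 0.8) * (g$n_bscans - 1),
                        z = round(g$n_depth * 0.4),
                        x = stats::runif(1, 0.2, 0.8) * (g$n_ascans - 1),
                        rb = max(1, 0.05 * g$n_bscans),
                        rz = 0.08 * g$n_depth, rx = 0.1 * g$n_ascans)),
      speckle_sigma = p$speckle_sigma,
      seed = seed + index)
  })
}

.volume_pairs <- function(v) {
  lapply(seq_len(v$volume$n_bscans), function(b)
    list(image = v$volume$voxels[b, , ], mask = v$truth$mask[b, , ]))
}

#' Run the full pipeline
#'
#' Executes phantom generation, dataset splitting, training of the four
#' architectures, ensemble prediction on the test volumes, en-face
#' quantification, ETDRS evaluation and the statistical comparisons, writing
#' per-stage artifacts under `config$out_dir` and returning (and saving) a
#' run manifest. A failed stage aborts with the stage name after persisting
#' the partial manifest.
#'
#' @param config a `run_config` from [default_run_config()] /
#'   [load_run_config()].
#' @param keep_models if TRUE, trained models are saved under `out_dir`.
#' @return the run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, keep_models = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  manifest <- list(config_hash = digest::digest(cfg_for_hash),
                   seed = config$seed,
                   versions = list(
                     prlquant = as.character(utils::packageVersion("prlquant")),
                     R = paste(R.version$major, R.version$minor, sep = ".")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  .persist <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    .persist()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  .stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) .fail(name, e))
    manifest$stages[[name]] <<- c(list(status = "ok",
                                       seconds = round(as.numeric(
                                         difftime(Sys.time(), t0,
                                                  units = "secs")), 2)),
                                  out)
    .persist()
  }

  vols <- NULL; folds <- NULL; models <- NULL; results <- NULL
  enface <- NULL; evalres <- NULL

  .stage("phantom", function() {
    seed <- .stage_seed(config$seed, "phantom")
    vols <<- lapply(seq_len(config$phantom$n_volumes), function(i)
      generate_volume(.phantom_spec_from_config(config, i, seed)))
    list(n_volumes = length(vols),
         geometry = unclass(config$geometry))
  })

  .stage("split", function() {
    strata <- seq_len(length(vols)) %% 2L
    folds <<- split_dataset(seq_along(vols), config$split$fractions,
                            seed = .stage_seed(config$seed, "split"),
                            strata = strata)
    if (length(folds$train) == 0L) stop("empty training fold")
    if (length(folds$test) == 0L)
      stop("empty test fold; adjust split fractions for ",
           length(vols), " volumes")
    lapply(folds, function(ix) as.integer(ix))
  })

  .stage("train", function() {
    train_pairs <- do.call(c, lapply(vols[folds$train], .volume_pairs))
    val_pairs <- if (length(folds$val) > 0)
      do.call(c, lapply(vols[folds$val], .volume_pairs)) else NULL
    if (!is.null(val_pairs) && length(val_pairs) > 8L) {
      # evenly spaced validation subset keeps per-epoch model selection cheap
      val_pairs <- val_pairs[round(seq(1, length(val_pairs), length.out = 8L))]
    }
    base_seed <- .stage_seed(config$seed, "train")
    models <<- lapply(seq_along(config$models), function(i) {
      mc <- config$models[[i]]
      mc$seed <- (base_seed + 7919L * i) %% .Machine$integer.max
      mdl <- build_model(mc)
      train_model(mdl, train_pairs, val_pairs, mc)
      if (keep_models)
        save_model(mdl, file.path(config$out_dir,
                                  paste0("model_", mc$arch_name, ".rds")))
      mdl
    })
    lapply(models, function(m)
      list(arch = m$config$arch_name, n_params = n_params(m),
           epochs = nrow(m$history), best_score = m$best_score))
  })

  .stage("predict", function() {
    results <<- lapply(vols[folds$test], function(v)
      segment_volume(models, v$volume))
    list(n_test_volumes = length(results),
         thresholds = lapply(results, function(rs)
           round(vapply(rs, function(r) r$threshold, numeric(1)), 4)))
  })

  .stage("quantify", function() {
    g <- config$geometry
    enface <<- lapply(seq_along(results), function(i) {
      th <- enface_thickness(results[[i]], dz_um = config$enface$dz_um,
                             dx_mm = g$dx_mm, dy_mm = g$dy_mm,
                             df_factor = config$enface$df_factor)
      sd <- enface_std(results[[i]], dx_mm = g$dx_mm, dy_mm = g$dy_mm,
                       df_factor = config$enface$df_factor)
      vix <- folds$test[i]
      save_enface_csv(th, file.path(config$out_dir,
                                    sprintf("thickness_vol%02d.csv", vix)))
      save_enface_csv(sd, file.path(config$out_dir,
                                    sprintf("std_vol%02d.csv", vix)))
      list(thickness = th, std = sd)
    })
    list(files = sort(list.files(config$out_dir, pattern = "csv$")))
  })

  .stage("evaluate", function() {
    g <- config$geometry
    regions <- etdrs_regions(g$n_bscans, g$n_ascans, g$dx_mm, g$dy_mm)
    per_vol <- lapply(seq_along(results), function(i) {
      v <- vols[[folds$test[i]]]
      pred <- abind::abind(lapply(results[[i]], function(r) r$binary),
                           along = 0)
      scores <- lapply(c(csf = "csf", cmm3 = "cmm3", ring31 = "ring31",
                         full = "full"), function(rn) {
        cc <- confusion_counts(pred, v$truth$mask, regions[[rn]])
        s <- segmentation_scores(cc, region = rn)
        list(precision = s$precision, recall = s$recall, dice = s$dice)
      })
      est <- region_mean_thickness(enface[[i]]$thickness, regions)
      tru <- region_mean_thickness(v$truth$thickness_true, regions)
      list(scores = scores, mean_thickness_est = as.list(est),
           mean_thickness_true = as.list(tru))
    })
    est_full <- vapply(per_vol, function(p) p$mean_thickness_est$full,
                       numeric(1))
    tru_full <- vapply(per_vol, function(p) p$mean_thickness_true$full,
                       numeric(1))
    bias <- if (length(est_full) >= 3)
      thickness_bias_test(est_full, tru_full) else NULL
    evalres <<- list(per_volume = per_vol, bias = bias)
    list(per_volume = per_vol,
         mean_test_dice_full = mean(vapply(per_vol, function(p)
           p$scores$full$dice, numeric(1))),
         bias_test = if (!is.null(bias))
           list(test_used = bias$test_used, p_value = bias$p_value,
                reject = bias$reject) else NULL)
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  .persist()
  invisible(manifest)
}
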