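# Unified run configuration and pipeline dispatch (the package's command
# surface; a thin Rscript wrapper lives in inst/scripts/greendet.R).

run_config_defaults <- function() {
  list(
    subcommand = "synth",
    data_dir = "dataset",
    out_dir = "runs",
    weights = NULL,
    seed = 0L,
    split_ratio = 0.7,
    iou_threshold = 0.5,
    conf_threshold = 0.25,
    n_images = 30L,
    desk_scale = TRUE,
    epochs = 30L,
    scene = list(),     # overrides for scene_config / scene_config_desk
    augment = list(),   # overrides for augment_config
    verbose = TRUE
  )
}

#' Load a run configuration
#'
#' Starts from the documented defaults (Copy-Paste probability 1 with 4
#' fruit and 15 leaf pastes, Mosaic 0.8, Mixup 0.3, IoU threshold 0.5,
#' split ratio 0.7), merges an optional YAML file, then applies explicit
#' overrides. Unknown keys and type mismatches are rejected.
#'
#' @param path optional YAML config file.
#' @param overrides named list of final overrides (e.g. parsed CLI flags).
#' @return a validated `run_config` list; the effective configuration is
#'   echoed to the console when `verbose` is `TRUE`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  apply_over <- function(cfg, new, where) {
    for (nm in names(new)) {
      if (!nm %in% names(cfg))
        stop(sprintf("unknown config key '%s' in %s; valid keys: %s", nm,
                     where, paste(names(cfg), collapse = ", ")))
      old <- cfg[[nm]]
      if (!is.null(old) && !is.list(old) && !is.null(new[[nm]]) &&
          is.numeric(old) != is.numeric(new[[nm]]))
        stop(sprintf("type mismatch for config key '%s'", nm))
      cfg[[nm]] <- if (is.list(old)) utils::modifyList(old, as.list(new[[nm]]))
                   else new[[nm]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_over(cfg, overrides, "overrides")
  cfg$seed <- as.integer(cfg$seed)
  # build the nested configs so validation happens up front
  cfg$scene_config <- do.call(if (cfg$desk_scale) scene_config_desk
                              else scene_config, cfg$scene)
  cfg$augment_config <- do.call(augment_config, c(
    cfg$augment,
    if (is.null(cfg$augment$preset_size))
      list(preset_size = cfg$scene_config$image_size[1])))
  class(cfg) <- "run_config"
  if (isTRUE(cfg$verbose)) {
    echo <- cfg[setdiff(names(cfg), c("scene_config", "augment_config"))]
    message("effective config:\n", yaml::as.yaml(echo))
  }
  cfg
}

#' Run a pipeline stage
#'
#' Dispatches on `config$subcommand`:
#' \describe{
#'   \item{synth}{render a synthetic dataset into `data_dir`.}
#'   \item{augment}{write before/after augmentation previews.}
#'   \item{train}{train on `data_dir`'s train split, checkpoint to
#'     `out_dir`.}
#'   \item{detect}{run a checkpoint over the test images, write YOLO-txt
#'     predictions with a confidence column.}
#'   \item{evaluate}{score prediction files against the test labels.}
#' }
#' The master seed fans out to per-stage seeds so stages can be re-run in
#' isolation.
#'
#' @param config a `run_config` from [load_config()].
#' @return stage-dependent result, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, c("synth", "augment", "train", "eval"))
  switch(config$subcommand,
    synth = {
      render_dataset(config$scene_config, config$n_images, config$data_dir,
                     config$split_ratio, seeds["synth"])
    },
    augment = {
      train_imgs <- load_dataset(config$data_dir, "train")
      scenes <- lapply(seq_len(min(4, length(train_imgs))), function(i)
        generate_scene(config$scene_config, seeds["augment"] + i))
      pool <- make_paste_pool(scenes)
      out <- apply_train_pipeline(train_imgs, pool, config$augment_config,
                                  min(4L, length(train_imgs)),
                                  seeds["augment"])
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(out)) {
        write_image(out[[i]]$pixels,
                    file.path(config$out_dir, sprintf("preview_%02d.png", i)))
        write_labels(out[[i]]$boxes,
                     file.path(config$out_dir, sprintf("preview_%02d.txt", i)))
      }
      jsonlite::write_json(attr(out, "applied"),
                           file.path(config$out_dir, "preview_schedule.json"))
      invisible(out)
    },
    train = {
      train_imgs <- load_dataset(config$data_dir, "train")
      val_imgs <- load_dataset(config$data_dir, "test")
      size <- config$scene_config$image_size[1]
      arch <- if (config$desk_scale) arch_config_mini(img_size = size)
              else arch_config(img_size = size)
      model <- build_detector(arch, seed = seeds["train"])
      wh <- do.call(rbind, lapply(train_imgs, function(im)
        cbind(im$boxes$w * size, im$boxes$h * size)))
      model$anchors <- autoanchor(wh, img_size = size, seed = seeds["train"])
      model <- train_loop(model, train_imgs, val_imgs,
                          train_hyp(epochs = config$epochs),
                          seed = seeds["train"], verbose = config$verbose)
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(model, file.path(config$out_dir, "best.rds"))
      write.csv(attr(model, "history"),
                file.path(config$out_dir, "history.csv"), row.names = FALSE)
      invisible(model)
    },
    detect = {
      model <- load_checkpoint(config$weights)
      imgs <- load_dataset(config$data_dir, "test")
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      for (im in imgs) {
        det <- detect_image(model, im, config$conf_threshold)
        d <- dim(im$pixels)
        lines <- if (nrow(det)) {
          nb <- convert_box(det, c(d[2], d[1]), "to_norm")
          sprintf("%d %.6f %.6f %.6f %.6f %.4f", nb$class, nb$cx, nb$cy,
                  nb$w, nb$h, det$conf)
        } else character()
        writeLines(lines, file.path(config$out_dir,
                                    paste0(im$image_id, ".txt")))
      }
      invisible(NULL)
    },
    evaluate = {
      model <- load_checkpoint(config$weights)
      imgs <- load_dataset(config$data_dir, "test")
      rep_ <- evaluate_model(model, imgs)
      print(rep_)
      invisible(rep_)
    },
    stop("unknown subcommand: ", config$subcommand))
}
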