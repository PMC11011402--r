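#' Run the desk-scale detection study
#'
#' The package's self-contained reference experiment: generate a
#' green-on-green synthetic dataset (64 training and 16 held-out 160-pixel
#' scenes under [scene_config_desk()]), estimate anchors from the training
#' boxes, train the miniature detector ([arch_config_mini()]) and report
#' IoU-0.5 metrics on the held-out scenes from the best-validation epoch.
#' Everything derives from `seed`, so a run is exactly reproducible.
#'
#' @param seed master seed for scene generation, initialization and
#'   training.
#' @param epochs training epochs (default 35).
#' @param n_train,n_val scene counts.
#' @param scene a [scene_config()]; defaults to the desk-scale conditions.
#' @param verbose print per-epoch progress.
#' @return list: `model` (trained `gd_model`), `report` (an
#'   `eval_report` on the held-out scenes), `history` (per-epoch metric
#'   data.frame), `map` (held-out mAP@0.5 of the reported model).
#' @export
run_desk_study <- function(seed = 1L, epochs = 35L, n_train = 64L,
                           n_val = 16L, scene = scene_config_desk(),
                           verbose = FALSE) {
  seeds <- derive_seeds(seed, c("scenes", "train"))
  size <- scene$image_size[1]
  train_imgs <- lapply(seq_len(n_train), function(i)
    generate_scene(scene, (seeds["scenes"] + i) %% 2147483647))
  val_imgs <- lapply(seq_len(n_val), function(i)
    generate_scene(scene, (seeds["scenes"] + 100000 + i) %% 2147483647))
  model <- build_detector(arch_config_mini(img_size = size),
                          seed = seeds["train"])
  wh <- do.call(rbind, lapply(train_imgs, function(im)
    cbind(im$boxes$w * size, im$boxes$h * size)))
  model$anchors <- autoanchor(wh, img_size = size, seed = seeds["train"])
  model <- train_loop(model, train_imgs, val_imgs,
                      train_hyp(epochs = epochs), seed = seeds["train"],
                      verbose = verbose)
  report <- evaluate_model(model, val_imgs)
  list(model = model, report = report,
       history = attr(model, "history"), map = report$map)
}
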