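#' Training hyperparameters
#'
#' Defaults are sized for desk-scale runs on synthetic scenes (small
#' inputs, batch 8); all constants are exposed so full-scale settings can
#' be supplied.
#'
#' @param epochs training epochs.
#' @param batch_size images per gradient step.
#' @param lr0 peak learning rate (SGD).
#' @param lrf final learning-rate fraction of `lr0` (cosine schedule).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution weights.
#' @param warmup_epochs linear warmup length (fractions allowed).
#' @param loss_weights named vector `c(box, obj, cls)`.
#' @return list of class `train_hyp`.
#' @export
train_hyp <- function(epochs = 30L, batch_size = 8L, lr0 = 0.02, lrf = 0.1,
                      momentum = 0.9, weight_decay = 5e-4,
                      warmup_epochs = 3, loss_weights = c(box = 2.0,
                                                          obj = 1.0,
                                                          cls = 0.5)) {
  structure(as.list(environment()), class = "train_hyp")
}

# Images (already letterboxed to the model input size) -> input batch
# array (3, s, s, B) in [0,1].
stack_batch <- function(images) {
  s <- dim(images[[1]]$pixels)[1]
  x <- array(0, c(3, s, s, length(images)))
  for (i in seq_along(images))
    x[, , , i] <- aperm(images[[i]]$pixels / 255, c(3, 1, 2))
  x
}

#' Train the detector
#'
#' Plain SGD with momentum, linear warmup and a cosine learning-rate
#' schedule. Augmentation (when a config is given) re-draws the training
#' stream every epoch through [apply_train_pipeline()]; otherwise images
#' are letterboxed once and flipped horizontally at random. The model is
#' evaluated on `val_images` after each epoch and the best-mAP parameters
#' are restored at the end. Training aborts with a diagnostic if the loss
#' goes non-finite.
#'
#' @param model a `gd_model` (modified in place and returned).
#' @param train_images,val_images lists of `labeled_image`.
#' @param hyp a [train_hyp()].
#' @param augment an [augment_config()] or `NULL`.
#' @param pool Copy-Paste pool when `augment` is given.
#' @param seed master seed (fans out to shuffling, flips, augmentation).
#' @param verbose print per-epoch progress.
#' @return the trained model; attribute `history` holds the per-epoch
#'   metric data.frame (loss terms + validation mAP).
#' @export
train_loop <- function(model, train_images, val_images, hyp = train_hyp(),
                       augment = NULL, pool = NULL, seed = 0L,
                       verbose = FALSE) {
  stopifnot(length(train_images) >= 1)
  s <- model$arch$img_size
  params <- collect_params(model)
  vel <- lapply(params, function(p) p$value * 0)
  decay_mask <- vapply(names(params), function(nm)
    grepl("\\.W$|\\.W1$|\\.W2$|\\.Wmix$", nm), logical(1))
  seeds <- derive_seeds(seed, c("stream", "eval"))
  history <- list()
  best <- list(map = -Inf, params = NULL, states = NULL)
  n_batches_total <- max(1, ceiling(length(train_images) / hyp$batch_size))
  step <- 0L
  warmup_steps <- hyp$warmup_epochs * n_batches_total
  for (epoch in seq_len(hyp$epochs)) {
    ep_seed <- (seeds["stream"] + epoch) %% 2147483647
    batch_imgs <- with_seed_(ep_seed, {
      if (!is.null(augment)) {
        apply_train_pipeline(train_images, pool, augment,
                             length(train_images), seed = ep_seed)
      } else {
        imgs <- lapply(train_images, function(im) letterbox(im, s)$image)
        lapply(imgs[sample(length(imgs))], function(im) {
          if (runif(1) < 0.5) {
            im$pixels <- im$pixels[, dim(im$pixels)[2]:1, , drop = FALSE]
            if (nrow(im$boxes)) im$boxes$cx <- 1 - im$boxes$cx
            im$masks <- NULL; im$mask_categories <- NULL
          }
          im
        })
      }
    })
    idx <- split(seq_along(batch_imgs),
                 ceiling(seq_along(batch_imgs) / hyp$batch_size))
    ep_terms <- c(box = 0, obj = 0, cls = 0, total = 0)
    for (bi in idx) {
      step <- step + 1L
      # schedule
      tprog <- (epoch - 1) / max(1, hyp$epochs - 1)
      lr_cos <- hyp$lr0 * (hyp$lrf + (1 - hyp$lrf) *
                             (1 + cos(pi * tprog)) / 2)
      lr <- if (step <= warmup_steps)
        lr_cos * step / max(1, warmup_steps) else lr_cos
      imgs <- batch_imgs[bi]
      x <- stack_batch(imgs)
      targets <- lapply(imgs, function(im)
        assign_targets(im$boxes, model$anchors, s))
      xn <- ad_const(x)
      heads <- detector_forward_nodes(model, xn, training = TRUE)
      raw <- lapply(heads, function(h) h$value)
      ls <- compute_loss(raw, targets, model$n_classes, model$anchors,
                         weights = hyp$loss_weights)
      if (!is.finite(ls$terms["total"]))
        stop(sprintf("training diverged at epoch %d (loss %s)", epoch,
                     paste(round(ls$terms, 3), collapse = "/")))
      for (p in params) p$grad <- NULL
      root <- ad_node(0, parents = heads, backfn = function(node) {
        for (i in 1:3) ad_accum(heads[[i]], ls$grads[[i]])
      })
      ad_backward(root, 1)
      for (j in seq_along(params)) {
        p <- params[[j]]
        g <- p$grad
        if (is.null(g)) next
        if (decay_mask[j]) g <- g + hyp$weight_decay * p$value
        vel[[j]] <- hyp$momentum * vel[[j]] - lr * g
        p$value <- p$value + vel[[j]]
      }
      ep_terms <- ep_terms + ls$terms * length(bi)
    }
    ep_terms <- ep_terms / length(batch_imgs)
    val_map <- NA_real_
    if (length(val_images)) {
      rep_ <- evaluate_model(model, val_images)
      val_map <- rep_$map
      if (!is.na(val_map) && val_map > best$map) {
        best$map <- val_map
        best$params <- lapply(params, function(p) p$value)
        best$states <- lapply(collect_states(model), function(e)
          list(mean = e$mean, var = e$var))
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, box = ep_terms["box"],
                                   obj = ep_terms["obj"],
                                   cls = ep_terms["cls"],
                                   total = ep_terms["total"],
                                   val_map = val_map)
    if (verbose)
      message(sprintf("epoch %3d  lr %.4f  box %.3f obj %.3f cls %.3f  mAP %.3f",
                      epoch, lr, ep_terms["box"], ep_terms["obj"],
                      ep_terms["cls"], val_map))
  }
  if (!is.null(best$params)) {
    for (nm in names(params)) params[[nm]]$value <- best$params[[nm]]
    sts <- collect_states(model)
    for (nm in names(sts)) {
      sts[[nm]]$mean <- best$states[[nm]]$mean
      sts[[nm]]$var <- best$states[[nm]]$var
    }
  }
  attr(model, "history") <- do.call(rbind, history)
  attr(model, "best_map") <- best$map
  model
}

#' Single-batch gradient steps (micro-overfit utility)
#'
#' Runs `n_steps` SGD steps on one fixed batch and returns the loss trace;
#' the smoke test that the whole differentiation/assignment/loss stack
#' points downhill.
#'
#' @param model a `gd_model`.
#' @param images list of `labeled_image` (already square is best).
#' @param n_steps gradient steps.
#' @param lr learning rate; @param momentum SGD momentum.
#' @return numeric vector of total-loss values, one per step.
#' @export
overfit_steps <- function(model, images, n_steps = 10L, lr = 5e-3,
                          momentum = 0.9) {
  s <- model$arch$img_size
  imgs <- lapply(images, function(im) letterbox(im, s)$image)
  x <- stack_batch(imgs)
  targets <- lapply(imgs, function(im) assign_targets(im$boxes,
                                                      model$anchors, s))
  params <- collect_params(model)
  vel <- lapply(params, function(p) p$value * 0)
  trace <- numeric(n_steps)
  for (it in seq_len(n_steps)) {
    heads <- detector_forward_nodes(model, ad_const(x), training = TRUE)
    ls <- compute_loss(lapply(heads, function(h) h$value), targets,
                       model$n_classes, model$anchors)
    trace[it] <- ls$terms["total"]
    for (p in params) p$grad <- NULL
    root <- ad_node(0, parents = heads, backfn = function(node) {
      for (i in 1:3) ad_accum(heads[[i]], ls$grads[[i]])
    })
    ad_backward(root, 1)
    for (j in seq_along(params)) {
      p <- params[[j]]
      if (is.null(p$grad)) next
      vel[[j]] <- momentum * vel[[j]] - lr * p$grad
      p$value <- p$value + vel[[j]]
    }
  }
  trace
}
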