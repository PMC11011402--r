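#' Harmonic mean of precision and recall
#'
#' `F1 = 2 P R / (P + R)`; works on proportions or percentages alike, and
#' returns 0 when both terms are 0.
#'
#' @param p,r precision and recall.
#' @return F1 on the same scale as the inputs.
#' @export
f1_score <- function(p, r) ifelse(p + r == 0, 0, 2 * p * r / (p + r))

#' Match detections against ground truth at an IoU threshold
#'
#' Detections are processed in descending confidence. Each is a true
#' positive if its IoU with some still-unmatched ground-truth box of the
#' same category is *strictly greater* than `iou_threshold` (ties at the
#' threshold count as false positives), matching the highest-IoU
#' candidate; every ground truth is matched at most once. Unmatched
#' ground truths are false negatives.
#'
#' @param dets data.frame `class, conf, x1, y1, x2, y2`.
#' @param gts data.frame `class, x1, y1, x2, y2`.
#' @param iou_threshold matching threshold (default 0.5).
#' @return list: `det` (input rows, sorted by confidence, plus `tp` flag
#'   and matched `gt` index), `fn` (count), `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  dets <- dets[order(-dets$conf), , drop = FALSE]
  tp <- logical(nrow(dets))
  gt_of <- rep(NA_integer_, nrow(dets))
  used <- logical(nrow(gts))
  if (nrow(dets) && nrow(gts)) {
    iom <- box_iou(dets, gts)
    for (i in seq_len(nrow(dets))) {
      cand <- which(!used & gts$class == dets$class[i])
      if (!length(cand)) next
      j <- cand[which.max(iom[i, cand])]
      if (iom[i, j] > iou_threshold) {
        tp[i] <- TRUE
        gt_of[i] <- j
        used[j] <- TRUE
      }
    }
  }
  det <- dets
  det$tp <- tp
  det$gt <- gt_of
  list(det = det, fn = sum(!used), n_gt = nrow(gts))
}

#' Average precision from pooled matches
#'
#' Sweeps pooled detections by descending confidence, accumulates the
#' precision-recall curve, applies the monotone (non-increasing) precision
#' envelope and integrates it over recall with all-point interpolation.
#'
#' @param conf detection confidences (pooled over the test set).
#' @param tp logical true-positive flags aligned with `conf`.
#' @param n_gt total ground-truth count for the category (>= 1).
#' @return list: `ap`, and the PR `curve` (recall, precision, envelope).
#' @export
average_precision <- function(conf, tp, n_gt) {
  stopifnot(n_gt >= 1)
  if (!length(conf))
    return(list(ap = 0, curve = data.frame(recall = 0, precision = 0,
                                           envelope = 0)))
  o <- order(-conf)
  tp <- tp[o]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, head(recall, -1))
  ap <- sum((recall - r_prev) * env)
  list(ap = ap,
       curve = data.frame(recall = recall, precision = precision,
                          envelope = env))
}

#' Summarize pooled matches into an evaluation report
#'
#' Computes per-category precision, recall and F1 at the confidence that
#' maximizes F1 (sweeping the observed confidences), the average
#' precision, and the dataset mAP (mean of per-category APs). Categories
#' without ground truth are excluded from the mAP with a warning.
#'
#' @param matches list of per-image results from [match_detections()].
#' @param n_classes number of categories.
#' @return object of class `eval_report`: `per_class` data.frame
#'   (`class, p, r, f1, ap, n_gt`), `map`, and per-class PR `curves`.
#' @export
summarize_metrics <- function(matches, n_classes = 1L) {
  pooled <- do.call(rbind, lapply(matches, `[[`, "det"))
  per <- list(); curves <- list()
  for (cl in seq_len(n_classes) - 1L) {
    # gt count for the class = its TPs + its FNs (per-class FN counts when
    # available, else the single-category totals)
    n_tp <- sum(vapply(matches, function(m)
      sum(m$det$tp & m$det$class == cl), numeric(1)))
    n_fn <- sum(vapply(matches, function(m) {
      if (!is.null(m$fn_by_class)) m$fn_by_class[[as.character(cl)]]
      else m$fn
    }, numeric(1)))
    n_gt <- n_tp + n_fn
    d <- pooled[pooled$class == cl, , drop = FALSE]
    if (n_gt < 1) {
      warning("category ", cl, " has no ground truth; excluded from mAP")
      next
    }
    apr <- average_precision(d$conf, d$tp, n_gt)
    # operating point: confidence maximizing F1
    if (nrow(d)) {
      o <- order(-d$conf)
      ct <- cumsum(d$tp[o]); cf <- cumsum(!d$tp[o])
      p_sweep <- ct / (ct + cf)
      r_sweep <- ct / n_gt
      f1s <- f1_score(p_sweep, r_sweep)
      i <- which.max(f1s)
      p <- p_sweep[i]; r <- r_sweep[i]; f1 <- f1s[i]
    } else {
      p <- 0; r <- 0; f1 <- 0
    }
    per[[length(per) + 1L]] <- data.frame(class = cl, p = p, r = r, f1 = f1,
                                          ap = apr$ap, n_gt = n_gt)
    curves[[as.character(cl)]] <- apr$curve
  }
  per <- do.call(rbind, per)
  structure(list(per_class = per,
                 map = if (is.null(per)) NA_real_ else mean(per$ap),
                 curves = curves),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation (IoU > 0.5)\n")
  if (!is.null(x$per_class)) {
    df <- x$per_class
    cat(sprintf("  class %d: P %.1f%%  R %.1f%%  F1 %.1f%%  AP %.1f%%\n",
                df$class, 100 * df$p, 100 * df$r, 100 * df$f1, 100 * df$ap),
        sep = "")
  }
  cat(sprintf("  mAP %.1f%%\n", 100 * x$map))
  invisible(x)
}

#' Evaluate detections against ground truth
#'
#' @param dets_list list (one per image) of detection data.frames
#'   (`class, conf, x1, y1, x2, y2`).
#' @param gts_list list (one per image) of ground-truth data.frames
#'   (`class, x1, y1, x2, y2`).
#' @param n_classes number of categories.
#' @param iou_threshold matching threshold (default 0.5).
#' @return an `eval_report`.
#' @export
evaluate_detections <- function(dets_list, gts_list, n_classes = 1L,
                                iou_threshold = 0.5) {
  stopifnot(length(dets_list) == length(gts_list))
  matches <- lapply(seq_along(dets_list), function(i) {
    m <- match_detections(dets_list[[i]], gts_list[[i]], iou_threshold)
    fnc <- vapply(seq_len(n_classes) - 1L, function(cl) {
      gt_cl <- which(gts_list[[i]]$class == cl)
      sum(!(gt_cl %in% m$det$gt))
    }, numeric(1))
    m$fn_by_class <- setNames(fnc, as.character(seq_len(n_classes) - 1L))
    m
  })
  summarize_metrics(matches, n_classes)
}

#' Evaluate a model on labeled images
#'
#' Runs detection (letterbox, forward, decode, NMS) on each image and
#' scores the results at IoU 0.5.
#'
#' @param model a `gd_model`.
#' @param images list of `labeled_image` with ground-truth boxes.
#' @param conf_threshold decode threshold (low, so the PR sweep is full).
#' @param iou_threshold NMS threshold.
#' @return an `eval_report`.
#' @export
evaluate_model <- function(model, images, conf_threshold = 0.001,
                           iou_threshold = 0.45) {
  dets <- detect_images(model, images, conf_threshold, iou_threshold)
  gts <- lapply(images, function(im) {
    d <- dim(im$pixels)
    convert_box(im$boxes, c(d[2], d[1]))
  })
  evaluate_detections(dets, gts, model$n_classes)
}
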