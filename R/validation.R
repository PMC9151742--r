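# Perimeter validation: confusion-matrix areas between tracked and
# reference burned polygons, the derived scores (ratio, accuracy,
# precision, recall, IoU, F1), overlap-based fire matching, and per-fire
# score statistics.

#' Confusion matrix of burned-area agreement
#'
#' Holds the four cell areas (any consistent unit) with the derived
#' margins: \code{FEDS_B = FP + TP} (predicted burned), \code{REF_B =
#' FN + TP} (reference burned) and \code{AREA_TOTAL}.
#'
#' @param tn,fp,fn,tp Cell areas (true negative, false positive, false
#'   negative, true positive); all non-negative.
#' @param units Unit label carried along (e.g. \code{"m2"}, \code{"Mha"}).
#' @return An object of class \code{fed_confusion}.
#' @export
confusion_matrix <- function(tn, fp, fn, tp, units = "m2") {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  structure(list(TN = tn, FP = fp, FN = fn, TP = tp,
                 FEDS_B = fp + tp, REF_B = fn + tp,
                 AREA_TOTAL = tn + fp + fn + tp, units = units),
            class = "fed_confusion")
}

#' @export
print.fed_confusion <- function(x, ...) {
  cat(sprintf("<fed_confusion> [%s] TN %.4g FP %.4g FN %.4g TP %.4g\n",
              x$units, x$TN, x$FP, x$FN, x$TP))
  invisible(x)
}

as_geom_list <- function(x) {
  if (inherits(x, "fgeom")) list(x)
  else if (inherits(x, "fed_hull")) list(x$geom)
  else lapply(x, function(g) if (inherits(g, "fed_hull")) g$geom else g)
}

#' Area confusion matrix from polygon sets
#'
#' Overlays predicted and reference burned polygons inside a region:
#' TP is the area of intersection of the two unions, FP the predicted-only
#' area, FN the reference-only area and TN the remaining region area. All
#' areas are computed exactly on the projected metre plane.
#'
#' @param pred,ref An \code{fgeom} (or \code{fed_hull}) or a list of them;
#'   overlaps within each set are handled (the set is treated as a union).
#' @param region An \code{fgeom} covering both sets.
#' @return A \code{\link{confusion_matrix}} in m2.
#' @export
area_confusion <- function(pred, ref, region) {
  pred <- as_geom_list(pred); ref <- as_geom_list(ref)
  pred <- Filter(function(g) !fg_is_empty(g), pred)
  ref <- Filter(function(g) !fg_is_empty(g), ref)
  verts <- do.call(rbind, c(lapply(pred, function(g) do.call(rbind, g$rings)),
                            lapply(ref, function(g) do.call(rbind, g$rings))))
  if (!is.null(verts) && nrow(verts) > 0 &&
      !all(fg_covers(region, verts, tol = 1)))
    stop("area_confusion: region does not cover pred and ref")
  # reference side in disjoint convex pieces; prediction side kept as
  # rings (tracked hulls can be large) when its members are disjoint
  rp <- disjoint_pieces(ref)
  a_ref <- sum(vapply(rp, ring_area, 0))
  if (geoms_pairwise_disjoint(pred)) {
    a_pred <- sum(vapply(pred, fg_area, 0))
    tp <- 0
    for (g in pred) {
      gb <- fg_bbox(g)
      for (p in rp) {
        if (!bbox_overlap(bbox_of(p), gb)) next
        for (m in g$rings) tp <- tp + sh_clip_area(m, p)
      }
    }
  } else {
    pp <- disjoint_pieces(pred)
    a_pred <- sum(vapply(pp, ring_area, 0))
    tp <- 0
    pb <- lapply(pp, bbox_of); rb <- lapply(rp, bbox_of)
    for (i in seq_along(pp)) {
      for (j in seq_along(rp)) {
        if (!bbox_overlap(pb[[i]], rb[[j]])) next
        tp <- tp + sh_clip_area(pp[[i]], rp[[j]])
      }
    }
  }
  fp <- max(0, a_pred - tp)
  fn <- max(0, a_ref - tp)
  tn <- max(0, fg_area(region) - tp - fp - fn)
  confusion_matrix(tn, fp, fn, tp, units = "m2")
}

#' Perimeter agreement scores
#'
#' Derives the score set from a confusion matrix: \code{ratio =
#' FEDS_B/REF_B}, \code{accuracy = (TP+TN)/AREA_TOTAL}, \code{precision =
#' TP/FEDS_B}, \code{recall = TP/REF_B}, \code{iou = TP/(TP+FP+FN)} and
#' \code{f1 = 2 precision recall / (precision + recall)}. Scores with a
#' zero denominator are NA.
#'
#' @param cm A \code{\link{confusion_matrix}}.
#' @return Named list of class \code{fed_scores}.
#' @export
perimeter_scores <- function(cm) {
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- sdiv(cm$TP, cm$FEDS_B)
  recall <- sdiv(cm$TP, cm$REF_B)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(
    ratio = sdiv(cm$FEDS_B, cm$REF_B),
    accuracy = sdiv(cm$TP + cm$TN, cm$AREA_TOTAL),
    precision = precision, recall = recall,
    iou = sdiv(cm$TP, cm$TP + cm$FP + cm$FN),
    f1 = f1), class = "fed_scores")
}

#' @export
print.fed_scores <- function(x, ...) {
  cat(sprintf(paste0("<fed_scores> ratio %.3f accuracy %s precision %.3f ",
                     "recall %.3f iou %.3f f1 %.3f\n"),
              x$ratio,
              if (is.na(x$accuracy)) "NA" else sprintf("%.3f", x$accuracy),
              x$precision, x$recall, x$iou, x$f1))
  invisible(x)
}

#' Match predicted fires to reference fires by spatial overlap
#'
#' Every predicted fire with positive intersection area with a reference
#' fire is mapped to it; a predicted fire may match several references
#' (and vice versa: one reference fire often corresponds to multiple
#' tracked objects).
#'
#' @param pred,ref Named lists of \code{fgeom} (names are the fire ids).
#' @return List with \code{mapping} (named list: reference id -> character
#'   vector of predicted ids), \code{unmatched_pred} and
#'   \code{unmatched_ref} (character vectors).
#' @export
match_by_overlap <- function(pred, ref) {
  pred <- as_geom_list_named(pred); ref <- as_geom_list_named(ref)
  mapping <- list()
  matched_pred <- character(0)
  for (rn in names(ref)) {
    hits <- character(0)
    for (pn in names(pred)) {
      if (fg_intersection_area(pred[[pn]], ref[[rn]]) > 1e-9)
        hits <- c(hits, pn)
    }
    if (length(hits)) {
      mapping[[rn]] <- hits
      matched_pred <- union(matched_pred, hits)
    }
  }
  list(mapping = mapping,
       unmatched_pred = setdiff(names(pred), matched_pred),
       unmatched_ref = setdiff(names(ref), names(mapping)))
}

as_geom_list_named <- function(x) {
  out <- as_geom_list(x)
  if (is.null(names(out)) || any(names(out) == ""))
    names(out) <- as.character(seq_along(out))
  out
}

#' Per-fire perimeter scores
#'
#' For each matched reference fire, scores the union of its matched
#' predicted fires against that reference (per-fire accuracy is not
#' defined, as there is no per-fire region). Reports the per-fire table
#' and the mean with 1-sigma (population) standard deviation of each
#' score.
#'
#' @param matching Result of \code{\link{match_by_overlap}}.
#' @param pred,ref Named lists of \code{fgeom} as in
#'   \code{\link{match_by_overlap}}.
#' @return List with \code{per_fire} (data.frame), \code{mean} and
#'   \code{sd} (named numeric vectors over ratio, precision, recall, iou,
#'   f1) and \code{n_unmatched_ref}.
#' @export
per_fire_scores <- function(matching, pred, ref) {
  pred <- as_geom_list_named(pred); ref <- as_geom_list_named(ref)
  if (length(matching$mapping) == 0)
    stop("per_fire_scores: empty matching")
  rows <- list()
  for (rn in names(matching$mapping)) {
    pg <- pred[matching$mapping[[rn]]]
    tp <- union_intersection_area(pg, ref[[rn]])
    feds_b <- fg_union_area(pg)
    ref_b <- fg_area(ref[[rn]])
    cm <- confusion_matrix(0, max(0, feds_b - tp), max(0, ref_b - tp), tp)
    s <- perimeter_scores(cm)
    rows[[rn]] <- data.frame(ref_id = rn, n_pred = length(pg),
                             ratio = s$ratio, precision = s$precision,
                             recall = s$recall, iou = s$iou, f1 = s$f1,
                             stringsAsFactors = FALSE)
  }
  per_fire <- do.call(rbind, rows)
  metrics <- c("ratio", "precision", "recall", "iou", "f1")
  mu <- vapply(metrics, function(m) mean(per_fire[[m]]), 0)
  psd <- vapply(metrics, function(m) {
    v <- per_fire[[m]]
    sqrt(mean((v - mean(v))^2))  # population sd
  }, 0)
  list(per_fire = per_fire, mean = mu, sd = psd,
       n_unmatched_ref = length(matching$unmatched_ref))
}
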