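# Segmentation quality measures: confusion-based overlap scores, the
# over-/under-segmentation conditional entropies, mutual information,
# unsupervised region-homogeneity measures, and Hausdorff distances.

as_mask <- function(x, what = "grid") {
  if (is.null(dim(x))) stop(what, " must be a matrix or array")
  x != 0
}

check_same_shape <- function(a, b, na = "seg", nb = "gt") {
  if (!identical(dim(a), dim(b)))
    stop(na, " shape ", paste(dim(a), collapse = "x"), " does not match ",
         nb, " shape ", paste(dim(b), collapse = "x"))
}

#' Supervised overlap metrics
#'
#' Pixel-wise confusion counts and overlap scores of a binary segmentation
#' against a binary ground truth (foreground is the positive class):
#' `dice = 2TP / (2TP + FP + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `jaccard = TP / (TP + FP + FN)`. Dice is the
#' harmonic mean of precision and recall, and `dice = 2J / (1 + J)`.
#' Degenerate foregrounds: when both are empty all four scores are defined
#' as 1; when exactly one is empty they are 0.
#'
#' @param seg Predicted binary label grid (0 = background, nonzero =
#'   foreground).
#' @param gt Ground truth binary label grid, same shape.
#' @return A list with `tp`, `fp`, `fn`, `tn`, `dice`, `precision`,
#'   `recall`, `jaccard`.
#' @examples
#' gt <- matrix(0, 4, 4); gt[2:3, 1:4] <- 1
#' supervised_metrics(gt, gt)$dice   # 1
#' @export
supervised_metrics <- function(seg, gt) {
  s <- as_mask(seg, "seg"); g <- as_mask(gt, "gt")
  check_same_shape(s, g)
  tp <- sum(s & g); fp <- sum(s & !g); fn <- sum(!s & g); tn <- sum(!s & !g)
  if (tp + fp + fn == 0) {           # both foregrounds empty
    dice <- precision <- recall <- jaccard <- 1
  } else if (tp == 0 && (fp == 0 || fn == 0)) {  # one-sided empty
    dice <- precision <- recall <- jaccard <- 0
  } else {
    dice <- 2 * tp / (2 * tp + fp + fn)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    jaccard <- tp / (tp + fp + fn)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, dice = dice,
       precision = precision, recall = recall, jaccard = jaccard)
}

# Joint relative frequencies P(T, S) over (ground truth segment, predicted
# segment); rows T, columns S.
joint_distribution <- function(seg, gt) {
  check_same_shape(seg, gt)
  tab <- table(T = as.vector(gt), S = as.vector(seg))
  tab / sum(tab)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# -sum_{T,S} P(T,S) log P(S|T) with rows of `joint` indexed by T (natural
# log; 0 log 0 terms dropped).
cond_entropy_cols_given_rows <- function(joint) {
  h <- 0
  pt <- rowSums(joint)
  for (i in seq_len(nrow(joint))) {
    if (pt[i] == 0) next
    p <- joint[i, ]
    p <- p[p > 0]
    h <- h - sum(p * log(p / pt[i]))
  }
  h
}

#' Over-segmentation entropy
#'
#' The conditional entropy H(S | T) of the segmentation S given the ground
#' truth T, in nats: how much a ground-truth segment is fragmented across
#' predicted segments. Zero iff every ground-truth segment maps into a single
#' predicted segment (no over-segmentation). Invariant to label renaming.
#'
#' @param seg Predicted label grid (any integer labels).
#' @param gt Ground truth label grid, same shape.
#' @return A non-negative scalar (nats).
#' @examples
#' gt <- matrix(rep(1:2, each = 8), 4)
#' ose(gt, gt)   # 0
#' @export
ose <- function(seg, gt) {
  cond_entropy_cols_given_rows(joint_distribution(seg, gt))
}

#' Under-segmentation entropy
#'
#' The conditional entropy H(T | S) of the ground truth T given the
#' segmentation S, in nats: how much a predicted segment mixes ground-truth
#' segments. Zero iff every predicted segment lies inside a single
#' ground-truth segment (no under-segmentation). Role-symmetric with [ose()]:
#' `use(seg, gt) == ose(gt, seg)`.
#'
#' @inheritParams ose
#' @return A non-negative scalar (nats).
#' @export
use <- function(seg, gt) {
  cond_entropy_cols_given_rows(t(joint_distribution(seg, gt)))
}

#' Mutual information between segmentation and ground truth
#'
#' `I(S; T) = H(S) + H(T) - H(S, T)` over the joint label distribution, in
#' nats; symmetric and non-negative, equal to `H(T) - use(seg, gt)`.
#'
#' @inheritParams ose
#' @return A non-negative scalar (nats).
#' @export
mutual_information <- function(seg, gt) {
  joint <- joint_distribution(seg, gt)
  hs <- entropy_nat(colSums(joint))
  ht <- entropy_nat(rowSums(joint))
  hst <- entropy_nat(as.vector(joint))
  max(0, hs + ht - hst)
}

#' Unsupervised region homogeneity
#'
#' Foreground and background error are the sums of squared differences
#' between the intensities of a region's pixels and the region's mean
#' intensity (an empty region contributes 0); uniformity is their convex
#' combination with coefficients given by the regions' pixel proportions.
#'
#' @param image Feature grid, intensities in [0, 1].
#' @param seg Binary label grid (0 = background, nonzero = foreground), same
#'   shape.
#' @return A list with `fg_error`, `bg_error`, `uniformity`.
#' @examples
#' img <- matrix(c(0.2, 0.4, 0.9, 0.9), 1)
#' region_errors(img, matrix(c(1, 1, 0, 0), 1))$fg_error   # 0.02
#' @export
region_errors <- function(image, seg) {
  s <- as_mask(seg, "seg")
  check_same_shape(image, s, "image", "seg")
  sse <- function(v) if (length(v) == 0L) 0 else sum((v - mean(v))^2)
  fg <- sse(image[s]); bg <- sse(image[!s])
  n <- length(image)
  list(fg_error = fg, bg_error = bg,
       uniformity = (sum(s) / n) * fg + (sum(!s) / n) * bg)
}

#' Discrepancy between an image and its segmentation
#'
#' Squared grey-level error between the image and its piecewise reconstruction
#' by per-region mean intensity: `sum_p (I(p) - mean(I over seg(p)'s
#' region))^2`. For a binary segmentation this equals
#' `fg_error + bg_error` of [region_errors()]. Zero iff the segmentation's
#' regions are exactly the image's constant pieces.
#'
#' @param image Feature grid.
#' @param seg Label grid (any integer labels), same shape.
#' @return A non-negative scalar.
#' @export
discrepancy <- function(image, seg) {
  check_same_shape(image, seg, "image", "seg")
  total <- 0
  for (lab in unique(as.vector(seg))) {
    v <- image[seg == lab]
    total <- total + sum((v - mean(v))^2)
  }
  total
}

# Foreground boundary pixels: foreground with at least one 4-neighbour that
# is background; pixels on the image border count as boundary (out-of-grid
# is not foreground). Returns an n x d coordinate matrix.
boundary_pixels <- function(mask) {
  d <- length(dim(mask))
  pad <- function(m, off) {
    out <- array(FALSE, dim = dim(m))
    src <- dst <- lapply(dim(m), seq_len)
    for (j in seq_len(d)) {
      if (off[j] == 1L) { src[[j]] <- src[[j]][-1L]; dst[[j]] <- dst[[j]][-dim(m)[j]] }
      if (off[j] == -1L) { src[[j]] <- src[[j]][-dim(m)[j]]; dst[[j]] <- dst[[j]][-1L] }
    }
    out[do.call(cbind, expand.grid(dst))] <- m[do.call(cbind, expand.grid(src))]
    out
  }
  interior <- array(TRUE, dim = dim(mask))
  for (j in seq_len(d)) {
    for (s in c(-1L, 1L)) {
      off <- rep(0L, d); off[j] <- s
      interior <- interior & pad(mask, off)
    }
  }
  which(mask & !interior, arr.ind = TRUE)
}

directed_hausdorff <- function(a, b, average = FALSE) {
  # a, b: coordinate matrices; distance from each point of a to its nearest
  # point of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  mins <- sqrt(apply(d2, 1L, min))
  if (average) mean(mins) else max(mins)
}

#' Hausdorff distance between two foreground boundaries
#'
#' The maximum of the two directed Hausdorff distances between the foreground
#' boundary pixel sets of two binary masks (Euclidean metric on pixel
#' coordinates); symmetric, zero for identical foregrounds. A foreground
#' pixel is boundary when any 4-neighbour is background (image border pixels
#' included). With `average = TRUE`, the average Hausdorff variant is
#' returned instead: the mean of the two mean directed nearest-neighbour
#' distances.
#'
#' @param segA,segB Binary label grids of identical shape with non-empty
#'   foregrounds.
#' @param average Return the average-Hausdorff variant. Default `FALSE`.
#' @return A non-negative scalar (pixels).
#' @examples
#' a <- matrix(0, 8, 8); a[3:4, 3:4] <- 1
#' b <- matrix(0, 8, 8); b[4:5, 3:4] <- 1
#' hausdorff_distance(a, b)   # 1
#' @export
hausdorff_distance <- function(segA, segB, average = FALSE) {
  ma <- as_mask(segA, "segA"); mb <- as_mask(segB, "segB")
  check_same_shape(ma, mb, "segA", "segB")
  if (!any(ma) || !any(mb))
    stop("hausdorff_distance is undefined for an empty foreground",
         call. = FALSE)
  ba <- boundary_pixels(ma); bb <- boundary_pixels(mb)
  if (average) {
    mean(c(directed_hausdorff(ba, bb, TRUE), directed_hausdorff(bb, ba, TRUE)))
  } else {
    max(directed_hausdorff(ba, bb), directed_hausdorff(bb, ba))
  }
}

#' Full metric report for one segmentation
#'
#' Convenience bundle of every scalar measure: the supervised overlap scores,
#' the entropy measures (`ose`, `use`, their sum `voi`, mutual information)
#' and, when `image` is supplied, the unsupervised homogeneity measures.
#' Hausdorff distances are `NA` when either foreground is empty.
#'
#' @param seg Predicted binary label grid.
#' @param gt Ground truth binary label grid.
#' @param image Optional feature grid for the unsupervised measures.
#' @return A one-row data frame of named scalars.
#' @export
metric_report <- function(seg, gt, image = NULL) {
  sm <- supervised_metrics(seg, gt)
  rep <- data.frame(
    dice = sm$dice, precision = sm$precision, recall = sm$recall,
    jaccard = sm$jaccard,
    tp = sm$tp, fp = sm$fp, fn = sm$fn, tn = sm$tn,
    ose = ose(seg, gt), use = use(seg, gt),
    mutual_information = mutual_information(seg, gt))
  rep$voi <- rep$ose + rep$use
  both_fg <- any(as_mask(seg) != 0) && any(as_mask(gt) != 0)
  rep$hausdorff <- if (both_fg) hausdorff_distance(seg, gt) else NA_real_
  rep$avg_hausdorff <-
    if (both_fg) hausdorff_distance(seg, gt, average = TRUE) else NA_real_
  if (!is.null(image)) {
    re <- region_errors(image, seg)
    rep$fg_error <- re$fg_error
    rep$bg_error <- re$bg_error
    rep$uniformity <- re$uniformity
    rep$discrepancy <- discrepancy(image, as_mask(seg) * 1L)
  }
  rep
}

#' Median and quartiles of metrics across a batch
#'
#' Aggregates a stack of per-image [metric_report()] rows by a grouping
#' column (typically the algorithm/configuration), reporting the median and
#' the 1st and 3rd quartiles of each metric.
#'
#' @param reports Data frame of metric rows plus a grouping column.
#' @param by Name of the grouping column. Default `"algorithm"`.
#' @return A long data frame with columns `by`, `metric`, `q1`, `median`,
#'   `q3`.
#' @export
aggregate_metrics <- function(reports, by = "algorithm") {
  if (!by %in% names(reports)) stop("no grouping column '", by, "'")
  metrics <- setdiff(names(reports), by)
  metrics <- metrics[vapply(reports[metrics], is.numeric, logical(1))]
  out <- do.call(rbind, lapply(split(reports, reports[[by]]), function(gr) {
    do.call(rbind, lapply(metrics, function(m) {
      q <- quantile(gr[[m]], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      df <- data.frame(group = gr[[by]][1L], metric = m,
                       q1 = q[1L], median = q[2L], q3 = q[3L])
      names(df)[1L] <- by
      df
    }))
  }))
  rownames(out) <- NULL
  out
}
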