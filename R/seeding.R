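# Algorithmic vertical-line seed generation from a ground-truth mask:
# one background and one foreground seed per image, each the tallest
# contiguous vertical run of its region, trimmed to a fraction of its height.

# Maximal vertical runs of `member` cells in one column; returns a matrix of
# (start, end) rows, possibly empty.
column_runs <- function(member) {
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Tallest run of a region over all columns; ties broken leftmost column then
# topmost run. Returns list(col, start, end) or NULL when the region is empty.
tallest_run <- function(mask) {
  best <- NULL
  for (j in seq_len(ncol(mask))) {
    runs <- column_runs(mask[, j])
    if (nrow(runs) == 0L) next
    for (i in seq_len(nrow(runs))) {
      h <- runs[i, "end"] - runs[i, "start"] + 1L
      if (is.null(best) || h > best$height)
        best <- list(col = j, start = runs[i, "start"],
                     end = runs[i, "end"], height = h)
    }
  }
  best
}

# Trim a run to max(1, floor(fraction * h)) pixels, centered; the slack is
# split floor(top)/ceiling(bottom).
trim_run <- function(run, fraction) {
  len <- max(1L, as.integer(floor(fraction * run$height)))
  slack <- run$height - len
  top <- run$start + slack %/% 2L
  seq.int(top, top + len - 1L)
}

#' Generate vertical line seeds from a ground truth mask
#'
#' For each of the two regions of a binary ground truth (background and
#' foreground), finds -- among all maximal contiguous vertical runs of that
#' region's pixels within single columns -- the tallest one (ties: leftmost
#' column, then topmost run), trims it to `max(1, floor(fraction * height))`
#' pixels centered within the run, and emits its pixels as seeds carrying the
#' region's label. This removes subjectivity from seed placement: every seed
#' pixel carries the ground-truth label of its own location.
#'
#' For a 3D ground truth, seeds are generated independently per slice and
#' tagged with a `slice` column (one background and one foreground seed per
#' slice); the same seed map serves both stitch and full volume modes.
#'
#' @param gt Binary ground truth grid: 0/`FALSE` = background, anything else
#'   = foreground. 2D matrix or 3D array.
#' @param fraction Fraction of the run height kept, in (0, 1]. Default 0.75.
#' @return Seed data frame with columns `row`, `col` (and `slice` for 3D)
#'   and `label` (1 = background, 2 = foreground).
#' @examples
#' gt <- matrix(0L, 8, 8); gt[, 4:6] <- 1L
#' generate_vertical_seeds(gt)   # 6-pixel seeds (floor(0.75 * 8))
#' @export
generate_vertical_seeds <- function(gt, fraction = 0.75) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (is.null(dim(gt))) stop("gt must be a matrix or 3D array")
  if (length(dim(gt)) == 3L) {
    per_slice <- lapply(seq_len(dim(gt)[3L]), function(s) {
      sm <- generate_vertical_seeds(gt[, , s], fraction)
      sm$slice <- s
      sm
    })
    return(do.call(rbind, per_slice)[, c("row", "col", "slice", "label")])
  }

  fg <- gt != 0
  out <- list()
  for (lab in 1:2) {
    mask <- if (lab == 1L) !fg else fg
    region <- c("background", "foreground")[lab]
    if (!any(mask))
      stop("ground truth contains no ", region, " pixels")
    run <- tallest_run(mask)
    rows <- trim_run(run, fraction)
    out[[lab]] <- data.frame(row = rows, col = run$col, label = lab)
  }
  do.call(rbind, out)
}
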