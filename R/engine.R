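# GrowCut / BBG automaton: user-facing runner, attack primitives, win-source
# classification, the naive double-loop reference implementation, and 3D
# (stitch / full) segmentation.

#' Attack attenuation function
#'
#' The strength-transfer attenuation `g(x) = 1 - x / max_diff`, a
#' non-increasing map of feature difference onto [0, 1]: identical features
#' transfer the attacker's full strength (`g(0) = 1`), a maximal feature
#' difference annihilates the attack (`g(max_diff) = 0`). With grey
#' intensities normalized to [0, 1], `max_diff = 1`.
#'
#' @param x Non-negative feature difference(s), `0 <= x <= max_diff`.
#' @param max_diff Largest possible feature difference (default 1).
#' @return `1 - x / max_diff`, in [0, 1]. Vectorized over `x`.
#' @examples
#' g_attenuation(0.9)   # 0.1
#' @export
g_attenuation <- function(x, max_diff = 1) {
  if (max_diff <= 0) stop("max_diff must be positive")
  if (any(x < 0 | x > max_diff))
    stop("feature difference outside [0, max_diff]; normalize features first")
  1 - x / max_diff
}

#' Attack strength of one cell on another
#'
#' The strength with which attacker `q` attacks defender `p`:
#' `g(|C(p) - C(q)|) * sigma(q)`. A capture occurs iff this value strictly
#' exceeds the defender's own strength `sigma(p)`.
#'
#' @param q,p Attacker and defender coordinates (1-based vectors), or scalar
#'   linear indices into the grid.
#' @param features Feature grid (matrix/array with values in [0, 1]).
#' @param strengths Strength grid of the same shape.
#' @return The attack strength, a scalar in [0, 1].
#' @examples
#' f <- matrix(c(1, 0.1, 1, 0.1), 1)
#' s <- matrix(c(1, 0, 0, 1), 1)
#' attack_strength(c(1, 1), c(1, 2), f, s)   # seed A attacks B: 0.1
#' @export
attack_strength <- function(q, p, features, strengths) {
  iq <- if (length(q) > 1L) coord_to_index(q, dim(features)) else as.integer(q)
  ip <- if (length(p) > 1L) coord_to_index(p, dim(features)) else as.integer(p)
  g_attenuation(abs(features[ip] - features[iq])) * strengths[iq]
}

#' Classify the source of a label propagation
#'
#' Given the best successful local and remote attack strengths against a
#' defender, names the capture source: `"local"` when the local attacker wins
#' (including ties with a remote attacker -- local wins ties), `"remote"` when
#' only a remote attacker succeeds, `"override"` when both succeed and the
#' remote one is strictly stronger (a local neighbour would have propagated
#' the label in the remote band's absence), and `"none"` when no attack
#' succeeds.
#'
#' @param best_local,best_remote Best local / remote attack strength, or `NA`
#'   / `NULL` when there is no such attacker.
#' @param defense The defender's strength.
#' @return One of `"local"`, `"remote"`, `"override"`, `"none"`.
#' @export
classify_win <- function(best_local, best_remote, defense) {
  bl <- if (is.null(best_local) || is.na(best_local)) -Inf else best_local
  br <- if (is.null(best_remote) || is.na(best_remote)) -Inf else best_remote
  local_ok <- bl > defense
  remote_ok <- br > defense
  if (remote_ok && (!local_ok || br > bl)) {
    if (local_ok) "override" else "remote"
  } else if (local_ok) "local" else "none"
}

coord_to_index <- function(coord, shape) {
  coord <- as.integer(coord)
  idx <- coord[1L]
  mult <- 1L
  for (j in seq_along(shape)[-1L]) {
    mult <- mult * shape[j - 1L]
    idx <- idx + (coord[j] - 1L) * mult
  }
  idx
}

# Seeds: data.frame (row, col[, slice], label) or a label grid with
# 0 = unlabeled. Returns initial label/strength grids (seeds get strength 1).
resolve_seeds <- function(seeds, shape) {
  labels <- array(0L, dim = shape)
  if (is.data.frame(seeds)) {
    need <- if (length(shape) == 2L) c("row", "col") else c("row", "col", "slice")
    if (!all(c(need, "label") %in% names(seeds)))
      stop("seed data frame needs columns ", paste(need, collapse = ", "),
           " and label")
    if (nrow(seeds) > 0L) {
      cm <- as.matrix(seeds[, need, drop = FALSE])
      storage.mode(cm) <- "integer"
      if (any(cm < 1L) || any(sweep(cm, 2L, shape, ">") > 0))
        stop("seed coordinates outside the grid")
      if (anyDuplicated(cm)) stop("duplicate seed coordinates")
      lab <- as.integer(seeds$label)
      if (anyNA(lab) || any(lab < 1L))
        stop("seed labels must be integers >= 1 (0 is reserved for unlabeled)")
      labels[cm] <- lab
    }
  } else {
    if (!identical(as.integer(dim(seeds)), as.integer(shape)))
      stop("seed grid shape ", paste(dim(seeds), collapse = "x"),
           " does not match image shape ", paste(shape, collapse = "x"))
    lab <- as.integer(seeds)
    if (anyNA(lab) || any(lab < 0L))
      stop("seed labels must be integers >= 0 (0 = unlabeled)")
    labels <- array(lab, dim = shape)
  }
  strengths <- array(0, dim = shape)
  strengths[labels > 0L] <- 1
  list(labels = labels, strengths = strengths)
}

check_image <- function(image) {
  if (is.null(dim(image)) || !length(dim(image)) %in% c(2L, 3L))
    stop("image must be a 2D matrix or 3D array")
  if (anyNA(image)) stop("image contains NA")
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]; see read_image() for scaling")
  image
}

#' Run the GrowCut / BBG automaton
#'
#' Evolves the seeded cellular automaton until an iteration produces zero
#' captures (convergence) or `max_iter` is reached, in which case the
#' segmentation is returned in its non-converged form. Updates are fully
#' synchronous. With a remote band in `spec`, `k` remote neighbours are
#' drawn per cell per iteration, and a remote attacker captures only when
#' strictly stronger than both the defence and the best local attack.
#'
#' @param image Feature grid (2D matrix or 3D array), intensities in [0, 1].
#' @param seeds Seed map: data frame with columns `row`, `col` (and `slice`
#'   for 3D) plus `label`, or an integer label grid with 0 = unlabeled.
#'   Seed cells start with strength 1.
#' @param spec A [neighbourhood_spec()]. Default: classical GrowCut with the
#'   radius-1 Moore neighbourhood.
#' @param max_iter Iteration cap (default 2000).
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the run (remote sampling included) is bit-reproducible.
#' @param record_samples Record the remote neighbours drawn at every
#'   iteration (for replay through [growcut_reference()]); memory-heavy, for
#'   small grids only.
#' @param record_history Record the label grid after every iteration.
#' @return An object of class `growcut_result`: `labels` (final label grid),
#'   `strengths`, `converged`, `iterations`, `wins` (named vector: local,
#'   remote, override, total), `seconds`, and optionally `samples` /
#'   `history`.
#' @examples
#' wx <- worked_example()
#' res <- growcut(wx$image, wx$seeds)
#' res$labels       # 1 1 2 2: pixels B and C are mislabeled
#' res$iterations   # 2
#' @export
growcut <- function(image, seeds, spec = neighbourhood_spec(),
                    max_iter = 2000L, seed = NULL,
                    record_samples = FALSE, record_history = FALSE) {
  stopifnot(inherits(spec, "nb_spec"))
  image <- check_image(image)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("max_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  shape <- dim(image)
  init <- resolve_seeds(seeds, shape)
  d <- length(shape)
  local_off <- offsets_standard(spec$standard, spec$r, d)
  band_off <- if (is_classical(spec)) {
    matrix(integer(0), 0L, d)
  } else {
    offsets_band(spec$band[1L], spec$band[2L], d)
  }

  t0 <- proc.time()[["elapsed"]]
  raw <- bbg_run_cpp(as.numeric(image), as.integer(shape),
                     as.integer(init$labels), as.numeric(init$strengths),
                     local_off, band_off, spec$k, max_iter,
                     record_samples, record_history)
  secs <- proc.time()[["elapsed"]] - t0

  wins <- c(local = raw$local_wins, remote = raw$remote_wins,
            override = raw$remote_overrides)
  wins <- c(wins, total = sum(wins))
  out <- list(labels = array(raw$labels, dim = shape),
              strengths = array(raw$strengths, dim = shape),
              converged = raw$converged,
              iterations = raw$iterations,
              wins = wins,
              seconds = secs,
              spec = spec)
  if (record_samples) out$samples <- raw$samples
  if (record_history)
    out$history <- lapply(raw$history, array, dim = shape)
  structure(out, class = "growcut_result")
}

#' @export
print.growcut_result <- function(x, ...) {
  cat(sprintf("GrowCut segmentation: %s after %d iteration%s (%.3f s)\n",
              if (x$converged) "converged" else "NOT converged (cap hit)",
              x$iterations, if (x$iterations == 1L) "" else "s", x$seconds))
  tw <- x$wins[["total"]]
  if (tw > 0) {
    cat(sprintf("  wins: %d total | local %.1f%%, remote %.1f%%, override %.1f%%\n",
                as.integer(tw), 100 * x$wins[["local"]] / tw,
                100 * x$wins[["remote"]] / tw, 100 * x$wins[["override"]] / tw))
  } else {
    cat("  wins: none (no successful attacks)\n")
  }
  lv <- sort(unique(as.integer(x$labels)))
  cat("  labels present:", paste(lv, collapse = ", "), "\n")
  invisible(x)
}

#' Run statistics as JSON
#'
#' Serializes the run-level statistics of a [growcut()] result to a JSON
#' string: iterations, convergence flag, win counts by source, and wall time.
#'
#' @param result A `growcut_result`.
#' @return A JSON string (class `json`).
#' @export
run_stats_json <- function(result) {
  stopifnot(inherits(result, "growcut_result"))
  jsonlite::toJSON(list(
    iterations = result$iterations,
    converged = result$converged,
    local_wins = unname(result$wins[["local"]]),
    remote_wins = unname(result$wins[["remote"]]),
    remote_overrides = unname(result$wins[["override"]]),
    total_wins = unname(result$wins[["total"]]),
    seconds = result$seconds), auto_unbox = TRUE, digits = NA)
}

#' Naive reference implementation of the automaton
#'
#' A deliberately unoptimized double loop over cells and neighbours with the
#' same capture semantics as [growcut()], used as an independent oracle for
#' the compiled engine on small grids. For BBG runs it can replay the exact
#' remote samples recorded by `growcut(..., record_samples = TRUE)`, making
#' the two paths comparable iteration by iteration despite the stochastic
#' neighbourhood.
#'
#' @inheritParams growcut
#' @param samples Optional list (one element per iteration) of two-column
#'   matrices of (defender, sampled neighbour) linear indices, as recorded by
#'   the engine. When `NULL` and `spec` has a band, fresh samples are drawn
#'   with [sample_remote()].
#' @return A list with `labels`, `strengths`, `converged`, `iterations`,
#'   `wins`, and `history` (label grid after each iteration).
#' @export
growcut_reference <- function(image, seeds, spec = neighbourhood_spec(),
                              max_iter = 2000L, samples = NULL) {
  stopifnot(inherits(spec, "nb_spec"))
  image <- check_image(image)
  shape <- dim(image)
  d <- length(shape)
  init <- resolve_seeds(seeds, shape)
  lab <- init$labels
  sig <- init$strengths
  n <- length(image)
  coords <- arrayInd(seq_len(n), shape)
  wins <- c(local = 0, remote = 0, override = 0)
  history <- list()
  converged <- FALSE
  iterations <- 0L

  enum_local <- function(center) {
    if (spec$standard == "moore") enumerate_moore(center, spec$r, shape)
    else enumerate_von_neumann(center, spec$r, shape)
  }

  for (t in seq_len(max_iter)) {
    lab_new <- lab
    sig_new <- sig
    captures <- 0L
    iter_samples <- if (!is.null(samples)) samples[[t]] else NULL
    for (p in seq_len(n)) {
      center <- coords[p, ]
      defense <- sig[p]

      best_local <- -Inf; best_local_q <- NA_integer_
      loc <- enum_local(center)
      if (nrow(loc) > 0L) {
        for (i in seq_len(nrow(loc))) {
          q <- coord_to_index(loc[i, ], shape)
          att <- g_attenuation(abs(image[p] - image[q])) * sig[q]
          if (att > best_local) { best_local <- att; best_local_q <- q }
        }
      }

      best_remote <- -Inf; best_remote_q <- NA_integer_
      if (!is_classical(spec)) {
        qs <- if (!is.null(iter_samples)) {
          iter_samples[iter_samples[, 1L] == p, 2L]
        } else {
          cells <- sample_remote(
            enumerate_band(center, spec$band[1L], spec$band[2L], shape),
            spec$k)
          if (nrow(cells) > 0L)
            apply(cells, 1L, coord_to_index, shape = shape)
          else integer(0)
        }
        for (q in qs) {
          att <- g_attenuation(abs(image[p] - image[q])) * sig[q]
          if (att > best_remote) { best_remote <- att; best_remote_q <- q }
        }
      }

      cls <- classify_win(
        if (is.na(best_local_q)) NA else best_local,
        if (is.na(best_remote_q)) NA else best_remote, defense)
      if (cls != "none") {
        winner <- if (cls == "local") best_local_q else best_remote_q
        att <- if (cls == "local") best_local else best_remote
        lab_new[p] <- lab[winner]
        sig_new[p] <- att
        wins[[cls]] <- wins[[cls]] + 1
        captures <- captures + 1L
      }
    }
    lab <- lab_new
    sig <- sig_new
    iterations <- t
    history[[t]] <- lab
    if (captures == 0L) { converged <- TRUE; break }
  }

  list(labels = lab, strengths = sig, converged = converged,
       iterations = iterations, wins = c(wins, total = sum(wins)),
       history = history)
}

#' Segment a 3D volume
#'
#' Two interpretations of a volume: `"stitch"` segments every slice
#' independently as a 2D image (stacking the per-slice label grids, summing
#' win statistics, reporting the maximum per-slice iteration count), while
#' `"full"` runs a single automaton whose cells are voxels, with the 3D
#' extension of the neighbourhoods. In stitch mode a slice without seeds is
#' returned all-unlabeled with a warning.
#'
#' @param volume 3D feature array, intensities in [0, 1].
#' @param seeds Seed data frame with columns `row`, `col`, `slice`, `label`,
#'   or a 3D label array (0 = unlabeled).
#' @param spec A [neighbourhood_spec()]; in full mode its radii are applied
#'   with 3D Chebyshev distance.
#' @param mode `"stitch"` or `"full"`.
#' @inheritParams growcut
#' @return A `growcut_result` over the volume.
#' @export
segment_volume <- function(volume, seeds, spec = neighbourhood_spec(),
                           mode = c("stitch", "full"), max_iter = 2000L,
                           seed = NULL) {
  mode <- match.arg(mode)
  volume <- check_image(volume)
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  if (mode == "full")
    return(growcut(volume, seeds, spec, max_iter = max_iter, seed = seed))

  if (!is.null(seed)) set.seed(seed)
  shape <- dim(volume)
  seed_grid <- resolve_seeds(seeds, shape)$labels
  labels <- array(0L, dim = shape)
  strengths <- array(0, dim = shape)
  wins <- c(local = 0, remote = 0, override = 0, total = 0)
  iters <- 0L
  converged <- TRUE
  t0 <- proc.time()[["elapsed"]]
  for (s in seq_len(shape[3L])) {
    sl_seeds <- seed_grid[, , s]
    if (all(sl_seeds == 0L)) {
      warning("slice ", s, " has no seeds; returned all-unlabeled")
      next
    }
    r <- growcut(volume[, , s], sl_seeds, spec, max_iter = max_iter)
    labels[, , s] <- r$labels
    strengths[, , s] <- r$strengths
    wins <- wins + r$wins
    iters <- max(iters, r$iterations)
    converged <- converged && r$converged
  }
  structure(list(labels = labels, strengths = strengths,
                 converged = converged, iterations = iters, wins = wins,
                 seconds = proc.time()[["elapsed"]] - t0,
                 spec = spec, mode = mode),
            class = "growcut_result")
}

#' Expected remote fraction of a neighbourhood
#'
#' The fraction of a cell's per-iteration attackers that are remote:
#' `k / (n_local + k)`. With the 8-cell radius-1 Moore neighbourhood and
#' `k = 5` this is 5/13, approximately 38% -- the uniformly-random reference
#' value against which observed remote win shares are compared.
#'
#' @param k Remote neighbours sampled per iteration.
#' @param n_local Number of standard local neighbours (8 for Moore r = 1 in
#'   2D).
#' @return `k / (n_local + k)`.
#' @examples
#' round(100 * remote_fraction(5, 8))   # 38
#' @export
remote_fraction <- function(k, n_local = 8L) {
  k / (n_local + k)
}
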