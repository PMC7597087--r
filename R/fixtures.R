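# Synthetic scene generators: the four-pixel worked example, disconnected
# foreground scenes (a seeded and a seedless component separated by a
# background gap), noisy two-region shapes, and the ten-scene corpus used to
# study the segmentation-granularity behaviour of the band neighbourhoods.

#' The four-pixel worked example
#'
#' A 1x4 image with intensities (1.0, 0.1, 1.0, 0.1); pixel A (column 1) is
#' seeded background and pixel D (column 4) foreground, both with strength 1.
#' Label propagation from these seeds mislabels pixels B and C: one
#' synchronous iteration gives strengths (1.0, 0.1, 0.1, 1.0) and labels
#' (BG, BG, FG, FG), and the automaton converges at iteration 2 with no
#' successful attacks. The expected post-iteration states are bundled for
#' the test suite.
#'
#' @return A list: `image` (1x4 matrix), `seeds` (seed data frame),
#'   `initial` (strengths/labels at t = 0) and `expected` (strengths and
#'   labels after iteration 1, and the convergence iteration).
#' @examples
#' wx <- worked_example()
#' growcut(wx$image, wx$seeds)$iterations   # 2
#' @export
worked_example <- function() {
  list(
    image = matrix(c(1.0, 0.1, 1.0, 0.1), nrow = 1),
    seeds = data.frame(row = c(1L, 1L), col = c(1L, 4L), label = c(1L, 2L)),
    initial = list(strengths = c(1, 0, 0, 1), labels = c(1L, 0L, 0L, 2L)),
    expected = list(strengths_after_1 = c(1.0, 0.1, 0.1, 1.0),
                    labels_after_1 = c(1L, 1L, 2L, 2L),
                    converged_at = 2L))
}

#' Scene specification
#'
#' Declarative description of a synthetic two-region scene: a grid, a list of
#' foreground components (axis-aligned rectangles or disks), flat intensities
#' for foreground and background, and an optional noise model. Default
#' intensities are background 0.9 and foreground 0.1 (high contrast, the
#' worked example's values).
#'
#' @param shape Grid extents, 2D.
#' @param fg List of components; each is `list(type = "rect", rows = c(r1,
#'   r2), cols = c(c1, c2))` or `list(type = "disk", center = c(r, c),
#'   radius = rad)`.
#' @param bg_intensity,fg_intensity Flat region intensities in [0, 1].
#' @param noise `"none"`, `"gaussian"` or `"salt_pepper"`.
#' @param noise_param Standard deviation of the additive gaussian noise, or
#'   the corruption rate of salt-and-pepper noise.
#' @param seed RNG seed for the noise draw, making the scene reproducible
#'   from the spec alone.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape, fg, bg_intensity = 0.9, fg_intensity = 0.1,
                       noise = c("none", "gaussian", "salt_pepper"),
                       noise_param = 0, seed = NULL) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("shape must be 2D")
  if (bg_intensity < 0 || bg_intensity > 1 ||
      fg_intensity < 0 || fg_intensity > 1)
    stop("intensities must lie in [0, 1]")
  if (noise == "gaussian" && noise_param < 0)
    stop("gaussian noise sd must be >= 0")
  if (noise == "salt_pepper" && (noise_param < 0 || noise_param > 1))
    stop("salt-and-pepper rate must lie in [0, 1]")
  structure(list(shape = shape, fg = fg, bg_intensity = bg_intensity,
                 fg_intensity = fg_intensity, noise = noise,
                 noise_param = noise_param, seed = seed),
            class = "scene_spec")
}

component_mask <- function(comp, shape) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  if (comp$type == "rect") {
    r <- pmax(1L, pmin(shape[1L], as.integer(comp$rows)))
    cc <- pmax(1L, pmin(shape[2L], as.integer(comp$cols)))
    m[r[1L]:r[2L], cc[1L]:cc[2L]] <- TRUE
  } else if (comp$type == "disk") {
    rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cols <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    m <- (rows - comp$center[1L])^2 + (cols - comp$center[2L])^2 <=
      comp$radius^2
  } else stop("unknown component type '", comp$type, "'")
  m
}

apply_noise <- function(image, noise, param) {
  if (noise == "gaussian" && param > 0) {
    image <- image + rnorm(length(image), sd = param)
  } else if (noise == "salt_pepper" && param > 0) {
    hit <- runif(length(image)) < param
    image[hit] <- ifelse(runif(sum(hit)) < 0.5, 0, 1)
  }
  image[] <- pmin(pmax(image, 0), 1)
  image
}

#' Render a noisy two-region scene
#'
#' Renders the piecewise-constant image described by a [scene_spec()] (all
#' foreground components at `fg_intensity` over a `bg_intensity` background),
#' applies its noise model, clips to [0, 1], and returns the image with its
#' noise-free binary ground truth. Deterministic given the spec's seed.
#' Foreground components must be pairwise disjoint.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` and `gt` (0 = background, 1 = foreground).
#' @examples
#' sp <- scene_spec(c(32, 32),
#'                  list(list(type = "rect", rows = c(8, 24), cols = c(8, 24))),
#'                  noise = "gaussian", noise_param = 0.05, seed = 1)
#' sc <- noisy_shapes(sp)
#' range(sc$image)
#' @export
noisy_shapes <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  masks <- lapply(spec$fg, component_mask, shape = spec$shape)
  if (length(masks) > 1L) {
    overlap <- Reduce(`+`, lapply(masks, `*`, 1L))
    if (any(overlap > 1L)) stop("foreground components overlap")
  }
  gt <- matrix(0L, spec$shape[1L], spec$shape[2L])
  for (m in masks) gt[m] <- 1L
  image <- matrix(spec$bg_intensity, spec$shape[1L], spec$shape[2L])
  image[gt == 1L] <- spec$fg_intensity
  if (!is.null(spec$seed)) set.seed(spec$seed)
  image <- apply_noise(image, spec$noise, spec$noise_param)
  list(image = image, gt = gt)
}

#' Disconnected-foreground scene
#'
#' A scene with two foreground components of (near-)identical intensity
#' separated by a background gap of width `gap` columns: a seeded component
#' (left) and a seedless one (right). Seeds are generated algorithmically
#' but only from the seeded component, so classical GrowCut has no path
#' through which the foreground label can reach the seedless component,
#' while a band-based neighbourhood whose outer radius bridges the gap can
#' rescue it through remote attacks.
#'
#' @param shape Grid extents, 2D. Default `c(32, 44)`.
#' @param gap Background gap width in columns between the two components
#'   (>= 1). Default 4.
#' @param noise,noise_param,seed Passed to the underlying [scene_spec()].
#' @return A list with `image`, `gt` (both components foreground), `seeds`
#'   (inside the seeded component and the background only), and the
#'   component masks `seeded` and `seedless`.
#' @export
disconnected_scene <- function(shape = c(32L, 44L), gap = 4L,
                               noise = "none", noise_param = 0, seed = NULL) {
  shape <- as.integer(shape)
  gap <- as.integer(gap)
  if (gap < 1L) stop("gap width must be >= 1")
  margin <- 4L
  r1 <- margin + 1L; r2 <- shape[1L] - margin
  # seeded component spans columns c1..c2, seedless c3..c4, gap between
  width <- (shape[2L] - 2L * margin - gap) %/% 2L
  if (width < 2L) stop("grid too narrow for gap ", gap)
  c1 <- margin + 1L; c2 <- c1 + width - 1L
  c3 <- c2 + gap + 1L; c4 <- min(shape[2L] - margin, c3 + width - 1L)
  comps <- list(list(type = "rect", rows = c(r1, r2), cols = c(c1, c2)),
                list(type = "rect", rows = c(r1, r2), cols = c(c3, c4)))
  sc <- noisy_shapes(scene_spec(shape, comps, noise = noise,
                                noise_param = noise_param, seed = seed))
  seeded <- component_mask(comps[[1L]], shape)
  seedless <- component_mask(comps[[2L]], shape)
  # seed generation sees only the seeded component as foreground
  gt_for_seeds <- matrix(0L, shape[1L], shape[2L])
  gt_for_seeds[seeded] <- 1L
  seeds <- generate_vertical_seeds(gt_for_seeds)
  list(image = sc$image, gt = sc$gt, seeds = seeds,
       seeded = seeded, seedless = seedless, gap = gap)
}

#' Ten-scene synthetic corpus
#'
#' A reproducible corpus of `n` two-region scenes in the style used to probe
#' segmentation granularity: each 64x64 scene has a large main foreground
#' component (rectangle or disk, alternating) plus one or two small satellite
#' foreground components placed at increasing distance from it. Vertical
#' seeds generated from the ground truth land in the main component (it
#' carries the tallest vertical run), so the satellites are seedless and
#' reachable only through remote neighbours. Half the scenes carry additive
#' gaussian noise (sd 0.02-0.14), half salt-and-pepper noise (rate
#' 0.02-0.16).
#'
#' @param n Number of scenes (default 10).
#' @param shape Scene extents (default `c(64, 64)`).
#' @param seed Base RNG seed; scene i uses `seed + i`.
#' @return A list of scenes, each with `image`, `gt` and `seeds`.
#' @export
synthetic_corpus <- function(n = 10L, shape = c(64L, 64L), seed = 1L) {
  shape <- as.integer(shape)
  scenes <- vector("list", n)
  gauss_sd <- c(0.02, 0.05, 0.08, 0.11, 0.14)
  sp_rate <- c(0.02, 0.05, 0.08, 0.12, 0.16)
  for (i in seq_len(n)) {
    main <- if (i %% 2L == 1L) {
      list(type = "rect", rows = c(10L, 50L), cols = c(6L, 22L))
    } else {
      list(type = "disk", center = c(30L, 15L), radius = 11L)
    }
    sat_dist <- 10L + 3L * (i - 1L)            # distance grows with index
    sat_col <- min(shape[2L] - 6L, 22L + sat_dist)
    sats <- list(list(type = "rect", rows = c(12L, 15L),
                      cols = c(sat_col, min(shape[2L] - 2L, sat_col + 3L))))
    if (i %% 3L == 0L)
      sats <- c(sats, list(list(type = "rect", rows = c(44L, 47L),
                                cols = c(sat_col, min(shape[2L] - 2L,
                                                      sat_col + 3L)))))
    gauss <- ((i - 1L) %/% 5L) %% 2L == 0L
    pi <- (i - 1L) %% 5L + 1L
    sp <- scene_spec(shape, c(list(main), sats),
                     noise = if (gauss) "gaussian" else "salt_pepper",
                     noise_param = if (gauss) gauss_sd[pi] else sp_rate[pi],
                     seed = seed + i)
    sc <- noisy_shapes(sp)
    scenes[[i]] <- list(image = sc$image, gt = sc$gt,
                        seeds = generate_vertical_seeds(sc$gt))
  }
  scenes
}
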