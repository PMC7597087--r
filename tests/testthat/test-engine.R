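test_that("attenuation g maps feature differences onto [0, 1]", {
  expect_equal(g_attenuation(0), 1)
  expect_equal(g_attenuation(0.9), 0.1)
  expect_equal(g_attenuation(1), 0)
  expect_equal(g_attenuation(0.25, max_diff = 0.5), 0.5)
  expect_error(g_attenuation(1.2), "outside")
  # non-increasing over a grid of differences
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(g_attenuation(x)) <= 0))
})

test_that("attack strength multiplies attenuation by attacker strength", {
  wx <- worked_example()
  f <- wx$image
  s <- matrix(wx$initial$strengths, 1)
  # seed A attacks B across a 0.9 intensity difference
  expect_equal(attack_strength(c(1, 1), c(1, 2), f, s), 0.1)
  # zero-strength attacker can never capture
  expect_equal(attack_strength(c(1, 2), c(1, 1), f, s), 0)
  # after B holds strength 0.1, its counter-attack on A is 0.01
  s2 <- matrix(c(1, 0.1, 0.1, 1), 1)
  expect_equal(attack_strength(c(1, 2), c(1, 1), f, s2), 0.01)
})

test_that("win-source classification follows the ties-go-local rule", {
  expect_equal(classify_win(0.5, NA, 0.2), "local")
  expect_equal(classify_win(NA, 0.5, 0.2), "remote")
  expect_equal(classify_win(0.4, 0.6, 0.3), "override")
  expect_equal(classify_win(0.4, 0.4, 0.3), "local")   # tie goes local
  expect_equal(classify_win(0.2, 0.2, 0.3), "none")
  expect_equal(classify_win(NA, NA, 0), "none")
  # remote succeeded, local failed
  expect_equal(classify_win(0.1, 0.5, 0.2), "remote")
})

test_that("one synchronous step reproduces the worked example's states", {
  wx <- worked_example()
  r1 <- growcut(wx$image, wx$seeds, max_iter = 1)
  expect_equal(as.vector(r1$strengths), wx$expected$strengths_after_1)
  expect_equal(as.vector(r1$labels), wx$expected$labels_after_1)
  expect_false(r1$converged)
  # full run converges at iteration 2 with B and C mislabeled
  r <- growcut(wx$image, wx$seeds)
  expect_true(r$converged)
  expect_equal(r$iterations, wx$expected$converged_at)
  expect_equal(as.vector(r$labels), c(1L, 1L, 2L, 2L))
})

test_that("degenerate automata behave as fixed points", {
  img <- matrix(runif(25, min = 0, max = 1), 5, 5)
  # no seeds: no positive attack is possible, state unchanged
  r0 <- growcut(img, matrix(0L, 5, 5), max_iter = 10)
  expect_true(r0$converged)
  expect_equal(r0$iterations, 1L)
  expect_true(all(r0$labels == 0L))
  expect_equal(r0$wins[["total"]], 0)
  # fully seeded: nothing can strictly exceed strength 1
  full <- matrix(rep(1:2, length.out = 25), 5, 5)
  rf <- growcut(img, full, max_iter = 10)
  expect_true(rf$converged)
  expect_equal(rf$iterations, 1L)
  expect_equal(rf$labels, array(full, dim = c(5, 5)))
})

test_that("strengths stay in [0, 1] and captures strictly increase strength", {
  set.seed(21)
  for (i in 1:5) {
    img <- matrix(runif(64), 8, 8)
    seeds <- data.frame(row = c(1, 8), col = c(1, 8), label = c(1, 2))
    spec <- if (i %% 2 == 0) neighbourhood_spec(band = c(2, 4), k = 3)
            else neighbourhood_spec()
    r <- growcut(img, seeds, spec, seed = i, record_history = TRUE)
    expect_true(all(r$strengths >= 0 & r$strengths <= 1))
    # a converged classical state is a fixed point: no local attack can
    # strictly exceed any defender's strength
    if (is.null(spec$band) && r$converged) {
      viol <- 0L
      for (p in seq_len(64)) {
        center <- arrayInd(p, c(8, 8))[1, ]
        for (qi in seq_len(nrow(nb <- enumerate_moore(center, 1, c(8, 8))))) {
          att <- attack_strength(nb[qi, ], center, img, r$strengths)
          if (att > r$strengths[p]) viol <- viol + 1L
        }
      }
      expect_equal(viol, 0L)
    }
  }
})

test_that("engine validates inputs", {
  img <- matrix(runif(16), 4, 4)
  expect_error(growcut(img, matrix(0L, 5, 5)), "does not match")
  expect_error(growcut(img, data.frame(row = 1, col = 9, label = 1)),
               "outside the grid")
  expect_error(growcut(img, data.frame(row = 1, col = 1, label = -1)),
               "labels must be")
  expect_error(growcut(img * 300, matrix(0L, 4, 4)), "\\[0, 1\\]")
  expect_error(growcut(img, data.frame(row = c(1, 1), col = c(1, 1),
                                       label = c(1, 2))), "duplicate")
})

test_that("compiled engine matches the naive reference on random images", {
  set.seed(33)
  for (i in 1:8) {
    img <- matrix(runif(36), 6, 6)
    seeds <- data.frame(row = c(1, 6), col = c(6, 1), label = c(1, 2))
    a <- growcut(img, seeds)
    b <- growcut_reference(img, seeds)
    expect_identical(as.vector(a$labels), as.vector(b$labels))
    expect_equal(as.vector(a$strengths), as.vector(b$strengths))
    expect_equal(a$iterations, b$iterations)
    expect_equal(a$converged, b$converged)
    expect_equal(unname(a$wins), unname(b$wins))
  }
})

test_that("reference replay of recorded remote samples matches BBG runs", {
  set.seed(34)
  spec <- neighbourhood_spec(band = c(2, 4), k = 3)
  for (i in 1:5) {
    img <- matrix(runif(36), 6, 6)
    seeds <- data.frame(row = c(1, 6), col = c(1, 6), label = c(1, 2))
    a <- growcut(img, seeds, spec, seed = 300 + i, record_samples = TRUE,
                 record_history = TRUE)
    b <- growcut_reference(img, seeds, spec, samples = a$samples)
    expect_identical(as.vector(a$labels), as.vector(b$labels))
    expect_equal(as.vector(a$strengths), as.vector(b$strengths))
    expect_equal(a$iterations, b$iterations)
    expect_equal(unname(a$wins), unname(b$wins))
    # label evolution matches iteration by iteration
    for (t in seq_along(a$history))
      expect_identical(as.vector(a$history[[t]]),
                       as.vector(b$history[[t]]))
  }
})

test_that("classical runs attribute every win to a local neighbour", {
  sc <- two_region_scene(seed = 5)
  seeds <- generate_vertical_seeds(sc$gt)
  r <- growcut(sc$image, seeds, seed = 5)
  expect_gt(r$wins[["total"]], 0)
  expect_equal(r$wins[["remote"]], 0)
  expect_equal(r$wins[["override"]], 0)
  expect_equal(r$wins[["local"]], r$wins[["total"]])
})

test_that("identical config and seed give bit-identical results", {
  sc <- two_region_scene(seed = 8, shape = c(32L, 32L))
  seeds <- generate_vertical_seeds(sc$gt)
  spec <- neighbourhood_spec(band = c(5, 10), k = 5)
  a <- growcut(sc$image, seeds, spec, seed = 99, max_iter = 300)
  b <- growcut(sc$image, seeds, spec, seed = 99, max_iter = 300)
  expect_identical(a$labels, b$labels)
  expect_identical(a$strengths, b$strengths)
  expect_identical(a$wins, b$wins)
  expect_identical(a$iterations, b$iterations)
})

test_that("stitch mode segments slices independently", {
  sc <- two_region_scene(seed = 12, shape = c(16L, 16L), noise = 0)
  vol <- array(sc$image, dim = c(16, 16, 3))
  seeds2d <- generate_vertical_seeds(sc$gt)
  gt3 <- array(sc$gt, dim = c(16, 16, 3))
  seeds3d <- generate_vertical_seeds(gt3)
  r2 <- growcut(sc$image, seeds2d)
  r3 <- segment_volume(vol, seeds3d, mode = "stitch")
  for (s in 1:3)
    expect_identical(as.vector(r3$labels[, , s]), as.vector(r2$labels))
  expect_equal(r3$iterations, r2$iterations)
  expect_equal(r3$wins[["total"]], 3 * r2$wins[["total"]])
})

test_that("classical stitch and full agree on an axis-uniform volume", {
  # slices identical along axis 3: cross-slice attackers mirror in-slice
  # ones, so the full 3D run reproduces the per-slice result
  sc <- two_region_scene(seed = 13, shape = c(8L, 8L), noise = 0.03)
  vol <- array(sc$image, dim = c(8, 8, 4))
  gt3 <- array(sc$gt, dim = c(8, 8, 4))
  seeds3d <- generate_vertical_seeds(gt3)
  rs <- segment_volume(vol, seeds3d, mode = "stitch")
  rf <- segment_volume(vol, seeds3d, mode = "full")
  expect_identical(rs$labels, rf$labels)
})

test_that("a seedless slice is returned unlabeled with a warning", {
  sc <- two_region_scene(seed = 14, shape = c(12L, 12L), noise = 0)
  vol <- array(sc$image, dim = c(12, 12, 2))
  seeds <- generate_vertical_seeds(sc$gt)   # slice 1 only
  seeds$slice <- 1L
  expect_warning(r <- segment_volume(vol, seeds, mode = "stitch"),
                 "no seeds")
  expect_true(all(r$labels[, , 2] == 0L))
  expect_false(all(r$labels[, , 1] == 0L))
})

test_that("run statistics serialize to the documented JSON document", {
  wx <- worked_example()
  r <- growcut(wx$image, wx$seeds)
  j <- jsonlite::fromJSON(run_stats_json(r))
  expect_named(j, c("iterations", "converged", "local_wins", "remote_wins",
                    "remote_overrides", "total_wins", "seconds"),
               ignore.order = TRUE)
  expect_equal(j$iterations, 2)
  expect_true(j$converged)
  expect_equal(j$local_wins, 2)
  expect_equal(j$total_wins, 2)
})
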