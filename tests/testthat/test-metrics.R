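test_that("supervised metrics reproduce hand-counted confusion values", {
  gt <- matrix(0L, 4, 4); gt[2:3, 1:4] <- 1L        # 8 fg pixels
  # identical masks
  m <- supervised_metrics(gt, gt)
  expect_equal(c(m$dice, m$precision, m$recall, m$jaccard), rep(1, 4))
  # disjoint equal-size foregrounds
  a <- matrix(0L, 4, 4); a[1, 1:4] <- 1L
  b <- matrix(0L, 4, 4); b[4, 1:4] <- 1L
  expect_equal(supervised_metrics(a, b)$dice, 0)
  # 6 of 8 fg covered plus 2 bg pixels: dice 12/16, jaccard 6/10
  seg <- matrix(0L, 4, 4); seg[2:3, 1:3] <- 1L; seg[c(1, 4), 1] <- 1L
  m2 <- supervised_metrics(seg, gt)
  expect_equal(m2$tp, 6); expect_equal(m2$fp, 2); expect_equal(m2$fn, 2)
  expect_equal(m2$dice, 0.75)
  expect_equal(m2$jaccard, 0.6)
  expect_equal(m2$dice, 2 * m2$jaccard / (1 + m2$jaccard))
  expect_error(supervised_metrics(seg, matrix(0L, 5, 5)), "does not match")
})

test_that("degenerate foregrounds follow the stated conventions", {
  z <- matrix(0L, 3, 3)
  o <- matrix(0L, 3, 3); o[2, 2] <- 1L
  expect_equal(supervised_metrics(z, z)$dice, 1)
  expect_equal(supervised_metrics(z, o)$dice, 0)
  expect_equal(supervised_metrics(o, z)$dice, 0)
})

test_that("over-segmentation entropy evaluates its defining sum", {
  gt <- matrix(rep(1:2, each = 8), 4, 4)            # two equal segments
  # label renaming leaves OSE at zero
  expect_equal(ose(gt, gt), 0)
  expect_equal(ose(3 - gt, gt), 0)
  # splitting each gt segment into two equal parts gives log 2
  seg4 <- matrix(c(rep(1:2, each = 4), rep(3:4, each = 4)), 4, 4)
  expect_equal(ose(seg4, gt), log(2))
  # a single predicted segment shows no over-segmentation
  expect_equal(ose(matrix(1L, 4, 4), gt), 0)
})

test_that("under-segmentation entropy is the role-symmetric counterpart", {
  gt <- matrix(rep(1:2, each = 8), 4, 4)
  seg4 <- matrix(c(rep(1:2, each = 4), rep(3:4, each = 4)), 4, 4)
  expect_equal(use(gt, gt), 0)
  expect_equal(use(matrix(1L, 4, 4), gt), log(2))   # full merge
  expect_equal(use(seg4, gt), 0)                    # pure split
  # role symmetry on random label grids
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(sample.int(3, 36, replace = TRUE), 6, 6)
    b <- matrix(sample.int(4, 36, replace = TRUE), 6, 6)
    expect_equal(use(a, b), ose(b, a))
  }
})

test_that("mutual information satisfies the entropy identities", {
  gt <- matrix(rep(1:2, each = 8), 4, 4)
  expect_equal(mutual_information(gt, gt), log(2))
  # checkerboard vs half-split on a 2x2-periodic grid: independent labels
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  half <- matrix(rep(0:1, each = 8), 4, 4)
  expect_equal(mutual_information(cb, half), 0)
  # MI = H(T) - H(T|S) on random grids
  set.seed(6)
  for (i in 1:10) {
    s <- matrix(sample.int(3, 36, replace = TRUE), 6, 6)
    t_ <- matrix(sample.int(3, 36, replace = TRUE), 6, 6)
    pt <- as.vector(table(t_)) / 36
    ht <- -sum(pt * log(pt))
    expect_equal(mutual_information(s, t_), ht - use(s, t_))
  }
})

test_that("entropy metrics are invariant under label permutation", {
  set.seed(7)
  s <- matrix(sample.int(3, 64, replace = TRUE), 8, 8)
  g <- matrix(sample.int(3, 64, replace = TRUE), 8, 8)
  perm <- c(5L, 9L, 2L)
  sp <- array(perm[s], dim = dim(s))
  expect_equal(ose(sp, g), ose(s, g))
  expect_equal(use(sp, g), use(s, g))
  expect_equal(mutual_information(sp, g), mutual_information(s, g))
})

test_that("region errors and uniformity follow the squared-deviation form", {
  # fg pixels {0.2, 0.4}: mean 0.3, error 2 * 0.01
  img <- matrix(c(0.2, 0.4, 0.9, 0.9), 1)
  seg <- matrix(c(1, 1, 0, 0), 1)
  re <- region_errors(img, seg)
  expect_equal(re$fg_error, 0.02)
  expect_equal(re$bg_error, 0)
  expect_equal(re$uniformity, 0.5 * 0.02)
  # piecewise-constant image split on its pieces: all zero
  sc <- two_region_scene(seed = 1, shape = c(16L, 16L), noise = 0)
  re0 <- region_errors(sc$image, sc$gt)
  expect_equal(re0$uniformity, 0)
  # all pixels in one region: degenerate convex combination
  re1 <- region_errors(img, matrix(1, 1, 4))
  expect_equal(re1$uniformity, re1$fg_error)
})

test_that("discrepancy is squared error to the region-mean reconstruction", {
  img <- matrix(c(1.0, 0.1, 1.0, 0.1), 1)
  seg <- matrix(c(1, 1, 0, 0), 1)          # both region means are 0.55
  expect_equal(discrepancy(img, seg), 4 * 0.45^2)
  sc <- two_region_scene(seed = 2, shape = c(16L, 16L), noise = 0)
  expect_equal(discrepancy(sc$image, sc$gt), 0)
  # identity with fg_error + bg_error for binary segmentations
  set.seed(8)
  for (i in 1:5) {
    im <- matrix(runif(64), 8, 8)
    sg <- random_mask(c(8, 8))
    re <- region_errors(im, sg)
    expect_equal(discrepancy(im, sg), re$fg_error + re$bg_error)
  }
})

test_that("Hausdorff distance measures boundary displacement", {
  a <- matrix(0, 8, 8); a[3:4, 3:4] <- 1
  expect_equal(hausdorff_distance(a, a), 0)
  b <- matrix(0, 8, 8); b[4:5, 3:4] <- 1   # unit shift
  expect_equal(hausdorff_distance(a, b), 1)
  expect_equal(hausdorff_distance(b, a), hausdorff_distance(a, b))
  expect_equal(hausdorff_distance(a, b, average = TRUE),
               hausdorff_distance(b, a, average = TRUE))
  expect_lte(hausdorff_distance(a, b, average = TRUE),
             hausdorff_distance(a, b))
  expect_error(hausdorff_distance(a, matrix(0, 8, 8)), "empty foreground")
})

test_that("dice identities hold on random mask pairs", {
  set.seed(9)
  for (i in 1:50) {
    s <- random_mask(c(8, 8)); g <- random_mask(c(8, 8))
    m <- supervised_metrics(s, g)
    expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard))
    if (m$precision + m$recall > 0)
      expect_equal(m$dice,
                   2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("the metric report bundles consistent scalars", {
  sc <- two_region_scene(seed = 3, shape = c(24L, 24L))
  seeds <- generate_vertical_seeds(sc$gt)
  r <- growcut(sc$image, seeds, seed = 3)
  rep <- metric_report(r$labels == 2, sc$gt, image = sc$image)
  expect_equal(rep$voi, rep$ose + rep$use)
  expect_true(rep$dice >= 0 && rep$dice <= 1)
  expect_equal(rep$discrepancy, rep$fg_error + rep$bg_error)
  agg <- aggregate_metrics(
    transform(rbind(rep, rep), algorithm = c("a", "b")))
  expect_true(all(c("metric", "median", "q1", "q3") %in% names(agg)))
  expect_equal(agg$median[agg$algorithm == "a" & agg$metric == "dice"],
               rep$dice)
})
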