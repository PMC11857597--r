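test_that("gaussian blur preserves constants, mass, and the impulse kernel", {
  p <- detection_params()
  const <- image_frame(matrix(37, 32, 32))
  expect_equal(unclass(gaussian_blur(const, p)), matrix(37, 32, 32),
               ignore_attr = TRUE)

  # unit impulse reproduces the analytic normalized kernel
  f <- matrix(0, 31, 31); f[16, 16] <- 1
  blurred <- gaussian_blur(image_frame(f), p)
  expect_equal(unclass(blurred[12:20, 12:20]),
               gaussian_kernel(9, p$blur_sigma), tolerance = 1e-12,
               ignore_attr = TRUE)

  # reflective borders conserve total mass
  set.seed(301)
  for (i in 1:5) {
    g <- matrix(runif(40 * 55, 0, 255), 40, 55)
    expect_equal(sum(gaussian_blur(image_frame(g), p)), sum(g),
                 tolerance = 1e-6)
  }
  expect_error(gaussian_blur(const, kernel = 8), "odd")
  expect_error(gaussian_blur(image_frame(matrix(1, 4, 4)), p), "fit")
})

test_that("blur bounds the range and shrinks variance", {
  set.seed(302)
  for (i in 1:10) {
    g <- matrix(runif(48 * 48, 0, 255), 48, 48)
    b <- gaussian_blur(image_frame(g))
    expect_lte(max(b), max(g) + 1e-9)
    expect_gte(min(b), min(g) - 1e-9)
    expect_lt(stats::var(as.vector(b)), stats::var(as.vector(g)))
  }
})

test_that("threshold_mask resolves each mode correctly", {
  f <- matrix(0, 20, 20)
  f[5:8, 5:8] <- 200
  m <- threshold_mask(image_frame(f),
                      detection_params(threshold_mode = "absolute",
                                       threshold_value = 100))
  expect_equal(sum(m), 16)
  expect_true(all(which(m) %in% which(f == 200)))

  # constant frame: sd = 0, mean + k sd keeps everything at >= mean;
  # a strictly positive k over a constant frame cannot separate anything,
  # but the mask is >= threshold = mean, so it is full, not empty, unless
  # values are below; the spot-free case of interest is noise-only:
  const <- image_frame(matrix(50, 10, 10))
  mk <- threshold_mask(const, detection_params(threshold_value = 3))
  expect_equal(attr(mk, "threshold"), 50)

  expect_error(detection_params(threshold_mode = "percentile",
                                threshold_value = 0), "percentile")
  expect_error(detection_params(threshold_mode = "percentile",
                                threshold_value = 100), "percentile")

  sc <- render_synthetic_array(make_scene(seed = 9, noise_sigma = 3))
  fr <- extract_red_channel(sc$image)
  bl <- gaussian_blur(fr)
  mp <- threshold_mask(bl, detection_params(threshold_mode = "percentile",
                                            threshold_value = 99.5))
  thr <- attr(mp, "threshold")
  # footprint pixels whose blurred value clears the threshold are kept
  hot <- unclass(bl) >= thr
  expect_gte(sum(mp & hot) / sum(hot), 0.9)
})

test_that("connected components match the flood-fill oracle (both connectivities)", {
  set.seed(303)
  for (i in 1:100) {
    mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
    conn <- if (i %% 2 == 0) 4L else 8L
    expect_true(same_labeling(label_components(mask, conn),
                              oracle_label(mask, conn)))
  }
})

test_that("find_contours reports geometry of simple shapes exactly", {
  p <- detection_params()
  f <- image_frame(matrix(10, 60, 60))
  empty <- find_contours(matrix(FALSE, 60, 60), f, p)
  expect_equal(nrow(empty), 0)

  # 10x10 filled square with top-left pixel (x=20, y=40)
  mask <- matrix(FALSE, 60, 60)
  mask[41:50, 21:30] <- TRUE
  fr <- matrix(0, 60, 60); fr[41:50, 21:30] <- 120
  ct <- find_contours(mask, image_frame(fr), p)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$area, 100)
  expect_equal(ct$x, 24.5)
  expect_equal(ct$y, 44.5)
  expect_equal(ct$mean_intensity, 120)
  expect_gt(ct$circularity, 0.9)  # squares pass the "circular" gate

  # two discs separated by background
  mk2 <- matrix(FALSE, 64, 64)
  xs <- matrix(0:63, 64, 64, byrow = TRUE); ys <- matrix(0:63, 64, 64)
  mk2[(xs - 15)^2 + (ys - 20)^2 <= 36] <- TRUE
  mk2[(xs - 45)^2 + (ys - 40)^2 <= 36] <- TRUE
  ct2 <- find_contours(mk2, image_frame(matrix(1, 64, 64)), p)
  expect_equal(nrow(ct2), 2)
  centres <- ct2[order(ct2$x), c("x", "y")]
  expect_lt(max(abs(centres$x - c(15, 45))), 0.5)
  expect_lt(max(abs(centres$y - c(20, 40))), 0.5)
  expect_true(all(abs(ct2$circularity - 1) < 0.15))

  expect_error(find_contours(matrix(TRUE, 3, 3), image_frame(matrix(1, 4, 4))),
               "dimensions differ")
})

test_that("centroids always lie inside the component bounding box", {
  set.seed(304)
  for (i in 1:20) {
    mask <- matrix(runif(32 * 32) < 0.3, 32, 32)
    ct <- find_contours(mask, image_frame(matrix(1, 32, 32)))
    px <- attr(ct, "pixels")
    for (j in seq_len(nrow(ct))) {
      rows <- ((px[[j]] - 1) %% 32)
      cols <- ((px[[j]] - 1) %/% 32)
      expect_gte(ct$x[j], min(cols)); expect_lte(ct$x[j], max(cols))
      expect_gte(ct$y[j], min(rows)); expect_lte(ct$y[j], max(rows))
      expect_gt(ct$circularity[j], 0)
      expect_lte(ct$circularity[j], 1)
    }
  }
})

test_that("area gate is inclusive at 100 px and circularity gates shape", {
  p <- detection_params()  # min_area 100, min_circularity 0.6
  sq99 <- data.frame(id = 1, x = 0, y = 0, area = 99, perimeter = 40,
                     circularity = 0.9, mean_intensity = 1)
  sq100 <- transform(sq99, area = 100)
  bar <- data.frame(id = 2, x = 0, y = 0, area = 150, perimeter = 62,
                    circularity = 0.29, mean_intensity = 1)
  expect_equal(nrow(filter_contours(sq99, p)), 0)
  expect_equal(nrow(filter_contours(sq100, p)), 1)
  expect_equal(nrow(filter_contours(bar, p)), 0)
  expect_equal(nrow(filter_contours(sq99[0, ], p)), 0)

  # filtering is a subset-preserving idempotent operation
  mixed <- rbind(sq99, sq100, bar)
  once <- filter_contours(mixed, p)
  expect_true(all(once$id %in% mixed$id))
  expect_equal(filter_contours(once, p), once)
})

test_that("dust artifacts below the area cut are rejected on rendered scenes", {
  lay <- default_layout()
  art <- data.frame(x = c(100, 500, 900), y = c(80, 600, 300),
                    radius = c(3, 4, 3), amplitude = c(60, 50, 70))
  cfg <- scene_config(layout = lay, noise_sigma = 5, seed = 21,
                      artifacts = art)
  sc <- render_synthetic_array(cfg)
  fr <- extract_red_channel(sc$image)
  p <- detection_params()
  ct <- filter_contours(find_contours(threshold_mask(gaussian_blur(fr, p), p),
                                      fr, p), p)
  expect_equal(nrow(ct), 22)   # 22 true spots survive, 3 dust specks do not
  # every survivor matches a ground-truth spot centre
  d <- vapply(seq_len(nrow(ct)), function(i)
    min(sqrt((ct$x[i] - sc$truth$x)^2 + (ct$y[i] - sc$truth$y)^2)),
    numeric(1))
  expect_lt(max(d), 2)
})

test_that("noiseless detection recovers centroids to sub-pixel accuracy", {
  sc <- render_synthetic_array(make_scene(seed = 31, noise_sigma = 0))
  fr <- extract_red_channel(sc$image)
  p <- detection_params()
  ct <- filter_contours(find_contours(threshold_mask(gaussian_blur(fr, p), p),
                                      fr, p), p)
  expect_equal(nrow(ct), 22)
  d <- vapply(seq_len(nrow(sc$truth)), function(i)
    min(sqrt((sc$truth$x[i] - ct$x)^2 + (sc$truth$y[i] - ct$y)^2)),
    numeric(1))
  expect_lt(max(d), 0.5)
})
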