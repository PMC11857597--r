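# Helper: contours exactly at the scaled layout positions of the
# positive controls, plus optional distractors.
ideal_contours <- function(layout, frame_dim, shift = c(0, 0), scale = 1) {
  sp <- layout$spots[layout$spots$role == "control_positive", ]
  sx <- frame_dim[2] / layout$ref_width
  sy <- frame_dim[1] / layout$ref_height
  data.frame(id = seq_len(nrow(sp)),
             x = sp$x * sx * scale + shift[1],
             y = sp$y * sy * scale + shift[2],
             area = 300, perimeter = 62, circularity = 0.9,
             mean_intensity = 100)
}

test_that("identity and rigid-shift control fits are exact", {
  lay <- default_layout()
  dim_ <- c(768L, 1024L)
  g <- identify_controls(ideal_contours(lay, dim_), lay, dim_)
  expect_equal(g$residual, 0, tolerance = 1e-9)
  expect_equal(g$scale, 1, tolerance = 1e-9)
  expect_equal(unname(g$translation), c(0, 0), tolerance = 1e-9)

  g2 <- identify_controls(ideal_contours(lay, dim_, shift = c(30, -12)),
                          lay, dim_)
  expect_equal(unname(g2$translation), c(30, -12), tolerance = 1e-9)
  expect_equal(g2$residual, 0, tolerance = 1e-9)
  expect_equal(g2$scale, 1, tolerance = 1e-9)

  # pure scale change is absorbed by the similarity fit
  g3 <- identify_controls(ideal_contours(lay, dim_, scale = 1.05),
                          lay, dim_)
  expect_equal(g3$scale, 1.05, tolerance = 1e-9)
  expect_equal(g3$residual, 0, tolerance = 1e-6)
})

test_that("control identification fails loudly when it should", {
  lay <- default_layout()
  dim_ <- c(768L, 1024L)
  few <- ideal_contours(lay, dim_)[1:3, ]
  expect_error(identify_controls(few, lay, dim_),
               "detection failure.*3 contour")
  # scrambled positions cannot be aligned within tolerance
  bad <- ideal_contours(lay, dim_)
  bad$x <- rev(bad$x) + c(40, -35, 60, -80, 25)
  expect_error(identify_controls(bad, lay, dim_), "alignment failure")
})

test_that("control assignment is optimal and permutation-stable", {
  lay <- default_layout()
  dim_ <- c(768L, 1024L)
  ct <- ideal_contours(lay, dim_, shift = c(10, 5))
  # add distractor contours near (but not at) control positions
  distract <- data.frame(id = 100:102, x = ct$x[1:3] + 25,
                         y = ct$y[1:3] + 20, area = 200, perimeter = 50,
                         circularity = 0.8, mean_intensity = 50)
  full <- rbind(ct, distract)
  ref <- identify_controls(full, lay, dim_)
  set.seed(42)
  for (i in 1:10) {
    perm <- full[sample(nrow(full)), ]
    perm$id <- perm$id  # ids travel with rows
    g <- identify_controls(perm, lay, dim_)
    expect_equal(g$assignments[order(g$assignments$label), ],
                 ref$assignments[order(ref$assignments$label), ],
                 ignore_attr = TRUE)
  }
})

test_that("noisy scenes still assign all positive controls to ground truth", {
  for (seed in c(101, 102, 103)) {
    sc <- render_synthetic_array(make_scene(seed = seed, noise_sigma = 5))
    fr <- extract_red_channel(sc$image)
    p <- detection_params()
    ct <- filter_contours(find_contours(threshold_mask(gaussian_blur(fr, p), p),
                                        fr, p), p)
    g <- identify_controls(ct, default_layout(), dim(fr), p)
    truth <- sc$truth
    for (i in seq_len(nrow(g$assignments))) {
      t_row <- truth[truth$label == g$assignments$label[i], ]
      d <- sqrt((g$assignments$x[i] - t_row$x)^2 +
                (g$assignments$y[i] - t_row$y)^2)
      expect_lt(d, 2)
    }
  }
})

test_that("test-spot ROIs honour the bounded search rule", {
  lay <- default_layout()
  dim_ <- c(768L, 1024L)
  g <- identify_controls(ideal_contours(lay, dim_), lay, dim_)
  rois <- locate_test_spots(g, lay)
  expect_equal(nrow(rois), 15)
  expect_false(any(rois$missing))
  sx <- dim_[2] / lay$ref_width; sy <- dim_[1] / lay$ref_height
  tests <- lay$spots[lay$spots$role == "test", ]
  expect_equal(rois$x, tests$x * sx, tolerance = 1e-9)
  expect_equal(rois$y, tests$y * sy, tolerance = 1e-9)
  expect_true(all(rois$half >= 4))

  # push one spot 1 px beyond the C4-C7 bounding box: flagged missing
  lay2 <- lay
  c7 <- lay2$spots$label == "C7"
  i <- which(lay2$spots$label == "TNFRSF1B-r3")
  lay2$spots$y[i] <- lay2$spots$y[c7] + 1 / (dim_[1] / lay2$ref_height) + 4
  g2 <- identify_controls(ideal_contours(lay2, dim_), lay2, dim_)
  rois2 <- locate_test_spots(g2, lay2)
  expect_true(rois2$missing[rois2$label == "TNFRSF1B-r3"])
  expect_equal(sum(rois2$missing), 1)

  # spots beyond the lateral search range are rejected too
  lay3 <- lay
  lay3$search_range <- 100   # ~25 px at rendered scale: rows 3-4 excluded
  g3 <- identify_controls(ideal_contours(lay3, dim_), lay3, dim_)
  rois3 <- locate_test_spots(g3, lay3)
  expect_true(all(rois3$missing[lay$spots$replicate[match(rois3$label,
    lay$spots$label)] >= 2]))
})

test_that("quantify_spot measures net intensity against a local annulus", {
  # flat frame + one rendered Gaussian spot, noiseless
  lay <- default_layout()
  cfg <- scene_config(layout = lay, noise_sigma = 0,
                      background_level = 10, seed = 1)
  sc <- render_synthetic_array(cfg)
  fr <- extract_red_channel(sc$image)
  t1 <- sc$truth[sc$truth$label == "C2", ]
  roi <- list(x = t1$x, y = t1$y, half = 12L)
  q <- quantify_spot(fr, roi)
  expect_equal(q$background, 10, tolerance = 0.5)
  expect_equal(q$net, t1$true_mean, tolerance = 0.05 * t1$true_mean)

  # all-constant frame: net exactly 0, snr 0
  flat <- image_frame(matrix(42, 100, 100))
  q0 <- quantify_spot(flat, list(x = 50, y = 50, half = 10L))
  expect_equal(q0$net, 0)
  expect_equal(q0$snr, 0)

  # saturated spot is flagged
  amps <- default_amplitudes(lay)
  amps["C2"] <- 250
  cfg_s <- scene_config(layout = lay, amplitudes = amps, noise_sigma = 0,
                        background_level = 20, seed = 1,
                        allow_saturation = TRUE)
  sc_s <- render_synthetic_array(cfg_s)
  q_s <- quantify_spot(extract_red_channel(sc_s$image), roi)
  expect_true(q_s$saturated)

  expect_error(quantify_spot(flat, list(x = 500, y = 500, half = 5L)),
               "outside the frame")
})

test_that("net intensity is invariant to a constant background shift", {
  lay <- default_layout()
  base <- scene_config(layout = lay, noise_sigma = 4,
                       background_level = 20, seed = 5)
  up <- scene_config(layout = lay, noise_sigma = 4,
                     background_level = 40, seed = 5)
  m1 <- process_well(render_synthetic_array(base)$image, lay)
  m2 <- process_well(render_synthetic_array(up)$image, lay)
  on_spots <- m1$net > 20
  expect_lt(max(abs(m2$net[on_spots] - m1$net[on_spots]) /
                m1$net[on_spots]), 0.02)
})

test_that("process_well measures all 22 spots on a clean scene", {
  sc <- render_synthetic_array(make_scene(seed = 3, noise_sigma = 0))
  m <- process_well(sc$image, well_id = "w0")
  expect_equal(nrow(m), 22)
  expect_false(any(m$missing | m$saturated | m$low_snr))
  expect_setequal(m$label, sc$truth$label)
  # triplicates un-aggregated: 3 rows per analyte
  expect_true(all(table(m$analyte[m$role == "test"]) == 3))
  m <- m[match(sc$truth$label, m$label), ]
  err <- sqrt((m$x - sc$truth$x)^2 + (m$y - sc$truth$y)^2)
  expect_lt(max(err), 0.5)
})

test_that("an absent analyte is reported as signal-free, not mislocated", {
  lay <- default_layout()
  amps <- default_amplitudes(lay)
  amps[c("OPN-r1", "OPN-r2", "OPN-r3")] <- 0
  cfg <- scene_config(layout = lay, amplitudes = amps, noise_sigma = 3,
                      seed = 13)
  m <- process_well(render_synthetic_array(cfg)$image, lay)
  opn <- m[m$analyte %in% "OPN", ]
  expect_true(all(opn$missing | abs(opn$net) < 5))
  others <- m[m$role == "test" & !(m$analyte %in% "OPN"), ]
  expect_true(all(others$net > 20))
})

test_that("noisy quantification stays within 10% of ground truth", {
  rel_errs <- c()
  for (seed in 201:205) {
    cfg <- make_scene(seed = seed, noise_sigma = 8)
    sc <- render_synthetic_array(cfg)
    m <- process_well(sc$image)
    m <- m[match(sc$truth$label, m$label), ]
    ok <- sc$truth$true_peak >= 80
    rel_errs <- c(rel_errs,
                  abs(m$net[ok] - sc$truth$true_mean[ok]) /
                    sc$truth$true_mean[ok])
  }
  expect_lt(max(rel_errs), 0.10)
})
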