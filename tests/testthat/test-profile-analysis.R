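test_that("green-channel extraction returns the G plane unchanged", {
  g <- matrix(c(0L, 10L, 255L, 20L), 2, 2)
  im <- rgb_image(matrix(0L, 2, 2), g, matrix(0L, 2, 2))
  expect_identical(extract_green_channel(im), g)
  # grayscale image: green plane equals any channel
  gray <- rgb_image(g, g, g)
  expect_identical(extract_green_channel(gray), g)
  # red-only image: all zeros
  red <- rgb_image(matrix(200L, 2, 2), matrix(0L, 2, 2), matrix(0L, 2, 2))
  expect_true(all(extract_green_channel(red) == 0L))
  expect_error(extract_green_channel(array(0L, c(2, 2, 4))), "3-channel")
  expect_error(extract_green_channel(rgb_image(g, g + 300L, g)), "8-bit")
})

test_that("sampled profiles are the exact mean of the drawn rows", {
  spec <- render_spec(noise_sd = 4, seed = 31L)
  im <- generate_array_image(spec, 24)
  p1 <- sample_profiles(im, mode = "line", seed = 7)
  p2 <- sample_profiles(im, mode = "line", seed = 7)
  expect_identical(p1$line_ids, p2$line_ids)
  expect_identical(p1$intensities, p2$intensities)
  g <- extract_green_channel(im)
  expect_equal(p1$intensities,
               colMeans(g[p1$line_ids, , drop = FALSE]))
  expect_length(p1$line_ids, 5)
  # MN mode samples tip-band centre rows, all within tip bands
  pm <- sample_profiles(im, mode = "MN", seed = 7)
  tips <- mnphotodose:::.row_bands(array_geometry(), im$um_per_px,
                                   nrow(g))$tip_rows
  expect_true(all(pm$line_ids %in% tips))
})

test_that("a noiseless constant render yields a flat profile at that constant", {
  spec <- quiet_spec(gap_law = constant_law(140), tip_law = constant_law(140),
                     tip_shadow_frac = 1)
  im <- generate_array_image(spec, 0)
  p <- sample_profiles(im, mode = "line", seed = 2)
  w <- p$positions_um >= 2000 & p$positions_um < 4000
  expect_true(all(p$intensities[w] == 140))
})

test_that("unresolvable projections error with the exclusion reason", {
  spec <- quiet_spec()
  im77 <- generate_array_image(spec, 77)
  expect_error(sample_profiles(im77, mode = "line"),
               class = "unresolvable_projection")
  expect_error(sample_profiles(im77, mode = "MN"),
               "unresolvable projection at 77 deg")
})

test_that("central window mean is the arithmetic mean over [lo, hi)", {
  spec <- quiet_spec(gap_law = constant_law(99), tip_shadow_frac = 1)
  im <- generate_array_image(spec, 0)
  p <- sample_profiles(im, mode = "line", seed = 1)
  expect_equal(central_window_mean(p)$mean_intensity, 99)
  # linear ramp: mean over the window is the midpoint value
  ramp <- structure(list(positions_um = seq(1000, 5000, by = 10),
                         intensities = seq(1000, 5000, by = 10) / 40,
                         label = "line", angle_deg = 0, line_ids = 1:5),
                    class = "intensity_profile")
  # positions 2000..3990 inside [2000, 4000): mean = midpoint of that range
  expect_equal(central_window_mean(ramp)$mean_intensity,
               mean(c(2000, 3990)) / 40)
  expect_error(central_window_mean(ramp, c(9000, 9500)),
               "does not overlap")
  expect_error(central_window_mean(ramp, c(4000, 2000)), "lo < hi")
})

test_that("isotropy index is the population CV of per-angle means", {
  s_flat <- data.frame(angle_deg = c(0, 24, 31), label = "MN",
                       mean_intensity = c(80, 80, 80))
  expect_equal(isotropy_index(s_flat, "MN"), 0)
  s_two <- data.frame(angle_deg = c(0, 57), label = "line",
                      mean_intensity = c(100, 0))
  expect_equal(isotropy_index(s_two, "line"), 1)
  expect_error(isotropy_index(s_two[1, ], "line"), "two angles")
  s_zero <- data.frame(angle_deg = c(0, 57), label = "line",
                       mean_intensity = c(0, 0))
  expect_error(isotropy_index(s_zero, "line"), "zero mean")
})

test_that("ground truth is recovered end-to-end across noise levels", {
  geom <- array_geometry()
  for (sd in c(0, 1, 3)) {
    spec <- render_spec(noise_sd = sd, seed = 41L)
    set <- render_angle_set(spec)
    summaries <- list()
    for (im in set$images) {
      if (!im$resolvable) next
      for (mode in c("line", "MN")) {
        p <- sample_profiles(im, geom, mode = mode, seed = 13)
        s <- central_window_mean(p)
        summaries[[length(summaries) + 1L]] <- s
        gt <- if (mode == "line") im$ground_truth$expected_line_mean
              else im$ground_truth$expected_mn_mean
        n <- s$n_positions * s$n_lines
        tol <- if (sd == 0) 1e-9 else 3 * sd / sqrt(n)
        expect_lt(abs(s$mean_intensity - gt), tol)
      }
    }
    sdf <- do.call(rbind, summaries)
    # transmitted light falls off with angle; tip light does not
    line_means <- sdf$mean_intensity[sdf$label == "line"]
    expect_true(all(diff(line_means) < 0))  # ordered 0 > 24 > 31 > 57
    expect_lt(isotropy_index(sdf, "MN"), isotropy_index(sdf, "line"))
    if (sd == 0) expect_lt(isotropy_index(sdf, "MN"), 1e-3)
  }
})

test_that("MN-label isotropy shrinks toward zero as noise vanishes", {
  iso <- vapply(c(3, 1, 0), function(sd) {
    spec <- render_spec(noise_sd = sd, seed = 51L)
    set <- render_angle_set(spec)
    summaries <- lapply(Filter(function(im) im$resolvable, set$images),
                        function(im)
                          central_window_mean(
                            sample_profiles(im, mode = "MN", seed = 3)))
    isotropy_index(do.call(rbind, summaries), "MN")
  }, numeric(1))
  expect_lt(iso[3], 1e-3)
  expect_true(all(iso < 0.01))
})
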