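test_that("point source follows the inverse-square law", {
  expect_equal(point_source_intensity(1, 1, 1), 1)
  expect_equal(point_source_intensity(2, 1, 2), 0.5)
  # doubling the distance quarters the intensity, whatever (I0, r0)
  set.seed(4)
  for (i in 1:20) {
    I0 <- runif(1, 0.1, 10); r0 <- runif(1, 0.1, 10); d <- runif(1, 0.1, 10)
    expect_equal(point_source_intensity(I0, r0, 2 * d),
                 point_source_intensity(I0, r0, d) / 4)
  }
  expect_error(point_source_intensity(1, 1, 0), "d must be > 0")
  expect_error(point_source_intensity(1, 0, 1), "r0 must be > 0")
})

test_that("annulus integrand matches direct substitution and vanishes at r = 0", {
  d <- unit_disk()
  expect_equal(annulus_integrand(1, 0, d), 0)
  expect_equal(annulus_integrand(1, 1, d), pi)  # 2*pi*1/(1+1)
  expect_error(annulus_integrand(0, 1, d), "rho must be > 0")
})

test_that("closed form matches its printed value and factorizes attenuation", {
  d <- unit_disk()
  expect_equal(disk_intensity(1, d), pi * log(2), tolerance = 1e-14)
  # attenuated result is exactly the unattenuated one times exp(-alpha*rho)
  da <- unit_disk(alpha = 0.7)
  rho <- c(0.2, 1, 3.5)
  expect_equal(disk_intensity(rho, da, attenuated = TRUE),
               disk_intensity(rho, da) * exp(-0.7 * rho))
  expect_error(disk_intensity(1e-9, d), "singularity guard")
})

test_that("closed form agrees with adaptive quadrature of the integrand", {
  for (alpha in c(0, 0.5)) {
    d <- emitter_disk(R = 2, sigma = 0.3, I0 = 1.7, r0 = 0.9, alpha = alpha)
    rho <- d$R * c(0.1, 0.5, 1, 2, 10)
    closed <- disk_intensity(rho, d, attenuated = alpha > 0)
    quad <- disk_intensity_quadrature(rho, d, attenuated = alpha > 0)
    expect_lt(max(abs(closed - quad) / closed), 1e-8)
  }
})

test_that("Monte-Carlo brute force converges to the closed form", {
  d <- unit_disk()
  mc <- disk_intensity_bruteforce(1, d, n_emitters = 1e5L, seed = 123)
  expect_lt(abs(mc$intensity - pi * log(2)), 3 * mc$se)
  # and the estimate is within 1% at this n
  expect_lt(abs(mc$intensity - pi * log(2)) / (pi * log(2)), 0.01)
  # determinism under seed
  mc2 <- disk_intensity_bruteforce(1, d, n_emitters = 1e5L, seed = 123)
  expect_identical(mc$intensity, mc2$intensity)
})

test_that("per-emitter path attenuation never exceeds the global factor", {
  # every emitter path d_i >= rho, so e^(-alpha*d_i) <= e^(-alpha*rho)
  for (alpha in c(0.2, 1, 3)) for (R in c(0.5, 1, 4)) {
    d <- emitter_disk(R = R, alpha = alpha)
    per <- disk_intensity_bruteforce(1, d, n_emitters = 2e4L, seed = 9,
                                     attenuated = TRUE,
                                     per_emitter_attenuation = TRUE)
    glob <- disk_intensity_bruteforce(1, d, n_emitters = 2e4L, seed = 9,
                                      attenuated = TRUE)
    expect_lte(per$intensity, glob$intensity)
  }
})

test_that("disk intensity is monotone and linear where it should be", {
  d <- unit_disk()
  rho <- seq(0.1, 5, length.out = 50)
  I <- disk_intensity(rho, d)
  expect_true(all(diff(I) < 0))  # strictly decreasing in rho
  # strictly increasing in R
  Rs <- seq(0.5, 4, length.out = 20)
  IR <- vapply(Rs, function(R) disk_intensity(1, emitter_disk(R = R)),
               numeric(1))
  expect_true(all(diff(IR) > 0))
  # linear in sigma and in I0 * r0^2
  expect_equal(disk_intensity(1, emitter_disk(R = 1, sigma = 3)),
               3 * disk_intensity(1, unit_disk()))
  expect_equal(disk_intensity(1, emitter_disk(R = 1, I0 = 2, r0 = 3)),
               18 * disk_intensity(1, unit_disk()))
})

test_that("small-source limit approaches a single point source", {
  # for R << rho, I -> sigma*pi*R^2 * I0 * (r0/rho)^2
  rel_err <- vapply(c(1e-1, 1e-2, 1e-3), function(Rr) {
    d <- emitter_disk(R = Rr)  # rho = 1
    approx <- d$sigma * pi * d$R^2 * d$I0 * (d$r0 / 1)^2
    abs(disk_intensity(1, d) - approx) / approx
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[2], 1e-4)
})

test_that("discrete array brute force reduces to and extends the disk model", {
  g1 <- array_geometry(n_rows = 1L, n_cols = 1L)
  expect_equal(array_intensity_bruteforce(c(0, 0, 500), g1, I0 = 2,
                                          r0 = 450, alpha = 0.001),
               2 * (450 / 500)^2 * exp(-0.001 * 500))
  geom <- array_geometry()
  # mirror-symmetric off-axis points see identical intensity
  expect_equal(array_intensity_bruteforce(c(700, -300, 900), geom),
               array_intensity_bruteforce(c(-700, 300, 900), geom))
  # far field: continuum disk with equivalent-area radius, sigma = 1/pitch^2
  extent <- 19 * 350
  z <- 20 * extent
  R_eq <- sqrt(19 * 19 * 350^2 / pi)
  disk <- emitter_disk(R = R_eq, sigma = 1 / 350^2)
  expect_equal(array_intensity_bruteforce(c(0, 0, z), geom),
               disk_intensity(z, disk), tolerance = 0.01)
  expect_error(array_intensity_bruteforce(c(0, 0, 0), g1), "guard distance")
})

test_that("directed beam obeys Beer-Lambert and its semigroup", {
  expect_equal(directed_intensity(0, I0 = 5, alpha = 2), 5)
  expect_equal(directed_intensity(c(1, 10, 100), I0 = 3, alpha = 0),
               rep(3, 3))
  # composition: I(z1 + z2) = I(z1) * exp(-alpha * z2)
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 0, 2); z1 <- runif(1, 0, 3); z2 <- runif(1, 0, 3)
    expect_equal(directed_intensity(z1 + z2, alpha = a),
                 directed_intensity(z1, alpha = a) * exp(-a * z2))
  }
  expect_error(directed_intensity(-1), "z must be >= 0")
  expect_error(directed_intensity(0, dispersion = TRUE), "divergent")
})

test_that("model comparison is normalized, sized, and guarded", {
  disk <- emitter_disk(R = 1, alpha = 0.5)
  depths <- seq(0.5, 3, length.out = 25)
  cm <- compare_models(disk, depths)
  expect_equal(nrow(cm$profiles), 2 * length(depths))
  first <- cm$profiles$intensity[cm$profiles$depth_um == depths[1]]
  expect_equal(first, c(1, 1))  # both profiles normalized at first depth
  expect_error(compare_models(disk, numeric(0)), "empty depth grid")
  expect_error(compare_models(disk, c(2, 1)), "strictly increasing")
})

test_that("the extended disk outlasts a dispersive directed beam at depth", {
  # normalized disk profile decays more slowly than inverse-square
  # dispersion + shared Beer-Lambert, across the whole regime sweep;
  # against a *pure* exponential the ordering reverses (extra log factor).
  for (Rr in c(0.1, 0.3, 1, 3, 10)) for (ar in c(0.1, 0.5, 1, 3)) {
    disk <- emitter_disk(R = Rr, alpha = ar)
    cm <- compare_models(disk, seq(1, 5, length.out = 20))
    expect_gt(cm$summary$relative_attenuation_difference, 0)
  }
  cm_exp <- compare_models(emitter_disk(R = 1, alpha = 1),
                           seq(0.5, 3, length.out = 20),
                           beam_dispersion = FALSE)
  expect_lt(cm_exp$summary$relative_attenuation_difference, 0)
})
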