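test_that("plane fits recover exact planes and agree with an SVD oracle", {
  pts <- cbind(runif(50, -5, 5), runif(50, -5, 5), 3)
  fit <- fit_plane(pts, orient = c(0, 0, 1))
  expect_equal(fit$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fit$offset, 3, tolerance = 1e-12)
  # four corners of the unit square at z = 0: zero residuals
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f2 <- fit_plane(sq)
  expect_equal(abs(f2$normal[3]), 1, tolerance = 1e-12)
  expect_equal(as.numeric(flatness_error(f2, sq)), 0, tolerance = 1e-12)
  # noisy tilted planes vs independent SVD fit
  set.seed(11)
  for (k in 1:5) {
    n0 <- rnorm(3); n0 <- n0 / sqrt(sum(n0^2))
    basis <- svd(diag(3) - tcrossprod(n0))$u[, 1:2]
    p <- t(replicate(200, as.numeric(basis %*% runif(2, -10, 10)))) +
      rnorm(200, sd = 0.05) %o% n0 + rep(1, 200) %o% (3 * n0)
    got <- fit_plane(p)$normal
    ctr <- colMeans(p)
    oracle <- svd(sweep(p, 2, ctr))$v[, 3]
    expect_equal(abs(sum(got * oracle)), 1, tolerance = 1e-9)
  }
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))), "collinear")
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 0, 0))), "3 points")
})

test_that("flatness is the sum of the extreme distances on either side", {
  # dense corrugated grid alternating z = +/- 0.1: best-fit plane is the
  # mid-plane, so flatness = 0.2
  g <- expand.grid(x = 0:19, y = 0:19)
  z <- 0.1 * (-1)^(g$x + g$y)
  pts <- cbind(g$x, g$y, z)
  fit <- fit_plane(pts, orient = c(0, 0, 1))
  fl <- flatness_error(fit, pts)
  expect_equal(as.numeric(fl), 0.2, tolerance = 1e-9)
  expect_equal(attr(fl, "x_positive"), 0.1, tolerance = 1e-9)
  expect_equal(attr(fl, "x_negative"), 0.1, tolerance = 1e-9)
  # property: a least-squares plane always leaves points on both sides of
  # any non-planar set
  set.seed(21)
  for (k in 1:10) {
    p <- matrix(runif(60, -5, 5), ncol = 3)
    f <- fit_plane(p)
    flp <- flatness_error(f, p)
    expect_gt(attr(flp, "x_positive"), 0)
    expect_gt(attr(flp, "x_negative"), 0)
  }
})

test_that("parallelism and perpendicularity follow the angular definitions", {
  base_pts <- cbind(runif(40, -20, 20), runif(40, -20, 20), 0)
  base <- fit_plane(base_pts, orient = c(0, 0, 1), region = "base:upper")
  tilt <- function(deg) {
    R <- rotation_about_axis(c(1, 0, 0), deg)
    cbind(runif(40, -5, 5), runif(40, -5, 5), 6) %*% t(R)
  }
  occl <- fit_plane(tilt(0.5), region = "UR-FM:occlusal")
  expect_equal(parallelism_error(occl, base), 0.5, tolerance = 1e-9)
  # anti-parallel normals still give an acute angle of 0
  flipped <- occl; flipped$normal <- -occl$normal
  expect_equal(parallelism_error(flipped, base), 0.5, tolerance = 1e-9)
  same <- fit_plane(tilt(0), region = "UL-C:occlusal")
  expect_equal(parallelism_error(same, base), 0, tolerance = 1e-9)

  vert_pts <- function(deg) {
    R <- rotation_about_axis(c(0, 1, 0), deg)
    cbind(0, runif(40, -5, 5), runif(40, 0, 8)) %*% t(R)
  }
  vert <- fit_plane(vert_pts(0), region = "UR-FM:buccal")
  expect_equal(perpendicularity_error(vert, base), 0, tolerance = 1e-9)
  tilted <- fit_plane(vert_pts(0.8), region = "UR-FM:buccal")
  expect_equal(perpendicularity_error(tilted, base), 0.8, tolerance = 1e-9)
  horiz_as_vert <- fit_plane(tilt(0), region = "UR-FM:lingual")
  expect_equal(perpendicularity_error(horiz_as_vert, base), 90, tolerance = 1e-9)
  # class checks
  expect_error(parallelism_error(vert, base), "horizontal")
  expect_error(perpendicularity_error(occl, base), "vertical")
  expect_error(parallelism_error(occl, occl), "base plane")
  # both angle metrics derive from the same acute angle
  as_vertical <- occl
  as_vertical$orientation_class <- "vertical"
  expect_equal(parallelism_error(occl, base),
               90 - perpendicularity_error(as_vertical, base), tolerance = 1e-9)
})

test_that("per-jaw form summaries count 42 flatness, 14 parallelism, 28 perpendicularity", {
  mesh <- ref_mesh("maxillary")
  fm <- form_metrics(mesh, density = 2)
  expect_equal(nrow(fm), 43)  # 42 SDC planes + base plane
  s <- summarize_form_metrics(fm)
  expect_equal(s$flatness$n, 42)
  expect_equal(s$flatness_horizontal$n, 14)
  expect_equal(s$flatness_vertical$n, 28)
  expect_equal(s$parallelism$n, 14)
  expect_equal(s$perpendicularity$n, 28)
  # a perfect reference model scores 0 +/- 0 everywhere
  expect_equal(s$flatness$mean, 0, tolerance = 1e-9)
  expect_equal(s$parallelism$mean, 0, tolerance = 1e-9)
  expect_equal(s$parallelism$sd, 0, tolerance = 1e-9)
  expect_equal(s$perpendicularity$mean, 0, tolerance = 1e-9)
  expect_error(form_metrics(truedent:::labeled_mesh(mesh$vertices, mesh$faces,
                                                    mesh$regions["base:upper"]),
                            reference = mesh),
               "missing region")
})

test_that("summary means and SDs match direct arithmetic on known values", {
  mesh <- ref_mesh("maxillary")
  fm <- form_metrics(mesh, density = 2)
  vals <- c(0.10, 0.25, 0.07)
  fm$flatness[fm$region %in% c("UR-FM:occlusal", "UR-FM:buccal", "UR-FM:lingual")] <- vals
  s <- summarize_form_metrics(fm)
  nonzero <- vals
  expect_equal(s$flatness$mean, sum(nonzero) / 42, tolerance = 1e-12)
  expect_equal(s$flatness$sd, sd(c(nonzero, rep(0, 39))), tolerance = 1e-12)
})

test_that("form metrics are invariant under rigid motion of the whole model", {
  mesh <- ref_mesh("mandibular")
  warped <- apply_deformation(mesh, deformation_params(warp_k = 2e-5))
  fm0 <- summarize_form_metrics(form_metrics(warped, mesh, density = 2))
  moved <- transform_mesh(warped, rigid_transform(rotation_about_axis(c(1, 2, 3), 20),
                                                  c(4, 5, -6)))
  # flatness and the angle metrics only relate planes to each other, so
  # measuring the moved mesh in its own frame must give the same numbers
  fm1 <- summarize_form_metrics(form_metrics(moved, moved, density = 2))
  expect_equal(fm1$flatness$mean, fm0$flatness$mean, tolerance = 1e-9)
  expect_equal(fm1$parallelism$mean, fm0$parallelism$mean, tolerance = 1e-9)
  expect_equal(fm1$perpendicularity$mean, fm0$perpendicularity$mean, tolerance = 1e-9)
})
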