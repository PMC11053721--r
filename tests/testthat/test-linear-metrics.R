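test_that("the virtual caliper reproduces every designed feature size exactly", {
  schema <- ref_schema()
  for (jaw in c("maxillary", "mandibular")) {
    meas <- measure_features(ref_mesh(jaw), schema, jaw)
    expect_equal(nrow(meas), 48)
    expect_lt(max(abs(meas$measured - meas$designed)), 1e-9)
    expect_lt(max(abs(meas$relative_error)), 1e-9)
  }
})

test_that("caliper spans follow closed-form scaling laws", {
  mesh <- ref_mesh("maxillary")
  schema <- ref_schema()
  ctr <- colMeans(mesh$vertices)
  # uniform in-plane scale: every occlusal-plane feature scales by s
  s <- 1.01
  scaled <- mesh
  scaled$vertices <- sweep(mesh$vertices, 2, ctr)
  scaled$vertices[, 1:2] <- scaled$vertices[, 1:2] * s
  scaled$vertices <- sweep(scaled$vertices, 2, -ctr)
  meas <- measure_features(scaled, schema, "maxillary")
  occ <- meas$axis_class == "occlusal-plane"
  expect_equal(meas$measured[occ], meas$designed[occ] * s, tolerance = 1e-12)
  expect_equal(meas$measured[!occ], meas$designed[!occ], tolerance = 1e-12)
  expect_equal(meas$relative_error[occ], rep((s - 1) * 100, 34), tolerance = 1e-9)
})

test_that("caliper errors surface as failures, not silent numbers", {
  mesh <- ref_mesh("maxillary")
  expect_error(virtual_caliper(mesh, list(id = "x", region_a = "nope",
                                          region_b = "base:upper",
                                          ux = 0, uy = 0, uz = 1)),
               "unknown region")
  # overlapping regions along the axis: negative span is flagged
  feat <- list(id = "bad", region_a = "UR-FM:mesial", region_b = "UR-FM:distal",
               ux = unname(sdc_placements(default_spec("maxillary"))$ux[6]),
               uy = unname(sdc_placements(default_spec("maxillary"))$uy[6]), uz = 0)
  expect_warning(v <- virtual_caliper(mesh, feat), "measurement failure")
  expect_lt(v, 0)
})

test_that("relative error follows the percent formula with sign semantics", {
  expect_equal(relative_error(10, 10.002), 0.02, tolerance = 1e-12)
  expect_equal(relative_error(10, 10), 0)
  expect_equal(relative_error(8, 7.92), -1, tolerance = 1e-12)
  # antisymmetric around the designed value
  expect_equal(relative_error(7, 7 + 0.3), -relative_error(7, 7 - 0.3),
               tolerance = 1e-12)
  expect_error(relative_error(0, 1), "> 0")
  expect_error(relative_error(-2, 1), "> 0")
})

test_that("per-jaw linear summaries aggregate 34 + 14 relative errors", {
  schema <- ref_schema()
  meas <- measure_features(ref_mesh("maxillary"), schema, "maxillary")
  s <- summarize_linear(meas, "maxillary")
  expect_equal(s$occlusal_plane$n, 34)
  expect_equal(s$occlusogingival$n, 14)
  expect_equal(s$occlusal_plane$mean, 0, tolerance = 1e-9)
  expect_equal(s$occlusal_plane$sd, 0, tolerance = 1e-9)
  # all occlusal features at exactly +1 %
  forced <- meas
  forced$relative_error[forced$axis_class == "occlusal-plane"] <- 1
  s1 <- summarize_linear(forced, "maxillary")
  expect_equal(s1$occlusal_plane$mean, 1)
  expect_equal(s1$occlusal_plane$sd, 0)
  # three known values match direct arithmetic
  forced$relative_error[forced$axis_class == "occlusogingival"] <-
    c(0.2, -0.4, 0.9, rep(0, 11))
  s2 <- summarize_linear(forced, "maxillary")
  expect_equal(s2$occlusogingival$mean, mean(c(0.2, -0.4, 0.9, rep(0, 11))))
  expect_equal(s2$occlusogingival$sd, sd(c(0.2, -0.4, 0.9, rep(0, 11))))
  # incomplete sets are rejected with the missing ids named
  expect_error(summarize_linear(meas[meas$id != "MD-UR-FM", ], "maxillary"),
               "MD-UR-FM")
})

test_that("repeat averaging is the arithmetic mean", {
  expect_equal(average_repeats(rep(10, 5)), 10)
  expect_equal(average_repeats(c(9.98, 10.00, 10.02, 10.01, 9.99)), 10)
  expect_equal(average_repeats(42.3), 42.3)
  m <- rbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(average_repeats(m)), c(2, 5))
})

test_that("ICC matches the ANOVA mean-square oracle and known variance ratios", {
  # perfect agreement
  m <- matrix(rep(seq(5, 12, length.out = 10), 3), ncol = 3)
  expect_equal(icc(m), 1)
  # oracle: the same ICC(2,1) computed from aov() mean squares
  icc_aov <- function(m) {
    df <- data.frame(y = as.vector(m),
                     row = factor(rep(seq_len(nrow(m)), ncol(m))),
                     col = factor(rep(seq_len(ncol(m)), each = nrow(m))))
    ms <- summary(stats::aov(y ~ row + col, df))[[1]][["Mean Sq"]]
    n <- nrow(m); k <- ncol(m)
    (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
  }
  set.seed(99)
  m2 <- matrix(rnorm(60, 10), ncol = 4) + rnorm(15, sd = 2)
  expect_equal(icc(m2), icc_aov(m2), tolerance = 1e-12)
  # independent noise with no feature variance: ICC ~ 0
  set.seed(7)
  noise <- matrix(rnorm(3000), ncol = 3)
  expect_lt(abs(icc(noise)), 0.05)
  # synthetic variance components: ICC -> sr^2 / (sr^2 + sc^2 + se^2)
  sr <- 1; sc <- 0.3; se <- 0.4
  set.seed(8)
  n <- 600; k <- 5
  msim <- outer(rnorm(n, sd = sr), rep(1, k)) +
    outer(rep(1, n), rnorm(k, sd = sc)) + matrix(rnorm(n * k, sd = se), n, k)
  expect_equal(icc(msim), sr^2 / (sr^2 + sc^2 + se^2), tolerance = 0.1)
  expect_error(icc(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(icc(matrix(1:3, ncol = 1)), "at least 2")
})
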