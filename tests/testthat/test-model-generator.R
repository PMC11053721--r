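test_that("default specs carry the published crown dimensions", {
  smax <- default_spec("maxillary")
  smand <- default_spec("mandibular")
  fm <- subset(smax$sdc, code == "FM")
  expect_equal(c(fm$md, fm$bl, fm$ch), c(10, 11, 8))
  expect_equal(subset(smand$sdc, code == "SM")$ch, 12)
  # the jaws differ in every central-incisor dimension (the lateral
  # incisors share their 6 mm buccolingual diameter across jaws)
  for (dim in c("md", "bl", "ch"))
    expect_true(smax$sdc[[dim]][smax$sdc$code == "CI"] !=
                smand$sdc[[dim]][smand$sdc$code == "CI"])
  expect_false(identical(smax$sdc, smand$sdc))
  expect_silent(validate_spec(smax))
})

test_that("spec validation rejects non-positive dimensions and bad jaws", {
  spec <- default_spec("maxillary")
  spec$sdc$ch[3] <- -1
  expect_error(validate_spec(spec), "positive")
  expect_error(build_model(spec), "positive")
  spec2 <- default_spec("mandibular")
  spec2$jaw <- "sideways"
  expect_error(validate_spec(spec2), "jaw")
})

test_that("built models are watertight, outward-oriented, labeled cuboids on the base", {
  for (jaw in c("maxillary", "mandibular")) {
    spec <- default_spec(jaw)
    mesh <- ref_mesh(jaw)
    expect_true(is_watertight(mesh))
    expect_gt(mesh_volume(mesh), 0)
    # 14 SDCs x 6 faces + 3 base regions, pairwise disjoint by construction
    expect_length(mesh$regions, 14 * 6 + 3)
    expect_false(anyDuplicated(unlist(mesh$regions)) > 0)
    pl <- sdc_placements(spec)
    expect_equal(nrow(pl), 14)
    thick <- spec$arch$base_thickness
    for (i in seq_len(nrow(pl))) {
      occ <- mesh$vertices[unique(as.vector(
        mesh$faces[mesh$regions[[paste0(pl$code[i], ":occlusal")]], ])), ]
      expect_equal(unique(occ[, 3]), thick + pl$ch[i], tolerance = 1e-12)
    }
    # base upper surface sits at z = thickness
    bu <- mesh$vertices[unique(as.vector(
      mesh$faces[mesh$regions[["base:upper"]], ])), ]
    expect_equal(unique(bu[, 3]), thick)
  }
})

test_that("occlusal faces point up, gingival faces down, buccal faces outward", {
  mesh <- ref_mesh("maxillary")
  for (rn in grep(":occlusal$", names(mesh$regions), value = TRUE))
    expect_equal(truedent:::region_normal(mesh, rn), c(0, 0, 1), tolerance = 1e-9)
  for (rn in grep(":gingival$", names(mesh$regions), value = TRUE))
    expect_equal(truedent:::region_normal(mesh, rn), c(0, 0, -1), tolerance = 1e-9)
  # buccal normals point away from the arch centroid
  ctr <- colMeans(mesh$vertices)
  pl <- sdc_placements(default_spec("maxillary"))
  for (i in seq_len(nrow(pl))) {
    n <- truedent:::region_normal(mesh, paste0(pl$code[i], ":buccal"))
    outward <- c(pl$cx[i], pl$cy[i], 0) - c(ctr[1], ctr[2], 0)
    expect_gt(sum(n[1:2] * outward[1:2]), 0)
  }
})

test_that("the model is bilaterally mirror-symmetric about the midsagittal plane", {
  for (jaw in c("maxillary", "mandibular")) {
    mesh <- ref_mesh(jaw)
    v <- mesh$vertices
    reflected <- cbind(-v[, 1], v[, 2], v[, 3])
    key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9), round(m[, 3], 9)))
    expect_identical(key(v), key(reflected))
    # left/right SDCs of the same tooth type have identical dimensions
    pl <- sdc_placements(default_spec(jaw))
    left <- pl[pl$side == "left", ]; right <- pl[pl$side == "right", ]
    expect_equal(left[order(left$tooth), c("md", "bl", "ch")],
                 right[order(right$tooth), c("md", "bl", "ch")],
                 ignore_attr = TRUE)
    expect_equal(left$cx[order(left$tooth)], -right$cx[order(right$tooth)])
  }
})

test_that("a single cuboid solid matches its hand-built counterpart", {
  s <- truedent:::cuboid_solid(c(2, 3), c(1, 0), c(0, 1), 4, 6, 5, 13)
  expect_equal(nrow(s$vertices), 8)
  expect_equal(nrow(s$faces), 12)
  expect_setequal(names(s$regions),
                  c("occlusal", "gingival", "mesial", "distal", "buccal", "lingual"))
  # hand-computed corner set of a 4 x 6 x 8 cuboid centered at (2, 3)
  expected <- as.matrix(expand.grid(x = c(0, 4), y = c(0, 6), z = c(5, 13)))
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(s$vertices), key(expected))
  occ <- s$vertices[unique(as.vector(s$faces[s$regions$occlusal, ])), ]
  expect_true(all(occ[, 3] == 13))
})

test_that("overlapping SDC footprints raise a layout error", {
  spec <- default_spec("maxillary")
  pl <- sdc_placements(spec)
  pl$cx[2] <- pl$cx[1]; pl$cy[2] <- pl$cy[1]   # second SDC on top of the first
  spec$placements <- pl
  expect_error(build_model(spec), "overlap")
})

test_that("adjacent footprints keep the configured 2 mm clearance", {
  for (jaw in c("maxillary", "mandibular")) {
    spec <- default_spec(jaw)
    pl <- sdc_placements(spec)
    right <- pl[pl$side == "right", ]
    corners <- lapply(seq_len(nrow(right)), function(i)
      truedent:::footprint_corners(truedent:::arch_curve(spec$arch$curvature),
                                   right$s[i], right$md[i], right$bl[i]))
    for (i in seq_len(nrow(right) - 1)) {
      gap <- truedent:::rect_clearance(corners[[i]], corners[[i + 1]])
      expect_equal(gap, spec$arch$gap, tolerance = 1e-6)
    }
    # clearance across the midline equals the gap as well
    expect_equal(2 * min(corners[[1]][, 1]), spec$arch$gap, tolerance = 1e-6)
  }
})

test_that("export writes STL plus a sidecar that round-trips losslessly", {
  mesh <- ref_mesh("maxillary")
  stl <- tempfile(fileext = ".stl")
  paths <- export_model(mesh, stl)
  expect_true(all(file.exists(paths)))
  back <- read_model(paths[["stl"]], paths[["regions"]])
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  expect_equal(nrow(back$vertices), nrow(mesh$vertices))
  expect_identical(lapply(back$regions, as.integer),
                   lapply(mesh$regions, as.integer))
  empty <- truedent:::labeled_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_error(export_model(empty, tempfile()), "empty")
})
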