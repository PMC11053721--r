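# Arch-layout engine: places the 14 SDC footprints along a parabolic dental
# arch, arc-length parameterized, with an exact minimal clearance between
# adjacent footprints.  Everything here is deterministic.

# Dense arc-length parameterization of the right half-arch y = -a x^2, x >= 0.
# Returns interpolators s -> position / tangent / outward normal.
arch_curve <- function(a, x_max = 80, dx = 0.005) {
  x <- seq(0, x_max, by = dx)
  y <- -a * x^2
  dy <- -2 * a * x
  ds <- sqrt(1 + dy^2)
  s <- c(0, cumsum((ds[-1] + ds[-length(ds)]) / 2 * diff(x)))
  list(a = a, s_max = s[length(s)],
       x_of_s = stats::approxfun(s, x, rule = 2),
       s_of_x = stats::approxfun(x, s, rule = 2))
}

# Evaluate the curve at (signed) arc length s: position, unit tangent (u,
# the mesiodistal axis) in the direction of increasing |s| (away from the
# apex, i.e. pointing distally), and unit outward (buccal) normal.  Negative
# s mirrors to the left half (x < 0); the left frame is the exact mirror
# image of the right one about the midsagittal plane x = 0.
arch_point <- function(curve, s) {
  sgn <- ifelse(s < 0, -1, 1)
  x0 <- curve$x_of_s(abs(s))
  y <- -curve$a * x0^2
  t0x <- 1 / sqrt(1 + (2 * curve$a * x0)^2)
  t0y <- -2 * curve$a * x0 * t0x
  list(x = sgn * x0, y = y,
       tx = sgn * t0x, ty = t0y,
       nx = -sgn * t0y, ny = t0x)
}

# Footprint corners (4 x 2) of an SDC of size md x bl centered at arc s.
footprint_corners <- function(curve, s, md, bl) {
  p <- arch_point(curve, s)
  u <- c(p$tx, p$ty)            # mesiodistal axis (away from the midline)
  v <- c(p$nx, p$ny)            # buccolingual axis (outward)
  c0 <- c(p$x, p$y)
  rbind(c0 + md / 2 * u + bl / 2 * v,
        c0 + md / 2 * u - bl / 2 * v,
        c0 - md / 2 * u - bl / 2 * v,
        c0 - md / 2 * u + bl / 2 * v)
}

# Minimal Euclidean clearance between two convex quads (negative if they
# overlap, from the separating-axis penetration depth).
rect_clearance <- function(A, B) {
  axes <- rbind(A[2, ] - A[1, ], A[4, ] - A[1, ], B[2, ] - B[1, ], B[4, ] - B[1, ])
  axes <- axes / sqrt(rowSums(axes^2))
  sep <- -Inf
  for (i in seq_len(nrow(axes))) {
    pa <- A %*% axes[i, ]; pb <- B %*% axes[i, ]
    gap <- max(min(pb) - max(pa), min(pa) - max(pb))
    sep <- max(sep, gap)
  }
  if (sep < 0) return(sep)  # overlapping: SAT penetration is <= 0
  # disjoint: exact distance = min vertex-to-edge distance across both quads
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  d <- Inf
  for (i in 1:4) for (j in 1:4) {
    j2 <- if (j == 4) 1 else j + 1
    d <- min(d,
             seg_dist(A[i, ], B[j, ], B[j2, ]),
             seg_dist(B[i, ], A[j, ], A[j2, ]))
  }
  d
}

#' SDC placements along the dental arch
#'
#' Computes (or returns, if overridden in the spec) the placement of all 14
#' simulated dental crowns: footprint center on the occlusal (X-Y) plane,
#' mesiodistal and buccolingual axis directions, and arc position.  The right
#' half-arch is placed outward from the midline by bisection so that the
#' minimal clearance between adjacent footprints equals the configured gap
#' (and the clearance across the midsagittal plane equals the gap); the left
#' half is its exact mirror image, which guarantees bilateral symmetry and
#' non-overlap by construction.
#'
#' @param spec a `model_spec`.
#' @return data frame, one row per SDC: `code` (e.g. `"UR-FM"`), `side`,
#'   `tooth`, `md`, `bl`, `ch`, `s` (arc position mm), `cx`, `cy` (center,
#'   mm), `ux`, `uy` (unit mesiodistal axis, pointing distally i.e. away from
#'   the midline), `vx`, `vy` (unit buccolingual axis, pointing buccally i.e.
#'   outward).
#' @export
sdc_placements <- function(spec) {
  validate_spec(spec)
  if (!is.null(spec$placements)) return(spec$placements)
  curve <- arch_curve(spec$arch$curvature)
  gap <- spec$arch$gap
  sdc <- spec$sdc

  bisect <- function(f, lo, hi) {
    flo <- f(lo)
    if (flo > 0) stop("layout error: bracketing failed (footprints cannot abut)")
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  s <- numeric(7)
  prev <- NULL
  for (i in 1:7) {
    md <- sdc$md[i]; bl <- sdc$bl[i]
    if (i == 1) {
      # clearance gap/2 from the midsagittal plane x = 0 (mirror doubles it)
      f <- function(si) min(footprint_corners(curve, si, md, bl)[, 1]) - gap / 2
      s[i] <- bisect(f, md / 2, md / 2 + 30)
    } else {
      f <- function(si) rect_clearance(prev, footprint_corners(curve, si, md, bl)) - gap
      s[i] <- bisect(f, s[i - 1], s[i - 1] + (sdc$md[i - 1] + md) / 2 + 30)
    }
    prev <- footprint_corners(curve, s[i], md, bl)
  }

  pr <- side_prefixes(spec$jaw)
  build_half <- function(sign, prefix) {
    pts <- lapply(sign * s, function(si) arch_point(curve, si))
    data.frame(
      code = paste0(prefix, "-", sdc$code),
      side = if (sign > 0) "right" else "left",
      tooth = sdc$code,
      md = sdc$md, bl = sdc$bl, ch = sdc$ch,
      s = sign * s,
      cx = vapply(pts, `[[`, 0, "x"), cy = vapply(pts, `[[`, 0, "y"),
      ux = vapply(pts, `[[`, 0, "tx"), uy = vapply(pts, `[[`, 0, "ty"),
      vx = vapply(pts, `[[`, 0, "nx"), vy = vapply(pts, `[[`, 0, "ny"),
      stringsAsFactors = FALSE
    )
  }
  rbind(build_half(1, pr[["right"]]), build_half(-1, pr[["left"]]))
}

# Validate a placement table (also for user-supplied overrides): pairwise
# footprint clearance must be positive and dimensions valid.
validate_placements <- function(pl) {
  need <- c("code", "md", "bl", "ch", "cx", "cy", "ux", "uy", "vx", "vy")
  if (!all(need %in% names(pl))) stop("placements table is missing columns")
  if (any(pl$md <= 0 | pl$bl <= 0 | pl$ch <= 0))
    stop("all SDC dimensions must be strictly positive")
  corners <- lapply(seq_len(nrow(pl)), function(i) {
    u <- c(pl$ux[i], pl$uy[i]); v <- c(pl$vx[i], pl$vy[i]); c0 <- c(pl$cx[i], pl$cy[i])
    rbind(c0 + pl$md[i] / 2 * u + pl$bl[i] / 2 * v,
          c0 + pl$md[i] / 2 * u - pl$bl[i] / 2 * v,
          c0 - pl$md[i] / 2 * u - pl$bl[i] / 2 * v,
          c0 - pl$md[i] / 2 * u + pl$bl[i] / 2 * v)
  })
  n <- length(corners)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (rect_clearance(corners[[i]], corners[[j]]) <= 0)
      stop(sprintf("layout error: SDC footprints %s and %s overlap",
                   pl$code[i], pl$code[j]))
  }
  invisible(pl)
}
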