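#' Per-phytomer morphological descriptor set
#'
#' A phytomer's leaf is described by the midrib arc length and a small set of
#' heights and horizontal projections measured from the leaf collar: the
#' collar height (`HLBase`), the height of the highest midrib point
#' (`HLTop`), the tip height (`HLTip`), and the horizontal projections from
#' the collar to the highest point (`Ltop`) and to the tip (`Ltip`). The
#' derived rises `HDBTop = HLTop - HLBase` and `HDBTip = HLTip - HLBase`
#' (negative for tips drooping below the collar) fully constrain a planar
#' midrib curve.
#'
#' @param rank phytomer rank, integer >= 1 (1 = lowest leaf).
#' @param LL leaf (midrib) length, cm.
#' @param HLBase,HLTop,HLTip collar, highest-point and tip heights, cm.
#' @param Ltop,Ltip horizontal projections collar to highest point / tip, cm.
#' @param azimuth leaf plane compass direction, degrees clockwise from north.
#' @param max_width maximum blade width, cm.
#' @param inclination initial midrib elevation angle at the collar, degrees
#'   above horizontal. `NA` lets the midrib solver pick a heuristic tangent.
#' @param has_ear logical, whether this phytomer bears the ear.
#' @return An object of class `phytomer_spec` (a named list with the fields
#'   above plus derived `HDBTop` and `HDBTip`).
#' @examples
#' ps <- phytomer_spec(rank = 13, LL = 85, HLBase = 107, HLTop = 160,
#'                     HLTip = 130, Ltop = 45, Ltip = 65, azimuth = 90,
#'                     max_width = 10.5, inclination = 67, has_ear = TRUE)
#' ps$HDBTop
#' @export
phytomer_spec <- function(rank, LL, HLBase, HLTop, HLTip, Ltop, Ltip,
                          azimuth = 90, max_width = 10,
                          inclination = NA_real_, has_ear = FALSE) {
  spec <- list(rank = as.integer(rank), LL = LL, HLBase = HLBase,
               HLTop = HLTop, HLTip = HLTip, Ltop = Ltop, Ltip = Ltip,
               azimuth = azimuth %% 360, max_width = max_width,
               inclination = inclination, has_ear = isTRUE(has_ear))
  spec$HDBTop <- HLTop - HLBase
  spec$HDBTip <- HLTip - HLBase
  class(spec) <- "phytomer_spec"
  validate_phytomer_spec(spec)
  spec
}

validate_phytomer_spec <- function(spec) {
  with(spec, {
    if (rank < 1L) stop("rank must be >= 1")
    for (nm in c("LL", "Ltop", "Ltip", "max_width"))
      if (spec[[nm]] < 0) stop(sprintf("%s must be >= 0", nm))
    if (HDBTop < 0)
      stop("HDBTop violated: HLTop - HLBase >= 0 required, got ", HDBTop)
    if (Ltop > Ltip + 1e-9 * max(1, Ltip))
      stop("Ltop <= Ltip violated: Ltop = ", Ltop, ", Ltip = ", Ltip)
    chord_tip <- sqrt(Ltip^2 + HDBTip^2)
    if (chord_tip > LL * (1 + 1e-6))
      stop("chord <= arc violated: sqrt(Ltip^2 + HDBTip^2) = ",
           signif(chord_tip, 6), " > LL = ", LL)
    chord_top <- sqrt(Ltop^2 + HDBTop^2)
    if (chord_top > LL * (1 + 1e-6))
      stop("chord <= arc violated: sqrt(Ltop^2 + HDBTop^2) = ",
           signif(chord_top, 6), " > LL = ", LL)
  })
  invisible(spec)
}

#' Whole-plant specification
#'
#' @param cultivar cultivar label.
#' @param phytomers list of [phytomer_spec()] with contiguous ranks 1..N.
#' @param ear_rank rank of the ear-bearing phytomer.
#' @param plant_height plant height (to tassel tip), cm.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(cultivar, phytomers, ear_rank, plant_height) {
  ranks <- vapply(phytomers, function(p) p$rank, integer(1))
  if (!identical(ranks, seq_along(ranks)))
    stop("phytomer ranks must be contiguous 1..N")
  n <- length(ranks)
  if (ear_rank < 1L || ear_rank > n) stop("ear_rank outside 1..N")
  top <- max(vapply(phytomers, function(p) max(p$HLTop, p$HLTip), numeric(1)))
  if (top > plant_height * 1.02 + 1)
    stop("leaf heights exceed plant height: ", signif(top, 5), " > ",
         plant_height)
  structure(list(cultivar = cultivar, phytomers = phytomers,
                 ear_rank = as.integer(ear_rank),
                 plant_height = plant_height, n_phytomers = n),
            class = "plant_spec")
}

# Cubic Bezier in the (horizontal, vertical) leaf plane. Returns n x 2 matrix.
bezier_eval <- function(P, t) {
  b0 <- (1 - t)^3; b1 <- 3 * t * (1 - t)^2; b2 <- 3 * t^2 * (1 - t); b3 <- t^3
  cbind(b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1] + b3 * P[4, 1],
        b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2] + b3 * P[4, 2])
}

polyline_arclen <- function(xy) {
  sum(sqrt(rowSums(diff(xy)^2)))
}

# Weighted residuals of the five descriptor constraints, scaled by LL.
# The hard tier (arc length, max rise, end rise) carries weight sqrt(W);
# the horizontal projections (Ltop, Ltip) are the least-squares tier, so
# mutually infeasible descriptor sets resolve in favour of the hard tier.
midrib_residuals <- function(par, spec, t_dense, w_hard = 100) {
  P <- midrib_control_points(par, spec)
  xy <- bezier_eval(P, t_dense)
  arc <- polyline_arclen(xy)
  imax <- which.max(xy[, 2])
  n <- length(t_dense)
  c(w_hard * (arc - spec$LL),
    w_hard * (xy[imax, 2] - spec$HDBTop),
    w_hard * (xy[n, 2] - spec$HDBTip),
    xy[imax, 1] - spec$Ltop,
    xy[n, 1] - spec$Ltip) / spec$LL
}

# collar tangent angle: soft (a free parameter lightly pulled toward the
# spec's inclination) so the five geometric descriptors keep priority
midrib_incl_residual <- function(par, spec, weight = 0.03) {
  weight * (par[6] * 90 - midrib_inclination(spec)) / 90
}

midrib_inclination <- function(spec) {
  incl <- spec$inclination
  if (is.na(incl)) {
    # heuristic collar tangent: steeper than the chord to the highest point
    incl <- min(88, 180 / pi * atan2(spec$HDBTop, max(spec$Ltop, 1e-6)) + 12)
  }
  incl
}

midrib_control_points <- function(par, spec) {
  a <- par[6] * 90 * pi / 180          # collar tangent angle
  r1 <- exp(par[1]) * spec$LL          # collar control-arm length > 0
  rbind(c(0, 0),
        c(r1 * cos(a), r1 * sin(a)),
        c(par[2] * spec$LL, par[3] * spec$LL),
        c(par[4] * spec$LL, par[5] * spec$LL))
}

#' Build a 3D leaf midrib polyline from its descriptors
#'
#' Constructs a planar midrib curve (a cubic Bezier lying in the leaf's
#' vertical azimuth plane) whose end point sits exactly at the horizontal
#' projection `Ltip` and rise `HDBTip`, whose collar tangent follows the
#' spec's inclination angle, and whose remaining control parameters are
#' solved numerically so that the arc length matches `LL`, the maximum rise
#' matches `HDBTop`, and the horizontal distance of the highest point
#' matches `Ltop`. When the five descriptors are mutually over-determined
#' the solver satisfies `LL`/`HDBTop`/`HDBTip` most tightly and `Ltop`/`Ltip`
#' in a least-squares sense. A chord equal to the arc length forces a
#' straight segment.
#'
#' @param spec a [phytomer_spec()].
#' @param n_points number of polyline vertices (>= 8).
#' @return `n_points` x 3 matrix of coordinates (cm) in the leaf local frame:
#'   x horizontal along the leaf azimuth, y = 0, z vertical; first row is
#'   the collar at `(0, 0, HLBase)`.
#' @examples
#' ps <- phytomer_spec(1, LL = 60, HLBase = 0, HLTop = 30, HLTip = 0,
#'                     Ltop = 30, Ltip = 51.96)
#' m <- build_midrib(ps, 64)
#' sum(sqrt(rowSums(diff(m)^2)))  # ~= 60
#' @export
build_midrib <- function(spec, n_points = 48L) {
  stopifnot(inherits(spec, "phytomer_spec"))
  validate_phytomer_spec(spec)
  if (n_points < 8L) stop("n_points must be >= 8")
  chord <- sqrt(spec$Ltip^2 + spec$HDBTip^2)
  t_out <- seq(0, 1, length.out = n_points)
  if (chord >= spec$LL * (1 - 1e-6)) {
    # chord == arc: straight segment (e.g. a fully erect vertical midrib)
    xy <- cbind(t_out * spec$Ltip, t_out * spec$HDBTip)
    return(cbind(xy[, 1], 0, spec$HLBase + xy[, 2]))
  }
  t_dense <- seq(0, 1, length.out = 192L)
  fn <- function(par) c(midrib_residuals(par, spec, t_dense),
                        midrib_incl_residual(par, spec))
  obj <- function(par) sum(fn(par)^2)
  # multistart: collar-arm length fraction x (P2, P3) layouts around the
  # highest point and the tip
  L <- spec$LL
  incl0 <- midrib_inclination(spec) / 90
  tops <- rbind(c(spec$Ltop, 1.25 * spec$HDBTop),
                c(0.8 * spec$Ltop, 1.4 * spec$HDBTop),
                c(1.1 * spec$Ltop, 1.15 * spec$HDBTop))
  starts <- list()
  for (r1 in c(0.25, 0.45)) for (k in seq_len(nrow(tops))) {
    starts[[length(starts) + 1L]] <-
      c(log(r1), tops[k, 1] / L, tops[k, 2] / L,
        spec$Ltip / L, spec$HDBTip / L, incl0)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(s, fn = fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 80, ptol = 1e-11, ftol = 1e-11))),
      error = function(e) NULL)
    if (is.null(fit)) next
    val <- sum(fit$fvec^2)
    geo <- sum(fit$fvec[1:5]^2)     # geometric part, ignoring the soft
    if (is.null(best) || val < best$val)
      best <- list(par = fit$par, val = val, geo = geo)
    if (best$geo < 1e-10) break
  }
  if (is.null(best)) best <- list(par = starts[[1]], val = obj(starts[[1]]),
                                  geo = Inf)
  if (best$geo > 1e-10) {
    # polish with Nelder-Mead (robust to the which.max kink)
    pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-13))
    if (pol$value < best$val) best <- list(par = pol$par, val = pol$value)
  }
  # escalate on stubborn fits: longer LM run and NM from the incumbent
  # (soft-tier residuals above ~1.5% of LL trigger this)
  r <- midrib_residuals(best$par, spec, t_dense)
  if (max(abs(r[1:3])) > 0.35 || max(abs(r[4:5])) > 0.015) {
    for (s2 in list(best$par, best$par * c(1, 1.1, 1.05, 1, 1, 0.95))) {
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(s2, fn = fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 400, ptol = 1e-13, ftol = 1e-13))),
        error = function(e) NULL)
      if (!is.null(fit) && sum(fit$fvec^2) < best$val)
        best <- list(par = fit$par, val = sum(fit$fvec^2))
    }
    pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2500, reltol = 1e-14))
    if (pol$value < best$val) best <- list(par = pol$par, val = pol$value)
  }
  xy <- bezier_eval(midrib_control_points(best$par, spec), t_out)
  cbind(xy[, 1], 0, spec$HLBase + xy[, 2])
}

#' Extract midrib descriptors back from a built polyline
#'
#' Inverse of [build_midrib()] for round-trip checks: measures the arc
#' length, maximum rise, end rise, and the horizontal distances of the
#' highest point and the end point from the collar.
#'
#' @param polyline n x 3 matrix as returned by [build_midrib()].
#' @return named list: `LL`, `HDBTop`, `HDBTip`, `Ltop`, `Ltip`.
#' @export
midrib_descriptors <- function(polyline) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 3, nrow(polyline) >= 2)
  z0 <- polyline[1, 3]
  hor <- sqrt((polyline[, 1] - polyline[1, 1])^2 +
              (polyline[, 2] - polyline[1, 2])^2)
  imax <- which.max(polyline[, 3])
  n <- nrow(polyline)
  list(LL = polyline_arclen(polyline),
       HDBTop = polyline[imax, 3] - z0,
       HDBTip = polyline[n, 3] - z0,
       Ltop = hor[imax], Ltip = hor[n])
}

#' Blade width profile along the midrib
#'
#' Symmetric-tailed beta-shaped profile rising from zero at the collar to
#' the maximum width at `peak_frac` of the midrib length and tapering to
#' zero at the tip, normalised so the peak value is 1.
#'
#' @param s relative arc position in `[0, 1]`.
#' @param peak_frac position of maximum width (default 0.3).
#' @param shape sharpness exponent scale (default 2).
#' @export
width_profile <- function(s, peak_frac = 0.3, shape = 2) {
  a <- shape * peak_frac
  b <- shape * (1 - peak_frac)
  out <- (s / peak_frac)^a * ((1 - s) / (1 - peak_frac))^b
  out[s <= 0 | s >= 1] <- 0
  out
}

# integral of the width profile over s in [0, 1]
width_profile_integral <- function(peak_frac = 0.3, shape = 2) {
  stats::integrate(width_profile, 0, 1, peak_frac = peak_frac,
                   shape = shape)$value
}

#' Analytic one-sided blade area implied by the width profile
#'
#' @param LL midrib length, cm.
#' @param max_width maximum blade width, cm.
#' @inheritParams width_profile
#' @return area in cm^2.
#' @export
blade_area <- function(LL, max_width, peak_frac = 0.3, shape = 2) {
  LL * max_width * width_profile_integral(peak_frac, shape)
}

resample_polyline <- function(polyline, n) {
  seg <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(seg))
  tot <- s[length(s)]
  at <- seq(0, tot, length.out = n)
  cbind(stats::approx(s, polyline[, 1], xout = at)$y,
        stats::approx(s, polyline[, 2], xout = at)$y,
        stats::approx(s, polyline[, 3], xout = at)$y)
}

#' Triangulate a leaf blade around its midrib
#'
#' The blade is a ruled surface: at each midrib station the blade extends
#' `w/2` to each side along the horizontal direction perpendicular to the
#' leaf plane, where `w` follows [width_profile()] (or a constant for the
#' rectangular profile). Facet normals are unit length and oriented with a
#' non-negative vertical component.
#'
#' @param midrib n x 3 polyline from [build_midrib()].
#' @param max_width maximum blade width, cm.
#' @param n_segments longitudinal segments (quad rows; default 12).
#' @param n_width_strips transverse strips (default 2, one per side).
#' @param profile `"beta"` (default) or `"rectangular"`.
#' @param peak_frac peak position for the beta profile.
#' @return An object of class `leaf_mesh`: list with matrices `v1`, `v2`,
#'   `v3` (m x 3 triangle vertices, cm), `area` (cm^2), `normal` (m x 3).
#' @export
build_leaf_mesh <- function(midrib, max_width, n_segments = 12L,
                            n_width_strips = 2L,
                            profile = c("beta", "rectangular"),
                            peak_frac = 0.3) {
  profile <- match.arg(profile)
  if (!is.matrix(midrib) || nrow(midrib) < 2 ||
      polyline_arclen(midrib) <= 0)
    stop("degenerate midrib: need >= 2 distinct points")
  if (max_width <= 0) stop("max_width must be > 0")
  ring <- resample_polyline(midrib, n_segments + 1L)
  s <- seq(0, 1, length.out = n_segments + 1L)
  w <- if (profile == "beta") {
    pmax(max_width * width_profile(s, peak_frac), 1e-4 * max_width)
  } else rep(max_width, length(s))
  # lateral direction: horizontal, perpendicular to the dominant horizontal
  # midrib direction (leaf plane is vertical)
  dxy <- ring[nrow(ring), 1:2] - ring[1, 1:2]
  if (sqrt(sum(dxy^2)) < 1e-9) dxy <- c(1, 0)  # vertical midrib: pick x
  lat <- c(-dxy[2], dxy[1], 0) / sqrt(sum(dxy^2))
  # area-preserving tessellation: ring widths are rescaled so the summed
  # trapezoid strips (= the exact mesh area) equal the analytic blade area,
  # which removes the chord-vs-arc and profile-sampling deficits at any
  # segment count
  arclen <- polyline_arclen(midrib)
  chord <- sqrt(rowSums(diff(ring)^2))
  est <- sum((w[-1] + w[-length(w)]) / 2 * chord)
  target <- if (profile == "beta")
    blade_area(arclen, max_width, peak_frac) else arclen * max_width
  w <- w * target / est
  offs <- seq(-0.5, 0.5, length.out = n_width_strips + 1L)
  nv <- length(offs)
  verts <- lapply(seq_len(nrow(ring)), function(k) {
    outer(offs * w[k], lat) + matrix(ring[k, ], nv, 3, byrow = TRUE)
  })
  v1 <- v2 <- v3 <- matrix(0, 0, 3)
  for (k in seq_len(n_segments)) {
    A <- verts[[k]]; B <- verts[[k + 1L]]
    for (j in seq_len(n_width_strips)) {
      v1 <- rbind(v1, A[j, ], A[j + 1L, ])
      v2 <- rbind(v2, B[j, ], B[j + 1L, ])
      v3 <- rbind(v3, B[j + 1L, ], A[j, ])
    }
  }
  finish_mesh(v1, v2, v3)
}

# compute areas/oriented unit normals and wrap as leaf_mesh
finish_mesh <- function(v1, v2, v3) {
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm2 <- sqrt(rowSums(cr^2))
  area <- nrm2 / 2
  keep <- area > 1e-12
  cr <- cr[keep, , drop = FALSE] / nrm2[keep]
  flip <- cr[, 3] < 0 | (cr[, 3] == 0 & cr[, 2] < 0) |
    (cr[, 3] == 0 & cr[, 2] == 0 & cr[, 1] < 0)
  cr[flip, ] <- -cr[flip, , drop = FALSE]
  structure(list(v1 = v1[keep, , drop = FALSE],
                 v2 = v2[keep, , drop = FALSE],
                 v3 = v3[keep, , drop = FALSE],
                 area = area[keep], normal = cr),
            class = "leaf_mesh")
}

#' @export
print.leaf_mesh <- function(x, ...) {
  cat("leaf_mesh:", length(x$area), "facets, area",
      signif(sum(x$area), 5), "cm^2\n")
  invisible(x)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

transform_mesh <- function(mesh, azimuth_deg, origin) {
  # compass azimuth (clockwise from north = +y) -> math rotation about z
  R <- rot_z(-azimuth_deg)
  tr <- function(v) {
    out <- v %*% t(R)
    # local frame x points along azimuth; map local +x to compass direction
    sweep(out, 2, origin, "+")
  }
  m <- mesh
  m$v1 <- tr(mesh$v1); m$v2 <- tr(mesh$v2); m$v3 <- tr(mesh$v3)
  m$normal <- mesh$normal %*% t(R)
  m
}

# local frame has +x along azimuth 90 deg (east) before rotation; rotating by
# (90 - azimuth) compass degrees points the leaf at `azimuth`.
leaf_world_mesh <- function(mesh, azimuth_deg, origin) {
  transform_mesh(mesh, azimuth_deg - 90, origin)
}

#' Assemble a replicated canopy scene from plant specifications
#'
#' Places plant instances on a regular row grid (rows along the x axis,
#' row spacing along y), tessellates every leaf, assigns per-leaf compass
#' azimuths by the azimuth rule, and registers an opaque virtual wall around
#' the stand footprint at a fraction of the tallest plant's height. The
#' focal set is the interior central block of plants over which interception
#' records are collected.
#'
#' @param plants a `plant_spec` or list of them (recycled over the grid).
#' @param n_rows,n_cols grid dimensions (default 10 x 15 = 150 plants).
#' @param row_spacing_m distance between rows, m (default 0.6).
#' @param plant_density plants per m^2 (default 6); within-row spacing is
#'   `1 / (plant_density * row_spacing_m)`.
#' @param wall_fraction virtual wall height as a fraction of the maximum
#'   plant height (default 0.60).
#' @param azimuth_rule `"alternating"` (distichous +-90 deg off the row
#'   direction with uniform jitter; default) or `"spec"` (use each
#'   phytomer's recorded azimuth).
#' @param jitter_deg half-width of the uniform azimuth jitter, degrees.
#' @param focal_block edge length of the central focal block (default 3,
#'   i.e. 3 x 3 = 9 focal plants).
#' @param n_segments,n_width_strips tessellation passed to
#'   [build_leaf_mesh()].
#' @param seed integer seed controlling the azimuth jitter.
#' @return An object of class `canopy_scene`: triangle soup (`v1`, `v2`,
#'   `v3`, `area`, `normal`), facet ownership (`plant`, `rank`), plant
#'   positions, focal ids, footprint, wall height, `M` and `PD`.
#' @export
assemble_canopy <- function(plants, n_rows = 10L, n_cols = 15L,
                            row_spacing_m = 0.6, plant_density = 6,
                            wall_fraction = 0.6,
                            azimuth_rule = c("alternating", "spec"),
                            jitter_deg = 15, focal_block = 3L,
                            n_segments = 8L, n_width_strips = 2L,
                            seed = 1L) {
  azimuth_rule <- match.arg(azimuth_rule)
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  stopifnot(length(plants) >= 1, n_rows >= 1, n_cols >= 1,
            plant_density > 0, row_spacing_m > 0)
  if (focal_block > min(n_rows, n_cols) - 2L)
    focal_block <- max(1L, min(n_rows, n_cols) - 2L)  # keep focal interior
  row_cm <- row_spacing_m * 100
  within_cm <- 100 / (plant_density * row_spacing_m)
  # template leaf meshes in the local frame, built once per (template, rank)
  tmpl <- lapply(plants, function(pl) {
    lapply(pl$phytomers, function(ph) {
      mid <- build_midrib(ph)
      build_leaf_mesh(mid, ph$max_width, n_segments = n_segments,
                      n_width_strips = n_width_strips)
    })
  })
  set.seed(seed)
  ir <- rep(seq_len(n_rows), each = n_cols)
  ic <- rep(seq_len(n_cols), times = n_rows)
  px <- (ic - 1) * within_cm
  py <- (ir - 1) * row_cm
  r0 <- (n_rows - focal_block) %/% 2L
  c0 <- (n_cols - focal_block) %/% 2L
  focal <- ir > r0 & ir <= r0 + focal_block & ic > c0 & ic <= c0 + focal_block
  n_pl <- n_rows * n_cols
  ti <- rep_len(seq_along(plants), n_pl)
  V1 <- V2 <- V3 <- NRM <- vector("list", 0)
  AR <- PL <- RK <- vector("list", 0)
  for (p in seq_len(n_pl)) {
    spec <- plants[[ti[p]]]
    meshes <- tmpl[[ti[p]]]
    nl <- spec$n_phytomers
    az <- if (azimuth_rule == "alternating") {
      # distichous: odd ranks one side of the row, even ranks the other
      base <- ifelse(seq_len(nl) %% 2L == 1L, 0, 180)
      base + stats::runif(nl, -jitter_deg, jitter_deg)
    } else {
      vapply(spec$phytomers, function(ph) ph$azimuth, numeric(1)) +
        stats::runif(nl, -jitter_deg, jitter_deg)
    }
    origin <- c(px[p], py[p], 0)
    for (i in seq_len(nl)) {
      m <- leaf_world_mesh(meshes[[i]], az[i], origin)
      k <- length(V1) + 1L
      V1[[k]] <- m$v1; V2[[k]] <- m$v2; V3[[k]] <- m$v3
      NRM[[k]] <- m$normal; AR[[k]] <- m$area
      PL[[k]] <- rep(p, length(m$area)); RK[[k]] <- rep(i, length(m$area))
    }
  }
  hmax <- max(vapply(plants, function(pl) pl$plant_height, numeric(1)))
  scene <- structure(list(
    v1 = do.call(rbind, V1), v2 = do.call(rbind, V2),
    v3 = do.call(rbind, V3), normal = do.call(rbind, NRM),
    area = unlist(AR), plant = unlist(PL), rank = unlist(RK),
    plants = data.frame(id = seq_len(n_pl), x = px, y = py,
                        template = ti, focal = focal),
    focal_ids = which(focal),
    footprint = list(xlim = c(-within_cm / 2,
                              (n_cols - 1) * within_cm + within_cm / 2),
                     ylim = c(-row_cm / 2, (n_rows - 1) * row_cm + row_cm / 2)),
    wall_height = wall_fraction * hmax,
    wall_fraction = wall_fraction,
    M = sum(focal), PD = plant_density,
    ear_rank = plants[[1]]$ear_rank,
    n_rows = n_rows, n_cols = n_cols,
    within_spacing_cm = within_cm, row_spacing_cm = row_cm,
    seed = seed), class = "canopy_scene")
  scene$centroid <- (scene$v1 + scene$v2 + scene$v3) / 3
  scene
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat("canopy_scene:", nrow(x$plants), "plants (",
      x$n_rows, "x", x$n_cols, "),", length(x$area), "facets,",
      "focal M =", x$M, ", wall", signif(x$wall_height, 5), "cm\n")
  invisible(x)
}

#' Build a bare scene from a triangle soup (for tests and small studies)
#'
#' @param v1,v2,v3 m x 3 triangle vertex matrices, cm.
#' @param plant,rank integer ownership vectors (default all plant 1 rank 1).
#' @param wall_height wall height, cm, or `NULL` for no wall.
#' @param footprint list(xlim, ylim) in cm; default the triangle bounds.
#' @param M,PD focal plant count and plant density for upscaling.
#' @export
scene_from_triangles <- function(v1, v2, v3, plant = NULL, rank = NULL,
                                 wall_height = NULL, footprint = NULL,
                                 M = 1, PD = 1) {
  m <- finish_mesh(v1, v2, v3)
  n <- length(m$area)
  if (is.null(plant)) plant <- rep(1L, n)
  if (is.null(rank)) rank <- rep(1L, n)
  allv <- rbind(m$v1, m$v2, m$v3)
  if (is.null(footprint))
    footprint <- list(xlim = range(allv[, 1]) + c(-1, 1),
                      ylim = range(allv[, 2]) + c(-1, 1))
  structure(list(v1 = m$v1, v2 = m$v2, v3 = m$v3, normal = m$normal,
                 area = m$area, plant = plant, rank = rank,
                 plants = data.frame(id = unique(plant),
                                     focal = TRUE),
                 focal_ids = unique(plant), footprint = footprint,
                 wall_height = wall_height, M = M, PD = PD,
                 ear_rank = 1L,
                 centroid = (m$v1 + m$v2 + m$v3) / 3),
            class = "canopy_scene")
}

#' Leaf areas per (plant, rank) in a scene
#'
#' @param scene a `canopy_scene`.
#' @param focal_only restrict to focal plants (default TRUE).
#' @return data.frame (plant, rank, LA_cm2).
#' @export
scene_leaf_areas <- function(scene, focal_only = TRUE) {
  idx <- if (focal_only) scene$plant %in% scene$focal_ids else
    rep(TRUE, length(scene$plant))
  ag <- stats::aggregate(scene$area[idx],
                         list(plant = scene$plant[idx],
                              rank = scene$rank[idx]), sum)
  names(ag)[3] <- "LA_cm2"
  ag[order(ag$plant, ag$rank), ]
}

#' Read a phytomer descriptor table from CSV
#'
#' Expected columns: cultivar, rank, LL_cm, HLBase_cm, HLTop_cm, HLTip_cm,
#' Ltop_cm, Ltip_cm, azimuth_deg, max_width_cm, has_ear (and optionally
#' inclination_deg, plant_height_cm).
#'
#' @param path CSV path.
#' @return named list of [plant_spec()], one per cultivar.
#' @export
read_phytomer_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$cultivar), plant_spec_from_df)
}

plant_spec_from_df <- function(df) {
  df <- df[order(df$rank), ]
  ph <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    phytomer_spec(r$rank, r$LL_cm, r$HLBase_cm, r$HLTop_cm, r$HLTip_cm,
                  r$Ltop_cm, r$Ltip_cm, azimuth = r$azimuth_deg,
                  max_width = r$max_width_cm,
                  inclination = if ("inclination_deg" %in% names(df))
                    r$inclination_deg else NA_real_,
                  has_ear = as.logical(r$has_ear))
  })
  h <- if ("plant_height_cm" %in% names(df)) df$plant_height_cm[1] else
    max(df$HLTop_cm, df$HLTip_cm) * 1.1
  plant_spec(df$cultivar[1], ph, which(as.logical(df$has_ear))[1], h)
}

#' Write plant specs to the phytomer CSV interchange format
#'
#' @param plants named list of `plant_spec`.
#' @param path output CSV path.
#' @export
write_phytomer_table <- function(plants, path) {
  rows <- lapply(plants, function(pl) {
    do.call(rbind, lapply(pl$phytomers, function(p) {
      data.frame(cultivar = pl$cultivar, rank = p$rank, LL_cm = p$LL,
                 HLBase_cm = p$HLBase, HLTop_cm = p$HLTop,
                 HLTip_cm = p$HLTip, Ltop_cm = p$Ltop, Ltip_cm = p$Ltip,
                 azimuth_deg = p$azimuth, max_width_cm = p$max_width,
                 inclination_deg = p$inclination,
                 has_ear = p$has_ear, plant_height_cm = pl$plant_height)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export a scene's leaves as an ASCII OBJ or PLY file
#'
#' One OBJ object (`o plant<j>_rank<i>`) per leaf; PLY is written as a
#' single element with per-face ownership dropped.
#'
#' @param scene a `canopy_scene`.
#' @param path output file; format chosen by extension (.obj / .ply).
#' @export
write_scene_mesh <- function(scene, path) {
  fmt <- tolower(tools::file_ext(path))
  n <- length(scene$area)
  V <- rbind(scene$v1, scene$v2, scene$v3)  # 3n vertices, triangle soup
  idx <- cbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n)
  if (fmt == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    ord <- order(scene$plant, scene$rank)
    writeLines(sprintf("v %.4f %.4f %.4f", V[, 1], V[, 2], V[, 3]), con)
    last <- c(NA, NA)
    for (f in ord) {
      key <- c(scene$plant[f], scene$rank[f])
      if (!identical(key, last)) {
        writeLines(sprintf("o plant%d_rank%d", key[1], key[2]), con)
        last <- key
      }
      writeLines(sprintf("f %d %d %d", idx[f, 1], idx[f, 2], idx[f, 3]), con)
    }
  } else if (fmt == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", n),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    writeLines(sprintf("%.4f %.4f %.4f", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", idx[, 1] - 1L, idx[, 2] - 1L,
                       idx[, 3] - 1L), con)
  } else stop("unsupported mesh format: ", fmt)
  invisible(path)
}
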