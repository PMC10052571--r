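#' Solar position from latitude, day of year and local solar hour
#'
#' Standard declination (Spencer series) and hour-angle astronomy. The hour
#' is local solar time, so no equation-of-time or longitude correction is
#' applied. Azimuth is measured clockwise from north; the scene axes are
#' x = east (row direction), y = north, z = up.
#'
#' @param latitude degrees north (site default 39.93).
#' @param doy day of year, 1..366.
#' @param hour local solar hour (12 = solar noon).
#' @return `solar_geometry` list: `zenith`, `elevation`, `azimuth` (deg),
#'   `sun_vec` (unit vector pointing from the ground toward the sun),
#'   `sunrise`, `sunset` (solar hours), `declination` (deg).
#' @export
sun_position <- function(latitude = 39.93, doy, hour) {
  if (doy < 1 || doy > 366) stop("doy outside 1..366")
  if (abs(latitude) > 90) stop("invalid latitude")
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)        # radians
  phi <- latitude * pi / 180
  H <- (hour - 12) * 15 * pi / 180
  sin_el <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  sin_el <- max(-1, min(1, sin_el))
  el <- asin(sin_el)
  cos_az <- (sin(decl) - sin_el * sin(phi)) / (cos(el) * cos(phi))
  cos_az <- max(-1, min(1, cos_az))
  az0 <- acos(cos_az) * 180 / pi              # east-side value in [0, 180]
  az <- if (H > 0) 360 - az0 else az0
  elv <- el * 180 / pi
  sun_vec <- c(cos(el) * sin(az * pi / 180),  # x east
               cos(el) * cos(az * pi / 180),  # y north
               sin(el))
  cosHs <- -tan(phi) * tan(decl)
  Hs <- if (cosHs <= -1) 12 else if (cosHs >= 1) 0 else
    acos(cosHs) * 180 / pi / 15
  structure(list(latitude = latitude, doy = doy, hour = hour,
                 zenith = 90 - elv, elevation = elv, azimuth = az,
                 sun_vec = sun_vec, sunrise = 12 - Hs, sunset = 12 + Hs,
                 declination = decl * 180 / pi),
            class = "solar_geometry")
}

#' Discretized diffuse sky hemisphere
#'
#' Equal-solid-angle sectors on the hemisphere (Fibonacci spiral layout)
#' under a uniform-radiance (UOC) sky: sector weights are proportional to
#' the cosine of the sector zenith angle and sum to 1, so an unobstructed
#' horizontal receiver intercepts exactly the horizontal diffuse flux.
#'
#' @param n_sectors number of sky sectors (default 46).
#' @return `sky_model` list: `dir` (n x 3 unit vectors toward the sky),
#'   `weight` (sums to 1), `cos_zenith`.
#' @export
sky_model <- function(n_sectors = 46L) {
  stopifnot(n_sectors >= 1)
  i <- seq_len(n_sectors)
  cz <- (i - 0.5) / n_sectors          # uniform in cos(zenith): equal area
  sz <- sqrt(1 - cz^2)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  dir <- cbind(sz * cos(phi), sz * sin(phi), cz)
  w <- cz / sum(cz)
  structure(list(dir = dir, weight = w, cos_zenith = cz,
                 n_sectors = n_sectors), class = "sky_model")
}

# Does the ray origin + t*dir (t > 0) hit the virtual wall (four vertical
# rectangles on the footprint perimeter, z in [0, H])? Vectorized over rows
# of `origins`.
wall_blocks <- function(origins, dir, footprint, wall_height,
                        t_eps = 1e-6) {
  n <- nrow(origins)
  if (is.null(wall_height) || wall_height <= 0) return(rep(FALSE, n))
  xl <- footprint$xlim; yl <- footprint$ylim
  blocked <- rep(FALSE, n)
  planes <- list(c(1, xl[1]), c(1, xl[2]), c(2, yl[1]), c(2, yl[2]))
  for (p in planes) {
    ax <- p[1]; val <- p[2]
    if (abs(dir[ax]) < 1e-12) next
    t <- (val - origins[, ax]) / dir[ax]
    other <- if (ax == 1) 2 else 1
    lim <- if (ax == 1) yl else xl
    oc <- origins[, other] + t * dir[other]
    zc <- origins[, 3] + t * dir[3]
    blocked <- blocked | (t > t_eps & oc >= lim[1] & oc <= lim[2] &
                            zc >= 0 & zc <= wall_height)
  }
  blocked
}

#' Facet occlusion test along a beam
#'
#' For each queried facet, casts a ray from the facet centroid toward the
#' source direction and reports whether any other facet (or the virtual
#' wall) intersects it. `method = "grid"` is the production algorithm: an
#' orthographic beam projection bins triangles in a uniform 2D grid and
#' candidate triangles are then tested exactly (Moller-Trumbore), so its
#' decisions match the `"brute"` all-pairs oracle facet for facet.
#'
#' @param scene a `canopy_scene`.
#' @param dir unit-ish 3-vector pointing from the surface toward the source
#'   (e.g. `sun$sun_vec`).
#' @param facet_ids indices of facets to test (default: focal facets).
#' @param method `"grid"` (default) or `"brute"`.
#' @param include_wall test the virtual wall as an occluder (default TRUE).
#' @param t_eps minimum ray parameter for a hit, cm.
#' @return logical vector along `facet_ids`: TRUE = occluded.
#' @export
facet_occluded <- function(scene, dir, facet_ids = NULL,
                           method = c("grid", "brute"),
                           include_wall = TRUE, t_eps = 1e-3) {
  method <- match.arg(method)
  if (is.null(facet_ids)) facet_ids <- focal_facets(scene)
  org <- scene$centroid[facet_ids, , drop = FALSE]
  dir <- dir / sqrt(sum(dir^2))
  occ <- if (method == "grid") {
    cpp_occluded(org, dir, scene$v1, scene$v2, scene$v3,
                 as.integer(facet_ids - 1L), cell = 5, t_eps = t_eps)
  } else {
    occluded_brute(org, dir, scene$v1, scene$v2, scene$v3,
                   facet_ids, t_eps = t_eps)
  }
  if (include_wall && !is.null(scene$wall_height))
    occ <- occ | wall_blocks(org, dir, scene$footprint, scene$wall_height)
  occ
}

#' Brute-force all-pairs ray-triangle occlusion (oracle)
#'
#' Vectorized Moller-Trumbore over every (origin, triangle) pair, with the
#' same epsilon semantics as the production grid algorithm. Intended for
#' small scenes and as the independent reference in tests.
#'
#' @param origins n x 3 ray origins, cm.
#' @param dir 3-vector toward the source.
#' @param v1,v2,v3 m x 3 triangle vertices.
#' @param self_ids origin i belongs to triangle `self_ids[i]` (excluded).
#' @param t_eps minimum ray parameter for a hit.
#' @return logical n-vector.
#' @export
occluded_brute <- function(origins, dir, v1, v2, v3, self_ids = NULL,
                           t_eps = 1e-3) {
  n <- nrow(origins); m <- nrow(v1)
  dir <- dir / sqrt(sum(dir^2))
  out <- logical(n)
  e1 <- v2 - v1; e2 <- v3 - v1
  p <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * p)
  ok0 <- abs(det) >= 1e-12
  inv <- ifelse(ok0, 1 / det, NA_real_)
  for (q in seq_len(n)) {
    s <- sweep(v1, 2, origins[q, ], "-")
    s <- -s
    u <- rowSums(s * p) * inv
    qv <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
                s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
                s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
    v <- (dir[1] * qv[, 1] + dir[2] * qv[, 2] + dir[3] * qv[, 3]) * inv
    t <- rowSums(e2 * qv) * inv
    hit <- ok0 & !is.na(u) & u >= 0 & u <= 1 & v >= 0 & (u + v) <= 1 &
      t > t_eps
    if (!is.null(self_ids)) hit[self_ids[q]] <- FALSE
    out[q] <- any(hit, na.rm = TRUE)
  }
  out
}

focal_facets <- function(scene) {
  which(scene$plant %in% scene$focal_ids)
}

#' Direct-beam PAR interception per facet
#'
#' A facet is sunlit iff it faces the beam (the angle between its normal
#' and the ray direction from sun to ground exceeds 90 degrees, i.e. the
#' normal has a positive component toward the sun) and no other facet or
#' the virtual wall occludes the path to the sun. Sunlit facets receive
#' `(I_dir / cos(zenith)) * |cos(normal, beam)|`; shaded facets receive 0.
#'
#' @param scene a `canopy_scene`.
#' @param sun a `solar_geometry` (daylight: zenith < 90).
#' @param I_dir direct PAR on a horizontal plane, umol m-2 s-1.
#' @param facet_ids facets to evaluate (default focal facets).
#' @param method occlusion method, `"grid"` or `"brute"`.
#' @param occlusion_aware if FALSE, use the orientation-only sunlit
#'   criterion (no shading test) -- the literal normal-angle definition.
#' @return data.frame: `facet`, `flux_density` (umol m-2 s-1 on the facet),
#'   `flux_umol_s` (per facet), `sunlit`.
#' @export
direct_interception <- function(scene, sun, I_dir, facet_ids = NULL,
                                method = c("grid", "brute"),
                                occlusion_aware = TRUE) {
  method <- match.arg(method)
  if (sun$zenith >= 90) stop("no direct beam: sun below horizon")
  if (I_dir < 0) stop("I_dir must be >= 0")
  if (is.null(facet_ids)) facet_ids <- focal_facets(scene)
  nrm <- scene$normal[facet_ids, , drop = FALSE]
  cosang <- as.numeric(nrm %*% sun$sun_vec)
  facing <- cosang > 0
  occluded <- if (occlusion_aware) {
    facet_occluded(scene, sun$sun_vec, facet_ids, method = method)
  } else rep(FALSE, length(facet_ids))
  sunlit <- facing & !occluded
  beam_normal <- I_dir / cos(sun$zenith * pi / 180)
  dens <- ifelse(sunlit, beam_normal * abs(cosang), 0)
  data.frame(facet = facet_ids, flux_density = dens,
             flux_umol_s = dens * scene$area[facet_ids] * 1e-4,
             sunlit = sunlit)
}

#' Direct-beam power available to a scene (conservation bound)
#'
#' Total direct power that can reach the scene's leaves: the beam-normal
#' irradiance `I_dir / cos(zenith)` times the area of the scene's bounding
#' box projected along the beam. For overhead sun this reduces to
#' `I_dir x ground footprint`; at lower sun it also counts the beam tube
#' entering through the box sides (a field canopy receives such light over
#' its borders; inside the stand the virtual wall blocks the sub-wall part
#' of it). Total intercepted direct power can never exceed this bound.
#'
#' @param scene a `canopy_scene`.
#' @param sun a `solar_geometry`.
#' @param I_dir direct horizontal PAR, umol m-2 s-1.
#' @return bound in umol s-1.
#' @export
beam_power_bound <- function(scene, sun, I_dir) {
  allv <- rbind(scene$v1, scene$v2, scene$v3)
  L <- apply(allv, 2, max) - apply(allv, 2, min)
  s <- sun$sun_vec
  aproj_m2 <- (abs(s[1]) * L[2] * L[3] + abs(s[2]) * L[1] * L[3] +
                 abs(s[3]) * L[1] * L[2]) * 1e-4
  I_dir / cos(sun$zenith * pi / 180) * aproj_m2
}

#' Per-facet diffuse interception factor for a sky model
#'
#' Each sky sector is a directional source carrying `weight * I_diff` on
#' the horizontal; a facet intercepts it when it faces the sector and the
#' path is unoccluded. The returned factor `D` gives the facet's diffuse
#' flux density as `D * I_diff`, so it can be reused across hours (sector
#' visibility does not depend on time of day).
#'
#' @inheritParams direct_interception
#' @param sky a [sky_model()].
#' @return numeric vector of factors along `facet_ids`.
#' @export
diffuse_factor <- function(scene, sky, facet_ids = NULL,
                           method = c("grid", "brute")) {
  method <- match.arg(method)
  if (is.null(facet_ids)) facet_ids <- focal_facets(scene)
  nrm <- scene$normal[facet_ids, , drop = FALSE]
  D <- numeric(length(facet_ids))
  for (k in seq_len(sky$n_sectors)) {
    d <- sky$dir[k, ]
    cosang <- as.numeric(nrm %*% d)
    facing <- cosang > 0
    if (!any(facing)) next
    occ <- rep(TRUE, length(facet_ids))
    occ[facing] <- facet_occluded(scene, d, facet_ids[facing],
                                  method = method)
    vis <- facing & !occ
    D[vis] <- D[vis] + sky$weight[k] / sky$cos_zenith[k] * cosang[vis]
  }
  D
}

#' Diffuse PAR interception per facet
#'
#' @inheritParams diffuse_factor
#' @param I_diff diffuse PAR on a horizontal plane, umol m-2 s-1.
#' @param factors optional precomputed [diffuse_factor()] output.
#' @return data.frame: `facet`, `flux_density`, `flux_umol_s`.
#' @export
diffuse_interception <- function(scene, sky, I_diff, facet_ids = NULL,
                                 method = c("grid", "brute"),
                                 factors = NULL) {
  if (I_diff < 0) stop("I_diff must be >= 0")
  if (is.null(facet_ids)) facet_ids <- focal_facets(scene)
  if (is.null(factors)) factors <- diffuse_factor(scene, sky, facet_ids,
                                                  method = method)
  dens <- factors * I_diff
  data.frame(facet = facet_ids, flux_density = dens,
             flux_umol_s = dens * scene$area[facet_ids] * 1e-4)
}

#' Hourly interception records for the focal plants
#'
#' Mirrors the radiation module's output row: one record per (focal plant,
#' leaf rank, hour) holding leaf area `LA_cm2`, intercepted photosynthetic
#' photons `IPP_umol_leaf_h` (direct + diffuse over the hour) and sunlit
#' leaf area `LA_sun_cm2` (total area of facets flagged sunlit).
#'
#' @param scene a `canopy_scene`.
#' @param doy day of year.
#' @param hour local solar hour.
#' @param I_dir,I_diff direct/diffuse horizontal PAR, umol m-2 s-1.
#' @param latitude degrees north.
#' @param sky a [sky_model()].
#' @param dfac optional precomputed [diffuse_factor()] for the focal facets.
#' @param method occlusion method.
#' @return data.frame with columns DOY, plant, rank, hour, LA_cm2,
#'   IPP_umol_leaf_h, LA_sun_cm2.
#' @export
hourly_records <- function(scene, doy, hour, I_dir, I_diff,
                           latitude = 39.93, sky = sky_model(),
                           dfac = NULL, method = "grid") {
  fid <- focal_facets(scene)
  la <- scene_leaf_areas(scene)
  dens <- numeric(length(fid))
  sun_area <- numeric(length(fid))
  sun <- sun_position(latitude, doy, hour)
  if (I_dir > 0 && sun$zenith < 90) {
    di <- direct_interception(scene, sun, I_dir, fid, method = method)
    dens <- dens + di$flux_density
    sun_area[di$sunlit] <- scene$area[fid][di$sunlit]
  }
  if (I_diff > 0) {
    if (is.null(dfac)) dfac <- diffuse_factor(scene, sky, fid,
                                              method = method)
    dens <- dens + dfac * I_diff
  }
  flux <- dens * scene$area[fid] * 1e-4          # umol s-1 per facet
  key <- paste(scene$plant[fid], scene$rank[fid])
  ipp <- tapply(flux, key, sum) * 3600
  las <- tapply(sun_area, key, sum)
  kk <- paste(la$plant, la$rank)
  out <- data.frame(DOY = doy, plant = la$plant, rank = la$rank,
                    hour = hour, LA_cm2 = la$LA_cm2,
                    IPP_umol_leaf_h = as.numeric(ipp[kk]),
                    LA_sun_cm2 = as.numeric(las[kk]))
  out$IPP_umol_leaf_h[is.na(out$IPP_umol_leaf_h)] <- 0
  out$LA_sun_cm2[is.na(out$LA_sun_cm2)] <- 0
  out
}

#' Daylight interception records for one day of weather
#'
#' Runs [hourly_records()] over the integer solar hours from
#' `ceil(sunrise)` to `floor(sunset)`, reusing one diffuse-sky visibility
#' pass for the whole day.
#'
#' @param scene a `canopy_scene`.
#' @param doy day of year.
#' @param weather data.frame with columns `doy`, `hour`, `I_dir`, `I_diff`
#'   (umol m-2 s-1 on the horizontal).
#' @inheritParams hourly_records
#' @return row-bound records for the day's daylight hours.
#' @export
interception_day <- function(scene, doy, weather, latitude = 39.93,
                             sky = sky_model(), dfac = NULL,
                             method = "grid") {
  sun0 <- sun_position(latitude, doy, 12)
  hours <- seq(ceiling(sun0$sunrise), floor(sun0$sunset))
  wd <- weather[weather$doy == doy, ]
  if (nrow(wd) == 0) stop("missing weather for doy ", doy)
  fid <- focal_facets(scene)
  if (is.null(dfac)) dfac <- diffuse_factor(scene, sky, fid, method = method)
  out <- vector("list", length(hours))
  for (h in seq_along(hours)) {
    wr <- wd[wd$hour == hours[h], ]
    if (nrow(wr) == 0) stop("missing weather hour ", hours[h],
                            " on doy ", doy)
    out[[h]] <- hourly_records(scene, doy, hours[h], wr$I_dir[1],
                               wr$I_diff[1], latitude = latitude,
                               sky = sky, dfac = dfac, method = method)
  }
  do.call(rbind, out)
}

#' Write interception records in the standard CSV layout
#'
#' Columns: DOY, plant, rank, hour, LA_cm2, IPP_umol_leaf_h, LA_sun_cm2.
#'
#' @param records records from [hourly_records()]/[interception_day()].
#' @param path output CSV path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records[, c("DOY", "plant", "rank", "hour", "LA_cm2",
                               "IPP_umol_leaf_h", "LA_sun_cm2")],
                   path, row.names = FALSE)
  invisible(path)
}
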