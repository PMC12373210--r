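#' Cone-beam acquisition geometry
#'
#' Describes a point X-ray source and a flat-panel detector in the standard
#' isocentric arrangement: the source sits at distance `sad_mm` from the
#' isocenter (source-to-axis distance, SAD), the detector plane at distance
#' `sid_mm` from the source (source-to-image distance, SID), perpendicular to
#' the central ray which always points at the isocenter. Their ratio
#' `sid_mm / sad_mm` is the geometric magnification of objects at isocenter.
#'
#' When `det_pitch_mm` is `NULL` it defaults to the pitch at which the
#' detector's shorter side covers a `fov_mm` object at isocenter with a 10%
#' margin after magnification, i.e.
#' `1.1 * fov_mm * (sid_mm / sad_mm) / min(det_rows, det_cols)`.
#'
#' @param sad_mm Source-to-isocenter distance in mm (default 570, a common
#'   diagnostic CT geometry).
#' @param sid_mm Source-to-detector distance in mm (default 1040).
#' @param det_rows,det_cols Detector pixel counts.
#' @param det_pitch_mm Detector pixel spacing in mm (both axes), or `NULL`.
#' @param fov_mm Nominal object extent at isocenter used only for the default
#'   pitch (default 320 mm, a thorax field of view).
#' @return An object of class `source_setup`.
#' @export
#' @examples
#' geo <- source_setup(det_rows = 64, det_cols = 64)
#' geo$det_pitch_mm
source_setup <- function(sad_mm = 570, sid_mm = 1040,
                         det_rows = 128L, det_cols = 128L,
                         det_pitch_mm = NULL, fov_mm = 320) {
  stopifnot(is.numeric(sad_mm), length(sad_mm) == 1, sad_mm > 0)
  if (!(is.numeric(sid_mm) && sid_mm > sad_mm))
    stop("sid_mm must exceed sad_mm (detector beyond the isocenter)")
  det_rows <- as.integer(det_rows); det_cols <- as.integer(det_cols)
  stopifnot(det_rows >= 1L, det_cols >= 1L)
  if (is.null(det_pitch_mm))
    det_pitch_mm <- 1.1 * fov_mm * (sid_mm / sad_mm) / min(det_rows, det_cols)
  stopifnot(det_pitch_mm > 0)
  structure(list(sad_mm = sad_mm, sid_mm = sid_mm,
                 det_rows = det_rows, det_cols = det_cols,
                 det_pitch_mm = det_pitch_mm),
            class = "source_setup")
}

#' @export
print.source_setup <- function(x, ...) {
  cat(sprintf("<source_setup> SAD %.1f mm, SID %.1f mm (mag %.3f), detector %d x %d @ %.3f mm\n",
              x$sad_mm, x$sid_mm, x$sid_mm / x$sad_mm,
              x$det_rows, x$det_cols, x$det_pitch_mm))
  invisible(x)
}

#' View pose on the acquisition ring
#'
#' A pose is the direction the source is seen from the isocenter, given as an
#' azimuth `theta_deg` on the axial ring and an elevation `phi_deg` off the
#' axial plane. The anterior-posterior (AP) view is `theta_deg = 0` with the
#' source on the +y axis; azimuth increases towards +x. The central ray always
#' points at the origin.
#'
#' @param theta_deg Azimuth in degrees.
#' @param phi_deg Elevation in degrees (default 0, an axial ring).
#' @return An object of class `pose`.
#' @export
pose <- function(theta_deg, phi_deg = 0) {
  stopifnot(is.finite(theta_deg), is.finite(phi_deg))
  structure(list(theta_deg = as.numeric(theta_deg),
                 phi_deg = as.numeric(phi_deg)), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> theta %.2f deg, phi %.2f deg\n", x$theta_deg, x$phi_deg))
  invisible(x)
}

#' Equally spaced poses covering a full rotation
#'
#' Standard sparse acquisition patterns: `n_views = 5` gives a 72-degree
#' spacing, `n_views = 10` a 36-degree spacing, `n_views = 72` the dense
#' 5-degree reference set, all starting from the AP view by default.
#'
#' @param n_views Number of views (>= 1).
#' @param start_deg Azimuth of the first view (default 0 = AP).
#' @return A list of [pose] objects.
#' @export
#' @examples
#' vapply(make_circular_poses(5), function(p) p$theta_deg, 0)
make_circular_poses <- function(n_views, start_deg = 0) {
  if (!(is.numeric(n_views) && length(n_views) == 1 && n_views >= 1))
    stop("n_views must be a positive count")
  n_views <- as.integer(n_views)
  lapply(seq_len(n_views) - 1L,
         function(k) pose(start_deg + k * 360 / n_views, 0))
}

# Source position, central direction and detector frame for a pose.
# Right-handed mm coordinates, isocenter at origin; AP (theta = 0) puts the
# source on +y; detector columns increase along the +u axis, rows along +v.
pose_frame <- function(setup, pose) {
  th <- pose$theta_deg * pi / 180
  ph <- pose$phi_deg * pi / 180
  src <- setup$sad_mm * c(cos(ph) * sin(th), cos(ph) * cos(th), sin(ph))
  w <- -src / setup$sad_mm                      # central ray, source -> origin
  if (abs(cos(ph)) > 1e-12) {
    u <- c(-w[2], w[1], 0); u <- u / sqrt(sum(u^2))
  } else {                                      # looking straight down/up
    u <- c(cos(th), -sin(th), 0)
  }
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(source = src, w = w, u = u, v = v,
       det_center = src + setup$sid_mm * w)
}

#' Patch sampling pattern on the detector
#'
#' A sparse training patch: an `size_m` x `size_m` block of detector
#' positions centered at the continuous detector coordinate `center_uv`
#' (0-based `(col, row)` pixel units) with inter-pixel stride `scale_s`. At
#' `scale_s = 1` the patch reads contiguous pixels; at the upper bound
#' `min(det_rows, det_cols) / size_m` its footprint spans the whole field of
#' view at reduced resolution. The dilated footprint must lie inside the
#' detector domain.
#'
#' @param center_uv Numeric length-2, `(col, row)` center in pixel units.
#' @param scale_s Dilation factor, `>= 1`.
#' @param size_m Patch side in pixels.
#' @param setup A [source_setup] used to validate the footprint (optional).
#' @return An object of class `patch_pattern`.
#' @export
patch_pattern <- function(center_uv, scale_s, size_m, setup = NULL) {
  stopifnot(length(center_uv) == 2, is.finite(center_uv),
            scale_s >= 1, size_m >= 1)
  size_m <- as.integer(size_m)
  pat <- structure(list(center_uv = as.numeric(center_uv),
                        scale_s = as.numeric(scale_s),
                        size_m = size_m), class = "patch_pattern")
  if (!is.null(setup)) validate_pattern(setup, pat)
  pat
}

validate_pattern <- function(setup, pattern) {
  m <- pattern$size_m
  if (m > min(setup$det_rows, setup$det_cols))
    stop("patch side exceeds the detector")
  half <- pattern$scale_s * (m - 1) / 2
  cx <- pattern$center_uv[1]; cy <- pattern$center_uv[2]
  if (cx - half < -1e-9 || cx + half > setup$det_cols - 1 + 1e-9 ||
      cy - half < -1e-9 || cy + half > setup$det_rows - 1 + 1e-9)
    stop("dilated patch footprint falls outside the detector domain")
  invisible(pattern)
}

#' Draw a random patch pattern
#'
#' The dilation is uniform on `[1, S]` with `S = min(det_rows, det_cols) /
#' size_m`, and the center is uniform over the sub-domain of the detector in
#' which the dilated footprint still fits. Uses the current R random stream
#' unless `seed` is given.
#'
#' @param setup A [source_setup].
#' @param size_m Patch side in pixels (`<= min(det_rows, det_cols)`).
#' @param seed Optional integer seed for a local, reproducible draw.
#' @return A [patch_pattern].
#' @export
sample_patch_pattern <- function(setup, size_m, seed = NULL) {
  size_m <- as.integer(size_m)
  if (size_m > min(setup$det_rows, setup$det_cols))
    stop("patch side exceeds the detector")
  if (!is.null(seed)) set.seed(seed)
  s_max <- min(setup$det_rows, setup$det_cols) / size_m
  s <- stats::runif(1, 1, s_max)
  half <- s * (size_m - 1) / 2
  cx_lo <- half; cx_hi <- setup$det_cols - 1 - half
  cy_lo <- half; cy_hi <- setup$det_rows - 1 - half
  cx <- if (cx_hi > cx_lo) stats::runif(1, cx_lo, cx_hi) else (setup$det_cols - 1) / 2
  cy <- if (cy_hi > cy_lo) stats::runif(1, cy_lo, cy_hi) else (setup$det_rows - 1) / 2
  patch_pattern(c(cx, cy), s, size_m, setup)
}

# Continuous detector (col, row) coordinates of a pattern's pixels,
# row-major (row outer, column inner).
pattern_pixel_coords <- function(setup, pattern) {
  m <- pattern$size_m
  off <- pattern$scale_s * (seq_len(m) - 1 - (m - 1) / 2)
  cols <- pattern$center_uv[1] + off
  rows <- pattern$center_uv[2] + off
  list(col = rep(cols, times = m), row = rep(rows, each = m),
       rows = m, cols = m)
}

ray_bundle <- function(origins, dirs, rows, cols, t_near = NULL, t_far = NULL) {
  n <- nrow(dirs)
  structure(list(origins = origins, dirs = dirs,
                 rows = rows, cols = cols,
                 t_near = if (is.null(t_near)) rep(NA_real_, n) else t_near,
                 t_far = if (is.null(t_far)) rep(NA_real_, n) else t_far),
            class = "ray_bundle")
}

#' @export
print.ray_bundle <- function(x, ...) {
  cat(sprintf("<ray_bundle> %d rays (%d x %d), %s\n",
              nrow(x$dirs), x$rows, x$cols,
              if (all(is.na(x$t_near))) "unclipped"
              else sprintf("%d hit the bounds", sum(ray_hits(x)))))
  invisible(x)
}

#' @rdname rays_for_patch
#' @export
ray_hits <- function(rays) !is.na(rays$t_near) & !is.na(rays$t_far)

rays_from_detector_coords <- function(setup, pose, col, row, rows, cols,
                                      bounds = NULL) {
  f <- pose_frame(setup, pose)
  du <- (col - (setup$det_cols - 1) / 2) * setup$det_pitch_mm
  dv <- (row - (setup$det_rows - 1) / 2) * setup$det_pitch_mm
  n <- length(col)
  pix <- matrix(f$det_center, n, 3, byrow = TRUE) +
    outer(du, f$u) + outer(dv, f$v)
  dirs <- pix - matrix(f$source, n, 3, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  origins <- matrix(f$source, n, 3, byrow = TRUE)
  rays <- ray_bundle(origins, dirs, rows, cols)
  if (!is.null(bounds)) rays <- clip_rays(rays, bounds)
  rays
}

#' Rays through a detector patch or the full detector
#'
#' Builds one ray per detector position, from the posed source point through
#' the (possibly dilated) pixel centers on the detector plane, in row-major
#' order. When `bounds` (a [voxel_grid] or a 2 x 3 `rbind(lo, hi)` matrix in
#' mm) is supplied, each ray carries the entry/exit parameters `t_near` /
#' `t_far` of the bounding box; rays that miss it are flagged with `NA` and
#' reported by `ray_hits()`.
#'
#' @param setup A [source_setup].
#' @param pose A [pose].
#' @param pattern A [patch_pattern].
#' @param bounds Optional clipping bounds ([voxel_grid] or 2 x 3 matrix).
#' @return A `ray_bundle` with `origins`, unit `dirs`, and `t_near` / `t_far`.
#' @export
rays_for_patch <- function(setup, pose, pattern, bounds = NULL) {
  validate_pattern(setup, pattern)
  pc <- pattern_pixel_coords(setup, pattern)
  rays_from_detector_coords(setup, pose, pc$col, pc$row, pc$rows, pc$cols,
                            bounds)
}

#' @rdname rays_for_patch
#' @export
rays_for_detector <- function(setup, pose, bounds = NULL) {
  cols <- rep(seq_len(setup$det_cols) - 1, times = setup$det_rows)
  rows <- rep(seq_len(setup$det_rows) - 1, each = setup$det_cols)
  rays_from_detector_coords(setup, pose, cols, rows,
                            setup$det_rows, setup$det_cols, bounds)
}

#' @rdname rays_for_patch
#' @param rays A `ray_bundle`.
#' @export
clip_rays <- function(rays, bounds) {
  bb <- grid_bounds(bounds)
  tt <- cpp_box_clip(bb[1, ], bb[2, ], rays$origins, rays$dirs)
  rays$t_near <- tt[, 1]
  rays$t_far <- tt[, 2]
  rays
}

grid_bounds <- function(bounds) {
  if (inherits(bounds, "voxel_grid")) {
    lo <- bounds$origin_mm
    rbind(lo, lo + bounds$dims * bounds$spacing_mm)
  } else if (is.matrix(bounds) && all(dim(bounds) == c(2, 3))) {
    bounds
  } else stop("bounds must be a voxel_grid or a 2 x 3 matrix")
}

#' Stratified sampling of points along rays
#'
#' Splits each ray's `[t_near, t_far]` interval into `q` equal bins and draws
#' one uniform sample per bin (the NeRF stratified scheme), so the bin lengths
#' sum exactly to the chord length. Rays flagged as missing the bounds
#' contribute no samples and are marked in the returned `hit` vector.
#'
#' @param rays A clipped `ray_bundle` (see [rays_for_patch]).
#' @param q Samples per ray (>= 1).
#' @param seed Optional integer seed for a local, reproducible draw.
#' @param jitter Set `FALSE` for deterministic bin midpoints.
#' @return A list with `points` (n_hit * q rows, 3 columns, ray-major),
#'   `t` (matrix n_hit x q), `dt` (bin length per hit ray), `hit`, and the
#'   patch shape carried over from the bundle.
#' @export
stratified_sample <- function(rays, q, seed = NULL, jitter = TRUE) {
  stopifnot(q >= 1)
  q <- as.integer(q)
  if (!is.null(seed)) set.seed(seed)
  hit <- ray_hits(rays)
  nh <- sum(hit)
  if (nh == 0)
    return(list(points = matrix(numeric(0), 0, 3), t = matrix(numeric(0), 0, q),
                dt = numeric(0), hit = hit, q = q,
                rows = rays$rows, cols = rays$cols))
  tn <- rays$t_near[hit]; tf <- rays$t_far[hit]
  dt <- (tf - tn) / q
  u <- if (jitter) matrix(stats::runif(nh * q), nh, q)
       else matrix(0.5, nh, q)
  tmat <- tn + dt * (matrix(rep(seq_len(q) - 1, each = nh), nh, q) + u)
  o <- rays$origins[hit, , drop = FALSE]
  d <- rays$dirs[hit, , drop = FALSE]
  tv <- as.vector(t(tmat))                       # ray-major ordering
  idx <- rep(seq_len(nh), each = q)
  pts <- o[idx, , drop = FALSE] + tv * d[idx, , drop = FALSE]
  list(points = pts, t = tmat, dt = dt, hit = hit, q = q,
       rows = rays$rows, cols = rays$cols)
}
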