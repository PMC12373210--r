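#' Discrete attenuation volume
#'
#' A regular voxel grid of non-negative attenuation values (normalized [0,1]
#' units unless stated otherwise). `values` is a 3D array indexed `[i, j, k]`
#' along the x, y, z axes; `origin_mm` is the position of the corner of voxel
#' `(1,1,1)`, so the grid spans `origin_mm + [0, dims * spacing_mm]`. By
#' default the grid is centered on the isocenter.
#'
#' @param values 3D numeric array of finite, non-negative values.
#' @param spacing_mm Per-axis voxel size in mm (length 1 or 3).
#' @param origin_mm Corner position in mm, or `NULL` to center at the origin.
#' @return An object of class `voxel_grid` with `values`, `dims`,
#'   `spacing_mm`, `origin_mm`.
#' @export
voxel_grid <- function(values, spacing_mm = 1, origin_mm = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(!is.finite(values)) || any(values < 0))
    stop("voxel values must be finite and non-negative")
  dims <- dim(values)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  stopifnot(all(spacing_mm > 0))
  if (is.null(origin_mm)) origin_mm <- -dims * spacing_mm / 2
  stopifnot(length(origin_mm) == 3)
  structure(list(values = values, dims = as.integer(dims),
                 spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, values [%.3g, %.3g]\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Siddon voxel traversal of a single ray
#'
#' Computes the exact chord length of the ray inside every voxel it crosses,
#' ordered by increasing ray parameter. The lengths sum to the chord of the
#' ray inside the grid bounding box; a ray that misses the grid yields an
#' empty result. Voxel-edge and corner hits are merged with a 1e-12 tie
#' tolerance and zero-length segments are dropped.
#'
#' @param grid A [voxel_grid].
#' @param origin_mm Ray origin (length 3, mm).
#' @param dir Unit direction (length 3).
#' @return A data.frame with 1-based voxel indices `i, j, k`, `length_mm`, and
#'   the entry parameter `t_entry_mm`.
#' @export
siddon_trace <- function(grid, origin_mm, dir) {
  nd <- sqrt(sum(dir^2))
  if (abs(nd - 1) > 1e-9) stop("ray direction must be unit-norm")
  out <- cpp_siddon_trace(grid$dims, grid$spacing_mm, grid$origin_mm,
                          as.numeric(origin_mm), as.numeric(dir))
  as.data.frame(out)
}

#' Exact line integrals through a voxel grid
#'
#' Sums `value * chord length` over the Siddon traversal of each ray; rays
#' that miss the grid integrate to 0. Units are value x mm.
#'
#' @param grid A [voxel_grid].
#' @param rays A `ray_bundle`, or a list with `origins` and `dirs` matrices.
#' @return Numeric vector of integrals, one per ray.
#' @export
line_integral <- function(grid, rays) {
  cpp_siddon_integrate(grid$values, grid$dims, grid$spacing_mm,
                       grid$origin_mm, rays$origins, rays$dirs)
}

#' Digitally reconstructed radiograph (DRR)
#'
#' Projects the volume onto the posed detector by exact Siddon line
#' integration, one ray per detector pixel. The raw projection is the linear
#' attenuation integral (no Beer-Lambert exponentiation); by default it is
#' min-max normalized to [0, 1] per image, the convention used for all
#' projection data here. A constant raw image (including all-zero) normalizes
#' to zeros.
#'
#' @param grid A [voxel_grid].
#' @param setup A [source_setup].
#' @param pose A [pose].
#' @param normalize Min-max normalize to [0,1] (default `TRUE`).
#' @param beer_lambert Apply `1 - exp(-integral)` before normalization
#'   (default `FALSE`; the linear integral is the supervised quantity).
#' @return Numeric matrix `det_rows x det_cols` (`image[row, col]`).
#' @export
make_drr <- function(grid, setup, pose, normalize = TRUE,
                     beer_lambert = FALSE) {
  rays <- rays_for_detector(setup, pose)
  vals <- line_integral(grid, rays)
  img <- matrix(vals, setup$det_rows, setup$det_cols, byrow = TRUE)
  if (beer_lambert) img <- 1 - exp(-img)
  if (normalize) img <- normalize_01(img)
  img
}

#' Min-max normalize to the unit interval
#'
#' Constant inputs (zero range) return all zeros, the documented convention
#' for degenerate projections.
#'
#' @param x Numeric array.
#' @return `x` rescaled to [0, 1].
#' @export
normalize_01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(x) %||% length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a projection patch from a continuous density field
#'
#' The X-ray replacement for optical volume rendering: each pixel is the
#' stratified Riemann sum `sum_i density(x_i) * dt_i` along its ray — a
#' discrete attenuation line integral with no opacity compositing. Returns
#' the sampled 3D points with their densities (the sub-volume sample set used
#' for 3D supervision) alongside the rendered patch.
#'
#' @param field_fn Function mapping an `n x 3` point matrix to `n` densities.
#' @param rays A clipped `ray_bundle`.
#' @param q Samples per ray.
#' @param seed Optional integer seed for the stratified draw.
#' @param jitter Set `FALSE` for deterministic bin midpoints.
#' @return A list with `patch` (rows x cols matrix), `points`, `densities`,
#'   `dt`, `hit`, `q`.
#' @export
render_patch_from_field <- function(field_fn, rays, q, seed = NULL,
                                    jitter = TRUE) {
  ss <- stratified_sample(rays, q, seed = seed, jitter = jitter)
  n_rays <- length(ss$hit)
  pix <- numeric(n_rays)
  dens <- numeric(0)
  if (nrow(ss$points) > 0) {
    dens <- field_fn(ss$points)
    sums <- rowSums(matrix(dens, ncol = q, byrow = TRUE))
    pix[ss$hit] <- sums * ss$dt
  }
  patch <- matrix(pix, ss$rows, ss$cols, byrow = TRUE)
  list(patch = patch, points = ss$points, densities = dens,
       t = ss$t, dt = ss$dt, hit = ss$hit, q = q,
       rows = ss$rows, cols = ss$cols)
}

#' Point samplers backed by a voxel grid
#'
#' `grid_lookup_fn` returns the value of the voxel containing each query
#' point (0 outside the grid); `grid_trilinear_fn` interpolates between voxel
#' centers. Both return functions suitable as `field_fn` in
#' [render_patch_from_field].
#'
#' @param grid A [voxel_grid].
#' @return A function from `n x 3` point matrices to `n` values.
#' @export
grid_lookup_fn <- function(grid) {
  force(grid)
  function(pts) cpp_voxel_lookup(grid$values, grid$dims, grid$spacing_mm,
                                 grid$origin_mm, pts)
}

#' @rdname grid_lookup_fn
#' @export
grid_trilinear_fn <- function(grid) {
  force(grid)
  function(pts) cpp_trilinear(grid$values, grid$dims, grid$spacing_mm,
                              grid$origin_mm, pts)
}
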