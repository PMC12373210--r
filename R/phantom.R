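#' Procedural thorax-like phantom
#'
#' Generates a randomized anthropomorphic test volume with the contrast
#' structure the reconstruction method assumes: a soft-tissue body ellipsoid
#' containing two low-attenuation lung ellipsoids, a high-attenuation
#' spine-like cylinder, 0-3 tumor spheres constrained to lie inside the
#' lungs, and optionally a small very dense pacemaker-like blob. Values are
#' normalized attenuation in [0, 1] (air 0, soft tissue ~0.5, bone ~0.9);
#' boundaries are anti-aliased over one voxel so projections of the phantom
#' are close to those of the underlying continuous object. The output is
#' fully determined by the seed.
#'
#' @param dims Voxel counts per axis (scalar or length 3, each >= 8).
#' @param seed Optional integer seed.
#' @param fov_mm Physical edge length of the volume (default 320 mm); voxel
#'   spacing is `fov_mm / dims`.
#' @param complexity 0-1 knob scaling how much anatomy is randomized
#'   (default 1; 0 gives the nominal phantom).
#' @param pacemaker_prob Probability of including the dense implant
#'   (default 0.25).
#' @return A [voxel_grid] centered on the isocenter, with attribute
#'   `structures` describing the generated components (including the lung
#'   masks and tumor locations).
#' @export
#' @examples
#' ph <- make_phantom(32, seed = 7)
#' range(ph$values)
make_phantom <- function(dims = 64, seed = NULL, fov_mm = 320,
                         complexity = 1, pacemaker_prob = 0.25) {
  dims <- rep(as.integer(dims), length.out = 3)
  stopifnot(all(dims >= 8), complexity >= 0, complexity <= 1)
  if (!is.null(seed)) set.seed(seed)
  spacing <- fov_mm / dims
  j <- function(nominal, spread) nominal + complexity * stats::runif(1, -spread, spread)
  # voxel-center coordinates (mm, isocenter at volume center)
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1] - fov_mm / 2
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2] - fov_mm / 2
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3] - fov_mm / 2
  X <- array(rep(cx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
  aa <- mean(spacing)  # anti-aliasing width: one voxel
  # signed "inside" weight of an ellipsoid, smoothed over one voxel
  ellipsoid <- function(c0, r0) {
    d <- sqrt(((X - c0[1]) / r0[1])^2 + ((Y - c0[2]) / r0[2])^2 +
              ((Z - c0[3]) / r0[3])^2)
    # approximate mm distance to the surface
    pmin(1, pmax(0, 0.5 + (1 - d) * min(r0) / aa))
  }
  vals <- array(0, dims)
  v_tissue <- 0.5; v_lung <- 0.15; v_spine <- 0.9
  v_tumor <- 0.6; v_pacer <- 1.0
  body_r <- c(j(0.42, 0.03), j(0.32, 0.03), 0.46) * fov_mm
  body <- ellipsoid(c(0, 0, 0), body_r)
  vals <- vals + v_tissue * body
  lungs <- array(0, dims)
  lung_info <- list()
  for (side in c(-1, 1)) {
    lc <- c(side * j(0.19, 0.02) * fov_mm, j(0.02, 0.02) * fov_mm, 0)
    lr <- c(j(0.13, 0.015), j(0.17, 0.02), j(0.30, 0.03)) * fov_mm
    lungs <- pmax(lungs, ellipsoid(lc, lr))
    lung_info[[length(lung_info) + 1]] <- list(center = lc, radii = lr)
  }
  vals <- vals + (v_lung - v_tissue) * lungs * body
  # spine: a cylinder along z at the posterior midline
  sc <- c(0, -j(0.22, 0.02) * fov_mm)
  sr <- j(0.045, 0.005) * fov_mm
  dxy <- sqrt((X - sc[1])^2 + (Y - sc[2])^2)
  spine <- pmin(1, pmax(0, 0.5 + (sr - dxy) / aa)) *
    pmin(1, pmax(0, 0.5 + (0.42 * fov_mm - abs(Z)) / aa))
  vals <- pmax(vals, v_spine * spine)
  # tumors: spheres fully inside a lung
  n_tumor <- sample(0:3, 1)
  tumors <- list()
  if (n_tumor > 0) for (ti in seq_len(n_tumor)) {
    li <- lung_info[[sample(length(lung_info), 1)]]
    tr <- stats::runif(1, 0.02, 0.045) * fov_mm
    # place inside the lung ellipsoid with margin tr
    frac <- pmax(0, 1 - tr / li$radii)
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum((u / frac)^2) <= 1) break
    }
    tc <- li$center + u * li$radii
    dt <- sqrt((X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2)
    tum <- pmin(1, pmax(0, 0.5 + (tr - dt) / aa))
    vals <- pmax(vals, v_tumor * tum)
    tumors[[ti]] <- list(center = tc, radius = tr)
  }
  pacer <- NULL
  if (stats::runif(1) < pacemaker_prob) {
    pc <- c(j(0.28, 0.02) * fov_mm, j(0.18, 0.02) * fov_mm, 0.25 * fov_mm)
    pr <- 0.03 * fov_mm
    dp <- sqrt((X - pc[1])^2 + (Y - pc[2])^2 + (Z - pc[3])^2)
    vals <- pmax(vals, v_pacer * pmin(1, pmax(0, 0.5 + (pr - dp) / aa)))
    pacer <- list(center = pc, radius = pr)
  }
  vals <- array(pmin(pmax(vals, 0), 1), dims)
  g <- voxel_grid(vals, spacing_mm = spacing)
  attr(g, "structures") <- list(
    values = c(tissue = v_tissue, lung = v_lung, spine = v_spine,
               tumor = v_tumor, pacemaker = v_pacer),
    body = list(radii = body_r), lungs = lung_info,
    lung_mask = lungs > 0.5, body_mask = body > 0.5,
    spine_mask = spine > 0.5, tumors = tumors, pacemaker = pacer)
  g
}

#' Map normalized attenuation to Hounsfield units
#'
#' Affine map fixing air (normalized 0) at -1000 HU and water (the nominal
#' soft-tissue value, normalized `water_value`) at 0 HU, used for reporting
#' RMSE on the clinical HU scale.
#'
#' @param v Normalized values in [0, 1].
#' @param water_value Normalized value corresponding to water (default 0.5).
#' @return Values in HU.
#' @export
normalized_to_hu <- function(v, water_value = 0.5) {
  v / water_value * 1000 - 1000
}

#' Synthetic multi-view acquisition dataset
#'
#' Generates `n_patients` random phantoms, each with a ring of DRRs at
#' equally spaced azimuths rendered by the Siddon projector, emulating the
#' standard data convention: projections min-max normalized to [0, 1], dense
#' reference sampling of 72 views every 5 degrees (configurable down to the
#' sparse regimes). Optionally writes volumes, projection stacks and a JSON
#' manifest to `dir`.
#'
#' @param n_patients Number of phantoms.
#' @param dims Phantom voxel counts per axis.
#' @param n_views Views per phantom (default 72).
#' @param start_deg Azimuth of the first view (default 0 = AP).
#' @param setup A [source_setup]; defaults to a detector matched to the
#'   phantom dimensions.
#' @param seed Optional integer seed (controls phantoms only; projection is
#'   deterministic).
#' @param dir Optional output directory (see [write_dataset]).
#' @param ... Passed to [make_phantom].
#' @return A `ct_dataset`: list with `patients` (each `volume`, `drrs` list of
#'   matrices, `poses`), `setup`, and `angles_deg`.
#' @export
make_dataset <- function(n_patients, dims = 64, n_views = 72, start_deg = 0,
                         setup = NULL, seed = NULL, dir = NULL, ...) {
  stopifnot(n_patients >= 1, n_views >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(setup)) {
    d <- rep(dims, length.out = 3)
    setup <- source_setup(det_rows = d[3], det_cols = max(d[1], d[2]))
  }
  poses <- make_circular_poses(n_views, start_deg)
  patients <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    vol <- make_phantom(dims, ...)
    drrs <- lapply(poses, function(ps) make_drr(vol, setup, ps))
    patients[[p]] <- list(id = sprintf("phantom%03d", p), volume = vol,
                          drrs = drrs, poses = poses)
  }
  ds <- structure(list(patients = patients, setup = setup,
                       angles_deg = vapply(poses, function(p) p$theta_deg, 0)),
                  class = "ct_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.ct_dataset <- function(x, ...) {
  cat(sprintf("<ct_dataset> %d patient(s), %d view(s) at angles %s...\n",
              length(x$patients), length(x$angles_deg),
              paste(utils::head(x$angles_deg, 4), collapse = ", ")))
  invisible(x)
}
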