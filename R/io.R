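#' Read and write attenuation volumes
#'
#' Supported formats: NIfTI (`.nii` / `.nii.gz`, spacing carried in the
#' header, via the RNifti package) and a raw float32 array (`.raw`) with a
#' JSON sidecar (`<file>.json` holding `dims`, `spacing_mm`, `origin_mm`).
#' Spacing and origin round-trip exactly; values are stored as float32.
#'
#' @param path File path; format chosen by extension.
#' @return `read_volume`: a [voxel_grid].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim(img))
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- attr(img, "tomofield_origin") %||% (-dim(img) * spacing / 2)
    voxel_grid(vals, spacing_mm = spacing, origin_mm = origin)
  } else if (grepl("\\.raw$", path)) {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    n <- prod(meta$dims)
    vals <- readBin(path, "double", n = n, size = 4)
    voxel_grid(array(vals, meta$dims), spacing_mm = meta$spacing_mm,
               origin_mm = meta$origin_mm)
  } else stop("unsupported volume format: ", path,
              " (expected .nii, .nii.gz or .raw)")
}

#' @rdname read_volume
#' @param grid A [voxel_grid].
#' @return `write_volume`: the path, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("writing NIfTI requires the RNifti package")
    img <- RNifti::asNifti(grid$values)
    RNifti::pixdim(img) <- grid$spacing_mm
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.raw$", path)) {
    writeBin(as.numeric(grid$values), path, size = 4)
    jsonlite::write_json(list(dims = grid$dims,
                              spacing_mm = grid$spacing_mm,
                              origin_mm = grid$origin_mm),
                         paste0(path, ".json"),
                         auto_unbox = FALSE, digits = NA)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read and write posed projection stacks
#'
#' A projection stack is a directory of float TIFF images (one per view)
#' plus a `poses.json` manifest listing, per view, the file name and the
#' pose angles, together with the geometry and a normalization flag. View
#' order follows the manifest.
#'
#' @param dir Directory containing the stack.
#' @return `read_projection_stack`: list with `projections` (list of
#'   matrices), `poses` (list of [pose]), `setup`, `normalized`.
#' @export
read_projection_stack <- function(dir) {
  manifest_path <- file.path(dir, "poses.json")
  if (!dir.exists(dir)) stop("projection directory not found: ", dir)
  if (!file.exists(manifest_path))
    stop("missing poses.json manifest in ", dir)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  files <- man$views$file
  if (length(files) == 0) stop("manifest lists no views")
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading projection stacks requires the tiff package")
  projections <- lapply(file.path(dir, files), function(f) {
    if (!file.exists(f)) stop("projection image missing: ", f)
    img <- tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  poses <- Map(pose, man$views$theta_deg,
               man$views$phi_deg %||% rep(0, length(files)))
  setup <- if (!is.null(man$geometry))
    do.call(source_setup, man$geometry[c("sad_mm", "sid_mm", "det_rows",
                                         "det_cols", "det_pitch_mm")])
  list(projections = projections, poses = poses, setup = setup,
       normalized = isTRUE(man$normalized))
}

#' @rdname read_projection_stack
#' @param projections List of projection matrices.
#' @param poses List of [pose]s (same length).
#' @param setup A [source_setup] recorded in the manifest.
#' @param normalized Flag recorded in the manifest.
#' @return `write_projection_stack`: the directory, invisibly.
#' @export
write_projection_stack <- function(projections, poses, dir, setup = NULL,
                                   normalized = TRUE) {
  if (length(projections) != length(poses))
    stop("projection/pose count mismatch: ", length(projections), " vs ",
         length(poses))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing projection stacks requires the tiff package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("view%03d.tif", seq_along(projections))
  for (i in seq_along(projections))
    tiff::writeTIFF(pmin(pmax(projections[[i]], 0), 1),
                    file.path(dir, files[i]), bits.per.sample = 32)
  man <- list(
    views = data.frame(file = files,
                       theta_deg = vapply(poses, function(p) p$theta_deg, 0),
                       phi_deg = vapply(poses, function(p) p$phi_deg, 0)),
    normalized = normalized)
  if (!is.null(setup)) man$geometry <- unclass(setup)
  jsonlite::write_json(man, file.path(dir, "poses.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Write a synthetic dataset to disk
#'
#' One sub-directory per patient with the volume (`volume.raw` + sidecar)
#' and the DRR stack, plus a top-level `manifest.json` linking patients,
#' angles and geometry.
#'
#' @param dataset A `ct_dataset` from [make_dataset].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(dataset$patients, function(p) p$id, "")
  for (p in dataset$patients) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    write_volume(p$volume, file.path(pd, "volume.raw"))
    write_projection_stack(p$drrs, p$poses, file.path(pd, "projections"),
                           setup = dataset$setup)
  }
  jsonlite::write_json(list(patients = ids,
                            angles_deg = dataset$angles_deg,
                            geometry = unclass(dataset$setup)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset]
#'
#' @param dir Dataset directory.
#' @return A `ct_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  setup <- do.call(source_setup, man$geometry[c("sad_mm", "sid_mm",
                                                "det_rows", "det_cols",
                                                "det_pitch_mm")])
  patients <- lapply(man$patients, function(id) {
    vol <- read_volume(file.path(dir, id, "volume.raw"))
    stk <- read_projection_stack(file.path(dir, id, "projections"))
    list(id = id, volume = vol, drrs = stk$projections, poses = stk$poses)
  })
  structure(list(patients = patients, setup = setup,
                 angles_deg = man$angles_deg), class = "ct_dataset")
}
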