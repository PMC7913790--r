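#' Load a DCE time series into a concentration stack
#'
#' Reads a dynamic series from a NIfTI-1 file (x, y, t; or x, y, z, t with
#' `slice_index`) or from an array file written by [write_stack_array()]
#' (`.rds` plus a JSON sidecar). A JSON sidecar named `<file>.json` next to
#' a NIfTI file overrides its header timing; without either a sidecar or a
#' positive time step in the header, loading fails rather than inventing a
#' default. Frames are reordered by acquisition time when the stored order
#' disagrees with the sidecar times.
#'
#' DICOM series directories are not supported; convert to NIfTI first (e.g.
#' with dcm2niix) and supply timing in the sidecar.
#'
#' @param source path to a `.nii`/`.nii.gz` or `.rds` file.
#' @param slice_index z-slice to extract from a 4D volume.
#' @param time_indices optional 1-based frame subset (applied after time
#'   ordering), e.g. from [select_spanning_frames()].
#' @param pre_contrast_count pre-contrast frame count; a sidecar value takes
#'   precedence.
#' @return A [conc_stack()].
#' @export
load_stack <- function(source, slice_index = NULL, time_indices = NULL,
                       pre_contrast_count = 1) {
  if (dir.exists(source))
    stop("DICOM series directories are not supported; convert the series ",
         "to NIfTI (x, y, t) with timing in a JSON sidecar")
  if (!file.exists(source)) stop("no such file: ", source)
  sidecar_path <- paste0(sub("\\.nii(\\.gz)?$|\\.rds$", "", source), ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)

  if (grepl("\\.rds$", source)) {
    frames <- readRDS(source)
    if (is.null(sidecar))
      stop("array input requires the JSON sidecar ", sidecar_path,
           " (frame_times, pixel_spacing, pre_contrast_count)")
    spacing <- sidecar$pixel_spacing
    times <- sidecar$frame_times
  } else if (grepl("\\.nii(\\.gz)?$", source)) {
    img <- RNifti::readNifti(source)
    d <- dim(img)
    if (length(d) == 4L) {
      if (is.null(slice_index))
        stop("4D volume: supply 'slice_index'")
      img <- img[, , slice_index, , drop = FALSE]
      dim(img) <- d[c(1L, 2L, 4L)]
    } else if (length(d) != 3L) {
      stop("expected a 3D (x, y, t) or 4D (x, y, z, t) NIfTI volume")
    }
    pd <- RNifti::pixdim(img)
    if (abs(pd[1L] - pd[2L]) > 1e-6 * max(pd[1:2]))
      stop("anisotropic in-plane pixel spacing is not supported")
    spacing <- pd[1L]
    ## storage frame: [row = y, col = x]; NIfTI stores x fastest
    frames <- aperm(unclass(img)[, , , drop = FALSE], c(2L, 1L, 3L))
    times <- if (!is.null(sidecar$frame_times)) sidecar$frame_times
    else if (length(pd) >= 3L && isTRUE(pd[3L] > 0))
      (seq_len(dim(frames)[3L]) - 1L) * pd[3L]
    else stop("no frame timing metadata: NIfTI time step is missing and ",
              "there is no JSON sidecar ", sidecar_path)
  } else {
    stop("unrecognized input format: ", source)
  }

  if (!is.null(sidecar)) {
    if (!is.null(sidecar$pixel_spacing)) spacing <- sidecar$pixel_spacing
    if (!is.null(sidecar$pre_contrast_count))
      pre_contrast_count <- sidecar$pre_contrast_count
    if (!is.null(sidecar$frame_times)) times <- sidecar$frame_times
  }
  if (length(times) != dim(frames)[3L])
    stop("frame timing metadata does not match the number of frames")
  ord <- order(times)
  frames <- frames[, , ord, drop = FALSE]
  times <- times[ord]
  if (any(diff(times) <= 0))
    stop("acquisition times are not strictly increasing after sorting")
  if (!is.null(time_indices)) {
    frames <- frames[, , time_indices, drop = FALSE]
    times <- times[time_indices]
    keep_pre <- sum(time_indices <= pre_contrast_count)
    pre_contrast_count <- keep_pre
  }
  if (dim(frames)[3L] < 4L)
    stop("fewer than 4 frames after selection")
  conc_stack(frames, times, pixel_spacing = spacing,
             pre_contrast_count = pre_contrast_count)
}

#' Write a concentration stack
#'
#' `write_stack_nifti()` writes an (x, y, t) NIfTI-1 volume plus a JSON
#' sidecar carrying `frame_times`, `pixel_spacing` and
#' `pre_contrast_count`; `write_stack_array()` writes the raw array as
#' `.rds` with the same sidecar. Both round-trip through [load_stack()].
#'
#' @param stack a [conc_stack()].
#' @param path output path (`.nii`/`.nii.gz` or `.rds`).
#' @return The path, invisibly.
#' @export
write_stack_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "conc_stack"))
  arr <- aperm(stack$frames, c(2L, 1L, 3L))  # back to x-fastest
  dts <- diff(stack$frame_times)
  img <- RNifti::asNifti(arr, reference = NULL)
  img <- RNifti::`pixdim<-`(img, c(stack$pixel_spacing, stack$pixel_spacing,
                                   mean(dts)))
  RNifti::writeNifti(img, path)
  write_stack_sidecar(stack, path)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
write_stack_array <- function(stack, path) {
  stopifnot(inherits(stack, "conc_stack"))
  saveRDS(stack$frames, path)
  write_stack_sidecar(stack, path)
  invisible(path)
}

write_stack_sidecar <- function(stack, path) {
  sidecar <- paste0(sub("\\.nii(\\.gz)?$|\\.rds$", "", path), ".json")
  jsonlite::write_json(
    list(frame_times = stack$frame_times,
         pixel_spacing = stack$pixel_spacing,
         pre_contrast_count = stack$pre_contrast_count),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Export transport maps
#'
#' Writes the diffusion map, velocity components, speed and status codes of
#' a fitted field as NIfTI volumes (one per map) plus a JSON provenance
#' sidecar (units, options, grid shape).
#'
#' @param field a [transport_field()] (typically a fit from
#'   [estimate_transport()]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_field_maps <- function(field, dir, prefix = "transport") {
  stopifnot(inherits(field, "transport_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list(D = field$diffusion_map, ux = field$velocity_x,
               uy = field$velocity_y, speed = velocity_magnitude(field))
  if (!is.null(field$status)) maps$status <- field$status + 0
  paths <- character(0)
  for (nm in names(maps)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    m <- maps[[nm]]
    m[is.na(m)] <- -1  # sentinel for invalid pixels in the exported volume
    RNifti::writeNifti(RNifti::asNifti(aperm(array(m, c(dim(m), 1L)),
                                             c(2L, 1L, 3L))), p)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, paste0(prefix, "_provenance.json"))
  jsonlite::write_json(
    list(units = field$units, pixel_spacing = field$pixel_spacing,
         frame_interval_s = field$frame_interval_s,
         shape = dim(field), invalid_sentinel = -1,
         n_valid = sum(field$valid_mask)),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
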