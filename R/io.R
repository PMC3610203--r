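# Readers and writers: contours (JSON/CSV), masks (NIfTI/TIFF/text),
# case loading with validation.

#' Write contours to JSON
#'
#' Schema: `{rv_insertion_angle_rad, slices: [{z_index, slice_span_mm,
#' pixel_spacing_mm: [dx, dy], grid_shape: [rows, cols],
#' endo: [[x, y], ...], epi: [[x, y], ...]}]}`.
#'
#' @param stack a [contour_stack()].
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_contours <- function(stack, path) {
  obj <- list(
    rv_insertion_angle_rad = stack$rv_insertion_angle,
    slices = lapply(stack$slices, function(sl) {
      list(
        z_index = sl$z_index,
        slice_span_mm = sl$slice_span,
        pixel_spacing_mm = sl$pixel_spacing,
        grid_shape = sl$grid_shape,
        endo = sl$endo,
        epi = sl$epi
      )
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read contours from JSON or CSV
#'
#' JSON follows the schema of [write_contours()]. The flat CSV dialect has
#' columns `slice, boundary, vertex_index, x_mm, y_mm` and carries no
#' metadata, so `pixel_spacing`, `slice_span`, `grid_shape` and
#' `rv_insertion_angle` must then be supplied as arguments.
#'
#' @param path input file (`.json` or `.csv`).
#' @param pixel_spacing,slice_span,grid_shape,rv_insertion_angle metadata
#'   for the CSV dialect (ignored for JSON).
#' @return A [contour_stack()].
#' @export
read_contours <- function(path, pixel_spacing = NULL, slice_span = NULL,
                          grid_shape = NULL, rv_insertion_angle = 0) {
  if (!file.exists(path)) {
    .stop_scarq(sprintf("contour file not found: %s", path), "scarq_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- tryCatch(
      jsonlite::read_json(path, simplifyVector = TRUE),
      error = function(e) .stop_scarq(
        sprintf("malformed contour JSON '%s': %s", path, conditionMessage(e)),
        "scarq_parse_error")
    )
    slices <- lapply(seq_len(nrow_or_len(obj$slices)), function(i) {
      s <- index_records(obj$slices, i)
      slice_geometry(as.matrix(s$endo), as.matrix(s$epi),
                     unlist(s$pixel_spacing_mm), s$slice_span_mm,
                     z_index = s$z_index, grid_shape = unlist(s$grid_shape))
    })
    contour_stack(slices, obj$rv_insertion_angle_rad)
  } else if (ext == "csv") {
    if (is.null(pixel_spacing) || is.null(slice_span) || is.null(grid_shape)) {
      .stop_scarq("CSV contours need pixel_spacing, slice_span and grid_shape",
                  "scarq_io_error")
    }
    df <- read.csv(path)
    need <- c("slice", "boundary", "vertex_index", "x_mm", "y_mm")
    if (!all(need %in% names(df))) {
      .stop_scarq("contour CSV must have columns slice, boundary, vertex_index, x_mm, y_mm",
                  "scarq_parse_error")
    }
    zs <- sort(unique(df$slice))
    slices <- lapply(seq_along(zs), function(i) {
      d <- df[df$slice == zs[i], ]
      poly <- function(b) {
        dd <- d[d$boundary == b, ]
        as.matrix(dd[order(dd$vertex_index), c("x_mm", "y_mm")])
      }
      slice_geometry(poly("endo"), poly("epi"), pixel_spacing, slice_span,
                     z_index = zs[i], grid_shape = grid_shape)
    })
    contour_stack(slices, rv_insertion_angle)
  } else {
    .stop_scarq(sprintf("unsupported contour format: .%s", ext), "scarq_io_error")
  }
}

#' @noRd
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' @noRd
index_records <- function(x, i) if (is.data.frame(x)) lapply(x, `[[`, i) else x[[i]]

#' Write contours to the flat CSV dialect
#'
#' @inheritParams write_contours
#' @export
write_contours_csv <- function(stack, path) {
  rows <- do.call(rbind, lapply(stack$slices, function(sl) {
    rbind(
      data.frame(slice = sl$z_index, boundary = "endo",
                 vertex_index = seq_len(nrow(sl$endo)) - 1L,
                 x_mm = sl$endo[, 1L], y_mm = sl$endo[, 2L]),
      data.frame(slice = sl$z_index, boundary = "epi",
                 vertex_index = seq_len(nrow(sl$epi)) - 1L,
                 x_mm = sl$epi[, 1L], y_mm = sl$epi[, 2L])
    )
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-slice mask volume
#'
#' The format follows the file extension: `.nii`/`.nii.gz` (NIfTI, rows x
#' cols x slices), `.tif`/`.tiff` (multi-page TIFF) or `.txt` (plain text:
#' one space-separated matrix per slice, slices separated by blank lines).
#' Nonzero = scar.
#'
#' @param masks list of matrices (logical or numeric), one per slice, or
#'   a [scar_raster()] (its binary masks are written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(masks, path) {
  if (inherits(masks, "scar_raster")) masks <- masks$masks
  masks <- lapply(masks, function(m) { m <- as.matrix(m) * 1; m })
  ext <- tolower(sub(".*?\\.(nii\\.gz|[[:alnum:]]+)$", "\\1", path))
  if (ext %in% c("nii", "nii.gz")) {
    arr <- array(unlist(masks), dim = c(dim(masks[[1L]]), length(masks)))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(masks, path, bits.per.sample = 8L)
  } else if (ext == "txt") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(masks)) {
      if (i > 1L) writeLines("", con)
      write.table(masks[[i]], con, row.names = FALSE, col.names = FALSE)
    }
  } else {
    .stop_scarq(sprintf("unsupported mask format: %s", path), "scarq_io_error")
  }
  invisible(path)
}

#' Read a per-slice mask volume
#'
#' @param path input path; format by extension as in [write_mask()].
#' @return list of numeric matrices, one per slice.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    .stop_scarq(sprintf("mask file not found: %s", path), "scarq_io_error")
  }
  ext <- tolower(sub(".*?\\.(nii\\.gz|[[:alnum:]]+)$", "\\1", path))
  if (ext %in% c("nii", "nii.gz")) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    lapply(seq_len(dim(arr)[3L]), function(i) arr[, , i])
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  } else if (ext == "txt") {
    txt <- readLines(path)
    breaks <- c(0L, which(txt == ""), length(txt) + 1L)
    out <- list()
    for (i in seq_len(length(breaks) - 1L)) {
      block <- txt[(breaks[i] + 1L):(breaks[i + 1L] - 1L)]
      block <- block[nzchar(block)]
      if (!length(block)) next
      out[[length(out) + 1L]] <-
        do.call(rbind, lapply(strsplit(block, "[[:space:]]+"), as.numeric))
    }
    out
  } else {
    .stop_scarq(sprintf("unsupported mask format: %s", path), "scarq_io_error")
  }
}

#' Load and validate a co-registered case
#'
#' Reads contours and scar mask, checks dimensional consistency slice by
#' slice, and clips scar pixels outside the rasterized myocardium (with a
#' warning reporting the clipped count).
#'
#' @param contours_path contour JSON/CSV path.
#' @param mask_path scar mask path (nonzero = scar).
#' @param intensity_path optional intensity volume path.
#' @param remote_intensity,core_intensity calibration for the intensity
#'   channel.
#' @param ... metadata passed to [read_contours()] for the CSV dialect.
#' @return list with `stack` (a [contour_stack()]) and `scar`
#'   (a [scar_raster()], clipped to the myocardium).
#' @export
load_case <- function(contours_path, mask_path, intensity_path = NULL,
                      remote_intensity = NULL, core_intensity = NULL, ...) {
  stack <- read_contours(contours_path, ...)
  masks <- read_mask(mask_path)
  if (length(masks) != length(stack$slices)) {
    .stop_scarq(sprintf("mask has %d slice(s) but contours have %d",
                        length(masks), length(stack$slices)), "scarq_shape_error")
  }
  for (i in seq_along(masks)) {
    gs <- stack$slices[[i]]$grid_shape
    if (!identical(dim(masks[[i]]), as.integer(gs))) {
      .stop_scarq(sprintf("slice z=%d: mask is %s but grid_shape is %s",
                          stack$slices[[i]]$z_index,
                          paste(dim(masks[[i]]), collapse = "x"),
                          paste(gs, collapse = "x")), "scarq_shape_error")
    }
  }
  intensity <- NULL
  if (!is.null(intensity_path)) {
    intensity <- read_mask(intensity_path)
    if (length(intensity) != length(masks)) {
      .stop_scarq("intensity volume slice count mismatch", "scarq_shape_error")
    }
  }
  scar <- scar_raster(lapply(masks, function(m) m != 0), intensity = intensity,
                      remote_intensity = remote_intensity,
                      core_intensity = core_intensity)
  myo <- rasterize_myocardium(stack)
  scar <- .clip_scar(scar, myo)
  list(stack = stack, scar = scar)
}

#' Write a phantom or loaded case to a directory
#'
#' Writes `contours.json` and `mask.<format>` side by side (plus
#' `truth.json` when a truth object is given), the layout [load_case()]
#' reads back.
#'
#' @param stack a [contour_stack()].
#' @param scar a [scar_raster()].
#' @param dir output directory (created if needed).
#' @param mask_format `"txt"`, `"nii"`, `"nii.gz"` or `"tiff"`.
#' @param truth optional [phantom_truth()] list to serialize.
#' @return Named character vector of the files written, invisibly.
#' @export
write_case <- function(stack, scar, dir, mask_format = "txt", truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(contours = file.path(dir, "contours.json"),
             mask = file.path(dir, paste0("mask.", mask_format)))
  write_contours(stack, paths[["contours"]])
  write_mask(scar, paths[["mask"]])
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  }
  invisible(paths)
}
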