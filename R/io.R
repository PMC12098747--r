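# Image I/O. In-memory conventions (used everywhere in the package):
#   ri    : numeric array (z, y, x), refractive-index values (~1.33-1.60)
#   rgb   : integer array (z, y, x, 3), 0..255
#   label : integer array (z, y, x), 0 = background, ids up to 65535
# 0-based pixel-centre coordinates, half-open patch windows.
#
# On disk: multi-page TIFF for all kinds (PNG also accepted for 2-D RGB).
# RI values are stored as 16-bit samples over a fixed physical window
# (quantization step ~5e-6 RI, far below imaging noise); a JSON sidecar
# `<path>.json` carries the metadata and the window so reads are
# self-describing. Write-read-write is bit-stable.

RI_STORE_WINDOW <- c(1.30, 1.65)

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta, extra = list()) {
  rec <- c(list(pixel_size_xy = meta$pixel_size_xy, z_step = meta$z_step,
                kind = meta$kind, axes = meta$axes), extra)
  jsonlite::write_json(rec, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

#' Write an image, volume or label mask
#'
#' @param img array in the package's in-memory convention (see
#'   [read_image()]); 2-D inputs are treated as single-slice volumes.
#' @param path output path; `.tif`/`.tiff`, or `.png` for 2-D RGB.
#' @param meta an [image_meta()] whose `kind` selects the encoding.
#' @return `path`, invisibly.
#' @seealso [read_image()]
#' @export
write_image <- function(img, path, meta) {
  stopifnot(inherits(meta, "image_meta"))
  img <- normalize_axes(img, meta$kind)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "png"))
    vs_error("vistain_format_error", sprintf("unsupported extension: .%s", ext))
  extra <- list()
  if (meta$kind == "ri") {
    lo <- RI_STORE_WINDOW[1]; hi <- RI_STORE_WINDOW[2]
    if (min(img) < lo || max(img) > hi)
      vs_error("vistain_value_error",
               sprintf("RI values outside storable window [%.2f, %.2f]", lo, hi))
    q <- round((img - lo) / (hi - lo) * 65535)
    pages <- lapply(seq_len(dim(q)[1]), function(z) q[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    extra$ri_window <- RI_STORE_WINDOW
  } else if (meta$kind == "label") {
    if (max(img) > 65535)
      vs_error("vistain_value_error", "label ids exceed 16-bit range")
    pages <- lapply(seq_len(dim(img)[1]), function(z) img[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else { # rgb
    if (min(img) < 0 || max(img) > 255)
      vs_error("vistain_value_error", "rgb values must lie in [0, 255]")
    if (ext == "png") {
      if (dim(img)[1] != 1)
        vs_error("vistain_format_error", "PNG supports a single slice only")
      png::writePNG(img[1, , , , drop = TRUE] / 255, path)
    } else {
      pages <- lapply(seq_len(dim(img)[1]),
                      function(z) img[z, , , , drop = TRUE] / 255)
      tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
    }
  }
  write_sidecar(path, meta, extra)
  invisible(path)
}

#' Read an image, volume or label mask
#'
#' Axes are normalized to `(z, y, x)` for single-channel data and
#' `(z, y, x, channel)` for RGB, so a 2-D RGB PNG comes back with shape
#' `(1, y, x, 3)`. Metadata is taken from the JSON sidecar written by
#' [write_image()]; without a sidecar, `expected_kind` and `default_meta`
#' fill in.
#'
#' @param path file to read.
#' @param expected_kind optional kind the caller requires; a mismatch with the
#'   stored kind (or with the file's channel structure) raises a
#'   `vistain_kind_error`.
#' @param default_meta [image_meta()] used when no sidecar exists.
#' @return list with elements `img` (array) and `meta` ([image_meta()]).
#' @export
read_image <- function(path, expected_kind = NULL, default_meta = NULL) {
  if (!file.exists(path))
    vs_error("vistain_io_error", sprintf("file not found: %s", path))
  side <- NULL
  if (file.exists(sidecar_path(path)))
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  kind <- side$kind %||% expected_kind %||% (default_meta$kind %||% NULL)
  if (is.null(kind))
    vs_error("vistain_kind_error",
             "value kind unknown: no sidecar and no expected_kind given")
  if (!is.null(expected_kind) && !identical(kind, expected_kind))
    vs_error("vistain_kind_error",
             sprintf("kind mismatch: file is '%s', caller expects '%s'",
                     kind, expected_kind))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch({
    if (ext == "png") list(png::readPNG(path))
    else tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }, error = function(e)
    vs_error("vistain_format_error",
             sprintf("cannot decode '%s' as an image: %s", path,
                     conditionMessage(e))))
  if (ext == "png") raw[[1]] <- round(raw[[1]] * 255)
  nch <- if (length(dim(raw[[1]])) == 3) dim(raw[[1]])[3] else 1L
  if (kind == "rgb" && nch != 3)
    vs_error("vistain_kind_error",
             sprintf("RGB requested but file has %d channel(s)", nch))
  if (kind != "rgb" && nch != 1)
    vs_error("vistain_kind_error",
             sprintf("'%s' requested but file has %d channels", kind, nch))
  nz <- length(raw)
  d <- dim(raw[[1]])
  img <- if (kind == "rgb") array(0, c(nz, d[1], d[2], 3))
         else array(0, c(nz, d[1], d[2]))
  for (z in seq_len(nz)) {
    if (kind == "rgb") img[z, , , ] <- raw[[z]] else img[z, , ] <- raw[[z]]
  }
  if (kind == "ri") {
    win <- as.numeric(side$ri_window %||% RI_STORE_WINDOW)
    img <- win[1] + img / 65535 * (win[2] - win[1])
  } else {
    storage.mode(img) <- "integer"
  }
  meta <- image_meta(
    pixel_size_xy = side$pixel_size_xy %||% default_meta$pixel_size_xy %||% 0.156,
    z_step = side$z_step %||% default_meta$z_step %||% 1.0,
    kind = kind)
  list(img = img, meta = meta)
}

# Coerce 2-D/3-D input to the canonical (z, y, x[, c]) layout.
normalize_axes <- function(img, kind) {
  nd <- length(dim(img) %||% integer(0))
  if (nd == 0 && is.matrix(img)) nd <- 2
  if (kind == "rgb") {
    if (nd == 3) img <- array(img, c(1, dim(img)))          # (y, x, 3)
    if (length(dim(img)) != 4 || dim(img)[4] != 3)
      vs_error("vistain_kind_error", "rgb arrays must end in a 3-channel axis")
  } else {
    if (nd == 2) img <- array(img, c(1, dim(img)))          # (y, x)
    if (length(dim(img)) != 3)
      vs_error("vistain_kind_error",
               sprintf("'%s' arrays must be (z, y, x)", kind))
  }
  img
}
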