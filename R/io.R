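io_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "scatterbmd_error")))
}

#' Read an image stack from disk
#'
#' Accepts either a NIfTI volume (`.nii` / `.nii.gz`; pixel spacing and
#' slice thickness from the header) or a directory of numbered 16-bit
#' TIFF/PNG slices with a `stack.yaml` sidecar holding the spacing
#' metadata. HU values are signed integers (TIFF/PNG slices store
#' `HU + 1024` as unsigned 16-bit).
#'
#' Failure modes raise distinct conditions: `scatterbmd_read_error`
#' (unreadable input), `scatterbmd_shape_error` (inconsistent slice
#' shapes), `scatterbmd_metadata_error` (missing spacing metadata).
#'
#' @param path NIfTI file or slice directory.
#' @return A `slice_stack` with `slice_index` 0..n-1.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) return(read_stack_dir(path))
  if (!file.exists(path))
    io_error(sprintf("no such file or directory: %s", path),
             "scatterbmd_read_error")
  if (!grepl("\\.nii(\\.gz)?$", path))
    io_error("expected a .nii/.nii.gz file or a slice directory",
             "scatterbmd_read_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    io_error(sprintf("failed to read NIfTI: %s",
                                     conditionMessage(e)),
                             "scatterbmd_read_error"))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 2L || any(pd[1:2] <= 0))
    io_error("NIfTI header lacks positive pixel spacing",
             "scatterbmd_metadata_error")
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  thickness <- if (length(pd) >= 3L && pd[3] > 0) pd[3] else 1
  slices <- lapply(seq_len(dim(arr)[3]), function(k)
    slice_image(matrix(as.numeric(arr[, , k]), dim(arr)[1], dim(arr)[2]),
                pixel_spacing = pd[1], slice_thickness = thickness,
                slice_index = k - 1L))
  new_slice_stack(slices)
}

read_stack_dir <- function(path) {
  meta_file <- file.path(path, "stack.yaml")
  if (!file.exists(meta_file))
    io_error("slice directory has no stack.yaml sidecar with spacing metadata",
             "scatterbmd_metadata_error")
  meta <- yaml::read_yaml(meta_file)
  if (is.null(meta$pixel_spacing) || is.null(meta$slice_thickness))
    io_error("stack.yaml must record pixel_spacing and slice_thickness",
             "scatterbmd_metadata_error")
  files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    io_error("slice directory contains no TIFF/PNG slices",
             "scatterbmd_read_error")
  mats <- lapply(files, read_slice_file)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    io_error("slices in the directory have inconsistent shapes",
             "scatterbmd_shape_error")
  slices <- lapply(seq_along(mats), function(k)
    slice_image(mats[[k]], pixel_spacing = meta$pixel_spacing,
                slice_thickness = meta$slice_thickness,
                slice_index = k - 1L))
  new_slice_stack(slices)
}

read_slice_file <- function(f) {
  raw <- if (grepl("\\.png$", f)) {
    round(png::readPNG(f) * 65535)
  } else {
    tiff::readTIFF(f, as.is = TRUE)
  }
  if (length(dim(raw)) != 2L)
    io_error(sprintf("slice %s is not a single-channel image", basename(f)),
             "scatterbmd_read_error")
  matrix(as.numeric(raw) - 1024, nrow(raw), ncol(raw))
}

#' Write an image stack to disk
#'
#' `format = "nifti"` writes one int16 NIfTI volume with pixel spacing
#' and slice thickness in the header. `format = "tiff"` writes numbered
#' 16-bit TIFF slices (`slice_000.tif`, ...; stored as `HU + 1024`
#' unsigned) plus a `stack.yaml` sidecar with the spacing metadata.
#' Round trips through [read_stack()] are lossless for integer HU data.
#'
#' @param stack a `slice_stack` or non-empty list of [slice_image()].
#' @param path output file (NIfTI) or directory (TIFF).
#' @param format `"nifti"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("nifti", "tiff")) {
  format <- match.arg(format)
  stack <- as_slice_list(stack)
  s1 <- stack[[1L]]
  if (format == "nifti") {
    arr <- array(0L, c(dim(s1$pixels), length(stack)))
    for (k in seq_along(stack)) arr[, , k] <- as.integer(stack[[k]]$pixels)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(s1$pixel_spacing, s1$pixel_spacing,
                             s1$slice_thickness)
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(stack)) {
      f <- file.path(path, sprintf("slice_%03d.tif", k - 1L))
      tiff::writeTIFF((stack[[k]]$pixels + 1024) / 65535, f,
                      bits.per.sample = 16L, compression = "none")
    }
    yaml::write_yaml(
      list(pixel_spacing = s1$pixel_spacing,
           slice_thickness = s1$slice_thickness,
           n_slices = length(stack), hu_offset = 1024),
      file.path(path, "stack.yaml"))
  }
  invisible(path)
}

#' Read and write flat key-value configuration files
#'
#' Phantom, scan and streak parameter blocks, threshold specs and seeds
#' travel as YAML. `parse_thresholds()` expands a `"start:stop:step"`
#' spec into an ascending HU vector.
#'
#' @param path YAML file path.
#' @param x a named list to serialize.
#' @return `read_config()`: a named list. `write_config()`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    io_error(sprintf("no such config file: %s", path),
             "scatterbmd_read_error")
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname read_config
#' @param spec threshold specification string `"start:stop:step"`.
#' @export
parse_thresholds <- function(spec) {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":")[[1L]]))
  if (length(parts) != 3L || any(!is.finite(parts)) || parts[3] <= 0 ||
      parts[2] < parts[1])
    stop("threshold spec must be 'start:stop:step' with stop >= start, step > 0")
  seq(parts[1], parts[2], by = parts[3])
}

#' Write a reproducibility manifest
#'
#' Records the configuration, master seed and package version needed to
#' reproduce a run bit-for-bit (deterministic stages) or count-for-count
#' (seeded stochastic stages).
#'
#' @param dir output directory.
#' @param config named list of run configuration.
#' @param seed master seed used.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(
    list(package = "scatterbmd",
         version = as.character(utils::packageVersion("scatterbmd")),
         seed = seed,
         config = config),
    path)
  invisible(path)
}
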