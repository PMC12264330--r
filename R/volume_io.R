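#' Construct a multi-contrast image volume
#'
#' An image volume is a 4D array indexed (slice, row, column, channel) with a
#' physical voxel spacing in millimetres. The seven channels hold co-registered
#' contrasts of the same anatomy (e.g. the magnitude/real/imaginary forms of a
#' multi-contrast MR acquisition).
#'
#' @param data 4D numeric array, dim `(N, H, W, C)`.
#' @param spacing Numeric length-3 voxel spacing `(slice, row, col)` in mm.
#' @param id Volume identifier string.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(2, 0.31, 0.31), id = "volume") {
  stopifnot(is.array(data), length(dim(data)) == 4)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing), id = as.character(id)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume '%s'> %d slices x %d x %d, %d channels, spacing %s mm\n",
              x$id, d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Construct a one-hot label mask
#'
#' Labels are stored in three-channel one-hot form with channel order
#' (lumen, vessel wall, background) and carry a registration-quality flag:
#' `"well_registered"` labels are trusted; `"misaligned"` labels may have a
#' displaced contour on part of the boundary and are handled by the
#' surrogate-label machinery during fine-tuning.
#'
#' @param onehot 4D `{0,1}` array, dim `(N, H, W, 3)`, channels summing to 1.
#' @param quality `"well_registered"` or `"misaligned"`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(onehot, quality = c("well_registered", "misaligned")) {
  quality <- match.arg(quality)
  stopifnot(is.array(onehot), length(dim(onehot)) == 4, dim(onehot)[4] == 3)
  if (!all(onehot %in% c(0, 1))) {
    stop("one-hot mask entries must be 0 or 1")
  }
  sums <- onehot[, , , 1] + onehot[, , , 2] + onehot[, , , 3]
  if (!all(sums == 1)) {
    stop("exactly one channel must be 1 at every voxel")
  }
  structure(list(onehot = onehot, quality = quality), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$onehot)
  counts <- apply(x$onehot, 4, sum)
  cat(sprintf("<label_mask> %d x %d x %d (%s); lumen %d, wall %d, background %d voxels\n",
              d[1], d[2], d[3], x$quality, counts[1], counts[2], counts[3]))
  invisible(x)
}

#' Normalize each channel to zero mean and unit variance
#'
#' Standardization is computed per channel over the whole volume using the
#' population standard deviation, prior to any windowing. Constant channels
#' are rejected (zero variance gives no intensity information and would
#' divide by zero).
#'
#' @param vol An [image_volume].
#' @return The normalized [image_volume].
#' @export
normalize_volume <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  m <- matrix(vol$data, ncol = d[4])
  mu <- colMeans(m)
  sdp <- sqrt(colMeans(m^2) - mu^2)
  if (any(sdp <= 0 | !is.finite(sdp))) {
    stop("degenerate input: channel(s) ",
         paste(which(sdp <= 0 | !is.finite(sdp)), collapse = ", "),
         " have zero variance")
  }
  m <- sweep(sweep(m, 2, mu, "-"), 2, sdp, "/")
  vol$data <- array(m, dim = d)
  vol
}

#' One-hot encode / decode a class map
#'
#' Class ids are 0 = lumen, 1 = vessel wall, 2 = background. Encoding and
#' decoding are exact inverses on valid class maps.
#'
#' @param class_map 3D integer array with values in `{0, 1, 2}`.
#' @param quality Registration-quality flag for the resulting mask.
#' @return `onehot_encode`: a [label_mask]; `onehot_decode`: a 3D integer array.
#' @export
onehot_encode <- function(class_map, quality = "well_registered") {
  stopifnot(is.array(class_map), length(dim(class_map)) == 3)
  if (!all(class_map %in% 0:2)) {
    stop("class map values must be in {0, 1, 2}")
  }
  d <- dim(class_map)
  onehot <- array(0, dim = c(d, 3))
  for (k in 0:2) {
    onehot[, , , k + 1][class_map == k] <- 1
  }
  label_mask(onehot, quality)
}

#' @param mask A [label_mask].
#' @rdname onehot_encode
#' @export
onehot_decode <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  d <- dim(mask$onehot)
  cm <- array(2L, dim = d[1:3])
  cm[mask$onehot[, , , 1] == 1] <- 0L
  cm[mask$onehot[, , , 2] == 1] <- 1L
  cm
}

#' Enumerate fixed-length slice windows of a volume
#'
#' The segmentation model operates on windows of exactly 8 consecutive
#' slices. A volume with N = 8 yields one window; 8 < N <= 16 yields two
#' windows covering the first and last eight slices (so mid-volume slices are
#' covered twice and predictions are averaged at inference). Volumes with
#' N > 16 cannot be covered by two windows: in `"strict"` mode they are
#' rejected, in `"permissive"` mode they are tiled with stride 8 plus a final
#' flush window.
#'
#' @param vol An [image_volume], or a single integer slice count.
#' @param mode `"strict"` (default) or `"permissive"`.
#' @return Integer vector of 0-based window start indices (windows are
#'   half-open `[start, start + 8)`).
#' @export
enumerate_windows <- function(vol, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  n <- if (inherits(vol, "image_volume")) dim(vol$data)[1] else as.integer(vol)
  if (n < 8) stop("volume must have at least 8 slices, got ", n)
  if (n == 8) return(0L)
  if (n <= 16) return(c(0L, n - 8L))
  if (mode == "strict") {
    stop("volume has ", n, " slices; two 8-slice windows cannot cover it ",
         "(use mode = \"permissive\" to tile)")
  }
  starts <- seq(0L, n - 8L, by = 8L)
  if (starts[length(starts)] != n - 8L) starts <- c(starts, n - 8L)
  starts
}

#' Extract one 8-slice window from a volume (and optionally its label)
#'
#' @param vol An [image_volume].
#' @param start 0-based start slice index.
#' @param label Optional matching [label_mask].
#' @return A list with `start_index`, `data` (8 x H x W x C array) and
#'   `label` (8 x H x W x 3 one-hot array or `NULL`).
#' @export
extract_window <- function(vol, start, label = NULL) {
  n <- dim(vol$data)[1]
  stopifnot(start >= 0, start + 8 <= n)
  idx <- seq.int(start + 1, start + 8)
  out <- list(start_index = as.integer(start),
              data = vol$data[idx, , , , drop = FALSE],
              label = NULL)
  if (!is.null(label)) {
    out$label <- label$onehot[idx, , , , drop = FALSE]
    out$quality <- label$quality
  }
  out
}

#' Read / write volumes and label masks as NIfTI
#'
#' Images are stored as 4D NIfTI files with 7 channels in the 4th dimension;
#' labels are stored compactly as 3D integer class maps (0 = lumen,
#' 1 = wall, 2 = background) and expanded to one-hot in memory.
#'
#' @param path Path of a `.nii`/`.nii.gz` image file.
#' @param label_path Optional path to a class-map label file.
#' @param quality Quality flag to attach to the label.
#' @param id Volume identifier; defaults to the file name.
#' @return `read_volume`: a list with `volume` ([image_volume]) and `label`
#'   ([label_mask] or `NULL`).
#' @export
read_volume <- function(path, label_path = NULL, quality = "well_registered",
                        id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) {
    stop("expected a 4D image (slices x H x W x channels), got ",
         length(dim(arr)), "D in ", path)
  }
  if (dim(arr)[4] != 7) {
    stop("expected 7 contrast channels, got ", dim(arr)[4], " in ", path)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  vol <- image_volume(arr, spacing = spacing,
                      id = if (is.null(id)) sub("\\.nii(\\.gz)?$", "", basename(path)) else id)
  lab <- NULL
  if (!is.null(label_path)) {
    larr <- as.array(RNifti::readNifti(label_path))
    if (length(dim(larr)) != 3) {
      stop("expected a 3D class-map label, got ", length(dim(larr)), "D in ", label_path)
    }
    storage.mode(larr) <- "integer"
    lab <- onehot_encode(larr, quality = quality)
  }
  list(volume = vol, label = lab)
}

#' @param vol An [image_volume] to write.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param mask A [label_mask] to write (stored as a class map).
#' @param spacing Voxel spacing recorded in the label header.
#' @rdname read_volume
#' @export
write_mask <- function(mask, path, spacing = c(2, 0.31, 0.31)) {
  cm <- onehot_decode(mask)
  img <- RNifti::asNifti(cm)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with columns `volume_id`, `image_path`, `label_path`,
#' `quality` and `split`; paths are interpreted relative to the manifest's
#' directory unless absolute.
#'
#' @param path Manifest CSV path.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  mf <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("volume_id", "image_path", "label_path", "quality", "split")
  if (!all(need %in% names(mf))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  for (col in c("image_path", "label_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", mf[[col]]) & nzchar(mf[[col]])
    mf[[col]][rel] <- file.path(base, mf[[col]][rel])
  }
  mf
}

#' @param manifest A manifest data.frame.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load every volume referenced by a manifest into memory
#'
#' @param manifest A manifest data.frame (see [read_manifest]).
#' @param normalize Standardize channels after reading (default `TRUE`).
#' @return A list with one entry per split; each entry is a list of
#'   `list(volume, label)` pairs.
#' @export
load_dataset <- function(manifest, normalize = TRUE) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- read_volume(row$image_path,
                       label_path = if (nzchar(row$label_path)) row$label_path else NULL,
                       quality = row$quality, id = row$volume_id)
    if (normalize) rec$volume <- normalize_volume(rec$volume)
    out[[row$split]] <- c(out[[row$split]], list(rec))
  }
  out
}
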