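#' Configuration for synthetic multi-contrast vessel phantoms
#'
#' Phantoms emulate axial slices of a carotid-style vessel: a circular lumen
#' of radius `lumen_radius` inside an annular wall extending to `wall_radius`,
#' on a textured background, with the vessel centerline drifting sinusoidally
#' in-plane across slices. Each of the 7 channels draws voxel intensities
#' from a class-dependent mean plus correlated Gaussian noise, so channels
#' differ in how well they separate the three classes (some are
#' near-uninformative, mimicking variable contrast between acquisitions).
#'
#' @param N,H,W Volume dimensions (slices, rows, columns).
#' @param lumen_radius,wall_radius Radii in voxels; `wall_radius > lumen_radius >= 2`.
#' @param centerline_amplitude In-plane sinusoidal drift amplitude in voxels.
#' @param class_channel_means 3 x 7 matrix of mean intensities, rows =
#'   (lumen, wall, background).
#' @param noise_sd Gaussian noise standard deviation.
#' @param noise_cor Correlation of the noise shared across channels, in `[0, 1)`.
#' @param texture_sd Amplitude of a smooth random in-plane intensity ramp
#'   added to all channels (0 disables the texture).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(N = 8, H = 64, W = 64,
                           lumen_radius = 6, wall_radius = 10,
                           centerline_amplitude = 3,
                           class_channel_means = default_channel_means(),
                           noise_sd = 1, noise_cor = 0.3, texture_sd = 0.3,
                           spacing = c(2, 0.31, 0.31), seed = 1L) {
  stopifnot(lumen_radius >= 2, wall_radius > lumen_radius,
            wall_radius + centerline_amplitude < min(H, W) / 2,
            N >= 1, noise_sd >= 0, noise_cor >= 0, noise_cor < 1,
            is.matrix(class_channel_means),
            nrow(class_channel_means) == 3, ncol(class_channel_means) == 7)
  structure(list(N = N, H = H, W = W, lumen_radius = lumen_radius,
                 wall_radius = wall_radius,
                 centerline_amplitude = centerline_amplitude,
                 class_channel_means = class_channel_means,
                 noise_sd = noise_sd, noise_cor = noise_cor,
                 texture_sd = texture_sd, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default class-by-channel mean intensities
#'
#' Classes separate well in some channels (1, 3, 4), weakly in others, and
#' not at all in channels 6-7, emulating the variable lumen/wall/background
#' contrast across a multi-contrast acquisition.
#'
#' @return A 3 x 7 numeric matrix, rows = (lumen, wall, background).
#' @export
default_channel_means <- function() {
  rbind(lumen      = c( 2.0, -1.5,  1.8,  0.0, 1.2, 0.3, 0.0),
        wall       = c( 0.5,  0.8, -0.6,  1.5, 0.0, 0.3, 0.0),
        background = c(-0.8,  0.0,  0.0, -0.5, 0.6, 0.3, 0.0))
}

# Per-slice centerline of the phantom vessel: (row, col) centers.
phantom_centerline <- function(cfg, phase) {
  s <- seq_len(cfg$N) - 1
  cy <- (cfg$H + 1) / 2 + cfg$centerline_amplitude * sin(2 * pi * s / cfg$N + phase[1])
  cx <- (cfg$W + 1) / 2 + cfg$centerline_amplitude * cos(2 * pi * s / cfg$N + phase[2])
  cbind(cy, cx)
}

#' Generate one synthetic phantom volume with its ground-truth label
#'
#' The label is derived exactly from the geometry: a voxel is lumen iff its
#' in-plane distance to the slice centerline is `< lumen_radius`, wall iff
#' the distance lies in `[lumen_radius, wall_radius)`, background otherwise.
#' Channel intensities are the class mean plus texture and correlated noise;
#' the returned image is channel-normalized unless `normalize = FALSE`.
#'
#' @param cfg A [phantom_config].
#' @param normalize Standardize channels of the output (default `TRUE`).
#' @param id Volume identifier.
#' @return A list with `volume` ([image_volume]) and `label` ([label_mask]).
#' @export
generate_phantom <- function(cfg, normalize = TRUE, id = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  with_rng(cfg$seed, {
    phase <- runif(2, 0, 2 * pi)
    centers <- phantom_centerline(cfg, phase)
    cm <- array(2L, dim = c(cfg$N, cfg$H, cfg$W))
    rows <- matrix(seq_len(cfg$H), cfg$H, cfg$W)
    cols <- matrix(seq_len(cfg$W), cfg$H, cfg$W, byrow = TRUE)
    for (s in seq_len(cfg$N)) {
      dist <- sqrt((rows - centers[s, 1])^2 + (cols - centers[s, 2])^2)
      sl <- matrix(2L, cfg$H, cfg$W)
      sl[dist < cfg$wall_radius] <- 1L
      sl[dist < cfg$lumen_radius] <- 0L
      cm[s, , ] <- sl
    }
    img <- array(0, dim = c(cfg$N, cfg$H, cfg$W, 7))
    means <- cfg$class_channel_means
    # smooth texture: a random in-plane ramp, identical across channels
    g <- rnorm(2, sd = cfg$texture_sd)
    ramp <- g[1] * (rows - cfg$H / 2) / cfg$H + g[2] * (cols - cfg$W / 2) / cfg$W
    nvox <- cfg$N * cfg$H * cfg$W
    shared <- array(rnorm(nvox), dim = c(cfg$N, cfg$H, cfg$W))
    a <- sqrt(cfg$noise_cor)
    b <- sqrt(1 - cfg$noise_cor)
    for (c in 1:7) {
      ch <- means[cm + 1L, c]
      dim(ch) <- dim(cm)
      eps <- array(rnorm(nvox), dim = dim(cm))
      noise <- cfg$noise_sd * (a * shared + b * eps)
      for (s in seq_len(cfg$N)) ch[s, , ] <- ch[s, , ] + ramp
      img[, , , c] <- ch + noise
    }
    vol <- image_volume(img, spacing = cfg$spacing, id = id)
    if (normalize) vol <- normalize_volume(vol)
    list(volume = vol, label = onehot_encode(cm))
  })
}

#' Specification of label misalignment to inject into a phantom
#'
#' Two corruption modes mimic registration error between the modality the
#' contours were drawn on and the target image. `"slice_shift"` translates
#' the entire label of affected slices by `shift` voxels (a whole-slice
#' mapping error). `"sector_displace"` moves only the part of the lumen and
#' outer boundaries whose polar angle (about the slice foreground centroid)
#' falls inside `sector`, then re-rasterizes — reproducing the partial-contour
#' misalignment seen in practice, where only a portion of the drawn contour
#' misses the vessel.
#'
#' @param mode `"sector_displace"` (default) or `"slice_shift"`.
#' @param shift Integer `(drow, dcol)` displacement in voxels.
#' @param sector Numeric `(start, end)` angles in degrees (span in (0, 360]).
#' @param affected_slices 0-based slice indices to corrupt.
#' @return A `misalignment_spec` list.
#' @export
misalignment_spec <- function(mode = c("sector_displace", "slice_shift"),
                              shift = c(3, 0), sector = c(90, 210),
                              affected_slices = 0:7) {
  mode <- match.arg(mode)
  span <- sector[2] - sector[1]
  stopifnot(length(shift) == 2, span > 0, span <= 360)
  structure(list(mode = mode, shift = shift, sector = sector,
                 affected_slices = as.integer(affected_slices)),
            class = "misalignment_spec")
}

# Star-convex boundary polygon of a binary region about `centroid`:
# max radius per angular wedge (empty wedges interpolated circularly).
region_polygon <- function(region, centroid, n_vertices = 180) {
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  dy <- idx[, 1] - centroid[1]
  dx <- idx[, 2] - centroid[2]
  theta <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dy^2 + dx^2) + 0.5  # half-pixel so the polygon covers the raster
  wedge <- floor(theta / (2 * pi) * n_vertices) + 1
  rad <- rep(NA_real_, n_vertices)
  agg <- tapply(r, wedge, max)
  rad[as.integer(names(agg))] <- agg
  if (anyNA(rad)) {
    # circular nearest-neighbour fill for wedges with no pixel
    known <- which(!is.na(rad))
    for (j in which(is.na(rad))) {
      d <- pmin(abs(known - j), n_vertices - abs(known - j))
      rad[j] <- rad[known[which.min(d)]]
    }
  }
  ang <- (seq_len(n_vertices) - 0.5) / n_vertices * 2 * pi
  cbind(row = centroid[1] + rad * sin(ang),
        col = centroid[2] + rad * cos(ang),
        angle = ang)
}

# Even-odd point-in-polygon test, vectorized over pixel centers.
points_in_polygon <- function(py, px, poly) {
  inside <- rep(FALSE, length(py))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    y1 <- poly[i, 1]; x1 <- poly[i, 2]
    y2 <- poly[j, 1]; x2 <- poly[j, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Inject misalignment into a label mask
#'
#' Affected slices are corrupted according to the [misalignment_spec];
#' unaffected slices are bit-identical to the input. The output is a valid
#' one-hot mask flagged `"misaligned"`.
#'
#' @param label A valid [label_mask].
#' @param spec A [misalignment_spec].
#' @return The corrupted [label_mask].
#' @export
corrupt_label <- function(label, spec) {
  stopifnot(inherits(label, "label_mask"), inherits(spec, "misalignment_spec"))
  cm <- onehot_decode(label)
  d <- dim(cm)
  if (all(spec$shift == 0)) {
    out <- label
    out$quality <- "misaligned"
    return(out)
  }
  for (s0 in spec$affected_slices) {
    s <- s0 + 1L
    stopifnot(s >= 1, s <= d[1])
    sl <- cm[s, , ]
    if (!any(sl < 2)) stop("empty foreground on affected slice ", s0)
    if (spec$mode == "slice_shift") {
      new <- matrix(2L, d[2], d[3])
      dr <- spec$shift[1]; dc <- spec$shift[2]
      r_src <- seq_len(d[2]) - dr
      c_src <- seq_len(d[3]) - dc
      ok_r <- r_src >= 1 & r_src <= d[2]
      ok_c <- c_src >= 1 & c_src <= d[3]
      new[ok_r, ok_c] <- sl[r_src[ok_r], c_src[ok_c]]
      cm[s, , ] <- new
    } else {
      fg <- sl < 2
      centroid <- c(mean(which(fg, arr.ind = TRUE)[, 1]),
                    mean(which(fg, arr.ind = TRUE)[, 2]))
      outer_poly <- region_polygon(fg, centroid)
      lumen_poly <- region_polygon(sl == 0, centroid)
      displace <- function(poly) {
        if (is.null(poly)) return(NULL)
        deg <- poly[, "angle"] * 180 / pi
        rel <- (deg - spec$sector[1]) %% 360
        span <- spec$sector[2] - spec$sector[1]
        in_sector <- rel <= span
        poly[in_sector, "row"] <- poly[in_sector, "row"] + spec$shift[1]
        poly[in_sector, "col"] <- poly[in_sector, "col"] + spec$shift[2]
        poly
      }
      outer_poly <- displace(outer_poly)
      lumen_poly <- displace(lumen_poly)
      py <- as.vector(matrix(seq_len(d[2]), d[2], d[3]))
      px <- as.vector(matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE))
      new <- rep(2L, d[2] * d[3])
      new[points_in_polygon(py, px, outer_poly)] <- 1L  # wall painted first
      if (!is.null(lumen_poly)) {
        new[points_in_polygon(py, px, lumen_poly)] <- 0L
      }
      cm[s, , ] <- matrix(new, d[2], d[3])
    }
  }
  onehot_encode(cm, quality = "misaligned")
}

#' Generate an in-memory phantom dataset with clean and misaligned labels
#'
#' The first `n_clean` volumes keep their exact geometric labels; the
#' remaining `n_misaligned` are served corrupted labels (the clean label is
#' retained separately for oracle evaluation). Per-volume seeds, misalignment
#' direction and sector placement, and the affected-slice subset are derived
#' deterministically from the master seed.
#'
#' @param n_clean,n_misaligned Volume counts.
#' @param cfg A [phantom_config] (its `seed` is ignored in favour of per-volume
#'   derived seeds).
#' @param spec A [misalignment_spec] template.
#' @param seed Master seed.
#' @param vary Per-volume randomization of the misalignment placement:
#'   `"slices"` (default) keeps the spec's shift and sector fixed across
#'   volumes — emulating a systematic registration bias — but draws a random
#'   75% subset of affected slices per volume; `"all"` additionally rotates
#'   the shift direction and sector start per volume (zero-mean,
#'   non-systematic noise); `"none"` applies the spec verbatim to every
#'   misaligned volume.
#' @param prefix Volume-id prefix.
#' @param jitter Relative per-volume geometry jitter: vessel radii and
#'   centerline amplitude are scaled by independent uniform factors in
#'   `[1 - jitter, 1 + jitter]`, emulating anatomical variation in vessel
#'   caliber across subjects (0 disables).
#' @return A list of records `list(volume, label, clean_label)`.
#' @export
generate_phantom_dataset <- function(n_clean, n_misaligned, cfg,
                                     spec = misalignment_spec(),
                                     seed = 1L,
                                     vary = c("slices", "all", "none"),
                                     prefix = "phantom", jitter = 0.2) {
  stopifnot(n_clean >= 0, n_misaligned >= 0, jitter >= 0, jitter < 0.5)
  vary <- match.arg(vary)
  out <- list()
  total <- n_clean + n_misaligned
  for (i in seq_len(total)) {
    vs <- derive_seed(seed, paste0("vol", i))
    cfg_i <- cfg
    cfg_i$seed <- vs
    if (jitter > 0) {
      with_rng(derive_seed(seed, paste0("geom", i)), {
        rs <- runif(1, 1 - jitter, 1 + jitter)
        cfg_i$lumen_radius <- cfg$lumen_radius * rs
        cfg_i$wall_radius <- cfg$wall_radius * rs
        cfg_i$centerline_amplitude <-
          cfg$centerline_amplitude * runif(1, 1 - jitter, 1 + jitter)
      })
    }
    id <- sprintf("%s_%03d", prefix, i)
    rec <- generate_phantom(cfg_i, id = id)
    rec$clean_label <- rec$label
    if (i > n_clean) {
      spec_i <- spec
      if (vary != "none") {
        with_rng(derive_seed(seed, paste0("mis", i)), {
          if (vary == "all") {
            ang <- runif(1, 0, 2 * pi)
            mag <- sqrt(sum(spec$shift^2))
            spec_i$shift <- round(mag * c(sin(ang), cos(ang)))
            if (all(spec_i$shift == 0)) spec_i$shift <- c(round(mag), 0)
            rot <- runif(1, 0, 360)
            spec_i$sector <- (spec$sector - spec$sector[1] + rot)
          }
          n <- dim(rec$label$onehot)[1]
          spec_i$affected_slices <- sort(sample.int(n, ceiling(0.75 * n)) - 1L)
        })
      }
      rec$label <- corrupt_label(rec$clean_label, spec_i)
    }
    out[[id]] <- rec
  }
  out
}

#' Write a phantom dataset to disk with a manifest
#'
#' Volumes and served labels are written as NIfTI; misaligned volumes
#' additionally get a `*_clean.nii.gz` file holding the uncorrupted label for
#' oracle evaluation (not referenced by the manifest).
#'
#' @inheritParams generate_phantom_dataset
#' @param out_dir Output directory (created if missing).
#' @param split Split name written to the manifest.
#' @return The manifest data.frame (invisibly writes `manifest.csv`).
#' @export
generate_dataset <- function(n_clean, n_misaligned, cfg,
                             spec = misalignment_spec(), seed = 1L,
                             out_dir, split = "train", vary = "slices") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_phantom_dataset(n_clean, n_misaligned, cfg, spec,
                                   seed = seed, vary = vary)
  rows <- list()
  for (id in names(recs)) {
    rec <- recs[[id]]
    ipath <- file.path(out_dir, paste0(id, ".nii.gz"))
    lpath <- file.path(out_dir, paste0(id, "_label.nii.gz"))
    write_volume(rec$volume, ipath)
    write_mask(rec$label, lpath, spacing = rec$volume$spacing)
    if (rec$label$quality == "misaligned") {
      write_mask(rec$clean_label, file.path(out_dir, paste0(id, "_clean.nii.gz")),
                 spacing = rec$volume$spacing)
    }
    rows[[id]] <- data.frame(volume_id = id,
                             image_path = basename(ipath),
                             label_path = basename(lpath),
                             quality = rec$label$quality,
                             split = split,
                             stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
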