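## Synthetic OCT / D-OCT phantom volumes. The structural channel renders a
## rough air-tissue interface, an epidermal dark band over a brighter
## dermis, and a dermal pattern (glabrous ridge lines or a jittered grid of
## dark papillary spots) in a band 0.3 mm below the surface; the vascular
## channel renders an arborizing en-face vessel tree in the depth slab of
## the papillary plexus. Everything is deterministic given the seed, and
## the generative ground truth travels with the volume.

I_AIR     <- 0.05
I_EPI     <- 0.25
I_DERMIS  <- 0.70
ATTEN_PER_UM <- 1e-4          # gentle signal falloff with depth
PATTERN_DEPTH_UM <- 300       # skin lines / papillary spots live here
PATTERN_HALFW_UM <- 60
LINE_PERIOD_UM   <- 350
SPOT_SPACING_UM  <- 300
SPOT_RADIUS_UM   <- 55
SPOT_JITTER_UM   <- 40
PATTERN_AMP   <- c(0.8, 0.3, 0)    # glabrous line contrast per level
SPOT_KEEP     <- c(1, 0.5, 0)      # fraction of papillary spots per level
VESSEL_SLAB_UM   <- 300       # centre of the vascular slab below surface
VESSEL_SLAB_SD_UM <- 100
TRUNK_WIDTH_UM   <- 150
WIDTH_DECAY      <- 0.72
LENGTH_DECAY     <- 0.8
TRUNK_LENGTH_UM  <- 900
MIN_WIDTH_UM     <- 35
PRUNE_QUANTILE   <- 0.85      # vascular level 1 drops widths below this

#' Specification of a synthetic OCT phantom
#'
#' Generative parameters with known ground-truth grades. Degradation
#' levels follow the score items: `dermal_pattern_level` 0 renders crisp
#' skin lines (glabrous) or a full spot grid (hair-bearing), 1 an
#' attenuated/partial pattern, 2 none; `vascular_level` 0 renders the full
#' arborized tree, 1 prunes the thinnest vessels, 2 keeps only unbranched
#' trunks.
#'
#' @param skin_type `"glabrous"` or `"hair_bearing"`.
#' @param surface_roughness_um RMS height deviation of the air-tissue
#'   interface, micrometres (healthy skin ~8, burned ~40).
#' @param epidermis_present logical; `FALSE` removes the dark epidermal
#'   band (blistering at the dermo-epidermal junction).
#' @param epidermis_thickness_um epidermal band thickness.
#' @param dermal_pattern_level 0/1/2 as above.
#' @param vascular_level 0/1/2 as above.
#' @param noise_sd additive truncated-Gaussian noise scale, both channels.
#' @param seed integer seed; identical spec + seed give identical volumes.
#' @param field_mm lateral extent (y, x) in millimetres.
#' @param depth_mm imaged depth, at most 2 mm.
#' @param voxel_um voxel pitch `c(dz, dy, dx)` in micrometres.
#' @param tilt_um height difference across the x extent (a tilted scan
#'   head); graders must be invariant to it.
#' @param surface_depth_um mean depth of the surface below the top of the
#'   volume (air gap).
#' @return Validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(skin_type = "hair_bearing",
                         surface_roughness_um = 8,
                         epidermis_present = TRUE,
                         epidermis_thickness_um = 100,
                         dermal_pattern_level = 0L,
                         vascular_level = 0L,
                         noise_sd = 0.03,
                         seed = 1L,
                         field_mm = c(6, 6),
                         depth_mm = 1.0,
                         voxel_um = c(dz = 4, dy = 12, dx = 12),
                         tilt_um = 0,
                         surface_depth_um = 200) {
  validate_skin_type(skin_type)
  if (!is_whole_number(dermal_pattern_level) || dermal_pattern_level < 0L ||
      dermal_pattern_level > 2L) {
    stopf("invalid spec: dermal_pattern_level must be 0, 1 or 2")
  }
  if (!is_whole_number(vascular_level) || vascular_level < 0L ||
      vascular_level > 2L) {
    stopf("invalid spec: vascular_level must be 0, 1 or 2")
  }
  if (epidermis_present && epidermis_thickness_um <= 0) {
    stopf("invalid spec: epidermis_thickness_um must be > 0 when present")
  }
  if (surface_roughness_um < 0 || noise_sd < 0) {
    stopf("invalid spec: roughness and noise_sd must be nonnegative")
  }
  if (depth_mm <= 0 || depth_mm > 2) {
    stopf("invalid spec: depth_mm must be in (0, 2]")
  }
  if (length(field_mm) != 2L || any(field_mm <= 0)) {
    stopf("invalid spec: field_mm must be two positive extents")
  }
  if (length(voxel_um) != 3L || any(voxel_um <= 0)) {
    stopf("invalid spec: voxel_um must be c(dz, dy, dx), all positive")
  }
  if (!is_whole_number(seed)) stopf("invalid spec: seed must be an integer")
  structure(list(
    skin_type = skin_type,
    surface_roughness_um = surface_roughness_um,
    epidermis_present = isTRUE(epidermis_present),
    epidermis_thickness_um = epidermis_thickness_um,
    dermal_pattern_level = as.integer(dermal_pattern_level),
    vascular_level = as.integer(vascular_level),
    noise_sd = noise_sd,
    seed = as.integer(seed),
    field_mm = as.numeric(field_mm),
    depth_mm = depth_mm,
    voxel_um = stats::setNames(as.numeric(voxel_um), c("dz", "dy", "dx")),
    tilt_um = tilt_um,
    surface_depth_um = surface_depth_um
  ), class = "phantom_spec")
}

#' Construct an OCT volume container
#'
#' @param structural,vascular 3-D arrays indexed (z, y, x), values in
#'   \[0, 1\]; z increases with depth.
#' @param voxel_um voxel pitch `c(dz, dy, dx)` in micrometres.
#' @return Object of class `oct_volume`.
#' @export
oct_volume <- function(structural, vascular, voxel_um) {
  if (!identical(dim(structural), dim(vascular)) ||
      length(dim(structural)) != 3L) {
    stopf("structural and vascular channels must be 3-D arrays of one shape")
  }
  rng <- range(structural, vascular)
  if (rng[1] < 0 || rng[2] > 1) stopf("voxel values must lie in [0, 1]")
  structure(list(structural = structural, vascular = vascular,
                 voxel_um = stats::setNames(as.numeric(voxel_um),
                                            c("dz", "dy", "dx"))),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$structural)
  v <- x$voxel_um
  cat(sprintf(
    "OCT volume: %d x %d x %d voxels (z,y,x), %.0f x %.0f um lateral field, %.0f um deep\n",
    d[1], d[2], d[3], d[2] * v["dy"], d[3] * v["dx"], d[1] * v["dz"]))
  invisible(x)
}

## Smooth Gaussian random surface with exact RMS, in micrometres.
rough_surface <- function(ny, nx, dy, rms_um, corr_um = 200) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  z <- as.matrix(EBImage::gblur(z, sigma = max(1, corr_um / dy)))
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0 && rms_um > 0) z * (rms_um / s) else z * 0
}

## En-face dermal pattern map in [0, 1]; 1 = full local pattern contrast.
make_pattern_map <- function(spec, ys, xs) {
  lvl <- spec$dermal_pattern_level
  ny <- length(ys); nx <- length(xs)
  if (spec$skin_type == "glabrous") {
    theta <- stats::runif(1L, 0, pi)
    phi <- stats::runif(1L, 0, 2 * pi)
    u <- outer(ys, rep(1, nx)) * sin(theta) + outer(rep(1, ny), xs) * cos(theta)
    p <- 0.5 * (1 + cos(2 * pi * u / LINE_PERIOD_UM + phi))
    list(map = p, amp = PATTERN_AMP[lvl + 1L])
  } else {
    cy <- seq(SPOT_SPACING_UM / 2, max(ys), by = SPOT_SPACING_UM)
    cx <- seq(SPOT_SPACING_UM / 2, max(xs), by = SPOT_SPACING_UM)
    centres <- expand.grid(y = cy, x = cx)
    centres$y <- centres$y + stats::rnorm(nrow(centres), 0, SPOT_JITTER_UM)
    centres$x <- centres$x + stats::rnorm(nrow(centres), 0, SPOT_JITTER_UM)
    keep_n <- round(SPOT_KEEP[lvl + 1L] * nrow(centres))
    keep <- if (keep_n >= 1L) sort(sample.int(nrow(centres), keep_n)) else integer(0)
    p <- matrix(0, ny, nx)
    feather <- max(diff(xs)[1], 1)
    for (i in keep) {
      iy <- which(abs(ys - centres$y[i]) <= SPOT_RADIUS_UM + 2 * feather)
      ix <- which(abs(xs - centres$x[i]) <= SPOT_RADIUS_UM + 2 * feather)
      if (!length(iy) || !length(ix)) next
      dist <- sqrt(outer((ys[iy] - centres$y[i])^2,
                         (xs[ix] - centres$x[i])^2, "+"))
      contrib <- pmin(pmax((SPOT_RADIUS_UM + feather - dist) / feather, 0), 1)
      p[iy, ix] <- pmax(p[iy, ix], contrib)
    }
    list(map = p, amp = if (keep_n >= 1L) 0.8 else 0)
  }
}

## Recursive arborizing vessel tree covering the field. Trunks enter from
## the left edge; each segment bifurcates with decaying length and width
## until the calibre floor. Returns a data.frame of segments.
make_vessel_tree <- function(field_um) {
  segs <- list()
  grow <- function(y0, x0, ang, len, wid, gen) {
    y1 <- y0 + len * sin(ang)
    x1 <- x0 + len * cos(ang)
    segs[[length(segs) + 1L]] <<- c(y0, x0, y1, x1, wid, gen)
    if (wid * WIDTH_DECAY >= MIN_WIDTH_UM) {
      for (s in c(-1, 1)) {
        a <- ang + s * stats::rnorm(1L, 30, 8) * pi / 180
        grow(y1, x1, a, len * LENGTH_DECAY, wid * WIDTH_DECAY, gen + 1L)
      }
    }
  }
  area_mm2 <- prod(field_um) / 1e6
  n_trunks <- max(2L, round(2L * area_mm2 / 9))
  y_starts <- field_um[1] * (seq_len(n_trunks) - 0.5) / n_trunks
  for (y0 in y_starts) {
    grow(y0, 0, stats::runif(1L, -10, 10) * pi / 180,
         TRUNK_LENGTH_UM, TRUNK_WIDTH_UM, 0L)
  }
  out <- do.call(rbind, segs)
  colnames(out) <- c("y0", "x0", "y1", "x1", "width", "gen")
  as.data.frame(out)
}

## Vascular level 1 removes the thinnest-calibre quantile (small vessels
## disappear first); level 2 keeps only the unbranched trunk segments.
prune_vessel_tree <- function(segs, level) {
  if (level == 1L) {
    segs[segs$width >= stats::quantile(segs$width, PRUNE_QUANTILE), ,
         drop = FALSE]
  } else if (level == 2L) {
    segs[segs$gen == 0L, , drop = FALSE]
  } else {
    segs
  }
}

## Rasterize segments into an en-face intensity map in [0, 1].
render_vessel_map <- function(segs, ys, xs) {
  ny <- length(ys); nx <- length(xs)
  v <- matrix(0, ny, nx)
  feather <- max(diff(xs)[1], 1)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    half <- s$width / 2
    pad <- half + 2 * feather
    iy <- which(ys >= min(s$y0, s$y1) - pad & ys <= max(s$y0, s$y1) + pad)
    ix <- which(xs >= min(s$x0, s$x1) - pad & xs <= max(s$x0, s$x1) + pad)
    if (!length(iy) || !length(ix)) next
    gy <- matrix(ys[iy], length(iy), length(ix))
    gx <- matrix(xs[ix], length(iy), length(ix), byrow = TRUE)
    vy <- s$y1 - s$y0; vx <- s$x1 - s$x0
    len2 <- vy^2 + vx^2
    t <- pmin(pmax(((gy - s$y0) * vy + (gx - s$x0) * vx) / len2, 0), 1)
    dist <- sqrt((gy - (s$y0 + t * vy))^2 + (gx - (s$x0 + t * vx))^2)
    contrib <- pmin(pmax((half + feather - dist) / feather, 0), 1)
    v[iy, ix] <- pmax(v[iy, ix], contrib)
  }
  v
}

truncated_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -2.5 * sd), 2.5 * sd)
}

#' Generate a synthetic OCT/D-OCT phantom volume
#'
#' Renders the structural and vascular channels described by a
#' [phantom_spec()]. The dermal pattern and the vascular slab are placed
#' relative to the (possibly tilted, rough) surface, the way real en-face
#' views follow the skin. The generative ground truth — the surface height
#' map and the intended item grades — is attached as attribute `"truth"`.
#'
#' @param spec a `phantom_spec`.
#' @return An [oct_volume()] with attribute `truth` (list: `surface_um`
#'   height map, `grades` the ground-truth `feature_grades`, `spec`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stopf("invalid spec: expected a phantom_spec object")
  }
  dz <- spec$voxel_um[["dz"]]; dy <- spec$voxel_um[["dy"]]
  dx <- spec$voxel_um[["dx"]]
  nz <- round(spec$depth_mm * 1000 / dz)
  ny <- round(spec$field_mm[1] * 1000 / dy)
  nx <- round(spec$field_mm[2] * 1000 / dx)
  ys <- (seq_len(ny) - 0.5) * dy
  xs <- (seq_len(nx) - 0.5) * dx
  t_epi <- spec$epidermis_thickness_um
  with_seed(spec$seed, {
    h <- spec$surface_depth_um +
      spec$tilt_um * (xs[col(matrix(0, ny, nx))] / max(xs) - 0.5) +
      rough_surface(ny, nx, dy, spec$surface_roughness_um)
    pat <- make_pattern_map(spec, ys, xs)
    segs <- prune_vessel_tree(make_vessel_tree(c(max(ys), max(xs))),
                              spec$vascular_level)
    vmap <- render_vessel_map(segs, ys, xs)
    structural <- array(0, c(nz, ny, nx))
    vascular <- array(0, c(nz, ny, nx))
    for (iz in seq_len(nz)) {
      d <- (iz - 0.5) * dz - h
      tissue <- d >= 0
      I <- matrix(I_AIR, ny, nx)
      if (spec$epidermis_present) {
        epi <- tissue & d < t_epi
        der <- tissue & !epi
        I[epi] <- I_EPI
      } else {
        der <- tissue
      }
      I[der] <- I_DERMIS - ATTEN_PER_UM * d[der]
      band <- der & abs(d - PATTERN_DEPTH_UM) <= PATTERN_HALFW_UM
      if (pat$amp > 0 && any(band)) {
        I[band] <- I[band] * (1 - pat$amp * pat$map[band])
      }
      I <- I + truncated_noise(ny * nx, spec$noise_sd)
      structural[iz, , ] <- pmin(pmax(I, 0), 1)
      env <- exp(-0.5 * ((d - VESSEL_SLAB_UM) / VESSEL_SLAB_SD_UM)^2)
      env[!tissue] <- 0
      V <- I_AIR + 0.85 * vmap * env +
        truncated_noise(ny * nx, spec$noise_sd)
      vascular[iz, , ] <- pmin(pmax(V, 0), 1)
    }
    vol <- oct_volume(structural, vascular, spec$voxel_um)
    truth_grades <- feature_grades(
      as.integer(spec$surface_roughness_um > grader_thresholds()$surface_rms_um),
      as.integer(!spec$epidermis_present),
      spec$dermal_pattern_level,
      spec$vascular_level,
      spec$skin_type
    )
    attr(vol, "truth") <- list(surface_um = h, grades = truth_grades,
                               spec = spec)
    vol
  })
}

#' Write an OCT volume as multi-page TIFF files
#'
#' One 32-bit float TIFF per channel (one page per depth slice) plus a
#' small YAML sidecar with the voxel geometry.
#'
#' @param volume an `oct_volume`.
#' @param prefix output path prefix; writes `<prefix>_structural.tif`,
#'   `<prefix>_vascular.tif`, `<prefix>_meta.yml`.
#' @return The three paths, invisibly.
#' @export
write_oct_volume <- function(volume, prefix) {
  stopifnot(inherits(volume, "oct_volume"))
  paths <- c(structural = paste0(prefix, "_structural.tif"),
             vascular   = paste0(prefix, "_vascular.tif"),
             meta       = paste0(prefix, "_meta.yml"))
  slices <- function(a) lapply(seq_len(dim(a)[1]), function(i) a[i, , ])
  tiff::writeTIFF(slices(volume$structural), paths[["structural"]],
                  bits.per.sample = 32L, compression = "none")
  tiff::writeTIFF(slices(volume$vascular), paths[["vascular"]],
                  bits.per.sample = 32L, compression = "none")
  yaml::write_yaml(list(voxel_um = as.list(volume$voxel_um),
                        dim_zyx = dim(volume$structural)),
                   paths[["meta"]])
  invisible(paths)
}

#' Read an OCT volume written by [write_oct_volume()]
#'
#' @param prefix the path prefix used at write time.
#' @return An `oct_volume` (float32 precision).
#' @export
read_oct_volume <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yml"))
  stack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
  }
  oct_volume(stack(paste0(prefix, "_structural.tif")),
             stack(paste0(prefix, "_vascular.tif")),
             unlist(meta$voxel_um))
}
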