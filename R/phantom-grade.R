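## Automated graders: explicit, machine-checkable stand-ins for the human
## grading of the four score items. Thresholds are calibrated on phantoms,
## not on patients, and make no clinical claim.

#' Default thresholds of the automated feature graders
#'
#' All tunables of the image graders in one place. Units are micrometres
#' for lengths, intensity units (volume values are in \[0, 1\]) for
#' contrasts, and counts per square millimetre for densities.
#'
#' * `surface_rms_um` (20): plane-detrended surface RMS above which the
#'   surface is graded irregular.
#' * `band_contrast` (0.15): dermis-minus-band mean intensity below which
#'   the dark epidermal band is called absent.
#' * `line_amp_lo` / `line_amp_hi` (0.03 / 0.15): dominant spectral line
#'   amplitude (glabrous skin lines) separating grades 2/1 and 1/0.
#' * `spot_density_lo` / `spot_density_hi` (2 / 8): papillary spot count
#'   per mm2 separating grades 2/1 and 1/0 on hair-bearing skin.
#' * `branch_density_lo` / `branch_density_hi` (0.25 / 1.8): vessel
#'   skeleton branch points per mm2 separating grades 2/1 and 1/0.
#' * `small_vessel_um` (60): calibre below which a vessel counts as small.
#' * `vessel_binarize` (0.4): intensity cut for the vascular channel.
#' * `surface_threshold_frac` (0.25): position of the adaptive surface
#'   threshold between background and bright-tissue intensity.
#' * `pattern_depth_um` (300): depth below the detected surface of the
#'   en-face slice used for the dermal pattern.
#'
#' @return Named list of thresholds.
#' @export
grader_thresholds <- function() {
  list(
    surface_rms_um = 20,
    band_contrast = 0.15,
    line_amp_lo = 0.03,
    line_amp_hi = 0.15,
    spot_density_lo = 2,
    spot_density_hi = 8,
    branch_density_lo = 0.25,
    branch_density_hi = 1.8,
    small_vessel_um = 60,
    vessel_binarize = 0.4,
    surface_threshold_frac = 0.25,
    pattern_depth_um = 300
  )
}

#' Extract the air-tissue surface from the structural channel
#'
#' Per lateral position, the shallowest depth whose intensity first
#' exceeds an adaptive threshold placed between the background (air) level
#' and the bright-tissue level. Columns without a crossing are completed
#' with the median height of the found columns; the fraction of columns
#' with a genuine crossing is reported.
#'
#' @param volume an `oct_volume`.
#' @param thresholds grader threshold list, see [grader_thresholds()].
#' @return Matrix (ny x nx) of surface heights in micrometres below the
#'   volume top, with attribute `coverage`.
#' @export
extract_surface <- function(volume, thresholds = grader_thresholds()) {
  stopifnot(inherits(volume, "oct_volume"))
  arr <- volume$structural
  nz <- dim(arr)[1]
  bg <- stats::quantile(arr, 0.02, names = FALSE)
  hi <- stats::quantile(arr, 0.99, names = FALSE)
  thr <- bg + thresholds$surface_threshold_frac * (hi - bg)
  first <- matrix(Inf, dim(arr)[2], dim(arr)[3])
  for (iz in rev(seq_len(nz))) {
    first[arr[iz, , ] > thr] <- iz
  }
  found <- is.finite(first)
  coverage <- mean(found)
  if (coverage < 0.5) {
    stopf("surface not found: only %.0f%% of columns cross the threshold",
          100 * coverage)
  }
  dz <- volume$voxel_um[["dz"]]
  h <- (first - 1) * dz           # boundary above the first tissue voxel
  h[!found] <- stats::median(h[found])
  attr(h, "coverage") <- coverage
  h
}

## Plane-detrended RMS of a height map (tilt must not read as roughness).
surface_rms <- function(height) {
  yy <- row(height); xx <- col(height)
  fit <- stats::lm.fit(cbind(1, as.vector(yy), as.vector(xx)),
                       as.vector(height))
  sqrt(mean(fit$residuals^2))
}

## Mean structural intensity in a depth window measured from the surface.
depth_window_mean <- function(volume, height, from_um, to_um) {
  arr <- volume$structural
  dz <- volume$voxel_um[["dz"]]
  total <- 0; count <- 0
  for (iz in seq_len(dim(arr)[1])) {
    d <- (iz - 0.5) * dz - height
    m <- d >= from_um & d <= to_um
    if (any(m)) {
      sl <- arr[iz, , ]
      total <- total + sum(sl[m])
      count <- count + sum(m)
    }
  }
  if (count == 0) NA_real_ else total / count
}

## En-face slice at a fixed depth below the detected surface.
slice_below_surface <- function(volume, height, depth_um) {
  dz <- volume$voxel_um[["dz"]]
  nz <- dim(volume$structural)[1]
  iz <- pmin(pmax(round((height + depth_um) / dz + 0.5), 1), nz)
  ny <- dim(volume$structural)[2]; nx <- dim(volume$structural)[3]
  idx <- cbind(as.vector(iz), as.vector(row(iz)), as.vector(col(iz)))
  matrix(volume$structural[idx], ny, nx)
}

#' Grade surface irregularity from a height map
#'
#' @param height surface height map from [extract_surface()].
#' @param thresholds grader thresholds.
#' @return List: `grade` (0 smooth / 1 irregular) and `surface_rms_um`.
#' @export
grade_surface <- function(height, thresholds = grader_thresholds()) {
  rms <- surface_rms(height)
  list(grade = as.integer(rms > thresholds$surface_rms_um),
       surface_rms_um = rms)
}

#' Grade epidermal loss from the sub-surface band contrast
#'
#' The epidermis reads as a dark band just below the surface; its loss
#' makes the band as bright as the dermis. The contrast is the mean dermis
#' intensity (130-230 um below the surface) minus the mean band intensity
#' (10-90 um).
#'
#' @param volume `oct_volume`.
#' @param height surface height map.
#' @param thresholds grader thresholds.
#' @return List: `grade` (0 band present / 1 absent) and `band_contrast`.
#' @export
grade_epidermis <- function(volume, height, thresholds = grader_thresholds()) {
  band <- depth_window_mean(volume, height, 10, 90)
  dermis <- depth_window_mean(volume, height, 130, 230)
  contrast <- dermis - band
  list(grade = as.integer(contrast < thresholds$band_contrast),
       band_contrast = contrast)
}

## Amplitude of the dominant periodic component of an en-face slice:
## 2 * sqrt(power in the peak neighbourhood) / N for a real cosine.
line_pattern_amplitude <- function(slice) {
  s <- slice - mean(slice)
  P <- Mod(stats::fft(s))^2
  n <- length(s)
  nr <- nrow(P); nc <- ncol(P)
  fr <- pmin(row(P) - 1, nr - (row(P) - 1))   # torus frequency distance
  fc <- pmin(col(P) - 1, nc - (col(P) - 1))
  ac <- fr > 2 | fc > 2                        # drop DC and slow trends
  k <- which(ac)[which.max(P[ac])]
  kr <- (k - 1) %% nr + 1; kc <- (k - 1) %/% nr + 1
  nb_r <- ((kr - 2):(kr)) %% nr + 1            # 3x3 torus neighbourhood
  nb_c <- ((kc - 2):(kc)) %% nc + 1
  peak_power <- sum(P[nb_r, nb_c])
  2 * sqrt(peak_power) / n
}

## Dark-spot census of an en-face slice: density per mm2 and the
## coefficient of variation of nearest-neighbour spot spacing.
spot_census <- function(slice, dy_um, dx_um) {
  bg <- stats::median(slice)
  binary <- slice < bg - 0.15
  lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
  n_obj <- max(lab)
  area_mm2 <- nrow(slice) * ncol(slice) * dy_um * dx_um / 1e6
  if (n_obj == 0) {
    return(list(density = 0, cv_spacing = NA_real_, n_spots = 0L))
  }
  labv <- as.vector(EBImage::imageData(lab))
  sizes <- tabulate(labv, nbins = n_obj)
  keep <- which(sizes >= 3L)
  if (!length(keep)) {
    return(list(density = 0, cv_spacing = NA_real_, n_spots = 0L))
  }
  yy <- as.vector(row(slice)); xx <- as.vector(col(slice))
  cy <- vapply(keep, function(k) mean(yy[labv == k]), numeric(1)) * dy_um
  cx <- vapply(keep, function(k) mean(xx[labv == k]), numeric(1)) * dx_um
  cv <- NA_real_
  if (length(keep) >= 3L) {
    dm <- as.matrix(stats::dist(cbind(cy, cx)))
    diag(dm) <- Inf
    nn <- apply(dm, 1, min)
    cv <- stats::sd(nn) / mean(nn)
  }
  list(density = length(keep) / area_mm2, cv_spacing = cv,
       n_spots = length(keep))
}

#' Grade the dermal pattern at the 0.3 mm en-face level
#'
#' Uses the en-face slice 0.3 mm below the *detected* surface (so tilted
#' volumes grade like flat ones). Glabrous skin is graded from the
#' amplitude of the dominant spectral peak of the skin-line pattern;
#' hair-bearing skin from the papillary spot density (the coefficient of
#' variation of nearest-neighbour spot spacing is reported alongside).
#'
#' @param volume `oct_volume`.
#' @param height surface height map.
#' @param skin_type `"glabrous"` or `"hair_bearing"`.
#' @param thresholds grader thresholds.
#' @return List: `grade` (0/1/2), `pattern_regularity` (line amplitude or
#'   spot density), plus `spot_cv_spacing` for hair-bearing skin.
#' @export
grade_dermal_pattern <- function(volume, height, skin_type,
                                 thresholds = grader_thresholds()) {
  validate_skin_type(skin_type)
  slice <- slice_below_surface(volume, height, thresholds$pattern_depth_um)
  if (skin_type == "glabrous") {
    amp <- line_pattern_amplitude(slice)
    grade <- if (amp >= thresholds$line_amp_hi) 0L
             else if (amp > thresholds$line_amp_lo) 1L else 2L
    list(grade = grade, pattern_regularity = amp,
         spot_cv_spacing = NA_real_)
  } else {
    cen <- spot_census(slice, volume$voxel_um[["dy"]],
                       volume$voxel_um[["dx"]])
    grade <- if (cen$density >= thresholds$spot_density_hi) 0L
             else if (cen$density > thresholds$spot_density_lo) 1L else 2L
    list(grade = grade, pattern_regularity = cen$density,
         spot_cv_spacing = cen$cv_spacing)
  }
}

## Zero-padded shift of a matrix by (dy, dx).
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

## Zhang-Suen binary thinning to a 1-pixel skeleton.
skeletonize <- function(binary) {
  B <- matrix(as.integer(binary), nrow(binary), ncol(binary))
  neigh_offsets <- list(  # P2..P9: N, NE, E, SE, S, SW, W, NW
    c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
    c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
  )
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(neigh_offsets, function(o) shift_mat(B, o[1], o[2]))
      Bsum <- Reduce(`+`, nb)
      seqn <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (seqn[[i]] == 0L) & (seqn[[i + 1L]] == 1L)
      }))
      if (step == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L
      }
      del <- B == 1L & Bsum >= 2L & Bsum <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        B[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  B
}

## Branch points: skeleton pixels whose circular 8-neighbourhood makes
## three or more 0->1 transitions (crossing number), which ignores the
## staircase corners a plain neighbour count picks up.
skeleton_branch_points <- function(skel) {
  offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                  c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nb <- lapply(offsets, function(o) shift_mat(skel, o[1], o[2]))
  seqn <- c(nb, nb[1])
  A <- Reduce(`+`, lapply(1:8, function(i) {
    (seqn[[i]] == 0L) & (seqn[[i + 1L]] == 1L)
  }))
  sum(skel == 1L & A >= 3L)
}

#' Grade the microvascular network from the D-OCT channel
#'
#' The en-face maximum-intensity projection of the vascular channel is
#' binarized and skeletonized; the grade follows the density of skeleton
#' branch points (arborization) per mm2. The mean vessel calibre and the
#' small-vessel fraction are reported as supporting measurements.
#'
#' @param volume `oct_volume`.
#' @param thresholds grader thresholds.
#' @return List: `grade` (0 arborized / 1 pruned / 2 truncated-or-none),
#'   `branch_density_per_mm2`, `mean_vessel_width_um`,
#'   `small_vessel_fraction`.
#' @export
grade_vasculature <- function(volume, thresholds = grader_thresholds()) {
  arr <- volume$vascular
  mip <- arr[1, , ]
  for (iz in seq_len(dim(arr)[1])[-1]) mip <- pmax(mip, arr[iz, , ])
  binary <- mip > thresholds$vessel_binarize
  area_mm2 <- prod(dim(mip)) * volume$voxel_um[["dy"]] *
    volume$voxel_um[["dx"]] / 1e6
  if (!any(binary)) {
    return(list(grade = 2L, branch_density_per_mm2 = 0,
                mean_vessel_width_um = NA_real_,
                small_vessel_fraction = NA_real_))
  }
  skel <- skeletonize(binary)
  density <- skeleton_branch_points(skel) / area_mm2
  dmap <- EBImage::imageData(EBImage::distmap(EBImage::Image(binary * 1)))
  widths <- 2 * dmap[skel == 1L] * volume$voxel_um[["dx"]]
  grade <- if (density >= thresholds$branch_density_hi) 0L
           else if (density > thresholds$branch_density_lo) 1L else 2L
  list(grade = grade,
       branch_density_per_mm2 = density,
       mean_vessel_width_um = mean(widths),
       small_vessel_fraction = mean(widths < thresholds$small_vessel_um))
}

#' Grade a whole phantom volume
#'
#' Runs the four automated graders and assembles the result into a
#' feature-grade set plus the underlying measurements, closing the loop
#' from image to score.
#'
#' @param volume `oct_volume`.
#' @param skin_type `"glabrous"` or `"hair_bearing"` (selects the dermal
#'   pattern grader).
#' @param thresholds grader thresholds, see [grader_thresholds()].
#' @return Object of class `autograde_report`: `grades`
#'   (a `feature_grades`), `score`, and `measurements` (surface RMS, band
#'   contrast, pattern regularity, branch density, mean vessel width,
#'   small-vessel fraction, spot-spacing CV, surface coverage).
#' @export
grade_volume <- function(volume, skin_type,
                         thresholds = grader_thresholds()) {
  height <- extract_surface(volume, thresholds)
  gs <- grade_surface(height, thresholds)
  ge <- grade_epidermis(volume, height, thresholds)
  gd <- grade_dermal_pattern(volume, height, skin_type, thresholds)
  gv <- grade_vasculature(volume, thresholds)
  grades <- feature_grades(gs$grade, ge$grade, gd$grade, gv$grade, skin_type)
  structure(list(
    grades = grades,
    score = compute_score(grades),
    measurements = list(
      surface_rms_um = gs$surface_rms_um,
      band_contrast = ge$band_contrast,
      pattern_regularity = gd$pattern_regularity,
      branch_density_per_mm2 = gv$branch_density_per_mm2,
      mean_vessel_width_um = gv$mean_vessel_width_um,
      small_vessel_fraction = gv$small_vessel_fraction,
      spot_cv_spacing = gd$spot_cv_spacing,
      surface_coverage = attr(height, "coverage")
    )
  ), class = "autograde_report")
}

#' @export
print.autograde_report <- function(x, ...) {
  g <- x$grades
  cat(sprintf(
    "Automated grading (%s skin): surface=%d epidermis=%d dermal=%d vascular=%d -> score %d\n",
    g$skin_type, g$surface_irregularity, g$epidermal_loss,
    g$dermal_pattern, g$vascular_network, x$score))
  m <- x$measurements
  cat(sprintf("  surface RMS %.1f um | band contrast %.3f | pattern %.3g | branches %.2f /mm2\n",
              m$surface_rms_um, m$band_contrast, m$pattern_regularity,
              m$branch_density_per_mm2))
  invisible(x)
}

#' Flatten an autograde report to one delimited record
#'
#' Produces a one-row data.frame whose grade columns match the cohort CSV
#' schema (observer-1 columns), so phantom gradings can be appended to a
#' cohort table.
#'
#' @param report an `autograde_report`.
#' @param id identifier for the graded volume.
#' @return One-row data.frame.
#' @export
autograde_record <- function(report, id = "phantom") {
  g <- report$grades
  m <- report$measurements
  data.frame(
    wound_id = id, skin_type = g$skin_type,
    surf1 = g$surface_irregularity, epi1 = g$epidermal_loss,
    dermal1 = g$dermal_pattern, vasc1 = g$vascular_network,
    score = report$score,
    surface_rms_um = m$surface_rms_um,
    band_contrast = m$band_contrast,
    pattern_regularity = m$pattern_regularity,
    branch_density_per_mm2 = m$branch_density_per_mm2,
    mean_vessel_width_um = m$mean_vessel_width_um,
    stringsAsFactors = FALSE
  )
}

#' Default phantom benchmark grid
#'
#' The 3 x 3 grid of dermal-pattern level by vascular level used to
#' benchmark the automated graders, rendered at a compact geometry
#' (3 x 3 mm lateral field at 24 um pitch, 0.88 mm depth at 8 um) so the
#' full grid over many seeds stays small in memory. All cells use a rough
#' (40 um RMS) surface with the epidermal band lost, as in a burn; the
#' clean extreme is covered by a separate healthy phantom. Skin type
#' alternates with seed parity so both dermal graders are exercised.
#'
#' @param seeds integer seeds; each grid cell is rendered once per seed.
#' @return data.frame with one row per (cell, seed): generative levels and
#'   the ground-truth grades.
#' @export
default_phantom_grid <- function(seeds = 1:10) {
  cells <- expand.grid(dermal_level = 0:2, vascular_level = 0:2,
                       seed = as.integer(seeds), KEEP.OUT.ATTRS = FALSE)
  cells$skin_type <- ifelse(cells$seed %% 2 == 0, "glabrous", "hair_bearing")
  cells$surface_grade <- 1L
  cells$epidermis_grade <- 1L
  cells
}

#' Build the phantom_spec for one benchmark grid row
#'
#' @param row one row of [default_phantom_grid()].
#' @param tilt_um optional scan-plane tilt.
#' @return A `phantom_spec`.
#' @export
grid_phantom_spec <- function(row, tilt_um = 0) {
  phantom_spec(
    skin_type = row$skin_type,
    surface_roughness_um = 40,
    epidermis_present = FALSE,
    dermal_pattern_level = row$dermal_level,
    vascular_level = row$vascular_level,
    noise_sd = 0.03,
    seed = row$seed,
    field_mm = c(3, 3),
    depth_mm = 0.88,
    voxel_um = c(dz = 8, dy = 24, dx = 24),
    tilt_um = tilt_um
  )
}
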