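test_that("phantom spec validation catches out-of-range parameters", {
  expect_error(phantom_spec(dermal_pattern_level = 3), "dermal_pattern_level")
  expect_error(phantom_spec(vascular_level = -1), "vascular_level")
  expect_error(phantom_spec(epidermis_thickness_um = 0), "epidermis_thickness")
  expect_error(phantom_spec(depth_mm = 2.5), "depth_mm")
  expect_error(generate_phantom(list()), "invalid spec")
})

test_that("identical spec and seed give bit-identical volumes", {
  sp <- tiny_phantom_spec(seed = 5L, dermal_pattern_level = 1L)
  v1 <- generate_phantom(sp)
  v2 <- generate_phantom(sp)
  expect_identical(v1$structural, v2$structural)
  expect_identical(v1$vascular, v2$vascular)
  v3 <- generate_phantom(tiny_phantom_spec(seed = 6L, dermal_pattern_level = 1L))
  expect_false(identical(v1$structural, v3$structural))
})

test_that("surface extraction recovers flat, rough and missing surfaces", {
  flat <- generate_phantom(tiny_phantom_spec(surface_roughness_um = 0, seed = 9L))
  h <- extract_surface(flat)
  expect_lte(grade_surface(h)$surface_rms_um, 8)  # within one voxel (dz = 8)
  expect_equal(attr(h, "coverage"), 1)

  rough <- generate_phantom(tiny_phantom_spec(surface_roughness_um = 30, seed = 9L))
  rms <- grade_surface(extract_surface(rough))$surface_rms_um
  expect_gt(rms, 30 * 0.7)
  expect_lt(rms, 30 * 1.3)

  dark <- oct_volume(array(0, c(20, 30, 30)), array(0, c(20, 30, 30)),
                     c(dz = 8, dy = 24, dx = 24))
  expect_error(extract_surface(dark), "surface not found")
})

test_that("epidermal band contrast vanishes when the epidermis is removed", {
  with_epi <- generate_phantom(tiny_phantom_spec(epidermis_present = TRUE, seed = 2L))
  no_epi <- generate_phantom(tiny_phantom_spec(epidermis_present = FALSE, seed = 2L))
  c1 <- grade_epidermis(with_epi, extract_surface(with_epi))
  c0 <- grade_epidermis(no_epi, extract_surface(no_epi))
  expect_gt(c1$band_contrast, 0.3)
  expect_identical(c1$grade, 0L)
  expect_lt(abs(c0$band_contrast), 0.05)
  expect_identical(c0$grade, 1L)
})

test_that("fully disrupted papillary pattern leaves zero spots at the 0.3 mm slice", {
  sp <- tiny_phantom_spec(skin_type = "hair_bearing", dermal_pattern_level = 2L,
                          seed = 4L)
  vol <- generate_phantom(sp)
  g <- grade_dermal_pattern(vol, extract_surface(vol), "hair_bearing")
  expect_equal(g$pattern_regularity, 0)  # spots per mm2
  expect_identical(g$grade, 2L)
})

test_that("skeleton branch counting agrees with a brute-force connectivity oracle", {
  sp0 <- tiny_phantom_spec(vascular_level = 0L, seed = 3L)
  sp2 <- tiny_phantom_spec(vascular_level = 2L, seed = 3L)
  count_branches <- function(spec) {
    vol <- generate_phantom(spec)
    arr <- vol$vascular
    mip <- arr[1, , ]
    for (iz in 2:dim(arr)[1]) mip <- pmax(mip, arr[iz, , ])
    skel <- octburnscore:::skeletonize(mip > 0.4)
    ## brute-force: loop over pixels, count circular 0->1 transitions
    oracle <- 0L
    nr <- nrow(skel); nc <- ncol(skel)
    ring <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                  c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
    for (i in 2:(nr - 1)) {
      for (j in 2:(nc - 1)) {
        if (skel[i, j] == 1L) {
          vals <- skel[cbind(i + ring[, 1], j + ring[, 2])]
          trans <- sum(vals == 0L & c(vals[-1], vals[1]) == 1L)
          if (trans >= 3L) oracle <- oracle + 1L
        }
      }
    }
    pkg <- octburnscore:::skeleton_branch_points(skel)
    list(pkg = pkg, oracle = oracle)
  }
  full <- count_branches(sp0)
  trunk <- count_branches(sp2)
  expect_identical(full$pkg, full$oracle)
  expect_identical(trunk$pkg, trunk$oracle)
  expect_gt(full$pkg, trunk$pkg)  # arborized vs truncated network
})

test_that("whole-volume grading recovers extreme phantoms and is self-consistent", {
  healthy <- tiny_phantom_spec(skin_type = "hair_bearing",
                               surface_roughness_um = 8,
                               epidermis_present = TRUE,
                               dermal_pattern_level = 0L,
                               vascular_level = 0L, seed = 10L)
  rep_h <- grade_volume(generate_phantom(healthy), "hair_bearing")
  expect_equal(rep_h$score, 0)

  deep <- tiny_phantom_spec(skin_type = "glabrous",
                            surface_roughness_um = 40,
                            epidermis_present = FALSE,
                            dermal_pattern_level = 2L,
                            vascular_level = 2L, seed = 10L)
  rep_d <- grade_volume(generate_phantom(deep), "glabrous")
  expect_equal(rep_d$score, 6)

  ## the reported score always equals the sum of the reported item grades
  for (r in list(rep_h, rep_d)) {
    g <- r$grades
    expect_identical(r$score, g$surface_irregularity + g$epidermal_loss +
                       g$dermal_pattern + g$vascular_network)
  }
})

test_that("grading matches stored ground truth on benchmark cells", {
  rows <- default_phantom_grid(seeds = c(1L, 2L))
  cells <- rows[rows$dermal_level != rows$vascular_level, ][c(1, 3, 5), ]
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    vol <- generate_phantom(grid_phantom_spec(row))
    truth <- attr(vol, "truth")$grades
    got <- grade_volume(vol, row$skin_type)$grades
    expect_identical(unlist(got[1:4]), unlist(truth[1:4]))
  }
})

test_that("volumes survive a TIFF round trip at float precision", {
  sp <- tiny_phantom_spec(seed = 11L, depth_mm = 0.4)
  vol <- generate_phantom(sp)
  prefix <- file.path(tempdir(), "phantom_rt")
  write_oct_volume(vol, prefix)
  back <- read_oct_volume(prefix)
  expect_equal(dim(back$structural), dim(vol$structural))
  expect_equal(back$voxel_um, vol$voxel_um)
  expect_lt(max(abs(back$structural - vol$structural)), 1e-6)
  expect_lt(max(abs(back$vascular - vol$vascular)), 1e-6)
})
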