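test_that("phantom classes order bone volume and lesion masks as designed", {
  p <- tiny_params()
  ctrl <- generate_phantom("control", p, seed = 7)
  ero <- generate_phantom("erosive", p, seed = 7)
  pro <- generate_phantom("proliferative", p, seed = 7)
  # control carries no lesion; erosions remove and spurs add material on a
  # shared base geometry (same seed)
  expect_identical(sum(ctrl$lesion_mask), 0)
  expect_gt(sum(ero$lesion_mask), 0)
  expect_gt(sum(pro$lesion_mask), 0)
  expect_lt(sum(ero$bone_mask), sum(ctrl$bone_mask))
  expect_gt(sum(pro$bone_mask), sum(ctrl$bone_mask))
  # masks are binary and intensity carries signal only around the bone
  expect_true(is_binary_grid(ero$bone_mask))
  expect_true(is_binary_grid(ero$lesion_mask))
  expect_gt(mean(ctrl$intensity[ctrl$bone_mask == 1]),
            mean(ctrl$intensity[ctrl$bone_mask == 0]) + 0.5)
})

test_that("phantom generation is bitwise deterministic in the seed", {
  p <- tiny_params()
  a <- generate_phantom("proliferative", p, seed = 11)
  b <- generate_phantom("proliferative", p, seed = 11)
  expect_identical(as.numeric(a$bone_mask), as.numeric(b$bone_mask))
  expect_identical(as.numeric(a$intensity), as.numeric(b$intensity))
  c <- generate_phantom("proliferative", p, seed = 12)
  expect_false(identical(as.numeric(a$bone_mask), as.numeric(c$bone_mask)))
  # repeat scans: same anatomy seed, different scan seed -> same lesion count,
  # different pose/texture
  d <- generate_phantom("proliferative", p, seed = 11, scan_seed = 99)
  expect_false(identical(as.numeric(a$intensity), as.numeric(d$intensity)))
})

test_that("every lesion voxel stays near the unlesioned bone surface", {
  p <- tiny_params()
  for (s in c(2, 5, 9)) {
    ph <- generate_phantom("erosive", p, seed = s)
    base <- generate_phantom("control", p, seed = s)$bone_mask  # same geometry
    inner <- csae:::dilate_mask(1 - base, 1)  # complement dilation
    boundary <- (base == 1 & inner == 1) + 0  # surface voxels of the base
    # lesion ball centres sit on the continuous surface; allow one voxel of
    # discretization slack beyond the maximum lesion radius
    reach <- csae:::dilate_mask(boundary, p$lesion_radius_range[2] + 1)
    expect_true(all(reach[ph$lesion_mask == 1] == 1))
  }
})

test_that("undifferentiated phantoms hide an erosive or proliferative truth", {
  p <- tiny_params()
  ph <- generate_phantom("undifferentiated", p, seed = 21)
  expect_identical(ph$class_label, "undifferentiated")
  expect_true(ph$latent_class %in% c("erosive", "proliferative"))
  expect_gt(sum(ph$lesion_mask), 0)
})

test_that("degenerate parameters are rejected before generation", {
  expect_error(phantom_params(lesion_radius_range = c(5, 20),
                              head_radius_range = c(14, 18)),
               "smaller than the head")
  expect_error(phantom_params(base_extent = c(8, 8, 8)), ">= 16")
  expect_error(phantom_params(head_radius_range = c(18, 14)), "min <= max")
})

test_that("cohort manifests have the right shape, repeats and determinism", {
  m <- generate_cohort(10, c(0.3, 0.4, 0.3), repeat_scan_prob = 0,
                       params = tiny_params(), seed = 1)
  expect_identical(nrow(m), 10L)
  expect_identical(length(unique(m$patient_id)), 10L)
  m2 <- generate_cohort(10, c(0.3, 0.4, 0.3), repeat_scan_prob = 0,
                        params = tiny_params(), seed = 1)
  expect_identical(as.data.frame(m), as.data.frame(m2))
  expect_false(anyDuplicated(m$scan_id) > 0)

  # expected scan count n * (1 + p) within 3 sigma of the binomial
  m3 <- generate_cohort(200, rep(1 / 3, 3), repeat_scan_prob = 0.3,
                        params = tiny_params(), seed = 2)
  expect_gte(nrow(m3), 200)
  sigma <- sqrt(200 * 0.3 * 0.7)
  expect_lt(abs(nrow(m3) - 200 * 1.3), 3 * sigma)
  # class constant within patient
  expect_true(all(tapply(m3$class_label, m3$patient_id,
                         function(x) length(unique(x))) == 1))
  expect_error(generate_cohort(0, rep(1 / 3, 3), 0, tiny_params(), 1), ">= 1")
  expect_error(generate_cohort(5, c(0.5, 0.4, 0.2), 0, tiny_params(), 1),
               "summing to 1")
})

test_that("written cohorts round-trip through the reader", {
  p <- tiny_params()
  m <- generate_cohort(3, c(1, 0, 0), 0, p, seed = 4, n_undifferentiated = 1)
  dir <- tempfile()
  m <- write_cohort(m, dir)
  expect_identical(nrow(read_cohort(dir)), nrow(m))
  # one triplet of files per manifest row
  expect_identical(length(list.files(dir, pattern = "_mask\\.nii\\.gz$")), nrow(m))
  # control lesion file exists but is all zero
  ctrl_rows <- which(m$class_label == "control")
  lesion <- read_volume(file.path(dir, m$lesion_path[ctrl_rows[1]]))
  expect_identical(sum(lesion), 0)
  # masks round-trip voxel-wise
  ph <- generate_phantom(m$class_label[1], p, m$geom_seed[1], m$scan_seed[1])
  back <- read_volume(file.path(dir, m$mask_path[1]))
  expect_identical(as.numeric(back), as.numeric(ph$bone_mask))
  # the undifferentiated row's latent class matches the rendered phantom
  ua <- which(m$class_label == "undifferentiated")
  ph_ua <- generate_phantom("undifferentiated", p, m$geom_seed[ua], m$scan_seed[ua])
  expect_identical(ph_ua$latent_class, m$latent_class[ua])
})
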