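half_diag <- function(ph) sqrt(sum(ph$voxel_size^2)) / 2

test_that("default pediatric layout reproduces the clinical organ distances", {
  ph <- pediatric_phantom()
  ref <- tld_reference_doses()
  tol <- half_diag(ph)
  for (i in seq_len(nrow(ref))) {
    expect_equal(organ_distance(ph, "ptv", ref$organ[i]), ref$distance_cm[i],
                 tolerance = tol / ref$distance_cm[i],
                 info = ref$organ[i])
  }
})

test_that("organ distances are symmetric, zero on identity, and exact on a grid", {
  ph <- pediatric_phantom()
  expect_equal(organ_distance(ph, "ptv", "ptv"), 0)
  expect_equal(organ_distance(ph, "ptv", "thyroid"),
               organ_distance(ph, "thyroid", "ptv"))
  expect_error(organ_distance(ph, "ptv", "spleen"), "unknown")
  # two single-voxel organs ten voxels apart along z at 0.3 cm spacing
  vs <- c(0.2, 0.2, 0.3)
  a <- organ_spec("a", "box", vs / 2 * 0.99, c(0, 0, 0), is_target = TRUE)
  b <- organ_spec("b", "box", vs / 2 * 0.99, c(0, 0, 10 * 0.3))
  body <- organ_spec("body", "box", c(2, 2, 6))
  ph2 <- build_phantom(list(a, b), body, dims = c(21, 21, 45),
                       voxel_size = vs)
  expect_equal(organ_distance(ph2, "a", "b"), 3.0, tolerance = 1e-9)
})

test_that("body-only phantom is uniformly labeled body", {
  body <- organ_spec("body", "box", c(5, 5, 5), is_target = TRUE)
  ph <- build_phantom(list(), body, dims = c(10, 10, 10),
                      voxel_size = c(1, 1, 1))
  expect_true(all(ph$organ_label == ph$label_names["body"]))
  expect_true(all(ph$material_index == 1L))
})

test_that("painter's order resolves overlaps and building is deterministic", {
  body <- organ_spec("body", "box", c(5, 5, 5), is_target = TRUE)
  first <- organ_spec("first", "ellipsoid", c(2, 2, 2), c(0, 0, 0),
                      material = "water")
  second <- organ_spec("second", "ellipsoid", c(2, 2, 2), c(1, 0, 0),
                       material = "bone")
  ph1 <- build_phantom(list(first, second), body, c(20, 20, 20),
                       c(0.5, 0.5, 0.5))
  ph2 <- build_phantom(list(first, second), body, c(20, 20, 20),
                       c(0.5, 0.5, 0.5))
  expect_identical(ph1$organ_label, ph2$organ_label)
  expect_identical(ph1$material_index, ph2$material_index)
  # the overlap voxels belong to the later organ
  centre_vox <- ph1$organ_label[12, 10, 10]   # x ~ +0.75: inside both
  expect_equal(unname(ph1$label_names["second"]), centre_vox)
})

test_that("voxelized organ volumes track the analytic primitive volumes", {
  ph <- pediatric_phantom()
  sp <- pediatric_organ_specs()
  analytic <- function(s) {
    switch(s$shape,
           ellipsoid = 4 / 3 * pi * prod(s$semi_axes),
           box = 8 * prod(s$semi_axes),
           cylinder = pi * s$semi_axes[1] * s$semi_axes[2] *
             2 * s$semi_axes[3])
  }
  # organs that no later spec overwrites
  for (nm in c("c_spine", "thyroid", "right_lung", "heart", "left_lung")) {
    s <- Filter(function(o) o$name == nm, sp$organs)[[1]]
    v <- organ_volume(ph, nm)$volume_cm3
    expect_equal(v, analytic(s), tolerance = 0.15, info = nm)
  }
  expect_equal(organ_volume(ph, "ptv")$volume_cm3, 9.8, tolerance = 0.15)
})

test_that("an organ entirely outside the grid is refused by name", {
  body <- organ_spec("body", "box", c(5, 5, 5), is_target = TRUE)
  out <- organ_spec("stray", "ellipsoid", c(1, 1, 1), c(50, 0, 0))
  expect_error(build_phantom(list(out), body, c(10, 10, 10), c(1, 1, 1)),
               "stray")
})

test_that("exactly one target volume is required", {
  body <- organ_spec("body", "box", c(5, 5, 5))
  expect_error(build_phantom(list(), body, c(10, 10, 10), c(1, 1, 1)),
               "is_target")
})

test_that("header + raw phantom files round-trip", {
  ph <- pediatric_phantom(voxel_size = c(0.5, 0.5, 0.6))
  path <- file.path(tempdir(), "phantom_test.mhd")
  write_phantom(ph, path)
  ph2 <- read_phantom(path)
  expect_identical(ph$dims, ph2$dims)
  expect_equal(ph$voxel_size, ph2$voxel_size)
  expect_equal(ph$origin, ph2$origin)
  expect_identical(as.integer(ph$material_index),
                   as.integer(ph2$material_index))
  expect_identical(as.integer(ph$organ_label), as.integer(ph2$organ_label))
  expect_identical(names(ph$label_names), names(ph2$label_names))
  unlink(c(path, paste0(path, c(".material.raw", ".label.raw"))))
})

test_that("the CT-resolution grid carries about 47 million voxels", {
  g <- clinical_grid()
  expect_equal(prod(g$dims), 4.7e7, tolerance = 0.10)
  expect_equal(g$voxel_size, c(0.09766, 0.09766, 0.3))
})
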