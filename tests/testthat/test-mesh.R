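test_that("a single voxel splits into 5 tetrahedra conserving its volume", {
  lab <- array(NA_integer_, c(3, 3, 3))
  lab[2, 2, 2] <- 2L
  mask <- array(FALSE, c(3, 3, 3))
  mask[2, 2, 2] <- TRUE
  f <- structure(list(labels = lab, config = threshold_config(40, 60),
                      spacing = c(1.3, 1.3, 5), mask = mask),
                 class = "tissue_label_field")
  mesh <- build_labeled_mesh(f)
  expect_identical(nrow(mesh$elements), 5L)
  expect_equal(mesh_volume(mesh, "ml"), 1.3 * 1.3 * 5 / 1000,
               tolerance = 1e-9)
  expect_true(all(mesh$labels == 2L))
})

test_that("all-healthy fields give single-label meshes", {
  lab <- array(0L, c(5, 5, 4))
  mesh <- build_labeled_mesh(field_from_labels(lab))
  expect_identical(unique(mesh$labels), 0L)
  expect_identical(nrow(mesh$elements), 5L * 5L * 5L * 4L)
})

test_that("voxel-mesh volume matches the analytic shell volume", {
  st <- generate_phantom(spherical_shell_spec(22, 32))
  mesh <- build_labeled_mesh(truth_label_field(st))
  analytic_ml <- 4 / 3 * pi * (32^3 - 22^3) / 1000
  expect_lt(abs(mesh_volume(mesh) - analytic_ml) / analytic_ml, 0.02)
  # exact agreement with the voxel count (decomposition conservation)
  expect_equal(mesh_volume(mesh, "mm3"),
               sum(st$myocardium_mask) * prod(st$spacing),
               tolerance = 1e-6)
})

test_that("cuboidal core interface area equals brute-force facet geometry", {
  d <- c(16, 16, 10)
  sp <- c(1.3, 1.3, 5)
  lab <- array(1L, d)
  lab[5:9, 6:11, 4:7] <- 2L  # 5 x 6 x 4 voxel block
  mesh <- build_labeled_mesh(field_from_labels(lab, sp))
  got <- interface_area(mesh, "bz_vs_core", method = "facet",
                        units = "mm2")
  # independent oracle: enumerate exposed voxel faces of the block
  oracle <- 0
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (lab[i, j, k] != 2L) next
    for (o in 1:6) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
      if (lab[ii, jj, kk] == 1L) {
        oracle <- oracle + face_area[which(offs[o, ] != 0)]
      }
    }
  }
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(got, 2 * (5 * 6 * sp[1] * sp[2] + 6 * 4 * sp[2] * sp[3] +
                           5 * 4 * sp[1] * sp[3]), tolerance = 1e-9)
})

test_that("spherical core area is recovered by the normal-weighted estimator", {
  lab <- sphere_core_labels(24L, 1.3, 10)
  mesh <- build_labeled_mesh(field_from_labels(lab, rep(1.3, 3)))
  truth <- 4 * pi * 10^2 / 100  # cm^2
  aw <- interface_area(mesh, "bz_vs_core", method = "normal_weighted")
  expect_lt(abs(aw - truth) / truth, 0.05)
  # the raw staircase area overestimates a smooth sphere
  af <- interface_area(mesh, "bz_vs_core", method = "facet")
  expect_gt(af, 1.3 * truth)
})

test_that("halving the voxel edge moves the sphere area by little", {
  a1 <- interface_area(build_labeled_mesh(
    field_from_labels(sphere_core_labels(24L, 1.3, 10), rep(1.3, 3))),
    "bz_vs_core", method = "normal_weighted")
  a2 <- interface_area(build_labeled_mesh(
    field_from_labels(sphere_core_labels(48L, 0.65, 10), rep(0.65, 3))),
    "bz_vs_core", method = "normal_weighted")
  expect_lt(abs(a2 - a1) / a1, 0.05)
})

test_that("healthy-HE area ignores the BZ/core split", {
  set.seed(5)
  lab <- array(sample(0:2, 1000, replace = TRUE), c(10, 10, 10))
  f1 <- field_from_labels(lab)
  swapped <- lab
  swapped[lab == 1L] <- 2L
  swapped[lab == 2L] <- 1L
  f2 <- field_from_labels(swapped)
  m1 <- build_labeled_mesh(f1)
  m2 <- build_labeled_mesh(f2)
  expect_equal(interface_area(m1, "healthy_vs_he"),
               interface_area(m2, "healthy_vs_he"), tolerance = 1e-12)
})

test_that("absent class pairs give zero area", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:4, 2:4, 2:4] <- 1L
  mesh <- build_labeled_mesh(field_from_labels(lab))
  expect_identical(interface_area(mesh, "bz_vs_core"), 0)
  expect_gt(interface_area(mesh, "healthy_vs_he"), 0)
})

test_that("layer-path meshes approximate the shell with centroid labels", {
  st <- generate_phantom(spherical_shell_spec(22, 32))
  psi <- compute_psi(st, mode = "global_max")
  model <- build_layered_model(st, psi, n_layers = 5, n_theta = 96)
  mesh <- build_labeled_mesh(model, psi = psi,
                             config = threshold_config(40, 60))
  analytic_ml <- 4 / 3 * pi * (32^3 - 22^3) / 1000
  # ray-cast surfaces at 5 mm slices clip the polar caps, so the layer
  # path is held to a looser band than the voxel path
  expect_lt(abs(mesh_volume(mesh) - analytic_ml) / analytic_ml, 0.08)
  # uniform noise-free shell: one PSI level, hence one element label
  expect_identical(length(unique(mesh$labels)), 1L)
  # inverted surfaces are rejected
  bad <- model
  bad$r_epi <- model$r_endo - 1
  expect_error(build_labeled_mesh(bad, psi = psi,
                                  config = threshold_config(40, 60)),
               "inverted")
})

test_that("BZ-core surface is smallest at the widest PSI window", {
  # gradation phantoms: heterogeneous enhancement via thick partial-volume
  # blur, so the apparent core shrinks as the window widens
  areas <- sapply(1:4, function(s) {
    st <- generate_phantom(gradation_phantom_spec(seed = s))
    psi <- compute_psi(st)
    vapply(psi_threshold_presets(), function(cfg) {
      interface_area(build_labeled_mesh(classify_psi(psi, cfg)),
                     "bz_vs_core")
    }, 0)
  })
  mean_area <- rowMeans(areas)
  expect_lt(mean_area["psi30_70"], mean_area["psi45_55"])
  expect_lt(mean_area["psi30_70"], mean_area["psi40_60"])
  expect_lt(mean_area["psi30_70"], mean_area["psi35_65"])
})
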