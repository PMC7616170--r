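test_that("fields without border zone or without core give empty sets", {
  lab <- array(0L, c(8, 8, 8))
  lab[1:20] <- 2L
  cs <- detect_corridors(field_from_labels(lab))
  expect_identical(cs$total_count, 0L)
  expect_identical(cs$total_mass_g, 0)
  # BZ present but no core at all: empty set, not an error
  lab2 <- array(0L, c(8, 8, 8))
  lab2[200:260] <- 1L
  cs2 <- detect_corridors(field_from_labels(lab2))
  expect_identical(cs2$total_count, 0L)
})

test_that("phantom channels are recovered as corridors with BZ-only voxels", {
  st <- generate_phantom(channels_phantom_spec(k = 3, noise_sigma = 0,
                                               blur_sigma_mm = 0))
  fld <- truth_label_field(st)
  cs <- detect_corridors(fld)
  expect_identical(cs$total_count, 3L)
  all_vox <- unlist(lapply(cs$corridors, `[[`, "voxels"))
  expect_false(any(duplicated(all_vox)))             # disjoint
  expect_true(all(fld$labels[all_vox] == 1L))        # entirely BZ
  # each detected corridor is fully core-enclosed in this phantom
  expect_true(all(vapply(cs$corridors, `[[`, 0, "core_fraction") == 1))
  expect_equal(cs$total_mass_g,
               sum(vapply(cs$corridors, `[[`, 0, "mass_g")),
               tolerance = 1e-12)
})

test_that("an outer BZ rim touching mostly healthy tissue is not a corridor", {
  # core block wrapped in a BZ shell wrapped in healthy: the shell's outer
  # surface contacts healthy, its inner surface core -> fraction ~1/2 < 2/3
  lab <- array(0L, c(20, 20, 20))
  lab[7:14, 7:14, 7:14] <- 1L
  lab[9:12, 9:12, 9:12] <- 2L
  f <- field_from_labels(lab)
  cs <- detect_corridors(f)
  expect_identical(cs$total_count, 0L)
  # the same shell is admitted when the required core fraction is lowered
  cs2 <- detect_corridors(f, core_fraction_min = 0.2)
  expect_identical(cs2$total_count, 1L)
})

test_that("boundary-contact counts match an exhaustive neighbour scan", {
  set.seed(13)
  lab <- array(sample(0:2, 8000, replace = TRUE, prob = c(.4, .2, .4)),
               c(20, 20, 20))
  f <- field_from_labels(lab)
  cs <- detect_corridors(f, core_fraction_min = 2 / 3, min_voxels = 1L)
  comp <- scarshape:::label_components_26(lab == 1L)
  oracle <- contact_counts_brute(lab, comp)
  frac <- ifelse(oracle$core + oracle$healthy > 0,
                 oracle$core / (oracle$core + oracle$healthy), 0)
  sizes <- tabulate(comp[comp > 0], max(comp))
  expect_identical(cs$total_count,
                   length(which(frac >= 2 / 3 & sizes >= 1)))
  for (co in cs$corridors) {
    cid <- comp[co$voxels[1]]
    expect_identical(co$core_contacts, as.integer(oracle$core[cid]))
    expect_identical(co$healthy_contacts, as.integer(oracle$healthy[cid]))
  }
})

test_that("detection is a pure function of the label field", {
  st <- generate_phantom(channels_phantom_spec(k = 2, seed = 3))
  f <- classify_psi(compute_psi(st), threshold_config(40, 60))
  a <- detect_corridors(f)
  b <- detect_corridors(f)
  expect_identical(corridor_report(a), corridor_report(b))
})

test_that("corridor report totals follow the mass convention", {
  # two BZ slabs of 10 and 20 voxels embedded in core
  lab <- array(2L, c(20, 20, 6))
  lab[3:4, 3:7, 3] <- 1L    # 10 voxels
  lab[10:13, 10:14, 3] <- 1L  # 20 voxels
  f <- field_from_labels(lab, spacing = c(1.3, 1.3, 5))
  cs <- detect_corridors(f)
  expect_identical(cs$total_count, 2L)
  expect_equal(cs$total_mass_g, 30 * 0.00845 * 1.05)
  rep <- corridor_report(cs)
  expect_identical(nrow(rep), 3L)
  tot <- rep[rep$corridor_id == "total", ]
  expect_equal(tot$mass_g, sum(rep$mass_g[rep$corridor_id != "total"]),
               tolerance = 1e-9)
  # canonical ordering by minimum linear index
  expect_true(cs$corridors[[1]]$voxels[1] < cs$corridors[[2]]$voxels[1])
  # empty report
  empty <- corridor_report(detect_corridors(
    field_from_labels(array(0L, c(4, 4, 4)))))
  expect_identical(empty$n_voxels, 0L)
  expect_identical(empty$mass_g, 0)
})
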