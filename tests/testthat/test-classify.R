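make_psi_field <- function(values) {
  # psi_map with given in-mask PSI values laid out in a cube
  n <- ceiling(length(values)^(1 / 3))
  arr <- array(NA_real_, c(n, n, n))
  mask <- array(FALSE, c(n, n, n))
  arr[seq_along(values)] <- values
  mask[seq_along(values)] <- TRUE
  structure(list(psi = arr, reference_max = 100,
                 normalization_mode = "global_max", percentile = NA,
                 spacing = c(1.3, 1.3, 5), mask = mask),
            class = "psi_map")
}

test_that("threshold boundaries assign the border zone (closed interval)", {
  psi <- make_psi_field(c(39.99, 40, 50, 60, 60.01))
  f <- classify_psi(psi, threshold_config(40, 60))
  lab <- f$labels[f$mask]
  expect_identical(lab, c(0L, 1L, 1L, 1L, 2L))
})

test_that("classification is idempotent and voxel-order independent", {
  set.seed(42)
  psi <- make_psi_field(stats::runif(1000, 0, 100))
  cfg <- threshold_config(40, 60)
  a <- classify_psi(psi, cfg)
  b <- classify_psi(psi, cfg)
  expect_identical(a$labels, b$labels)
  # order independence: the rule is per voxel, so a permuted field maps to
  # the permuted labels
  perm <- sample(1000)
  psi_p <- make_psi_field(psi$psi[psi$mask][perm])
  c2 <- classify_psi(psi_p, cfg)
  expect_identical(c2$labels[c2$mask], a$labels[a$mask][perm])
})

test_that("widening the threshold window grows BZ and shrinks core", {
  set.seed(7)
  psi <- make_psi_field(stats::runif(1000, 0, 100))
  narrow <- classify_psi(psi, threshold_config(45, 55))$labels
  wide <- classify_psi(psi, threshold_config(30, 70))$labels
  # brute-force set comparison over all voxels
  expect_true(all(which(narrow == 1L) %in% which(wide == 1L)))
  expect_true(all(which(wide == 2L) %in% which(narrow == 2L)))
  expect_true(all(which(wide == 0L) %in% which(narrow == 0L)))
})

test_that("masses follow the voxel-count x volume x density convention", {
  lab <- array(0L, c(10, 10, 10))
  lab[seq_len(1000)] <- 1L  # 1000 BZ voxels
  f <- field_from_labels(lab, spacing = c(1.3, 1.3, 5.0))
  rep <- quantify_masses(f, density = 1.05)
  expect_equal(rep$bz_g, 1000 * 0.00845 * 1.05)
  expect_equal(rep$bz_g, 8.8725)
})

test_that("a field without core has zero core mass and HE equal to BZ", {
  lab <- array(0L, c(6, 6, 6))
  lab[1:40] <- 1L
  f <- field_from_labels(lab)
  rep <- quantify_masses(f)
  expect_identical(rep$core_g, 0)
  expect_equal(rep$total_enhancement_g, rep$bz_g)
})

test_that("mass partition identities hold exactly on random fields", {
  set.seed(11)
  for (i in 1:5) {
    lab <- array(sample(0:2, 512, replace = TRUE), c(8, 8, 8))
    f <- field_from_labels(lab)
    rep <- quantify_masses(f)
    expect_identical(rep$total_enhancement_g, rep$bz_g + rep$core_g)
    expect_identical(rep$healthy_g + rep$total_enhancement_g,
                     rep$total_myocardium_g)
    expect_true(all(c(rep$healthy_g, rep$bz_g, rep$core_g) >= 0))
  }
})

test_that("threshold configurations validate their bounds", {
  expect_error(threshold_config(60, 40), "t_low < t_high")
  expect_error(threshold_config(0, 60), "t_low")
  expect_error(threshold_config(40, 100), "t_high")
  cfg <- threshold_config(40, 60)
  expect_identical(cfg$id, "psi40_60")
  presets <- psi_threshold_presets()
  expect_identical(names(presets),
                   c("psi45_55", "psi40_60", "psi35_65", "psi30_70"))
  widths <- vapply(presets, function(cc) cc$t_high - cc$t_low, 0)
  expect_true(all(diff(widths) > 0))  # ordered narrow to wide
})
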