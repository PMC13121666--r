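# Texture-matrix families against hand-enumerated examples, degenerate-region
# conventions, normalization/invariance properties, and the brute-force
# oracles on random small regions (the full 100-seed sweep runs in the
# acceptance suite; a faster sweep here guards day-to-day development).

test_that("GLCM joint probabilities match hand-enumerated pairs on a 2x2x1 region", {
  disc <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))  # column 1 = level 1, column 2 = level 2
  mask <- array(TRUE, c(2, 2, 1))
  mats <- glcm_matrices(disc, mask, 2)
  # in-column direction (0,1,0): pairs (1,2) and (1,2) -> symmetric counts
  # in-row direction (1,0,0): pairs (1,1) and (2,2)
  P_row <- mats[["1,0,0"]]
  expect_equal(P_row[1, 1], 1 / 2)   # P(1,1) along the in-row direction
  expect_equal(P_row[2, 2], 1 / 2)
  expect_equal(P_row[1, 2], 0)
  for (P in mats) {
    expect_true(all(P >= 0))
    expect_equal(sum(P), 1, tolerance = 1e-9)
    expect_equal(P, t(P))
  }
})

test_that("constant regions give the documented degenerate conventions", {
  disc <- array(1L, c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  tx <- texture_matrix_features(disc, mask, 1)
  expect_equal(unname(tx["glcm_Contrast"]), 0)
  expect_equal(unname(tx["glcm_Correlation"]), 1)
  expect_equal(unname(tx["ngtdm_Contrast"]), 0)
  # a constant region is one run per direction line; GLRLM GLN = Nr per dir
  R <- habitatrad:::glrlm_matrix_dir(disc, mask, 1, c(1, 0, 0), 3)
  expect_equal(sum(R), 9)            # 9 lines along x, one run each
  expect_equal(R[1, 3], 9)           # all runs have length 3
  # single zone of size 27
  expect_equal(unname(tx["glszm_ZonePercentage"]), 1 / 27)
  expect_equal(unname(tx["glszm_LargeAreaEmphasis"]), 27^2)
})

test_that("single-voxel regions return conventions, not exceptions", {
  d <- c(3, 3, 3)
  mask <- array(FALSE, d); mask[2, 2, 2] <- TRUE
  disc <- array(0L, d); disc[2, 2, 2] <- 1L
  expect_silent(tx <- texture_matrix_features(disc, mask, 1))
  expect_equal(unname(tx["glcm_Correlation"]), 1)
  expect_true(all(is.finite(tx)))
})

test_that("texture features are invariant to affine intensity transforms via discretization", {
  set.seed(7)
  d <- c(6, 6, 6)
  v <- array(runif(prod(d)), d)
  m <- array(runif(prod(d)) > 0.4, d)
  d1 <- discretize(v, m, 8)
  d2 <- discretize(3 * v + 2, m, 8)
  expect_identical(d1, d2)
  expect_equal(texture_matrix_features(d1, m, 8),
               texture_matrix_features(d2, m, 8))
})

test_that("texture features are translation invariant", {
  set.seed(8)
  core <- array(sample.int(4, 27, replace = TRUE), c(3, 3, 3))
  place <- function(at) {
    disc <- array(0L, c(8, 8, 8)); mask <- array(FALSE, c(8, 8, 8))
    disc[at[1]:(at[1] + 2), at[2]:(at[2] + 2), at[3]:(at[3] + 2)] <- core
    mask[at[1]:(at[1] + 2), at[2]:(at[2] + 2), at[3]:(at[3] + 2)] <- TRUE
    texture_matrix_features(disc, mask, 4)
  }
  expect_equal(place(c(1, 1, 1)), place(c(4, 5, 6)), tolerance = 1e-12)
})

test_that("all 75 texture features match the brute-force oracle on random regions", {
  for (seed in 1:12) {
    reg <- random_region(seed, side = 4 + seed %% 3, n_levels = 4)
    got <- texture_matrix_features(reg$disc, reg$mask, reg$n_levels)
    want <- oracle_texture_battery(reg$disc, reg$mask, reg$n_levels)
    expect_equal(got[names(want)], want, tolerance = 1e-8,
                 label = sprintf("seed %d", seed))
  }
})

test_that("run-length and zone matrices match the naive walkers exactly", {
  for (seed in 20:24) {
    reg <- random_region(seed, side = 5, n_levels = 3)
    max_len <- max(dim(reg$disc))
    for (dir in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, -1))) {
      expect_equal(
        habitatrad:::glrlm_matrix_dir(reg$disc, reg$mask, reg$n_levels, dir, max_len),
        oracle_glrlm_matrix(reg$disc, reg$mask, reg$n_levels, dir, max_len))
    }
    z <- oracle_zones(reg$disc, reg$mask, reg$n_levels)
    # compare zone size multisets per level
    for (l in seq_len(reg$n_levels)) {
      comp <- habitatrad:::connected_components26(reg$mask & reg$disc == l)
      sizes <- sort(tabulate(comp[comp > 0]))
      sizes <- sizes[sizes > 0]
      expect_equal(sizes, sort(unname(z[z[, "level"] == l, "size"])))
    }
  }
})

test_that("the region feature vector has the documented layout and missing rules", {
  case <- fixture_case()
  cfg <- extraction_config()
  fv <- extract_region(case, case$roi, cfg, "ROI")
  expect_length(fv, 293)             # 3 x (18 + 75) + 14
  expect_false(anyNA(fv))
  parsed <- parse_feature_name(names(fv))
  expect_setequal(unique(parsed$modality), c("ICVF", "ISOVF", "ODI", "mask"))
  expect_setequal(unique(parsed$class),
                  c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm", "shape"))
  # shape features appear once, independent of modality
  expect_equal(sum(parsed$class == "shape"), 14)

  tiny <- array(FALSE, dim(case$roi)); tiny[1:3] <- TRUE
  fv2 <- extract_region(case, tiny, cfg, "H3")
  expect_true(all(is.na(fv2)))
  expect_equal(attr(fv2, "missing_reason"), "too_small")

  # determinism
  expect_identical(fv, extract_region(case, case$roi, cfg, "ROI"))
})

test_that("prefusion concatenates subregion vectors and preserves missingness", {
  case <- fixture_case()
  cfg <- extraction_config()
  masks <- list(H1 = case$truth_labels == 1, H2 = case$truth_labels == 2,
                H3 = array(FALSE, dim(case$roi)))
  vecs <- lapply(names(masks), function(h) extract_region(case, masks[[h]], cfg, h))
  names(vecs) <- names(masks)
  fused <- prefuse(vecs)
  expect_length(fused, 3 * 293)
  expect_true(all(is.na(fused[grep("^H3_", names(fused))])))
  expect_false(anyNA(fused[grep("^H1_", names(fused))]))
  parsed <- parse_feature_name(names(fused))
  expect_setequal(unique(parsed$subregion), c("H1", "H2", "H3"))
  expect_error(prefuse(list(vecs$H1, vecs$H1)), "duplicate")
})

test_that("the extended filter bank produces the documented feature count", {
  cfg <- extraction_preset("extended")
  nm <- feature_names(cfg, "ROI")
  expect_length(nm, 3 * 12 * 93 + 14)  # 3 maps x (1 + 3 LoG + 8 wavelet) x 93 + shape
  # filters are applied without error on a small case
  case <- fixture_case()
  small <- habitatrad:::crop_bbox(case$maps$ICVF, habitatrad:::bbox_ranges(case$roi, 2))
  for (f in cfg$filter_bank)
    expect_true(all(is.finite(apply_filter(small, f, c(1, 1, 1)))))
})
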