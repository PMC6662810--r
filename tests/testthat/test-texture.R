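test_that("quantization bins the 8-bit range uniformly and monotonically", {
  q <- quantize(matrix(128, 8, 8), levels = 16)
  expect_length(unique(as.vector(q$pixels)), 1L)

  q2 <- quantize(matrix(c(0, 255), 2, 2), levels = 2)
  expect_equal(sort(unique(as.vector(q2$pixels))), c(0L, 1L))
  expect_equal(q2$pixels[matrix(c(0, 255), 2, 2) == 0][1], 0L)
  expect_equal(q2$pixels[matrix(c(0, 255), 2, 2) == 255][1], 1L)

  ramp <- quantize(matrix(0:255, 16, 16), levels = 4)
  expect_equal(as.vector(table(ramp$pixels)), rep(64L, 4L))

  expect_error(quantize(matrix(0, 4, 4), levels = 1), "levels")
  expect_error(quantize(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("mask dimensions are validated and passed through", {
  img <- matrix(0:63, 8, 8)
  expect_error(quantize(img, mask = matrix(TRUE, 4, 4)), "dimensions")
  q <- quantize(img, mask = matrix(c(TRUE, FALSE), 8, 8))
  expect_true(is.logical(q$mask))
})

test_that("GLCM matches hand enumeration on degenerate and toy grids", {
  # constant image: single co-occurring pair type
  qc <- quantize(matrix(100, 8, 8), 16)
  for (d in texture_directions()) {
    g <- compute_glcm(qc, distance = 3, direction = d)
    expect_equal(sum(g$counts), 1)
    expect_equal(max(g$counts), 1)
  }

  # checkerboard, d = 1, 0 degrees: every horizontal pair differs
  cb <- matrix((outer(1:8, 1:8, "+") %% 2) * 255, 8, 8)
  g <- compute_glcm(quantize(cb, 2), 1, "0")
  expect_equal(g$counts, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # toy 4x4 grid against the brute-force pair-counting oracle
  q <- toy_qimage()
  for (d in texture_directions()) {
    g <- compute_glcm(q, 1, d)
    expect_equal(g$counts, glcm_oracle(toy_grid(), 3L, 1L, d),
                 tolerance = 1e-15)
  }
})

test_that("GLCM respects distance preconditions and masks", {
  q <- quantize(matrix(0:63, 8, 8), 8)
  expect_error(compute_glcm(q, distance = 8, direction = "0"), "exceed")
  expect_error(compute_glcm(q, distance = 0), ">= 1")

  # mask excluding one half: pairs crossing the boundary are dropped
  mask <- matrix(FALSE, 8, 8); mask[, 1:4] <- TRUE
  qm <- quantize(matrix(rep(0:7, each = 8) * 32, 8, 8), 8, mask = mask)
  g <- compute_glcm(qm, 1, "0")
  expect_equal(g$npairs, 8 * 3)
})

test_that("GLCM is normalized and symmetric on random images; rotation by 90
          degrees permutes the direction axes", {
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(sample(0:255, 30 * 40, replace = TRUE), 30, 40)
    q <- quantize(img, 8)
    for (d in texture_directions()) {
      g <- compute_glcm(q, 2, d)
      expect_equal(sum(g$counts), 1, tolerance = 1e-12)
      expect_equal(g$counts, t(g$counts))
    }
    # counterclockwise rotation: 0 <-> 90 and 45 <-> 135 swap exactly
    rot <- t(img)[ncol(img):1, ]
    qr <- quantize(rot, 8)
    expect_equal(compute_glcm(qr, 2, "90")$counts,
                 compute_glcm(q, 2, "0")$counts)
    expect_equal(compute_glcm(qr, 2, "135")$counts,
                 compute_glcm(q, 2, "45")$counts)
  }
})

test_that("Haralick parameters match the independent summation oracle", {
  # constant image: deterministic extreme values, undefined correlation
  qc <- quantize(matrix(100, 8, 8), 16)
  g <- compute_glcm(qc, 3, "45")
  expect_warning(f <- glcm_features(g), "correlation undefined")
  expect_equal(unname(f["angular_second_moment"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["inverse_difference_moment"]), 1)
  expect_true(is.na(f["correlation"]))

  # checkerboard: all pairs differ by exactly one level
  cb <- matrix((outer(1:8, 1:8, "+") %% 2) * 255, 8, 8)
  f2 <- glcm_features(compute_glcm(quantize(cb, 2), 1, "0"))
  expect_equal(unname(f2["contrast"]), 1)
  expect_equal(unname(f2["inverse_difference_moment"]), 0.5)

  # toy grid, all four directions, against the double-loop oracle
  for (d in texture_directions()) {
    g <- compute_glcm(toy_qimage(), 1, d)
    expect_equal(glcm_features(g), haralick_oracle(g$counts),
                 tolerance = 1e-12)
  }
})

test_that("GLRLM counts maximal runs exactly", {
  # constant image: one run per row at 0 degrees
  r <- compute_glrlm(quantize(matrix(100, 8, 8), 8), "0")
  expect_equal(r$n_runs, 8L)
  expect_equal(sum(r$counts[, 8]), 8L)
  expect_equal(r$n_pixels, 64L)

  # checkerboard: 64 runs of length 1
  cb <- matrix((outer(1:8, 1:8, "+") %% 2) * 255, 8, 8)
  rc <- compute_glrlm(quantize(cb, 2), "0")
  expect_equal(rc$n_runs, 64L)
  expect_equal(ncol(rc$counts), 1L)

  # explicit row: runs (1,2), (2,3), (1,1)
  q1 <- structure(list(pixels = matrix(c(1L, 1L, 2L, 2L, 2L, 1L), 1, 6),
                       levels = 3L, mask = NULL), class = "quantized_image")
  rr <- compute_glrlm(q1, "0")
  expect_equal(rr$n_runs, 3L)
  expect_equal(rr$counts[2, 1], 1L)  # level 1, length 1
  expect_equal(rr$counts[2, 2], 1L)  # level 1, length 2
  expect_equal(rr$counts[3, 3], 1L)  # level 2, length 3
})

test_that("GLRLM matches the line-walking oracle in all four directions", {
  for (s in 1:3) {
    set.seed(s)
    px <- matrix(sample(0:3, 12 * 9, replace = TRUE), 12, 9)
    q <- structure(list(pixels = px, levels = 4L, mask = NULL),
                   class = "quantized_image")
    for (d in texture_directions()) {
      got <- compute_glrlm(q, d)$counts
      want <- glrlm_oracle(px, 4L, d)
      expect_equal(unname(got), unname(want))
      # every pixel belongs to exactly one run
      rr <- matrix(seq_len(ncol(got)), nrow(got), ncol(got), byrow = TRUE)
      expect_equal(sum(got * rr), length(px))
    }
  }
})

test_that("masked-out pixels break runs and are excluded", {
  px <- matrix(2L, 1, 6)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), 1, 6)
  q <- structure(list(pixels = px, levels = 4L, mask = mask),
                 class = "quantized_image")
  r <- compute_glrlm(q, "0")
  expect_equal(r$n_runs, 2L)
  expect_equal(r$n_pixels, 5L)
  expect_error(compute_glrlm(
    structure(list(pixels = px, levels = 4L,
                   mask = matrix(FALSE, 1, 6)), class = "quantized_image"),
    "0"), "mask")
})

test_that("run-length parameters obey their closed forms", {
  cb <- matrix((outer(1:8, 1:8, "+") %% 2) * 255, 8, 8)
  f <- glrlm_features(compute_glrlm(quantize(cb, 2), "0"))
  expect_equal(unname(f["short_run_emphasis"]), 1)
  expect_equal(unname(f["long_run_emphasis"]), 1)

  fc <- glrlm_features(compute_glrlm(quantize(matrix(100, 8, 8), 8), "0"))
  expect_equal(unname(fc["short_run_emphasis"]), 1 / 64)
  expect_equal(unname(fc["long_run_emphasis"]), 64)
  expect_equal(unname(fc["grey_level_nonuniformity"]), 8)
  expect_equal(unname(fc["run_length_nonuniformity"]), 8)

  q1 <- structure(list(pixels = matrix(c(1L, 1L, 2L, 2L, 2L, 1L), 1, 6),
                       levels = 3L, mask = NULL), class = "quantized_image")
  f1 <- glrlm_features(compute_glrlm(q1, "0"))
  expect_equal(unname(f1["long_run_emphasis"]), 14 / 3)

  # random grids against the oracle formulas
  for (s in 1:3) {
    set.seed(s)
    px <- matrix(sample(0:3, 60, replace = TRUE), 6, 10)
    q <- structure(list(pixels = px, levels = 4L, mask = NULL),
                   class = "quantized_image")
    R <- compute_glrlm(q, "45")
    expect_equal(glrlm_features(R), glrlm_features_oracle(R$counts),
                 tolerance = 1e-12)
  }
})

test_that("directional tables carry 15 parameters x 4 directions and
          register anisotropy", {
  # isotropic (constant) input: all directions agree where defined
  suppressWarnings(tab <- directional_table(quantize(matrix(100, 12, 12), 8),
                                            distance = 3))
  expect_equal(dim(tab), c(15L, 4L))
  expect_equal(rownames(tab), texture_parameter_names())
  iso <- tab[setdiff(rownames(tab), "correlation"), ]
  expect_equal(iso[, "0"], iso[, "90"])

  # horizontal stripes (alternating rows): 0 vs 90 degrees must differ
  stripes <- matrix(rep(c(0, 255), 12), 24, 24)
  tabs <- directional_table(quantize(stripes, 2), distance = 1)
  expect_gt(abs(tabs["contrast", "90"] - tabs["contrast", "0"]), 0.5)

  # matches the per-direction primitives it is assembled from
  q <- toy_qimage()
  tt <- directional_table(q, distance = 1)
  expect_equal(tt["contrast", "45"],
               unname(glcm_features(compute_glcm(q, 1, "45"))["contrast"]))
  expect_equal(tt["long_run_emphasis", "135"],
               unname(glrlm_features(compute_glrlm(q, "135"))["long_run_emphasis"]))

  # long-form export: one row per direction, parameters as columns
  df <- as.data.frame(tt)
  expect_equal(nrow(df), 4L)
  expect_equal(df$direction, texture_directions())
  expect_true(all(df$distance == 1L))
  expect_equal(df$contrast, unname(tt["contrast", ]))
})
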