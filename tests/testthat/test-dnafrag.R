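test_that("adaptive thresholding reacts to gradients with the declared polarity", {
  uniform <- matrix(128, 80, 80)
  expect_equal(sum(adaptive_threshold(uniform, adaptive_threshold_params(15, 5))), 0)

  img <- matrix(200, 100, 100)
  rr <- outer((1:100 - 50)^2, (1:100 - 50)^2, "+")
  img[rr <= 10^2] <- 80   # dark disc, radius 10
  dark <- adaptive_threshold(img, adaptive_threshold_params(31, 5, "dark"))
  disc <- rr <= 10^2
  expect_true(all(dark[disc] == 1))
  expect_lte(sum(dark[!disc]), sum(rr <= 11^2) - sum(disc))  # at most a 1-px rim

  bright <- adaptive_threshold(img, adaptive_threshold_params(31, 5, "bright"))
  expect_equal(sum(bright[disc]), 0)

  expect_error(adaptive_threshold(matrix(0, 20, 20),
                                  adaptive_threshold_params(21, 5)),
               class = "spermfx_parameter_error")
  expect_error(adaptive_threshold_params(window = 10),
               class = "spermfx_parameter_error")
})

test_that("head segmentation applies the sanity filter and finds every rendered head", {
  mask <- matrix(0L, 60, 60)
  mask[2:3, 2:5] <- 1L          # 8 px, below sanity
  mask[10:15, 10:19] <- 1L      # 60 px
  mask[30:59, 30:59] <- 1L      # 900 px, above sanity
  segs <- segment_heads(mask, segment_filter(10, 500))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$area_px, 60L)
  expect_equal(nrow(segment_heads(matrix(0L, 10, 10))), 0L)

  sc <- gen_halo_field(small_halo(0.3, seed = 5, n_cells = 50))
  segs2 <- segment_heads(adaptive_threshold(sc$image))
  expect_equal(nrow(segs2), 50L)
})

test_that("fragmentation scoring counts strictly-small heads, threshold inclusive-large", {
  res <- score_fragmentation(c(30, 30, 120, 120), a_star = 60)
  expect_equal(res$score, 50)
  expect_equal(res$n_fragmented, 2L)
  expect_equal(score_fragmentation(c(100, 200, 300), 60)$score, 0)
  expect_equal(score_fragmentation(c(59, 60), 60)$score, 50)  # 60 is non-fragmented
  expect_error(score_fragmentation(numeric(0), 60), class = "spermfx_no_cells_error")
})

test_that("score is order-invariant and non-decreasing in the threshold", {
  with_seed_local(41, {
    areas <- c(rnorm(30, 40, 8), rnorm(70, 140, 8))
    shuffled <- sample(areas)
    expect_equal(score_fragmentation(areas, 90)$score,
                 score_fragmentation(shuffled, 90)$score)
    scores <- vapply(seq(20, 200, 10),
                     function(a) score_fragmentation(areas, a)$score, numeric(1))
    expect_true(all(diff(scores) >= 0))
  })
})

test_that("calibration recovers a separating threshold and reproduces known scores", {
  cal <- lapply(list(c(f = 0.2, seed = 61), c(f = 0.7, seed = 67)), function(p) {
    sc <- gen_halo_field(small_halo(p[["f"]], seed = p[["seed"]], n_cells = 60))
    list(images = list(sc$image), known_score = 100 * p[["f"]])
  })
  a_star <- calibrate_area_threshold(cal)
  expect_gt(a_star, 55)
  expect_lt(a_star, 110)
  for (s in cal) {
    segs <- segment_heads(adaptive_threshold(s$images[[1]]))
    expect_lte(abs(score_fragmentation(segs, a_star)$score - s$known_score), 3)
  }

  # degenerate: every sample is score 0 with large heads -> smallest zero-MAE grid value
  degenerate <- list(list(areas = c(150, 160, 170), known_score = 0),
                     list(areas = c(140, 180), known_score = 0))
  expect_equal(calibrate_area_threshold(degenerate, grid = 50:140), 50,
               ignore_attr = TRUE)
  expect_error(calibrate_area_threshold(degenerate[1]),
               class = "spermfx_insufficient_calibration_error")
})

test_that("a held-out sample scores within tolerance using the calibrated threshold", {
  cal <- lapply(list(c(0.2, 71), c(0.6, 73)), function(p) {
    sc <- gen_halo_field(small_halo(p[1], seed = p[2], n_cells = 60))
    list(images = list(sc$image), known_score = 100 * p[1])
  })
  a_star <- calibrate_area_threshold(cal)
  held <- gen_halo_field(small_halo(0.4, seed = 79, n_cells = 60))
  res <- run_dnafrag_assay(list(held$image), a_star = a_star)
  expect_lte(abs(res$score - 40), 5)
})

test_that("assay pools segments across images and rejects empty fields", {
  imgs <- lapply(c(83, 89, 97), function(s)
    gen_halo_field(small_halo(0.3, seed = s, n_cells = 40))$image)
  res <- run_dnafrag_assay(imgs, a_star = 90)
  expect_equal(res$n_total, 120L)
  expect_lte(abs(res$score - 30), 3)

  single <- matrix(200, 200, 200)
  rr <- outer((1:200 - 100)^2, (1:200 - 100)^2, "+")
  single[rr <= 7^2] <- 100
  res1 <- run_dnafrag_assay(list(single), a_star = 60)
  expect_equal(res1$score, 0)

  blank <- matrix(150, 200, 200)
  expect_error(run_dnafrag_assay(list(blank), a_star = 60),
               class = "spermfx_no_cells_error")
})
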