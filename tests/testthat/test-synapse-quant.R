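test_that("ROI extraction honours pixel size and refuses out-of-bounds ROIs", {
  geom <- embryo_geometry()
  img <- matrix(runif(prod(geom$shape)), geom$shape[1], geom$shape[2])
  roi <- extract_roi(img, geom, 1)
  expect_equal(dim(roi), c(20L, 20L))          # 400 um^2 at 1 um/px
  g05 <- embryo_geometry(pixel_size = 0.5, shape = c(280L, 720L),
                         exit_row = 40L, hm_row = 96L,
                         ventral_extent_row = 240L,
                         exit_cols = seq(80L, by = 80L, length.out = 8L))
  img2 <- matrix(0, 280, 720)
  expect_equal(dim(extract_roi(img2, g05, 1)), c(40L, 40L))
  # an ROI pushed over the border errors instead of clipping
  gsmall <- embryo_geometry(shape = c(60L, 360L), exit_row = 20L, hm_row = 55L,
                            ventral_extent_row = 58L)
  img3 <- matrix(0, 60, 360)
  expect_error(extract_roi(img3, gsmall, 1), "exceeds image bounds")
})

test_that("top-hat background subtraction removes offsets and preserves spots", {
  flat <- matrix(0.4, 30, 30)
  out <- subtract_background(flat, 10, 1)
  expect_true(all(out == 0))
  expect_true(all(out >= 0))
  # Gaussian spot on a constant offset: offset removed, peak preserved
  spot <- capscreen:::.add_spot(matrix(0.2, 30, 30), 15.5, 15.5, 1.5, 0.6)
  corr <- subtract_background(spot, 10, 1)
  expect_lt(abs(max(corr) - max(spot - 0.2)) / max(spot - 0.2), 0.05)
  expect_true(all(corr >= 0))
  expect_error(subtract_background(flat, -1), "positive")
})

test_that("percent-of-maximum binarisation is correct, monotone and safe on zeros", {
  roi <- matrix(0, 20, 20); roi[5, 5] <- 200; roi[10, 10] <- 70; roi[15, 15] <- 50
  m <- binarize(roi, 0.3)   # threshold 60
  expect_true(m[5, 5] && m[10, 10])
  expect_false(m[15, 15])
  m5 <- binarize(roi, 0.5)
  expect_true(all(!m5 | m))  # foreground shrinks as the fraction rises
  expect_equal(sum(binarize(matrix(0, 8, 8), 0.3)), 0L)
  expect_error(binarize(roi, 1.2), "fraction")
})

test_that("puncta statistics count 8-connected components above the size filter", {
  mask <- matrix(FALSE, 20, 20)
  mask[3:4, 3:4] <- TRUE           # 4-px punctum
  mask[10:11, 10:11] <- TRUE       # 4-px punctum
  roi <- matrix(1, 20, 20)
  s <- quantify_puncta(mask, roi, pixel_size = 1, min_size_px = 2)
  expect_equal(s$puncta_count, 2L)
  expect_equal(s$total_area_um2, 8)
  expect_equal(s$mean_intensity, 1)
  # an isolated single pixel is filtered out
  mask1 <- matrix(FALSE, 10, 10); mask1[5, 5] <- TRUE
  s1 <- quantify_puncta(mask1, matrix(1, 10, 10))
  expect_equal(s1$puncta_count, 0L)
  expect_equal(s1$total_area_um2, 0)
  expect_true(is.na(s1$mean_intensity))
  expect_error(quantify_puncta(mask, matrix(1, 5, 5)), "shapes differ")
})

test_that("component counts match a brute-force flood-fill oracle", {
  set.seed(123)
  for (i in 1:500) {
    mask <- matrix(runif(900) < runif(1, 0.1, 0.5), 30, 30)
    sizes <- flood_fill_sizes(mask)
    s <- quantify_puncta(mask, matrix(1, 30, 30), min_size_px = 2)
    expect_identical(s$puncta_count, length(sizes[sizes >= 2]))
    expect_identical(s$total_area_um2, as.numeric(sum(sizes[sizes >= 2])))
  }
})

test_that("overlap statistics respect intersection semantics", {
  pre <- matrix(FALSE, 15, 15); pre[3:6, 3:6] <- TRUE
  post <- matrix(FALSE, 15, 15); post[10:12, 10:12] <- TRUE
  roi <- matrix(1, 15, 15)
  # disjoint masks
  s <- overlap_stats(pre, post, roi)
  expect_equal(s$puncta_count, 0L)
  expect_equal(s$total_area_um2, 0)
  # identical masks reproduce single-channel statistics
  s2 <- overlap_stats(pre, pre, roi)
  expect_equal(s2, quantify_puncta(pre, roi))
  # overlap area never exceeds either compartment (random masks)
  set.seed(99)
  for (i in 1:100) {
    a <- matrix(runif(225) < 0.4, 15, 15)
    b <- matrix(runif(225) < 0.4, 15, 15)
    ov <- overlap_stats(a, b, roi, min_size_px = 1)$total_area_um2
    expect_lte(ov, quantify_puncta(a, roi, min_size_px = 1)$total_area_um2)
    expect_lte(ov, quantify_puncta(b, roi, min_size_px = 1)$total_area_um2)
  }
})

test_that("per-embryo measurement averages hemisegments and flags unusable embryos", {
  geom <- embryo_geometry()
  # identical synthetic content in every hemisegment
  img <- array(0, c(geom$shape, 3))
  for (h in 1:5) {
    cc <- geom$exit_cols[h]
    img[, , 2] <- capscreen:::.add_spot(img[, , 2], geom$hm_row, cc, 1.2, 0.5)
    img[, , 3] <- capscreen:::.add_spot(img[, , 3], geom$hm_row, cc, 1.2, 0.4)
  }
  m <- measure_embryo(img, geom)
  expect_true(m$usable)
  expect_equal(m$n_hemisegments, 5L)
  per <- m$per_hemisegment
  pre_area <- per$total_area_um2[per$compartment == "pre"]
  expect_true(all(pre_area == pre_area[1]))            # equal hemisegments
  expect_equal(m$pre$total_area_um2, pre_area[1])      # mean of equals
  # overlap bound at the per-hemisegment level
  for (h in 1:5) {
    sub <- per[per$hemisegment == h, ]
    expect_lte(sub$total_area_um2[sub$compartment == "overlap"],
               min(sub$total_area_um2[sub$compartment != "overlap"]))
  }
  # fewer than four valid ROIs: flagged unusable
  gtight <- embryo_geometry(shape = c(140L, 130L), exit_cols = c(
    15L, 40L, 60L, 80L, 100L, 112L, 120L, 126L))
  img_t <- array(0.1, c(140, 130, 3))
  expect_warning(mt <- measure_embryo(img_t, gtight, hemisegments = 5:8),
                 "unusable")
  expect_false(mt$usable)
})

test_that("noise-free synthetic puncta are counted exactly", {
  geom <- embryo_geometry()
  e <- generate_embryo("wild-type-DMSO", 11, snr = Inf)
  m <- measure_embryo(e$image, geom)
  true_counts <- vapply(e$truth$puncta, function(p) nrow(p$pre), 0L)
  per <- m$per_hemisegment
  expect_equal(per$puncta_count[per$compartment == "pre"], true_counts)
})
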