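test_that("a straight vertical pixel line is traced exactly", {
  geom <- line_geometry()
  img <- line_image(geom$shape, vertical_chain(5, 10, 50))
  tr <- trace_axon(img, geom, 10)
  expect_true(tr$present)
  expect_equal(nrow(tr$path), 51L)
  expect_equal(unname(tr$tip), c(55, 10))
  expect_equal(tr$length_um, 50)
  expect_equal(axon_length(tr, 1), 50)
})

test_that("a pure diagonal line measures sqrt(2) per step", {
  geom <- line_geometry()
  ch <- cbind(5:15, 10:20)
  img <- line_image(geom$shape, ch)
  tr <- trace_axon(img, geom, 10, window_halfwidth_um = 15)
  expect_equal(tr$length_um, 10 * sqrt(2), tolerance = 1e-8)
})

test_that("a blank channel yields an absent axon with zero length", {
  geom <- line_geometry()
  img <- matrix(0, geom$shape[1], geom$shape[2])
  tr <- trace_axon(img, geom, 10)
  expect_false(tr$present)
  expect_equal(tr$length_um, 0)
  expect_warning(len <- axon_length(tr), "absent")
  expect_equal(len, 0)
})

test_that("exit points outside the image are rejected", {
  geom <- line_geometry()
  img <- matrix(0, geom$shape[1], geom$shape[2])
  expect_error(trace_axon(img, geom, 1000), "outside image")
})

test_that("myoseptum crossing uses a margin and is monotone in tip row", {
  geom <- line_geometry() # hm_row = 30
  mk <- function(tip_row) {
    structure(list(exit_point = c(5, 10), exit_col = 10,
                   path = cbind(5:tip_row, 10), tip = c(tip_row, 10),
                   length_um = tip_row - 5, present = TRUE,
                   hm_status = NA), class = "axon_trace")
  }
  expect_equal(classify_hm(mk(30), geom), "stalled")   # exactly on the HM
  expect_equal(classify_hm(mk(32), geom), "stalled")   # inside the margin
  expect_equal(classify_hm(mk(40), geom), "crossed")   # 10 um ventral
  status <- vapply(25:45, function(r) classify_hm(mk(r), geom), "")
  expect_false(is.unsorted(match(status, c("stalled", "crossed"))))
  # absent axons are stalled
  blank <- structure(list(present = FALSE, tip = c(NA, NA)),
                     class = "axon_trace")
  expect_equal(classify_hm(blank, geom), "stalled")
})

test_that("length is invariant under translation and anterior-posterior mirroring", {
  geom <- line_geometry()
  ch <- rbind(vertical_chain(5, 20, 30), cbind(35 + 1:10, 20 + 1:10))
  img <- line_image(geom$shape, ch)
  len0 <- trace_axon(img, geom, 20, window_halfwidth_um = 18)$length_um
  # translate 7 columns to the right
  img_t <- line_image(geom$shape, cbind(ch[, 1], ch[, 2] + 7))
  expect_equal(trace_axon(img_t, geom, 27, window_halfwidth_um = 18)$length_um,
               len0)
  # mirror anterior-posterior
  img_m <- img[, ncol(img):1]
  expect_equal(trace_axon(img_m, geom, ncol(img) - 20L + 1L,
                          window_halfwidth_um = 18)$length_um, len0)
})

test_that("branch counting uses the 8 um offset lines and is side-symmetric", {
  geom <- line_geometry()
  main <- vertical_chain(5, 30, 50)
  add_branch <- function(extent, side = 1) {
    rbind(main, cbind(25 + round((1:extent) * 0.4), 30 + side * (1:extent)))
  }
  hw <- 20
  # a 12 um branch crosses the offset line
  img <- line_image(geom$shape, add_branch(12, -1))
  tr <- trace_axon(img, geom, 30, window_halfwidth_um = hw)
  expect_equal(count_branches(img, tr, geom), 1L)
  # a 5 um branch never reaches the line (filopodium)
  img5 <- line_image(geom$shape, add_branch(5, -1))
  tr5 <- trace_axon(img5, geom, 30, window_halfwidth_um = hw)
  expect_equal(count_branches(img5, tr5, geom), 0L)
  # unbranched axon
  img0 <- line_image(geom$shape, main)
  tr0 <- trace_axon(img0, geom, 30, window_halfwidth_um = hw)
  expect_equal(count_branches(img0, tr0, geom), 0L)
  # anterior/posterior relabelling (mirror) leaves the count unchanged
  img_m <- img[, ncol(img):1]
  tr_m <- trace_axon(img_m, geom, ncol(img) - 30L + 1L,
                     window_halfwidth_um = hw)
  expect_equal(count_branches(img_m, tr_m, geom), 1L)
})

test_that("noise-free renderings recover ground truth at documented tolerances", {
  geom <- embryo_geometry()
  e <- generate_embryo("chodl-DMSO", 7, snr = Inf)
  q <- quantify_axons(e$image, geom)
  ax <- e$truth$axons
  # crossing class and branch counts match truth exactly
  expect_equal(q$hm_status == "crossed", ax$crossed_hm)
  expect_equal(q$present, ax$present)
  expect_equal(q$branch_count, ax$n_branches_ge_8um)
  # lengths: within 10% per axon, 5% on the embryo mean
  rel <- q$length_um / ax$true_length_um - 1
  expect_true(all(abs(rel) < 0.10))
  expect_lt(abs(mean(q$length_um) / mean(ax$true_length_um) - 1), 0.05)
})

test_that("traced lengths track truth on rendered mutant embryos", {
  geom <- embryo_geometry()
  coh <- simulate_cohort("chodl-DMSO", 6, seed = 21)
  meas <- unlist(lapply(coh, function(e)
    quantify_axons(e$image, geom, branches = FALSE)$length_um))
  truth <- unlist(lapply(coh, function(e) e$truth$axons$true_length_um))
  expect_lt(abs(mean(meas) / mean(truth) - 1), 0.05)
})

test_that("abnormality scoring flags missing, truncated and branched axons", {
  geom <- embryo_geometry()
  rules <- abnormality_rules(geom)
  expect_equal(rules$min_normal_length_um,
               (geom$hm_row - geom$exit_row) * geom$pixel_size + 10)
  ax <- data.frame(
    axon_id = 1:7, present = c(FALSE, rep(TRUE, 6)),
    length_um = c(0, 20, rep(50, 5)),
    branch_count = c(0L, 0L, 2L, 0L, 0L, 0L, 0L))
  s <- score_abnormal(ax, rules)
  expect_equal(s$axons$abnormal,
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(s$percent_abnormal, 100 * 3 / 7)
  expect_error(score_abnormal(ax[0, ], rules), "no axons")
})

test_that("measured abnormal fractions recover the generator truth", {
  geom <- embryo_geometry()
  rules <- abnormality_rules(geom)
  coh <- simulate_cohort("uba1", 25, seed = 31)
  meas <- sapply(coh, function(e)
    score_abnormal(quantify_axons(e$image, geom), rules)$percent_abnormal)
  true_frac <- mean(sapply(coh, function(e) mean(e$truth$axons$abnormal)))
  expect_lt(abs(mean(meas) / (100 * true_frac) - 1), 0.10)
})
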