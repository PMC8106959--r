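test_that("generation is deterministic for a fixed preset and seed", {
  e1 <- generate_embryo("chodl-DMSO", 1)
  e2 <- generate_embryo("chodl-DMSO", 1)
  expect_identical(e1$image, e2$image)
  expect_identical(e1$truth$axons, e2$truth$axons)
  e3 <- generate_embryo("chodl-DMSO", 2)
  expect_false(identical(e1$image, e3$image))
})

test_that("unknown presets fail with the list of available presets", {
  expect_error(generate_embryo("no-such-preset", 1), "available presets")
  expect_error(get_preset("nope"), "chodl-DMSO")
})

test_that("control embryos have all axons beyond the myoseptum, mutants do not", {
  wt <- generate_embryo("wild-type-DMSO", 1, render = FALSE)$truth
  expect_equal(nrow(wt$axons), 8L)
  expect_true(all(wt$axons$crossed_hm))
  mu <- generate_embryo("chodl-DMSO", 1, render = FALSE)$truth
  expect_lt(sum(mu$axons$crossed_hm), 8L)
})

test_that("ground-truth invariants hold across presets and seeds", {
  geom <- embryo_geometry()
  for (preset in c("chodl-DMSO", "wild-type-DMSO", "uba1", "dipyridamole-10uM")) {
    for (seed in 1:5) {
      tr <- generate_embryo(preset, seed, render = FALSE)$truth
      ax <- tr$axons
      # crossed implies the tip lies ventral of the myoseptum row
      expect_true(all(ax$tip_row[ax$crossed_hm] > geom$hm_row))
      # absent axons have zero length and are abnormal
      ab <- ax[!ax$present, ]
      expect_true(all(ab$true_length_um == 0) && all(ab$abnormal))
      expect_true(all(ax$true_length_um >= 0))
      # stalled axons never render below the myoseptum
      expect_true(all(ax$tip_row[ax$present & !ax$crossed_hm] <= geom$hm_row))
    }
  }
})

test_that("realized stalled-axon lengths calibrate to the preset mean", {
  coh <- simulate_cohort("chodl-DMSO", 200, seed = 9, render = FALSE,
                         stratified = FALSE)
  lens <- unlist(lapply(coh, function(e) {
    ax <- e$truth$axons
    ax$true_length_um[ax$present & !ax$crossed_hm]
  }))
  nominal <- get_preset("chodl-DMSO")$axon$mean_length_um
  expect_lt(abs(mean(lens) / nominal - 1), 0.02)
})

test_that("the preset registry carries reported calibration values and round-trips", {
  reg <- list_presets()
  expect_true(all(c("chodl-DMSO", "wild-type-DMSO", "uba1",
                    "dipyridamole-10uM") %in% reg$name))
  expect_equal(get_preset("chodl-DMSO")$axon$mean_length_um, 35.06)
  expect_equal(get_preset("dipyridamole-10uM")$axon$mean_length_um,
               1.35 * 35.06)
  # UBEI-41 abnormality multiplier: +117% over the vehicle baseline
  expect_equal(get_preset("uba1")$abnormal$rate /
                 get_preset("wild-type-DMSO")$abnormal$rate, 2.17)
  # every preset survives YAML serialization unchanged
  for (nm in reg$name) {
    p <- get_preset(nm)
    f <- tempfile(fileext = ".yaml")
    yaml::write_yaml(p, f)
    p2 <- yaml::read_yaml(f)
    expect_equal(p2, p, ignore_attr = TRUE, tolerance = 1e-6)
  }
})

test_that("screen generation yields one record per compound embryo", {
  d <- screen_design(20, embryos_per_compound = 6, seed = 2)
  s <- generate_screen(d)
  expect_equal(sum(s$records$role == "compound"), 120L)
  expect_error(screen_design(0), ">= 1")
})

test_that("toxic compounds' embryos are flagged and never scoreable", {
  d <- screen_design(10, n_toxic = c(death = 2, delayed = 1, malformed = 1),
                     seed = 4)
  s <- generate_screen(d)
  tox <- s$records[s$records$toxicity != "none", ]
  expect_gt(nrow(tox), 0)
  expect_true(all(tox$n_scored == 0L))
  expect_true(all(is.na(tox$n_crossed)))
})

test_that("inactive-screen crossing counts follow the control binomial", {
  d <- screen_design(48, embryos_per_compound = 6, seed = 6)
  s <- generate_screen(d)
  x <- s$records$n_crossed[s$records$role == "compound"]
  p <- get_preset("chodl-DMSO")$axon$p_crossed
  obs <- tabulate(x + 1L, nbins = 9L)
  expected_p <- stats::dbinom(0:8, 8, p)
  # pool sparse upper tail for a valid chi-square comparison
  grp <- c(1, 2, 3, 4, rep(5, 5))
  gof <- stats::chisq.test(tapply(obs, grp, sum), p = tapply(expected_p, grp, sum))
  expect_gt(gof$p.value, 0.001)
})

test_that("written embryos round-trip through TIFF and the JSON sidecar", {
  e <- generate_embryo("wild-type-DMSO", 3)
  dir <- tempfile("emb")
  paths <- write_embryo(e, dir, "E00001")
  img <- read_embryo_image(paths["image"])
  expect_equal(dim(img), dim(e$image))
  expect_lt(max(abs(img - e$image)), 1e-6)
  gt <- read_ground_truth(paths["truth"])
  expect_equal(gt$preset, "wild-type-DMSO")
  expect_equal(gt$axons$true_length_um, e$truth$axons$true_length_um)
  expect_equal(gt$toxicity, "none")
})
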