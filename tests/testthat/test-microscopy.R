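# Confocal morphometry: projections, intensities, segmentation, caliber,
# leakage colocalization and tight-junction gap measurement.

test_that("max intensity projection matches a brute-force per-pixel loop", {
  set.seed(2)
  v <- array(runif(8 * 7 * 2 * 4), c(8, 7, 2, 4))
  stk <- z_stack(v, pixel_size = 0.2, channels = c(vessel = 1, tracer = 2, junction = 2))
  mip <- max_intensity_projection(stk)
  brute <- array(0, c(8, 7, 2))
  for (i in 1:8) for (j in 1:7) for (k in 1:2) brute[i, j, k] <- max(v[i, j, k, ])
  expect_equal(mip$channels, brute)
  # single plane -> identity
  one <- z_stack(v[, , , 1, drop = FALSE], 0.2, channels = c(vessel = 1, tracer = 2, junction = 2))
  expect_equal(max_intensity_projection(one)$channels, v[, , , 1])
  # disjoint bright pixels across planes -> union
  a <- array(0, c(4, 4, 1, 2)); a[1, 1, 1, 1] <- 5; a[3, 3, 1, 2] <- 7
  m <- max_intensity_projection(z_stack(a, 0.2, channels = c(vessel = 1)))
  expect_equal(m$channels[1, 1, 1], 5)
  expect_equal(m$channels[3, 3, 1], 7)
})

test_that("corrected intensity follows its formula, is linear, rejects overlap", {
  img <- matrix(20, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[1:2, 1:5] <- TRUE   # 10 px
  bg <- matrix(FALSE, 20, 20); bg[10:20, ] <- TRUE
  img[roi] <- 50
  r <- corrected_intensity(img, roi, bg)
  expect_equal(r$corrected, 500 - 10 * 20)  # 300
  # hand-computed oracle over random images; linear under scaling
  set.seed(5)
  for (i in 1:5) {
    im2 <- matrix(runif(400, 0, 100), 20, 20)
    r1 <- corrected_intensity(im2, roi, bg)
    expect_equal(r1$corrected, sum(im2[roi]) - sum(roi) * mean(im2[bg]))
    k <- runif(1, 0.5, 3)
    expect_equal(corrected_intensity(k * im2, roi, bg)$corrected, k * r1$corrected)
  }
  expect_equal(corrected_intensity(matrix(0, 20, 20), roi, bg)$corrected, 0)
  expect_error(corrected_intensity(img, roi, roi), "overlap")
})

test_that("normalized optical density is the ipsi/contra corrected ratio", {
  img <- matrix(10, 10, 10)
  roi1 <- matrix(FALSE, 10, 10); roi1[1:2, 1:2] <- TRUE
  roi2 <- matrix(FALSE, 10, 10); roi2[4:5, 4:5] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[8:10, ] <- TRUE
  img[roi1] <- 40; img[roi2] <- 20
  ips <- corrected_intensity(img, roi1, bg)
  con <- corrected_intensity(img, roi2, bg)
  expect_equal(normalized_optical_density(ips, con), (40 - 10) / (20 - 10))
})

test_that("immunofluorescence area mask recovers a bright blob and nothing else", {
  set.seed(6)
  img <- matrix(rnorm(200 * 200, 10, 1), 200, 200)
  blob <- matrix(FALSE, 200, 200); blob[80:120, 80:120] <- TRUE
  img[blob] <- img[blob] + 10  # 10 sd above noise
  noise_roi <- matrix(FALSE, 200, 200); noise_roi[1:40, 1:40] <- TRUE
  r <- if_area_mask(img, noise_roi, pixel_size = 0.2)
  expect_gte(sum(r$mask & blob) / sum(blob), 0.99)
  # constant image: nothing exceeds c + 0
  rc <- if_area_mask(matrix(5, 50, 50), corner_roi(c(50, 50), 10), 0.2)
  expect_equal(rc$area_um2, 0)
})

test_that("caliber classes split at 10 um with the boundary assigned large", {
  expect_equal(classify_caliber(4), "small")
  expect_equal(classify_caliber(12), "large")
  expect_equal(classify_caliber(10), "large")
  expect_error(classify_caliber(0), "> 0")
})

test_that("leakage mask demands an explicit threshold and thresholds strictly", {
  img <- matrix(runif(100, 0.1, 1), 10, 10)
  expect_error(leakage_mask(img), "threshold")
  expect_true(all(leakage_mask(img, 0)))
  expect_false(any(leakage_mask(img, 2)))
})

test_that("rendered tube widths match the scene at FWHM within one pixel", {
  diams <- c(4, 7, 10, 14, 20)
  vessels <- lapply(seq_along(diams), function(i)
    list(p0 = c(10, i * 28 - 14), p1 = c(74, i * 28 - 14), diameter = diams[i],
         is_leaky = FALSE))
  sc <- vessel_scene(vessels, list(), image_shape = c(700, 420),
                     noise_sd = c(glut1 = 0, tracer = 0, egfp = 0))
  img <- gen_vessel_image(sc)
  glut <- img$channels[, , "glut1"]
  for (i in seq_along(diams)) {
    prof <- glut[, 210]  # column through every tube midpoint
    ctr <- round((i * 28 - 14) / 0.2)
    seg <- prof[(ctr - 60):(ctr + 60)]
    fwhm_px <- sum(seg >= max(seg) / 2)
    expect_lte(abs(fwhm_px * 0.2 - diams[i]), 0.2 + 1e-9)  # 1 px
  }
})

test_that("noiseless fixture: segmentation recovers calibers and leaky flags exactly", {
  img <- noiseless_fixture()
  glut <- img$channels[, , "glut1"]
  segs <- segment_vessels(glut, img$pixel_size, threshold = 0.5)
  expect_length(segs, 5L)
  # match segments to truth by vertical position
  ctr_row <- vapply(segs, function(s) mean(which(s$mask, arr.ind = TRUE)[, 1]), numeric(1))
  ord <- order(ctr_row)
  truth <- img$truth$vessels
  meas <- vapply(segs[ord], `[[`, numeric(1), "diameter_um")
  expect_true(all(abs(meas - truth$diameter_um) <= img$pixel_size))
  expect_equal(vapply(segs[ord], `[[`, character(1), "caliber"), truth$caliber)

  lm <- leakage_mask(img$channels[, , "tracer"], 0.5)
  rec <- detect_leaky_vessels(segs[ord], lm, img$channels[, , "tracer"], img$pixel_size)
  expect_equal(rec$is_leaky, truth$is_leaky)

  fr <- fraction_leaky(rec, segs[ord])
  # truth: small = {6, 8, 4}, two leaky; large = {12, 16}, one leaky
  expect_equal(fr$fraction[fr$caliber == "small"], 2 / 3)
  expect_equal(fr$fraction[fr$caliber == "large"], 1 / 2)
})

test_that("leaky detection handles empty and full leakage masks", {
  img <- noiseless_fixture()
  segs <- segment_vessels(img$channels[, , "glut1"], img$pixel_size, threshold = 0.5)
  none <- matrix(FALSE, nrow(img$channels), ncol(img$channels))
  rec0 <- detect_leaky_vessels(segs, none, img$channels[, , "tracer"], img$pixel_size)
  expect_false(any(rec0$is_leaky))
  expect_true(all(rec0$leakage_area_um2 == 0))
  all_mask <- !none
  rec1 <- detect_leaky_vessels(segs, all_mask, img$channels[, , "tracer"], img$pixel_size)
  expect_true(all(rec1$is_leaky))
  hw <- round(20 / img$pixel_size)
  expect_true(all(rec1$leakage_area_um2[!rec1$roi_clipped] ==
                    (2 * hw + 1)^2 * img$pixel_size^2))
})

test_that("blank and two-tube images segment to zero and two vessels", {
  expect_length(segment_vessels(matrix(0, 50, 50), 0.2, threshold = 0.5), 0L)
  v <- list(list(p0 = c(4, 5), p1 = c(16, 5), diameter = 4, is_leaky = FALSE),
            list(p0 = c(4, 15), p1 = c(16, 15), diameter = 4, is_leaky = FALSE))
  sc <- vessel_scene(v, list(), image_shape = c(100, 100),
                     noise_sd = c(glut1 = 0, tracer = 0, egfp = 0))
  img <- gen_vessel_image(sc)
  expect_length(segment_vessels(img$channels[, , "glut1"], 0.2, threshold = 0.5), 2L)
})

test_that("fraction_leaky flags empty caliber classes and validates mapping", {
  img <- noiseless_fixture()
  segs <- segment_vessels(img$channels[, , "glut1"], img$pixel_size, threshold = 0.5)
  small_only <- Filter(function(s) s$caliber == "small", segs)
  rec <- detect_leaky_vessels(small_only, matrix(FALSE, nrow(img$channels), ncol(img$channels)),
                              img$channels[, , "tracer"], img$pixel_size)
  fr <- fraction_leaky(rec, small_only)
  expect_true(fr$undefined[fr$caliber == "large"])
  expect_true(is.na(fr$fraction[fr$caliber == "large"]))
  rec$vessel[1] <- 99L
  expect_error(fraction_leaky(rec, small_only), "map")
})

test_that("TJ strands: two edges traced, programmed gaps recovered within 2 px", {
  img <- noiseless_fixture()
  segs <- segment_vessels(img$channels[, , "glut1"], img$pixel_size, threshold = 0.5)
  ctr_row <- vapply(segs, function(s) mean(which(s$mask, arr.ind = TRUE)[, 1]), numeric(1))
  v1 <- segs[order(ctr_row)][[1]]  # the 6-um vessel carrying the strands
  strands <- trace_tj_strands(img$channels[, , "egfp"], v1, img$pixel_size,
                              threshold = 0.3)
  expect_length(strands, 2L)
  gaps <- lapply(strands, measure_gaps)
  lens <- sort(unlist(gaps))
  expect_length(lens, 2L)
  expect_lt(abs(lens[1] - 1.0), 0.4)  # 2 px at 0.2 um/px
  expect_lt(abs(lens[2] - 3.0), 0.4)
  # the continuous edge yields no gaps
  expect_true(any(vapply(gaps, length, integer(1)) == 0L))
})

test_that("a vessel with no junction signal is reported absent", {
  img <- noiseless_fixture()
  segs <- segment_vessels(img$channels[, , "glut1"], img$pixel_size, threshold = 0.5)
  ctr_row <- vapply(segs, function(s) mean(which(s$mask, arr.ind = TRUE)[, 1]), numeric(1))
  v2 <- segs[order(ctr_row)][[2]]  # no strands rendered on this vessel
  strands <- trace_tj_strands(img$channels[, , "egfp"], v2, img$pixel_size,
                              threshold = 0.3)
  expect_length(strands, 1L)
  expect_true(strands[[1]]$absent)
  expect_equal(measure_gaps(strands[[1]]), numeric(0))
})

test_that("sub-floor gaps are discarded and 2.5 um falls in the small bin", {
  v <- list(list(p0 = c(10, 12), p1 = c(70, 12), diameter = 8, is_leaky = FALSE))
  st <- list(list(vessel = 1, side = 1,
                  gaps = data.frame(position = c(15, 30, 45), length = c(0.2, 2.5, 4.0))),
             list(vessel = 1, side = -1, gaps = data.frame(position = numeric(0),
                                                           length = numeric(0))))
  sc <- vessel_scene(v, st, image_shape = c(120, 400),
                     noise_sd = c(glut1 = 0, tracer = 0, egfp = 0))
  img <- gen_vessel_image(sc)
  expect_true(any(grepl("cannot be resolved", img$warnings)))  # the 0.2 um gap
  segs <- segment_vessels(img$channels[, , "glut1"], img$pixel_size, threshold = 0.5)
  tj <- quantify_tj(img$channels[, , "egfp"], segs, img$pixel_size, threshold = 0.3)
  all_gaps <- sort(unlist(lapply(tj$strands, `[[`, "gaps")))
  expect_length(all_gaps, 2L)        # 0.2 um gap below the 0.4 um floor
  expect_true(all(all_gaps >= 0.4))
  per <- tj$summary$per_strand
  gappy <- per[per$n_gaps > 0, ]
  expect_true(gappy$has_gap_small)   # the 2.5 um gap (closed upper bound)
  expect_true(gappy$has_gap_big)     # the 4.0 um gap
})

test_that("gap binning fractions follow the strand counts", {
  mk <- function(gaps, absent = FALSE) structure(
    list(id = 1L, vessel = 1L, side = 1, absent = absent, gaps = gaps),
    class = "tj_strand")
  strands <- list(mk(c(1.0, 3.0)), mk(numeric(0)), mk(numeric(0)), mk(numeric(0)))
  s <- bin_gaps_and_fractions(strands)
  expect_equal(s$frac_gap_small, 0.25)
  expect_equal(s$frac_gap_big, 0.25)
  expect_equal(s$frac_absent, 0)
  s2 <- bin_gaps_and_fractions(list(mk(numeric(0), absent = TRUE)))
  expect_true(s2$undefined)
  expect_true(is.na(s2$frac_gap_small))
})

test_that("gap measurement is invariant under intensity rescaling", {
  img <- noiseless_fixture()
  segs <- segment_vessels(img$channels[, , "glut1"], img$pixel_size, threshold = 0.5)
  ctr_row <- vapply(segs, function(s) mean(which(s$mask, arr.ind = TRUE)[, 1]), numeric(1))
  v1 <- segs[order(ctr_row)][[1]]
  g1 <- sort(unlist(lapply(trace_tj_strands(img$channels[, , "egfp"], v1,
                                            img$pixel_size, threshold = 0.3),
                           measure_gaps)))
  k <- 7.3  # rescale image and threshold together
  g2 <- sort(unlist(lapply(trace_tj_strands(k * img$channels[, , "egfp"], v1,
                                            img$pixel_size, threshold = k * 0.3),
                           measure_gaps)))
  expect_equal(g1, g2)
})

test_that("tracer channel is noise-only when no vessel is leaky", {
  v <- list(list(p0 = c(10, 12), p1 = c(70, 12), diameter = 8, is_leaky = FALSE))
  sc <- vessel_scene(v, list(), image_shape = c(120, 400),
                     noise_sd = c(glut1 = 0, tracer = 0, egfp = 0))
  img <- gen_vessel_image(sc)
  expect_equal(max(img$channels[, , "tracer"]), 0)
})

test_that("scene validation rejects bad geometry", {
  expect_error(vessel_scene(list(list(p0 = c(1, 1), p1 = c(10, 1), diameter = 8,
                                      is_leaky = FALSE))), "exits")
  expect_error(vessel_scene(list(list(p0 = c(10, 10), p1 = c(40, 10), diameter = 0,
                                      is_leaky = FALSE)),
                            image_shape = c(100, 300)), "diameter")
  v <- list(list(p0 = c(10, 10), p1 = c(40, 10), diameter = 8, is_leaky = FALSE))
  expect_error(vessel_scene(v, list(list(vessel = 1, side = 1,
                                         gaps = data.frame(position = 29, length = 5))),
                            image_shape = c(100, 300)), "within the strand")
})

test_that("scenes round-trip through TIFF with ground-truth CSV sidecars", {
  img <- noiseless_fixture()
  dir <- withr::local_tempdir()
  paths <- write_vessel_image(img, dir)
  pages <- tiff::readTIFF(paths[1], all = TRUE)
  expect_length(pages, 3L)
  meta <- jsonlite::read_json(paths[2])
  expect_equal(unlist(meta$channel_order), c("glut1", "tracer", "egfp"))
  rec <- pages[[1]] * meta$channel_scale$glut1
  expect_lt(max(abs(rec - pmax(img$channels[, , "glut1"], 0))), 1e-6)
  truth <- utils::read.csv(file.path(dir, "vessels.csv"))
  expect_equal(truth$diameter_um, img$truth$vessels$diameter_um)
})
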