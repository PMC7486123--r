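mkImage <- function(nx = 80, ny = 80) matrix(0, nx, ny)
addRect <- function(im, x0, y0, w, h, value = 100) {
  im[x0:(x0 + w - 1), y0:(y0 + h - 1)] <- value
  im
}

test_that("chromogenic segmentation honors the 100-400 um^2 band inclusively", {
  im <- mkImage(120, 120)
  im <- addRect(im, 5, 5, 10, 10)     # 100 um^2 at 1 um/px -> retained
  im <- addRect(im, 30, 5, 20, 20)    # 400 um^2 -> retained
  im <- addRect(im, 60, 5, 21, 21)    # 441 um^2 -> dropped
  im <- addRect(im, 90, 5, 9, 11)     # 99 um^2 -> dropped
  rois <- segmentChromogenic(im, sigmaPx = 0, threshold = 50, pixelSize = 1)
  tab <- roiTable(rois)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$area_um2, c(100, 400))

  expect_warning(empty <- segmentChromogenic(mkImage(), sigmaPx = 0,
                                             threshold = 50, pixelSize = 1),
                 "threshold")
  expect_identical(nrow(roiTable(empty)), 0L)
})

test_that("disk fixtures are recovered with correct counts and centroids", {
  disks <- data.frame(x_um = c(15, 40, 30), y_um = c(15, 15, 45),
                      radius_um = sqrt(200 / pi),   # 200 um^2, in band
                      intensity = 100)
  pair <- simImageStack(disks, dimPx = c(60, 60, 3), pixelSize = 1)
  rois <- segmentChromogenic(pair$base, sigmaPx = 0, threshold = 50)
  tab <- roiTable(rois)
  expect_identical(nrow(tab), 3L)
  ord <- order(tab$x_um + 100 * tab$y_um)
  tru <- order(disks$x_um + 100 * disks$y_um)
  expect_lt(max(abs(tab$x_um[ord] - disks$x_um[tru])), 1)
  expect_lt(max(abs(tab$y_um[ord] - disks$y_um[tru])), 1)
  expect_lt(max(abs(tab$area_um2 - 200) / 200), 0.1)

  # counts equal generator truth across seeded fixtures
  for (s in 1:6) {
    set.seed(s)
    k <- sample(2:5, 1)
    cent <- cbind(runif(k, 15, 85), runif(k, 15, 85))
    while (k > 1 && min(dist(cent)) < 20) {
      cent <- cbind(runif(k, 15, 85), runif(k, 15, 85))
    }
    dd <- data.frame(x_um = cent[, 1], y_um = cent[, 2],
                     radius_um = sqrt(runif(k, 120, 380) / pi),
                     intensity = 100)
    got <- simImageStack(dd, dimPx = c(100, 100, 3), pixelSize = 1)
    rois <- segmentChromogenic(got$base, sigmaPx = 0, threshold = 50)
    expect_identical(nrow(roiTable(rois)), k)
  }
})

test_that("nuclei segmentation filters 40-200 um^2, splits doublets, dilates 5 um", {
  im <- mkImage(100, 100)
  im <- addRect(im, 5, 5, 6, 6)       # 36 um^2 -> discarded
  im <- addRect(im, 30, 5, 7, 6)      # 42 um^2 -> retained, then dilated
  im <- addRect(im, 60, 5, 15, 14)    # 210 um^2 -> discarded
  rois <- segmentNuclei(im, threshold = 50, pixelSize = 1)
  tab <- roiTable(rois)
  expect_identical(nrow(tab), 1L)
  expect_gt(tab$area_um2, 42)          # dilation grows the mask

  # two touching disks are split into two ROIs by the watershed
  touching <- data.frame(x_um = c(40, 52), y_um = c(50, 50),
                         radius_um = sqrt(120 / pi), intensity = 100)
  pair <- simImageStack(touching, dimPx = c(100, 100, 3), pixelSize = 1)
  rois2 <- segmentNuclei(pair$base, threshold = 50, dilationUm = 0)
  expect_identical(nrow(roiTable(rois2)), 2L)
})

test_that("Slc17a7 segmentation filters 75-450 um^2 and does not split", {
  im <- mkImage(120, 120)
  im <- addRect(im, 5, 5, 8, 8)       # 64 -> dropped
  im <- addRect(im, 30, 30, 18, 17)   # 306 -> retained
  im <- addRect(im, 60, 60, 22, 21)   # 462 -> dropped
  rois <- segmentSlc17a7(im, sigmaPx = 0, threshold = 50, pixelSize = 1)
  expect_identical(nrow(roiTable(rois)), 1L)
  expect_equal(roiTable(rois)$area_um2, 306)

  # touching disks merge (no watershed)
  touching <- data.frame(x_um = c(40, 52), y_um = c(50, 50),
                         radius_um = sqrt(150 / pi), intensity = 100)
  pair <- simImageStack(touching, dimPx = c(100, 100, 3), pixelSize = 1)
  rois2 <- segmentSlc17a7(pair$base, sigmaPx = 0, threshold = 50)
  expect_identical(nrow(roiTable(rois2)), 1L)
})

test_that("FFT registration recovers planted offsets exactly", {
  disks <- data.frame(x_um = c(20, 45, 30), y_um = c(20, 50, 70),
                      radius_um = 6, intensity = 100,
                      z_um = c(1, 2, 3), zsd_um = 1)
  pair0 <- simImageStack(disks, dimPx = c(96, 96, 10), pixelSize = 1,
                         zStep = 0.5, shift = c(0, 0, 0))
  expect_identical(registerRounds(pair0$base, pair0$moved), c(0L, 0L, 0L))

  pair <- simImageStack(disks, dimPx = c(96, 96, 10), pixelSize = 1,
                        zStep = 0.5, shift = c(5, -3, 2))
  expect_identical(registerRounds(pair$base, pair$moved), c(5L, -3L, 2L))

  # noiseless fixtures across a range of shifts up to a quarter image size
  for (s in list(c(24, 0, 0), c(-24, 10, -3), c(7, -24, 4))) {
    p <- simImageStack(disks, dimPx = c(96, 96, 10), pixelSize = 1,
                       zStep = 0.5, shift = s)
    expect_identical(registerRounds(p$base, p$moved), as.integer(s))
  }

  # robust to noise at SNR >= 5
  noisy <- simImageStack(disks, dimPx = c(96, 96, 10), pixelSize = 1,
                         zStep = 0.5, shift = c(5, -3, 2), noiseSd = 15,
                         seed = 2)
  expect_identical(registerRounds(noisy$base, noisy$moved), c(5L, -3L, 2L))

  flat <- new("ImageStack", data = array(1, c(8, 8, 2)), pixelSize = 1,
              zStep = 1)
  expect_error(registerRounds(flat, flat), "flat")
})

test_that("CPA is an exact positive-pixel fraction, shift-invariant in [0,1]", {
  im <- mkImage(40, 40)
  im <- addRect(im, 10, 10, 10, 10)
  rois <- segmentChromogenic(im, sigmaPx = 0, threshold = 50, pixelSize = 1,
                             areaMin = 0, areaMax = Inf)
  full <- quantifyCPA(rois, im, threshold = 50)
  expect_equal(full$cpa, 1)

  # exactly half the mask above threshold
  half <- mkImage(40, 40); half <- addRect(half, 10, 10, 5, 10)
  expect_equal(quantifyCPA(rois, half, threshold = 50)$cpa, 0.5)
  expect_equal(quantifyCPA(rois, mkImage(40, 40), threshold = 50)$cpa, 0)

  # identical rigid shift of ROI frame and probe leaves CPA unchanged
  sh <- c(6L, -4L)
  shiftedProbe <- blamap:::.circShift3(array(half, c(40, 40, 1)),
                                       c(sh, 0L))[, , 1]
  shiftedLabels <- blamap:::.circShift3(array(rois@labels, c(40, 40, 1)),
                                        c(sh, 0L))[, , 1]
  rois2 <- new("ROISet", labels = shiftedLabels,
               table = roiTable(rois), pixelSize = 1)
  expect_equal(quantifyCPA(rois2, shiftedProbe, threshold = 50)$cpa, 0.5)

  expect_error(quantifyCPA(rois, mkImage(20, 20), threshold = 50),
               "register")
})
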