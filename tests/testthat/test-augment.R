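test_that("zero-range geometric transform is the exact identity", {
  img <- tinyBank(n = 1L, side = 32L, seed = 31L)
  img <- loadImage(bankRecords(img)$path[1])
  expect_identical(applyGeometric(img), img)
  cfg0 <- geometricAugConfig(rotationDeg = 0, shiftFrac = 0, hflip = FALSE)
  out <- augmentGeometric(img, cfg0)
  expect_equal(unclass(out), img, ignore_attr = TRUE)
})

test_that("a pure shift relocates a one-hot pixel by the exact offset", {
  img <- onehotImage(20L, 20L, at = c(5L, 7L))
  dx <- 0.2 * 20 # +0.2 of width
  out <- applyGeometric(img, angle = 0, dx = dx, dy = 0, flip = FALSE)
  expect_equal(out[5, 11, 1], 1)
  out[5, 11, ] <- 0
  expect_equal(sum(out), 0)
  # vertical shift likewise
  outv <- applyGeometric(img, angle = 0, dx = 0, dy = 3, flip = FALSE)
  expect_equal(outv[8, 7, 2], 1)
})

test_that("geometric augmentation preserves shape and samples in range", {
  img <- array(runif(24 * 30 * 3), c(24, 30, 3))
  cfg <- geometricAugConfig()
  withr::with_seed(8, {
    draws <- replicate(200, {
      out <- augmentGeometric(img, cfg)
      expect_equal(dim(out), dim(img))
      d <- attr(out, "geomDraw")
      c(d$angle, d$dx / 30, d$dy / 24, d$flip)
    })
  })
  expect_true(all(abs(draws[1, ]) <= 20))
  expect_true(all(abs(draws[2, ]) <= 0.2))
  expect_true(all(abs(draws[3, ]) <= 0.2))
  expect_true(any(draws[4, ] == 1) && any(draws[4, ] == 0))
})

test_that("own HSV conversion matches the grDevices oracle", {
  withr::with_seed(2, {
    r <- sample(0:255, 400, TRUE)
    g <- sample(0:255, 400, TRUE)
    b <- sample(0:255, 400, TRUE)
  })
  ours <- rgbToHsv180(r, g, b)
  oracle <- grDevices::rgb2hsv(rbind(r, g, b))
  expect_equal(ours$h, unname(oracle[1, ] * 180), tolerance = 1e-9)
  expect_equal(ours$s, unname(oracle[2, ]), tolerance = 1e-9)
  expect_equal(ours$v, unname(oracle[3, ] * 255), tolerance = 1e-9)
  back <- hsvToRgb180(ours$h, ours$s, ours$v)
  expect_equal(back$r, r)
  expect_equal(back$g, g)
  expect_equal(back$b, b)
})

test_that("identity-parameter HSV round trip moves channels by at most 1", {
  img <- array(round(runif(16 * 16 * 3) * 255) / 255, c(16, 16, 3))
  out <- withr::with_seed(3, {
    augmentHSV(img, hsvAugConfig(hueShiftRange = c(0, 0),
                                 satScaleRange = c(1, 1),
                                 valScaleRange = c(1, 1)))
  })
  expect_lte(max(abs(out - img)) * 255, 1)
})

test_that("gray images are bit-invariant under hue shifts", {
  gray <- array(rep(matrix(runif(8 * 8), 8, 8), 3), c(8, 8, 3))
  gray <- round(gray * 255) / 255
  out <- withr::with_seed(4, augmentHSV(gray, hsvAugConfig(mode = "hue")))
  attr(out, "hsvMode") <- NULL
  attr(out, "hsvAmount") <- NULL
  expect_identical(out, gray)
})

test_that("forced value scaling darkens a constant image exactly", {
  img <- array(100 / 255, c(6, 6, 3))
  out <- withr::with_seed(5, {
    augmentHSV(img, hsvAugConfig(valScaleRange = c(0.8, 0.8), mode = "val"))
  })
  expect_equal(unique(round(as.vector(unclass(out)) * 255)), 80)
})

test_that("each HSV augmentation modifies exactly one attribute in range", {
  img <- tinyBank(n = 1L, side = 32L, seed = 31L)
  img <- loadImage(bankRecords(img)$path[1])
  before <- rgbToHsv180(round(img[, , 1] * 255), round(img[, , 2] * 255),
                        round(img[, , 3] * 255))
  cfg <- hsvAugConfig()
  withr::with_seed(6, {
    for (i in 1:200) {
      out <- augmentHSV(img, cfg)
      mode <- attr(out, "hsvMode")
      amt <- attr(out, "hsvAmount")
      expect_true(mode %in% c("hue", "sat", "val"))
      if (mode == "hue") {
        expect_true(amt >= -10 && amt <= 10)
        # value channel untouched by a pure hue rotation
        after <- rgbToHsv180(round(out[, , 1] * 255),
                             round(out[, , 2] * 255),
                             round(out[, , 3] * 255))
        expect_equal(after$v, before$v)
      } else {
        expect_true(amt >= 0.8 && amt <= 1.2)
      }
    }
  })
})

test_that("resize and normalization honour the backbone contract", {
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  spec <- backboneInputSpec("standin", side = 24)
  out <- resizeNormalize(img, spec)
  expect_equal(dim(out), c(24, 24, 3))
  # unit contract is the identity on [0, 1]: constant image passes through
  const <- array(37 / 255, c(10, 12, 3))
  expect_equal(unique(as.vector(resizeNormalize(const, spec))), 37 / 255)
  # resizing to the native size leaves values unchanged
  spec48 <- backboneInputSpec("standin", side = 48)
  expect_equal(resizeNormalize(img, spec48), img)
  # named-backbone sides
  expect_equal(backboneInputSpec("resnet50")$side, 224L)
  expect_equal(backboneInputSpec("xception")$side, 299L)
  expect_error(resizeNormalize(array(0, c(5, 5, 4)), spec), "RGB")
  # tf contract maps [0,1] to [-1,1] invertibly
  tfOut <- carniMark:::applyNormalization(img, "tf")
  expect_equal((tfOut + 1) / 2, img)
})
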