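test_that("wavelength follows lambda = hc/E", {
  expect_equal(wavelengthM(6.20), 1.23984193e-9 / 6.20)
  expect_equal(wavelengthM(6.20), 1.99975e-10, tolerance = 1e-5)
  expect_error(wavelengthM(-1))
})

test_that("reconstruction pixel size reproduces the reference beamline geometry", {
  opt <- opticsConfig(6.20, 7.33, 75e-6, 452L, 7e-6, 1e7)
  expect_equal(reconstructionPixelSize(opt), 43.25, tolerance = 1e-3)
})

test_that("pixel size scales as the closed form demands", {
  opt <- opticsConfig(12.4, 1, 100e-6, 100L, 5e-6, 1e7)
  # lambda ~ 0.99987 A -> p = lambda / 0.01 ~ 10.0 nm
  expect_equal(reconstructionPixelSize(opt), 9.9987, tolerance = 1e-4)
  opt2 <- opticsConfig(12.4, 1, 100e-6, 200L, 5e-6, 1e7)
  expect_equal(reconstructionPixelSize(opt2),
               reconstructionPixelSize(opt) / 2)
})

test_that("geometry fields are validated", {
  expect_error(opticsConfig(0, 7.33, 75e-6, 452L), "positive")
  expect_error(opticsConfig(6.2, 7.33, -75e-6, 452L), "positive")
})
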