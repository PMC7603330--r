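# Linescan extraction, FWHM diameters, and overlap classification.

test_that("extract_linescan reproduces flat fields and raw rows", {
  # uniform image -> flat profile at that value
  img <- array(0.7, c(20, 30, 2))
  sc <- extract_linescan(img, c(3, 10), c(25, 10), width = 4)
  expect_true(all(abs(sc$intensity - 0.7) < 1e-12))
  # width-1 horizontal scan returns the row verbatim
  img2 <- matrix(seq_len(200) / 200, nrow = 10) # 10 x 20
  sc2 <- extract_linescan(img2, c(2, 5), c(18, 5), width = 1)
  expect_equal(sc2$intensity, img2[5, 2:18], tolerance = 1e-12)
  # leaving the image is an error
  expect_error(extract_linescan(img, c(3, 10), c(40, 10)), "exits")
  expect_error(extract_linescan(img, c(3, 3), c(3, 3)), "coincide")
})

test_that("a Gaussian spot peaks at its centre and has FWHM 2.355 sigma", {
  img <- spot_image(61, list(c(31, 31)), sigmas = 3)
  sc <- extract_linescan(img[, , 1], c(5, 31), c(57, 31), width = 4)
  peak_pos <- sc$position_um[which.max(sc$intensity)]
  expect_lt(abs(peak_pos - (31 - 5)), 0.5) # position along scan, px units
  d <- dot_diameter(sc, "ch1")
  expect_lt(abs(d - 2 * sqrt(2 * log(2)) * 3), 0.25)
})

test_that("dot_diameter matches closed forms and generator truth", {
  pos <- seq(0, 40, by = 0.5)
  # Gaussian of sd sigma -> 2.355 sigma
  g <- tibble::tibble(position_um = pos,
                      intensity = gaussian_profile(20, 2, pos))
  expect_lt(abs(dot_diameter(g, channel = "any") - 2 * sqrt(2 * log(2)) * 2), 0.1)
  # rectangular pulse of width w -> w
  rect <- tibble::tibble(position_um = pos,
                         intensity = as.numeric(pos >= 10 & pos < 15))
  expect_lt(abs(dot_diameter(rect) - 5), 0.6)
  # 1 um synthetic dot measured at 0.1 um sampling -> 1 um within a pixel
  fine <- seq(0, 10, by = 0.1)
  dot <- tibble::tibble(position_um = fine,
                        intensity = gaussian_profile(5, 1 / 2.3548, fine))
  expect_lt(abs(dot_diameter(dot) - 1), 0.1)
  flat <- tibble::tibble(position_um = pos, intensity = rep(1, length(pos)))
  expect_error(dot_diameter(flat), "no detectable peak")
})

test_that("classify_overlap distinguishes the three published relationships", {
  pos <- seq(0, 30, by = 0.25)
  scan <- function(c_rna, s_rna, c_mk, s_mk, h_rna = 1, h_mk = 1) {
    dplyr::bind_rows(
      tibble::tibble(position_um = pos, channel = "rna",
                     intensity = gaussian_profile(c_rna, s_rna, pos, h_rna)),
      tibble::tibble(position_um = pos, channel = "marker",
                     intensity = gaussian_profile(c_mk, s_mk, pos, h_mk))
    )
  }
  # identical profiles -> complete
  expect_identical(classify_overlap(scan(15, 2, 15, 2))$relationship, "complete")
  # peaks separated far beyond their widths -> none
  expect_identical(classify_overlap(scan(6, 1, 24, 1))$relationship, "none")
  # narrow RNA peak centred in a 3x wider marker peak -> engulfed
  expect_identical(classify_overlap(scan(15, 1, 15, 3))$relationship, "engulfed")
  # moderate shift with overlapping supports -> partial
  expect_identical(classify_overlap(scan(14, 2, 17, 2))$relationship, "partial")
  # flat profiles -> none with a flag
  flat <- dplyr::bind_rows(
    tibble::tibble(position_um = pos, channel = "rna", intensity = 1),
    tibble::tibble(position_um = pos, channel = "marker", intensity = 1)
  )
  call <- classify_overlap(flat)
  expect_identical(call$relationship, "none")
  expect_identical(call$flag, "no detectable peak")
})

test_that("classification is invariant to joint translation and intensity scale", {
  pos <- seq(0, 30, by = 0.25)
  build <- function(shift = 0, scale = 1) {
    dplyr::bind_rows(
      tibble::tibble(position_um = pos, channel = "rna",
                     intensity = scale * gaussian_profile(12 + shift, 1, pos)),
      tibble::tibble(position_um = pos, channel = "marker",
                     intensity = scale * gaussian_profile(12.5 + shift, 3, pos))
    )
  }
  base <- classify_overlap(build())
  shifted <- classify_overlap(build(shift = 6))
  scaled <- classify_overlap(build(scale = 40))
  expect_identical(shifted$relationship, base$relationship)
  expect_identical(scaled$relationship, base$relationship)
  expect_equal(scaled$support_containment, base$support_containment, tolerance = 1e-9)
})

test_that("constructed relationship regimes classify without confusion", {
  pos <- seq(0, 40, by = 0.25)
  cases <- list(
    complete = list(rna = c(20, 2), mk = c(20, 2)),
    engulfed = list(rna = c(20, 1), mk = c(20, 4)),
    partial = list(rna = c(18, 2), mk = c(22, 2)),
    none = list(rna = c(10, 1), mk = c(32, 1))
  )
  for (truth in names(cases)) {
    cs <- cases[[truth]]
    scan <- dplyr::bind_rows(
      tibble::tibble(position_um = pos, channel = "rna",
                     intensity = gaussian_profile(cs$rna[1], cs$rna[2], pos)),
      tibble::tibble(position_um = pos, channel = "marker",
                     intensity = gaussian_profile(cs$mk[1], cs$mk[2], pos))
    )
    expect_identical(classify_overlap(scan)$relationship, truth)
  }
})
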