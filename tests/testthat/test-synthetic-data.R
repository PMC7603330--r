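# Generators: determinism, ground-truth bookkeeping, and zero-noise limits.

test_that("generators are bit-identical under a fixed seed", {
  m1 <- make_parenchyma_mask(80, 60, list(list(type = "disc", cx = 40, cy = 30, r = 15)),
                             debris_count = 5, seed = 42)
  m2 <- make_parenchyma_mask(80, 60, list(list(type = "disc", cx = 40, cy = 30, r = 15)),
                             debris_count = 5, seed = 42)
  expect_identical(m1$grid, m2$grid)

  f1 <- make_cell_field(20, 50, 4, 1, seed = 7)
  f2 <- make_cell_field(20, 50, 4, 1, seed = 7)
  expect_identical(f1$nuclei, f2$nuclei)
  expect_identical(f1$dots, f2$dots)

  t1 <- make_ocr_trace(c(100, 40, 180, 10), noise_sd = 3, seed = 9)
  t2 <- make_ocr_trace(c(100, 40, 180, 10), noise_sd = 3, seed = 9)
  expect_identical(t1$ocr, t2$ocr)

  r1 <- make_reads(50, error_rate = 0.02, off_target_fraction = 0.3, seed = 3)
  r2 <- make_reads(50, error_rate = 0.02, off_target_fraction = 0.3, seed = 3)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$reference, r2$reference)

  p1 <- make_isotopomer_panel(c(lactate = 0.4), noise_cv = 0.1, seed = 5)
  p2 <- make_isotopomer_panel(c(lactate = 0.4), noise_cv = 0.1, seed = 5)
  expect_identical(p1$intensity, p2$intensity)
})

test_that("parenchyma mask geometry matches its ground truth", {
  # single disc: analytic mean chord pi*r/2
  m <- make_parenchyma_mask(250, 250, list(list(type = "disc", cx = 125, cy = 125, r = 100)))
  gt <- ground_truth(m)
  expect_equal(gt$value[gt$param == "analytic_mean_chord_px"], pi * 100 / 2,
               tolerance = 1e-12)
  # zero shapes -> all tissue
  m0 <- make_parenchyma_mask(50, 40, list())
  expect_false(any(m0$grid))
  # shapes that do not fit are refused
  expect_error(
    make_parenchyma_mask(50, 50, list(list(type = "disc", cx = 5, cy = 5, r = 20))),
    "fit"
  )
  # overlapping shapes are unioned, not an error
  m2 <- make_parenchyma_mask(100, 100, list(
    list(type = "disc", cx = 45, cy = 50, r = 20),
    list(type = "disc", cx = 55, cy = 50, r = 20)
  ))
  expect_true(sum(m2$grid) < 2 * sum(make_parenchyma_mask(
    100, 100, list(list(type = "disc", cx = 50, cy = 50, r = 20))
  )$grid))
})

test_that("cell-field dot counts follow the generating Poisson rates", {
  # no AETII cells -> every dot belongs to a non-AETII cell
  f <- make_cell_field(0, 30, 0, 5, seed = 1)
  expect_true(all(!f$nuclei$surfactant_positive))
  expect_true(all(f$dots$true_cell_id %in% f$nuclei$cell_id))
  # zero rates -> zero dots
  f0 <- make_cell_field(10, 10, 0, 0, seed = 1)
  expect_identical(nrow(f0$dots), 0L)
  # rate recovery within 3 standard errors at large n
  n <- 800
  f <- make_cell_field(n, n, 10.7, 2.15, seed = 11, field_size_um = 3000)
  counts <- table(factor(f$dots$true_cell_id, levels = f$nuclei$cell_id))
  mean_a <- mean(counts[f$nuclei$surfactant_positive])
  mean_n <- mean(counts[!f$nuclei$surfactant_positive])
  expect_lt(abs(mean_a - 10.7), 3 * sqrt(10.7 / n))
  expect_lt(abs(mean_n - 2.15), 3 * sqrt(2.15 / n))
  expect_error(make_cell_field(5, 5, -1, 1), "non-negative")
})

test_that("OCR traces reproduce phase means exactly at zero noise", {
  tr <- make_ocr_trace(c(100, 40, 180, 10), readings_per_phase = 3, noise_sd = 0)
  expect_identical(nrow(tr), 12L)
  expect_equal(tr$ocr, rep(c(100, 40, 180, 10), each = 3))
  expect_identical(levels(tr$phase),
                   c("basal", "post_oligomycin", "post_fccp", "post_rotaa"))
  expect_error(make_ocr_trace(c(1, 2, 3, 4), readings_per_phase = 0), "readings_per_phase")
  expect_error(make_ocr_trace(c(1, 2, 3)), "4 numbers")
})

test_that("isotopomer panels encode flux x enrichment in the labeled bin", {
  # flux 1, enrichment 1, no noise -> fully labeled product
  p <- make_isotopomer_panel(c(lactate = 1), precursor_enrichment = 1, noise_cv = 0)
  lac <- p[p$metabolite == "lactate", ]
  expect_equal(lac$intensity[lac$mass_index == 0], 0)
  expect_equal(sum(lac$intensity[lac$mass_index > 0]), sum(lac$intensity))
  # flux 0 -> only M0 mass
  p0 <- make_isotopomer_panel(c(citrate = 0), noise_cv = 0)
  cit <- p0[p0$metabolite == "citrate", ]
  expect_true(all(cit$intensity[cit$mass_index > 0] == 0))
  # labeled fraction = flux x enrichment
  p2 <- make_isotopomer_panel(c(malate = 0.5), precursor_enrichment = 0.8, noise_cv = 0)
  mal <- p2[p2$metabolite == "malate", ]
  expect_equal(sum(mal$intensity[mal$mass_index > 0]) / sum(mal$intensity), 0.4)
  expect_error(make_isotopomer_panel(c(malate = 1.2)), "\\[0, 1\\]")
})

test_that("read sets respect the transcript interval and error model", {
  rs <- make_reads(40, error_rate = 0, off_target_fraction = 0,
                   full_length_fraction = 1, seed = 2)
  # every zero-error full-length read is exactly the 70-nt transcript
  expect_identical(nchar(rs$transcript), 70L)
  expect_true(all(rs$reads$seq == rs$transcript))
  # the transcript is the light strand: its reverse complement sits on the
  # heavy strand at 16,119..16,188
  heavy <- substr(as.character(rs$reference), 16119, 16188)
  expect_identical(oracle_revcomp(rs$transcript), heavy)
  expect_error(make_reads(0), "n_reads")
})
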