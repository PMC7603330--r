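# Seeded generators for every analysis stage. Each returns data shaped like
# the corresponding laboratory readout (binary parenchyma image, per-cell ISH
# dot field, mito-stress-test OCR trace, mass-isotopomer panel, small-RNA read
# set, Ct table) together with a ground_truth record of the generating values,
# so parameter recovery can be tested without any raw data.

#' Generate a binary parenchyma mask with known airspace geometry
#'
#' Builds a tissue image (all `FALSE`) and opens airspace regions (`TRUE`)
#' given as discs or ellipses. Optional debris (small tissue speckles inside
#' airspace) and pinholes (small airspace specks inside tissue) emulate the
#' imperfections the cleaning step of the morphometry workflow removes.
#'
#' For disc-only geometry the ground truth records the analytic mean chord
#' of parallel-line sampling, `(pi/2) * sum(r^2) / sum(r)` pixels (which
#' reduces to `pi * r / 2` for a single disc).
#'
#' @param width,height Image size in pixels.
#' @param airspace_shapes List of shapes. Each shape is a list with `type`
#'   ("disc" or "ellipse"), centre `cx`, `cy` in pixels, and radius `r` (disc)
#'   or `rx`, `ry` (ellipse) in micrometres. Overlapping shapes are unioned;
#'   an empty list yields an all-tissue mask.
#' @param pixel_size Micrometres per pixel.
#' @param debris_count Number of small tissue speckles dropped into airspace.
#' @param hole_count Number of small airspace pinholes punched into tissue.
#' @param seed Integer seed; the same seed reproduces the mask bit-identically.
#' @param image_id Label for the image.
#' @return A [parenchyma_mask] with a `ground_truth` attribute.
#' @export
make_parenchyma_mask <- function(width, height, airspace_shapes = list(),
                                 pixel_size = 1, debris_count = 0,
                                 hole_count = debris_count, seed = 1,
                                 image_id = "synthetic") {
  check_number(width, "width", min = 1, integerish = TRUE)
  check_number(height, "height", min = 1, integerish = TRUE)
  check_number(pixel_size, "pixel_size", min = .Machine$double.eps)
  check_number(debris_count, "debris_count", min = 0, integerish = TRUE)
  check_number(hole_count, "hole_count", min = 0, integerish = TRUE)
  withr::local_seed(seed)

  grid <- matrix(FALSE, nrow = height, ncol = width)
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)

  for (sh in airspace_shapes) {
    type <- sh$type %||% "disc"
    if (type == "disc") {
      r_px <- sh$r / pixel_size
      if (sh$cx - r_px < 1 || sh$cx + r_px > width ||
          sh$cy - r_px < 1 || sh$cy + r_px > height) {
        abort("disc does not fit within the image")
      }
      grid <- grid | ((xs - sh$cx)^2 + (ys - sh$cy)^2 <= r_px^2)
    } else if (type == "ellipse") {
      rx <- sh$rx / pixel_size
      ry <- sh$ry / pixel_size
      if (sh$cx - rx < 1 || sh$cx + rx > width ||
          sh$cy - ry < 1 || sh$cy + ry > height) {
        abort("ellipse does not fit within the image")
      }
      grid <- grid | (((xs - sh$cx) / rx)^2 + ((ys - sh$cy) / ry)^2 <= 1)
    } else {
      abort(sprintf("unknown shape type '%s'", type))
    }
  }

  speckle <- function(grid, where_value, set_to, count) {
    idx <- which(grid == where_value)
    if (count == 0 || length(idx) == 0) return(grid)
    centers <- sample(idx, min(count, length(idx)))
    for (ci in centers) {
      cy <- (ci - 1) %% nrow(grid) + 1
      cx <- (ci - 1) %/% nrow(grid) + 1
      n_extra <- sample(0:2, 1)
      py <- pmin(pmax(cy + c(0, sample(c(-1, 1), n_extra, replace = TRUE)), 1), nrow(grid))
      px <- pmin(pmax(cx + c(0, sample(c(-1, 1), n_extra, replace = TRUE)), 1), ncol(grid))
      grid[cbind(py, px)] <- set_to
    }
    grid
  }
  grid <- speckle(grid, TRUE, FALSE, debris_count)   # tissue debris in airspace
  grid <- speckle(grid, FALSE, TRUE, hole_count)     # pinholes in tissue

  disc_only <- length(airspace_shapes) > 0 &&
    all(map_dbl(airspace_shapes, ~ identical(.x$type %||% "disc", "disc")) == 1)
  analytic <- NA_real_
  if (disc_only) {
    r_px <- map_dbl(airspace_shapes, ~ .x$r / pixel_size)
    analytic <- (pi / 2) * sum(r_px^2) / sum(r_px)
  }

  mask <- parenchyma_mask(grid, pixel_size = pixel_size, image_id = image_id)
  attr(mask, "ground_truth") <- new_ground_truth("morphometry", list(
    n_shapes = length(airspace_shapes),
    analytic_mean_chord_px = analytic,
    pixel_size = pixel_size,
    debris_count = debris_count,
    hole_count = hole_count,
    seed = seed
  ))
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic ISH cell field
#'
#' Places AETII (surfactant-positive) and non-AETII nuclei uniformly in a
#' square field and assigns each cell a Poisson number of ISH dots at the
#' type-specific rate. Dot positions fall uniformly within the cell radius of
#' their parent nucleus; dot diameters are drawn uniformly from the observed
#' 0.25--2 um range of single visible dots.
#'
#' @param n_aetii,n_non Number of AETII and non-AETII cells.
#' @param dot_rate_aetii,dot_rate_non True mean dots per cell for each type
#'   (must be non-negative).
#' @param seed Integer seed.
#' @param field_size_um Side of the square field, micrometres.
#' @param cell_radius_um Radius within which a cell's dots are placed.
#' @param field_id Label.
#' @return A `cell_field`: list with tibbles `nuclei` (`cell_id`, `x`, `y`,
#'   `surfactant_positive`) and `dots` (`x`, `y`, `diameter`, `true_cell_id`),
#'   plus `field_id`; carries a `ground_truth` attribute.
#' @export
make_cell_field <- function(n_aetii, n_non, dot_rate_aetii, dot_rate_non,
                            seed = 1, field_size_um = 200, cell_radius_um = 5,
                            field_id = "synthetic") {
  check_number(n_aetii, "n_aetii", min = 0, integerish = TRUE)
  check_number(n_non, "n_non", min = 0, integerish = TRUE)
  if (dot_rate_aetii < 0 || dot_rate_non < 0) {
    abort("dot rates must be non-negative")
  }
  withr::local_seed(seed)

  n_total <- n_aetii + n_non
  nuclei <- tibble(
    cell_id = seq_len(n_total),
    x = runif(n_total, 0, field_size_um),
    y = runif(n_total, 0, field_size_um),
    surfactant_positive = rep(c(TRUE, FALSE), c(n_aetii, n_non))
  )

  counts <- rpois(n_total, rep(c(dot_rate_aetii, dot_rate_non), c(n_aetii, n_non)))
  parent <- rep(nuclei$cell_id, counts)
  n_dots <- length(parent)
  theta <- runif(n_dots, 0, 2 * pi)
  rad <- cell_radius_um * sqrt(runif(n_dots))
  dots <- tibble(
    x = nuclei$x[parent] + rad * cos(theta),
    y = nuclei$y[parent] + rad * sin(theta),
    diameter = runif(n_dots, 0.25, 2),
    true_cell_id = parent
  )

  field <- structure(
    list(nuclei = nuclei, dots = dots, field_id = field_id),
    class = "cell_field"
  )
  attr(field, "ground_truth") <- new_ground_truth("ish", list(
    n_aetii = n_aetii, n_non = n_non,
    dot_rate_aetii = dot_rate_aetii, dot_rate_non = dot_rate_non,
    cell_radius_um = cell_radius_um, seed = seed
  ))
  field
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf(
    "<cell_field '%s'> %d nuclei (%d surfactant+), %d dots\n",
    x$field_id, nrow(x$nuclei), sum(x$nuclei$surfactant_positive), nrow(x$dots)
  ))
  invisible(x)
}

#' Generate a mito stress test OCR trace
#'
#' Emulates a four-phase extracellular-flux run (basal, then sequential
#' oligomycin, FCCP and rotenone/antimycin A injections): each phase
#' contributes `readings_per_phase` readings equal to the phase mean plus
#' Gaussian instrument noise.
#'
#' @param phase_means Numeric length-4 vector of true phase means
#'   (pmol O2/min), in injection order basal, post-oligomycin, post-FCCP,
#'   post-rotenone/antimycin.
#' @param readings_per_phase Readings per phase (>= 1).
#' @param noise_sd Gaussian noise s.d., same units as the readings.
#' @param protein_ug Total protein per well, used for normalisation.
#' @param seed Integer seed.
#' @param well_id Label.
#' @param interval_min Minutes between consecutive readings.
#' @return An `ocr_trace` tibble with columns `well_id`, `time_min`, `ocr`,
#'   `phase`, `protein_ug`; injections are recorded in the `injections`
#'   attribute and the true means in `ground_truth`.
#' @export
make_ocr_trace <- function(phase_means, readings_per_phase = 3, noise_sd = 0,
                           protein_ug = 1, seed = 1, well_id = "A1",
                           interval_min = 6.5) {
  if (length(phase_means) != 4 || !is.numeric(phase_means)) {
    abort("`phase_means` must be 4 numbers (basal, oligomycin, FCCP, rot/AA)")
  }
  check_number(readings_per_phase, "readings_per_phase", min = 1, integerish = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  withr::local_seed(seed)

  phases <- ocr_phases()
  n <- 4 * readings_per_phase
  trace <- tibble(
    well_id = well_id,
    time_min = seq_len(n) * interval_min,
    ocr = rep(phase_means, each = readings_per_phase) + rnorm(n, 0, noise_sd),
    phase = factor(rep(phases, each = readings_per_phase), levels = phases),
    protein_ug = protein_ug
  )
  class(trace) <- c("ocr_trace", class(trace))
  attr(trace, "injections") <- tibble(
    injection = c("oligomycin", "FCCP", "rotenone/antimycin A"),
    after_time_min = trace$time_min[readings_per_phase * (1:3)]
  )
  attr(trace, "ground_truth") <- new_ground_truth("ocr", list(
    basal_mean = phase_means[1], post_oligomycin_mean = phase_means[2],
    post_fccp_mean = phase_means[3], post_rotaa_mean = phase_means[4],
    noise_sd = noise_sd, protein_ug = protein_ug, seed = seed
  ))
  trace
}

ocr_phases <- function() c("basal", "post_oligomycin", "post_fccp", "post_rotaa")

#' Carbon counts for the metabolites monitored by the flux workflow
#'
#' @return Named integer vector of carbon numbers per metabolite (glucose is
#'   monitored as M0--M5 on its pentaacetate fragment, so it carries 5 mass
#'   bins beyond M0).
#' @export
metabolite_carbons <- function() {
  c(
    glucose = 5L, # M0-M5 monitored on masses 331-337
    lactate = 3L, pyruvate = 3L, alanine = 3L, serine = 3L,
    citrate = 6L, alpha_ketoglutarate = 5L, succinate = 4L,
    fumarate = 4L, malate = 4L, oxaloacetate = 4L,
    aspartate = 4L, glutamate = 5L
  )
}

#' Generate a mass-isotopomer intensity panel
#'
#' Builds per-metabolite isotopomer intensity vectors in which the labeled
#' fraction of each product equals `true_fractional_flux * precursor_enrichment`,
#' placed in the fully labeled mass bin; the precursor (glucose) carries
#' `precursor_enrichment` in its M5 bin. Intensities are perturbed by
#' multiplicative log-normal noise of coefficient of variation `noise_cv`
#' (mean-one, so expected intensities are unchanged).
#'
#' @param true_fractional_fluxes Named numeric vector in \[0, 1\]; names are
#'   product metabolites (see [metabolite_carbons()]).
#' @param precursor_enrichment Fraction of precursor molecules fully labeled,
#'   in \[0, 1\].
#' @param pool_sizes Named numeric vector of relative concentrations; must
#'   cover the product metabolites (precursor pool defaults to 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param base_intensity Arbitrary-units intensity scale.
#' @return An `isotopomer_panel` tibble in long format: `metabolite`,
#'   `mass_index`, `intensity`, `n_carbons`, `pool_size`, `role`.
#' @export
make_isotopomer_panel <- function(true_fractional_fluxes, precursor_enrichment = 0.99,
                                  pool_sizes = NULL, noise_cv = 0, seed = 1,
                                  base_intensity = 1e5) {
  if (any(true_fractional_fluxes < 0 | true_fractional_fluxes > 1)) {
    abort("fractional fluxes must lie in [0, 1]")
  }
  check_number(precursor_enrichment, "precursor_enrichment", min = 0, max = 1)
  check_number(noise_cv, "noise_cv", min = 0)
  carbons <- metabolite_carbons()
  mets <- names(true_fractional_fluxes)
  unknown <- setdiff(mets, names(carbons))
  if (length(unknown) > 0) {
    abort(sprintf("unknown metabolites: %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(pool_sizes)) pool_sizes <- stats::setNames(rep(1, length(mets)), mets)
  withr::local_seed(seed)

  one <- function(name, labeled_fraction, pool, role) {
    nc <- carbons[[name]]
    intens <- numeric(nc + 1)
    intens[1] <- 1 - labeled_fraction
    intens[nc + 1] <- labeled_fraction
    tibble(
      metabolite = name, mass_index = 0:nc,
      intensity = intens * base_intensity * pool,
      n_carbons = nc, pool_size = pool, role = role
    )
  }

  panel <- bind_rows(
    one("glucose", precursor_enrichment, 1, "precursor"),
    imap(true_fractional_fluxes, function(f, m) {
      one(m, f * precursor_enrichment, pool_sizes[[m]], "product")
    }) %>% list_rbind()
  )
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    panel$intensity <- panel$intensity *
      exp(rnorm(nrow(panel), -sigma^2 / 2, sigma))
  }
  class(panel) <- c("isotopomer_panel", class(panel))
  attr(panel, "ground_truth") <- new_ground_truth("flux", c(
    as.list(stats::setNames(
      true_fractional_fluxes, paste0("flux_", mets)
    )),
    list(precursor_enrichment = precursor_enrichment, noise_cv = noise_cv, seed = seed)
  ))
  panel
}

#' Generate a synthetic circular mitochondrial reference
#'
#' Random DNA of the mouse mitochondrial genome length (16,299 nt by
#' default). The real mitochondrial sequence is not bundled; the synthetic
#' reference exercises the same circular coordinate arithmetic.
#'
#' @param length Reference length in nt.
#' @param seed Integer seed.
#' @return A single uppercase DNA string (character scalar) with attributes
#'   `name` and `circular = TRUE`.
#' @export
make_mt_reference <- function(length = 16299, seed = 1) {
  check_number(length, "length", min = 1, integerish = TRUE)
  withr::local_seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  structure(seq, name = "synthetic_mt", circular = TRUE)
}

#' Generate small-RNA reads from a circular reference
#'
#' On-target reads are (sub)sequences of the light-strand transcript defined
#' by `transcript_interval` (descending heavy-strand coordinates), with
#' per-base substitution errors; off-target reads are random sequence. Most
#' on-target reads are full length (`full_length_fraction`), matching a
#' discrete small-RNA species; the remainder are uniform sub-reads of at
#' least `min(length_range)` nt.
#'
#' @param n_reads Total number of reads (> 0).
#' @param reference Circular reference string (default: [make_mt_reference()]
#'   built from the same seed).
#' @param transcript_interval Length-2 vector `(start, end)` of 1-based
#'   heavy-strand coordinates; a descending pair denotes the light strand.
#' @param error_rate Per-base substitution probability.
#' @param off_target_fraction Fraction of reads drawn as random sequence.
#' @param length_range Allowed read lengths (nt), default 15--100.
#' @param full_length_fraction Fraction of on-target reads emitted at the
#'   full transcript length.
#' @param seed Integer seed.
#' @return A `read_set`: list with `reads` (tibble `read_id`, `seq`,
#'   `on_target`), `reference`, `transcript` (the true transcript sequence)
#'   and `interval`; carries `ground_truth`.
#' @export
make_reads <- function(n_reads, reference = NULL,
                       transcript_interval = c(16188, 16119),
                       error_rate = 0, off_target_fraction = 0,
                       length_range = c(15, 100), full_length_fraction = 0.8,
                       seed = 1) {
  check_number(n_reads, "n_reads", min = 1, integerish = TRUE)
  check_number(error_rate, "error_rate", min = 0, max = 1)
  check_number(off_target_fraction, "off_target_fraction", min = 0, max = 1)
  check_number(full_length_fraction, "full_length_fraction", min = 0, max = 1)
  withr::local_seed(seed)
  if (is.null(reference)) {
    seq <- paste(sample(c("A", "C", "G", "T"), 16299, replace = TRUE), collapse = "")
    reference <- structure(seq, name = "synthetic_mt", circular = TRUE)
  }
  ref_len <- nchar(reference)
  start <- transcript_interval[1]
  end <- transcript_interval[2]
  if (start < 1 || start > ref_len || end < 1 || end > ref_len) {
    abort("transcript interval out of range")
  }
  transcript <- transcript_sequence(reference, start, end)
  tlen <- nchar(transcript)

  n_off <- round(n_reads * off_target_fraction)
  n_on <- n_reads - n_off
  bases <- c("A", "C", "G", "T")

  mutate_seq <- function(s, rate) {
    if (rate == 0) return(s)
    chars <- strsplit(s, "")[[1]]
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(bases, b), 1), "")
    }
    paste(chars, collapse = "")
  }

  on_seqs <- character(0)
  if (n_on > 0) {
    full <- runif(n_on) < full_length_fraction
    min_len <- min(length_range[1], tlen)
    lens <- ifelse(full, tlen, sample(seq(min_len, tlen), n_on, replace = TRUE))
    starts <- vapply(lens, function(l) sample(seq_len(tlen - l + 1), 1), 1L)
    on_seqs <- vapply(seq_len(n_on), function(i) {
      mutate_seq(substr(transcript, starts[i], starts[i] + lens[i] - 1), error_rate)
    }, "")
  }
  off_seqs <- character(0)
  if (n_off > 0) {
    lens <- sample(seq(length_range[1], length_range[2]), n_off, replace = TRUE)
    off_seqs <- vapply(lens, function(l) {
      paste(sample(bases, l, replace = TRUE), collapse = "")
    }, "")
  }

  reads <- tibble(
    read_id = sprintf("read_%05d", seq_len(n_reads)),
    seq = c(on_seqs, off_seqs),
    on_target = rep(c(TRUE, FALSE), c(n_on, n_off))
  )
  out <- structure(
    list(reads = reads, reference = reference, transcript = transcript,
         interval = c(start = start, end = end)),
    class = "read_set"
  )
  attr(out, "ground_truth") <- new_ground_truth("reads", list(
    interval_start = start, interval_end = end, transcript_length = tlen,
    n_on_target = n_on, n_off_target = n_off,
    error_rate = error_rate, seed = seed
  ))
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf(
    "<read_set> %d reads (%d on-target), transcript %d nt at %d-%d\n",
    nrow(x$reads), sum(x$reads$on_target), nchar(x$transcript),
    x$interval["start"], x$interval["end"]
  ))
  invisible(x)
}

#' Generate a synthetic qPCR Ct table
#'
#' Builds control and treated Ct records whose group-averaged 2^-ddCt fold
#' change equals `true_fold` in the noiseless limit.
#'
#' @param true_fold True fold change of the target in the treated group.
#' @param n_replicates Replicates per group.
#' @param base_target_ct,base_reference_ct Control-group Ct values.
#' @param noise_sd Gaussian noise s.d. added to every Ct.
#' @param seed Integer seed.
#' @return Tibble `sample`, `group`, `target_ct`, `reference_ct` with a
#'   `ground_truth` attribute.
#' @export
make_ct_table <- function(true_fold = 2, n_replicates = 3,
                          base_target_ct = 25, base_reference_ct = 20,
                          noise_sd = 0, seed = 1) {
  check_number(true_fold, "true_fold", min = .Machine$double.eps)
  check_number(n_replicates, "n_replicates", min = 1, integerish = TRUE)
  withr::local_seed(seed)
  n <- 2 * n_replicates
  out <- tibble(
    sample = sprintf("s%02d", seq_len(n)),
    group = rep(c("control", "treated"), each = n_replicates),
    target_ct = c(
      rep(base_target_ct, n_replicates),
      rep(base_target_ct - log2(true_fold), n_replicates)
    ) + rnorm(n, 0, noise_sd),
    reference_ct = rep(base_reference_ct, n) + rnorm(n, 0, noise_sd)
  )
  attr(out, "ground_truth") <- new_ground_truth("qpcr", list(
    true_fold = true_fold, noise_sd = noise_sd, seed = seed
  ))
  out
}
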