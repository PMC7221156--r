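# Synthetic paired test-retest data: (a) a phantom mpMRI cohort with an
# ellipsoidal prostate gland, low-ADC lesions with a planted
# restricted-diffusion core, frozen per-patient texture, fresh per-timepoint
# voxel noise and optional lesion-boundary jitter emulating independent
# delineation; (b) designed feature matrices with known population CCC and
# forced-collinear duplicate blocks.

#' Phantom cohort configuration
#'
#' Defaults emulate a small test-retest prostate mpMRI cohort on a
#' scaled-down grid. ADC intensities are in 10^-6 mm^2/s-scaled units,
#' T2w in arbitrary units. Per-patient heterogeneity (gland/lesion size,
#' intensity means, noise scale) stands in for the biological diversity of
#' a real cohort.
#'
#' @param nPatients number of patients (one row of anatomy each).
#' @param grid array dimensions (nx, ny, nz).
#' @param spacing voxel spacing in mm.
#' @param glandSemiAxesMM gland ellipsoid semi-axes in mm (before the
#'   per-patient +/-10 percent variation).
#' @param lesionsPerPatient lesions planted per patient.
#' @param lesionRadiusMM nominal lesion radius in mm; per-patient,
#'   per-axis semi-axes vary +/-40 percent around it (index prostate
#'   lesions span roughly 5-20 mm, and the size spread must be wide enough
#'   that discrete size-coupled features -- slice counts, bounding-box
#'   extents, histogram bin counts -- genuinely vary between patients on a
#'   coarse 4 mm slice grid).
#' @param adcGlandMean,adcLesionMean,adcSD ADC gland mean, lesion-core
#'   mean and texture SD. The lesion shell sits midway between core and
#'   gland; the planted core occupies half the lesion volume (radius
#'   fraction 0.5^(1/3)) so the within-lesion sub-median habitat coincides
#'   with it.
#' @param t2GlandMean,t2LesionMean,t2SD T2w counterparts.
#' @param retestNoiseSD fresh-noise scale, as a multiplier of each
#'   modality's texture SD; applied independently to BOTH timepoints, so 0
#'   makes test and retest bitwise identical.
#' @param boundaryJitterMM maximum world radius of the random
#'   dilation/erosion applied to the RETEST lesion mask (independent
#'   re-delineation); 0 disables jitter.
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @return list of class `PhantomConfig`.
#' @export
phantomConfig <- function(nPatients = 13L,
                          grid = c(48L, 48L, 16L),
                          spacing = c(2, 2, 4),
                          glandSemiAxesMM = c(24, 20, 14),
                          lesionsPerPatient = 1L,
                          lesionRadiusMM = 7,
                          adcGlandMean = 1400, adcLesionMean = 700,
                          adcSD = 100,
                          t2GlandMean = 300, t2LesionMean = 200, t2SD = 40,
                          retestNoiseSD = 0.5,
                          boundaryJitterMM = 2,
                          seed = 1L) {
  stopifnot(nPatients >= 1, lesionsPerPatient >= 1,
            adcLesionMean < adcGlandMean,
            all(spacing > 0), all(grid >= 8), lesionRadiusMM > 0)
  structure(as.list(environment()), class = "PhantomConfig")
}

# ellipsoid membership field: values <= 1 inside
ellipsoidField <- function(grid, spacing, center, semi_axes) {
  x <- ((seq_len(grid[1]) - 1) * spacing[1] - center[1]) / semi_axes[1]
  y <- ((seq_len(grid[2]) - 1) * spacing[2] - center[2]) / semi_axes[2]
  z <- ((seq_len(grid[3]) - 1) * spacing[3] - center[3]) / semi_axes[3]
  outer(outer(x^2, y^2, "+"), z^2, "+")
}

# random dilation (grow = TRUE) or erosion with a world-radius ball
morphJitter <- function(mask, spacing, radius_mm, grow) {
  if (radius_mm <= 0) return(mask)
  offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  wd <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
               (offs[, 3] * spacing[3])^2)
  offs <- offs[wd <= radius_mm, , drop = FALSE]
  if (nrow(offs) <= 1L) return(mask)
  acc <- array(if (grow) 0 else 1, dim = dim(mask))
  for (r in seq_len(nrow(offs))) {
    sh <- shiftArray(array(as.numeric(mask), dim = dim(mask)), offs[r, ],
                     fill = if (grow) 0 else 1)
    acc <- if (grow) pmax(acc, sh) else pmin(acc, sh)
  }
  acc > 0
}

#' Generate a paired test-retest phantom cohort
#'
#' Each patient gets an ellipsoidal gland, `lesionsPerPatient` ellipsoidal
#' low-ADC lesions (with a planted restricted-diffusion core of half the
#' lesion volume), a frozen per-patient Gaussian texture shared by both
#' timepoints, independent fresh voxel noise per timepoint, and a RETEST
#' lesion mask jittered by random dilation/erosion. T2w and ADC are
#' generated on the same grid (pre-coregistered by construction).
#'
#' @param cfg a [phantomConfig()].
#' @return A cohort list: `list(config, patients)` where each patient is
#'   `list(patient_id, gland, test, retest)` and each timepoint is
#'   `list(volumes = list(T2W, ADC), lesions)`; each lesion is
#'   `list(lesion_id, mask, core)` with `core` the planted low-ADC core
#'   mask (synthetic ground truth, not an input to the pipeline).
#' @examples
#' coh <- generatePhantomCohort(phantomConfig(nPatients = 2, seed = 7))
#' length(coh$patients)
#' @export
generatePhantomCohort <- function(cfg = phantomConfig()) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  set.seed(cfg$seed)
  grid <- cfg$grid; sp <- cfg$spacing
  fov <- (grid - 1) * sp
  core_frac <- 0.5^(1 / 3)
  patients <- vector("list", cfg$nPatients)
  for (p in seq_len(cfg$nPatients)) {
    pid <- sprintf("P%02d", p)
    gl_axes <- cfg$glandSemiAxesMM * stats::runif(3, 0.9, 1.1)
    gl_center <- fov / 2
    gfield <- ellipsoidField(grid, sp, gl_center, gl_axes)
    gland_arr <- gfield <= 1

    adc_gland <- cfg$adcGlandMean * stats::runif(1, 0.92, 1.08)
    adc_core <- cfg$adcLesionMean * stats::runif(1, 0.92, 1.08)
    adc_shell <- (adc_gland + adc_core) / 2
    t2_gland <- cfg$t2GlandMean * stats::runif(1, 0.92, 1.08)
    t2_core <- cfg$t2LesionMean * stats::runif(1, 0.92, 1.08)
    t2_shell <- (t2_gland + t2_core) / 2
    noise_mult <- stats::runif(1, 0.6, 1.4)
    adc_sd <- cfg$adcSD * noise_mult
    t2_sd <- cfg$t2SD * noise_mult

    adc_clean <- array(adc_gland * 1.3, dim = grid)  # peri-gland background
    t2_clean <- array(t2_gland * 0.6, dim = grid)
    adc_clean[gland_arr] <- adc_gland
    t2_clean[gland_arr] <- t2_gland

    lesions <- vector("list", cfg$lesionsPerPatient)
    for (l in seq_len(cfg$lesionsPerPatient)) {
      les_axes <- cfg$lesionRadiusMM * stats::runif(3, 0.6, 1.4)
      placed <- FALSE
      for (try in 1:100) {
        u <- stats::runif(3, -0.55, 0.55)
        center <- gl_center + u * gl_axes
        margin <- max(les_axes / gl_axes)
        if (sqrt(sum(u^2)) + margin <= 0.95) { placed <- TRUE; break }
      }
      if (!placed)
        stop("lesion outside gland: could not place lesion inside the gland",
             call. = FALSE)
      lfield <- ellipsoidField(grid, sp, center, les_axes)
      les_arr <- lfield <= 1 & gland_arr
      core_arr <- lfield <= core_frac^2 & gland_arr
      if (sum(les_arr) < 8)
        stop("lesion outside gland: planted lesion too small on this grid",
             call. = FALSE)
      adc_clean[les_arr] <- adc_shell
      adc_clean[core_arr] <- adc_core
      t2_clean[les_arr] <- t2_shell
      t2_clean[core_arr] <- t2_core
      lesions[[l]] <- list(lesion_id = sprintf("L%d", l),
                           arr = les_arr, core_arr = core_arr)
    }

    # frozen per-patient texture, shared by both timepoints
    adc_tex <- adc_clean + array(stats::rnorm(prod(grid), 0, adc_sd), dim = grid)
    t2_tex <- t2_clean + array(stats::rnorm(prod(grid), 0, t2_sd), dim = grid)

    mk_tp <- function(tp) {
      fresh_adc <- if (cfg$retestNoiseSD > 0)
        array(stats::rnorm(prod(grid), 0, cfg$retestNoiseSD * adc_sd), dim = grid)
      else 0
      fresh_t2 <- if (cfg$retestNoiseSD > 0)
        array(stats::rnorm(prod(grid), 0, cfg$retestNoiseSD * t2_sd), dim = grid)
      else 0
      vols <- list(
        T2W = ScanVolume(t2_tex + fresh_t2, spacing = sp, origin = c(0, 0, 0),
                         modality = "T2W", timepoint = tp, patientID = pid),
        ADC = ScanVolume(adc_tex + fresh_adc, spacing = sp, origin = c(0, 0, 0),
                         modality = "ADC", timepoint = tp, patientID = pid))
      les_masks <- lapply(lesions, function(ls) {
        arr <- ls$arr
        if (tp == "RETEST" && cfg$boundaryJitterMM > 0) {
          grow <- stats::runif(1) < 0.5
          rad <- stats::runif(1, 0, cfg$boundaryJitterMM)
          jit <- morphJitter(arr, sp, rad, grow)
          if (sum(jit) >= 8) arr <- jit  # never jitter a lesion away
        }
        list(lesion_id = ls$lesion_id,
             mask = RegionMask(arr, spacing = sp, label = "LESION",
                               lesionID = ls$lesion_id),
             core = RegionMask(ls$core_arr, spacing = sp, label = "LESION",
                               lesionID = ls$lesion_id))
      })
      list(volumes = vols, lesions = les_masks)
    }
    test <- mk_tp("TEST")
    retest <- mk_tp("RETEST")

    patients[[p]] <- list(
      patient_id = pid,
      gland = RegionMask(gland_arr, spacing = sp, label = "GLAND"),
      test = test, retest = retest)
  }
  list(config = cfg, patients = patients)
}

#' Designed feature-matrix configuration
#'
#' @param nSubjects number of patient-lesions.
#' @param nFeatures number of features.
#' @param targetCCC population CCC per feature in `[0, 1]` (recycled).
#'   For a feature with between-subject SD b, the within-subject
#'   (measurement) SD is set to `b * sqrt((1 - ccc)/ccc)` so that
#'   `b^2 / (b^2 + w^2) = ccc`; target 0 uses b = 0, w = betweenSD and
#'   target 1 uses w = 0.
#' @param betweenSD between-subject SD per feature (recycled).
#' @param duplicateBlocks list of integer index vectors; within each block
#'   every member after the first is replaced by an exact affine copy of
#'   the first (population and sample R^2 = 1).
#' @param seed integer seed.
#' @return list of class `DesignedFeatureConfig`.
#' @export
designedFeatureConfig <- function(nSubjects = 200L, nFeatures = 60L,
                                  targetCCC = 0.65, betweenSD = 1,
                                  duplicateBlocks = list(), seed = 1L) {
  stopifnot(nSubjects >= 3, nFeatures >= 1,
            all(targetCCC >= 0), all(targetCCC <= 1), all(betweenSD >= 0))
  structure(list(nSubjects = as.integer(nSubjects),
                 nFeatures = as.integer(nFeatures),
                 targetCCC = rep_len(targetCCC, nFeatures),
                 betweenSD = rep_len(betweenSD, nFeatures),
                 duplicateBlocks = duplicateBlocks, seed = as.integer(seed)),
            class = "DesignedFeatureConfig")
}

#' Generate a paired feature matrix with designed concordance
#'
#' Subject i, feature j: `Test = mu_ij + e1`, `Retest = mu_ij + e2` with
#' `mu_ij ~ N(0, betweenSD_j^2)` and e drawn so the population CCC equals
#' `targetCCC_j`. Duplicate blocks are exact affine copies (slope > 0) of
#' their first member in both timepoints.
#'
#' @param cfg a [designedFeatureConfig()].
#' @return A [FeatureMatrix-class] with region_variant `"DESIGNED"`,
#'   modality `"SIM"`, feature ids `"F<j>:designed"`.
#' @export
generateDesignedFeatures <- function(cfg = designedFeatureConfig()) {
  stopifnot(inherits(cfg, "DesignedFeatureConfig"))
  set.seed(cfg$seed)
  n <- cfg$nSubjects
  test_m <- matrix(NA_real_, n, cfg$nFeatures)
  retest_m <- matrix(NA_real_, n, cfg$nFeatures)
  for (j in seq_len(cfg$nFeatures)) {
    tc <- cfg$targetCCC[j]
    b <- if (tc == 0) 0 else cfg$betweenSD[j]
    w <- if (tc == 0) cfg$betweenSD[j]
         else if (tc == 1) 0
         else b * sqrt((1 - tc) / tc)
    mu <- stats::rnorm(n, 0, b)
    test_m[, j] <- mu + stats::rnorm(n, 0, w)
    retest_m[, j] <- mu + stats::rnorm(n, 0, w)
  }
  for (blk in cfg$duplicateBlocks) {
    blk <- as.integer(blk)
    stopifnot(all(blk >= 1), all(blk <= cfg$nFeatures))
    for (k in seq_along(blk)[-1]) {
      a <- 1 + 0.5 * (k - 1)  # positive slope, distinct per copy
      b0 <- k - 1
      test_m[, blk[k]] <- a * test_m[, blk[1]] + b0
      retest_m[, blk[k]] <- a * retest_m[, blk[1]] + b0
    }
  }
  fid <- sprintf("F%d:designed", seq_len(cfg$nFeatures))
  subj <- sprintf("S%03d", seq_len(n))
  long <- rbind(
    data.frame(patient_id = rep(subj, cfg$nFeatures), lesion_id = "L1",
               timepoint = "TEST", region_variant = "DESIGNED",
               modality = "SIM",
               feature_id = rep(fid, each = n),
               value = as.vector(test_m), stringsAsFactors = FALSE),
    data.frame(patient_id = rep(subj, cfg$nFeatures), lesion_id = "L1",
               timepoint = "RETEST", region_variant = "DESIGNED",
               modality = "SIM",
               feature_id = rep(fid, each = n),
               value = as.vector(retest_m), stringsAsFactors = FALSE))
  FeatureMatrix(long)
}

#' Write a phantom cohort to disk (NIfTI + manifest JSON)
#'
#' Volumes and masks go to `<dir>/<patient>/` as NIfTI; a `manifest.json`
#' records patient ids, relative file paths and the generating seed.
#'
#' @param cohort a cohort from [generatePhantomCohort()].
#' @param dir output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (pat in cohort$patients) {
    pdir <- file.path(dir, pat$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    rel <- function(...) file.path(pat$patient_id, ...)
    gland_f <- rel("gland.nii.gz")
    writeVolume(pat$gland, file.path(dir, gland_f))
    tp_entries <- list()
    for (tp in c("test", "retest")) {
      scan <- pat[[tp]]
      vol_files <- list()
      for (mod in names(scan$volumes)) {
        f <- rel(sprintf("%s_%s.nii.gz", tolower(mod), tp))
        writeVolume(scan$volumes[[mod]], file.path(dir, f))
        vol_files[[mod]] <- f
      }
      les_files <- lapply(scan$lesions, function(ls) {
        f <- rel(sprintf("lesion_%s_%s.nii.gz", ls$lesion_id, tp))
        writeVolume(ls$mask, file.path(dir, f))
        list(lesion_id = ls$lesion_id, mask = f)
      })
      tp_entries[[tp]] <- list(volumes = vol_files, lesions = les_files)
    }
    entries[[length(entries) + 1L]] <-
      list(patient_id = pat$patient_id, gland = gland_f,
           test = tp_entries$test, retest = tp_entries$retest)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = cohort$config$seed, patients = entries),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a cohort from a manifest written by [writeCohort()]
#'
#' @param manifest path to `manifest.json`.
#' @return A cohort list with the same in-memory layout as
#'   [generatePhantomCohort()] (without planted-core ground truth).
#' @export
loadCohort <- function(manifest) {
  m <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  patients <- lapply(m$patients, function(pe) {
    pid <- pe$patient_id
    ref <- readVolume(file.path(dir, pe$test$volumes$T2W), "T2W", "TEST", pid)
    gland <- readMask(file.path(dir, pe$gland), ref, label = "GLAND")
    tp_load <- function(tpe, tp) {
      vols <- list(
        T2W = readVolume(file.path(dir, tpe$volumes$T2W), "T2W", tp, pid),
        ADC = readVolume(file.path(dir, tpe$volumes$ADC), "ADC", tp, pid))
      lesions <- lapply(tpe$lesions, function(le)
        list(lesion_id = le$lesion_id,
             mask = readMask(file.path(dir, le$mask), vols$T2W,
                             label = "LESION", lesionID = le$lesion_id)))
      list(volumes = vols, lesions = lesions)
    }
    list(patient_id = pid, gland = gland,
         test = tp_load(pe$test, "TEST"),
         retest = tp_load(pe$retest, "RETEST"))
  })
  list(config = list(seed = m$seed), patients = patients)
}
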