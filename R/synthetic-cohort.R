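#' Default clinical marginals for the synthetic cohort
#'
#' Per-class distributions of the 29 clinical and dosimetric variables used
#' by the cohort generator: category counts for categorical variables and
#' mean/SD pairs for continuous ones, separately for the non-RD2+ ("neg",
#' grade <= 1) and RD2+ ("pos", grade >= 2) groups of a 70/144 reference
#' cohort. Dose statistics are in cGy, volumes in percent.
#'
#' @return A named list; each element is either
#'   `list(type = "cat", levels, neg, pos)` (counts) or
#'   `list(type = "num", neg = c(mean, sd), pos = c(mean, sd), min, max)`.
#' @export
default_clinical_marginals <- function() {
  num <- function(negm, negs, posm, poss, lo = -Inf, hi = Inf)
    list(type = "num", neg = c(negm, negs), pos = c(posm, poss),
         min = lo, max = hi)
  cat_ <- function(levels, neg, pos)
    list(type = "cat", levels = levels, neg = neg, pos = pos)
  list(
    Age = num(50.04, 9.44, 49.48, 9.62, 18, 95),
    BMI = num(22.94, 3.03, 23.25, 2.70, 13, 45),
    Body.temperature = num(36.67, 0.33, 36.70, 0.35, 35, 39),
    Laterality = cat_(c("Left", "Right"), c(44, 26), c(82, 62)),
    Quadrant.position = cat_(
      c("Upper-Outer", "Upper-Inner", "Lower-Outer", "Lower-Inner"),
      c(17, 26, 13, 14), c(23, 57, 54, 10)),
    Tumor.maximum.diameter = num(1.97, 0.91, 2.28, 1.68, 0.1, 12),
    Tumor.grade = cat_(c("I", "II", "III"), c(5, 36, 29), c(13, 69, 62)),
    Histologic.type = cat_(c("DCIS", "IDC", "ILC", "IMC", "LCIS/DCIS"),
                           c(10, 59, 1, 0, 0), c(13, 124, 5, 1, 1)),
    Overall.Stage = cat_(c("0", "I", "IIA", "IIB", "IIIA", "IIIB", "IIIC", "IV"),
                         c(4, 14, 17, 0, 3, 18, 13, 1),
                         c(9, 16, 31, 1, 12, 30, 40, 5)),
    T.Stage = cat_(c("Tx~is", "T0", "T1", "T2", "T3", "T4"),
                   c(1, 3, 4, 43, 17, 2), c(4, 5, 5, 74, 48, 8)),
    N.Stage = cat_(c("0", "1", "2", "3"), c(36, 18, 11, 5), c(66, 46, 21, 11)),
    M.Stage = cat_(c("0", "1"), c(70, 0), c(143, 1)),
    CRP = num(2.27, 4.19, 2.36, 5.03, 0, 60),
    ER = cat_(c("Positive", "Negative"), c(55, 15), c(114, 30)),
    PR = cat_(c("Positive", "Negative"), c(50, 20), c(112, 32)),
    HER2 = cat_(c("Positive", "Negative"), c(14, 56), c(34, 110)),
    Surgery.method = cat_(c("Lumpectomy", "Mastectomy", "Reconstruction"),
                          c(41, 27, 2), c(84, 59, 1)),
    Chemotherapy = cat_(c("No", "Yes"), c(13, 57), c(32, 112)),
    Hormone.therapy = cat_(c("No", "Yes"), c(44, 26), c(77, 67)),
    EQD2_all = num(52.16, 5.18, 52.66, 4.16, 30, 80),
    Lotion.application = cat_(c("No", "Yes"), c(6, 64), c(5, 139)),
    PTV_mean = num(5098.71, 325.99, 5139.06, 317.50, 3000, 7000),
    PTV_max = num(5773.97, 477.05, 5839.24, 454.27, 3500, 8000),
    PTV_boost = cat_(c("Yes", "No"), c(41, 29), c(80, 64)),
    SKIN_mean = num(3608.40, 493.26, 3587.22, 570.25, 1000, 6000),
    SKIN_max = num(5447.94, 489.98, 5535.82, 464.63, 2000, 8000),
    SKIN_V20 = num(87.26, 10.00, 85.65, 12.01, 0, 100),
    SKIN_V30 = num(70.60, 14.74, 69.69, 15.31, 0, 100),
    SKIN_V40 = num(44.59, 21.24, 43.83, 20.93, 0, 100)
  )
}

#' Specification of a synthetic phantom cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort size
#' and class balance, phantom grid geometry, prescription dose, the planted
#' class-separating texture effect, clinical marginals and the seed.
#'
#' @param n_patients total number of patients (>= 10).
#' @param n_rd2plus number of patients labelled RD2+ (grade >= 2 dermatitis).
#' @param grid_shape integer voxel triple, each >= 16.
#' @param spacing_mm voxel spacing in mm.
#' @param prescription_Gy prescribed dose in Gy.
#' @param effect_size_delta unitless >= 0; scales the difference in noise SD
#'   and correlation length of the skin/PTV texture between classes. 0 means
#'   image statistics are identically distributed across classes.
#' @param clinical_marginals list as returned by [default_clinical_marginals()].
#' @param clinical_effects logical; when `TRUE`, additional weak log-odds
#'   label effects are planted on Hormone therapy, T stage and Quadrant
#'   position (off by default).
#' @param seed integer seed; identical specs produce identical cohorts.
#' @return An object of class `rd_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 214, n_rd2plus = 144,
                        grid_shape = c(64, 64, 40),
                        spacing_mm = c(4, 4, 5),
                        prescription_Gy = 50,
                        effect_size_delta = 1,
                        clinical_marginals = default_clinical_marginals(),
                        clinical_effects = FALSE,
                        seed = 1) {
  if (any(grid_shape < 16)) stop("degenerate grid: each dimension must be >= 16")
  if (n_patients < 10) stop("n_patients must be >= 10")
  if (n_rd2plus > n_patients) stop("n_rd2plus must not exceed n_patients")
  if (effect_size_delta < 0) stop("effect_size_delta must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 n_rd2plus = as.integer(n_rd2plus),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 prescription_Gy = prescription_Gy,
                 effect_size_delta = effect_size_delta,
                 clinical_marginals = clinical_marginals,
                 clinical_effects = isTRUE(clinical_effects),
                 seed = as.integer(seed)),
            class = "rd_cohort_spec")
}

# Phantom geometry: elliptic-cylinder thorax section with a half-ellipsoid
# breast attached to its anterior surface; everything parameterised as
# fractions of the physical extent so arbitrary grids work.
phantom_geometry <- function(shape, spacing) {
  L <- shape * spacing
  cx <- seq(0, by = spacing[1], length.out = shape[1])
  cy <- seq(0, by = spacing[2], length.out = shape[2])
  cz <- seq(0, by = spacing[3], length.out = shape[3])
  X <- array(rep(cx, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(cy, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), dim = shape)

  thorax <- ((X - 0.50 * L[1]) / (0.40 * L[1]))^2 +
            ((Y - 0.62 * L[2]) / (0.28 * L[2]))^2 <= 1
  breast <- ((X - 0.47 * L[1]) / (0.20 * L[1]))^2 +
            ((Y - 0.34 * L[2]) / (0.18 * L[2]))^2 +
            ((Z - 0.50 * L[3]) / (0.28 * L[3]))^2 <= 1
  body <- thorax | breast
  skin <- body & !erode_mask(body, spacing, 5)
  ptv <- breast & !skin
  list(body = body, breast = breast, skin = skin, ptv = ptv,
       X = X, Y = Y, Z = Z, L = L)
}

# Smooth dose field: plateau at 1.02 x Rx over the well-covered part of the
# breast (including the overlying skin) with exponential-like falloff from
# Gaussian smoothing of the breast indicator, plus one Gaussian hot spot
# taking the in-PTV maximum to >= 1.10 x Rx.
phantom_dose <- function(geom, spacing, rx, hot_centre) {
  u <- smooth_volume(geom$breast * 1.0, spacing, sigma_mm = 12, mode = "zero")
  q <- quantile(u[geom$breast], 0.40, names = FALSE)
  base <- 1.02 * rx * pmin(1, u / q)
  r2 <- ((geom$X - hot_centre[1])^2 + (geom$Y - hot_centre[2])^2 +
         (geom$Z - hot_centre[3])^2) / (2 * 12^2)
  dose <- base + 0.09 * rx * exp(-r2)
  pmin(dose, 1.12 * rx)
}

# Stationary Gaussian random field with marginal SD `sigma` and correlation
# length `ell` (voxels), via smoothed white noise renormalised empirically.
random_field <- function(shape, sigma, ell) {
  w <- array(rnorm(prod(shape)), dim = shape)
  f <- array(cpp_smooth3(as.numeric(w), as.integer(shape),
                         rep(ell, 3), 1L), dim = shape)
  f * (sigma / sd(f))
}

generate_patient <- function(spec, label, id, pseed) {
  with_seed(pseed, {
    shape <- spec$grid_shape
    spacing <- spec$spacing_mm
    geom <- phantom_geometry(shape, spacing)
    rx <- spec$prescription_Gy

    # hot spot centre drawn within the breast core
    core <- which(erode_mask(geom$breast, spacing, 10), arr.ind = TRUE)
    if (nrow(core) == 0) core <- which(geom$breast, arr.ind = TRUE)
    hc_idx <- core[sample.int(nrow(core), 1), ]
    hot_centre <- (hc_idx - 1) * spacing
    dose <- phantom_dose(geom, spacing, rx, hot_centre)

    # Class-conditional texture. Every patient has individual noise
    # amplitude and correlation length (lognormal inter-patient spread);
    # RD2+ patients additionally have rougher, noisier skin (sigma up,
    # correlation length down) and coarser PTV texture (correlation length
    # up), both scaled by delta. The same three-field construction runs for
    # both classes, so delta = 0 gives identical distributions.
    delta <- spec$effect_size_delta
    s_p <- exp(rnorm(1, 0, 0.08))
    l_p <- exp(rnorm(1, 0, 0.08))
    sigma0 <- 15 * s_p; ell0 <- 1.5 * l_p
    eff <- if (label == 1L) delta else 0
    skin_sigma <- sigma0 * (1 + 0.15 * eff)
    skin_ell <- ell0 / (1 + 0.15 * eff)
    ptv_ell <- ell0 * (1 + 0.20 * eff)
    base_field <- random_field(shape, sigma0, ell0)
    skin_field <- random_field(shape, skin_sigma, skin_ell)
    ptv_field <- random_field(shape, sigma0, ptv_ell)
    img <- array(-1000, dim = shape)
    img[geom$body] <- 40 + base_field[geom$body]
    img[geom$skin] <- 40 + skin_field[geom$skin]
    img[geom$ptv] <- 40 + ptv_field[geom$ptv]

    structure(list(
      id = id,
      image = rd_volume(img, spacing),
      dose = rd_volume(dose, spacing),
      ptv_mask = geom$ptv,
      skin_mask = geom$skin,
      label = as.integer(label)
    ), class = "rd_patient")
  })
}

# Largest-remainder allocation of n items to category probabilities.
allocate_counts <- function(weights, n) {
  if (sum(weights) == 0) weights <- rep(1, length(weights))
  p <- weights / sum(weights)
  raw <- p * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

generate_clinical <- function(spec, labels) {
  marg <- spec$clinical_marginals
  n <- length(labels)
  out <- data.frame(row.names = seq_len(n))
  for (v in names(marg)) {
    m <- marg[[v]]
    col <- rep(NA_character_, n)
    if (m$type == "cat") {
      for (cls in c(0, 1)) {
        idx <- which(labels == cls)
        if (!length(idx)) next
        cnt <- allocate_counts(if (cls == 1) m$pos else m$neg, length(idx))
        vals <- rep(m$levels, times = cnt)
        col[idx] <- sample(vals)
      }
      out[[v]] <- factor(col, levels = m$levels)
    } else {
      x <- numeric(n)
      for (cls in c(0, 1)) {
        idx <- which(labels == cls)
        if (!length(idx)) next
        par <- if (cls == 1) m$pos else m$neg
        x[idx] <- rnorm(length(idx), par[1], par[2])
      }
      out[[v]] <- pmin(pmax(x, m$min), m$max)
    }
  }
  if (spec$clinical_effects) {
    # weak planted log-odds effects: resample the three flagged variables
    # conditionally on the label
    eta <- 0.6 * (labels - mean(labels))
    for (v in c("Hormone.therapy", "T.Stage", "Quadrant.position")) {
      m <- marg[[v]]
      k <- length(m$levels)
      sc <- (seq_len(k) - (k + 1) / 2) / k
      for (i in seq_len(n)) {
        w <- (m$neg + m$pos) / sum(m$neg + m$pos)
        w <- w * exp(sc * eta[i] * 4)
        out[i, v] <- sample(m$levels, 1, prob = w / sum(w))
      }
    }
  }
  out
}

#' Generate a synthetic phantom cohort
#'
#' Builds `n_patients` synthetic patients: a breast-on-thorax CT phantom with
#' class-conditional correlated texture in the skin and PTV voxels, a smooth
#' dose distribution with an in-PTV hot spot exceeding 108% of prescription,
#' binary PTV and skin masks, a 29-variable clinical table drawn from the
#' configured marginals, and exactly `n_rd2plus` positive labels. Fully
#' deterministic under the spec seed.
#'
#' @param spec an [cohort_spec()] object.
#' @return An object of class `rd_cohort`: a list with elements `patients`
#'   (list of `rd_patient`), `clinical` (data.frame), `labels` (0/1 integer)
#'   and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rd_cohort_spec"))
  labels <- with_seed(derive_seed(spec$seed, "labels"), {
    l <- rep(0L, spec$n_patients)
    l[sample.int(spec$n_patients, spec$n_rd2plus)] <- 1L
    l
  })
  ids <- sprintf("P%03d", seq_len(spec$n_patients))
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    patients[[i]] <- generate_patient(
      spec, labels[i], ids[i],
      derive_seed(spec$seed, paste0("patient", i)))
  }
  clinical <- with_seed(derive_seed(spec$seed, "clinical"),
                        generate_clinical(spec, labels))
  clinical <- cbind(id = ids, clinical, stringsAsFactors = FALSE)
  structure(list(patients = patients, clinical = clinical,
                 labels = labels, spec = spec),
            class = "rd_cohort")
}

#' @export
print.rd_cohort <- function(x, ...) {
  cat(sprintf("<rd_cohort> %d patients (%d RD2+ / %d non-RD2+), grid %s, delta = %g\n",
              length(x$patients), sum(x$labels), sum(x$labels == 0),
              paste(x$spec$grid_shape, collapse = "x"),
              x$spec$effect_size_delta))
  invisible(x)
}

#' Write one synthetic patient to disk
#'
#' Writes image, dose and the two masks as NIfTI-1 (`.nii.gz`), appends the
#' patient's clinical row to `cohort.csv` and records all paths plus the
#' label in `manifest.json` inside `dir`.
#'
#' @param patient an `rd_patient`.
#' @param dir output directory (created if missing).
#' @param clinical optional single-row data.frame with the patient's
#'   clinical variables.
#' @return Invisibly, the named character vector of files written.
#' @export
write_patient <- function(patient, dir, clinical = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  wr <- function(arr, spacing, name) {
    path <- file.path(dir, paste0(patient$id, "_", name, ".nii.gz"))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
    path
  }
  sp <- patient$image$spacing
  files <- c(
    image = wr(patient$image$data, sp, "image"),
    dose = wr(patient$dose$data, patient$dose$spacing, "dose"),
    ptv_mask = wr(patient$ptv_mask * 1L, sp, "ptv_mask"),
    skin_mask = wr(patient$skin_mask * 1L, sp, "skin_mask")
  )
  if (!is.null(clinical)) {
    csv <- file.path(dir, "cohort.csv")
    write.table(clinical, csv, sep = ",", row.names = FALSE,
                col.names = !file.exists(csv), append = file.exists(csv),
                qmethod = "double")
  }
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  manifest[[patient$id]] <- list(files = as.list(files),
                                 label = patient$label)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}

#' Inject missing values into a table
#'
#' Blanks a controlled fraction of cells either completely at random (MCAR)
#' or at random conditional on an observed covariate (MAR; the missingness
#' rate varies across tertiles of `mar_driver`, which itself is never
#' blanked).
#'
#' @param table a data.frame.
#' @param fraction target proportion of missing cells in `[0, 0.5)`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed integer seed.
#' @param mar_driver name of the numeric column driving MAR missingness.
#' @param exclude columns never blanked (identifier columns etc.).
#' @return The table with `NA`s inserted.
#' @export
inject_missingness <- function(table, fraction, mechanism = c("MCAR", "MAR"),
                               seed = 1, mar_driver = "BMI",
                               exclude = "id") {
  mechanism <- match.arg(mechanism)
  if (fraction < 0 || fraction >= 0.5)
    stop("fraction must be in [0, 0.5)")
  if (fraction == 0) return(table)
  cols <- setdiff(names(table), exclude)
  if (mechanism == "MAR") cols <- setdiff(cols, mar_driver)
  cells <- expand.grid(row = seq_len(nrow(table)), col = cols,
                       stringsAsFactors = FALSE)
  n_null <- round(fraction * nrow(table) * length(cols))
  with_seed(seed, {
    if (mechanism == "MCAR") {
      pick <- sample.int(nrow(cells), n_null)
    } else {
      drv <- table[[mar_driver]]
      if (!is.numeric(drv)) stop("MAR driver must be numeric: ", mar_driver)
      ter <- cut(drv, quantile(drv, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                 labels = FALSE)
      w <- c(0.5, 1, 1.5)[ter[cells$row]]
      pick <- sample.int(nrow(cells), n_null, prob = w)
    }
    for (i in pick) table[cells$row[i], cells$col[i]] <- NA
    table
  })
}
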