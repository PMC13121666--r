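# Synthetic multiparametric tumor-cohort generator: ellipsoidal tumors with
# three planted concentric habitat shells and class-conditional NODDI
# intensity profiles (GB vs SBM).

NODDI_MAPS <- c("ICVF", "ISOVF", "ODI")
SHELLS <- c("core", "margin", "rim")

#' Default class-conditional shell intensity profiles
#'
#' Mean NODDI index per diagnosis (GB, SBM), per concentric shell (core,
#' margin, rim) and per map (ICVF, ISOVF, ODI), plus a between-patient SD
#' (default 0: shell intensities are fixed at the class mean and all
#' within-cohort variation comes from the voxel noise field and geometry).
#'
#' The means follow the qualitative microstructural contrasts reported for
#' the two tumor types: the enhancing margin in glioblastoma shows high ICVF
#' (dense cellular infiltration), relatively low ISOVF (little necrosis) and
#' elevated ODI (disordered neurites), whereas metastasis margins show lower
#' ICVF and higher free-water ISOVF with flatter ODI; the core carries
#' markedly high free water in both classes; the rim (peritumoral solid
#' region) shows strongly elevated ODI in GB but only moderate ODI in SBM.
#' Magnitudes are this generator's own calibration — only the directions are
#' established — chosen so the three shells form well-separated clusters
#' while the within-shell class contrast stays subordinate to the shell
#' contrast.
#'
#' @return data.frame with columns `diagnosis`, `shell`, `map`, `mean`, `sd`.
#' @export
default_class_profiles <- function() {
  means <- rbind(
    #             ICVF  ISOVF  ODI
    GB.core    = c(0.55, 0.80, 0.45),
    GB.margin  = c(0.62, 0.18, 0.55),
    GB.rim     = c(0.28, 0.10, 0.78),
    SBM.core   = c(0.50, 0.75, 0.50),
    SBM.margin = c(0.52, 0.28, 0.45),
    SBM.rim    = c(0.28, 0.16, 0.68)
  )
  key <- do.call(rbind, strsplit(rownames(means), ".", fixed = TRUE))
  data.frame(
    diagnosis = rep(key[, 1], each = 3),
    shell = rep(key[, 2], each = 3),
    map = rep(NODDI_MAPS, times = nrow(means)),
    mean = as.vector(t(means)),
    sd = 0,
    stringsAsFactors = FALSE
  )
}

# Out-of-ROI background intensity per map (normal-appearing tissue stand-in).
BACKGROUND_MEANS <- c(ICVF = 0.60, ISOVF = 0.08, ODI = 0.35)

#' Specify a synthetic tumor cohort
#'
#' @param n_gb,n_sbm number of glioblastoma / solitary-brain-metastasis cases.
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_spacing mm per axis (length 3).
#' @param tumor_radius_range min/max ellipsoid semi-axis length in mm.
#' @param shell_fractions named volume fractions of the core/margin/rim
#'   shells; must sum to 1.
#' @param class_profiles data.frame as [default_class_profiles()].
#' @param noise_sd marginal SD (intensity units) of the spatially smoothed
#'   voxel noise field added to every map.
#' @param noise_smoothing_sigma Gaussian smoothing of the noise field, in
#'   voxels; the smoothed field is renormalized so its per-voxel SD is
#'   exactly `noise_sd`.
#' @param age_params list with per-class `c(mean, sd)` in years.
#' @param male_fraction named per-class probability of male sex.
#' @param centers optional data.frame (`center`, `n_gb`, `n_sbm`) splitting
#'   the cohort across centers; defaults to a single center "A".
#' @param seed integer master seed; every case derives its own substream.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_gb = 30, n_sbm = 15,
                        grid_shape = c(48, 48, 48),
                        voxel_spacing = c(1, 1, 1),
                        tumor_radius_range = c(8, 16),
                        shell_fractions = c(core = 0.40, margin = 0.35, rim = 0.25),
                        class_profiles = default_class_profiles(),
                        noise_sd = 0.08,
                        noise_smoothing_sigma = 1,
                        age_params = list(GB = c(53.2, 11.2), SBM = c(57.1, 10.2)),
                        male_fraction = c(GB = 0.58, SBM = 0.571),
                        centers = NULL,
                        seed = 1L) {
  spec <- list(
    n_gb = n_gb, n_sbm = n_sbm, grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    tumor_radius_range = tumor_radius_range,
    shell_fractions = shell_fractions, class_profiles = class_profiles,
    noise_sd = noise_sd, noise_smoothing_sigma = noise_smoothing_sigma,
    age_params = age_params, male_fraction = male_fraction,
    centers = centers, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' @noRd
validate_cohort_spec <- function(spec) {
  if (spec$n_gb < 0 || spec$n_sbm < 0) stopf("n_gb and n_sbm must be >= 0")
  if (abs(sum(spec$shell_fractions) - 1) > 1e-9)
    stopf("shell_fractions must sum to 1 (got %.12f)", sum(spec$shell_fractions))
  if (any(spec$class_profiles$mean < 0 | spec$class_profiles$mean > 1))
    stopf("class profile means must lie in [0, 1]")
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 1))
    stopf("grid_shape must be three positive integers")
  if (any(spec$voxel_spacing <= 0)) stopf("voxel_spacing must be positive")
  if (diff(spec$tumor_radius_range) < 0 || spec$tumor_radius_range[1] <= 0)
    stopf("tumor_radius_range must be an increasing positive range")
  invisible(spec)
}

#' Cohort presets
#'
#' `"desk"` is the fast development/test preset: 30 GB + 15 SBM at center A
#' plus 10 GB + 5 SBM at center B (external test), on 48^3 1-mm grids.
#' `"full-scale"` matches the published two-center cohort: center A with
#' 146 GB + 58 SBM (split 7:3 into training/validation) and center B with
#' 50 GB + 25 SBM as the external test set — 196 GB and 83 SBM in total.
#'
#' @param name `"desk"` or `"full-scale"`.
#' @param ... overrides forwarded to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
cohort_preset <- function(name = c("desk", "full-scale"), ...) {
  name <- match.arg(name)
  centers <- switch(name,
    "desk" = data.frame(center = c("A", "B"), n_gb = c(30, 10), n_sbm = c(15, 5)),
    "full-scale" = data.frame(center = c("A", "B"), n_gb = c(146, 50), n_sbm = c(58, 25))
  )
  cohort_spec(
    n_gb = sum(centers$n_gb), n_sbm = sum(centers$n_sbm),
    centers = centers, ...
  )
}

#' Generate one synthetic patient case
#'
#' Plants an ellipsoidal tumor ROI partitioned into three concentric shells
#' (core, margin, rim, with the configured volume fractions), fills each
#' shell of each NODDI map with the class-conditional shell mean, adds a
#' smoothed Gaussian noise field (marginal SD `noise_sd`), and clips to
#' \[0, 1\]. `truth_labels` records the planted shell (1 = core, 2 = margin,
#' 3 = rim) of every ROI voxel.
#'
#' @param spec a [cohort_spec()].
#' @param diagnosis `"GB"` or `"SBM"`.
#' @param seed integer seed; the case is deterministic given `(spec, seed)`.
#' @param patient_id,center identifiers stored on the case.
#' @param maps with `FALSE`, skip volume synthesis and return demographics
#'   only (the manifest fields are identical either way).
#' @return object of class `patient_case`: fields `patient_id`, `diagnosis`,
#'   `age`, `sex`, `center`, `maps` (named list of 3-D arrays), `roi`
#'   (logical array), `truth_labels` (integer array), `grid`.
#' @export
generate_case <- function(spec, diagnosis = c("GB", "SBM"), seed = 1L,
                          patient_id = NULL, center = "A", maps = TRUE) {
  diagnosis <- match.arg(diagnosis)
  validate_cohort_spec(spec)
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  extent <- d * sp
  rmax <- spec$tumor_radius_range[2]
  if (any(extent < 2 * spec$tumor_radius_range[1] + 2 * sp))
    stopf("grid too small to contain the minimum tumor radius %.1f mm",
          spec$tumor_radius_range[1])
  set.seed(as.integer(seed))

  # demographics first, so the manifest is identical with and without maps
  ap <- spec$age_params[[diagnosis]]
  age <- round(min(max(rnorm(1, ap[1], ap[2]), 18), 90), 1)
  sex <- if (rbinom(1, 1, spec$male_fraction[[diagnosis]]) == 1) "male" else "female"
  if (!maps) {
    return(structure(list(
      patient_id = patient_id %||% sprintf("%s-%06d", diagnosis,
                                           as.integer(seed) %% 1000000L),
      diagnosis = diagnosis, age = age, sex = sex, center = center,
      maps = NULL, roi = NULL, truth_labels = NULL,
      grid = volume_grid(shape = d, spacing = sp)
    ), class = "patient_case"))
  }

  # ellipsoid semi-axes (mm), capped so the tumor fits with a 1-voxel border
  cap <- pmin(rmax, extent / 2 - sp)
  axes <- runif(3, spec$tumor_radius_range[1], cap)
  # center jitter within the room left after the tumor
  room <- pmax(0, extent / 2 - axes - sp)
  ctr <- extent / 2 + runif(3, -1, 1) * pmin(room, 2 * sp)

  # normalized elliptical radius on the voxel-center grid (0-based indices)
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * sp[ax])
  u2 <- outer(outer(((co[[1]] - ctr[1]) / axes[1])^2,
                    ((co[[2]] - ctr[2]) / axes[2])^2, "+"),
              ((co[[3]] - ctr[3]) / axes[3])^2, "+")
  u <- sqrt(u2)
  roi <- u <= 1
  if (!any(roi)) stopf("generated ROI is empty; grid/radius configuration invalid")
  f <- spec$shell_fractions
  s1 <- f[["core"]]^(1 / 3)
  s2 <- (f[["core"]] + f[["margin"]])^(1 / 3)
  truth <- array(0L, d)
  truth[roi] <- ifelse(u[roi] <= s1, 1L, ifelse(u[roi] <= s2, 2L, 3L))

  prof <- spec$class_profiles
  prof <- prof[prof$diagnosis == diagnosis, ]
  sdfac <- gaussian_smooth3_sd_factor(spec$noise_smoothing_sigma)
  maps <- list()
  for (m in NODDI_MAPS) {
    vol <- array(BACKGROUND_MEANS[[m]], d)
    for (si in 1:3) {
      row <- prof[prof$shell == SHELLS[si] & prof$map == m, ]
      shell_mean <- row$mean
      if (row$sd > 0 && spec$noise_sd > 0)
        shell_mean <- shell_mean + rnorm(1, 0, row$sd)
      vol[truth == si] <- shell_mean
    }
    if (spec$noise_sd > 0) {
      noise <- array(rnorm(prod(d)), d)
      noise <- gaussian_smooth3(noise, spec$noise_smoothing_sigma) / sdfac
      vol <- vol + spec$noise_sd * noise
    }
    maps[[m]] <- pmin(pmax(vol, 0), 1)
  }

  structure(list(
    patient_id = patient_id %||% sprintf("%s-%06d", diagnosis, as.integer(seed) %% 1000000L),
    diagnosis = diagnosis, age = age, sex = sex, center = center,
    maps = maps, roi = roi, truth_labels = truth,
    grid = volume_grid(shape = d, spacing = sp)
  ), class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case %s> %s, age %.1f, %s, center %s, ROI %d voxels\n",
              x$patient_id, x$diagnosis, x$age, x$sex, x$center, sum(x$roi)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Draws `n_gb + n_sbm` cases (optionally spread across centers), assigning
#' each case a deterministic sub-seed derived from the spec seed and the
#' patient id. With `out_dir` set, writes each map and the ROI as NIfTI and
#' the manifest as CSV.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @param keep_cases return the in-memory cases (default TRUE); set FALSE
#'   with `out_dir` to keep memory flat for large cohorts.
#' @param light with `TRUE`, draw demographics only (no volumes; manifest
#'   work at full cohort scale without the memory cost).
#' @return list with `cases` (list of `patient_case` or NULL) and `manifest`
#'   (data.frame: patient_id, diagnosis, age, sex, center, split, paths).
#' @export
generate_cohort <- function(spec, out_dir = NULL, keep_cases = TRUE,
                            light = FALSE) {
  validate_cohort_spec(spec)
  if (spec$n_gb + spec$n_sbm == 0) stopf("empty cohort: n_gb + n_sbm is 0")
  centers <- spec$centers %||%
    data.frame(center = "A", n_gb = spec$n_gb, n_sbm = spec$n_sbm)
  if (sum(centers$n_gb) != spec$n_gb || sum(centers$n_sbm) != spec$n_sbm)
    stopf("centers table must add up to n_gb / n_sbm")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list(); cases <- list(); idx <- 0L
  for (ci in seq_len(nrow(centers))) {
    for (cls in c("GB", "SBM")) {
      n <- centers[[if (cls == "GB") "n_gb" else "n_sbm"]][ci]
      for (i in seq_len(n)) {
        idx <- idx + 1L
        pid <- sprintf("%s%s%03d", centers$center[ci], cls, i)
        case_seed <- (spec$seed + hash32(pid)) %% 2147483647L
        case <- generate_case(spec, cls, seed = case_seed,
                              patient_id = pid, center = centers$center[ci],
                              maps = !light)
        paths <- rep(NA_character_, 4)
        names(paths) <- c("ICVF", "ISOVF", "ODI", "roi")
        if (!is.null(out_dir) && !light) {
          for (m in NODDI_MAPS) {
            p <- file.path(out_dir, sprintf("%s_%s.nii.gz", pid, m))
            write_volume(case$maps[[m]], case$grid, p)
            paths[m] <- p
          }
          p <- file.path(out_dir, sprintf("%s_roi.nii.gz", pid))
          write_volume(array(as.numeric(case$roi), dim(case$roi)), case$grid, p)
          paths["roi"] <- p
        }
        rows[[idx]] <- data.frame(
          patient_id = pid, diagnosis = cls, age = case$age, sex = case$sex,
          center = case$center, split = NA_character_,
          path_icvf = paths[["ICVF"]], path_isovf = paths[["ISOVF"]],
          path_odi = paths[["ODI"]], path_roi = paths[["roi"]],
          stringsAsFactors = FALSE
        )
        if (keep_cases && !light) cases[[pid]] <- case
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(cases = if (keep_cases) cases else NULL, manifest = manifest)
}

#' Assign training / validation / test splits
#'
#' Center-B rows (the external test center) are always labeled `"test"` and
#' never reassigned. Remaining rows are split with validation size
#' `ceiling((1 - ratio) * n)`; the stratified scheme apportions the
#' validation count across diagnoses by largest remainder so each split's
#' class fraction is within one case of the cohort's.
#'
#' @param manifest cohort manifest with at least `patient_id`, `diagnosis`,
#'   `center` columns.
#' @param ratio training fraction in (0, 1); default 0.7 (the 7:3 rule).
#' @param seed integer seed.
#' @param scheme `"stratified"` (default) or `"random"`.
#' @param test_center center label reserved for the external test set.
#' @return the manifest with its `split` column filled.
#' @export
split_cohort <- function(manifest, ratio = 0.7, seed = 1L,
                         scheme = c("stratified", "random"),
                         test_center = "B") {
  scheme <- match.arg(scheme)
  if (!all(c("diagnosis") %in% names(manifest)))
    stopf("manifest is missing required column: diagnosis")
  if (ratio <= 0 || ratio >= 1) stopf("ratio must be in (0, 1)")
  if (!"center" %in% names(manifest)) manifest$center <- "A"
  manifest$split <- NA_character_
  is_test <- manifest$center == test_center
  manifest$split[is_test] <- "test"
  pool <- which(!is_test)
  n <- length(pool)
  if (n == 0) return(manifest)
  n_val <- as.integer(ceiling((1 - ratio) * n - 1e-9))
  set.seed(as.integer(seed))
  if (scheme == "random") {
    val <- sample(pool, n_val)
  } else {
    classes <- unique(manifest$diagnosis[pool])
    target <- (1 - ratio) * table(factor(manifest$diagnosis[pool], classes))
    base <- floor(target)
    rem <- n_val - sum(base)
    if (rem > 0) {
      order_rem <- order(target - base, decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
    } else if (rem < 0) {
      order_rem <- order(target - base)
      base[order_rem[seq_len(-rem)]] <- base[order_rem[seq_len(-rem)]] - 1
    }
    val <- unlist(lapply(classes, function(cl) {
      cand <- pool[manifest$diagnosis[pool] == cl]
      sample(cand, base[[cl]])
    }))
  }
  manifest$split[val] <- "validation"
  manifest$split[setdiff(pool, val)] <- "training"
  manifest
}
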