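# Region-level feature extraction: filter bank, per-region batteries across
# the three NODDI maps, prefusion of subregion vectors, and the feature-name
# grammar  <subregion>_<modality>_<filter>_<class>_<feature>.

#' Configure radiomic feature extraction
#'
#' @param bin_count gray levels for fixed-bin-number discretization.
#' @param distances GLCM/GLRLM offset distance in voxels.
#' @param filter_bank character vector of image filters applied to each
#'   modality before intensity/texture extraction. `"original"` only by
#'   default; the `"extended"` preset of [extraction_preset()] adds
#'   Laplacian-of-Gaussian (`log1`, `log2`, `log3`; sigma in mm) and the 8
#'   single-level Haar wavelet bands (`waveletLLL` .. `waveletHHH`).
#' @param feature_classes subset of
#'   `c("firstorder", "shape", "glcm", "glrlm", "glszm", "ngtdm", "gldm")`.
#' @param min_region_voxels regions smaller than this yield an all-missing
#'   vector with reason `"too_small"`.
#' @param log_sigmas mm sigmas backing the `logN` filters.
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(bin_count = 32, distances = 1,
                              filter_bank = "original",
                              feature_classes = c("firstorder", "shape", "glcm",
                                                  "glrlm", "glszm", "ngtdm", "gldm"),
                              min_region_voxels = 10,
                              log_sigmas = c(1, 2, 3)) {
  if (bin_count < 2) stopf("bin_count must be >= 2")
  if (any(distances < 1)) stopf("distances must be >= 1")
  if (min_region_voxels < 1) stopf("min_region_voxels must be >= 1")
  structure(list(bin_count = bin_count, distances = distances,
                 filter_bank = filter_bank, feature_classes = feature_classes,
                 min_region_voxels = min_region_voxels, log_sigmas = log_sigmas),
            class = "extraction_config")
}

#' @rdname extraction_config
#' @param name `"default"` (original images only; 293 features per region)
#'   or `"extended"` (adds LoG and wavelet filters; 3 x 12 x 93 + 14 = 3362
#'   features per region).
#' @export
extraction_preset <- function(name = c("default", "extended")) {
  name <- match.arg(name)
  if (name == "default") return(extraction_config())
  extraction_config(filter_bank = c("original",
                                    paste0("log", 1:3),
                                    paste0("wavelet", c("LLL", "LLH", "LHL", "LHH",
                                                        "HLL", "HLH", "HHL", "HHH"))))
}

# single-level undecimated Haar band-pass along each axis
#' @noRd
haar_band <- function(vol, bands) {
  for (ax in 1:3) {
    d <- dim(vol)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(vol, perm), nrow = d[ax])
    n <- nrow(m)
    nxt <- c(2:n, n)  # replicate edge
    m <- if (substr(bands, ax, ax) == "L") (m + m[nxt, , drop = FALSE]) / sqrt(2)
         else (m - m[nxt, , drop = FALSE]) / sqrt(2)
    vol <- aperm(array(m, d[perm]), order(perm))
  }
  vol
}

#' Apply a named image filter to a whole volume
#'
#' @param vol 3-D array.
#' @param name `"original"`, `"logN"` (Laplacian of Gaussian, sigma =
#'   `log_sigmas[N]` mm) or `"waveletXYZ"` with X,Y,Z in {L,H}.
#' @param spacing mm per axis.
#' @param log_sigmas mm sigmas for the LoG filters.
#' @return filtered 3-D array.
#' @export
apply_filter <- function(vol, name, spacing = c(1, 1, 1), log_sigmas = c(1, 2, 3)) {
  if (name == "original") return(vol)
  if (grepl("^log[0-9]+$", name)) {
    k <- as.integer(sub("^log", "", name))
    sigma_mm <- log_sigmas[k]
    sigma_vox <- sigma_mm / mean(spacing)
    sm <- gaussian_smooth3(vol, sigma_vox)
    d <- dim(vol)
    lap <- -6 * sm
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      src <- shift_index(d, off)
      nb <- sm
      ok <- !is.na(src)
      nb[ok] <- sm[src[ok]]
      lap <- lap + nb
    }
    return(lap / mean(spacing)^2)
  }
  if (grepl("^wavelet[LH]{3}$", name)) {
    return(haar_band(vol, sub("^wavelet", "", name)))
  }
  stopf("unknown filter: %s", name)
}

#' Extract the feature battery for one region of one case
#'
#' For each modality and each filter in the bank: first-order and texture
#' features of the filtered intensities inside `region_mask`; shape features
#' once from the mask (modality slot `mask`, filter `original`). Regions
#' below `min_region_voxels` return a vector of NA with the missing reason
#' `"too_small"` stored in the `missing_reason` attribute.
#'
#' @param case a `patient_case`.
#' @param region_mask logical array (subset of the ROI).
#' @param config an [extraction_config()].
#' @param region_name prefix for the feature names (e.g. `"H1"`, `"ROI"`).
#' @param filtered optional precomputed filter responses:
#'   `filtered[[modality]][[filter]]` (reused across the regions of a case).
#' @return named numeric vector (a feature vector).
#' @export
extract_region <- function(case, region_mask, config = extraction_config(),
                           region_name = "ROI", filtered = NULL) {
  if (!all(dim(region_mask) == dim(case$roi)))
    stopf("region mask is misaligned with case %s", case$patient_id)
  nm <- feature_names(config, region_name)
  nvox <- sum(region_mask)
  if (nvox < config$min_region_voxels) {
    out <- setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "missing_reason") <- "too_small"
    return(out)
  }
  classes <- config$feature_classes
  voxvol <- prod(case$grid$spacing)
  rng <- bbox_ranges(region_mask, margin = 1L)
  cmask <- crop_bbox(region_mask, rng)
  out <- numeric(0)
  for (mod in NODDI_MAPS) {
    for (flt in config$filter_bank) {
      vol <- if (!is.null(filtered)) filtered[[mod]][[flt]]
             else apply_filter(case$maps[[mod]], flt, case$grid$spacing, config$log_sigmas)
      cvol <- crop_bbox(vol, rng)
      vals <- cvol[cmask]
      pre <- paste(region_name, mod, flt, sep = "_")
      if ("firstorder" %in% classes) {
        fo <- first_order_features(vals, config$bin_count, voxvol)
        out <- c(out, setNames(fo, paste(pre, "firstorder", names(fo), sep = "_")))
      }
      tex_classes <- intersect(classes, c("glcm", "glrlm", "glszm", "ngtdm", "gldm"))
      if (length(tex_classes)) {
        disc <- discretize(cvol, cmask, config$bin_count)
        tx <- texture_matrix_features(disc, cmask, config$bin_count,
                                      config$distances[1])
        keep <- sub("_.*$", "", names(tx)) %in% tex_classes
        tx <- tx[keep]
        out <- c(out, setNames(tx, paste(pre, names(tx), sep = "_")))
      }
    }
  }
  if ("shape" %in% classes) {
    sh <- shape_features(cmask, case$grid$spacing)
    out <- c(out, setNames(sh, paste(region_name, "mask", "original", "shape",
                                     names(sh), sep = "_")))
  }
  if (!identical(names(out), nm))
    stopf("internal error: feature vector names do not match the grammar")
  out
}

#' Enumerate the feature names an extraction config produces
#' @inheritParams extract_region
#' @return character vector of feature names.
#' @export
feature_names <- function(config, region_name = "ROI") {
  classes <- config$feature_classes
  nm <- character(0)
  for (mod in NODDI_MAPS) {
    for (flt in config$filter_bank) {
      pre <- paste(region_name, mod, flt, sep = "_")
      if ("firstorder" %in% classes)
        nm <- c(nm, paste(pre, "firstorder", FIRSTORDER_FEATURES, sep = "_"))
      for (cls in intersect(c("glcm", "glrlm", "glszm", "ngtdm", "gldm"), classes)) {
        feats <- switch(cls, glcm = GLCM_FEATURES, glrlm = GLRLM_FEATURES,
                        glszm = GLSZM_FEATURES, ngtdm = NGTDM_FEATURES,
                        gldm = GLDM_FEATURES)
        nm <- c(nm, paste(pre, cls, feats, sep = "_"))
      }
    }
  }
  if ("shape" %in% classes)
    nm <- c(nm, paste(region_name, "mask", "original", "shape", SHAPE_FEATURES, sep = "_"))
  nm
}

#' Parse feature names back into their components
#'
#' @param names character vector in the
#'   `subregion_modality_filter_class_feature` grammar.
#' @return data.frame with columns `subregion`, `modality`, `filter`,
#'   `class`, `feature`.
#' @export
parse_feature_name <- function(names) {
  parts <- strsplit(names, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 5
  if (any(bad))
    stopf("unparseable feature name(s): %s", paste(names[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  data.frame(subregion = m[, 1], modality = m[, 2], filter = m[, 3],
             class = m[, 4], feature = m[, 5], stringsAsFactors = FALSE)
}

#' Prefuse subregion feature vectors into one habitat vector
#'
#' Concatenates the per-subregion vectors (names already carry the subregion
#' prefix); missing values pass through with their reasons preserved.
#'
#' @param subregion_vectors named list of feature vectors (e.g. H1, H2, H3).
#' @return one named numeric vector.
#' @export
prefuse <- function(subregion_vectors) {
  out <- do.call(c, unname(subregion_vectors))
  if (anyDuplicated(names(out)))
    stopf("duplicate feature names after prefusion: %s",
          paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  reasons <- unlist(lapply(subregion_vectors, attr, "missing_reason"))
  if (length(reasons)) attr(out, "missing_reason") <- reasons
  out
}

#' Extract all feature tables for a cohort
#'
#' Runs [extract_region()] for the three habitat subregions and the whole
#' ROI of every case, prefusing the subregion vectors into the habitat
#' table. Filter responses are computed once per case and shared across its
#' regions.
#'
#' @param cases named list of `patient_case`.
#' @param labelmaps named list of habitat label maps (integer arrays
#'   matching `cases`).
#' @param config an [extraction_config()].
#' @param K number of habitat subregions.
#' @param verbose print one line per case.
#' @return list of data.frames (`H1`, `H2`, `H3`, `habitat`, `ROI`), rows =
#'   patients (rownames = patient ids), plus `missing` (data.frame of
#'   missing-region reasons).
#' @export
extract_cohort_features <- function(cases, labelmaps, config = extraction_config(),
                                    K = 3, verbose = FALSE) {
  subnames <- paste0("H", seq_len(K))
  rows <- setNames(vector("list", length(cases)), names(cases))
  missing <- list()
  for (pid in names(cases)) {
    case <- cases[[pid]]
    lm <- labelmaps[[pid]]
    filtered <- lapply(case$maps, function(v) {
      setNames(lapply(config$filter_bank, function(f)
        apply_filter(v, f, case$grid$spacing, config$log_sigmas)),
        config$filter_bank)
    })
    vecs <- list()
    for (h in seq_len(K)) {
      vec <- extract_region(case, lm == h, config, subnames[h], filtered)
      if (!is.null(attr(vec, "missing_reason")))
        missing[[length(missing) + 1L]] <- data.frame(
          patient_id = pid, region = subnames[h],
          reason = attr(vec, "missing_reason"), stringsAsFactors = FALSE)
      vecs[[subnames[h]]] <- vec
    }
    vecs$ROI <- extract_region(case, case$roi, config, "ROI", filtered)
    rows[[pid]] <- vecs
    if (verbose) message(sprintf("extracted %s (%d ROI voxels)", pid, sum(case$roi)))
  }
  tab <- function(region) {
    m <- do.call(rbind, lapply(rows, function(r) r[[region]]))
    as.data.frame(m)
  }
  fused <- do.call(rbind, lapply(rows, function(r) prefuse(r[subnames])))
  out <- c(setNames(lapply(subnames, tab), subnames),
           list(habitat = as.data.frame(fused), ROI = tab("ROI")))
  out$missing <- if (length(missing)) do.call(rbind, missing) else
    data.frame(patient_id = character(), region = character(), reason = character())
  out
}
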