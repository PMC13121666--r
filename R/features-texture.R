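# Gray-level texture-matrix features in 3-D: GLCM (24), GLRLM (16),
# GLSZM (16), NGTDM (5), GLDM (14). Matrices are built over the 13 unique
# direction pairs (GLCM/GLRLM symmetric, features averaged over directions);
# GLSZM zones and GLDM dependencies use the full 26-neighborhood.
# Degenerate regions (single gray level, single voxel) return documented
# conventions, never exceptions. eps guards all divisions and logs.

TEX_EPS <- 1e-12

GLCM_FEATURES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)
GLRLM_FEATURES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis"
)
GLSZM_FEATURES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance"
)
NGTDM_FEATURES <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
GLDM_FEATURES <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis"
)

#' Gray-level co-occurrence matrices
#'
#' One symmetric, normalized co-occurrence matrix per direction (13 unique
#' 3-D direction pairs at the given voxel distance); directions with no
#' valid pair are dropped.
#'
#' @param disc integer array from [discretize()] (0 outside the mask).
#' @param mask logical array.
#' @param n_levels number of gray levels.
#' @param distance offset length in voxels.
#' @return list of Ng x Ng probability matrices.
#' @export
glcm_matrices <- function(disc, mask, n_levels, distance = 1) {
  d <- dim(disc)
  dirs <- directions13() * distance
  out <- list()
  for (k in seq_len(nrow(dirs))) {
    src <- shift_index(d, dirs[k, ])
    valid <- mask & !is.na(src)
    valid[valid] <- mask[src[valid]]
    if (!any(valid)) next
    a <- disc[valid]
    b <- disc[src[valid]]
    cnt <- tabulate((a - 1L) * n_levels + b, n_levels * n_levels)
    C <- matrix(cnt, n_levels, n_levels, byrow = TRUE)
    C <- C + t(C)
    out[[paste(dirs[k, ] / distance, collapse = ",")]] <- C / sum(C)
  }
  out
}

# features of one normalized symmetric GLCM
#' @noRd
glcm_features_one <- function(P) {
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  # difference and sum distributions
  kdiff <- 0:(Ng - 1)
  pdiff <- vapply(kdiff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * Ng)
  psum <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(kdiff * pdiff)
  ent <- function(p) { p <- p[p > TEX_EPS]; -sum(p * log2(p)) }
  HX <- ent(px); HY <- ent(py); HXY <- ent(as.vector(P))
  lp <- function(x) log2(pmax(x, TEX_EPS))
  HXY1 <- -sum(P * lp(outer(px, py)))
  HXY2 <- -sum(outer(px, py) * lp(outer(px, py)))
  corr <- if (sx > TEX_EPS && sy > TEX_EPS)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > TEX_EPS) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  # maximal correlation coefficient
  mcc <- {
    nz <- which(px > TEX_EPS)
    if (length(nz) < 2) 1 else {
      Pn <- P[nz, nz, drop = FALSE]
      Q <- matrix(0, length(nz), length(nz))
      for (a in seq_along(nz)) for (bq in seq_along(nz))
        Q[a, bq] <- sum(Pn[a, ] * Pn[bq, ] / (px[nz][a] * py[nz]))
      evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(pmax(evq[2], 0))
    }
  }
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pdiff),
    DifferenceVariance = sum((kdiff - da)^2 * pdiff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ksum * psum),
    SumEntropy = ent(psum),
    SumSquares = sum((i - mux)^2 * P)
  )
}

#' GLCM features averaged over the 13 directions
#' @inheritParams glcm_matrices
#' @return named numeric vector of the 24 GLCM features.
#' @export
glcm_features <- function(disc, mask, n_levels, distance = 1) {
  mats <- glcm_matrices(disc, mask, n_levels, distance)
  if (!length(mats)) {
    out <- setNames(numeric(length(GLCM_FEATURES)), GLCM_FEATURES)
    out["Correlation"] <- 1; out["MCC"] <- 1
    return(out)
  }
  rowMeans(vapply(mats, glcm_features_one, numeric(length(GLCM_FEATURES))))
}

#' Gray-level run-length matrix for one direction
#' @noRd
glrlm_matrix_dir <- function(disc, mask, n_levels, dir, max_len) {
  d <- dim(disc)
  nxt <- shift_index(d, dir)
  prv <- shift_index(d, -dir)
  idx <- which(mask)
  lev <- disc[idx]
  prev <- prv[idx]
  has_prev <- !is.na(prev)
  same_prev <- has_prev
  same_prev[has_prev] <- mask[prev[has_prev]] & disc[prev[has_prev]] == lev[has_prev]
  starts <- idx[!same_prev]
  slev <- lev[!same_prev]
  len <- rep(1L, length(starts))
  cur <- starts
  alive <- rep(TRUE, length(starts))
  while (any(alive)) {
    idx_alive <- which(alive)
    nx <- nxt[cur[idx_alive]]
    ok <- !is.na(nx)
    ok[ok] <- mask[nx[ok]] & disc[nx[ok]] == slev[idx_alive][ok]
    len[idx_alive[ok]] <- len[idx_alive[ok]] + 1L
    cur[idx_alive[ok]] <- nx[ok]
    alive[idx_alive[!ok]] <- FALSE
  }
  tab <- tabulate((slev - 1L) * max_len + pmin(len, max_len), n_levels * max_len)
  matrix(tab, n_levels, max_len, byrow = TRUE)
}

# features of one run-length matrix
#' @noRd
glrlm_features_one <- function(R, n_voxels) {
  Nr <- sum(R)
  p <- R / Nr
  i <- row(R); j <- col(R)
  ri <- rowSums(R); rj <- colSums(R)
  mui <- sum(i * p); muj <- sum(j * p)
  pe <- p[p > TEX_EPS]
  c(
    GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelRunEmphasis = sum(i^2 * p),
    LongRunEmphasis = sum(j^2 * p),
    LongRunHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LongRunLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    RunEntropy = -sum(pe * log2(pe)),
    RunLengthNonUniformity = sum(rj^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / Nr^2,
    RunPercentage = Nr / n_voxels,
    RunVariance = sum((j - muj)^2 * p),
    ShortRunEmphasis = sum(p / j^2),
    ShortRunHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * j^2))
  )
}

#' GLRLM features averaged over the 13 directions
#' @inheritParams glcm_matrices
#' @return named numeric vector of the 16 GLRLM features.
#' @export
glrlm_features <- function(disc, mask, n_levels, distance = 1) {
  d <- dim(disc)
  max_len <- max(d)
  n_voxels <- sum(mask)
  dirs <- directions13() * distance
  vals <- vapply(seq_len(nrow(dirs)), function(k) {
    R <- glrlm_matrix_dir(disc, mask, n_levels, dirs[k, ], max_len)
    glrlm_features_one(R, n_voxels)
  }, numeric(length(GLRLM_FEATURES)))
  rowMeans(vals)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level.
#'
#' @inheritParams glcm_matrices
#' @return named numeric vector of the 16 GLSZM features.
#' @export
glszm_features <- function(disc, mask, n_levels) {
  n_voxels <- sum(mask)
  zl <- integer(0); zs <- integer(0)
  for (l in seq_len(n_levels)) {
    sel <- mask & disc == l
    if (!any(sel)) next
    comp <- connected_components26(sel)
    sizes <- tabulate(comp[comp > 0])
    zl <- c(zl, rep(l, length(sizes)))
    zs <- c(zs, sizes)
  }
  Nz <- length(zs)
  p <- rep(1 / Nz, Nz)
  mui <- sum(zl * p); mus <- sum(zs * p)
  si <- tapply(rep(1, Nz), factor(zl, seq_len(n_levels)), sum, default = 0)
  ss <- tapply(rep(1, Nz), factor(zs), sum)
  c(
    GrayLevelNonUniformity = sum(si^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(si^2) / Nz^2,
    GrayLevelVariance = sum((zl - mui)^2 * p),
    HighGrayLevelZoneEmphasis = sum(zl^2 * p),
    LargeAreaEmphasis = sum(zs^2 * p),
    LargeAreaHighGrayLevelEmphasis = sum(zl^2 * zs^2 * p),
    LargeAreaLowGrayLevelEmphasis = sum(zs^2 * p / zl^2),
    LowGrayLevelZoneEmphasis = sum(p / zl^2),
    SizeZoneNonUniformity = sum(ss^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(ss^2) / Nz^2,
    SmallAreaEmphasis = sum(p / zs^2),
    SmallAreaHighGrayLevelEmphasis = sum(zl^2 * p / zs^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (zl^2 * zs^2)),
    ZoneEntropy = {
      pz <- as.numeric(table(paste(zl, zs))) / Nz  # (level, size) cells
      -sum(pz * log2(pz))
    },
    ZonePercentage = Nz / n_voxels,
    ZoneVariance = sum((zs - mus)^2 * p)
  )
}

# per-voxel neighbor sums/counts over the 26-neighborhood, in-mask only
#' @noRd
neighbor_stats26 <- function(vals, mask) {
  d <- dim(vals)
  dirs <- directions13()
  nsum <- array(0, d); ncnt <- array(0, d)
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1, -1)) {
      src <- shift_index(d, sgn * dirs[k, ])
      ok <- !is.na(src)
      okm <- ok
      okm[ok] <- mask[src[ok]]
      nsum[okm] <- nsum[okm] + vals[src[okm]]
      ncnt[okm] <- ncnt[okm] + 1
    }
  }
  list(sum = nsum, count = ncnt)
}

#' Neighborhood gray-tone difference features
#'
#' Voxels with no in-mask neighbor are excluded from the neighborhood
#' statistics (documented convention).
#'
#' @inheritParams glcm_matrices
#' @return named numeric vector of the 5 NGTDM features.
#' @export
ngtdm_features <- function(disc, mask, n_levels) {
  st <- neighbor_stats26(disc, mask)
  use <- mask & st$count > 0
  v <- disc[use]
  nbm <- st$sum[use] / st$count[use]
  N <- length(v)
  if (N == 0) # isolated voxel(s): no valid neighborhood at all
    return(c(Busyness = 0, Coarseness = 1e6, Complexity = 0,
             Contrast = 0, Strength = 0))
  levs <- seq_len(n_levels)
  n_i <- tabulate(v, n_levels)
  s_i <- vapply(levs, function(l) sum(abs(v[v == l] - nbm[v == l])), numeric(1))
  p_i <- n_i / N
  act <- which(p_i > 0)
  Ngp <- length(act)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > TEX_EPS) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) * outer(levs[act], levs[act], "-")^2) /
       (Ngp * (Ngp - 1))) * (sum(s_i) / N)
  } else 0
  busy_den <- sum(abs(outer(levs[act] * p_i[act], levs[act] * p_i[act], "-")))
  busyness <- if (busy_den > TEX_EPS) sum(p_i * s_i) / busy_den else 0
  complexity <- if (Ngp > 0) {
    pa <- p_i[act]; la <- levs[act]; sa <- s_i[act]
    sum(abs(outer(la, la, "-")) *
          (outer(pa * sa, pa * sa, "+")) / outer(pa, pa, "+")) / N
  } else 0
  strength_num <- sum(outer(p_i[act], p_i[act], "+") * outer(levs[act], levs[act], "-")^2)
  strength <- if (sum(s_i) > TEX_EPS) strength_num / sum(s_i) else 0
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}

#' Gray-level dependence features
#'
#' The dependence of a voxel is 1 plus the number of in-mask 26-neighbors
#' whose gray level differs by at most `alpha` (default 0).
#'
#' @inheritParams glcm_matrices
#' @param alpha gray-level similarity tolerance.
#' @return named numeric vector of the 14 GLDM features.
#' @export
gldm_features <- function(disc, mask, n_levels, alpha = 0) {
  d <- dim(disc)
  dirs <- directions13()
  dep <- array(0L, d)
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1, -1)) {
      src <- shift_index(d, sgn * dirs[k, ])
      ok <- !is.na(src)
      ok[ok] <- mask[src[ok]]
      sel <- ok & mask
      close_enough <- sel
      close_enough[sel] <- abs(disc[src[sel]] - disc[sel]) <= alpha
      dep[close_enough] <- dep[close_enough] + 1L
    }
  }
  idx <- which(mask)
  lev <- disc[idx]
  k <- dep[idx] + 1L
  max_k <- max(k)
  D <- matrix(tabulate((lev - 1L) * max_k + k, n_levels * max_k),
              n_levels, max_k, byrow = TRUE)
  Nz <- sum(D)
  p <- D / Nz
  i <- row(D); j <- col(D)
  di <- rowSums(D); dj <- colSums(D)
  mui <- sum(i * p); muj <- sum(j * p)
  pe <- p[p > TEX_EPS]
  c(
    DependenceEntropy = -sum(pe * log2(pe)),
    DependenceNonUniformity = sum(dj^2) / Nz,
    DependenceNonUniformityNormalized = sum(dj^2) / Nz^2,
    DependenceVariance = sum((j - muj)^2 * p),
    GrayLevelNonUniformity = sum(di^2) / Nz,
    GrayLevelVariance = sum((i - mui)^2 * p),
    HighGrayLevelEmphasis = sum(i^2 * p),
    LargeDependenceEmphasis = sum(j^2 * p),
    LargeDependenceHighGrayLevelEmphasis = sum(i^2 * j^2 * p),
    LargeDependenceLowGrayLevelEmphasis = sum(j^2 * p / i^2),
    LowGrayLevelEmphasis = sum(p / i^2),
    SmallDependenceEmphasis = sum(p / j^2),
    SmallDependenceHighGrayLevelEmphasis = sum(i^2 * p / j^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2))
  )
}

#' All texture-matrix features of a discretized region
#'
#' @inheritParams glcm_matrices
#' @param distance GLCM/GLRLM offset distance in voxels.
#' @return named numeric vector of 75 values, names prefixed by class
#'   (`glcm_`, `glrlm_`, `glszm_`, `ngtdm_`, `gldm_`).
#' @export
texture_matrix_features <- function(disc, mask, n_levels, distance = 1) {
  out <- c(
    setNames(glcm_features(disc, mask, n_levels, distance),
             paste0("glcm_", GLCM_FEATURES)),
    setNames(glrlm_features(disc, mask, n_levels, distance),
             paste0("glrlm_", GLRLM_FEATURES)),
    setNames(glszm_features(disc, mask, n_levels),
             paste0("glszm_", GLSZM_FEATURES)),
    setNames(ngtdm_features(disc, mask, n_levels),
             paste0("ngtdm_", NGTDM_FEATURES)),
    setNames(gldm_features(disc, mask, n_levels),
             paste0("gldm_", GLDM_FEATURES))
  )
  out
}
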