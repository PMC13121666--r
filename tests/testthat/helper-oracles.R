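# Independent brute-force oracles: naive loop implementations of the
# radiomic matrices and reference statistics, used to cross-check the
# vectorized implementations. Deliberately written with explicit loops and
# none of the package's internal machinery.

oracle_dirs13 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    nz <- v[v != 0][1]
    if (nz > 0) out[[length(out) + 1]] <- v
  }
  out
}

oracle_in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# naive GLCM for one direction: loop over every voxel pair
oracle_glcm_matrix <- function(disc, mask, n_levels, dir) {
  d <- dim(disc)
  C <- matrix(0, n_levels, n_levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    q <- c(x, y, z) + dir
    if (!oracle_in_bounds(q, d)) next
    if (!mask[q[1], q[2], q[3]]) next
    a <- disc[x, y, z]; b <- disc[q[1], q[2], q[3]]
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1   # symmetric
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

# naive run-length matrix for one direction: walk each run explicitly
oracle_glrlm_matrix <- function(disc, mask, n_levels, dir, max_len) {
  d <- dim(disc)
  R <- matrix(0, n_levels, max_len)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    lvl <- disc[x, y, z]
    p <- c(x, y, z) - dir
    if (oracle_in_bounds(p, d) && mask[p[1], p[2], p[3]] &&
        disc[p[1], p[2], p[3]] == lvl) next  # not a run start
    len <- 1
    q <- c(x, y, z) + dir
    while (oracle_in_bounds(q, d) && mask[q[1], q[2], q[3]] &&
           disc[q[1], q[2], q[3]] == lvl) {
      len <- len + 1
      q <- q + dir
    }
    R[lvl, len] <- R[lvl, len] + 1
  }
  R
}

# naive zone list: BFS flood fill per gray level, 26-connectivity
oracle_zones <- function(disc, mask, n_levels) {
  d <- dim(disc)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z] || seen[x, y, z]) next
    lvl <- disc[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (!oracle_in_bounds(q, d)) next
        if (seen[q[1], q[2], q[3]] || !mask[q[1], q[2], q[3]]) next
        if (disc[q[1], q[2], q[3]] != lvl) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(level = lvl, size = size)
  }
  do.call(rbind, zones)
}

# naive per-voxel neighborhood means (NGTDM) and dependence counts (GLDM)
oracle_neighbors <- function(disc, mask, alpha = 0) {
  d <- dim(disc)
  res <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    nb <- c(); dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!oracle_in_bounds(q, d)) next
      if (!mask[q[1], q[2], q[3]]) next
      nb <- c(nb, disc[q[1], q[2], q[3]])
      if (abs(disc[q[1], q[2], q[3]] - disc[x, y, z]) <= alpha) dep <- dep + 1
    }
    res[[length(res) + 1]] <- list(level = disc[x, y, z],
                                   nmean = if (length(nb)) mean(nb) else NA,
                                   dependence = dep + 1)
  }
  res
}

# AUROC by explicit pairwise comparison
oracle_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# unpenalized logistic regression by hand-rolled IRLS (Newton-Raphson)
oracle_logistic <- function(X, y01, iter = 100, tol = 1e-12) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  for (i in seq_len(iter)) {
    eta <- as.numeric(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    gr <- crossprod(X1, y01 - mu)
    H <- crossprod(X1 * w, X1)
    step <- solve(H, gr)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

# label-stratified bootstrap of an AUROC difference; two-sided normal p
oracle_bootstrap_delong_p <- function(sa, sb, y01, B = 10000, seed = 1) {
  set.seed(seed)
  pos <- which(y01 == 1); neg <- which(y01 == 0)
  d_obs <- oracle_rank_auc(sa, y01) - oracle_rank_auc(sb, y01)
  ds <- numeric(B)
  for (b in seq_len(B)) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    yy <- y01[idx]
    ds[b] <- oracle_rank_auc(sa[idx], yy) - oracle_rank_auc(sb[idx], yy)
  }
  se <- sd(ds)
  if (se == 0) return(1)
  2 * pnorm(-abs(d_obs / se))
}

oracle_rank_auc <- function(s, y01) {
  r <- rank(s)
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# random small discretized test region
random_region <- function(seed, side = 5, n_levels = 4, p_mask = 0.6) {
  set.seed(seed)
  d <- c(side, side, side)
  mask <- array(runif(prod(d)) < p_mask, d)
  if (sum(mask) < 3) mask[sample(prod(d), 3)] <- TRUE
  disc <- array(0L, d)
  disc[mask] <- sample.int(n_levels, sum(mask), replace = TRUE)
  list(disc = disc, mask = mask, n_levels = n_levels)
}

# ---- independent feature formulas (plain scalar loops over the matrices) ----

oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:Ng) { sx <- sx + (i - mux)^2 * px[i]; sy <- sy + (i - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  f <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
         ClusterTendency = 0, Contrast = 0, Correlation = 0,
         DifferenceAverage = 0, DifferenceEntropy = 0, DifferenceVariance = 0,
         Id = 0, Idm = 0, Idmn = 0, Idn = 0, Imc1 = 0, Imc2 = 0,
         InverseVariance = 0, JointAverage = mux, JointEnergy = 0,
         JointEntropy = 0, MCC = 0, MaximumProbability = max(P),
         SumAverage = 0, SumEntropy = 0, SumSquares = 0)
  pd <- rep(0, Ng); ps <- rep(0, 2 * Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * p
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - mux - muy)^4 * p
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - mux - muy)^3 * p
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - mux - muy)^2 * p
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * p
    f["Id"] <- f["Id"] + p / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + p / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + p / (1 + (i - j)^2 / Ng^2)
    f["Idn"] <- f["Idn"] + p / (1 + abs(i - j) / Ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + p / (i - j)^2
    f["JointEnergy"] <- f["JointEnergy"] + p^2
    if (p > 1e-12) f["JointEntropy"] <- f["JointEntropy"] - p * log2(p)
    f["SumSquares"] <- f["SumSquares"] + (i - mux)^2 * p
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    ps[i + j] <- ps[i + j] + p
  }
  if (sx > 1e-12 && sy > 1e-12)
    f["Correlation"] <- (f[["Autocorrelation"]] - mux * muy) / (sx * sy)
  else f["Correlation"] <- 1
  da <- 0
  for (k in 0:(Ng - 1)) da <- da + k * pd[k + 1]
  f["DifferenceAverage"] <- da
  for (k in 0:(Ng - 1)) {
    f["DifferenceVariance"] <- f[["DifferenceVariance"]] + (k - da)^2 * pd[k + 1]
    if (pd[k + 1] > 1e-12)
      f["DifferenceEntropy"] <- f[["DifferenceEntropy"]] - pd[k + 1] * log2(pd[k + 1])
  }
  for (k in 2:(2 * Ng)) {
    f["SumAverage"] <- f[["SumAverage"]] + k * ps[k]
    if (ps[k] > 1e-12) f["SumEntropy"] <- f[["SumEntropy"]] - ps[k] * log2(ps[k])
  }
  HX <- 0; HY <- 0
  for (i in 1:Ng) {
    if (px[i] > 1e-12) HX <- HX - px[i] * log2(px[i])
    if (py[i] > 1e-12) HY <- HY - py[i] * log2(py[i])
  }
  HXY <- f[["JointEntropy"]]
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    q <- max(px[i] * py[j], 1e-12)
    HXY1 <- HXY1 - P[i, j] * log2(q)
    HXY2 <- HXY2 - px[i] * py[j] * log2(q)
  }
  f["Imc1"] <- if (max(HX, HY) > 1e-12) (HXY - HXY1) / max(HX, HY) else 0
  f["Imc2"] <- sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0))
  nz <- which(px > 1e-12)
  if (length(nz) < 2) f["MCC"] <- 1 else {
    Q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      s <- 0
      for (k in seq_along(nz))
        s <- s + P[nz[a], nz[k]] * P[nz[b], nz[k]] / (px[nz[a]] * py[nz[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    f["MCC"] <- sqrt(max(ev[2], 0))
  }
  f
}

oracle_glrlm_features <- function(R, n_voxels) {
  Ng <- nrow(R); Nl <- ncol(R)
  Nr <- sum(R)
  f <- setNames(numeric(16),
    c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"))
  mui <- 0; muj <- 0
  for (i in 1:Ng) for (j in 1:Nl) {
    mui <- mui + i * R[i, j] / Nr; muj <- muj + j * R[i, j] / Nr
  }
  for (i in 1:Ng) f["GrayLevelNonUniformity"] <- f[["GrayLevelNonUniformity"]] + sum(R[i, ])^2
  f["GrayLevelNonUniformityNormalized"] <- f[["GrayLevelNonUniformity"]] / Nr^2
  f["GrayLevelNonUniformity"] <- f[["GrayLevelNonUniformity"]] / Nr
  for (j in 1:Nl) f["RunLengthNonUniformity"] <- f[["RunLengthNonUniformity"]] + sum(R[, j])^2
  f["RunLengthNonUniformityNormalized"] <- f[["RunLengthNonUniformity"]] / Nr^2
  f["RunLengthNonUniformity"] <- f[["RunLengthNonUniformity"]] / Nr
  f["RunPercentage"] <- Nr / n_voxels
  for (i in 1:Ng) for (j in 1:Nl) {
    p <- R[i, j] / Nr
    if (p == 0) next
    f["GrayLevelVariance"] <- f[["GrayLevelVariance"]] + (i - mui)^2 * p
    f["RunVariance"] <- f[["RunVariance"]] + (j - muj)^2 * p
    f["HighGrayLevelRunEmphasis"] <- f[["HighGrayLevelRunEmphasis"]] + i^2 * p
    f["LowGrayLevelRunEmphasis"] <- f[["LowGrayLevelRunEmphasis"]] + p / i^2
    f["LongRunEmphasis"] <- f[["LongRunEmphasis"]] + j^2 * p
    f["ShortRunEmphasis"] <- f[["ShortRunEmphasis"]] + p / j^2
    f["LongRunHighGrayLevelEmphasis"] <- f[["LongRunHighGrayLevelEmphasis"]] + i^2 * j^2 * p
    f["LongRunLowGrayLevelEmphasis"] <- f[["LongRunLowGrayLevelEmphasis"]] + j^2 * p / i^2
    f["ShortRunHighGrayLevelEmphasis"] <- f[["ShortRunHighGrayLevelEmphasis"]] + i^2 * p / j^2
    f["ShortRunLowGrayLevelEmphasis"] <- f[["ShortRunLowGrayLevelEmphasis"]] + p / (i^2 * j^2)
    f["RunEntropy"] <- f[["RunEntropy"]] - p * log2(p)
  }
  f
}

oracle_glszm_features <- function(zones, n_voxels) {
  zl <- zones[, "level"]; zs <- zones[, "size"]
  Nz <- nrow(zones)
  f <- setNames(numeric(16),
    c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"))
  for (l in unique(zl)) f["GrayLevelNonUniformity"] <- f[["GrayLevelNonUniformity"]] + sum(zl == l)^2
  f["GrayLevelNonUniformityNormalized"] <- f[["GrayLevelNonUniformity"]] / Nz^2
  f["GrayLevelNonUniformity"] <- f[["GrayLevelNonUniformity"]] / Nz
  for (s in unique(zs)) f["SizeZoneNonUniformity"] <- f[["SizeZoneNonUniformity"]] + sum(zs == s)^2
  f["SizeZoneNonUniformityNormalized"] <- f[["SizeZoneNonUniformity"]] / Nz^2
  f["SizeZoneNonUniformity"] <- f[["SizeZoneNonUniformity"]] / Nz
  mui <- mean(zl); mus <- mean(zs)
  for (k in 1:Nz) {
    p <- 1 / Nz
    f["GrayLevelVariance"] <- f[["GrayLevelVariance"]] + (zl[k] - mui)^2 * p
    f["ZoneVariance"] <- f[["ZoneVariance"]] + (zs[k] - mus)^2 * p
    f["HighGrayLevelZoneEmphasis"] <- f[["HighGrayLevelZoneEmphasis"]] + zl[k]^2 * p
    f["LowGrayLevelZoneEmphasis"] <- f[["LowGrayLevelZoneEmphasis"]] + p / zl[k]^2
    f["LargeAreaEmphasis"] <- f[["LargeAreaEmphasis"]] + zs[k]^2 * p
    f["SmallAreaEmphasis"] <- f[["SmallAreaEmphasis"]] + p / zs[k]^2
    f["LargeAreaHighGrayLevelEmphasis"] <- f[["LargeAreaHighGrayLevelEmphasis"]] + zl[k]^2 * zs[k]^2 * p
    f["LargeAreaLowGrayLevelEmphasis"] <- f[["LargeAreaLowGrayLevelEmphasis"]] + zs[k]^2 * p / zl[k]^2
    f["SmallAreaHighGrayLevelEmphasis"] <- f[["SmallAreaHighGrayLevelEmphasis"]] + zl[k]^2 * p / zs[k]^2
    f["SmallAreaLowGrayLevelEmphasis"] <- f[["SmallAreaLowGrayLevelEmphasis"]] + p / (zl[k]^2 * zs[k]^2)
  }
  ent <- 0
  for (l in unique(zl)) for (s in unique(zs)) {
    cnt <- sum(zl == l & zs == s)
    if (cnt > 0) ent <- ent - (cnt / Nz) * log2(cnt / Nz)
  }
  f["ZoneEntropy"] <- ent
  f["ZonePercentage"] <- Nz / n_voxels
  f
}

oracle_ngtdm_features <- function(nbstats, n_levels) {
  keep <- !vapply(nbstats, function(r) is.na(r$nmean), logical(1))
  nb <- nbstats[keep]
  N <- length(nb)
  lev <- vapply(nb, `[[`, numeric(1), "level")
  dev <- vapply(nb, function(r) abs(r$level - r$nmean), numeric(1))
  n_i <- s_i <- numeric(n_levels)
  for (k in seq_len(N)) {
    n_i[lev[k]] <- n_i[lev[k]] + 1
    s_i[lev[k]] <- s_i[lev[k]] + dev[k]
  }
  p_i <- n_i / N
  act <- which(p_i > 0); Ngp <- length(act)
  coars_den <- sum(p_i * s_i)
  contrast <- 0
  if (Ngp > 1) {
    acc <- 0
    for (i in act) for (j in act) acc <- acc + p_i[i] * p_i[j] * (i - j)^2
    contrast <- acc / (Ngp * (Ngp - 1)) * sum(s_i) / N
  }
  busy_den <- 0; strength_num <- 0; complexity <- 0
  for (i in act) for (j in act) {
    busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
    strength_num <- strength_num + (p_i[i] + p_i[j]) * (i - j)^2
    complexity <- complexity + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
      (p_i[i] + p_i[j])
  }
  c(Busyness = if (busy_den > 1e-12) sum(p_i * s_i) / busy_den else 0,
    Coarseness = if (coars_den > 1e-12) 1 / coars_den else 1e6,
    Complexity = complexity / N,
    Contrast = contrast,
    Strength = if (sum(s_i) > 1e-12) strength_num / sum(s_i) else 0)
}

oracle_gldm_features <- function(nbstats, n_levels) {
  lev <- vapply(nbstats, `[[`, numeric(1), "level")
  dep <- vapply(nbstats, `[[`, numeric(1), "dependence")
  Nz <- length(lev)
  f <- setNames(numeric(14),
    c("DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"))
  for (l in unique(lev)) f["GrayLevelNonUniformity"] <- f[["GrayLevelNonUniformity"]] + sum(lev == l)^2
  f["GrayLevelNonUniformity"] <- f[["GrayLevelNonUniformity"]] / Nz
  for (k in unique(dep)) f["DependenceNonUniformity"] <- f[["DependenceNonUniformity"]] + sum(dep == k)^2
  f["DependenceNonUniformityNormalized"] <- f[["DependenceNonUniformity"]] / Nz^2
  f["DependenceNonUniformity"] <- f[["DependenceNonUniformity"]] / Nz
  mui <- mean(lev); muj <- mean(dep)
  for (k in seq_len(Nz)) {
    p <- 1 / Nz
    f["GrayLevelVariance"] <- f[["GrayLevelVariance"]] + (lev[k] - mui)^2 * p
    f["DependenceVariance"] <- f[["DependenceVariance"]] + (dep[k] - muj)^2 * p
    f["HighGrayLevelEmphasis"] <- f[["HighGrayLevelEmphasis"]] + lev[k]^2 * p
    f["LowGrayLevelEmphasis"] <- f[["LowGrayLevelEmphasis"]] + p / lev[k]^2
    f["LargeDependenceEmphasis"] <- f[["LargeDependenceEmphasis"]] + dep[k]^2 * p
    f["SmallDependenceEmphasis"] <- f[["SmallDependenceEmphasis"]] + p / dep[k]^2
    f["LargeDependenceHighGrayLevelEmphasis"] <- f[["LargeDependenceHighGrayLevelEmphasis"]] + lev[k]^2 * dep[k]^2 * p
    f["LargeDependenceLowGrayLevelEmphasis"] <- f[["LargeDependenceLowGrayLevelEmphasis"]] + dep[k]^2 * p / lev[k]^2
    f["SmallDependenceHighGrayLevelEmphasis"] <- f[["SmallDependenceHighGrayLevelEmphasis"]] + lev[k]^2 * p / dep[k]^2
    f["SmallDependenceLowGrayLevelEmphasis"] <- f[["SmallDependenceLowGrayLevelEmphasis"]] + p / (lev[k]^2 * dep[k]^2)
  }
  # entropy over the (level, dependence) joint distribution
  tab <- table(paste(lev, dep))
  p <- as.numeric(tab) / Nz
  f["DependenceEntropy"] <- -sum(p * log2(p))
  f
}

# full brute-force battery for one region, mirroring the averaging scheme
oracle_texture_battery <- function(disc, mask, n_levels) {
  dirs <- oracle_dirs13()
  gl <- list(); rl <- list()
  max_len <- max(dim(disc))
  for (d in dirs) {
    P <- oracle_glcm_matrix(disc, mask, n_levels, d)
    if (!is.null(P)) gl[[length(gl) + 1]] <- oracle_glcm_features(P)
    rl[[length(rl) + 1]] <- oracle_glrlm_features(
      oracle_glrlm_matrix(disc, mask, n_levels, d, max_len), sum(mask))
  }
  zones <- oracle_zones(disc, mask, n_levels)
  nb <- oracle_neighbors(disc, mask)
  c(setNames(rowMeans(do.call(cbind, gl)), paste0("glcm_", names(gl[[1]]))),
    setNames(rowMeans(do.call(cbind, rl)), paste0("glrlm_", names(rl[[1]]))),
    setNames(oracle_glszm_features(zones, sum(mask)), paste0("glszm_", names(oracle_glszm_features(zones, sum(mask))))),
    setNames(oracle_ngtdm_features(nb, n_levels), paste0("ngtdm_", names(oracle_ngtdm_features(nb, n_levels)))),
    setNames(oracle_gldm_features(nb, n_levels), paste0("gldm_", names(oracle_gldm_features(nb, n_levels)))))
}
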