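# Cohort-level habitat clustering: pooled voxel feature matrix, k-means with
# k-means++ restarts, Calinski-Harabasz model selection over K = 2..10,
# per-patient label assignment, anatomical ordering of the clusters, and
# KNN-based cleanup of fragmented labels.

#' Build the pooled voxel feature matrix
#'
#' Concatenates the (ICVF, ISOVF, ODI) values of every ROI voxel of every
#' case into one matrix (rows = voxels, columns = the three maps), the
#' cohort-level input to k-means. Columns are z-scored over the retained
#' rows when `standardize = TRUE` and the scaler (per-column mean/SD) is
#' stored for later assignment of new cases.
#'
#' @param cases list of `patient_case`.
#' @param standardize z-score the three channels (default TRUE).
#' @param max_voxels_per_case optional per-case subsampling cap; the
#'   subsample is seeded per case (derived from `seed` and the patient id)
#'   so adding or removing cases does not change other cases' rows.
#' @param seed integer seed for subsampling.
#' @return object of class `voxel_matrix`: `X` (numeric matrix), `meta`
#'   (data.frame patient_id, voxel_index), `scaler` (list center/scale or
#'   NULL), `standardized`.
#' @export
build_voxel_matrix <- function(cases, standardize = TRUE,
                               max_voxels_per_case = NULL, seed = 1L) {
  empty <- names(cases)[vapply(cases, function(cs) sum(cs$roi) == 0, logical(1))]
  if (length(empty))
    stopf("cases with empty ROI: %s", paste(empty, collapse = ", "))
  blocks <- list(); metas <- list()
  for (cs in cases) {
    idx <- which(cs$roi)
    vals <- cbind(ICVF = cs$maps$ICVF[idx], ISOVF = cs$maps$ISOVF[idx],
                  ODI = cs$maps$ODI[idx])
    if (any(!is.finite(vals))) {
      bad <- colnames(vals)[colSums(!is.finite(vals)) > 0]
      stopf("non-finite voxel values in patient %s, map(s) %s",
            cs$patient_id, paste(bad, collapse = ", "))
    }
    if (!is.null(max_voxels_per_case) && length(idx) > max_voxels_per_case) {
      set.seed((as.integer(seed) + hash32(cs$patient_id)) %% 2147483647L)
      keep <- sort(sample(length(idx), max_voxels_per_case))
      idx <- idx[keep]; vals <- vals[keep, , drop = FALSE]
    }
    blocks[[length(blocks) + 1L]] <- vals
    metas[[length(metas) + 1L]] <- data.frame(
      patient_id = cs$patient_id, voxel_index = idx, stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, blocks)
  scaler <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    if (any(scl <= 0)) stopf("constant channel(s): %s — cannot standardize",
                             paste(colnames(X)[scl <= 0], collapse = ", "))
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    scaler <- list(center = ctr, scale = scl)
  }
  structure(list(X = X, meta = do.call(rbind, metas), scaler = scaler,
                 standardized = standardize), class = "voxel_matrix")
}

# k-means++ initial centers (Arthur & Vassilvitskii), seeded by the caller.
#' @noRd
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (k in 2:K) {
    if (all(d2 <= 0)) {
      # fewer distinct points than K
      return(NULL)
    }
    pick <- sample.int(n, 1, prob = d2 / sum(d2))
    centers[k, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
  }
  centers
}

#' Fit k-means with k-means++ restarts
#'
#' Runs Lloyd's algorithm (via [stats::kmeans()]) from `n_init` independent
#' k-means++ initializations and keeps the lowest-inertia solution.
#' Deterministic given `seed`.
#'
#' @param X numeric matrix (or a `voxel_matrix`).
#' @param K number of clusters (>= 2).
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap.
#' @return list with `centroids`, `labels`, `inertia` (total within-cluster
#'   sum of squares), `K`, `seed`.
#' @export
fit_kmeans <- function(X, K, seed = 1L, n_init = 10, max_iter = 300) {
  if (inherits(X, "voxel_matrix")) X <- X$X
  if (K < 2) stopf("K must be >= 2")
  n_distinct <- nrow(unique(X))
  if (n_distinct < K)
    stopf("degenerate input: only %d distinct points for K = %d", n_distinct, K)
  set.seed(as.integer(seed))
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- kmeanspp_init(X, K)
    if (is.null(init)) stopf("degenerate input: could not seed %d distinct centers", K)
    km <- suppressWarnings(
      stats::kmeans(X, centers = init, iter.max = max_iter, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(centroids = unname(best$centers), labels = as.integer(best$cluster),
       inertia = best$tot.withinss, K = as.integer(K), seed = as.integer(seed))
}

#' Calinski-Harabasz score
#'
#' The variance-ratio criterion `[B/(K-1)] / [W/(N-K)]`, with B the
#' between-cluster and W the within-cluster sum of squared distances to the
#' respective centroids. A single cluster or W = 0 yields `Inf` with
#' attribute `degenerate = TRUE` rather than an error.
#'
#' @param X numeric matrix (or `voxel_matrix`).
#' @param labels integer cluster labels, one per row.
#' @return numeric score (possibly `Inf`, flagged via attribute).
#' @export
calinski_harabasz <- function(X, labels) {
  if (inherits(X, "voxel_matrix")) X <- X$X
  X <- as.matrix(X)
  N <- nrow(X)
  cl <- unique(labels)
  K <- length(cl)
  gm <- colMeans(X)
  W <- 0; B <- 0
  for (g in cl) {
    Xi <- X[labels == g, , drop = FALSE]
    ci <- colMeans(Xi)
    W <- W + sum(sweep(Xi, 2, ci)^2)
    B <- B + nrow(Xi) * sum((ci - gm)^2)
  }
  if (K < 2 || W <= 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (B / (K - 1)) / (W / (N - K))
}

#' Select the number of habitats by the Calinski-Harabasz criterion
#'
#' Fits k-means for every K in `k_range`, records the CH score of each fit,
#' and selects the argmax (ties broken toward smaller K). Returns the fitted
#' habitat model: chosen K, centroids in standardized space, the full CH
#' table, the stored channel scaler, and the anatomical cluster ordering
#' from [order_clusters()].
#'
#' @param vm a `voxel_matrix` (standardized).
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed integer seed.
#' @param n_init k-means restarts per K.
#' @param fit_scope bookkeeping tag: `"cohort"` (all cases pooled; the
#'   default, matching cohort-level clustering) or `"train_only"` (the
#'   leakage-safe variant where only training cases were pooled upstream).
#' @return object of class `habitat_model`.
#' @export
select_k <- function(vm, k_range = 2:10, seed = 1L, n_init = 10,
                     fit_scope = c("cohort", "train_only")) {
  fit_scope <- match.arg(fit_scope)
  if (!inherits(vm, "voxel_matrix")) stopf("vm must be a voxel_matrix")
  fits <- list(); ch <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    fit <- fit_kmeans(vm$X, K, seed = seed, n_init = n_init)
    fits[[i]] <- fit
    ch[i] <- calinski_harabasz(vm$X, fit$labels)
  }
  best <- which(ch == max(ch))[1]  # ties toward smaller K (k_range ascending)
  K <- k_range[best]
  centroids <- fits[[best]]$centroids
  ordering <- order_clusters(centroids, vm$scaler)
  structure(list(
    K = as.integer(K), centroids = centroids, ch_scores = ch,
    ordering = ordering, scaler = vm$scaler, standardized = vm$standardized,
    fit_scope = fit_scope, seed = as.integer(seed), k_range = k_range
  ), class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> K = %d (CH-selected over %s), fit_scope = %s\n",
              x$K, paste(range(x$k_range), collapse = ".."), x$fit_scope))
  invisible(x)
}

#' Order clusters into anatomical habitat indices
#'
#' For K = 3 (the expected configuration): H1 is the centroid with the
#' highest de-standardized ISOVF (free-water-rich core), H2 the higher-ICVF
#' centroid of the remaining two (cellular enhancing margin), H3 the last
#' (peritumoral rim). For other K, clusters are ordered by descending ISOVF.
#' Centroid ties within tolerance fall back to raw index order with a
#' warning.
#'
#' @param centroids K x 3 matrix in standardized space (columns ICVF,
#'   ISOVF, ODI).
#' @param scaler list(center, scale) used to de-standardize; NULL means the
#'   centroids are already on the raw scale.
#' @param tol tie tolerance on the de-standardized values.
#' @return integer permutation `ordering`: `ordering[raw_cluster]` is the
#'   habitat index (1..K).
#' @export
order_clusters <- function(centroids, scaler = NULL, tol = 1e-9) {
  raw <- centroids
  if (!is.null(scaler))
    raw <- sweep(sweep(centroids, 2, scaler$scale, "*"), 2, scaler$center, "+")
  colnames(raw) <- c("ICVF", "ISOVF", "ODI")
  K <- nrow(raw)
  tied <- function(v) any(abs(diff(sort(v))) <= tol)
  if (K == 3) {
    if (tied(raw[, "ISOVF"])) {
      warnf("centroid ISOVF tie; falling back to raw index order")
      return(seq_len(K))
    }
    h1 <- which.max(raw[, "ISOVF"])
    rest <- setdiff(1:3, h1)
    if (abs(diff(raw[rest, "ICVF"])) <= tol) {
      warnf("centroid ICVF tie among non-core clusters; falling back to raw index order")
      return(seq_len(K))
    }
    h2 <- rest[which.max(raw[rest, "ICVF"])]
    h3 <- setdiff(rest, h2)
    ordering <- integer(3)
    ordering[c(h1, h2, h3)] <- 1:3
    return(ordering)
  }
  if (tied(raw[, "ISOVF"])) {
    warnf("centroid ISOVF tie; falling back to raw index order")
    return(seq_len(K))
  }
  ordering <- integer(K)
  ordering[order(raw[, "ISOVF"], decreasing = TRUE)] <- seq_len(K)
  ordering
}

#' Assign habitat labels to a case
#'
#' Standardizes the case's ROI voxels with the model's stored scaler and
#' assigns each to its nearest centroid; labels are reported as habitat
#' indices (after ordering). Equidistant voxels take the lowest habitat
#' index. Out-of-ROI voxels are 0.
#'
#' @param case a `patient_case`.
#' @param model a `habitat_model`.
#' @return integer array (a habitat label map).
#' @export
assign_labels <- function(case, model) {
  if (isTRUE(model$standardized) && is.null(model$scaler))
    stopf("habitat model has no stored scaler; cannot standardize new cases")
  idx <- which(case$roi)
  V <- cbind(case$maps$ICVF[idx], case$maps$ISOVF[idx], case$maps$ODI[idx])
  if (!is.null(model$scaler))
    V <- sweep(sweep(V, 2, model$scaler$center), 2, model$scaler$scale, "/")
  # centroids reordered so row h is habitat h; first minimum = lowest index
  cen <- model$centroids[order(model$ordering), , drop = FALSE]
  d2 <- matrix(0, length(idx), nrow(cen))
  for (h in seq_len(nrow(cen)))
    d2[, h] <- rowSums(sweep(V, 2, cen[h, ])^2)
  lab <- max.col(-d2, ties.method = "first")
  out <- array(0L, dim(case$roi))
  out[idx] <- as.integer(lab)
  out
}

#' Clean fragmented habitat labels by KNN propagation
#'
#' Voxels in 26-connected same-label components smaller than
#' `min_component` are relabeled by majority vote of their `k` nearest
#' (world-distance) voxels belonging to components of at least
#' `min_component` voxels; vote ties take the label of the single nearest
#' such voxel. A single pass; reassignments are all computed against the
#' original large-component set.
#'
#' @param labelmap integer array from [assign_labels()].
#' @param spacing mm per axis for world distances.
#' @param k neighbor count (default 5).
#' @param min_component minimum surviving component size in voxels
#'   (default 8).
#' @return the cleaned label map.
#' @export
propagate_labels_knn <- function(labelmap, spacing = c(1, 1, 1), k = 5,
                                 min_component = 8) {
  d <- dim(labelmap)
  roi_idx <- which(labelmap > 0)
  if (length(roi_idx) < min_component) {
    warnf("ROI smaller than min_component (%d voxels); label map returned unchanged",
          min_component)
    return(labelmap)
  }
  # components per habitat label
  comp <- array(0L, d)
  ncomp <- 0L
  for (h in sort(unique(labelmap[roi_idx]))) {
    ch <- connected_components26(labelmap == h)
    sel <- ch > 0
    comp[sel] <- ch[sel] + ncomp
    ncomp <- ncomp + max(ch)
  }
  sizes <- tabulate(comp[roi_idx], nbins = ncomp)
  small <- which(sizes[comp[roi_idx]] < min_component)
  if (!length(small)) return(labelmap)
  big_idx <- roi_idx[sizes[comp[roi_idx]] >= min_component]
  if (!length(big_idx)) {
    warnf("no component reaches min_component (%d voxels); label map returned unchanged",
          min_component)
    return(labelmap)
  }
  small_idx <- roi_idx[small]
  ai <- arrayInd(small_idx, d)
  bi <- arrayInd(big_idx, d)
  aw <- sweep(ai - 1, 2, spacing, "*")
  bw <- sweep(bi - 1, 2, spacing, "*")
  big_lab <- labelmap[big_idx]
  out <- labelmap
  kk <- min(k, nrow(bw))
  for (r in seq_len(nrow(aw))) {
    d2 <- colSums((t(bw) - aw[r, ])^2)
    nn <- order(d2)[seq_len(kk)]
    votes <- table(big_lab[nn])
    winners <- as.integer(names(votes)[votes == max(votes)])
    out[small_idx[r]] <- if (length(winners) == 1) winners else big_lab[nn[1]]
  }
  out
}

#' Adjusted Rand index between two label maps (over a mask)
#'
#' Chance-corrected agreement between two partitions, used to compare
#' recovered habitat maps with planted shells.
#'
#' @param a,b integer vectors or arrays of equal length.
#' @param mask optional logical selector.
#' @return numeric ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b, mask = NULL) {
  a <- as.vector(a); b <- as.vector(b)
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
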