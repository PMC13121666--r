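# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic polynomial string hash, used to derive per-case seeds and to
# stamp artifacts with a config hash. Returns a non-negative integer < 2^31-1.
#' @noRd
hash32 <- function(x) {
  if (!is.character(x)) x <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Separable 3-D Gaussian smoothing with zero padding at the borders.
# Kernel is truncated at 3*sigma and renormalized to sum 1.
#' @noRd
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    # move target axis first, smooth columns of a matrix, move back
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

# L2 norm of the truncated separable Gaussian kernel: the factor by which
# smoothing shrinks the SD of a unit white-noise field.
#' @noRd
gaussian_smooth3_sd_factor <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sqrt(sum(k^2))^3
}

# The 13 unique 3-D direction offsets (one of each +/- pair) used for
# GLCM/GLRLM aggregation and, with their negatives, the 26-neighborhood.
#' @noRd
directions13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one of each antipodal pair: first nonzero component positive
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0][1]
    nz > 0
  })
  unname(d[keep, , drop = FALSE])
}

# Linear indices of voxels shifted by offset within an array of dim d;
# returns NA where the shift falls outside the array. Cached per (d, offset)
# since texture extraction calls this repeatedly on identical grids.
.shift_cache <- new.env(parent = emptyenv())

#' @noRd
shift_index <- function(d, offset) {
  key <- paste(c(d, offset), collapse = ",")
  hit <- .shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- shift_index_impl(d, offset)
  if (length(ls(.shift_cache)) > 200) rm(list = ls(.shift_cache), envir = .shift_cache)
  assign(key, out, envir = .shift_cache)
  out
}

#' @noRd
shift_index_impl <- function(d, offset) {
  ii <- array(seq_len(prod(d)), d)
  src <- array(NA_integer_, d)
  lo <- pmax(1, 1 + offset)
  hi <- pmin(d, d + offset)
  if (any(lo > hi)) return(src)  # shift exceeds an axis extent
  x1 <- lo[1]:hi[1]; y1 <- lo[2]:hi[2]; z1 <- lo[3]:hi[3]
  src[x1 - offset[1], y1 - offset[2], z1 - offset[3]] <- ii[x1, y1, z1]
  src
}

# Connected components (26-connectivity) of the TRUE voxels of a logical
# array, via igraph. Returns an integer array: 0 outside, component id inside.
#' @noRd
connected_components26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(array(0L, d))
  lab <- array(0L, d)
  if (length(idx) == 1L) {
    lab[idx] <- 1L
    return(lab)
  }
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  dirs <- directions13()
  edges <- list()
  for (k in seq_len(nrow(dirs))) {
    src <- shift_index(d, dirs[k, ])
    nb <- src[idx]
    ok <- !is.na(nb) & mask[nb]
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(pos[idx][ok], pos[nb[ok]])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(), ncol = 2),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Population skewness/kurtosis with the documented degenerate conventions.
#' @noRd
pop_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' @noRd
pop_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2
}

# Crop an array set to the bounding box of a mask (with margin), so texture
# and shape computations scale with the region, not the grid.
#' @noRd
bbox_ranges <- function(mask, margin = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lapply(1:3, function(ax) {
    max(1L, min(idx[, ax]) - margin):min(d[ax], max(idx[, ax]) + margin)
  })
}

#' @noRd
crop_bbox <- function(a, rng) a[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
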