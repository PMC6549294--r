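# Low-level 2-D image operations used by the segmentation pipeline.
# Heavy loops live in src/ (Rcpp); everything here works on plain numeric
# matrices indexed [row, col].

#' Maximum-intensity projection of a z-stack
#'
#' @param stack 3-D numeric array `[H, W, Z]` (a single 2-D matrix is treated
#'   as a one-slice stack).
#' @return `H x W` matrix with the per-pixel maximum across z.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  nz <- dim(stack)[3]
  if (nz < 1L) stop("empty stack: n_z must be >= 1")
  slice <- function(z) matrix(stack[, , z], dim(stack)[1], dim(stack)[2])
  out <- slice(1L)
  if (nz > 1L) for (z in 2:nz) out <- pmax(out, slice(z))
  out
}

#' Index of the sharpest slice of a z-stack
#'
#' Sharpness is the standard deviation of the slice's intensities; ties go to
#' the lowest index.
#'
#' @param stack 3-D numeric array `[H, W, Z]` or a matrix (one slice).
#' @return integer slice index (1-based).
#' @export
select_sharpest_slice <- function(stack) {
  if (is.matrix(stack)) return(1L)
  stopifnot(is.array(stack), length(dim(stack)) == 3L, dim(stack)[3] >= 1L)
  sds <- apply(stack, 3, stats::sd)
  which.max(sds)
}

gaussian_kernel1d <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma^2 * g)
  if (order == 2L) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    return(k - mean(k))  # zero DC: constant images give exactly no response
  }
  stop("unsupported derivative order")
}

#' Gaussian smoothing of an image
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels.
#' @return smoothed matrix of the same size (reflect padding).
#' @export
gaussian_blur <- function(img, sigma) {
  k <- gaussian_kernel1d(sigma)
  cpp_convsep(img, k, k)
}

#' Difference-of-Gaussians band-pass filter
#'
#' Spot-enhancement used before puncta segmentation: the image smoothed at
#' the narrow scale minus the image smoothed at the wide scale.
#'
#' @param img numeric matrix.
#' @param sigma_narrow,sigma_wide kernel sd in pixels; narrow < wide.
#' @export
dog_filter <- function(img, sigma_narrow = 1, sigma_wide = 3) {
  if (sigma_narrow >= sigma_wide)
    stop("dog_sigma_narrow must be smaller than dog_sigma_wide")
  gaussian_blur(img, sigma_narrow) - gaussian_blur(img, sigma_wide)
}

#' Frangi vesselness for bright tubular structures
#'
#' Multi-scale ridge filter on the scale-normalized Hessian. At each scale the
#' Hessian eigenvalues \eqn{|\lambda_1| \le |\lambda_2|} give a blobness ratio
#' \eqn{R_B = \lambda_1/\lambda_2} and structure strength
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}; vesselness is
#' \eqn{\exp(-R_B^2/2\beta^2)\,(1 - \exp(-S^2/2c^2))} where \eqn{\lambda_2 < 0}
#' (bright ridges), maximized over scales.
#'
#' @param img numeric matrix.
#' @param scales vector of Gaussian scales (pixels).
#' @param beta blobness sensitivity (default 0.5).
#' @param c structure-strength sensitivity; default half the maximum S
#'   observed across scales.
#' @return matrix of vesselness values in \[0, 1\].
#' @export
frangi_vesselness <- function(img, scales = c(1, 2, 3), beta = 0.5, c = NULL) {
  if (length(scales) == 0L) stop("frangi_scales must be nonempty")
  best <- matrix(0, nrow(img), ncol(img))
  resp <- vector("list", length(scales))
  smax <- 0
  for (i in seq_along(scales)) {
    s <- scales[i]
    g0 <- gaussian_kernel1d(s, 0L)
    g2 <- gaussian_kernel1d(s, 2L)
    g1 <- gaussian_kernel1d(s, 1L)
    hxx <- s^2 * cpp_convsep(img, g2, g0)
    hyy <- s^2 * cpp_convsep(img, g0, g2)
    hxy <- s^2 * cpp_convsep(img, g1, g1)
    # eigenvalues of [[hxx, hxy], [hxy, hyy]]
    tr <- hxx + hyy
    dq <- sqrt(pmax(0, (hxx - hyy)^2 + 4 * hxy^2))
    l_a <- (tr + dq) / 2
    l_b <- (tr - dq) / 2
    swap <- abs(l_a) > abs(l_b)  # ensure |l1| <= |l2|
    l1 <- ifelse(swap, l_b, l_a)
    l2 <- ifelse(swap, l_a, l_b)
    S2 <- l1^2 + l2^2
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2))
    v[l2 >= 0] <- 0
    resp[[i]] <- list(v = v, S2 = S2)
    smax <- max(smax, sqrt(max(S2)))
  }
  if (is.null(c)) c <- max(smax / 2, .Machine$double.eps)
  # structure strengths at numerical-noise level carry no ridge evidence
  tol2 <- (1e-9 * max(1, max(abs(img))))^2
  for (i in seq_along(scales)) {
    vi <- resp[[i]]$v * (1 - exp(-resp[[i]]$S2 / (2 * c^2)))
    vi[resp[[i]]$S2 < tol2] <- 0
    best <- pmax(best, vi)
  }
  best
}

#' Connected-component labeling
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer label matrix (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  cpp_label(as_mask(mask), as.integer(connectivity))
}

#' Binary dilation with a disk
#' @param mask logical matrix.
#' @param radius disk radius in pixels; `0` returns the mask unchanged.
#' @export
dilate_mask <- function(mask, radius) {
  m <- as_mask(mask)
  if (radius <= 0) return(m)
  cpp_dilate(m, radius)
}

#' Euclidean-approximate distance transform (chamfer 1, sqrt(2))
#' @param mask logical matrix; distances measured inside the foreground.
#' @export
distance_transform <- function(mask) cpp_disttrans(as_mask(mask))

#' Morphological skeleton (Zhang-Suen thinning)
#' @param mask logical matrix.
#' @return logical matrix with a 1-px-wide skeleton.
#' @export
skeletonize <- function(mask) cpp_thin(as_mask(mask))

as_mask <- function(x) {
  if (is.logical(x)) {
    m <- x
  } else {
    m <- x > 0
  }
  m[is.na(m)] <- FALSE
  storage.mode(m) <- "logical"
  m
}

#' Skeleton path length
#'
#' Sums skeleton edges once each: unit weight for orthogonal neighbor steps,
#' `sqrt(2)` for diagonal steps; diagonal edges shortcut by an orthogonal
#' pixel pair are not double counted.
#'
#' @param skeleton logical matrix (1-px-wide skeleton).
#' @param pixel_size pixel size in micrometers (default 1, i.e. pixels).
#' @return length in micrometers (or pixels when `pixel_size = 1`).
#' @export
skeleton_length <- function(skeleton, pixel_size = 1) {
  s <- as_mask(skeleton)
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- s
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  east  <- pad[2:(nr + 1L), 3:(nc + 2L)]
  south <- pad[3:(nr + 2L), 2:(nc + 1L)]
  se    <- pad[3:(nr + 2L), 3:(nc + 2L)]
  sw    <- pad[3:(nr + 2L), 1:nc]
  west  <- pad[2:(nr + 1L), 1:nc]
  n_orth <- sum(ctr & east) + sum(ctr & south)
  # a diagonal edge is skipped when an adjacent orthogonal 2-path exists
  n_se <- sum(ctr & se & !(east | south))
  n_sw <- sum(ctr & sw & !(west | south))
  (n_orth + sqrt(2) * (n_se + n_sw)) * pixel_size
}

#' Count skeleton endpoints
#'
#' Endpoints are skeleton pixels with exactly one skeleton neighbor
#' (8-connectivity); used for tip-loss compensation of skeleton length.
#'
#' @param skeleton logical matrix (1-px-wide skeleton).
#' @export
count_endpoints <- function(skeleton) {
  s <- as_mask(skeleton)
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- s
  nbr <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nbr <- nbr + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  sum(s & nbr == 1L)
}

#' Count branch nodes of a skeleton
#'
#' A node is a skeleton pixel from which at least three distinct branches
#' leave. Branch multiplicity is the crossing number: the number of 0-to-1
#' transitions around the pixel's 8-neighborhood ring (a raw neighbor count
#' misreads staircase remnants of thinning as junctions). Adjacent junction
#' pixels are clustered and counted once.
#'
#' @param skeleton logical matrix (1-px-wide skeleton).
#' @return integer number of branch points.
#' @export
count_nodes <- function(skeleton) {
  s <- as_mask(skeleton)
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- s
  ctr <- function(dr, dc) pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  # neighbors in ring order p2..p9 (N, NE, E, SE, S, SW, W, NW)
  ring <- list(ctr(-1, 0), ctr(-1, 1), ctr(0, 1), ctr(1, 1),
               ctr(1, 0), ctr(1, -1), ctr(0, -1), ctr(-1, -1))
  cross <- matrix(0L, nr, nc)
  for (k in 1:8) {
    nxt <- ring[[if (k == 8) 1 else k + 1]]
    cross <- cross + (!ring[[k]] & nxt)
  }
  junction <- s & cross >= 3L
  if (!any(junction)) return(0L)
  max(cpp_label(junction, 8L))
}

#' Watershed splitting of touching objects
#'
#' Markers are local maxima of the distance transform; basins are flooded on
#' the negative distance inside the mask.
#'
#' @param mask logical matrix of the (possibly fused) objects.
#' @param min_distance minimum distance-transform value for a marker and the
#'   radius of the local-maximum neighborhood (pixels).
#' @return integer label matrix.
#' @export
watershed_split <- function(mask, min_distance = 4) {
  m <- as_mask(mask)
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  d <- cpp_disttrans(m)
  mx <- cpp_maxfilter(d, min_distance)
  markers_mask <- m & d >= mx - 1e-9 & d >= pmax(1, min_distance / 2)
  markers <- cpp_label(markers_mask, 8L)
  if (max(markers) == 0L) markers <- cpp_label(m, 8L)
  lab <- cpp_watershed(-d, markers, m)
  relabel_sequential(lab)
}

relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  out <- lab
  out[lab > 0L] <- match(lab[lab > 0L], ids)
  out
}
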