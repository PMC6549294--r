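# Synthetic fluorescence fields with full ground truth. The stated world:
# two nucleus populations (neuronal: small, chromocenter-textured; glial:
# large, flat), branched dendritic trees with Gaussian cross-section
# (sigma ~ 2 px), pre/post puncta as 2-D Gaussians (sigma 1-2 px) anchored on
# dendrites, true synapses as pre/post pairs with centers <= 1 px apart,
# non-synaptic puncta kept >= 5 px from any opposite-channel punctum, and
# Poisson shot noise plus Gaussian read noise. Geometry is down-scaled
# relative to a real 40x field so that a 256 px field holds a workable
# network.

CHANNEL_ROLES <- c(nuclear = 1L, dendrite = 2L, presynaptic = 3L,
                   postsynaptic = 4L)

#' Parameters of a synthetic field
#'
#' Defaults describe a mid-maturity culture on a 256 x 256 px lattice.
#' Intensities are arbitrary fluorescence units over a background of
#' `background`.
#'
#' @param width,height field size in pixels (>= 256 recommended, >= 64
#'   required).
#' @param n_z number of z-slices (>= 3); the middle slice is in focus.
#' @param pixel_size micrometers per pixel.
#' @param n_neuronal,n_glial nucleus counts for the two populations.
#' @param neuronal_radius,glial_radius nucleus radii in pixels (neuronal
#'   nuclei are the smaller, textured population).
#' @param dendrite_total_px target summed dendrite centerline length (px).
#' @param branch_prob probability of bifurcation at the end of each segment.
#' @param n_pre,n_post presynaptic / postsynaptic puncta counts.
#' @param n_true_synapses number of pre/post pairs rendered with overlapping
#'   footprints (must be <= min(n_pre, n_post)).
#' @param spot_sigma punctum Gaussian sd in pixels (1-2 px regime).
#' @param background,nuclear_amp,glial_amp,dendrite_amp,spot_amp intensity
#'   levels (a.u.).
#' @param poisson_noise apply Poisson shot noise?
#' @param read_noise_sd Gaussian read noise sd (a.u.); 0 plus
#'   `poisson_noise = FALSE` gives a noiseless render.
#' @return object of class `field_params`.
#' @export
field_params <- function(width = 256L, height = 256L, n_z = 3L,
                         pixel_size = 0.149,
                         n_neuronal = 12L, n_glial = 5L,
                         neuronal_radius = 6, glial_radius = 11,
                         dendrite_total_px = 2800, branch_prob = 0.35,
                         n_pre = 90L, n_post = 90L, n_true_synapses = 45L,
                         spot_sigma = 1.4,
                         background = 50, nuclear_amp = 800, glial_amp = 500,
                         dendrite_amp = 600, spot_amp = 900,
                         poisson_noise = TRUE, read_noise_sd = 15) {
  p <- as.list(environment())
  if (p$width < 64L || p$height < 64L)
    stop("field too small: width/height must be >= 64 px")
  if (p$n_z < 1L) stop("n_z must be >= 1")
  if (p$pixel_size <= 0) stop("pixel_size must be > 0")
  for (nm in c("n_neuronal", "n_glial", "n_pre", "n_post", "n_true_synapses"))
    if (p[[nm]] < 0) stop("parameter out of range: ", nm, " must be >= 0")
  if (p$n_true_synapses > min(p$n_pre, p$n_post))
    stop("parameter out of range: n_true_synapses must be <= min(n_pre, n_post)")
  if (p$glial_radius <= p$neuronal_radius)
    stop("parameter out of range: glial_radius must exceed neuronal_radius")
  structure(p, class = "field_params")
}

#' Turn off all noise sources of a `field_params`
#' @param params a [field_params()] object.
#' @export
noiseless <- function(params) {
  params$poisson_noise <- FALSE
  params$read_noise_sd <- 0
  params
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rejection-sample n points with pairwise min distances; existing points may
# also repel. Returns n x 2 matrix (x, y) or errors naming `what`.
place_points <- function(n, xr, yr, min_sep, existing = NULL, what = "points",
                         max_tries = 4000L) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("parameter out of renderable range: cannot place ", n, " ", what)
    cand <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
    all_pts <- rbind(pts, existing)
    if (is.null(all_pts) || nrow(all_pts) == 0L ||
        min(sqrt((all_pts[, 1] - cand[1])^2 + (all_pts[, 2] - cand[2])^2)) >=
          min_sep) {
      pts <- rbind(pts, cand)
      tries <- 0L
    }
  }
  unname(pts)
}

render_gaussians <- function(h, w, centers, sigma, amps) {
  img <- matrix(0, h, w)
  if (is.null(centers) || nrow(centers) == 0L) return(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    gx <- exp(-(xs - cx)^2 / (2 * sigma^2))
    gy <- exp(-(ys - cy)^2 / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + amps[i] * outer(gy, gx)
  }
  img
}

render_discs <- function(h, w, centers, radii, amps, edge = 1.2) {
  img <- matrix(0, h, w)
  if (is.null(centers) || nrow(centers) == 0L) return(img)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r0 <- radii[i]
    r <- ceiling(r0 + 4 * edge)
    xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    img[ys, xs] <- img[ys, xs] + amps[i] / (1 + exp((d - r0) / edge))
  }
  img
}

# Grow one random tree from a soma; returns list(points = n x 2 path points
# at ~1 px spacing, nodes = branch-point coordinates, length_px).
grow_tree <- function(origin, budget_px, branch_prob, w, h) {
  pts <- matrix(numeric(0), 0, 2)
  nodes <- matrix(numeric(0), 0, 2)
  used <- 0
  n_trunks <- sample(2:3, 1)
  queue <- lapply(stats::runif(n_trunks, 0, 2 * pi) +
                    seq(0, 2 * pi, length.out = n_trunks + 1)[seq_len(n_trunks)],
                  function(a) list(pos = origin, dir = a, depth = 0L))
  while (length(queue) > 0L && used < budget_px) {
    br <- queue[[1]]; queue <- queue[-1]
    seg_len <- round(stats::runif(1, 18, 40))
    pos <- br$pos; ang <- br$dir
    alive <- TRUE
    for (s in seq_len(seg_len)) {
      ang <- ang + stats::rnorm(1, 0, 0.03)
      pos <- pos + c(cos(ang), sin(ang))
      if (pos[1] < 2 || pos[1] > w - 1 || pos[2] < 2 || pos[2] > h - 1) {
        alive <- FALSE
        break
      }
      pts <- rbind(pts, pos)
      used <- used + 1
      if (used >= budget_px) { alive <- FALSE; break }
    }
    if (alive && br$depth < 5L && stats::runif(1) < branch_prob) {
      spread <- stats::runif(1, 0.7, 1.2)
      nodes <- rbind(nodes, pos)
      queue <- c(queue, list(list(pos = pos, dir = ang - spread,
                                  depth = br$depth + 1L),
                             list(pos = pos, dir = ang + spread,
                                  depth = br$depth + 1L)))
    } else if (alive && stats::runif(1) < 0.7) {
      queue <- c(queue, list(list(pos = pos, dir = ang, depth = br$depth)))
    }
  }
  list(points = pts, nodes = nodes, length_px = used)
}

#' Generate one synthetic 4-channel field with ground truth
#'
#' Renders nuclear, dendrite, presynaptic and postsynaptic channels over
#' `n_z` slices (middle slice in focus, neighbors defocused and dimmed) and
#' returns both the image and a `field_truth` record of everything placed.
#'
#' @param params a [field_params()] object.
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   output.
#' @return list with elements `image` (a `field_image`: 4-D array
#'   `[H, W, Z, C]`, channel roles, pixel size, metadata) and `truth`
#'   (a `field_truth`).
#' @export
generate_field <- function(params = field_params(), seed = 1L) {
  stopifnot(inherits(params, "field_params"))
  with_seed(seed, {
    h <- params$height; w <- params$width
    rn <- params$neuronal_radius; rg <- params$glial_radius

    # --- nuclei ---
    margin_g <- rg + 3
    glial <- if (params$n_glial > 0)
      place_points(params$n_glial, c(margin_g, w - margin_g),
                   c(margin_g, h - margin_g), 2 * rg + 6, what = "glial nuclei")
      else NULL
    margin_n <- rn + 3
    neuronal <- if (params$n_neuronal > 0)
      place_points(params$n_neuronal, c(margin_n, w - margin_n),
                   c(margin_n, h - margin_n), rn + rg + 6, existing = glial,
                   what = "neuronal nuclei")
      else NULL

    nuc_base <- render_discs(h, w, neuronal,
                             rep(rn, params$n_neuronal),
                             rep(params$nuclear_amp, params$n_neuronal)) +
                render_discs(h, w, glial, rep(rg, params$n_glial),
                             rep(params$glial_amp, params$n_glial))
    # chromocenters inside neuronal nuclei -> high spot-texture score
    if (params$n_neuronal > 0) {
      ccs <- do.call(rbind, lapply(seq_len(params$n_neuronal), function(i) {
        k <- sample(3:5, 1)
        ang <- stats::runif(k, 0, 2 * pi)
        rad <- stats::runif(k, 0, 0.55 * rn)
        cbind(neuronal[i, 1] + rad * cos(ang), neuronal[i, 2] + rad * sin(ang))
      }))
      nuc_base <- nuc_base +
        render_gaussians(h, w, ccs, 1.2,
                         rep(0.8 * params$nuclear_amp, nrow(ccs)))
    }

    # --- dendrites ---
    dend_pts <- matrix(numeric(0), 0, 2)
    n_nodes <- 0L
    total_len_px <- 0
    if (params$n_neuronal > 0 && params$dendrite_total_px > 0) {
      budget_each <- params$dendrite_total_px / params$n_neuronal
      for (i in seq_len(params$n_neuronal)) {
        tr <- grow_tree(neuronal[i, ], budget_each, params$branch_prob, w, h)
        dend_pts <- rbind(dend_pts, tr$points)
        n_nodes <- n_nodes + nrow(tr$nodes)
        total_len_px <- total_len_px + tr$length_px
      }
      # trees near the border can exit early; regrow from random somata
      # until the stated length budget is actually rendered
      guard <- 0L
      while (total_len_px < 0.95 * params$dendrite_total_px && guard < 40L) {
        guard <- guard + 1L
        i <- sample(params$n_neuronal, 1)
        tr <- grow_tree(neuronal[i, ],
                        params$dendrite_total_px - total_len_px,
                        params$branch_prob, w, h)
        dend_pts <- rbind(dend_pts, tr$points)
        n_nodes <- n_nodes + nrow(tr$nodes)
        total_len_px <- total_len_px + tr$length_px
      }
    }
    dend_base <- matrix(0, h, w)
    union_length_um <- 0
    if (nrow(dend_pts) > 0) {
      imp <- matrix(0, h, w)
      ij <- cbind(pmin(pmax(round(dend_pts[, 2]), 1), h),
                  pmin(pmax(round(dend_pts[, 1]), 1), w))
      for (k in seq_len(nrow(ij))) imp[ij[k, 1], ij[k, 2]] <- 1
      sm <- gaussian_blur(imp, 2)
      ridge_peak <- 1 / (2 * sqrt(2 * pi))  # unit line impulse, sigma = 2
      dend_base <- sm * (params$dendrite_amp / ridge_peak)
      # truth length: centerline of the union tube network at its FWHM
      # half-width (sigma * sqrt(2 ln 2) ~ 2.35 px for sigma = 2): where
      # tubes merge (bifurcations, crossings) the rendered network really
      # has a single centerline, so summed path length would overstate it
      union_mask <- cpp_dilate(imp > 0, 2 * sqrt(2 * log(2)))
      union_length_um <- skeleton_length(cpp_thin(union_mask),
                                         params$pixel_size)
    }

    # --- puncta on dendrites, away from neuronal nuclei ---
    spot_fp <- 2.5  # approx thresholded footprint radius at default settings
    anchors <- dend_pts
    if (nrow(anchors) > 0) {
      keep <- anchors[, 1] > 8 & anchors[, 1] < w - 8 &
              anchors[, 2] > 8 & anchors[, 2] < h - 8
      if (params$n_neuronal > 0) {
        for (i in seq_len(params$n_neuronal))
          keep <- keep & sqrt((anchors[, 1] - neuronal[i, 1])^2 +
                              (anchors[, 2] - neuronal[i, 2])^2) > rn + 5
      }
      if (params$n_glial > 0) {
        for (i in seq_len(params$n_glial))
          keep <- keep & sqrt((anchors[, 1] - glial[i, 1])^2 +
                              (anchors[, 2] - glial[i, 2])^2) > rg + 5
      }
      anchors <- anchors[keep, , drop = FALSE]
    }
    # constraints: same-channel sep keeps thresholded components distinct;
    # non-synaptic puncta stay >= cross_sep from any opposite-channel punctum
    pick_anchor_sites <- function(n, constraints, what) {
      if (n == 0L) return(matrix(numeric(0), 0, 2))
      if (nrow(anchors) == 0L)
        stop("parameter out of renderable range: no dendrite to place ", what)
      for (attempt in 1:12) {  # greedy order matters; retry fresh shuffles
        sites <- matrix(numeric(0), 0, 2)
        ord <- sample(nrow(anchors))
        for (k in ord) {
          cand <- anchors[k, ]
          ok <- TRUE
          for (cs in constraints) {
            ref <- cs$pts
            if (isTRUE(cs$self)) ref <- rbind(ref, sites)
            if (!is.null(ref) && nrow(ref) > 0L &&
                min(sqrt((ref[, 1] - cand[1])^2 + (ref[, 2] - cand[2])^2)) <
                  cs$min_sep) {
              ok <- FALSE
              break
            }
          }
          if (ok) {
            sites <- rbind(sites, cand)
            if (nrow(sites) == n) return(unname(sites))
          }
        }
      }
      stop("parameter out of renderable range: cannot place ", n, " ", what)
    }

    same_sep <- 6   # same-channel separation keeps components distinct
    cross_sep <- 5  # non-synaptic puncta vs opposite channel
    # post spots of a synapse pair are jittered <= 1 px off the site, so
    # other post puncta keep an extra 1 px margin around synapse sites
    syn_sites <- pick_anchor_sites(
      params$n_true_synapses,
      list(list(pts = NULL, min_sep = same_sep + 2, self = TRUE)),
      "synapse sites")
    pre_only <- pick_anchor_sites(
      params$n_pre - params$n_true_synapses,
      list(list(pts = syn_sites, min_sep = same_sep, self = TRUE)),
      "presynaptic puncta")
    post_only <- pick_anchor_sites(
      params$n_post - params$n_true_synapses,
      list(list(pts = syn_sites, min_sep = same_sep + 1, self = FALSE),
           list(pts = NULL, min_sep = same_sep, self = TRUE),
           list(pts = pre_only, min_sep = cross_sep)),
      "postsynaptic puncta")
    jitter1 <- function(pts) {
      if (nrow(pts) == 0L) return(pts)
      a <- stats::runif(nrow(pts), 0, 2 * pi)
      r <- stats::runif(nrow(pts), 0, 1)
      pts + cbind(r * cos(a), r * sin(a))
    }
    pre_centers <- rbind(syn_sites, pre_only)
    post_centers <- rbind(jitter1(syn_sites), post_only)
    amp_jit <- function(n) params$spot_amp * stats::runif(n, 0.8, 1.2)
    pre_base <- render_gaussians(h, w, pre_centers, params$spot_sigma,
                                 amp_jit(nrow(pre_centers)))
    post_base <- render_gaussians(h, w, post_centers, params$spot_sigma,
                                  amp_jit(nrow(post_centers)))

    # --- z-stack + noise ---
    bases <- list(nuclear = nuc_base, dendrite = dend_base,
                  pre = pre_base, post = post_base)
    z_focus <- (params$n_z + 1L) %/% 2L
    px <- array(0, dim = c(h, w, params$n_z, 4L))
    for (ci in 1:4) {
      for (z in seq_len(params$n_z)) {
        dz <- abs(z - z_focus)
        img <- bases[[ci]]
        if (dz > 0) img <- gaussian_blur(img, 1.8 * dz) / (1 + 0.3 * dz)
        img <- img + params$background
        if (params$poisson_noise) {
          img <- stats::rpois(length(img), lambda = pmax(img, 0) * 0.5) / 0.5
          dim(img) <- c(h, w)
        }
        if (params$read_noise_sd > 0)
          img <- img + stats::rnorm(length(img), 0, params$read_noise_sd)
        px[, , z, ci] <- pmax(img, 0)
      }
    }

    truth <- structure(list(
      n_neuronal_nuclei = params$n_neuronal,
      n_glial_nuclei = params$n_glial,
      dendrite_total_length = union_length_um,
      dendrite_path_length = total_len_px * params$pixel_size,
      n_branch_nodes = n_nodes,
      n_pre_spots = nrow(pre_centers),
      n_post_spots = nrow(post_centers),
      n_true_synapses = params$n_true_synapses,
      pixel_size = params$pixel_size,
      seed = seed,
      neuronal_centers = neuronal, glial_centers = glial,
      pre_centers = pre_centers, post_centers = post_centers
    ), class = "field_truth")

    image <- field_image(px, pixel_size = params$pixel_size,
                         metadata = list(seed = seed))
    list(image = image, truth = truth)
  })
}

#' Construct a field image container
#'
#' @param pixels 4-D array `[H, W, Z, C]`.
#' @param channels named integer map of roles (nuclear, dendrite,
#'   presynaptic, postsynaptic) to channel indices.
#' @param pixel_size micrometers per pixel.
#' @param metadata named list (plate, well, field, DIV, condition, ...).
#' @export
field_image <- function(pixels, channels = CHANNEL_ROLES, pixel_size = 0.149,
                        metadata = list()) {
  stopifnot(length(dim(pixels)) == 4L)
  roles <- c("nuclear", "dendrite", "presynaptic", "postsynaptic")
  if (!all(roles %in% names(channels)))
    stop("channel roles must map: ", paste(roles, collapse = ", "))
  if (anyDuplicated(channels[roles]))
    stop("channel roles must map to distinct channels")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(pixels = pixels, channels = channels,
                 pixel_size = pixel_size, metadata = metadata),
            class = "field_image")
}

#' Extract one channel's z-stack from a field image
#' @param image a `field_image`.
#' @param role one of "nuclear", "dendrite", "presynaptic", "postsynaptic".
#' @return 3-D array `[H, W, Z]`.
#' @export
channel_stack <- function(image, role) {
  stopifnot(inherits(image, "field_image"))
  ci <- image$channels[[role]]
  image$pixels[, , , ci, drop = TRUE]
}

#' @export
print.field_truth <- function(x, ...) {
  cat("Synthetic field ground truth (seed ", x$seed, ")\n", sep = "")
  cat("  nuclei: ", x$n_neuronal_nuclei, " neuronal + ", x$n_glial_nuclei,
      " glial\n", sep = "")
  cat(sprintf("  dendrite: %.1f um, %d branch nodes\n",
              x$dendrite_total_length, x$n_branch_nodes))
  cat("  puncta: ", x$n_pre_spots, " pre, ", x$n_post_spots, " post, ",
      x$n_true_synapses, " true synapses\n", sep = "")
  invisible(x)
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("field_image: %d x %d px, %d z, %d channels (%.3f um/px)\n",
              d[1], d[2], d[3], d[4], x$pixel_size))
  invisible(x)
}
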