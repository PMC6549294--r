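# Morphological profiling of a fixed-culture field: nuclei and dendrite
# segmentation, neuronal/non-neuronal classification, synaptic spot
# detection inside the search region, object-overlap synapse calling and the
# per-field descriptor vector.

#' Default configuration of the morphological pipeline
#'
#' Every "user-defined" threshold of the assay has an explicit key here;
#' defaults are tuned on the synthetic generator's intensity regime.
#'
#' @param nuclei_threshold absolute intensity threshold of the nuclear
#'   channel (max projection).
#' @param min_nucleus_area minimum nucleus size in pixels.
#' @param rough_threshold absolute intensity threshold of the dendrite
#'   channel (rough segmentation).
#' @param frangi_scales Gaussian scales (px) of the vesselness filter.
#' @param fine_threshold vesselness threshold of the fine segmentation.
#' @param max_nucleus_area_um2 neuronal classification: maximal projected
#'   area (um^2).
#' @param min_circularity neuronal classification: minimal circularity.
#' @param min_occupancy neuronal classification: minimal fraction of the
#'   dilated nucleus footprint covered by the dendrite mask.
#' @param dendrite_dilation_px,nucleus_dilation_px search-region dilation
#'   radii.
#' @param dog_sigma_narrow,dog_sigma_wide difference-of-Gaussian kernel sds
#'   (px) for spot enhancement.
#' @param spot_threshold absolute threshold on the DoG response.
#' @param min_spot_px spots with `<= min_spot_px` pixels are discarded
#'   (default 4: only spots larger than 4 px are retained).
#' @param min_overlap_px minimal pre/post footprint overlap (px) to call a
#'   synapse.
#' @return named list of class `morpho_config`.
#' @export
morpho_config <- function(nuclei_threshold = 250, min_nucleus_area = 20,
                          rough_threshold = 300, frangi_scales = c(1, 2, 3),
                          fine_threshold = 0.35,
                          max_nucleus_area_um2 = 4.5, min_circularity = 0.6,
                          min_occupancy = 0.05,
                          dendrite_dilation_px = 3, nucleus_dilation_px = 2,
                          dog_sigma_narrow = 1, dog_sigma_wide = 3,
                          spot_threshold = 150, min_spot_px = 4L,
                          min_overlap_px = 1L) {
  structure(as.list(environment()), class = "morpho_config")
}

#' Threshold-based nucleus segmentation with watershed splitting
#'
#' Connected components of the supra-threshold nuclear image; touching
#' nuclei are split by watershed on the distance transform; components
#' smaller than `min_area` pixels are removed.
#'
#' @param nuclear_image 2-D matrix (typically a max projection).
#' @param threshold absolute intensity threshold.
#' @param min_area minimum component size (px).
#' @param watershed split touching components? (default TRUE)
#' @return integer label mask.
#' @export
segment_nuclei <- function(nuclear_image, threshold, min_area = 20,
                           watershed = TRUE) {
  mask <- nuclear_image >= threshold
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- if (watershed) watershed_split(mask, min_distance = 4)
         else label_components(mask)
  drop_small_labels(lab, min_area)
}

drop_small_labels <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0L
  relabel_sequential(lab)
}

#' Two-pass dendrite segmentation (rough threshold + Frangi fine mask)
#'
#' The dendrite mask is the union of the rough supra-threshold mask and the
#' thresholded multi-scale Frangi vesselness response; the skeleton is its
#' morphological thinning.
#'
#' @param dendrite_image 2-D matrix (max projection of the dendrite channel).
#' @param rough_threshold absolute intensity threshold.
#' @param fine_threshold vesselness threshold in \[0, 1\].
#' @param frangi_scales scales (px) for [frangi_vesselness()].
#' @return list with `mask` and `skeleton` (logical matrices).
#' @export
segment_dendrites <- function(dendrite_image, rough_threshold,
                              fine_threshold, frangi_scales = c(1, 2, 3)) {
  if (length(frangi_scales) == 0L) stop("frangi_scales must be nonempty")
  rough <- dendrite_image >= rough_threshold
  fine <- frangi_vesselness(dendrite_image, frangi_scales) >= fine_threshold
  mask <- rough | fine
  skel <- if (any(mask)) skeletonize(mask) else mask
  list(mask = mask, skeleton = skel)
}

region_perimeter <- function(mask_region) {
  # border-step count with the pi/4 isotropic correction: the Manhattan
  # boundary length of a smooth convex shape overestimates the true
  # perimeter by 4/pi (a disc of radius r has 8r boundary steps vs 2*pi*r),
  # so circularity of a rendered disc comes out ~1 instead of ~0.62.
  nr <- nrow(mask_region); nc <- ncol(mask_region)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask_region
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  steps <- sum(ctr & !pad[1:nr, 2:(nc + 1L)]) +
    sum(ctr & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(ctr & !pad[2:(nr + 1L), 1:nc]) + sum(ctr & !pad[2:(nr + 1L), 3:(nc + 2L)])
  steps * pi / 4
}

#' Classify nuclei as neuronal or non-neuronal
#'
#' A nucleus is neuronal when its projected area does not exceed
#' `max_area_um2`, its circularity (`4 pi area / perimeter^2`) is at least
#' `min_circularity`, and at least `min_occupancy` of its 2-px-dilated
#' footprint lies inside the dendrite mask. The texture score is the
#' variance of the Laplacian-of-Gaussian response inside the nucleus,
#' normalized by squared mean intensity (chromocenter spottiness).
#'
#' @param nuclei_labels integer label mask.
#' @param dendrite_mask logical matrix.
#' @param nuclear_image 2-D intensity matrix.
#' @param pixel_size micrometers per pixel.
#' @param max_area_um2,min_circularity,min_occupancy classification
#'   thresholds.
#' @return data.frame with one row per nucleus: id, projected_area_um2,
#'   circularity, occupancy, texture, mean_intensity, on_border,
#'   is_neuronal.
#' @export
classify_nuclei <- function(nuclei_labels, dendrite_mask, nuclear_image,
                            pixel_size = 0.149, max_area_um2 = 4.5,
                            min_circularity = 0.6, min_occupancy = 0.05) {
  n <- max(nuclei_labels)
  if (n == 0L)
    return(data.frame(id = integer(0), projected_area_um2 = numeric(0),
                      circularity = numeric(0), occupancy = numeric(0),
                      texture = numeric(0), mean_intensity = numeric(0),
                      on_border = logical(0), is_neuronal = logical(0)))
  g <- gaussian_kernel1d(1.5, 0L)
  g2 <- gaussian_kernel1d(1.5, 2L)
  log_resp <- cpp_convsep(nuclear_image, g2, g) +
              cpp_convsep(nuclear_image, g, g2)
  nr <- nrow(nuclei_labels); nc <- ncol(nuclei_labels)
  border_ids <- unique(c(nuclei_labels[1, ], nuclei_labels[nr, ],
                         nuclei_labels[, 1], nuclei_labels[, nc]))
  out <- lapply(seq_len(n), function(id) {
    sel <- nuclei_labels == id
    npx <- sum(sel)
    if (npx == 0L) stop("label ", id, " absent from mask")
    area <- npx * pixel_size^2
    per <- region_perimeter(sel)
    circ <- min(1, 4 * pi * npx / per^2)
    dil <- dilate_mask(sel, 2)
    occ <- sum(dil & dendrite_mask) / sum(dil)
    mi <- mean(nuclear_image[sel])
    tex <- stats::var(log_resp[sel]) / max(mi, 1e-9)^2
    data.frame(id = id, projected_area_um2 = area, circularity = circ,
               occupancy = occ, texture = tex, mean_intensity = mi,
               on_border = id %in% border_ids,
               is_neuronal = area <= max_area_um2 & circ >= min_circularity &
                 occ >= min_occupancy)
  })
  do.call(rbind, out)
}

#' Search region for synaptic spot detection
#'
#' Dilated dendrite mask minus dilated neuronal-nuclei mask.
#'
#' @param dendrite_mask,neuronal_nuclei_mask logical matrices.
#' @param dendrite_dilation_px,nucleus_dilation_px dilation radii (px).
#' @return logical matrix.
#' @export
build_search_region <- function(dendrite_mask, neuronal_nuclei_mask,
                                dendrite_dilation_px = 3,
                                nucleus_dilation_px = 2) {
  dilate_mask(dendrite_mask, dendrite_dilation_px) &
    !dilate_mask(neuronal_nuclei_mask, nucleus_dilation_px)
}

#' Detect synaptic spots by difference-of-Gaussians
#'
#' The channel image is band-pass filtered (narrow minus wide Gaussian), the
#' response thresholded inside the search region, and components with
#' `min_spot_px` pixels or fewer removed (default: only spots larger than
#' 4 px are retained).
#'
#' @param channel_image 2-D matrix (the sharpest slice of its channel).
#' @param search_region logical matrix.
#' @param dog_sigma_narrow,dog_sigma_wide DoG kernel sds (narrow < wide).
#' @param spot_threshold absolute threshold on the DoG response.
#' @param min_spot_px strict lower size bound (px).
#' @return integer spot label mask.
#' @export
detect_spots <- function(channel_image, search_region, dog_sigma_narrow = 1,
                         dog_sigma_wide = 3, spot_threshold,
                         min_spot_px = 4L) {
  enhanced <- dog_filter(channel_image, dog_sigma_narrow, dog_sigma_wide)
  mask <- enhanced >= spot_threshold & as_mask(search_region)
  lab <- label_components(mask)
  drop_small_labels(lab, min_spot_px + 1L)
}

#' Call synapses from overlapping pre/post spot footprints
#'
#' A synapse pair is any (pre, post) label pair whose footprints share at
#' least `min_overlap_px` pixels. The synapse count is the number of
#' distinct presynaptic spots participating in at least one pair.
#'
#' @param pre_spots,post_spots integer label masks (co-registered).
#' @param min_overlap_px minimal shared pixel count.
#' @return list with `pairs` (data.frame: pre_id, post_id, overlap_px) and
#'   `n_synapses`.
#' @export
call_synapses <- function(pre_spots, post_spots, min_overlap_px = 1L) {
  both <- pre_spots > 0L & post_spots > 0L
  if (!any(both)) {
    pairs <- data.frame(pre_id = integer(0), post_id = integer(0),
                        overlap_px = integer(0))
    return(list(pairs = pairs, n_synapses = 0L))
  }
  tab <- table(pre = pre_spots[both], post = post_spots[both])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq >= min_overlap_px, , drop = FALSE]
  pairs <- data.frame(pre_id = as.integer(df$pre),
                      post_id = as.integer(df$post),
                      overlap_px = as.integer(df$Freq))
  pairs <- pairs[order(pairs$pre_id, pairs$post_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, n_synapses = length(unique(pairs$pre_id)))
}

#' Pearson intensity colocalization over a region
#'
#' @param pre_image,post_image co-registered 2-D matrices.
#' @param region logical matrix (nonempty).
#' @return Pearson correlation of the two channels over the region's pixels;
#'   0 when either channel is constant there.
#' @export
pearson_colocalization <- function(pre_image, post_image, region) {
  region <- as_mask(region)
  if (!any(region)) stop("colocalization region is empty")
  a <- pre_image[region]; b <- post_image[region]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Segment one field and compute its morphological descriptors
#'
#' Runs the full fixed-culture pipeline on a `field_image` and returns the
#' segmentation plus a one-row descriptor data.frame (nuclei, dendrite and
#' synapse classes, with metadata columns).
#'
#' @param image a `field_image`.
#' @param config a [morpho_config()].
#' @return list with `segmentation` (label masks, search region, nucleus
#'   table, synapse pairs) and `descriptors` (one-row data.frame).
#' @export
profile_field <- function(image, config = morpho_config()) {
  stopifnot(inherits(image, "field_image"))
  ps <- image$pixel_size
  nuc_img <- max_project(channel_stack(image, "nuclear"))
  den_img <- max_project(channel_stack(image, "dendrite"))

  nuclei <- segment_nuclei(nuc_img, config$nuclei_threshold,
                           config$min_nucleus_area)
  dend <- segment_dendrites(den_img, config$rough_threshold,
                            config$fine_threshold, config$frangi_scales)
  nuc_tab <- classify_nuclei(nuclei, dend$mask, nuc_img, pixel_size = ps,
                             max_area_um2 = config$max_nucleus_area_um2,
                             min_circularity = config$min_circularity,
                             min_occupancy = config$min_occupancy)
  neuronal_mask <- nuclei > 0L &
    matrix(nuclei %in% nuc_tab$id[nuc_tab$is_neuronal], nrow(nuclei))
  search <- build_search_region(dend$mask, neuronal_mask,
                                config$dendrite_dilation_px,
                                config$nucleus_dilation_px)

  pre_stack <- channel_stack(image, "presynaptic")
  post_stack <- channel_stack(image, "postsynaptic")
  zi <- select_sharpest_slice(pre_stack)
  pre_img <- if (is.matrix(pre_stack)) pre_stack else pre_stack[, , zi]
  post_img <- if (is.matrix(post_stack)) post_stack else post_stack[, , zi]
  pre_spots <- detect_spots(pre_img, search, config$dog_sigma_narrow,
                            config$dog_sigma_wide, config$spot_threshold,
                            config$min_spot_px)
  post_spots <- detect_spots(post_img, search, config$dog_sigma_narrow,
                             config$dog_sigma_wide, config$spot_threshold,
                             config$min_spot_px)
  syn <- call_synapses(pre_spots, post_spots, config$min_overlap_px)

  seg <- list(nuclei_labels = nuclei, dendrite_mask = dend$mask,
              dendrite_skeleton = dend$skeleton, nucleus_table = nuc_tab,
              neuronal_mask = neuronal_mask, search_region = search,
              pre_spots = pre_spots, post_spots = post_spots,
              synapses = syn)
  desc <- compute_morphological_descriptors(seg, image,
                                            pre_img = pre_img,
                                            post_img = post_img)
  list(segmentation = seg, descriptors = desc)
}

#' Morphological descriptor vector of a segmented field
#'
#' Fills the nuclei, dendrite and synapse descriptor classes. Densities are
#' reported both per 100 um skeleton length and per square micrometer of
#' dendrite-mask area. Intensity-class descriptors carry "intensity" in
#' their name and are excluded from connectivity-score fitting. A field
#' without dendrite yields missing densities (flagged downstream by
#' [filter_fields()]).
#'
#' @param segmentation output of [profile_field()]'s segmentation step.
#' @param image the `field_image`.
#' @param pre_img,post_img the sharpest pre/post slices used for spot
#'   detection (for intensity and colocalization descriptors).
#' @return one-row data.frame.
#' @export
compute_morphological_descriptors <- function(segmentation, image,
                                              pre_img, post_img) {
  ps <- image$pixel_size
  nt <- segmentation$nucleus_table
  shape_tab <- nt[!nt$on_border, , drop = FALSE]  # unbiased shape statistics
  if (nrow(shape_tab) == 0L) shape_tab <- nt
  skel_um <- skeleton_length(segmentation$dendrite_skeleton, ps)
  dend_px <- sum(segmentation$dendrite_mask)
  # tip-loss compensation: thinning a tube erodes each end by about the
  # tube radius; add the mean mask half-width back per skeleton endpoint
  if (skel_um > 0) {
    r_px <- dend_px / (skel_um / ps) / 2
    skel_um <- skel_um +
      count_endpoints(segmentation$dendrite_skeleton) * r_px * ps
  }
  dend_area_um2 <- dend_px * ps^2
  density <- dend_px / length(segmentation$dendrite_mask)
  n_pre <- max(segmentation$pre_spots)
  n_post <- max(segmentation$post_spots)
  n_syn <- segmentation$synapses$n_synapses
  per100 <- function(n) if (skel_um > 0) n / skel_um * 100 else NA_real_
  per_area <- function(n) if (dend_area_um2 > 0) n / dend_area_um2 else NA_real_
  spot_area <- function(lab) {
    if (max(lab) == 0L) return(NA_real_)
    mean(tabulate(lab[lab > 0L])) * ps^2
  }
  spot_int <- function(lab, img) {
    if (max(lab) == 0L) return(NA_real_)
    mean(img[lab > 0L])
  }
  coloc <- if (any(segmentation$search_region))
    pearson_colocalization(pre_img, post_img, segmentation$search_region)
    else NA_real_
  nuc_img <- max_project(channel_stack(image, "nuclear"))
  den_img <- max_project(channel_stack(image, "dendrite"))
  desc <- data.frame(
    nuclei_count = nrow(nt),
    neuronal_count = sum(nt$is_neuronal),
    non_neuronal_count = sum(!nt$is_neuronal),
    neuronal_fraction = if (nrow(nt) > 0) mean(nt$is_neuronal) else NA_real_,
    nuclei_mean_area_um2 = mean(shape_tab$projected_area_um2),
    nuclei_mean_circularity = mean(shape_tab$circularity),
    nuclei_mean_texture = mean(nt$texture),
    nuclei_mean_intensity = mean(nt$mean_intensity),
    dendrite_density = density,
    dendrite_length_um = skel_um,
    dendrite_nodes = count_nodes(segmentation$dendrite_skeleton),
    dendrite_mean_width_um = if (skel_um > 0) dend_area_um2 / skel_um
      else NA_real_,
    dendrite_mean_intensity = mean(den_img[segmentation$dendrite_mask]),
    pre_count = n_pre,
    post_count = n_post,
    synapse_count = n_syn,
    pre_density_per_100um = per100(n_pre),
    post_density_per_100um = per100(n_post),
    synapse_density_per_100um = per100(n_syn),
    pre_density_per_um2 = per_area(n_pre),
    post_density_per_um2 = per_area(n_post),
    synapse_density_per_um2 = per_area(n_syn),
    pre_mean_area_um2 = spot_area(segmentation$pre_spots),
    post_mean_area_um2 = spot_area(segmentation$post_spots),
    pre_mean_intensity = spot_int(segmentation$pre_spots, pre_img),
    post_mean_intensity = spot_int(segmentation$post_spots, post_img),
    synapse_coloc_pearson = coloc)
  md <- image$metadata
  if (length(md) > 0) desc <- cbind(as.data.frame(md, stringsAsFactors = FALSE),
                                    desc)
  rownames(desc) <- NULL
  desc
}
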