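# Shared fixture builders; everything is generated in code at test time.

# binary disc in an h x w matrix
disc_mask <- function(h, w, cx, cy, r) {
  m <- matrix(FALSE, h, w)
  for (x in max(1, floor(cx - r)):min(w, ceiling(cx + r)))
    for (y in max(1, floor(cy - r)):min(h, ceiling(cy + r)))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y, x] <- TRUE
  m
}

# random label mask with n blobby components of ~sz pixels
random_label_mask <- function(h, w, n, sz = 8) {
  lab <- matrix(0L, h, w)
  for (id in seq_len(n)) {
    cx <- sample(3:(w - 2), 1)
    cy <- sample(3:(h - 2), 1)
    px <- cbind(cy, cx)
    while (nrow(px) < sz) {
      k <- sample(nrow(px), 1)
      cand <- px[k, ] + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      if (all(cand >= 1) && cand[1] <= h && cand[2] <= w)
        px <- unique(rbind(px, cand))
    }
    lab[px] <- id
  }
  lab
}

# brute-force synapse-pair oracle: double loop over label ids, explicit
# pixel-set intersection
oracle_synapse_pairs <- function(pre, post, min_overlap = 1L) {
  out <- data.frame(pre_id = integer(0), post_id = integer(0),
                    overlap_px = integer(0))
  for (i in seq_len(max(pre, 0))) {
    pix_i <- which(pre == i)
    if (length(pix_i) == 0) next
    for (j in seq_len(max(post, 0))) {
      ov <- length(intersect(pix_i, which(post == j)))
      if (ov >= min_overlap)
        out <- rbind(out, data.frame(pre_id = i, post_id = j,
                                     overlap_px = ov))
    }
  }
  out[order(out$pre_id, out$post_id), , drop = FALSE]
}

# small fast field for segmentation tests
quick_field_params <- function(...) {
  args <- utils::modifyList(
    list(n_neuronal = 8L, n_glial = 3L, dendrite_total_px = 1600,
         n_pre = 40L, n_post = 40L, n_true_synapses = 20L),
    list(...))
  do.call(field_params, args)
}
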