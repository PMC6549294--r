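# Pseudo-maturation model: deterministic ramps mapping culture age (DIV) to
# the generator's truth parameters. Directions follow the development of
# primary cultures: dendrite density and synapse density rise (synapses
# plateau late), neuron count slowly declines, and synchronous activity
# emerges after an onset age (~10 DIV).

#' Deterministic maturation ramps over pseudo-culture-age
#'
#' @param div_levels ordered numeric vector of pseudo-ages (days in vitro);
#'   default `c(3, 7, 10, 14, 18)`.
#' @param div_range range over which ramps are scaled (defaults to the span
#'   of `div_levels`).
#' @param synchrony_onset DIV at which network synchrony starts to rise.
#' @return object of class `maturation_model` with elements `div_levels`,
#'   `truth_at(div)` (ramp values) and `params_at(div)` (ready-to-render
#'   [field_params()] / [calcium_params()]).
#' @export
maturation_model <- function(div_levels = c(3, 7, 10, 14, 18),
                             div_range = range(div_levels),
                             synchrony_onset = 8) {
  if (length(div_levels) == 0L) stop("div_levels must be nonempty")
  div_levels <- sort(div_levels)
  span <- max(div_range[2] - div_range[1], 1e-9)
  truth_at <- function(div) {
    u <- min(max((div - div_range[1]) / span, 0), 1)
    dend_px <- 900 + 2400 * u                  # strictly increasing
    len_um <- dend_px * 0.149
    # puncta counts scale with dendrite length x a ramped linear density,
    # so densities per dendrite length rise with age: presynaptic quickly
    # then plateaus, postsynaptic gradually, synapses rise and plateau late
    syn_per_um <- 0.05 + 0.08 * min(u / 0.75, 1)
    pre_per_um <- 0.10 + 0.10 * min(u / 0.6, 1)
    post_per_um <- 0.10 + 0.08 * u
    syn <- round(len_um * syn_per_um)
    list(
      div = div,
      dendrite_total_px = dend_px,
      n_neuronal = round(16 - 5 * u),          # gradual neuron loss
      n_glial = 5L,
      n_true_synapses = syn,
      n_pre = max(syn, round(len_um * pre_per_um)),
      n_post = max(syn, round(len_um * post_per_um)),
      burst_rate = 0.02 + 0.04 * u,
      synchrony_fraction =
        min(max((div - synchrony_onset) / 12, 0), 1)
    )
  }
  params_at <- function(div) {
    tr <- truth_at(div)
    list(
      field = field_params(n_neuronal = tr$n_neuronal, n_glial = tr$n_glial,
                           dendrite_total_px = tr$dendrite_total_px,
                           n_pre = tr$n_pre, n_post = tr$n_post,
                           n_true_synapses = tr$n_true_synapses),
      calcium = calcium_params(burst_rate = tr$burst_rate,
                               synchrony_fraction = tr$synchrony_fraction)
    )
  }
  structure(list(div_levels = div_levels, truth_at = truth_at,
                 params_at = params_at, synchrony_onset = synchrony_onset),
            class = "maturation_model")
}

#' Generate a synthetic plate of fields with metadata
#'
#' Lays out `n_wells_per_div` wells per pseudo-age with `n_fields_per_well`
#' fields each and renders every field at the maturation model's parameters.
#'
#' @param model a [maturation_model()].
#' @param n_wells_per_div,n_fields_per_well layout counts.
#' @param seed integer master seed; per-field seeds are derived from it and
#'   recorded in the metadata.
#' @param noise `FALSE` renders every field noiseless.
#' @param plate,experiment,replicate,condition,cell_type metadata constants.
#' @return list with `fields` (list of `list(image, truth)`) and `metadata`
#'   (data.frame: plate, well, field, DIV, cell_type, condition, dose,
#'   experiment, replicate, seed — one row per field).
#' @export
generate_plate <- function(model = maturation_model(), n_wells_per_div = 3L,
                           n_fields_per_well = 2L, seed = 1L, noise = TRUE,
                           plate = "P1", experiment = "E1", replicate = 1L,
                           condition = "control", cell_type = "cortical") {
  stopifnot(inherits(model, "maturation_model"))
  divs <- model$div_levels
  rows <- list()
  fields <- list()
  well_i <- 0L
  for (div in divs) {
    fp <- model$params_at(div)$field
    if (!noise) fp <- noiseless(fp)
    for (wi in seq_len(n_wells_per_div)) {
      well_i <- well_i + 1L
      well <- sprintf("%s%02d", LETTERS[(well_i - 1L) %/% 12L + 1L],
                      (well_i - 1L) %% 12L + 1L)
      for (fi in seq_len(n_fields_per_well)) {
        fseed <- (seed * 10007L + well_i * 101L + fi) %% 2147483647L
        fld <- generate_field(fp, seed = fseed)
        fld$image$metadata <- list(plate = plate, well = well, field = fi,
                                   DIV = div, cell_type = cell_type,
                                   condition = condition, dose = 0,
                                   experiment = experiment,
                                   replicate = replicate, seed = fseed)
        fields[[length(fields) + 1L]] <- fld
        rows[[length(rows) + 1L]] <- data.frame(
          plate = plate, well = well, field = fi, DIV = div,
          cell_type = cell_type, condition = condition, dose = 0,
          experiment = experiment, replicate = replicate, seed = fseed,
          stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, rows)
  key <- paste(metadata$plate, metadata$well, metadata$field)
  if (anyDuplicated(key)) stop("layout error: duplicate well/field keys")
  list(fields = fields, metadata = metadata)
}

#' Simulate a well-level descriptor table directly from the maturation ramps
#'
#' Bypasses image rendering: each well's descriptors are the ramp-implied
#' expectations perturbed by multiplicative Gaussian noise, which is what the
#' imaging pipeline would deliver after well averaging. Intensity-class
#' descriptors are generated age-independent with occasional outliers, the
#' behavior that motivates excluding them from the connectivity score.
#'
#' @param model a [maturation_model()].
#' @param n_wells_per_div wells per DIV level per experiment.
#' @param n_experiments number of experiments (z-scoring groups).
#' @param seed integer seed.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param condition condition label for every row.
#' @return data.frame: metadata columns plus morphological and functional
#'   descriptors (one row = one well).
#' @export
simulate_descriptor_table <- function(model = maturation_model(),
                                      n_wells_per_div = 6L,
                                      n_experiments = 3L, seed = 1L,
                                      noise_cv = 0.12,
                                      condition = "control") {
  stopifnot(inherits(model, "maturation_model"))
  with_seed(seed, {
    rows <- list()
    for (e in seq_len(n_experiments)) {
      scale_e <- stats::runif(1, 0.8, 1.25)  # batch effect per experiment
      for (div in model$div_levels) {
        tr <- model$truth_at(div)
        for (wi in seq_len(n_wells_per_div)) {
          nz <- function(mu) mu * (1 + stats::rnorm(1, 0, noise_cv))
          dens <- tr$dendrite_total_px * 4 / (256 * 256)
          len_um <- tr$dendrite_total_px * 0.149
          syn_per100 <- tr$n_true_synapses / len_um * 100
          outlier <- stats::runif(1) < 0.05
          rows[[length(rows) + 1L]] <- data.frame(
            plate = paste0("P", e), well = sprintf("W%03d", length(rows) + 1L),
            DIV = div, cell_type = "cortical", condition = condition,
            dose = 0, experiment = paste0("E", e), replicate = 1L,
            nuclei_count = nz(scale_e * (tr$n_neuronal + tr$n_glial)),
            neuronal_count = nz(scale_e * tr$n_neuronal),
            non_neuronal_count = nz(scale_e * tr$n_glial),
            neuronal_fraction =
              min(1, nz(tr$n_neuronal / (tr$n_neuronal + tr$n_glial))),
            nuclei_mean_area_um2 = nz(3.5),
            nuclei_mean_texture = nz(0.5 + 0.02 * div),
            nuclei_mean_intensity =
              nz(scale_e * 800) * (1 + 3 * outlier),
            dendrite_density = nz(scale_e * dens),
            dendrite_length_um = nz(scale_e * len_um),
            dendrite_nodes = nz(scale_e * (4 + 1.5 * div)),
            dendrite_mean_width_um = nz(0.6),
            dendrite_mean_intensity =
              nz(scale_e * 600) * (1 + 3 * outlier),
            pre_density_per_100um = nz(tr$n_pre / len_um * 100),
            post_density_per_100um = nz(tr$n_post / len_um * 100),
            synapse_density_per_100um = nz(syn_per100),
            synapse_coloc_pearson = min(1, nz(0.2 + 0.02 * div)),
            pre_mean_intensity = nz(scale_e * 900) * (1 + 3 * outlier),
            post_mean_intensity = nz(scale_e * 900) * (1 + 3 * outlier),
            # functional readouts are far noisier well-to-well than
            # morphology (separate live recordings, few neurons per field)
            pct_active = min(100, max(5,
              100 * (0.4 + 0.5 * tr$synchrony_fraction) *
                (1 + stats::rnorm(1, 0, 0.25)))),
            burst_freq_hz = tr$burst_rate * (1 + stats::rnorm(1, 0, 0.25)),
            burst_amplitude = nz(0.8),
            network_burst_freq_hz =
              max(0, tr$burst_rate * (0.1 + 0.9 * tr$synchrony_fraction) *
                       (1 + stats::rnorm(1, 0, 0.4))),
            burst_correlation =
              min(1, max(0, 0.9 * tr$synchrony_fraction *
                              (1 + stats::rnorm(1, 0, 0.3)) +
                              stats::rnorm(1, 0, 0.1))),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Shift a descriptor class toward the immature phenotype
#'
#' Test helper for score-sensitivity analyses: moves every descriptor of one
#' class a fraction `lambda` of the way toward that descriptor's mean at the
#' youngest age in the table, i.e. toward a less-connected culture state.
#'
#' @param tab descriptor table (data.frame).
#' @param class one of "nuclei", "dendrite", "synapse", "functional".
#' @param lambda fraction of the displacement applied, in \[0, 1\].
#' @export
degrade_descriptors <- function(tab, class, lambda = 0.5) {
  cols <- descriptor_columns(tab)
  cols <- cols[descriptor_class(cols) == class]
  young <- tab$DIV == min(tab$DIV)
  for (cl in cols) {
    mu0 <- mean(tab[[cl]][young], na.rm = TRUE)
    tab[[cl]] <- tab[[cl]] + lambda * (mu0 - tab[[cl]])
  }
  tab
}
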