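#' Names of the questionnaire symptoms
#'
#' The 17 side-effect symptoms rated daily on the 0-3 ordinal scale.
#'
#' @return character vector of length 17.
#' @export
symptom_names <- function() {
  c("dizziness", "skin_reactions", "appetite_changes", "confusion",
    "hallucinations", "tantrums", "sleeplessness", "nervousness",
    "headaches", "constipation", "nausea", "vertigo", "inner_restlessness",
    "sleepiness", "concentration_problems", "libido_alterations", "fatigue")
}

#' Generative condition profile
#'
#' The knobs through which a pharmacological condition acts on the
#' synthetic BOLD generator, encoding the qualitative sedation signature:
#' global decoupling of the ROI network together with increased local
#' coherence and low-frequency amplitude in low-level sensory regions.
#'
#' @param coupling_scale multiplier (> 0) on the inter-ROI (off-diagonal)
#'   latent covariance; sedation < 1.
#' @param local_coherence_boost multiplier (> 0) on the shared within-patch
#'   signal amplitude in the designated sensory ROIs.
#' @param lowfreq_gain multiplier (> 0) on the 0.01-0.05 Hz component of
#'   the sensory ROIs' shared signal.
#' @param noise_sd independent vertex noise standard deviation (> 0).
#' @param side_effect_p per-symptom daily probability parameter of the
#'   Binomial(3, p) rating distribution (length 17).
#' @return list of class `condition_profile`.
#' @export
condition_profile <- function(coupling_scale = 1, local_coherence_boost = 1,
                              lowfreq_gain = 1, noise_sd = 0.7,
                              side_effect_p = rep(0.08, 17L)) {
  if (any(c(coupling_scale, local_coherence_boost, lowfreq_gain, noise_sd) <= 0)) {
    stop("all condition-profile multipliers must be > 0")
  }
  if (any(side_effect_p < 0) || any(side_effect_p > 1)) {
    stop("side-effect probabilities must lie in [0, 1]")
  }
  structure(list(coupling_scale = coupling_scale,
                 local_coherence_boost = local_coherence_boost,
                 lowfreq_gain = lowfreq_gain, noise_sd = noise_sd,
                 side_effect_p = side_effect_p),
            class = "condition_profile")
}

#' Stock condition profiles
#'
#' `profile_placebo()` is the neutral condition. `profile_sedation()` plants
#' the benzodiazepine-like signature: inter-ROI coupling reduced to 0.7,
#' sensory within-patch coherence and low-frequency power raised by 1.5,
#' and elevated ratings for fatigue, sleepiness, concentration problems,
#' dizziness and confusion. `profile_anxiolytic()` is the TSPO-ligand-like
#' condition: no planted imaging effect and placebo-level side effects.
#'
#' @return `condition_profile`.
#' @export
profile_placebo <- function() condition_profile()

#' @rdname profile_placebo
#' @export
profile_sedation <- function() {
  p <- rep(0.08, 17L)
  names(p) <- symptom_names()
  p[c("fatigue", "sleepiness", "concentration_problems",
      "dizziness", "confusion")] <- 0.5
  condition_profile(coupling_scale = 0.7, local_coherence_boost = 1.5,
                    lowfreq_gain = 1.5, side_effect_p = unname(p))
}

#' @rdname profile_placebo
#' @export
profile_anxiolytic <- function() condition_profile()

#' Synthetic study configuration
#'
#' Desk-scale emulation of a repeated-measures pharmaco-fMRI study:
#' a triangulated grid cortex of `n_rois` square patches of
#' `vertices_per_roi` vertices each, ROI latent signals that are
#' band-limited Gaussian processes with a block (network) covariance
#' structure, and four within-subject conditions.
#'
#' @param n_subjects number of subjects.
#' @param n_rois number of ROIs; must factor into a near-square block grid.
#' @param vertices_per_roi vertices per ROI patch; must be a perfect square.
#' @param n_timepoints session length in volumes.
#' @param dt sampling interval (TR) in seconds.
#' @param n_networks number of networks; must divide `n_rois`.
#' @param sensory_rois indices of the designated low-level sensory ROIs.
#' @param conditions named list of [condition_profile()]s.
#' @param latent_band [band_spec()] of the ROI latent signals.
#' @param within_r,between_r latent correlation within / between networks.
#' @param patch_sd baseline amplitude of the shared within-patch signal.
#' @param inband_noise_sd amplitude of the band-limited (latent-band)
#'   independent vertex noise that models in-band physiological noise;
#'   white measurement noise comes from each condition's `noise_sd`.
#' @param n_days number of questionnaire (treatment) days.
#' @param spacing_mm grid spacing in mm.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_subjects = 30L, n_rois = 24L,
                         vertices_per_roi = 25L, n_timepoints = 600L,
                         dt = 1, n_networks = 8L, sensory_rois = 1:6,
                         conditions = list(baseline = profile_placebo(),
                                           placebo = profile_placebo(),
                                           drug_a = profile_sedation(),
                                           drug_b = profile_anxiolytic()),
                         latent_band = band_spec(0.008, 0.12),
                         within_r = 0.6, between_r = 0.2, patch_sd = 0.4,
                         inband_noise_sd = 0.9, n_days = 5L, spacing_mm = 3) {
  side <- sqrt(vertices_per_roi)
  if (side != round(side)) stop("vertices_per_roi must be a perfect square")
  if (n_rois %% n_networks != 0L) stop("n_networks must divide n_rois")
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("conditions must be a named list of condition profiles")
  }
  for (p in conditions) stopifnot(inherits(p, "condition_profile"))
  if (any(sensory_rois < 1L) || any(sensory_rois > n_rois)) {
    stop("sensory_rois out of range")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    vertices_per_roi = as.integer(vertices_per_roi),
    n_timepoints = as.integer(n_timepoints), dt = dt,
    n_networks = as.integer(n_networks), sensory_rois = as.integer(sensory_rois),
    conditions = conditions, latent_band = latent_band,
    within_r = within_r, between_r = between_r, patch_sd = patch_sd,
    inband_noise_sd = inband_noise_sd,
    n_days = as.integer(n_days), spacing_mm = spacing_mm
  ), class = "study_config")
}

# Band-limited Gaussian noise synthesized in the frequency domain (flat
# spectrum inside the band), one unit-variance series per row. Much cheaper
# than time-domain filtering for many rows.
bandlimited_noise <- function(n_rows, n_t, dt, band) {
  freqs <- (0:(n_t - 1)) / (n_t * dt)
  half <- floor(n_t / 2)
  sel <- which(freqs > 0 & seq_len(n_t) <= half + 1L &
                 freqs >= band$low_hz & freqs <= band$high_hz)
  spec <- matrix(0 + 0i, n_rows, n_t)
  re <- matrix(stats::rnorm(n_rows * length(sel)), n_rows)
  im <- matrix(stats::rnorm(n_rows * length(sel)), n_rows)
  spec[, sel] <- complex(real = re, imaginary = im)
  spec[, n_t - sel + 2L] <- Conj(spec[, sel])
  x <- Re(t(stats::mvfft(t(spec), inverse = TRUE))) / n_t
  x / sqrt(rowMeans(x^2))
}

# near-square factorization for the ROI block grid
block_grid <- function(n_rois) {
  br <- floor(sqrt(n_rois))
  while (n_rois %% br != 0L) br <- br - 1L
  c(rows = br, cols = n_rois %/% br)
}

# deterministic per-(subject, condition, stream) seed below 2^31
session_seed <- function(master, subject, condition_idx, stream = 0L) {
  as.integer((as.numeric(master) %% 19997) * 100000 +
               subject * 250 + condition_idx * 40 + stream)
}

#' Generate a synthetic multi-subject study
#'
#' Builds the mesh, parcellation, network references and side-effect table
#' up front; BOLD sessions are materialized lazily and reproducibly through
#' [get_session()] (a full study of vertex series would occupy several GB).
#' Every quantity is a deterministic function of `(config, seed)`, and
#' per-subject seeding is hierarchical, so subsetting subjects never changes
#' the data of the others.
#'
#' Per session, each ROI's latent signal is a band-limited Gaussian process;
#' latents are correlated according to the block (network) structure with
#' off-diagonal covariance scaled by the condition's `coupling_scale`. A
#' vertex time course is its ROI latent plus a shared within-patch signal
#' (amplitude `patch_sd`, multiplied by `local_coherence_boost` in sensory
#' ROIs) plus independent Gaussian noise; sensory ROIs additionally get
#' their shared signal's 0.01-0.05 Hz component multiplied by
#' `lowfreq_gain`.
#'
#' @param config [study_config()].
#' @param seed master integer seed.
#' @return object of class `study_dataset` with `mesh`, `parcellation`,
#'   `references` ([reference_set()]), `network_masks`, `roi_networks`,
#'   `side_effects` ([side_effect_table()]), `config`, `seed`.
#' @export
make_study <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  bg <- block_grid(config$n_rois)
  side <- as.integer(sqrt(config$vertices_per_roi))
  nx <- bg["cols"] * side
  ny <- bg["rows"] * side
  mesh <- grid_mesh(nx, ny, config$spacing_mm)
  if (config$n_rois * config$vertices_per_roi != mesh$n_vertices) {
    stop("inconsistent config: n_rois * vertices_per_roi != mesh size")
  }
  ix <- ((seq_len(mesh$n_vertices) - 1L) %% nx) + 1L
  iy <- ((seq_len(mesh$n_vertices) - 1L) %/% nx) + 1L
  bx <- (ix - 1L) %/% side
  by <- (iy - 1L) %/% side
  labels <- by * bg["cols"] + bx + 1L
  parc <- parcellation(as.integer(labels), config$n_rois)

  per_net <- config$n_rois %/% config$n_networks
  roi_networks <- rep(seq_len(config$n_networks), each = per_net)
  network_masks <- lapply(seq_len(config$n_networks), function(j) {
    parc$labels %in% which(roi_networks == j)
  })
  ref_maps <- do.call(rbind, lapply(network_masks, as.numeric))
  refs <- reference_set(ref_maps)

  n_cond <- length(config$conditions)
  ratings <- array(0L, dim = c(config$n_subjects, 17L, n_cond, config$n_days))
  for (s in seq_len(config$n_subjects)) {
    set.seed(session_seed(seed, s, 0L, stream = 1L))
    for (ci in seq_len(n_cond)) {
      p <- config$conditions[[ci]]$side_effect_p
      ratings[s, , ci, ] <- stats::rbinom(17L * config$n_days, 3L,
                                          rep(p, times = config$n_days))
    }
  }
  side_effects <- side_effect_table(ratings, symptoms = symptom_names(),
                                    conditions = names(config$conditions))

  structure(list(mesh = mesh, parcellation = parc, references = refs,
                 network_masks = network_masks, roi_networks = roi_networks,
                 side_effects = side_effects, config = config,
                 seed = as.integer(seed)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "study_dataset: %d subjects x %d conditions (%s), %d vertices, %d ROIs, %d tp, dt = %g s, seed = %d\n",
    x$config$n_subjects, length(x$config$conditions),
    paste(names(x$config$conditions), collapse = ", "),
    x$mesh$n_vertices, x$config$n_rois, x$config$n_timepoints,
    x$config$dt, x$seed))
  invisible(x)
}

#' Materialize one session of a synthetic study
#'
#' Deterministically regenerates the vertex BOLD series of one (subject,
#' condition) cell from the study's hierarchical seed.
#'
#' @param study [make_study()] result.
#' @param subject subject index.
#' @param condition condition name or index.
#' @return [vertex_series()].
#' @export
get_session <- function(study, subject, condition) {
  stopifnot(inherits(study, "study_dataset"))
  cfg <- study$config
  if (subject < 1L || subject > cfg$n_subjects) stop("subject out of range")
  if (is.character(condition)) {
    ci <- match(condition, names(cfg$conditions))
    if (is.na(ci)) stop("unknown condition: ", condition)
  } else {
    ci <- as.integer(condition)
    if (ci < 1L || ci > length(cfg$conditions)) stop("condition out of range")
  }
  if (!is.null(study$session_dir)) {
    return(session_from_files(study, subject, names(cfg$conditions)[ci]))
  }
  prof <- cfg$conditions[[ci]]
  n_r <- cfg$n_rois
  n_t <- cfg$n_timepoints
  set.seed(session_seed(study$seed, subject, ci, stream = 0L))

  z <- matrix(stats::rnorm(n_r * n_t), n_r, n_t)
  z <- bandpass(z, cfg$latent_band, dt = cfg$dt)
  z <- z / apply(z, 1L, stats::sd)
  cmat <- matrix(cfg$between_r, n_r, n_r)
  for (j in seq_len(cfg$n_networks)) {
    members <- which(study$roi_networks == j)
    cmat[members, members] <- cfg$within_r
  }
  diag(cmat) <- 1
  cmat[upper.tri(cmat)] <- cmat[upper.tri(cmat)] * prof$coupling_scale
  cmat[lower.tri(cmat)] <- t(cmat)[lower.tri(cmat)]
  latents <- t(chol(cmat)) %*% z

  # fine-scale local coherence: per-ROI carrier signals mixed through smooth
  # zero-mean spatial basis patterns, so nearby vertices share signal while
  # the ROI average (and hence FC) stays nearly unaffected
  n_car <- 4L
  carriers <- matrix(stats::rnorm(n_r * n_car * n_t), n_r * n_car, n_t)
  carriers <- bandpass(carriers, cfg$latent_band, dt = cfg$dt)
  carriers <- carriers / apply(carriers, 1L, stats::sd)

  if (prof$lowfreq_gain != 1) {
    # the gain acts on the ROI-wide (shared) component: it raises sensory
    # low-frequency amplitude and local synchrony without altering
    # inter-ROI correlations
    sr <- cfg$sensory_rois
    lowpart <- bandpass(latents[sr, , drop = FALSE], band_spec(0.01, 0.05),
                        dt = cfg$dt)
    latents[sr, ] <- latents[sr, ] + (prof$lowfreq_gain - 1) * lowpart
  }

  side <- as.integer(sqrt(cfg$vertices_per_roi))
  u <- (rep(seq_len(side), times = side) - 0.5) / side
  v <- (rep(seq_len(side), each = side) - 0.5) / side
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  basis <- vapply(seq_len(n_car), function(k) {
    exp(-((u - corners[k, 1])^2 + (v - corners[k, 2])^2) / (2 * 0.5^2))
  }, numeric(length(u)))
  basis <- sweep(basis, 2L, colMeans(basis))
  basis <- basis / sqrt(rowSums(basis^2))

  data <- latents[study$parcellation$labels, , drop = FALSE]
  for (r in seq_len(n_r)) {
    rows <- which(study$parcellation$labels == r)
    field <- basis %*% carriers[(r - 1L) * n_car + seq_len(n_car), , drop = FALSE]
    data[rows, ] <- data[rows, ] + cfg$patch_sd * field
  }
  # the local-coherence boost scales the whole shared within-patch signal
  # (latent + field) of sensory ROIs; amplitude scaling leaves every
  # inter-regional correlation invariant but raises vertex-level synchrony
  if (prof$local_coherence_boost != 1) {
    sv <- study$parcellation$labels %in% cfg$sensory_rois
    data[sv, ] <- data[sv, ] * prof$local_coherence_boost
  }
  n_v <- study$mesh$n_vertices
  if (cfg$inband_noise_sd > 0) {
    data <- data + cfg$inband_noise_sd *
      bandlimited_noise(n_v, n_t, cfg$dt, cfg$latent_band)
  }
  noise <- matrix(stats::rnorm(n_v * n_t), ncol = n_t)
  vertex_series(data + prof$noise_sd * noise, cfg$dt)
}

#' Superposed drug level from repeated dosing
#'
#' Instant-absorption, first-order-elimination superposition: the relative
#' serum level at `eval_time_h` is the sum over all earlier doses of
#' `2^(-(eval - t_i)/half_life)`, expressed in units of one dose (so a
#' single dose evaluated at its own time gives 1).
#'
#' @param half_life_h elimination half-life in hours (> 0).
#' @param dose_times_h dose times in hours.
#' @param eval_time_h evaluation time in hours.
#' @return relative level (0 if evaluated before the first dose).
#' @export
accumulate_doses <- function(half_life_h, dose_times_h, eval_time_h) {
  if (!is.numeric(half_life_h) || half_life_h <= 0) stop("half-life must be > 0")
  past <- dose_times_h[dose_times_h <= eval_time_h]
  if (length(past) == 0L) return(0)
  sum(2^(-(eval_time_h - past) / half_life_h))
}

#' Write a synthetic study to a directory tree
#'
#' Materializes every session and writes mesh (GIFTI geometry), sessions
#' (GIFTI functional), parcellation and side effects (TSV), references
#' (GIFTI) and a JSON manifest.
#'
#' @param study [make_study()] result.
#' @param dir output directory.
#' @param format `"gii"` (GIFTI float32) or `"rds"` (lossless archive).
#' @export
write_study <- function(study, dir, format = c("gii", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gifti_surface(study$mesh, file.path(dir, "mesh.surf.gii"))
  utils::write.table(
    data.frame(vertex = seq_len(study$mesh$n_vertices),
               roi = study$parcellation$labels,
               network = study$roi_networks[study$parcellation$labels]),
    file.path(dir, "parcellation.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (j in seq_len(study$references$n_components)) {
    save_surface_data(vertex_map(study$references$maps[j, ], "zmap"),
                      file.path(dir, sprintf("reference_%02d.func.gii", j)))
  }
  se <- study$side_effects
  idx <- expand.grid(subject = seq_len(dim(se$ratings)[1L]),
                     symptom = seq_along(se$symptoms),
                     condition = seq_along(se$conditions),
                     day = seq_len(dim(se$ratings)[4L]))
  utils::write.table(
    data.frame(subject = idx$subject, symptom = se$symptoms[idx$symptom],
               condition = se$conditions[idx$condition], day = idx$day,
               rating = se$ratings[as.matrix(idx)]),
    file.path(dir, "side_effects.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (s in seq_len(study$config$n_subjects)) {
    for (cn in names(study$config$conditions)) {
      f <- file.path(dir, sprintf("sub-%02d_cond-%s.func.%s", s, cn,
                                  if (format == "gii") "gii" else "rds"))
      save_surface_data(get_session(study, s, cn), f)
    }
  }
  manifest <- list(
    generator = "sedconn synthetic study", seed = study$seed,
    n_subjects = study$config$n_subjects,
    conditions = names(study$config$conditions),
    n_vertices = study$mesh$n_vertices, n_rois = study$config$n_rois,
    n_timepoints = study$config$n_timepoints, dt = study$config$dt,
    sensory_rois = study$config$sensory_rois, format = format)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
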