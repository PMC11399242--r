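#' Analysis parameters of the standard pipeline
#'
#' Defaults mirror the study protocol: FC on 0.01-0.1 Hz band-passed ROI
#' averages thresholded at sigma = 0.5/0.6/0.7; ReHo on 0.01-0.1 Hz
#' band-passed vertex series with 2- and 4-hop neighbourhoods; fALFF over
#' 0.01-0.05 Hz against the full spectrum; constrained ICA on 0.2 Hz
#' low-passed series; Gaussian surface smoothing (FWHM 3 mm) before the
#' vertex-wise metrics; paired tests with BH-FDR at q <= 0.05 and z-maps
#' thresholded at |z| >= 2.
#'
#' @param sigmas ascending FC thresholds in (0, 1).
#' @param fc_band band for the connectivity analysis.
#' @param reho_hops integer vector of ReHo neighbourhood radii.
#' @param reho_band band applied before ReHo.
#' @param falff_low low band of the fALFF ratio.
#' @param ica_lowpass_hz low-pass cutoff before constrained ICA.
#' @param smooth_fwhm_mm surface smoothing kernel FWHM (0 disables).
#' @param cica [cica_config()].
#' @param q FDR level in (0, 1].
#' @param z_abs z-map threshold.
#' @param families which metric families to compute: subset of
#'   `"graph"`, `"reho"`, `"falff"`, `"cica"`.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(sigmas = c(0.5, 0.6, 0.7),
                            fc_band = band_spec(0.01, 0.1),
                            reho_hops = c(2L, 4L),
                            reho_band = band_spec(0.01, 0.1),
                            falff_low = band_spec(0.01, 0.05),
                            ica_lowpass_hz = 0.2,
                            smooth_fwhm_mm = 3,
                            cica = cica_config(),
                            q = 0.05, z_abs = 2,
                            families = c("graph", "reho", "falff", "cica")) {
  if (is.unsorted(sigmas, strictly = TRUE) || any(sigmas <= 0) || any(sigmas >= 1)) {
    stop("sigmas must be strictly ascending values in (0, 1)")
  }
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  families <- match.arg(families, several.ok = TRUE)
  structure(list(sigmas = sigmas, fc_band = fc_band,
                 reho_hops = as.integer(reho_hops), reho_band = reho_band,
                 falff_low = falff_low, ica_lowpass_hz = ica_lowpass_hz,
                 smooth_fwhm_mm = smooth_fwhm_mm, cica = cica, q = q,
                 z_abs = z_abs, families = families),
            class = "pipeline_params")
}

#' Analyze a single session
#'
#' Runs the per-session metric extraction: ROI-averaged band-passed FC and
#' its binarized graph summaries at every sigma; smoothed vertex-wise ReHo
#' and fALFF aggregated per ROI; constrained ICA with per-network
#' within-mask coherence (mean correlation between the component time
#' course and the mask vertices' low-passed time courses).
#'
#' @param series [vertex_series()].
#' @param mesh `surface_mesh`.
#' @param parc [parcellation()].
#' @param refs [reference_set()] (required for the cica family).
#' @param network_masks list of logical vertex masks, one per reference.
#' @param roi_networks integer vector mapping each ROI to its network
#'   (required for the cica family).
#' @param params [pipeline_params()].
#' @param cache optional environment for study-level precomputations
#'   (smoothing operator, neighbourhoods), reused across sessions.
#' @return list with data.frames `global`, `rich` (long k/phi), `nodal`,
#'   `reho`, `falff`, `coherence`.
#' @export
analyze_session <- function(series, mesh, parc, refs = NULL,
                            network_masks = NULL, roi_networks = NULL,
                            params = pipeline_params(), cache = NULL) {
  stopifnot(inherits(series, "vertex_series"), inherits(mesh, "surface_mesh"),
            inherits(parc, "parcellation"))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  fam <- params$families
  out <- list()

  if ("graph" %in% fam) {
    parcels <- bandpass(roi_average(series, parc), params$fc_band)
    fc <- compute_fc(parcels)
    g_rows <- list(); rc_rows <- list(); nd_rows <- list()
    for (sg in params$sigmas) {
      g <- binarize(fc, sg)
      g_rows[[length(g_rows) + 1L]] <- data.frame(
        sigma = sg, edge_density = edge_density(g),
        global_efficiency = global_efficiency(g),
        local_efficiency = local_efficiency(g))
      phi <- rich_club_curve(g)
      rc_rows[[length(rc_rows) + 1L]] <- data.frame(
        sigma = sg, k = seq_along(phi) - 1L, phi = as.numeric(phi))
      nd <- nodal_metrics(g)
      nd$sigma <- sg
      nd_rows[[length(nd_rows) + 1L]] <- nd
    }
    out$global <- do.call(rbind, g_rows)
    out$rich <- do.call(rbind, rc_rows)
    out$nodal <- do.call(rbind, nd_rows)
  }

  needs_vertexwise <- any(c("reho", "falff", "cica") %in% fam)
  if (needs_vertexwise && params$smooth_fwhm_mm > 0) {
    if (is.null(cache$smooth_op)) {
      cache$smooth_op <- smoothing_operator(mesh, params$smooth_fwhm_mm)
    }
    series <- smooth_surface(series, mesh, operator = cache$smooth_op)
  }

  if ("reho" %in% fam) {
    filtered <- bandpass(series, params$reho_band)
    rows <- list()
    for (h in params$reho_hops) {
      key <- paste0("hoods", h)
      if (is.null(cache[[key]])) cache[[key]] <- khop_neighborhoods(mesh, h)
      map <- reho_map_from_filtered(filtered, cache[[key]])
      rows[[length(rows) + 1L]] <- data.frame(
        hops = h, roi = seq_len(parc$n_rois),
        reho = as.numeric(rowsum(map$values, parc$labels) /
                            tabulate(parc$labels, parc$n_rois)))
    }
    out$reho <- do.call(rbind, rows)
  }

  if ("falff" %in% fam) {
    map <- falff_map(series, params$falff_low)
    out$falff <- data.frame(
      roi = seq_len(parc$n_rois),
      falff = as.numeric(rowsum(map$values, parc$labels) /
                           tabulate(parc$labels, parc$n_rois)))
  }

  if ("cica" %in% fam) {
    if (is.null(refs) || is.null(network_masks) || is.null(roi_networks)) {
      stop("the cica family needs references, network masks and roi_networks")
    }
    lp <- lowpass(series, params$ica_lowpass_hz)
    fit <- fit_cica(lp, refs, params$cica)
    # within-network coherence: how strongly the network's vertices follow
    # the component's time course
    coh <- vapply(seq_len(refs$n_components), function(j) {
      mean(stats::cor(t(lp$data[network_masks[[j]], , drop = FALSE]),
                      fit$timecourses[j, ]))
    }, numeric(1))
    mask_frac <- vapply(seq_len(refs$n_components), function(j) {
      mean(threshold_zmap(fit$spatial_zmaps[j, ], params$z_abs)[network_masks[[j]]])
    }, numeric(1))
    out$coherence <- data.frame(
      network = seq_len(refs$n_components), coherence = coh,
      mask_fraction = mask_frac,
      similarity = fit$similarity, converged = fit$converged)
  }
  out
}

# ReHo from an already-filtered series with precomputed neighbourhoods
reho_map_from_filtered <- function(series, hoods) {
  x <- series$data
  n_t <- ncol(x)
  xc <- x - rowMeans(x)
  sds <- sqrt(rowSums(xc^2) / (n_t - 1))
  degenerate <- sds == 0
  xs <- xc / ifelse(degenerate, 1, sds)
  xs[degenerate, ] <- 0
  cmat <- tcrossprod(xs) / (n_t - 1)
  vals <- vapply(seq_along(hoods), function(v) {
    if (degenerate[v]) return(0)
    nb <- hoods[[v]]
    nb <- nb[!degenerate[nb]]
    m <- length(nb)
    if (m < 2L) return(0)
    (sum(cmat[nb, nb]) - m) / (m * (m - 1))
  }, numeric(1))
  vertex_map(pmin(1, pmax(-1, vals)), "reho")
}

#' Analyze every session of a study
#'
#' @param study [make_study()] result (or a study loaded with
#'   [load_study()]).
#' @param params [pipeline_params()].
#' @param subjects subject subset (default all).
#' @param conditions condition subset (default all).
#' @param progress print one line per session.
#' @return object of class `study_results`: long data.frames `global`,
#'   `rich`, `nodal`, `reho`, `falff`, `coherence` (each with `subject`
#'   and `condition` columns), plus `params` and the study's side effects.
#' @export
analyze_study <- function(study, params = pipeline_params(),
                          subjects = NULL, conditions = NULL,
                          progress = FALSE) {
  stopifnot(inherits(study, "study_dataset"))
  if (is.null(subjects)) subjects <- seq_len(study$config$n_subjects)
  if (is.null(conditions)) conditions <- names(study$config$conditions)
  cache <- new.env(parent = emptyenv())
  acc <- list()
  for (cn in conditions) {
    for (s in subjects) {
      if (progress) message(sprintf("analyzing subject %d, condition %s", s, cn))
      res <- analyze_session(get_session(study, s, cn), study$mesh,
                             study$parcellation, study$references,
                             study$network_masks, study$roi_networks,
                             params, cache)
      for (nm in names(res)) {
        df <- res[[nm]]
        df$subject <- s
        df$condition <- cn
        acc[[nm]][[length(acc[[nm]]) + 1L]] <- df
      }
    }
  }
  out <- lapply(acc, function(lst) do.call(rbind, lst))
  out$params <- params
  out$side_effects <- study$side_effects
  out$conditions <- conditions
  out$n_networks <- study$config$n_networks
  class(out) <- "study_results"
  out
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("study_results: conditions %s; families %s\n",
              paste(x$conditions, collapse = ", "),
              paste(intersect(names(x), c("global", "reho", "falff", "coherence")),
                    collapse = ", ")))
  invisible(x)
}

#' Pairwise condition comparison with family-wise FDR
#'
#' Paired t-tests (condition a minus condition b, within subject) for every
#' metric of every computed family, with Benjamini-Hochberg FDR applied
#' within each family:
#' * `global` — edge density, global and local efficiency at every sigma;
#' * `rich_club` — the PCA-loading test of the per-subject rich-club curves
#'   at every sigma, on the shared `max_common_k` grid;
#' * `reho_h<hops>` — per-ROI mean ReHo, one family per neighbourhood
#'   radius;
#' * `falff` — per-ROI mean fALFF;
#' * `coherence` — per-network within-mask component coherence;
#' * `nodal_degree` / `nodal_efficiency` / `nodal_betweenness` — per-ROI
#'   nodal metrics at the middle sigma.
#'
#' @param results [analyze_study()] output.
#' @param cond_a,cond_b condition names; positive t means larger in
#'   `cond_a`.
#' @param q FDR level (default from the results' params).
#' @return data.frame with columns `family`, `metric`, `unit`, `t`, `df`,
#'   `p`, `effect_size`, `significant_after_fdr`, `extra` (PC1 explained
#'   variance for rich-club rows).
#' @export
compare_conditions <- function(results, cond_a, cond_b, q = NULL) {
  stopifnot(inherits(results, "study_results"))
  if (is.null(q)) q <- results$params$q
  rows <- list()
  add <- function(family, metric, unit, res, extra = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, metric = metric, unit = as.character(unit),
      t = res$t, df = res$df, p = res$p, effect_size = res$effect_size,
      extra = extra)
  }
  pair_vals <- function(df, value_col, by_cols) {
    a <- df[df$condition == cond_a, ]
    b <- df[df$condition == cond_b, ]
    key <- function(d) do.call(paste, c(d[by_cols], list(d$subject), sep = "_"))
    b <- b[match(key(a), key(b)), ]
    list(a = a[[value_col]], b = b[[value_col]], meta = a[by_cols],
         subject = a$subject)
  }

  if (!is.null(results$global)) {
    df <- results$global
    for (sg in unique(df$sigma)) {
      for (m in c("edge_density", "global_efficiency", "local_efficiency")) {
        sub <- df[df$sigma == sg, c("subject", "condition", m)]
        pv <- pair_vals(sub, m, character(0))
        add("global", m, sprintf("sigma=%.2f", sg), paired_t_safe(pv$a, pv$b))
      }
    }
    rc <- results$rich
    for (sg in unique(rc$sigma)) {
      sub <- rc[rc$sigma == sg & rc$condition %in% c(cond_a, cond_b), ]
      # shared defined-k grid across both conditions' subjects
      per <- split(sub, list(sub$condition, sub$subject), drop = TRUE)
      kmax <- min(vapply(per, function(d) {
        def <- d$k[!is.na(d$phi)]
        if (length(def) == 0L) -1L else max(def)
      }, integer(1)))
      if (kmax >= 1L) {
        grab <- function(cond) {
          d <- sub[sub$condition == cond & sub$k <= kmax, ]
          m <- tapply(d$phi,
                      list(factor(d$subject), factor(d$k, levels = 0:kmax)),
                      function(v) v[1L])
          rich_club_curves(m[order(as.integer(rownames(m))), , drop = FALSE],
                           0:kmax)
        }
        res <- rich_club_pca_test(grab(cond_a), grab(cond_b))
        add("rich_club", "pc1_loading", sprintf("sigma=%.2f", sg), res,
            extra = res$explained_variance)
      }
    }
    nd <- results$nodal
    mid <- sort(unique(nd$sigma))[ceiling(length(unique(nd$sigma)) / 2)]
    nd <- nd[nd$sigma == mid, ]
    for (m in c("degree", "efficiency", "betweenness")) {
      for (node in unique(nd$node)) {
        sub <- nd[nd$node == node, c("subject", "condition", m)]
        pv <- pair_vals(sub, m, character(0))
        add(paste0("nodal_", m), m,
            sprintf("roi=%d,sigma=%.2f", node, mid), paired_t_safe(pv$a, pv$b))
      }
    }
  }

  if (!is.null(results$reho)) {
    for (h in unique(results$reho$hops)) {
      sub <- results$reho[results$reho$hops == h, ]
      for (roi in unique(sub$roi)) {
        s2 <- sub[sub$roi == roi, c("subject", "condition", "reho")]
        pv <- pair_vals(s2, "reho", character(0))
        add(sprintf("reho_h%d", h), "reho", sprintf("roi=%d", roi),
            paired_t_safe(pv$a, pv$b))
      }
    }
  }

  if (!is.null(results$falff)) {
    for (roi in unique(results$falff$roi)) {
      sub <- results$falff[results$falff$roi == roi,
                           c("subject", "condition", "falff")]
      pv <- pair_vals(sub, "falff", character(0))
      add("falff", "falff", sprintf("roi=%d", roi), paired_t_safe(pv$a, pv$b))
    }
  }

  if (!is.null(results$coherence)) {
    for (net in unique(results$coherence$network)) {
      sub <- results$coherence[results$coherence$network == net,
                               c("subject", "condition", "coherence")]
      pv <- pair_vals(sub, "coherence", character(0))
      add("coherence", "coherence", sprintf("network=%d", net),
          paired_t_safe(pv$a, pv$b))
    }
  }

  out <- do.call(rbind, rows)
  out$condition_a <- cond_a
  out$condition_b <- cond_b
  out$significant_after_fdr <- FALSE
  for (f in unique(out$family)) {
    sel <- out$family == f
    out$significant_after_fdr[sel] <- fdr_bh(out$p[sel], q)
  }
  out[, c("family", "metric", "unit", "condition_a", "condition_b",
          "t", "df", "p", "effect_size", "significant_after_fdr", "extra")]
}

#' Compare every condition against placebo and baseline
#'
#' @param results [analyze_study()] output.
#' @param reference_conditions conditions each other condition is compared
#'   against.
#' @param q FDR level.
#' @return data.frame of stacked [compare_conditions()] tables.
#' @export
compare_all <- function(results, reference_conditions = c("placebo", "baseline"),
                        q = NULL) {
  conds <- results$conditions
  refs <- intersect(reference_conditions, conds)
  # reference conditions (placebo, then baseline) sort to the b side
  refness <- function(cn) {
    r <- match(cn, rev(refs))
    if (is.na(r)) 0L else r
  }
  tabs <- list()
  for (i in seq_along(conds)) {
    for (j in seq_along(conds)) {
      if (i >= j) next
      a <- conds[i]
      b <- conds[j]
      if (refness(a) > refness(b)) {
        tmp <- a; a <- b; b <- tmp
      }
      tabs[[length(tabs) + 1L]] <- compare_conditions(results, a, b, q)
    }
  }
  do.call(rbind, tabs)
}

#' Write study results as TSV tables
#'
#' @param results [analyze_study()] output.
#' @param dir output directory.
#' @export
write_results_tsvs <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in intersect(names(results),
                       c("global", "rich", "nodal", "reho", "falff",
                         "coherence"))) {
    utils::write.table(results[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Run the complete study pipeline
#'
#' Simulate (or accept) a study, analyze every session, compare all
#' conditions against placebo and baseline (imaging metrics and side
#' effects), and write every table plus a JSON manifest. Deterministic:
#' rerunning with the same inputs reproduces identical outputs.
#'
#' @param study a [make_study()] result, or a [study_config()] (the study
#'   is then generated with `seed`).
#' @param out_dir output directory.
#' @param params [pipeline_params()].
#' @param seed master seed, used when `study` is a config.
#' @return invisibly, a list with `results`, `comparisons`,
#'   `side_effect_comparisons`.
#' @export
run_all <- function(study, out_dir, params = pipeline_params(), seed = 1L) {
  if (inherits(study, "study_config")) study <- make_study(study, seed)
  stopifnot(inherits(study, "study_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- analyze_study(study, params)
  write_results_tsvs(results, out_dir)
  comparisons <- compare_all(results, q = params$q)
  utils::write.table(comparisons, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  se <- side_effect_comparison(study$side_effects, q = params$q)
  utils::write.table(se, file.path(out_dir, "side_effect_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "sedconn",
    version = as.character(utils::packageVersion("sedconn")),
    seed = study$seed,
    n_subjects = study$config$n_subjects,
    conditions = names(study$config$conditions),
    n_timepoints = study$config$n_timepoints, dt = study$config$dt,
    sigmas = params$sigmas, reho_hops = params$reho_hops,
    fc_band = unclass(params$fc_band), falff_low = unclass(params$falff_low),
    ica_lowpass_hz = params$ica_lowpass_hz,
    smooth_fwhm_mm = params$smooth_fwhm_mm,
    fdr_q = params$q, z_abs = params$z_abs,
    families = params$families)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, comparisons = comparisons,
                 side_effect_comparisons = se))
}

#' Simulate a two-condition study and compare the conditions
#'
#' Convenience driver for validation experiments: builds a study with the
#' two given condition profiles, analyzes every session and returns the
#' pairwise comparison table (positive t means larger under `profile_a`).
#'
#' @param seed master seed.
#' @param profile_a,profile_b [condition_profile()]s for the test and
#'   control conditions.
#' @param config_args named list of [study_config()] overrides.
#' @param params [pipeline_params()].
#' @return [compare_conditions()] data.frame.
#' @export
simulate_and_compare <- function(seed,
                                 profile_a = profile_sedation(),
                                 profile_b = profile_placebo(),
                                 config_args = list(),
                                 params = pipeline_params()) {
  cfg <- do.call(study_config,
                 c(list(conditions = list(drug = profile_a,
                                          placebo = profile_b)),
                   config_args))
  study <- make_study(cfg, seed)
  res <- analyze_study(study, params)
  compare_conditions(res, "drug", "placebo", params$q)
}
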