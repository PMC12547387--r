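# End-to-end pipeline: simulate/load -> smooth -> nuisance -> first level ->
# jackknife -> group + thresholds -> ROI profiles.

#' Reconstruct a run design from an event table
#'
#' The acquisition schedule is protocol-determined; block onsets, durations
#' and conditions come from the events file. Lets the pipeline analyse runs
#' from a written cohort without regenerating them.
#'
#' @param events Data.frame from [read_events()].
#' @param protocol A [sparse_protocol()].
#' @return A `run_design`.
#' @export
design_from_events <- function(events, protocol = sparse_protocol()) {
  p <- protocol
  n_cycles <- nrow(events)
  period <- p$gap_s + p$cluster_volumes * p$volume_spacing_s
  gap_start <- (seq_len(n_cycles) - 1) * period
  blocks <- data.frame(onset_s = events$onset, duration_s = events$duration,
                       condition = events$trial_type,
                       main_category = events$main_category,
                       jitter_s = events$onset - gap_start,
                       stringsAsFactors = FALSE)
  schedule <- data.frame(cluster = seq_len(n_cycles),
                         start_time_s = gap_start + p$gap_s,
                         n_volumes = p$cluster_volumes,
                         volume_spacing_s = p$volume_spacing_s)
  vt <- as.vector(t(outer(schedule$start_time_s,
                          (seq_len(p$cluster_volumes) - 1) *
                            p$volume_spacing_s, "+")))
  structure(list(schedule = schedule, blocks = blocks, volume_times_s = vt,
                 n_volumes = length(vt), run_duration_s = n_cycles * period,
                 protocol = p, seed = NA_integer_),
            class = "run_design")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages on a simulated (or previously written)
#' cohort: spatial smoothing; eroded white-matter/CSF PCA covariates with
#' optional per-subject component-count optimisation; per-run GLMs (a
#' 2-category model for the Sound-vs-Silence and Macaque-vs-NonVocal
#' contrasts, an 8-subcategory model for ROI profiles); subject-level
#' fixed-effects combination; jackknife run selection on the
#' Macaque-vs-NonVocal contrast; fixed- and random-effects group maps with
#' GRF peak and cluster-extent correction; per-subject peak-t/extent
#' summaries in the A1-like and IC-like fields; and ROI subcategory
#' profiles.
#'
#' @param config A [pipeline_config()].
#' @param atlas Optional `tissue_atlas` (default: phantom from the config).
#' @param manifest Optional manifest of an existing cohort; when `NULL` a
#'   cohort is simulated into `out_dir`.
#' @param out_dir Directory for the simulated cohort (default: a session
#'   temporary directory).
#' @param truth Optional [ground_truth()] for simulation.
#' @param verbose Print stage progress.
#' @return A report bundle (list) stamped with the config hash and seed.
#' @export
run_pipeline <- function(config = pipeline_config(), atlas = NULL,
                         manifest = NULL, out_dir = NULL,
                         truth = ground_truth(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  if (is.null(atlas))
    atlas <- make_phantom(volume_grid(config$grid_dims,
                                      config$voxel_size_mm))
  grid <- atlas$grid
  protocol <- do.call(sparse_protocol, config$protocol)
  rf <- do.call(mion_rf, config$rf)
  if (is.null(manifest)) {
    if (is.null(out_dir))
      out_dir <- file.path(tempdir(), sprintf("cohort_%s",
                                              config_hash(config)))
    say("simulating cohort (%d subjects) into %s", config$n_subjects,
        out_dir)
    manifest <- simulate_cohort(config$n_subjects, config$runs_per_subject,
                                atlas, truth, rf, protocol,
                                seed = config$seed, out_dir = out_dir)
  }
  brain <- atlas_mask(atlas, "brain")
  wm_ero <- erode_mask(atlas_mask(atlas, "white"), config$erosion_kernel_mm,
                       grid)
  csf_ero <- erode_mask(atlas_mask(atlas, "csf"), config$erosion_kernel_mm,
                        grid)
  kmax <- max(config$nuisance$k_white_grid, config$nuisance$k_csf_grid,
              config$nuisance$k_white, config$nuisance$k_csf)

  subjects <- unique(manifest$subject_id)
  subj_maps <- list()   # per subject: svs, mvn, subcat maps, run-level mvn
  choices <- list()
  for (sid in subjects) {
    rows <- which(manifest$subject_id == sid)
    say("subject %s: %d runs", sid, length(rows))
    runs <- lapply(rows, function(i) {
      vol <- read_volume(manifest$image[i], expect_4d = TRUE)
      ev <- read_events(manifest$events[i])
      design <- design_from_events(ev, protocol)
      img <- structure(list(data = vol$data,
                            timestamps_s = design$volume_times_s,
                            grid = vol$grid,
                            subject_id = sid, run_id = manifest$run_id[i],
                            seed = manifest$seed[i]), class = "run_image")
      smoothed <- smooth_volumes(img, config$smoothing_fwhm_mm)
      list(run_id = manifest$run_id[i], design = design, image = smoothed,
           task2 = build_task_regressors(design, rf, "main_category"),
           task8 = build_task_regressors(design, rf, "subcategory"),
           wm_pcs = compute_pcs(img, wm_ero, kmax, "white")$components,
           csf_pcs = compute_pcs(img, csf_ero, kmax, "csf")$components)
    })
    if (isTRUE(config$nuisance$optimize)) {
      sel <- select_component_counts(
        lapply(runs, function(r)
          list(image = r$image, task = r$task2$X,
               timestamps = r$task2$timestamps,
               wm_pcs = r$wm_pcs, csf_pcs = r$csf_pcs)),
        brain, config$nuisance$k_white_grid, config$nuisance$k_csf_grid,
        config$drift_order, config$ar_order)
      kw <- sel$k_white; kc <- sel$k_csf
      choices[[sid]] <- sel
    } else { kw <- config$nuisance$k_white; kc <- config$nuisance$k_csf }
    per_run <- lapply(runs, function(r) {
      nuis <- cbind(r$wm_pcs[, seq_len(kw), drop = FALSE],
                    r$csf_pcs[, seq_len(kc), drop = FALSE])
      if (!ncol(nuis)) nuis <- NULL
      dm2 <- assemble_design_matrix(r$task2, drift_order = config$drift_order,
                                    nuisance = nuis)
      fit2 <- fit_run_glm(r$image, dm2, config$ar_order)
      dm8 <- assemble_design_matrix(r$task8, drift_order = config$drift_order,
                                    nuisance = nuis)
      fit8 <- fit_run_glm(r$image, dm8, config$ar_order)
      list(run_id = r$run_id,
           svs = compute_contrast(fit2, sound_vs_silence_weights(dm2),
                                  "sound_vs_silence"),
           mvn = compute_contrast(fit2, macaque_vs_nonvocal_weights(dm2),
                                  "macaque_vs_nonvocal"),
           subcat = {
             k <- sum(dm8$meta$kind == "task")
             nm <- dm8$meta$name[dm8$meta$kind == "task"]
             stats::setNames(lapply(seq_len(k), function(j)
               compute_contrast(fit8, as.numeric(seq_len(k) == j), nm[j])),
               nm)
           })
    })
    names(per_run) <- vapply(per_run, function(r) r$run_id, character(1))
    subj_maps[[sid]] <- list(
      run_mvn = lapply(per_run, function(r) r$mvn),
      svs = combine_runs(lapply(per_run, function(r) r$svs)),
      mvn_all = combine_runs(lapply(per_run, function(r) r$mvn)),
      subcat = {
        nm <- names(per_run[[1]]$subcat)
        stats::setNames(lapply(nm, function(cn)
          combine_runs(lapply(per_run, function(r) r$subcat[[cn]]))), nm)
      })
  }

  # jackknife run selection on Macaque-vs-NonVocal
  reports <- NULL
  selected_manifest <- manifest
  if (isTRUE(config$jackknife)) {
    say("jackknife run selection")
    reports <- lapply(subjects, function(sid)
      jackknife_select(subj_maps[[sid]]$run_mvn, brain, sid,
                       "macaque_vs_nonvocal"))
    selected_manifest <- apply_selection(manifest, reports)
    for (sid in subjects) {
      kept <- reports[[match(sid, subjects)]]$selected
      subj_maps[[sid]]$mvn_sel <-
        if (length(kept)) combine_runs(subj_maps[[sid]]$run_mvn[kept])
        else NULL
    }
  } else {
    for (sid in subjects) subj_maps[[sid]]$mvn_sel <- subj_maps[[sid]]$mvn_all
  }

  say("group maps and thresholds")
  svs_subj <- lapply(subj_maps, function(s) s$svs)
  mvn_subj <- Filter(Negate(is.null), lapply(subj_maps, function(s) s$mvn_sel))
  smooth_est <- estimate_smoothness(mask = brain, grid = grid,
                                    fwhm_mm = max(config$smoothing_fwhm_mm,
                                                  grid$voxel_size_mm))
  th <- config$thresholds
  group <- list(
    svs_fixed = fixed_effects_group(svs_subj),
    svs_random = if (length(svs_subj) >= 3) random_effects_group(svs_subj),
    mvn_fixed = if (length(mvn_subj) >= 2) fixed_effects_group(mvn_subj),
    mvn_random = if (length(mvn_subj) >= 3) random_effects_group(mvn_subj))
  thresh <- lapply(Filter(Negate(is.null), group), function(gmap)
    cluster_correct(map_volume(gmap), brain, smooth_est, gmap$df,
                    th$cluster_forming_p, th$alpha, th$connectivity,
                    th$gaussian_limit))
  t_c <- thresh[[1]]$cluster_forming_t

  # per-subject peak t and significant extent in auditory fields
  table1 <- do.call(rbind, lapply(subjects, function(sid) {
    tv <- map_volume(subj_maps[[sid]]$svs)
    do.call(rbind, lapply(c("A1", "IC"), function(fld) {
      msk <- if (fld == "A1")
        atlas_mask(atlas, "A1-like-left") | atlas_mask(atlas, "A1-like-right")
      else atlas_mask(atlas, "IC-like")
      data.frame(subject_id = sid, field = fld,
                 peak_t = max(tv[msk], na.rm = TRUE),
                 n_sig_voxels = sum(tv[msk] > t_c, na.rm = TRUE))
    }))
  }))

  say("ROI profiles")
  sig_masks <- lapply(subj_maps, function(s)
    array(s$svs$t > t_c & as.vector(brain), grid$dims))
  rois <- try(define_rois(atlas,
                          group$svs_random %||% group$svs_fixed,
                          group$mvn_fixed %||% group$svs_fixed,
                          sig_masks, config$roi$diameter_mm), silent = TRUE)
  profiles <- NULL
  if (!inherits(rois, "try-error") && length(subjects) >= 2) {
    profiles <- lapply(rois$group, function(roi)
      group_profile(lapply(subj_maps, function(s)
        extract_profile(s$subcat, roi, config$roi$statistic)), roi$name))
    a1 <- lapply(seq_along(subjects), function(i) {
      s <- subj_maps[[i]]
      colMeans(rbind(
        extract_profile(s$subcat, rois$subject[[i]][["A1-like-left"]],
                        config$roi$statistic),
        extract_profile(s$subcat, rois$subject[[i]][["A1-like-right"]],
                        config$roi$statistic)))
    })
    profiles[["A1-like"]] <- group_profile(a1, "A1-like")
  }

  say("done in %.1f s",
      as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  list(config = config, config_hash = config_hash(config),
       seed = config$seed, manifest = manifest,
       selected_manifest = selected_manifest,
       component_choices = choices, subject_maps = subj_maps,
       jackknife = reports, group = group, thresholds = thresh,
       smoothness = smooth_est, table1 = table1, rois = rois,
       profiles = profiles)
}
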