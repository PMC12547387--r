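# Jackknife leave-one-run-out selection of positively contributing runs.

#' Whole-brain maximum t of a combined run subset
#'
#' Combines the given run-level contrast maps into a subject-level
#' fixed-effects map and returns the maximum t inside the mask. No
#' topographical constraint beyond the mask is applied.
#'
#' @param maps Non-empty list of `contrast_map`s.
#' @param mask Logical array (or voxel index vector) defining the brain.
#' @param combine_fn Combination function (default [combine_runs()]).
#' @return Scalar maximum t.
#' @export
subject_max_t <- function(maps, mask, combine_fn = combine_runs) {
  if (!length(maps)) stop("empty run subset")
  combined <- combine_fn(maps)
  vox <- if (is.logical(mask) || !is.null(dim(mask))) which(mask > 0)
         else as.integer(mask)
  max(combined$t[vox], na.rm = TRUE)
}

#' Jackknife run selection
#'
#' Computes the subject's whole-brain maximum t with all runs (`T_all`),
#' then with each run left out (`T_minus_r`). A run is kept iff removing it
#' *lowers* the maximum (`T_minus_r < T_all`, strict), i.e. iff it
#' contributes positively to the contrast. Exactly `n + 1` subject-level
#' combinations are performed for `n` runs.
#'
#' @param run_maps Named list of run-level `contrast_map`s (>= 2 runs; with
#'   a single run it is kept and a warning is raised).
#' @param mask Whole-brain mask for the maximum.
#' @param subject_id,contrast Bookkeeping labels for the report.
#' @param combine_fn Combination function (default [combine_runs()]).
#' @return An object of class `jackknife_report`: `T_all`, per-run
#'   `T_minus_r`, `delta = T_all - T_minus_r`, `keep`, `selected`.
#' @export
jackknife_select <- function(run_maps, mask, subject_id = NA_character_,
                             contrast = NA_character_,
                             combine_fn = combine_runs) {
  n <- length(run_maps)
  if (n == 0) stop("no runs")
  ids <- names(run_maps) %||% sprintf("run-%02d", seq_len(n))
  if (is.null(names(run_maps))) names(run_maps) <- ids
  if (n == 1) {
    warning("single run: jackknife not applicable, run kept")
    tab <- data.frame(run = ids, T_minus_r = NA_real_, delta = NA_real_,
                      keep = TRUE, stringsAsFactors = FALSE)
    return(structure(list(subject_id = subject_id, contrast = contrast,
                          T_all = subject_max_t(run_maps, mask, combine_fn),
                          runs = tab, selected = ids),
                     class = "jackknife_report"))
  }
  T_all <- subject_max_t(run_maps, mask, combine_fn)
  T_minus <- vapply(seq_len(n), function(r)
    subject_max_t(run_maps[-r], mask, combine_fn), numeric(1))
  keep <- T_minus < T_all
  tab <- data.frame(run = ids, T_minus_r = T_minus, delta = T_all - T_minus,
                    keep = keep, stringsAsFactors = FALSE)
  structure(list(subject_id = subject_id, contrast = contrast, T_all = T_all,
                 runs = tab, selected = ids[keep]),
            class = "jackknife_report")
}

#' @export
print.jackknife_report <- function(x, ...) {
  cat(sprintf("<jackknife_report> %s%s: T_all = %.3f, %d/%d runs kept\n",
              x$subject_id,
              if (is.na(x$contrast)) "" else paste0(" (", x$contrast, ")"),
              x$T_all, length(x$selected), nrow(x$runs)))
  print(x$runs, row.names = FALSE)
  invisible(x)
}

#' Write a jackknife report as tab-separated text
#' @param report A `jackknife_report`.
#' @param path Output path.
#' @export
write_jackknife_report <- function(report, path) {
  tab <- cbind(subject_id = report$subject_id, contrast = report$contrast,
               T_all = report$T_all, report$runs)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a cohort manifest by jackknife reports
#'
#' Keeps only runs flagged as positive contributors. A subject whose every
#' run is dropped is retained in the cohort with zero runs (and a warning),
#' which excludes it from group maps.
#'
#' @param manifest Cohort manifest data.frame (one row per run).
#' @param reports List of `jackknife_report`s, one per subject.
#' @return The filtered manifest, with attributes `total_runs` and
#'   `median_runs_per_subject`.
#' @export
apply_selection <- function(manifest, reports) {
  subs <- vapply(reports, function(r) r$subject_id, character(1))
  if (anyDuplicated(subs)) stop("multiple reports for one subject")
  missing <- setdiff(unique(manifest$subject_id), subs)
  if (length(missing))
    stop(sprintf("no jackknife report for subject(s): %s",
                 paste(missing, collapse = ", ")))
  keep <- logical(nrow(manifest))
  for (r in reports) {
    rows <- manifest$subject_id == r$subject_id
    keep[rows] <- manifest$run_id[rows] %in% r$selected
    if (!any(keep[rows]))
      warning(sprintf("subject %s retains zero runs after selection",
                      r$subject_id))
  }
  out <- manifest[keep, , drop = FALSE]
  kept_counts <- table(factor(out$subject_id,
                              levels = unique(manifest$subject_id)))
  attr(out, "total_runs") <- nrow(out)
  attr(out, "median_runs_per_subject") <- stats::median(as.integer(kept_counts))
  out
}
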