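# Reversed-sign contrast-agent response function and design-matrix assembly.

#' Reversed-sign MION/CBV response function
#'
#' A sign-flipped gamma-variate impulse response for blood-pool contrast-agent
#' (MION) fMRI, where activation increases cerebral blood volume and therefore
#' *decreases* the measured signal: `h(t) = -c (t/theta)^(k-1) exp(-t/theta)`.
#' The functional form guarantees a single extremum at `t = (k-1) theta`, no
#' undershoot (h never crosses zero), and a long monotone tail. The constant
#' `c > 0` is fixed by the normalization mode: `"peak"` makes the sampled
#' minimum exactly -1; `"area"` makes the kernel integrate to -1.
#'
#' @param k Shape parameter (> 1, dimensionless).
#' @param theta Timescale in seconds (> 0).
#' @param duration_s Support length in seconds (>= 5 * (k - 1) * theta).
#' @param normalization `"peak"` or `"area"`.
#' @param step_s Sampling step of the kernel grid (<= 0.05 s).
#' @return An object of class `mion_rf` with fields `t`, `h` and parameters.
#' @export
mion_rf <- function(k = 3, theta = 4, duration_s = 60,
                    normalization = c("peak", "area"), step_s = 0.01) {
  normalization <- match.arg(normalization)
  if (!is.numeric(k) || k <= 1) stop("`k` must be > 1")
  if (!is.numeric(theta) || theta <= 0) stop("`theta` must be > 0")
  if (step_s <= 0 || step_s > 0.05) stop("`step_s` must be in (0, 0.05]")
  if (duration_s < 5 * (k - 1) * theta)
    stop("`duration_s` must be at least 5 * (k - 1) * theta to cover the tail")
  t <- seq(0, duration_s, by = step_s)
  g <- (t / theta)^(k - 1) * exp(-t / theta)
  h <- if (normalization == "peak") -g / max(g) else -g / (sum(g) * step_s)
  structure(list(t = t, h = h, k = k, theta = theta, duration_s = duration_s,
                 normalization = normalization, step_s = step_s,
                 peak_time_s = (k - 1) * theta),
            class = "mion_rf")
}

#' @export
print.mion_rf <- function(x, ...) {
  cat(sprintf(paste0("<mion_rf> reversed-sign gamma kernel: k = %.3g, ",
                     "theta = %.3g s, peak at %.3g s, %s-normalized, ",
                     "%g s support\n"),
              x$k, x$theta, x$peak_time_s, x$normalization, x$duration_s))
  invisible(x)
}

#' @export
plot.mion_rf <- function(x, ...) {
  graphics::plot(x$t, x$h, type = "l", xlab = "time (s)",
                 ylab = "response", main = "MION response function", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Build task regressors sampled at the acquisition times
#'
#' For each condition a boxcar (1 during its blocks) on a fine grid is
#' convolved with the response function and evaluated at each acquired
#' volume's timestamp, as required by the non-uniform clustered sparse
#' sampling. Silence is the implicit baseline and receives no column.
#'
#' @param design A [make_run_design()] result.
#' @param rf A [mion_rf()] kernel.
#' @param conditions Character vector of condition labels to model, or a
#'   level keyword: `"subcategory"` (default, 8 columns) or
#'   `"main_category"` (2 columns).
#' @return A list with `X` (n_volumes x n_conditions matrix, named columns),
#'   `timestamps` and `categories` (main-category of each column).
#' @export
build_task_regressors <- function(design, rf,
                                  conditions = "subcategory") {
  stopifnot(inherits(design, "run_design"), inherits(rf, "mion_rf"))
  blocks <- design$blocks
  sub <- subcategory_table()
  if (length(conditions) == 1 && conditions %in% c("subcategory",
                                                   "main_category")) {
    lvl <- conditions
    conditions <- if (lvl == "subcategory") sub$subcategory
                  else unique(sub$main_category)
  } else {
    lvl <- if (all(conditions %in% sub$subcategory)) "subcategory"
           else if (all(conditions %in% sub$main_category)) "main_category"
           else stop("`conditions` must be subcategory or main-category labels")
  }
  key <- if (lvl == "subcategory") blocks$condition else blocks$main_category
  step <- rf$step_s
  n_fine <- ceiling(design$run_duration_s / step) + 2
  X <- matrix(0, design$n_volumes, length(conditions),
              dimnames = list(NULL, conditions))
  # linear interpolation of the fine-grid regressor at the volume times
  pos <- design$volume_times_s / step + 1
  lo <- pmin(floor(pos), n_fine - 1)
  frac <- pos - lo
  for (j in seq_along(conditions)) {
    rows <- which(key == conditions[j])
    if (!length(rows))
      stop(sprintf("condition '%s' has no blocks in this design",
                   conditions[j]))
    box <- boxcar_fine(blocks$onset_s[rows], blocks$duration_s[rows], step,
                       n_fine)
    r <- fine_convolve(box, rf$h) * step
    r[abs(r) < 1e-10] <- 0          # remove FFT round-off dust
    X[, j] <- r[lo] * (1 - frac) + r[lo + 1] * frac
  }
  cats <- if (lvl == "subcategory")
    sub$main_category[match(conditions, sub$subcategory)] else conditions
  list(X = X, timestamps = design$volume_times_s,
       categories = stats::setNames(cats, conditions))
}

# Boxcar on the fine grid with fractional edge weights: sample i (at time
# (i-1)*step) carries the fraction of [t_i - step/2, t_i + step/2] covered
# by any block, so the rectangle-rule convolution is second-order accurate.
boxcar_fine <- function(onsets, durations, step, n_fine) {
  box <- numeric(n_fine)
  edges <- (seq_len(n_fine) - 1) * step   # sample centers
  for (b in seq_along(onsets)) {
    a <- onsets[b]; z <- onsets[b] + durations[b]
    i0 <- max(1L, floor(a / step - 0.5) + 1L)
    i1 <- min(n_fine, ceiling(z / step + 0.5) + 1L)
    if (i0 > i1) next                 # block entirely beyond the fine grid
    idx <- i0:i1
    cover <- pmin(edges[idx] + step / 2, z) - pmax(edges[idx] - step / 2, a)
    box[idx] <- pmin(1, box[idx] + pmax(cover, 0) / step)
  }
  box
}

# Causal discrete convolution, first `length(x)` samples (FFT-based).
fine_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- stats::nextn(n, 2)
  xp <- c(x, numeric(nf - length(x)))
  hp <- c(h, numeric(nf - length(h)))
  Re(stats::fft(stats::fft(xp) * stats::fft(hp), inverse = TRUE))[
    seq_along(x)] / nf
}

#' Assemble a GLM design matrix
#'
#' Binds task columns, per-run orthogonal polynomial drift terms (including
#' the constant) and optional nuisance columns into one design matrix with
#' column metadata, and rejects rank-deficient combinations.
#'
#' @param task Matrix of task regressors (named columns), as produced by
#'   [build_task_regressors()], or the list that function returns.
#' @param timestamps Volume acquisition times (ignored if `task` is the list
#'   form, which carries them).
#' @param drift_order Polynomial drift order (0 = constant only).
#' @param nuisance Optional matrix of nuisance regressors (n rows).
#' @param categories Optional named main-category map for the task columns.
#' @return An object of class `design_matrix`: `X`, `meta` (name, kind,
#'   category), `timestamps`.
#' @export
assemble_design_matrix <- function(task, timestamps = NULL, drift_order = 3,
                                   nuisance = NULL, categories = NULL) {
  if (is.list(task) && !is.null(task$X)) {
    timestamps <- task$timestamps
    categories <- task$categories
    task <- task$X
  }
  stopifnot(is.matrix(task), !is.null(timestamps),
            nrow(task) == length(timestamps), drift_order >= 0)
  if (is.null(colnames(task)))
    colnames(task) <- sprintf("task_%d", seq_len(ncol(task)))
  if (any(colSums(abs(task)) == 0))
    stop(sprintf("all-zero task column(s): %s",
                 paste(colnames(task)[colSums(abs(task)) == 0],
                       collapse = ", ")))
  drift <- cbind(constant = rep(1, length(timestamps)))
  if (drift_order > 0) {
    P <- stats::poly(timestamps, degree = drift_order)
    colnames(P) <- sprintf("drift_%d", seq_len(drift_order))
    drift <- cbind(drift, P)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (ncol(nuisance) > 0 && nrow(nuisance) != length(timestamps))
      stop("nuisance rows must match the run's volume count")
    if (ncol(nuisance) > 0 && is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nuisance_%d", seq_len(ncol(nuisance)))
    if (ncol(nuisance) == 0) nuisance <- NULL
  }
  X <- cbind(task, drift, nuisance)
  if (anyDuplicated(colnames(X)))
    stop("design matrix column names must be unique")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; dependent column(s): %s",
                 paste(dep, collapse = ", ")))
  }
  kind <- c(rep("task", ncol(task)), rep("drift", ncol(drift)),
            if (!is.null(nuisance)) rep("nuisance", ncol(nuisance)))
  cat_col <- rep(NA_character_, ncol(X))
  if (!is.null(categories))
    cat_col[seq_len(ncol(task))] <- unname(categories[colnames(task)])
  meta <- data.frame(name = colnames(X), kind = kind, category = cat_col,
                     stringsAsFactors = FALSE)
  structure(list(X = X, meta = meta, timestamps = timestamps),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d columns (%d task, %d drift, %d nuisance)\n",
              nrow(x$X), ncol(x$X), sum(x$meta$kind == "task"),
              sum(x$meta$kind == "drift"), sum(x$meta$kind == "nuisance")))
  invisible(x)
}

#' Export a design matrix as tab-separated text
#'
#' @param design A `design_matrix`.
#' @param path Output file path.
#' @export
write_design_matrix <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  utils::write.table(cbind(timestamp_s = design$timestamps, design$X), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
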