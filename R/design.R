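# Clustered sparse-sampling acquisition schedule and block randomization.

#' Acquisition protocol parameters
#'
#' Defaults reproduce the study protocol: 48 cycles, each a 3.5 s
#' scanner-silent gap (hosting one stimulus or silent block) followed by an
#' acquisition cluster of 7 volumes spaced 646 ms apart; 32 stimulus blocks
#' (4 per subcategory) and 16 silent blocks per run; stimulus-block onsets
#' jittered 100-250 ms after the end of the preceding acquisition cluster;
#' 6 stimuli per block with a 50 ms inter-stimulus interval.
#'
#' @param n_stim_blocks,n_silent_blocks Block counts per run.
#' @param blocks_per_subcategory Stimulus blocks per subcategory.
#' @param cluster_volumes Volumes per acquisition cluster.
#' @param volume_spacing_s Acquisition time per volume (s).
#' @param gap_s Scanner-silent gap before each cluster (s).
#' @param jitter_range_s Length-2 bounds for stimulus-block onset jitter (s).
#' @param stimuli_per_block,stimulus_duration_s,isi_s Within-block structure.
#' @return A list of class `sparse_protocol`.
#' @export
sparse_protocol <- function(n_stim_blocks = 32, n_silent_blocks = 16,
                            blocks_per_subcategory = 4,
                            cluster_volumes = 7, volume_spacing_s = 0.646,
                            gap_s = 3.5, jitter_range_s = c(0.100, 0.250),
                            stimuli_per_block = 6, stimulus_duration_s = 0.5,
                            isi_s = 0.050) {
  p <- list(n_stim_blocks = n_stim_blocks, n_silent_blocks = n_silent_blocks,
            blocks_per_subcategory = blocks_per_subcategory,
            cluster_volumes = cluster_volumes,
            volume_spacing_s = volume_spacing_s, gap_s = gap_s,
            jitter_range_s = jitter_range_s,
            stimuli_per_block = stimuli_per_block,
            stimulus_duration_s = stimulus_duration_s, isi_s = isi_s)
  stopifnot(p$n_stim_blocks > 0, p$n_silent_blocks >= 0,
            p$cluster_volumes >= 1, p$volume_spacing_s > 0, p$gap_s > 0,
            length(p$jitter_range_s) == 2,
            p$jitter_range_s[1] >= 0,
            p$jitter_range_s[2] >= p$jitter_range_s[1])
  if (p$n_stim_blocks != 8 * p$blocks_per_subcategory)
    stop("n_stim_blocks must equal 8 * blocks_per_subcategory")
  structure(p, class = "sparse_protocol")
}

block_duration_s <- function(protocol) {
  protocol$stimuli_per_block * protocol$stimulus_duration_s +
    (protocol$stimuli_per_block - 1) * protocol$isi_s
}

#' Generate one run's timed block/acquisition schedule
#'
#' Each cycle is a silent gap followed by an acquisition cluster. One block
#' (stimulus or silence) is assigned to each gap; block order is a seeded
#' uniform random permutation under the per-subcategory count constraints.
#' Stimulus blocks start `jitter` seconds into the gap; the configured
#' jitter upper bound plus the block duration must fit inside the gap.
#'
#' @param seed Integer seed; the same seed always yields the same design.
#' @param protocol A [sparse_protocol()].
#' @return An object of class `run_design` with fields `schedule` (one row
#'   per acquisition cluster), `blocks` (one row per block, with onset,
#'   duration, condition, main category and jitter), `volume_times_s`,
#'   `n_volumes` and `run_duration_s`.
#' @export
make_run_design <- function(seed, protocol = sparse_protocol()) {
  p <- protocol
  bdur <- block_duration_s(p)
  if (p$jitter_range_s[2] + bdur > p$gap_s + 1e-9)
    stop(sprintf(paste0("stimulus block (%.3f s) plus maximum jitter (%.3f s) ",
                        "does not fit in the %.3f s silent gap"),
                 bdur, p$jitter_range_s[2], p$gap_s))
  subcats <- subcategory_table()
  n_cycles <- p$n_stim_blocks + p$n_silent_blocks
  cluster_len <- p$cluster_volumes * p$volume_spacing_s
  period <- p$gap_s + cluster_len

  conds <- c(rep(subcats$subcategory, each = p$blocks_per_subcategory),
             rep("silence", p$n_silent_blocks))
  stopifnot(length(conds) == n_cycles)
  ord <- with_seed(derive_seed(seed, 1L), sample.int(n_cycles))
  conds <- conds[ord]
  is_stim <- conds != "silence"
  jit <- numeric(n_cycles)
  jit[is_stim] <- with_seed(derive_seed(seed, 2L),
                            stats::runif(sum(is_stim), p$jitter_range_s[1],
                                         p$jitter_range_s[2]))
  gap_start <- (seq_len(n_cycles) - 1) * period
  onset <- gap_start + jit
  dur <- ifelse(is_stim, bdur, p$gap_s)
  mc <- subcats$main_category[match(conds, subcats$subcategory)]
  mc[!is_stim] <- "silence"

  blocks <- data.frame(onset_s = onset, duration_s = dur, condition = conds,
                       main_category = mc, jitter_s = jit,
                       stringsAsFactors = FALSE)
  schedule <- data.frame(cluster = seq_len(n_cycles),
                         start_time_s = gap_start + p$gap_s,
                         n_volumes = p$cluster_volumes,
                         volume_spacing_s = p$volume_spacing_s)
  vt <- as.vector(t(outer(schedule$start_time_s,
                          (seq_len(p$cluster_volumes) - 1) * p$volume_spacing_s,
                          "+")))
  structure(list(schedule = schedule, blocks = blocks, volume_times_s = vt,
                 n_volumes = length(vt), run_duration_s = n_cycles * period,
                 protocol = p, seed = seed),
            class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  ns <- sum(x$blocks$condition != "silence")
  cat(sprintf(paste0("<run_design> %d blocks (%d stimulus, %d silence), ",
                     "%d volumes in %d clusters, %.1f s\n"),
              nrow(x$blocks), ns, nrow(x$blocks) - ns, x$n_volumes,
              nrow(x$schedule), x$run_duration_s))
  invisible(x)
}
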