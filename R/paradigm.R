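#' Go/NoGo paradigm specification
#'
#' Defaults reproduce the mixed block/event Go-NoGo design used throughout
#' the package: two runs of 12 blocks each (6 Go, 6 NoGo, order randomized
#' per run); a Go block holds 18 Go trials (100% Go), a NoGo block holds 12
#' Go and 6 NoGo trials (66.7% / 33.3%). Trial SOA and block gap are not
#' part of the published design and default to 2 s and 10 s; they are
#' recorded in the paradigm metadata.
#'
#' @param n_runs Number of runs.
#' @param blocks_per_run Total blocks per run.
#' @param go_blocks_per_run,nogo_blocks_per_run Number of Go and NoGo blocks.
#' @param trials_per_go_block Go trials in a Go block.
#' @param go_trials_per_nogo_block,nogo_trials_per_nogo_block Composition of
#'   a NoGo block.
#' @param soa Stimulus onset asynchrony within a block (s).
#' @param block_gap Rest gap between blocks (s).
#' @param lead_in,tail Rest before the first and after the last block (s).
#' @param TR Repetition time (s).
#' @param seed Randomization seed for block order and trial positions.
#' @return Object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_runs = 2L, blocks_per_run = 12L,
                          go_blocks_per_run = 6L, nogo_blocks_per_run = 6L,
                          trials_per_go_block = 18L,
                          go_trials_per_nogo_block = 12L,
                          nogo_trials_per_nogo_block = 6L,
                          soa = 2, block_gap = 10, lead_in = 10, tail = 16,
                          TR = 2, seed = 11L) {
  stopifnot(go_blocks_per_run + nogo_blocks_per_run == blocks_per_run)
  structure(as.list(environment()), class = "paradigm_spec")
}

#' Generate a Go/NoGo session: design plus trial table
#'
#' Builds block-level Go and NoGo condition boxcars (the two model inputs)
#' and the trial-level event table. Trial counts are exact functions of the
#' specification; only block order and the positions of NoGo trials within
#' NoGo blocks are randomized (deterministically, from `spec$seed`).
#'
#' @param spec A [paradigm_spec()].
#' @return A list with `design` (an [experiment_design()]) and `trials`
#'   (data frame: `run`, `block`, `block_type`, `onset`, `duration`,
#'   `trial_type`).
#' @export
generate_paradigm <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  n_go_trials <- spec$trials_per_go_block
  n_nogo_blk <- spec$go_trials_per_nogo_block + spec$nogo_trials_per_nogo_block
  block_len_go <- n_go_trials * spec$soa
  block_len_nogo <- n_nogo_blk * spec$soa
  if (max(block_len_go, block_len_nogo) <= 0) stop("empty blocks")

  out <- with_seed(spec$seed, {
    trials <- list()
    blocks <- list()
    for (r in seq_len(spec$n_runs)) {
      order_r <- sample(c(rep("Go", spec$go_blocks_per_run),
                          rep("NoGo", spec$nogo_blocks_per_run)))
      onset <- spec$lead_in
      for (b in seq_along(order_r)) {
        type <- order_r[b]
        n_tr <- if (type == "Go") n_go_trials else n_nogo_blk
        blen <- n_tr * spec$soa
        tt <- rep("Go", n_tr)
        if (type == "NoGo") {
          tt[sample(n_tr, spec$nogo_trials_per_nogo_block)] <- "NoGo"
        }
        trials[[length(trials) + 1L]] <- data.frame(
          run = r, block = b, block_type = type,
          onset = onset + (seq_len(n_tr) - 1) * spec$soa,
          duration = 1, trial_type = tt
        )
        blocks[[length(blocks) + 1L]] <- data.frame(
          run = r, condition = type, onset = onset, duration = blen
        )
        onset <- onset + blen + spec$block_gap
      }
      run_duration <- onset - spec$block_gap + spec$tail
      if (r == 1) attr(blocks, "run_duration") <- run_duration
    }
    list(trials = do.call(rbind, trials), blocks = blocks,
         run_duration = attr(blocks, "run_duration"))
  })

  n_volumes <- as.integer(ceiling(out$run_duration / spec$TR))
  design <- experiment_design(
    blocks = do.call(rbind, out$blocks), TR = spec$TR,
    n_volumes = n_volumes, n_runs = spec$n_runs,
    conditions = c("Go", "NoGo")
  )
  last <- max(out$trials$onset + out$trials$duration)
  if (last > n_volumes * spec$TR) stop("infeasible timing: trials overrun run")
  list(design = design, trials = out$trials, spec = spec)
}
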