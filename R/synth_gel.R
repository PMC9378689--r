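#' Generate a synthetic gel-quantification dataset with known activities
#'
#' Inverts the relative anti-pausing activity formula to per-lane paused
#' fractions, converts them to cytosine-weighted band intensities, and
#' applies multiplicative log-normal noise at the given coefficient of
#' variation.  `WT` and `put-` calibrator lanes are always included with
#' true activities 1 and 0.
#'
#' @param true_activities named numeric vector of mutant activities (each in
#'   [-0.2, 1.2]).
#' @param p_wt,p_putminus paused fractions of the calibrators (defaults
#'   emulate an efficient pause suppressed by wild-type put).
#' @param n_replicates replicates per construct.
#' @param noise_cv multiplicative noise CV in [0, 0.5].
#' @param n_c_paused,n_c_runoff transcript cytosine counts used for
#'   calibration.
#' @param seed RNG seed.
#' @return a `GelFixture`: `lanes` (data frame accepted by
#'   [classify_mutants()]), `true_activities`, `noise_cv`, `seed`.
#' @export
make_gel_dataset <- function(true_activities, p_wt = 0.15, p_putminus = 0.60,
                             n_replicates = 3L, noise_cv = 0.05,
                             n_c_paused = 17L, n_c_runoff = 37L, seed = 1L) {
  if (abs(p_putminus - p_wt) < 1e-9) stop("p_wt and p_putminus must differ")
  if (noise_cv < 0 || noise_cv > 0.5) stop("noise_cv must lie in [0, 0.5]")
  if (is.null(names(true_activities)) || any(names(true_activities) == ""))
    stop("true_activities must be a named vector")
  if (any(true_activities < -0.2 | true_activities > 1.2))
    stop("true activities outside [-0.2, 1.2]")
  acts <- c(WT = 1, `put-` = 0)
  acts <- c(acts, true_activities[setdiff(names(true_activities), names(acts))])
  sdlog <- sqrt(log(1 + noise_cv^2))
  total <- 1000
  lanes <- with_seed(seed, {
    rows <- list()
    for (rep_id in seq_len(n_replicates)) for (lb in names(acts)) {
      p <- p_wt + (1 - acts[[lb]]) * (p_putminus - p_wt)
      fac <- if (noise_cv > 0) rlnorm(2L, meanlog = -sdlog^2 / 2,
                                      sdlog = sdlog) else c(1, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        label = lb, replicate = rep_id,
        paused_intensity = p * total * n_c_paused * fac[1L],
        runoff_intensity = (1 - p) * total * n_c_runoff * fac[2L],
        n_c_paused = n_c_paused, n_c_runoff = n_c_runoff,
        time_min = 0.5, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  rownames(lanes) <- NULL
  structure(list(lanes = lanes, true_activities = acts,
                 p_wt = p_wt, p_putminus = p_putminus,
                 noise_cv = noise_cv, seed = seed),
            class = "GelFixture")
}
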