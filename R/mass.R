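# elemental compositions of internal RNA chain residues (nucleoside
# 5'-monophosphate minus water) and atomic masses; average masses are the
# native-MS default for large RNA
RNA_RESIDUE_COMPOSITION <- list(
  A = c(C = 10, H = 12, N = 5, O = 6, P = 1),
  C = c(C = 9,  H = 12, N = 3, O = 7, P = 1),
  G = c(C = 10, H = 12, N = 5, O = 7, P = 1),
  U = c(C = 9,  H = 11, N = 2, O = 8, P = 1))

ATOMIC_MASS <- list(
  average      = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                   P = 30.973762),
  monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151))

PROTON_MASS <- 1.00728

composition_mass <- function(comp, mode) {
  w <- ATOMIC_MASS[[mode]]
  sum(w[names(comp)] * comp)
}

water_mass <- function(mode) composition_mass(c(H = 2, O = 1), mode)
hpo3_mass <- function(mode) composition_mass(c(H = 1, P = 1, O = 3), mode)

#' Mass of an RNA chain residue
#'
#' @param base one of A, C, G, U.
#' @param mass_mode `"average"` or `"monoisotopic"`.
#' @return residue mass in Da (chain contribution, water excluded).
#' @export
rna_residue_mass <- function(base, mass_mode = c("average", "monoisotopic")) {
  mass_mode <- match.arg(mass_mode)
  comp <- RNA_RESIDUE_COMPOSITION[[toupper(base)]]
  if (is.null(comp)) stop("unknown RNA base: ", base)
  composition_mass(comp, mass_mode)
}

#' Neutral mass of an RNA transcript
#'
#' Sum of residue masses from the shipped elemental-composition table, plus
#' one water, with the 5' terminus adjusted for the end chemistry.  In-vitro
#' transcripts initiated with rNTPs carry a 5'-triphosphate (the default);
#' the 3' end is a hydroxyl.
#'
#' @param sequence RNA sequence over A/C/G/U (string).
#' @param five_prime `"triphosphate"`, `"monophosphate"` or `"hydroxyl"`.
#' @param mass_mode `"average"` (native-MS default) or `"monoisotopic"`.
#' @return neutral mass in Da.
#' @export
rna_mass <- function(sequence, five_prime = c("triphosphate", "monophosphate",
                                              "hydroxyl"),
                     mass_mode = c("average", "monoisotopic")) {
  five_prime <- match.arg(five_prime)
  mass_mode <- match.arg(mass_mode)
  bases <- strsplit(toupper(sequence), "")[[1L]]
  if (!length(bases)) stop("empty sequence")
  bad <- which(!bases %in% names(RNA_RESIDUE_COMPOSITION))
  if (length(bad))
    stop(sprintf("invalid RNA character '%s' at position %d", bases[bad[1L]],
                 bad[1L]))
  m <- sum(vapply(bases, rna_residue_mass, 0, mass_mode = mass_mode)) +
    water_mass(mass_mode)
  m + switch(five_prime,
             triphosphate = 2 * hpo3_mass(mass_mode),
             monophosphate = 0,
             hydroxyl = -hpo3_mass(mass_mode))
}

#' Simulate a positive-mode charge-state peak series
#'
#' @param mass neutral mass in Da.
#' @param z_range `c(z_min, z_max)`, integers >= 1.
#' @param proton_mass proton mass in Da.
#' @return data frame of class `PeakSeries` with columns `mz` (ascending)
#'   and `intensity` (unit).
#' @export
simulate_charge_series <- function(mass, z_range, proton_mass = PROTON_MASS) {
  if (mass <= 0) stop("mass must be positive")
  z <- seq(z_range[1L], z_range[2L])
  if (!length(z) || any(z < 1)) stop("charge range must cover integers >= 1")
  out <- data.frame(mz = (mass + z * proton_mass) / z, intensity = 1,
                    charge = z)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PeakSeries", "data.frame")
  out
}

#' Recover a neutral mass from a charge-state series
#'
#' Simplified consistency deconvolution: assuming consecutive peaks carry
#' consecutive charges (descending with m/z), every candidate charge of the
#' first peak implies one neutral mass per peak; the assignment minimising
#' the spread of implied masses wins.  The consensus is the
#' intensity-weighted mean.
#'
#' @param peaks data frame with `mz` (and optional `intensity`), ascending.
#' @param z_search `c(z_min, z_max)` candidate charges for the lowest-m/z
#'   peak.
#' @param tolerance maximum acceptable residual (Da).
#' @param proton_mass proton mass in Da.
#' @return a `DeconvolutionResult`: `neutral_mass`, `charge_assignments`
#'   (data frame peak/mz/charge/implied mass), `residual`.
#' @export
deconvolve_charge_series <- function(peaks, z_search = c(1L, 40L),
                                     tolerance = 5, proton_mass = PROTON_MASS) {
  mz <- peaks$mz
  if (is.null(mz)) stop("peaks must have an 'mz' column")
  if (is.unsorted(mz)) stop("m/z values must be sorted ascending")
  inten <- peaks$intensity %||% rep(1, length(mz))
  n <- length(mz)
  if (n < 2L && diff(range(z_search)) > 0)
    stop("need >= 2 peaks (or a single fixed charge in z_search)")
  best <- NULL
  for (z0 in seq(max(z_search[1L] + n - 1L, z_search[1L]), z_search[2L])) {
    z <- z0 - (seq_len(n) - 1L)      # charges descend as m/z ascends
    if (any(z < 1L)) next
    masses <- z * mz - z * proton_mass
    spread <- max(masses) - min(masses)
    if (is.null(best) || spread < best$spread)
      best <- list(z = z, masses = masses, spread = spread)
  }
  if (is.null(best)) stop("charge search range admits no assignment")
  consensus <- weighted.mean(best$masses, inten)
  residual <- max(abs(best$masses - consensus))
  if (residual > tolerance)
    stop(sprintf(paste0("no charge assignment within tolerance ",
                        "(best residual %.3f Da > %.3f Da)"),
                 residual, tolerance))
  structure(list(neutral_mass = consensus,
                 charge_assignments = data.frame(peak = seq_len(n), mz = mz,
                                                 charge = best$z,
                                                 implied_mass = best$masses),
                 residual = residual),
            class = "DeconvolutionResult")
}

#' @export
print.DeconvolutionResult <- function(x, ...) {
  cat(sprintf("Deconvolved neutral mass: %.2f Da (z %d-%d, residual %.3f Da)\n",
              x$neutral_mass, min(x$charge_assignments$charge),
              max(x$charge_assignments$charge), x$residual))
  invisible(x)
}
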