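#' Cytosine-calibrated paused fraction of a transcription lane
#'
#' Band intensities from the radiolabeled assay are calibrated by the number
#' of cytosines each transcript contains (the label enters via alpha-32P
#' CTP), then the paused fraction is the calibrated paused intensity over
#' the calibrated total:
#' `P = (paused/nC_paused) / (paused/nC_paused + runoff/nC_runoff)`.
#'
#' @param paused_intensity,runoff_intensity background-corrected band
#'   intensities (arbitrary units, >= 0).
#' @param n_c_paused,n_c_runoff cytosine counts of the two transcripts
#'   (>= 1).
#' @return paused fraction in [0, 1].
#' @export
paused_fraction <- function(paused_intensity, runoff_intensity,
                            n_c_paused, n_c_runoff) {
  if (any(paused_intensity < 0) || any(runoff_intensity < 0))
    stop("band intensities must be >= 0")
  if (any(n_c_paused < 1) || any(n_c_runoff < 1))
    stop("cytosine counts must be >= 1")
  p <- paused_intensity / n_c_paused
  r <- runoff_intensity / n_c_runoff
  if (any(p + r <= 0)) stop("both calibrated intensities are zero")
  p / (p + r)
}

#' Relative anti-pausing activity
#'
#' `1 - (P_x - P_wt) / (P_putminus - P_wt)`: wild type maps to 1 and the
#' inactive put- mutant to 0 by construction.  Values are not clipped to
#' [0, 1]; the linear scale permits slight excursions.
#'
#' @param p_x paused fraction of the mutant.
#' @param p_wt,p_putminus paused fractions of wild-type put and put-.
#' @return relative activity (dimensionless).
#' @export
relative_anti_pausing <- function(p_x, p_wt, p_putminus) {
  if (any(abs(p_putminus - p_wt) < 1e-12))
    stop("P_putminus equals P_wt: activity scale undefined")
  1 - (p_x - p_wt) / (p_putminus - p_wt)
}

#' Per-mutant anti-pausing activity with SEM and classification
#'
#' Computes each lane's paused fraction, converts it to relative
#' anti-pausing activity against the same replicate's wild-type and put-
#' lanes, then summarises per mutant: mean, SEM (sd/sqrt(n)) and class —
#' `inactivating` below 0.2, `inert` above 0.9, `other` between.
#'
#' @param lanes data frame with columns `label`, `replicate`,
#'   `paused_intensity`, `runoff_intensity`, `n_c_paused`, `n_c_runoff`.
#' @param wt_label,putminus_label labels of the two calibrator constructs.
#' @param inactivating_below,inert_above class thresholds on the mean.
#' @return data frame of class `ActivityResult`: `label`, `n`,
#'   `mean_activity`, `sem`, `class`, plus a `replicate_activities` list
#'   column.
#' @export
classify_mutants <- function(lanes, wt_label = "WT", putminus_label = "put-",
                             inactivating_below = 0.2, inert_above = 0.9) {
  need <- c("label", "replicate", "paused_intensity", "runoff_intensity",
            "n_c_paused", "n_c_runoff")
  miss <- setdiff(need, names(lanes))
  if (length(miss)) stop("lane table lacks columns: ", paste(miss, collapse = ", "))
  for (lb in c(wt_label, putminus_label))
    if (!lb %in% lanes$label) stop("no lanes labelled '", lb, "'")
  lanes$P <- paused_fraction(lanes$paused_intensity, lanes$runoff_intensity,
                             lanes$n_c_paused, lanes$n_c_runoff)
  out <- list()
  for (lb in unique(lanes$label)) {
    sub <- lanes[lanes$label == lb, , drop = FALSE]
    act <- vapply(seq_len(nrow(sub)), function(i) {
      rep_id <- sub$replicate[i]
      wt <- lanes$P[lanes$label == wt_label & lanes$replicate == rep_id]
      pm <- lanes$P[lanes$label == putminus_label & lanes$replicate == rep_id]
      if (length(wt) != 1L || length(pm) != 1L)
        stop("replicate ", rep_id, " lacks a unique ", wt_label, " or ",
             putminus_label, " lane")
      relative_anti_pausing(sub$P[i], wt, pm)
    }, 0)
    m <- mean(act)
    cls <- if (m < inactivating_below) "inactivating"
    else if (m > inert_above) "inert" else "other"
    row <- data.frame(label = lb, n = length(act), mean_activity = m,
                      sem = if (length(act) >= 2L) sd(act) / sqrt(length(act))
                      else NA_real_,
                      class = cls, stringsAsFactors = FALSE)
    row$replicate_activities <- list(act)
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ActivityResult", "data.frame")
  res
}

#' Per-column conservation scores against a reference sequence
#'
#' For each non-gap column of the reference, the score is the number of
#' aligned sequences (reference included) whose character matches the
#' reference character, case-insensitively; gaps never match.  With the ten
#' aligned put sequences this yields the 0-10 scores painted on the putRNA
#' structure.
#'
#' @param alignment path to an aligned FASTA/Clustal/Stockholm file, a named
#'   character vector of aligned sequences, or a character matrix.
#' @param reference_id name of the reference sequence.
#' @param format alignment format when `alignment` is a path.
#' @return a `ConservationProfile`: `reference_id`, `n_sequences`, `scores`
#'   (named by reference residue number 1..L), `column_map` (alignment
#'   column per reference residue).
#' @export
conservation_profile <- function(alignment, reference_id,
                                 format = c("fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  mat <- alignment_matrix(alignment, format)
  if (!reference_id %in% rownames(mat))
    stop("reference '", reference_id, "' absent from alignment (has: ",
         paste(utils::head(rownames(mat), 5L), collapse = ", "), " ...)")
  mat <- toupper(mat)
  gap <- mat %in% c("-", ".", "~")
  dim(gap) <- dim(mat)
  ref <- mat[reference_id, ]
  ref_cols <- which(!gap[rownames(mat) == reference_id, ])
  scores <- vapply(ref_cols, function(j)
    sum(mat[, j] == ref[j] & !gap[, j]), 0L)
  names(scores) <- seq_along(ref_cols)
  structure(list(reference_id = reference_id, n_sequences = nrow(mat),
                 scores = scores,
                 column_map = setNames(ref_cols, seq_along(ref_cols))),
            class = "ConservationProfile")
}

alignment_matrix <- function(alignment, format = "fasta") {
  if (is.matrix(alignment)) return(alignment)
  if (is.character(alignment) && !is.null(names(alignment)) &&
      all(nzchar(names(alignment)))) {
    if (length(unique(nchar(alignment))) != 1L)
      stop("aligned sequences must have equal length")
    return(do.call(rbind, strsplit(setNames(toupper(alignment),
                                            names(alignment)), "")))
  }
  if (!is.character(alignment) || length(alignment) != 1L)
    stop("alignment must be a file path, named character vector, or matrix")
  aln <- tryCatch(
    Biostrings::readRNAMultipleAlignment(alignment, format = format),
    error = function(e) tryCatch(
      Biostrings::readDNAMultipleAlignment(alignment, format = format),
      error = function(e2)
        Biostrings::readAAMultipleAlignment(alignment, format = format)))
  rows <- as.character(Biostrings::unmasked(aln))
  do.call(rbind, strsplit(rows, ""))
}

#' @export
print.ConservationProfile <- function(x, ...) {
  cat(sprintf("Conservation of '%s' over %d sequences (%d residues)\n",
              x$reference_id, x$n_sequences, length(x$scores)))
  cat("  scores:", paste(x$scores, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.ActivityResult <- function(x, ...) {
  cat(sprintf("Anti-pausing activities (%d constructs):\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %.3f +/- %s (n=%d, %s)\n", x$label[i],
                x$mean_activity[i],
                ifelse(is.na(x$sem[i]), "NA", sprintf("%.3f", x$sem[i])),
                x$n[i], x$class[i]))
  invisible(x)
}
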