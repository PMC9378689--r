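#' RNA-DNA hybrid length and translocation register
#'
#' Finds the contiguous run of Watson-Crick RNA:template-DNA pairs ending at
#' the RNA 3' terminus — the transcription-bubble hybrid.  Pair detection
#' uses the same geometric criteria as [detect_base_pairs()], restricted to
#' inter-chain pairs with complementary bases.
#'
#' The translocation register is called against the template position
#' adjacent to the downstream DNA duplex (`downstream_template_resno`, the
#' i+1 site): if the RNA 3' nucleotide pairs that template base the complex
#' is pre-translocated; if it pairs the preceding base, post-translocated;
#' `"ambiguous"` otherwise or when the junction is not supplied (e.g. mixed
#' populations modelled at partial occupancy).
#'
#' @param model a `StructureModel`.
#' @param rna_chain,template_dna_chain chain IDs.
#' @param downstream_template_resno optional template residue number at the
#'   i+1 position.
#' @param ... passed to [detect_base_pairs()].
#' @return a `HybridReport`: `n_template_bases`, `n_rna_bases`, `register`,
#'   `pairs` (data frame template residue vs RNA residue).
#' @export
hybrid_length <- function(model, rna_chain, template_dna_chain,
                          downstream_template_resno = NULL, ...) {
  bp <- detect_base_pairs(model, chains = c(rna_chain, template_dna_chain), ...)
  inter <- bp[(bp$chain_i == rna_chain & bp$chain_j == template_dna_chain) |
                (bp$chain_i == template_dna_chain & bp$chain_j == rna_chain), ,
              drop = FALSE]
  if (nrow(inter) > 0L) {
    comp_ok <- vapply(seq_len(nrow(inter)), function(k) {
      bi <- inter$base_i[k]; bj <- inter$base_j[k]
      identical(wc_complement(bi, dna = TRUE), bj) ||
        identical(wc_complement(bj), bi) || identical(wc_complement(bi), bj)
    }, TRUE)
    inter <- inter[comp_ok, , drop = FALSE]
  }
  if (nrow(inter) == 0L)
    stop("no RNA:template base pairs between chains '", rna_chain, "' and '",
         template_dna_chain, "'")
  swap <- inter$chain_i != rna_chain
  pairs <- data.frame(
    rna_resno = ifelse(swap, inter$res_j, inter$res_i),
    template_resno = ifelse(swap, inter$res_i, inter$res_j))
  pairs <- pairs[order(pairs$rna_resno), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$rna_resno), , drop = FALSE]

  rna_res <- sort(unique(model$atoms$resno[model$atoms$chain == rna_chain &
                                             is_nucleic(model$atoms$resid)]))
  three_prime <- rna_res[length(rna_res)]
  # walk 5'-ward from the 3' end over consecutive RNA positions paired to
  # consecutive template positions
  run <- pairs[pairs$rna_resno == three_prime, , drop = FALSE]
  if (nrow(run) == 0L)
    stop("RNA 3' residue ", three_prime, " is not base-paired to the template")
  repeat {
    nxt <- pairs[pairs$rna_resno == run$rna_resno[1L] - 1L, , drop = FALSE]
    if (nrow(nxt) == 0L) break
    if (abs(nxt$template_resno - run$template_resno[1L]) != 1L) break
    run <- rbind(nxt, run)
  }
  register <- "ambiguous"
  if (!is.null(downstream_template_resno)) {
    t3 <- run$template_resno[nrow(run)]
    if (t3 == downstream_template_resno) register <- "pre_translocated"
    else if (abs(t3 - downstream_template_resno) == 1L)
      register <- "post_translocated"
  }
  structure(list(n_template_bases = nrow(run), n_rna_bases = nrow(run),
                 register = register, pairs = run),
            class = "HybridReport")
}

#' @export
print.HybridReport <- function(x, ...) {
  cat(sprintf("RNA-DNA hybrid: %d bp (RNA %d-%d / template %d-%d), %s\n",
              x$n_template_bases, x$pairs$rna_resno[1L],
              x$pairs$rna_resno[nrow(x$pairs)], x$pairs$template_resno[1L],
              x$pairs$template_resno[nrow(x$pairs)], x$register))
  invisible(x)
}

fit_helix_axis <- function(model, segment, ...) {
  bp <- detect_base_pairs(model, chains = segment, ...)
  if (nrow(bp) < 3L)
    stop("helix segment yields ", nrow(bp), " base pairs (<3): cannot fit an axis")
  atoms <- if (is.character(segment) && !any(grepl(":", segment)))
    model$atoms[model$atoms$chain %in% segment, , drop = FALSE]
  else select_atoms(model, segment)
  c1 <- atoms[atoms$name == "C1'", , drop = FALSE]
  key <- function(ch, res) paste(ch, res)
  kk <- key(c1$chain, c1$resno)
  mid <- t(mapply(function(ci, ri, cj, rj) {
    (as.numeric(atom_xyz(c1[match(key(ci, ri), kk), ])) +
       as.numeric(atom_xyz(c1[match(key(cj, rj), kk), ]))) / 2
  }, bp$chain_i, bp$res_i, bp$chain_j, bp$res_j))
  ax <- principal_axis(mid)
  list(axis = ax, n_pairs = nrow(bp), midpoints = mid)
}

#' Kink angle between two helical segments
#'
#' Fits a least-squares helical axis through the C1' midpoints of the base
#' pairs of each segment and reports the angle between the two axes, folded
#' to [0, 90] degrees — e.g. the ~19-degree kink the unpaired U68* wedge
#' introduces in put stem II.
#'
#' @param model a `StructureModel`.
#' @param segment1,segment2 selections (strings, expressions or chain IDs)
#'   delimiting the two helical segments; each must contain at least 3 pairs.
#' @param ... passed to [detect_base_pairs()].
#' @return angle in degrees.
#' @export
kink_angle <- function(model, segment1, segment2, ...) {
  a1 <- fit_helix_axis(model, segment1, ...)
  a2 <- fit_helix_axis(model, segment2, ...)
  ang <- angle_between_deg(a1$axis$direction, a2$axis$direction)
  min(ang, 180 - ang)
}
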