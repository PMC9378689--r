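#' Substitute an RNA base in place
#'
#' Replaces the base atoms of one residue with an idealized template
#' superposed on the glycosidic anchor geometry (glycosidic N, the C1'
#' direction and the base plane), leaving ribose and phosphate untouched —
#' the in-silico substitution used to ask how many hydrogen bonds each base
#' could donate into a protein pocket (the U28* analysis).
#'
#' @param model a `StructureModel`.
#' @param chain,resno residue locator (author numbering).
#' @param new_base target base, one of A, C, G, U.
#' @return a new `StructureModel` with the residue renamed and rebuilt.
#' @export
mutate_base <- function(model, chain, resno, new_base) {
  new_base <- toupper(new_base)
  if (!new_base %in% c("A", "C", "G", "U"))
    stop("new_base must be one of A, C, G, U")
  a <- model$atoms
  a$is_ion <- NULL
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) stop("residue ", chain, ":", resno, " not found")
  resat <- a[sel, , drop = FALSE]
  old_resid <- resat$resid[1L]
  if (!is_nucleic(old_resid) || toupper(old_resid) %in% DNA_RESIDUES)
    stop("residue ", chain, ":", resno, " (", old_resid, ") is not RNA")
  old_base <- base_letter(old_resid)
  gly_old <- glycosidic_n(old_resid)
  anchors <- c(gly_old, "C1'")
  idx <- match(anchors, resat$name)
  if (anyNA(idx))
    stop("residue lacks glycosidic anchor atom(s): ",
         paste(anchors[is.na(idx)], collapse = ", "))
  ring_idx <- match(BASE_RING_ATOMS[[old_base]], resat$name)
  ring_idx <- ring_idx[!is.na(ring_idx)]
  if (length(ring_idx) < 4L) stop("residue lacks base ring atoms")

  frame_of <- function(n_pos, c1_pos, adj_pos) {
    e1 <- unit(c1_pos - n_pos)
    v <- adj_pos - n_pos
    e2 <- unit(v - sum(v * e1) * e1)
    e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
            e1[3L] * e2[1L] - e1[1L] * e2[3L],
            e1[1L] * e2[2L] - e1[2L] * e2[1L])
    rbind(e1, e2, e3)
  }
  # ring neighbour of the glycosidic N on the WC-edge side
  adj_name <- if (is_purine(old_resid)) "C4" else "C2"
  adj_idx <- match(adj_name, resat$name)
  if (is.na(adj_idx)) stop("residue lacks ring anchor atom ", adj_name)
  n_pos <- as.numeric(atom_xyz(resat[idx[1L], ]))
  c1_pos <- as.numeric(atom_xyz(resat[idx[2L], ]))
  B_old <- frame_of(n_pos, c1_pos, as.numeric(atom_xyz(resat[adj_idx, ])))

  tmpl <- base_template(new_base)
  gly_new <- attr(tmpl, "glycosidic")
  adj_new <- if (new_base %in% c("A", "G")) "C4" else "C2"
  Bt <- frame_of(tmpl[gly_new, ], tmpl["C1'", ], tmpl[adj_new, ])
  # template base atoms (all but C1') expressed in the old residue's frame
  base_names <- setdiff(rownames(tmpl), "C1'")
  local <- sweep(tmpl[base_names, , drop = FALSE], 2L, tmpl[gly_new, ]) %*% t(Bt)
  new_xyz <- sweep(local %*% B_old, 2L, n_pos, `+`)

  keep_names <- setdiff(resat$name,
                        unique(c(BASE_RING_ATOMS[[old_base]],
                                 BASE_DONORS[[old_base]],
                                 BASE_ACCEPTORS[[old_base]], "C7",
                                 if (old_base == "G") "N2")))
  kept <- resat[resat$name %in% keep_names, , drop = FALSE]
  added <- residue_rows(new_xyz, chain, resno, new_base)
  added$serial <- max(a$serial) + seq_len(nrow(added))
  kept$resid <- new_base
  out <- rbind(a[!sel, , drop = FALSE], kept, added)
  out <- out[order(out$chain, out$resno, out$insert, out$name), , drop = FALSE]
  out$serial <- seq_len(nrow(out))
  m <- structure_model(out, id = sprintf("%s_%s%d%s", model$id, chain, resno,
                                         new_base))
  m
}

#' Count potential hydrogen bonds from one residue into a pocket
#'
#' Convenience wrapper: [detect_polar_contacts()] between a single residue
#' and a pocket selection, counting hydrogen bonds (salt bridges excluded).
#'
#' @param model a `StructureModel`.
#' @param chain,resno residue locator.
#' @param pocket selection for the surrounding residues.
#' @param base_atoms_only count only H bonds made by base atoms.
#' @return integer H-bond count.
#' @export
count_pocket_hbonds <- function(model, chain, resno, pocket,
                                base_atoms_only = TRUE) {
  res_sel <- selection(chain = chain, ranges = c(resno, resno))
  cts <- detect_polar_contacts(model, res_sel, pocket)
  cts <- cts[cts$kind == "hbond", , drop = FALSE]
  if (base_atoms_only) {
    resid <- model$atoms$resid[model$atoms$chain == chain &
                                 model$atoms$resno == resno][1L]
    bl <- base_letter(resid)
    edge <- c(BASE_DONORS[[bl]], BASE_ACCEPTORS[[bl]])
    cts <- cts[cts$atom_a %in% edge, , drop = FALSE]
  }
  nrow(cts)
}
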