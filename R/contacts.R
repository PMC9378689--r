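#' Detect typed polar contacts between two selections
#'
#' Hydrogen-free geometric criteria suitable for cryo-EM models without
#' hydrogens; contacts are "potential" interactions:
#' \describe{
#'   \item{hbond}{donor heavy atom to acceptor heavy atom at or below
#'     `hbond_cutoff` (3.5 A), with the donor-acceptor-antecedent angle at
#'     least 90 degrees when a covalent antecedent of the acceptor exists.}
#'   \item{salt_bridge}{charged-group nitrogen (Arg/Lys/His) to phosphate or
#'     carboxylate oxygen at or below `salt_cutoff` (4.0 A); takes priority
#'     over hbond for the same atom pair.}
#'   \item{cation_pi}{charged-group nitrogen to base / aromatic ring centroid
#'     at or below `catpi_cutoff` (6.0 A) with the centroid-to-N vector
#'     within `catpi_angle` (30 degrees) of the ring normal.}
#' }
#'
#' @param model a `StructureModel`.
#' @param A,B disjoint selections.
#' @param hbond_cutoff,salt_cutoff,catpi_cutoff distances in Angstrom.
#' @param catpi_angle maximum centroid-normal angle in degrees.
#' @return data frame of class `ContactSet`, columns `kind`, `chain_a`,
#'   `res_a`, `resid_a`, `atom_a`, `chain_b`, `res_b`, `resid_b`, `atom_b`,
#'   `distance`, `angle`; deterministically sorted.  Zero rows is a valid
#'   result.
#' @export
detect_polar_contacts <- function(model, A, B, hbond_cutoff = 3.5,
                                  salt_cutoff = 4.0, catpi_cutoff = 6.0,
                                  catpi_angle = 30) {
  at_A <- select_atoms(model, A)
  at_B <- select_atoms(model, B)
  key <- function(a) paste(a$chain, a$resno, a$insert, a$name)
  if (length(intersect(key(at_A), key(at_B))))
    stop("selections A and B overlap")
  res <- list()

  xyz_A <- atom_xyz(at_A); xyz_B <- atom_xyz(at_B)
  cross <- outer(rowSums(xyz_A^2), rowSums(xyz_B^2), `+`) -
    2 * xyz_A %*% t(xyz_B)
  cross[cross < 0] <- 0
  dmat <- sqrt(cross)

  don_A <- is_donor_atom(at_A$resid, at_A$name)
  acc_A <- is_acceptor_atom(at_A$resid, at_A$name)
  don_B <- is_donor_atom(at_B$resid, at_B$name)
  acc_B <- is_acceptor_atom(at_B$resid, at_B$name)
  cat_A <- is_cation_atom(at_A$resid, at_A$name)
  ani_A <- is_anion_atom(at_A$resid, at_A$name)
  cat_B <- is_cation_atom(at_B$resid, at_B$name)
  ani_B <- is_anion_atom(at_B$resid, at_B$name)

  antecedent_ok <- function(model, acc_row, donor_pos) {
    a <- model$atoms
    same <- a$chain == acc_row$chain & a$resno == acc_row$resno &
      a$insert == acc_row$insert & a$name != acc_row$name
    if (!any(same)) return(TRUE)
    cand <- a[same, , drop = FALSE]
    acc_pos <- as.numeric(atom_xyz(acc_row))
    dd <- sqrt(rowSums(sweep(atom_xyz(cand), 2L, acc_pos)^2))
    bonded <- which(dd < 1.8)
    if (!length(bonded)) return(TRUE)
    ante <- as.numeric(atom_xyz(cand[bonded[which.min(dd[bonded])], ]))
    ang <- angle_between_deg(donor_pos - acc_pos, ante - acc_pos)
    ang >= 90
  }

  hits <- which(((don_A %o% acc_B) | (acc_A %o% don_B)) &
                  dmat <= hbond_cutoff, arr.ind = TRUE)
  salt_pairs <- which((cat_A %o% ani_B) | (ani_A %o% cat_B), arr.ind = TRUE)
  salt_keys <- paste(salt_pairs[, 1L], salt_pairs[, 2L])

  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1L]; j <- hits[k, 2L]
    if (paste(i, j) %in% salt_keys && dmat[i, j] <= salt_cutoff) next
    ra <- at_A[i, ]; rb <- at_B[j, ]
    don_is_a <- don_A[i] && acc_B[j]
    ok <- if (don_is_a)
      antecedent_ok(model, rb, as.numeric(atom_xyz(ra)))
    else antecedent_ok(model, ra, as.numeric(atom_xyz(rb)))
    if (!ok) next
    res[[length(res) + 1L]] <- contact_row("hbond", ra, rb, dmat[i, j], NA_real_)
  }

  for (k in seq_len(nrow(salt_pairs))) {
    i <- salt_pairs[k, 1L]; j <- salt_pairs[k, 2L]
    if (dmat[i, j] > salt_cutoff) next
    res[[length(res) + 1L]] <- contact_row("salt_bridge", at_A[i, ], at_B[j, ],
                                           dmat[i, j], NA_real_)
  }

  res <- c(res, catpi_contacts(at_A, at_B, cat_A, catpi_cutoff, catpi_angle,
                               a_is_cation = TRUE))
  res <- c(res, catpi_contacts(at_B, at_A, cat_B, catpi_cutoff, catpi_angle,
                               a_is_cation = FALSE))

  out <- if (length(res)) do.call(rbind, res) else
    contact_row("hbond", at_A[0, ], at_B[0, ], numeric(0), numeric(0))
  out <- out[order(out$kind, out$chain_a, out$res_a, out$atom_a,
                   out$chain_b, out$res_b, out$atom_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ContactSet", "data.frame")
  out
}

contact_row <- function(kind, a, b, distance, angle) {
  data.frame(kind = rep(kind, length(distance)),
             chain_a = a$chain, res_a = a$resno, resid_a = a$resid,
             atom_a = a$name,
             chain_b = b$chain, res_b = b$resno, resid_b = b$resid,
             atom_b = b$name,
             distance = distance, angle = angle, stringsAsFactors = FALSE)
}

# rings in `ring_side`, cations in `cation_side`; reported with the cation
# as partner A when a_is_cation
catpi_contacts <- function(cation_side, ring_side, cation_mask, cutoff,
                           max_angle, a_is_cation) {
  out <- list()
  cations <- cation_side[cation_mask, , drop = FALSE]
  if (nrow(cations) == 0L) return(out)
  rk <- paste(ring_side$chain, ring_side$resno, ring_side$insert)
  for (resk in unique(rk)) {
    resat <- ring_side[rk == resk, , drop = FALSE]
    rings <- residue_rings(resat)
    for (ring in rings) {
      ctr <- colMeans(ring$xyz)
      nrm <- ring_normal(ring$xyz)
      for (i in seq_len(nrow(cations))) {
        v <- as.numeric(atom_xyz(cations[i, ])) - ctr
        d <- vnorm(v)
        if (d > cutoff || d < 1e-6) next
        ang <- angle_between_deg(v, nrm)
        ang <- min(ang, 180 - ang)
        if (ang > max_angle) next
        centroid_row <- resat[1L, ]
        centroid_row$name <- ring$label
        row <- if (a_is_cation)
          contact_row("cation_pi", cations[i, ], centroid_row, d, ang)
        else contact_row("cation_pi", centroid_row, cations[i, ], d, ang)
        out[[length(out) + 1L]] <- row
      }
    }
  }
  out
}

# ring atom sets present in one residue's atom table
residue_rings <- function(resat) {
  resid <- toupper(resat$resid[1L])
  defs <- NULL
  if (is_nucleic(resid)) {
    bl <- base_letter(resid)
    ring6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
    defs <- if (!is.na(bl) && bl %in% c("A", "G"))
      list(ring6, c("C4", "C5", "N7", "C8", "N9")) else list(ring6)
  } else defs <- AROMATIC_RINGS[[resid]]
  out <- list()
  for (d in defs %||% list()) {
    idx <- match(d, resat$name)
    if (anyNA(idx)) next
    out[[length(out) + 1L]] <- list(xyz = atom_xyz(resat[idx, ]),
                                    label = paste0("ring[", d[1L], "]"))
  }
  out
}

ring_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  unit(svd(sweep(xyz, 2L, ctr))$v[, 3L])
}
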