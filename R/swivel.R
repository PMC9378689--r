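#' Measure the RNAP swivel angle between two elongation complexes
#'
#' Two-stage measurement of the pausing-associated swivel motion: (1) the
#' target structure is superposed onto the reference using the core-module
#' atoms; (2) the residual rigid transform carrying the core-aligned target
#' swivel module (clamp + shelf + jaw + SI3 + beta' C-terminal region) onto
#' the reference's is extracted, and its rotation angle is the swivel angle.
#' The residual axis is compared with the reference bridge-helix axis
#' (principal axis through the bridge-helix CA atoms, oriented N to C), and
#' per-domain CA RMSDs after core alignment are reported.
#'
#' @param reference,target `StructureModel`s.
#' @param domains a `DomainSet` with core and the five swivel members;
#'   a `bridge_helix` domain enables the axis comparison.
#' @param atom_subset `"CA"` (default) or `"all_backbone"` (N, CA, C, O).
#' @param min_atoms minimum shared atoms required in core and swivel fits.
#' @return a `SwivelReport`: `angle_deg`, `axis`, `axis_point`,
#'   `screw_translation`, `bridge_helix_axis_angle`, `per_domain_rmsd`,
#'   `n_core_atoms`, `n_swivel_atoms`, `core_rmsd`, `swivel_rmsd`.
#' @export
swivel_angle <- function(reference, target, domains,
                         atom_subset = c("CA", "all_backbone"),
                         min_atoms = 50L) {
  atom_subset <- match.arg(atom_subset)
  nm <- if (atom_subset == "CA") "CA" else c("N", "CA", "C", "O")

  core_ref <- resolve_domain(reference, domains, "core", atoms = nm)
  core_tgt <- resolve_domain(target, domains, "core", atoms = nm)
  fit_core <- kabsch_superpose(core_tgt, core_ref, pairing = "by_identity")
  if (fit_core$n_atoms < min_atoms)
    stop("fewer than ", min_atoms, " shared core atoms (", fit_core$n_atoms, ")")
  aligned <- apply_transform(fit_core$transform, target)

  members <- intersect(SWIVEL_MEMBERS, names(domains$domains))
  sw_exprs <- unlist(lapply(members, function(d) domains$domains[[d]]),
                     recursive = FALSE)
  sw_exprs <- lapply(sw_exprs, function(e) { e$atoms <- nm; e })
  sw_ref <- select_atoms(reference, sw_exprs)
  sw_tgt <- select_atoms(aligned, sw_exprs)
  p <- pair_by_identity(sw_tgt, sw_ref)
  if (nrow(p$mobile) < min_atoms)
    stop("fewer than ", min_atoms, " shared swivel-module atoms (",
         nrow(p$mobile), ")")
  fit_sw <- kabsch_superpose(p$mobile, p$reference, pairing = "by_order")
  R <- fit_sw$transform$rotation
  tvec <- fit_sw$transform$translation
  angle <- rotation_angle(R)

  bh_angle <- NA_real_
  bh_dir <- NULL
  if ("bridge_helix" %in% names(domains$domains)) {
    bh <- tryCatch(resolve_domain(reference, domains, "bridge_helix", atoms = "CA"),
                   error = function(e) NULL)
    if (!is.null(bh)) bh_dir <- principal_axis(atom_xyz(bh))$direction
  }

  axis <- c(NA_real_, NA_real_, NA_real_)
  axis_point <- c(NA_real_, NA_real_, NA_real_)
  screw <- 0
  if (angle > 1e-6) {
    ax <- rotation_axis(R, reference_direction = bh_dir)
    axis <- ax$axis
    screw <- sum(tvec * axis)
    # a point on the screw axis: solve (I - R) p = t_perp in the plane
    # orthogonal to the axis (rank-2 system; use least squares)
    t_perp <- tvec - screw * axis
    A <- diag(3) - R
    axis_point <- tryCatch(
      as.numeric(solve(crossprod(A) + tcrossprod(axis),
                       crossprod(A, t_perp))),
      error = function(e) c(NA_real_, NA_real_, NA_real_))
    if (!is.null(bh_dir)) {
      bh_angle <- angle_between_deg(axis, bh_dir)
      if (bh_angle > 90) bh_angle <- 180 - bh_angle
    }
  }

  per_domain <- c(core = fit_core$rmsd)
  for (d in members) {
    dr <- tryCatch(resolve_domain(reference, domains, d, atoms = nm),
                   error = function(e) NULL)
    dt <- tryCatch(resolve_domain(aligned, domains, d, atoms = nm),
                   error = function(e) NULL)
    if (is.null(dr) || is.null(dt)) { per_domain[d] <- NA_real_; next }
    pp <- pair_by_identity(dt, dr)
    per_domain[d] <- if (nrow(pp$mobile) == 0L) NA_real_ else
      sqrt(mean(rowSums((atom_xyz(pp$mobile) - atom_xyz(pp$reference))^2)))
  }

  structure(list(reference = reference$id, target = target$id,
                 angle_deg = angle, axis = axis, axis_point = axis_point,
                 screw_translation = screw,
                 bridge_helix_axis_angle = bh_angle,
                 per_domain_rmsd = per_domain,
                 n_core_atoms = fit_core$n_atoms,
                 n_swivel_atoms = fit_sw$n_atoms,
                 core_rmsd = fit_core$rmsd, swivel_rmsd = fit_sw$rmsd,
                 atom_subset = atom_subset),
            class = "SwivelReport")
}

#' @export
print.SwivelReport <- function(x, ...) {
  cat(sprintf("Swivel %s -> %s: %.3f deg", x$reference, x$target, x$angle_deg))
  if (is.finite(x$bridge_helix_axis_angle))
    cat(sprintf(" (axis %.1f deg off the bridge helix)", x$bridge_helix_axis_angle))
  cat(sprintf("\n  core fit: %d atoms, rmsd %.3f A; swivel module: %d atoms\n",
              x$n_core_atoms, x$core_rmsd, x$n_swivel_atoms))
  rm <- x$per_domain_rmsd
  cat("  per-domain CA rmsd after core alignment (A):\n")
  for (d in names(rm)) cat(sprintf("    %-16s %.3f\n", d, rm[[d]]))
  invisible(x)
}

#' Displacement of a single atom between two aligned structures
#'
#' Aligns `target` onto `reference` on `align_on` (identity pairing) and
#' reports the Euclidean distance between the probe atom in the two models,
#' e.g. the 15-A displacement of the beta E1006 CA between swiveled and
#' non-swiveled complexes after core alignment.
#'
#' @param reference,target `StructureModel`s.
#' @param align_on selection (expression or string) used for the alignment.
#' @param probe selection resolving to exactly one atom in each model.
#' @return distance in Angstrom.
#' @export
atom_displacement <- function(reference, target, align_on, probe) {
  ref_at <- select_atoms(reference, align_on)
  tgt_at <- select_atoms(target, align_on)
  fit <- kabsch_superpose(tgt_at, ref_at, pairing = "by_identity")
  aligned <- apply_transform(fit$transform, target)
  p_ref <- select_one_atom(reference, probe)
  p_tgt <- select_one_atom(aligned, probe)
  vnorm(as.numeric(atom_xyz(p_tgt) - atom_xyz(p_ref)))
}

#' Distance between two atoms of one structure
#'
#' @param model a `StructureModel`.
#' @param a,b selections each resolving to exactly one atom (e.g. the
#'   catalytic Mg2+ and the beta' ZBD Zn2+).
#' @return distance in Angstrom.
#' @export
pairwise_distance <- function(model, a, b) {
  at_a <- select_one_atom(model, a, "atom a")
  at_b <- select_one_atom(model, b, "atom b")
  vnorm(as.numeric(atom_xyz(at_a) - atom_xyz(at_b)))
}
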