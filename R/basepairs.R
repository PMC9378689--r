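# Saenger catalog: classes the putRNA analysis names, plus canonical WC.
# Each entry: unordered base identities + donor/acceptor edge-atom pattern
# (atom of the first-listed base, atom of the second).
SAENGER_CATALOG <- list(
  XIX    = list(bases = c("G", "C"),
                pattern = list(c("N1", "N3"), c("N2", "O2"), c("O6", "N4"))),
  XX     = list(bases = c("A", "U"),
                pattern = list(c("N1", "N3"), c("N6", "O4"))),
  XX.AT  = list(bases = c("A", "T"),
                pattern = list(c("N1", "N3"), c("N6", "O4")), class = "XX"),
  XXVIII = list(bases = c("G", "U"),
                pattern = list(c("N1", "O2"), c("O6", "N3"))),
  XXVIII.GT = list(bases = c("G", "T"),
                   pattern = list(c("N1", "O2"), c("O6", "N3")),
                   class = "XXVIII"),
  VIII   = list(bases = c("A", "G"),
                pattern = list(c("N1", "N1"), c("N6", "O6"))),
  XI     = list(bases = c("G", "A"),
                pattern = list(c("N2", "N7"), c("N3", "N6"))))

# per-residue nucleic geometry used by pair detection
residue_base_info <- function(atoms) {
  k <- paste(atoms$chain, atoms$resno, atoms$insert)
  keep <- is_nucleic(atoms$resid)
  atoms <- atoms[keep, , drop = FALSE]
  k <- k[keep]
  out <- list()
  for (resk in unique(k)) {
    resat <- atoms[k == resk, , drop = FALSE]
    bl <- base_letter(resat$resid[1L])
    if (is.na(bl)) next
    c1 <- which(resat$name == "C1'")
    ring <- BASE_RING_ATOMS[[bl]]
    ring_idx <- match(ring, resat$name)
    ring_idx <- ring_idx[!is.na(ring_idx)]
    if (!length(c1) || length(ring_idx) < 4L) next
    ring_xyz <- atom_xyz(resat[ring_idx, ])
    don <- resat[resat$name %in% BASE_DONORS[[bl]], , drop = FALSE]
    acc <- resat[resat$name %in% BASE_ACCEPTORS[[bl]], , drop = FALSE]
    out[[resk]] <- list(key = resk, chain = resat$chain[1L],
                        resno = resat$resno[1L], insert = resat$insert[1L],
                        resid = resat$resid[1L], base = bl,
                        c1 = as.numeric(atom_xyz(resat[c1[1L], ])),
                        normal = ring_normal(ring_xyz),
                        donors = don, acceptors = acc)
  }
  out
}

count_base_hbonds <- function(ri, rj, cutoff, max_elevation = 35) {
  # pairing H bonds are coplanar with the bases: the donor-acceptor vector
  # must stay within `max_elevation` degrees of both base planes, which
  # excludes stacking contacts between neighbouring steps
  in_plane <- function(v) {
    for (nrm in list(ri$normal, rj$normal)) {
      elev <- abs(90 - angle_between_deg(v, nrm))
      if (elev > max_elevation) return(FALSE)
    }
    TRUE
  }
  score <- function(d_at, a_at) {
    if (nrow(d_at) == 0L || nrow(a_at) == 0L) return(NULL)
    dx <- atom_xyz(d_at); ax <- atom_xyz(a_at)
    dm <- sqrt(pmax(outer(rowSums(dx^2), rowSums(ax^2), `+`) -
                      2 * (dx %*% t(ax)), 0))
    hit <- which(dm <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    ok <- vapply(seq_len(nrow(hit)), function(k)
      in_plane(ax[hit[k, 2L], ] - dx[hit[k, 1L], ]), TRUE)
    hit <- hit[ok, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(a = d_at$name[hit[, 1L]], b = a_at$name[hit[, 2L]],
               dist = dm[hit], stringsAsFactors = FALSE)
  }
  h1 <- score(ri$donors, rj$acceptors)
  h2 <- score(rj$donors, ri$acceptors)
  if (!is.null(h2)) h2 <- data.frame(a = h2$b, b = h2$a, dist = h2$dist)
  hb <- rbind(h1, h2)
  if (is.null(hb) || nrow(hb) == 0L) return(hb)
  # one H bond per unordered atom pair
  hb <- hb[!duplicated(paste(hb$a, hb$b)), , drop = FALSE]
  hb[order(hb$dist), , drop = FALSE]
}

#' Detect base pairs in nucleic-acid chains
#'
#' Candidate pairs satisfy a C1'-C1' distance window, an inter-base-plane
#' angle cutoff, and at least one inter-base hydrogen bond (heavy-atom
#' donor/acceptor edge atoms).  Pairs are accepted greedily by descending
#' H-bond count then ascending C1'-C1' distance; each residue may take at
#' most `max_partners` partners (2 by default, supporting the put stem I
#' minor-groove triplex) and a second partner is flagged `is_triplex_extra`.
#'
#' @param model a `StructureModel`.
#' @param chains character vector of chain IDs, a selection, or `NULL` (all).
#' @param c1c1_range allowed C1'-C1' distance window in Angstrom.
#' @param max_plane_angle maximum angle between base planes (degrees).
#' @param hbond_cutoff heavy-atom H-bond distance cutoff (Angstrom).
#' @param min_separation minimum |residue number| separation within a chain.
#' @param max_partners partners allowed per residue.
#' @return data frame of class `BasePairSet`: `chain_i`, `res_i`, `base_i`,
#'   `chain_j`, `res_j`, `base_j`, `n_hbonds`, `c1_c1_distance`,
#'   `coplanarity_angle`, `is_watson_crick`, `saenger_class`,
#'   `is_triplex_extra`, plus a `hbond_atoms` list column.
#' @export
detect_base_pairs <- function(model, chains = NULL,
                              c1c1_range = c(7.5, 11.5),
                              max_plane_angle = 35, hbond_cutoff = 3.5,
                              min_separation = 3L, max_partners = 2L) {
  atoms <- if (is.null(chains)) model$atoms
  else if (is.character(chains) && !any(grepl(":", chains)))
    model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  else select_atoms(model, chains)
  info <- residue_base_info(atoms)
  if (!length(info)) stop("no nucleic-acid residues with base atoms found")
  keys <- names(info)
  n <- length(keys)
  cand <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ri <- info[[i]]; rj <- info[[j]]
    if (ri$chain == rj$chain && abs(ri$resno - rj$resno) < min_separation) next
    d <- vnorm(ri$c1 - rj$c1)
    if (d < c1c1_range[1L] || d > c1c1_range[2L]) next
    pl <- angle_between_deg(ri$normal, rj$normal)
    pl <- min(pl, 180 - pl)
    if (pl > max_plane_angle) next
    hb <- count_base_hbonds(ri, rj, hbond_cutoff)
    if (is.null(hb) || nrow(hb) == 0L) next
    cand[[length(cand) + 1L]] <- list(i = i, j = j, d = d, plane = pl, hb = hb)
  }
  if (!length(cand))
    return(empty_basepair_set())
  nhb <- vapply(cand, function(p) nrow(p$hb), 0L)
  dd <- vapply(cand, function(p) p$d, 0)
  ij <- vapply(cand, function(p) paste(keys[p$i], keys[p$j]), "")
  cand <- cand[order(-nhb, dd, ij)]
  used <- setNames(integer(n), keys)
  rows <- list()
  for (p in cand) {
    ki <- keys[p$i]; kj <- keys[p$j]
    if (used[ki] >= max_partners || used[kj] >= max_partners) next
    extra <- used[ki] > 0L || used[kj] > 0L
    used[ki] <- used[ki] + 1L; used[kj] <- used[kj] + 1L
    ri <- info[[p$i]]; rj <- info[[p$j]]
    cls <- match_saenger(ri$base, rj$base, p$hb)
    rows[[length(rows) + 1L]] <- data.frame(
      chain_i = ri$chain, res_i = ri$resno, base_i = ri$base,
      chain_j = rj$chain, res_j = rj$resno, base_j = rj$base,
      n_hbonds = nrow(p$hb), c1_c1_distance = p$d,
      coplanarity_angle = p$plane,
      is_watson_crick = cls %in% c("XIX", "XX") && nrow(p$hb) >= 2L,
      saenger_class = cls, is_triplex_extra = extra,
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$hbond_atoms <- list(p$hb)
  }
  if (!length(rows)) return(empty_basepair_set())
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_i, out$res_i, out$chain_j, out$res_j), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("BasePairSet", "data.frame")
  out
}

empty_basepair_set <- function() {
  out <- data.frame(chain_i = character(0), res_i = integer(0),
                    base_i = character(0), chain_j = character(0),
                    res_j = integer(0), base_j = character(0),
                    n_hbonds = integer(0), c1_c1_distance = numeric(0),
                    coplanarity_angle = numeric(0),
                    is_watson_crick = logical(0),
                    saenger_class = character(0),
                    is_triplex_extra = logical(0), stringsAsFactors = FALSE)
  out$hbond_atoms <- list()
  class(out) <- c("BasePairSet", "data.frame")
  out
}

# classify one observed pair against the catalog; the catalog pattern must
# be fully contained in the observed H-bond atom pairs
match_saenger <- function(base_i, base_j, hb) {
  obs_fwd <- paste(hb$a, hb$b)
  obs_rev <- paste(hb$b, hb$a)
  matches <- character(0)
  for (nm in names(SAENGER_CATALOG)) {
    ent <- SAENGER_CATALOG[[nm]]
    pat <- vapply(ent$pattern, paste, "", collapse = " ")
    ok <- if (base_i == ent$bases[1L] && base_j == ent$bases[2L])
      all(pat %in% obs_fwd)
    else if (base_i == ent$bases[2L] && base_j == ent$bases[1L])
      all(pat %in% obs_rev)
    else FALSE
    if (ok) matches <- c(matches, ent$class %||% nm)
  }
  matches <- unique(matches)
  if (length(matches) == 1L) matches else
    if (length(matches) > 1L) "unassigned" else "other"
}

#' Saenger class of a detected base pair
#'
#' Re-classifies one row of a [detect_base_pairs()] result (or an equivalent
#' record with `base_i`, `base_j` and a `hbond_atoms` data frame) against the
#' shipped catalog: XIX/XX canonical Watson-Crick, XXVIII G.U wobble,
#' VIII A.G imino, XI G.A sheared; anything else is `other`, ambiguous
#' patterns `unassigned`.
#'
#' @param pair single-row `BasePairSet` or list with `base_i`, `base_j`,
#'   `hbond_atoms`.
#' @return character class label.
#' @export
assign_saenger_class <- function(pair) {
  hb <- pair$hbond_atoms
  if (is.list(hb) && !is.data.frame(hb)) hb <- hb[[1L]]
  if (is.null(hb) || nrow(hb) == 0L) return("unassigned")
  match_saenger(pair$base_i[1L], pair$base_j[1L], hb)
}
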