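METAL_RESIDUES <- c("ZN", "MG", "MN", "FE", "NA", "K", "CA", "NI", "CU", "CO")
WATER_RESIDUES <- c("HOH", "WAT", "DOD")

#' Construct a structure model from an atom table
#'
#' A `StructureModel` is the coordinate container used by every geometric
#' stage: a data frame of heavy atoms (author numbering, altlocs resolved)
#' plus a flag marking metal ions such as the catalytic Mg2+ and the two
#' Zn2+ of the beta' subunit.
#'
#' @param atoms data frame with columns `serial`, `name`, `elem`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `occ`, `alt`, `het`.
#' @param id accession or label for the model.
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(atoms, id = "model") {
  required <- c("serial", "name", "elem", "resid", "chain", "resno",
                "insert", "x", "y", "z", "occ", "alt", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  bad_occ <- !is.na(atoms$occ) & (atoms$occ < 0 | atoms$occ > 1)
  if (any(bad_occ)) stop("occupancy outside [0,1] for ", sum(bad_occ), " atom(s)")
  atoms$is_ion <- atoms$het & (toupper(atoms$resid) %in% METAL_RESIDUES)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, atoms$alt)
  if (anyDuplicated(key))
    stop("duplicate atoms after altloc resolution: ",
         key[duplicated(key)][1L])
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("StructureModel '%s': %d atoms, %d chains (%s), %d ions\n",
              x$id, nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              sum(a$is_ion)))
  invisible(x)
}

# keep highest occupancy per (chain,resno,insert,name); ties -> first altloc
# alphabetically.  Deterministic and idempotent.
resolve_altlocs <- function(atoms) {
  alt <- ifelse(is.na(atoms$alt) | atoms$alt == "", "", atoms$alt)
  occ <- ifelse(is.na(atoms$occ), 1, atoms$occ)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  ord <- order(key, -occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- atoms[keep, , drop = FALSE]
  out[order(out$serial), , drop = FALSE]
}

#' Read an atomic coordinate file
#'
#' Reads PDB (fixed-width v3.3) or mmCIF files into a [structure_model()].
#' Alternate locations are resolved by keeping the highest-occupancy copy
#' (ties broken alphabetically by altloc), waters are discarded by default
#' (none are modelled in cryo-EM depositions at this resolution), and
#' hetero metal ions are retained and flagged.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param id model label; defaults to the file base name.
#' @param keep_waters keep water molecules (default `FALSE`).
#' @return a `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           id = NULL, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s' as %s: %s",
                                     path, format, conditionMessage(e))))
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in ", path)
  # strip paired CIF quoting only; a trailing prime (C1') is a real name
  dequote <- function(x) sub("^'(.*)'$", "\\1",
                             sub('^"(.*)"$', "\\1", trimws(x)))
  a$elety <- dequote(a$elety)
  a$resid <- dequote(a$resid)
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name   = trimws(a$elety),
    elem   = trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                           guess_element(a$elety), a$elesy)),
    resid  = trimws(a$resid),
    chain  = ifelse(is.na(a$chain), "", a$chain),
    resno  = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ    = ifelse(is.na(a$o), 1, pmin(1, pmax(0, a$o))),
    alt    = ifelse(is.na(a$alt), "", a$alt),
    het    = a$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!keep_waters)
    atoms <- atoms[!(toupper(atoms$resid) %in% WATER_RESIDUES), , drop = FALSE]
  atoms <- atoms[toupper(atoms$elem) != "H", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty model (no heavy atoms) in ", path)
  atoms <- resolve_altlocs(atoms)
  atoms$alt <- ""
  structure_model(atoms, id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

# element from an atom name when the element column is absent (PDB shortcuts)
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- substr(sub("^[0-9']+", "", nm), 1, 1)
  out[two %in% METAL_RESIDUES & nchar(nm) == 2] <- two[two %in% METAL_RESIDUES & nchar(nm) == 2]
  out
}

#' Write a structure model to disk
#'
#' Writes PDB through bio3d; mmCIF as a minimal `atom_site` loop (the subset
#' read back by [read_structure()]).
#'
#' @param model a `StructureModel`.
#' @param path output path.
#' @param format `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (format == "pdb") {
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid, eleno = a$serial,
                     elety = a$name, chain = a$chain,
                     insert = ifelse(a$insert == "", NA, a$insert),
                     o = a$occ, b = rep(0, nrow(a)), elesy = a$elem,
                     end = TRUE)
  } else {
    # standard PDBx/mmCIF atom_site loop (deposition column order)
    hdr <- c(sprintf("data_%s", gsub("[^A-Za-z0-9_]", "_", model$id)),
             "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    nm <- ifelse(grepl("'", a$name), paste0('"', a$name, '"'), a$name)
    ch <- ifelse(a$chain == "", ".", a$chain)
    rows <- sprintf(paste("%-6s %d %s %s . %s %s 1 %d %s",
                          "%.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1"),
                    ifelse(a$het, "HETATM", "ATOM"), a$serial, a$elem, nm,
                    a$resid, ch, a$resno,
                    ifelse(a$insert == "", "?", a$insert),
                    a$x, a$y, a$z, a$occ, 0, a$resno, a$resid, ch, nm)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}
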