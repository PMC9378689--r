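#' Build an atom selection expression
#'
#' Selections address atoms by chain, inclusive author-numbered residue
#' ranges, atom names and/or elements.  Overlapping ranges have set
#' semantics (a residue is selected once).
#'
#' @param chain chain identifier, or `NULL` for any chain.
#' @param ranges list of `c(start, end)` inclusive residue ranges (author
#'   numbering), a single such vector, or `NULL` for all residues.
#' @param atoms character vector of atom names (e.g. `"CA"`, `"P"`), or
#'   `NULL` for all.
#' @param elements character vector of element symbols, or `NULL`.
#' @return an object of class `SelectionExpr`.
#' @export
selection <- function(chain = NULL, ranges = NULL, atoms = NULL,
                      elements = NULL) {
  if (!is.null(ranges)) {
    if (is.numeric(ranges)) ranges <- list(ranges)
    for (r in ranges) {
      if (length(r) != 2L || any(!is.finite(r)))
        stop("each range must be c(start, end)")
      if (r[1L] > r[2L]) stop("range start exceeds end: ", r[1L], "-", r[2L])
    }
  }
  structure(list(chain = chain, ranges = ranges, atoms = atoms,
                 elements = elements), class = "SelectionExpr")
}

#' Parse a compact selection string
#'
#' Accepts `"chain:start-end[:atom1,atom2]"`; `start-end` may be a single
#' residue number, and several comma-separated ranges are allowed
#' (`"C:3-342,1318-1344:CA"`).  A bare chain (`"R"`) selects the whole chain.
#'
#' @param text selection string.
#' @return a `SelectionExpr`.
#' @export
parse_selection <- function(text) {
  parts <- strsplit(trimws(text), ":", fixed = TRUE)[[1L]]
  if (length(parts) < 1L || length(parts) > 3L || parts[1L] == "")
    stop("cannot parse selection string: ", text)
  ranges <- NULL
  if (length(parts) >= 2L && nzchar(parts[2L])) {
    ranges <- lapply(strsplit(parts[2L], ",", fixed = TRUE)[[1L]], function(r) {
      nums <- as.integer(strsplit(r, "-", fixed = TRUE)[[1L]])
      if (anyNA(nums) || length(nums) > 2L)
        stop("bad residue range '", r, "' in selection: ", text)
      if (length(nums) == 1L) nums <- c(nums, nums)
      nums
    })
  }
  atoms <- if (length(parts) == 3L && nzchar(parts[3L]))
    strsplit(parts[3L], ",", fixed = TRUE)[[1L]] else NULL
  selection(chain = parts[1L], ranges = ranges, atoms = atoms)
}

selection_mask <- function(model, expr) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(expr$chain)) keep <- keep & a$chain == expr$chain
  if (!is.null(expr$ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in expr$ranges)
      in_range <- in_range | (a$resno >= r[1L] & a$resno <= r[2L])
    keep <- keep & in_range
  }
  if (!is.null(expr$atoms)) keep <- keep & a$name %in% expr$atoms
  if (!is.null(expr$elements))
    keep <- keep & toupper(a$elem) %in% toupper(expr$elements)
  keep
}

#' Select atoms from a structure model
#'
#' @param model a `StructureModel`.
#' @param expr a `SelectionExpr` (or list of them, whose union is taken), or
#'   a selection string understood by [parse_selection()].
#' @param allow_empty return a zero-row table instead of erroring when
#'   nothing matches.
#' @return atom data frame ordered by (chain, residue, atom name).
#' @export
select_atoms <- function(model, expr, allow_empty = FALSE) {
  if (is.character(expr)) expr <- parse_selection(expr)
  exprs <- if (inherits(expr, "SelectionExpr")) list(expr) else expr
  keep <- rep(FALSE, nrow(model$atoms))
  for (e in exprs) keep <- keep | selection_mask(model, e)
  out <- model$atoms[keep, , drop = FALSE]
  if (nrow(out) == 0L && !allow_empty)
    stop("selection resolved to zero atoms on model '", model$id, "'")
  out <- out[order(out$chain, out$resno, out$insert, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

select_one_atom <- function(model, expr, what = "probe") {
  at <- select_atoms(model, expr, allow_empty = TRUE)
  if (nrow(at) != 1L)
    stop(sprintf("%s selection must resolve to exactly one atom (got %d)",
                 what, nrow(at)))
  at
}
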