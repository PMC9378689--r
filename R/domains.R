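SWIVEL_MEMBERS <- c("clamp", "shelf", "jaw", "SI3", "betaprime_cterm")

#' Construct a named domain set
#'
#' A `DomainSet` maps domain names (core, clamp, shelf, jaw, SI3,
#' betaprime_cterm, optionally dock, lid, ZBD, bridge_helix, ...) to atom
#' selections.  The five swivel-module members rotate as a rigid body during
#' RNAP swiveling; the core module is the frame everything is aligned on.
#' Swivel-module selections must be pairwise disjoint at the residue level.
#'
#' @param domains named list; each element a `SelectionExpr`, a list of
#'   `SelectionExpr`s, or a selection string / vector of strings.
#' @param name label for the set.
#' @param require_swivel insist on core plus all five swivel members.
#' @return an object of class `DomainSet`.
#' @export
domain_set <- function(domains, name = "domains", require_swivel = TRUE) {
  domains <- lapply(domains, function(d) {
    if (is.character(d)) d <- lapply(unlist(strsplit(d, "\\s+")), parse_selection)
    if (inherits(d, "SelectionExpr")) d <- list(d)
    d
  })
  if (require_swivel) {
    needed <- c("core", SWIVEL_MEMBERS)
    miss <- setdiff(needed, names(domains))
    if (length(miss))
      stop("domain set lacks mandatory domain(s): ", paste(miss, collapse = ", "))
  }
  res_keys <- lapply(domains, function(d) {
    keys <- character(0)
    for (e in d) {
      ranges <- e$ranges %||% list(c(-1e9, 1e9))
      for (r in ranges)
        keys <- c(keys, paste(e$chain %||% "*", seq(r[1L], r[2L])))
    }
    unique(keys)
  })
  members <- intersect(SWIVEL_MEMBERS, names(domains))
  if (length(members) > 1L) {
    for (i in seq_len(length(members) - 1L))
      for (j in seq(i + 1L, length(members))) {
        ov <- intersect(res_keys[[members[i]]], res_keys[[members[j]]])
        if (length(ov))
          stop(sprintf("swivel-module domains '%s' and '%s' overlap at residue %s",
                       members[i], members[j], ov[1L]))
      }
  }
  structure(list(name = name, domains = domains), class = "DomainSet")
}

#' @export
print.DomainSet <- function(x, ...) {
  cat(sprintf("DomainSet '%s' with %d domains: %s\n", x$name,
              length(x$domains), paste(names(x$domains), collapse = ", ")))
  invisible(x)
}

#' Load a domain-definition config file
#'
#' The config is a structured text file of `[domain.<name>]` tables whose
#' `select` entry holds one or more space-separated selection strings
#' (`"C:3-342 C:1318-1344"`).  The file must declare `core` and all five
#' swivel-module members.  The packaged default
#' (`system.file("extdata", "domains_ecoli.cfg", package = "putkit")`) holds
#' curated E. coli RNAP residue ranges; users override per structure.
#'
#' @param path config file path; defaults to the packaged E. coli set.
#' @return a validated `DomainSet`.
#' @export
load_domain_config <- function(path = default_domain_config()) {
  if (!file.exists(path)) stop("domain config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  domains <- list()
  current <- NULL
  for (ln in lines) {
    hdr <- regmatches(ln, regexec("^\\[domain\\.([A-Za-z0-9_]+)\\]$", ln))[[1L]]
    if (length(hdr) == 2L) { current <- hdr[2L]; next }
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*\"?([^\"]*)\"?$", ln))[[1L]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    if (is.null(current)) stop("entry outside a [domain.*] table: ", ln)
    if (kv[2L] != "select")
      stop("unknown key '", kv[2L], "' in [domain.", current, "]")
    domains[[current]] <- strsplit(trimws(kv[3L]), "\\s+")[[1L]]
  }
  if (!length(domains)) stop("no [domain.*] tables found in ", path)
  domain_set(domains, name = basename(path))
}

#' @rdname load_domain_config
#' @export
default_domain_config <- function() {
  system.file("extdata", "domains_ecoli.cfg", package = "putkit", mustWork = TRUE)
}

# resolve one named domain to its atom table; the >=3-atom invariant is
# enforced here, against a concrete structure
resolve_domain <- function(model, domains, name, atoms = NULL) {
  if (!name %in% names(domains$domains))
    stop("domain '", name, "' not present in DomainSet '", domains$name, "'")
  exprs <- domains$domains[[name]]
  if (!is.null(atoms))
    exprs <- lapply(exprs, function(e) { e$atoms <- atoms; e })
  chains <- unlist(lapply(exprs, `[[`, "chain"))
  missing_ch <- setdiff(chains, unique(model$atoms$chain))
  if (length(missing_ch))
    stop(sprintf("domain '%s' names chain(s) absent from model '%s': %s",
                 name, model$id, paste(missing_ch, collapse = ", ")))
  at <- select_atoms(model, exprs, allow_empty = TRUE)
  if (nrow(at) < 3L)
    stop(sprintf("domain '%s' resolves to %d atom(s) (<3) on model '%s'",
                 name, nrow(at), model$id))
  at
}
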