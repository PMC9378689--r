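# Idealized planar base templates built from standard ring geometry
# (regular hexagon/pentagon rings, standard bond lengths), plus a numeric
# base-pair placement that matches hydrogen-bond donor-acceptor distances.
# Generator-side code: geometry is idealized, not refined.

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L, byrow = TRUE)
}

# planar heavy-atom template for one base, from the shipped idealized
# template table; named n x 3 matrix (z = 0) with C1' included; glycosidic
# N at the conventional N1/N9
base_template <- function(base) {
  base <- toupper(base)
  if (is.null(.putkit_cache$base_templates)) {
    path <- system.file("extdata", "base_templates.tsv", package = "putkit",
                        mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .putkit_cache$base_templates <- lapply(split(tab, tab$base), function(d) {
      m <- cbind(x = d$x, y = d$y, z = 0)
      rownames(m) <- d$atom
      attr(m, "glycosidic") <- if ("N9" %in% d$atom) "N9" else "N1"
      m
    })
  }
  tmpl <- .putkit_cache$base_templates[[base]]
  if (is.null(tmpl)) stop("no base template for '", base, "'")
  tmpl
}

# approximate ribose + phosphate heavy atoms in the local frame at C1'
# (x away from the base, z = base normal); used by the duplex generator
SUGAR_OFFSETS <- rbind(
  `O4'` = c(0.70, 1.20, 0.25),
  `C2'` = c(0.80, -0.90, 0.95),
  `O2'` = c(0.40, -2.05, 0.35),
  `C3'` = c(2.20, -0.85, 1.20),
  `O3'` = c(2.95, -2.00, 1.05),
  `C4'` = c(2.10, 0.70, 1.05),
  `C5'` = c(3.05, 1.55, 0.15),
  `O5'` = c(2.65, 2.85, -0.30),
  P     = c(3.45, 4.05, -0.65),
  OP1   = c(4.65, 3.95, -1.45),
  OP2   = c(2.55, 5.05, -1.05))

place_base_2d <- function(tmpl, theta, c1_at, mirror = FALSE) {
  xy <- tmpl[, 1:2, drop = FALSE]
  if (mirror) xy[, 2L] <- -xy[, 2L]
  xy <- sweep(xy, 2L, xy["C1'", ])             # C1' to origin
  xy <- xy %*% t(rot2(theta))
  sweep(xy, 2L, c1_at, `+`)
}

# place two bases in a plane so the listed donor-acceptor atom pairs sit at
# ~2.9 A; deterministic multi-start Nelder-Mead.  Returns named coordinate
# matrices (z = 0) with C1'(1) at the origin and C1'(2) on +x.
pair_geometry <- function(base_i, base_j, hbond_atoms, c1c1_init = 10.4,
                          c1c1_bounds = c(8.2, 11.3), lambda_weight = 0.002) {
  keyname <- paste(base_i, base_j,
                   paste(vapply(hbond_atoms, paste, "", collapse = "-"),
                         collapse = ","),
                   c1c1_init, paste(c1c1_bounds, collapse = "-"), lambda_weight)
  if (is.null(.putkit_cache$pairs)) .putkit_cache$pairs <- list()
  if (!is.null(.putkit_cache$pairs[[keyname]]))
    return(.putkit_cache$pairs[[keyname]])
  ti <- base_template(base_i); tj <- base_template(base_j)
  gi <- attr(ti, "glycosidic"); gj <- attr(tj, "glycosidic")
  hb_i <- match(vapply(hbond_atoms, `[`, "", 1L), rownames(ti))
  hb_j <- match(vapply(hbond_atoms, `[`, "", 2L), rownames(tj))
  if (anyNA(hb_i) || anyNA(hb_j))
    stop("hbond atoms not present in base templates for ", base_i, "/", base_j)
  hb_pair_idx <- cbind(hb_i, hb_j)
  # atom pairs taking part in an H bond are exempt from the clash penalty
  clash_exempt <- matrix(FALSE, nrow(ti), nrow(tj))
  clash_exempt[hb_pair_idx] <- TRUE
  obj <- function(p) {
    th1 <- p[1L]; th2 <- p[2L]; cc <- p[3L]
    xi <- place_base_2d(ti, th1, c(0, 0))
    xj <- place_base_2d(tj, th2, c(cc, 0), mirror = TRUE)
    dm2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * (xi %*% t(xj))
    dm <- sqrt(pmax(dm2, 0))
    err <- sum((dm[hb_pair_idx] - 2.9)^2)
    lam1 <- angle_between_deg(c(1, 0), xi[gi, ])
    lam2 <- angle_between_deg(c(-1, 0), xj[gj, ] - c(cc, 0))
    err <- err + lambda_weight * ((lam1 - 55)^2 + (lam2 - 55)^2)
    if (cc < c1c1_bounds[1L]) err <- err + 10 * (c1c1_bounds[1L] - cc)^2
    if (cc > c1c1_bounds[2L]) err <- err + 10 * (cc - c1c1_bounds[2L])^2
    clash <- !clash_exempt & dm < 2.6
    if (any(clash)) err <- err + 2 * sum((2.6 - dm[clash])^2)
    err
  }
  best <- NULL
  for (th1 in seq(0, 270, by = 90)) for (th2 in seq(0, 270, by = 90)) {
    fit <- optim(c(th1, th2, c1c1_init), obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  out <- list(
    base_i = cbind(place_base_2d(ti, p[1L], c(0, 0)), z = 0),
    base_j = cbind(place_base_2d(tj, p[2L], c(p[3L], 0), mirror = TRUE), z = 0),
    c1c1 = p[3L], hbond_atoms = hbond_atoms, objective = best$value)
  .putkit_cache$pairs[[keyname]] <- out
  out
}

WC_PATTERNS <- list(
  `G:C` = list(c("N1", "N3"), c("N2", "O2"), c("O6", "N4")),
  `A:U` = list(c("N1", "N3"), c("N6", "O4")),
  `A:T` = list(c("N1", "N3"), c("N6", "O4")))

wc_complement <- function(base, dna = FALSE) {
  comp <- c(A = if (dna) "T" else "U", U = "A", T = "A", G = "C", C = "G")
  unname(comp[toupper(base)])
}

# Watson-Crick geometry with `base` on strand 1; the H-bond pattern is the
# canonical one, written from the strand-1 base
wc_pair_geometry <- function(base, dna_partner = FALSE) {
  base <- toupper(base)
  comp <- wc_complement(base, dna = dna_partner)
  key <- if (base %in% c("G", "C")) "G:C" else if (comp == "T" || base == "T")
    "A:T" else "A:U"
  pat <- WC_PATTERNS[[key]]
  if (base == substr(key, 1L, 1L))
    pair_geometry(base, comp, pat)
  else
    pair_geometry(base, comp, lapply(pat, rev))
}
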