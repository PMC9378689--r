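# sugar/backbone placement at a base's C1' given the base's glycosidic
# geometry; approximate idealized geometry, adequate for selections and I/O
attach_sugar <- function(base_xyz, gly_name, normal_z = 1, dna = FALSE) {
  c1 <- base_xyz["C1'", ]
  x <- unit(c1 - base_xyz[gly_name, ])
  z <- c(0, 0, normal_z)
  y <- c(z[2L] * x[3L] - z[3L] * x[2L],
         z[3L] * x[1L] - z[1L] * x[3L],
         z[1L] * x[2L] - z[2L] * x[1L])
  basis <- rbind(x, y, z)
  off <- SUGAR_OFFSETS
  if (dna) off <- off[rownames(off) != "O2'", , drop = FALSE]
  sug <- sweep(off %*% basis, 2L, c1, `+`)
  rownames(sug) <- rownames(off)
  sug
}

# third-strand base placed against the minor-groove edge of the strand-1
# purine of a Watson-Crick pair; one N3(U)...N3(purine) hydrogen bond
third_base_geometry <- function(purine) {
  key <- paste0("third:", purine)
  if (!is.null(.putkit_cache$pairs[[key]])) return(.putkit_cache$pairs[[key]])
  g <- wc_pair_geometry(purine)
  tu <- base_template("U")
  pair_xy <- rbind(g$base_i[, 1:2, drop = FALSE], g$base_j[, 1:2, drop = FALSE])
  n3 <- g$base_i["N3", 1:2]
  c1p <- g$base_i["C1'", 1:2]
  hb_idx <- match("N3", rownames(tu))
  obj <- function(p) {
    xu <- place_base_2d(tu, p[1L], p[2:3])
    err <- (vnorm(xu[hb_idx, ] - n3) - 2.9)^2
    err <- err + 0.25 * (vnorm(xu["C1'", ] - c1p) - 9.5)^2
    dm <- sqrt(pmax(outer(rowSums(xu^2), rowSums(pair_xy^2), `+`) -
                      2 * (xu %*% t(pair_xy)), 0))
    dm[hb_idx, match("N3", rownames(pair_xy))] <- 99
    cl <- dm < 2.9
    if (any(cl)) err <- err + 4 * sum((2.9 - dm[cl])^2)
    err
  }
  best <- NULL
  for (th in seq(0, 300, by = 60)) for (sx in c(-6, -2, 2)) {
    fit <- optim(c(th, n3[1L] + sx, n3[2L] - 6), obj,
                 control = list(maxit = 800, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out <- list(xyz = cbind(place_base_2d(tu, best$par[1L], best$par[2:3]), z = 0),
              objective = best$value)
  .putkit_cache$pairs[[key]] <- out
  out
}

residue_rows <- function(xyz, chain, resno, resid, het = FALSE) {
  data.frame(serial = NA_integer_, name = rownames(xyz),
             elem = guess_element(rownames(xyz)), resid = resid,
             chain = chain, resno = resno, insert = "",
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             occ = 1, alt = "", het = het, stringsAsFactors = FALSE)
}

#' Generate an idealized duplex (or triplex) with known ground truth
#'
#' Full heavy-atom nucleotides placed by helical symmetry from the shipped
#' idealized templates: Watson-Crick pair geometry solved against standard
#' H-bond distances, stacked with A-form fiber parameters (twist 32.7
#' degrees, rise 2.81 A).  Options add a mid-helix bend (for kink-angle
#' ground truth) and a minor-groove third strand donating one H bond per
#' purine of strand 1 (triplex ground truth).
#'
#' @param n_pairs duplex length (>= 4); ignored if `sequence` given.
#' @param sequence strand-1 sequence (characters in ACGU); default a
#'   deterministic repeat of "GACU".
#' @param form `"A_RNA"` (chains A/B) or `"hybrid_RNA_DNA"` (RNA chain R,
#'   template DNA chain T).
#' @param bend_angle bend inserted between the two helix halves (degrees,
#'   <= 60).
#' @param third_strand add the minor-groove third strand (chain X).
#' @param twist,rise,axis_offset helical parameters (degrees, A, A).
#' @return a `DuplexFixture`: `model`, `n_pairs`, `form`, `bend_angle`,
#'   `third_strand`, `sequence`, `pairs` (ground-truth pairing table),
#'   `triples` (ground-truth triple table).
#' @export
make_duplex <- function(n_pairs = 10L, sequence = NULL,
                        form = c("A_RNA", "hybrid_RNA_DNA"),
                        bend_angle = 0, third_strand = FALSE,
                        twist = 32.7, rise = 2.81, axis_offset = 4.4) {
  form <- match.arg(form)
  if (bend_angle > 60) stop("bend_angle above 60 degrees is not supported")
  if (is.null(sequence))
    sequence <- paste(rep_len(strsplit("GACU", "")[[1L]], n_pairs),
                      collapse = "")
  bases <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(bases %in% c("A", "C", "G", "U")))
    stop("sequence must be RNA over A/C/G/U")
  L <- length(bases)
  if (L < 4L) stop("need at least 4 base pairs")
  dna <- form == "hybrid_RNA_DNA"
  ch1 <- if (dna) "R" else "A"
  ch2 <- if (dna) "T" else "B"
  bend_at <- floor(L / 2)
  z_bend <- (bend_at - 0.5) * rise
  Rbend <- rotation_from_axis_angle(c(1, 0, 0), bend_angle)

  all_rows <- list()
  pairs_gt <- list()
  triples_gt <- list()
  for (k in seq_len(L)) {
    b <- bases[k]
    g <- wc_pair_geometry(b, dna_partner = dna)
    gi <- attr(base_template(b), "glycosidic")
    comp <- wc_complement(b, dna = dna)
    gj <- attr(base_template(comp), "glycosidic")
    res1 <- rbind(g$base_i, attach_sugar(g$base_i, gi, normal_z = 1))
    res2 <- rbind(g$base_j, attach_sugar(g$base_j, gj, normal_z = -1,
                                         dna = dna))
    placed <- list(list(xyz = res1, chain = ch1, resno = k,
                        resid = if (dna) b else b),
                   list(xyz = res2, chain = ch2, resno = L + 1L - k,
                        resid = if (dna) paste0("D", comp) else comp))
    if (third_strand && b %in% c("A", "G")) {
      tg <- third_base_geometry(b)
      res3 <- rbind(tg$xyz, attach_sugar(tg$xyz, "N1", normal_z = 1))
      placed[[3L]] <- list(xyz = res3, chain = "X", resno = k, resid = "U")
      triples_gt[[length(triples_gt) + 1L]] <-
        data.frame(chain = ch1, resno = k, third_chain = "X", third_resno = k)
    }
    shift <- c(-(g$c1c1 / 2) - axis_offset, 0, 0)
    Rz <- rotation_from_axis_angle(c(0, 0, 1), (k - 1L) * twist)
    for (p in placed) {
      xyz <- sweep(p$xyz, 2L, shift, `+`)
      xyz <- xyz %*% t(Rz)
      xyz[, 3L] <- xyz[, 3L] + (k - 1L) * rise
      if (bend_angle > 0 && k > bend_at) {
        xyz[, 3L] <- xyz[, 3L] - z_bend
        xyz <- xyz %*% t(Rbend)
        xyz[, 3L] <- xyz[, 3L] + z_bend
      }
      all_rows[[length(all_rows) + 1L]] <-
        residue_rows(xyz, p$chain, p$resno, p$resid)
    }
    pairs_gt[[k]] <- data.frame(chain_i = ch1, res_i = k, base_i = b,
                                chain_j = ch2, res_j = L + 1L - k,
                                base_j = sub("^D", "", comp))
  }
  atoms <- do.call(rbind, all_rows)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$name), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, id = sprintf("duplex_%s_L%d", form, L))
  structure(list(model = model, n_pairs = L, form = form,
                 bend_angle = bend_angle, third_strand = third_strand,
                 sequence = paste(bases, collapse = ""),
                 pairs = do.call(rbind, pairs_gt),
                 triples = if (length(triples_gt)) do.call(rbind, triples_gt)
                 else NULL),
            class = "DuplexFixture")
}
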