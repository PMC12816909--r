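#' @title Per-residue structural features
#' @description Windowed-pLDDT order class, contact density, Shrake-Rupley
#'   solvent accessibility with burial classification, Kabsch-Sander
#'   secondary structure, and catalytic-site overlap, all computed from a
#'   `structure_model`.
#' @name structural-features
NULL

# van der Waals radii (Angstrom) for heavy elements; unknown elements fall
# back to carbon with a warning.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_FALLBACK <- 1.70

# Theoretical maximum accessible surface areas (Tien et al. 2013), Angstrom^2,
# used to normalise SASA into relative solvent accessibility.
MAX_ASA_TIEN <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

#' Order/disorder call from a windowed pLDDT mean
#'
#' A position is called `Order` when the mean pLDDT over a window of
#' `window` residues either side of the position (truncated at the termini,
#' `NA` values excluded) is greater than or equal to `threshold`, and
#' `Disorder` otherwise. A window with no finite values returns `NA`. The
#' boundary case of a mean of exactly `threshold` is `Order`.
#'
#' @param plddt_track Numeric vector of per-residue pLDDT values, indexed by
#'   1-based position (`NA` allowed at gaps).
#' @param pos 1-based position to classify.
#' @param window Integer window radius (default 2, i.e. a +/-2 window).
#' @param threshold pLDDT threshold (default 50).
#' @return `"Order"`, `"Disorder"` or `NA_character_`.
#' @export
classify_order <- function(plddt_track, pos, window = 2L, threshold = 50) {
  n <- length(plddt_track)
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > n) {
    stop("position ", pos, " out of range 1..", n)
  }
  lo <- max(1L, pos - window)
  hi <- min(n, pos + window)
  vals <- plddt_track[lo:hi]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_character_)
  if (mean(vals) >= threshold) "Order" else "Disorder"
}

#' Residue contact density
#'
#' Counts the distinct residues `j` with `|j - pos| > neighbor_exclusion`
#' (positions taken from residue numbering) that have any heavy atom within
#' `radius` of any heavy atom of the residue at `pos`.
#'
#' @param model A `structure_model`.
#' @param pos 1-based residue position (residue number).
#' @param radius Heavy-atom distance cutoff in Angstrom (default 5.0).
#' @param neighbor_exclusion Sequence-neighbour exclusion: residues within
#'   this many positions are never counted (default 2).
#' @return Non-negative integer, or `NA` if the residue has no heavy atoms.
#' @export
count_contacts <- function(model, pos, radius = 5.0, neighbor_exclusion = 2L) {
  at <- model$atoms
  if (!(pos %in% at$resno)) stop("no residue at position ", pos)
  self <- at[at$resno == pos, c("x", "y", "z"), drop = FALSE]
  if (nrow(self) == 0L) return(NA_integer_)
  other <- at[abs(at$resno - pos) > neighbor_exclusion, , drop = FALSE]
  if (nrow(other) == 0L) return(0L)
  sm <- as.matrix(self)
  om <- as.matrix(other[, c("x", "y", "z")])
  # min distance from each candidate atom to any atom of the query residue
  d2min <- rep(Inf, nrow(om))
  for (k in seq_len(nrow(sm))) {
    d2 <- (om[, 1] - sm[k, 1])^2 + (om[, 2] - sm[k, 2])^2 + (om[, 3] - sm[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  length(unique(other$resno[d2min <= radius^2]))
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice); the quadrature behind the Shrake-Rupley accessible area.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Orthonormal frame built from the molecule's own atoms (first distinct
# pair, first non-collinear third atom). The quadrature lattice is expressed
# in this frame so it co-rotates with the molecule, making the computed
# areas invariant under rigid motions to rounding error. For collinear
# molecules any perpendicular completes the frame: occlusion is then
# axially symmetric and the azimuthal orientation is immaterial.
molecule_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(diag(3))
  u <- NULL
  for (k in 2:n) {
    d <- xyz[k, ] - xyz[1, ]
    len <- sqrt(sum(d^2))
    if (len > 1e-6) { u <- d / len; break }
  }
  if (is.null(u)) return(diag(3))
  w <- NULL
  for (m in 2:n) {
    d <- xyz[m, ] - xyz[1, ]
    cr <- cross3(u, d)
    if (sqrt(sum(cr^2)) > 1e-6 * max(1, sqrt(sum(d^2)))) {
      w <- unit3(cr); break
    }
  }
  if (is.null(w)) {
    e <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- unit3(cross3(u, e))
  }
  cbind(u, cross3(w, u), w)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface: each atom is
#' expanded by the probe radius and sampled with a deterministic spherical
#' lattice of `n_points` points; a point is accessible when it lies outside
#' every other atom's expanded sphere. Per-atom areas are summed per
#' residue. The lattice is expressed in a frame built from the molecule's
#' own atoms, so areas are invariant under rigid rotation and translation
#' to rounding error. A sample point lying exactly on another atom's
#' expanded sphere (possible only for degenerate inputs such as coincident
#' atoms) is resolved by atom index: the lower-indexed atom keeps the
#' surface, so two coincident identical atoms jointly expose the area of
#' one.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Lattice points per atom (default 960).
#' @return Named numeric vector of per-residue SASA (Angstrom^2), names are
#'   residue numbers.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960L) {
  at <- model$atoms
  n <- nrow(at)
  radii <- unname(VDW_RADII[at$element])
  if (anyNA(radii)) {
    warning("unknown element(s) ", paste(unique(at$element[is.na(radii)]), collapse = ", "),
            "; using fallback vdW radius ", VDW_FALLBACK)
    radii[is.na(radii)] <- VDW_FALLBACK
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pts <- sphere_points(n_points) %*% t(molecule_frame(xyz))
  rexp <- radii + probe
  tol2 <- 1e-9
  area <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can occlude points of atom i
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rexp[i] + rexp)^2 & seq_len(n) != i)
    P <- pts * rexp[i]
    P[, 1] <- P[, 1] + xyz[i, 1]
    P[, 2] <- P[, 2] + xyz[i, 2]
    P[, 3] <- P[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 + (P[, 3] - xyz[j, 3])^2
      occ <- dj2 < rexp[j]^2 - tol2
      tie <- !occ & dj2 <= rexp[j]^2 + tol2
      if (j < i) occ <- occ | tie
      acc <- acc & !occ
    }
    area[i] <- 4 * pi * rexp[i]^2 * sum(acc) / n_points
  }
  tapply(area, at$resno, sum)[as.character(unique(at$resno))]
}

#' Relative solvent accessibility
#'
#' SASA divided by the residue type's theoretical maximum accessible area
#' (Tien et al. 2013), clipped to \[0, 1\]. Unknown residue types (`X`)
#' yield `NA`.
#'
#' @param sasa Per-residue SASA values (Angstrom^2).
#' @param aa One-letter residue codes, same length as `sasa`.
#' @return Numeric vector of RSA fractions in \[0, 1\].
#' @export
relative_accessibility <- function(sasa, aa) {
  maxasa <- unname(MAX_ASA_TIEN[aa])
  pmin(pmax(sasa / maxasa, 0), 1)
}

#' Burial class from relative solvent accessibility
#'
#' `Core` below 5% RSA, `MediumBuried` in \[5%, 50%), `MediumExposed` in
#' \[50%, 75%\] and `Exposed` above 75%; the four classes partition \[0, 1\].
#'
#' @param rsa Numeric vector of RSA fractions in \[0, 1\] (`NA` allowed).
#' @return Character vector of classes, `NA` propagated.
#' @export
classify_burial <- function(rsa) {
  out <- rep(NA_character_, length(rsa))
  ok <- !is.na(rsa)
  out[ok & rsa < 0.05] <- "Core"
  out[ok & rsa >= 0.05 & rsa < 0.50] <- "MediumBuried"
  out[ok & rsa >= 0.50 & rsa <= 0.75] <- "MediumExposed"
  out[ok & rsa > 0.75] <- "Exposed"
  out
}

backbone_coords <- function(at, resno, name) {
  row <- which(at$resno == resno & at$elety == name)
  if (length(row) == 0L) return(NULL)
  as.numeric(at[row[1], c("x", "y", "z")])
}

#' Secondary-structure assignment (Kabsch-Sander style)
#'
#' Detects backbone hydrogen bonds with the Kabsch-Sander electrostatic
#' energy model. The amide H position is inferred from the preceding peptide
#' plane (N-H parallel to the previous residue's C=O, 1.0 Angstrom from N);
#' a bond is called when the dipole-dipole energy
#' `27.888 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol is below -0.5.
#' Two consecutive i -> i+4 turns mark an alpha-helix; parallel or
#' antiparallel bridge patterns mark strands; everything else is loop.
#' Helix takes precedence over strand. Residues with incomplete backbones
#' (missing N, CA, C or O) are assigned `Loop` with a warning and excluded
#' from hydrogen-bond detection. Chain breaks (gaps in residue numbering)
#' are respected: turn and bridge patterns never span a gap.
#'
#' @param model A `structure_model` with backbone atoms N, CA, C, O.
#' @return Character vector per residue: `"Helix"`, `"Strand"` or `"Loop"`.
#' @export
assign_secondary_structure <- function(model) {
  at <- model$atoms
  resno <- unique(at$resno)
  n <- length(resno)
  idx_of <- function(r) match(r, resno)

  N <- Cc <- O <- H <- matrix(NA_real_, n, 3)
  complete <- logical(n)
  aa <- model_residues(model)$aa
  for (i in seq_len(n)) {
    ni <- backbone_coords(at, resno[i], "N")
    ci <- backbone_coords(at, resno[i], "C")
    oi <- backbone_coords(at, resno[i], "O")
    cai <- backbone_coords(at, resno[i], "CA")
    if (is.null(ni) || is.null(ci) || is.null(oi) || is.null(cai)) next
    N[i, ] <- ni; Cc[i, ] <- ci; O[i, ] <- oi
    complete[i] <- TRUE
  }
  if (!all(complete)) {
    warning("incomplete backbone at residue(s) ",
            paste(resno[!complete], collapse = ", "), "; assigned Loop")
  }
  # amide H from the preceding peptide plane; none for the chain start,
  # prolines, or after a numbering gap
  has_h <- logical(n)
  for (i in seq_len(n)) {
    if (!complete[i] || aa[i] == "P") next
    p <- idx_of(resno[i] - 1L)
    if (is.na(p) || !complete[p]) next
    v <- Cc[p, ] - O[p, ]
    H[i, ] <- N[i, ] + v / sqrt(sum(v^2))
    has_h[i] <- TRUE
  }
  # HB[i, j]: C=O of residue i accepts the N-H of residue j
  HB <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!complete[i]) next
    for (j in seq_len(n)) {
      if (!has_h[j] || abs(resno[j] - resno[i]) < 2L) next
      don <- rbind(N[j, ], H[j, ])
      dON <- sqrt(sum((O[i, ] - don[1, ])^2))
      dOH <- sqrt(sum((O[i, ] - don[2, ])^2))
      dCN <- sqrt(sum((Cc[i, ] - don[1, ])^2))
      dCH <- sqrt(sum((Cc[i, ] - don[2, ])^2))
      if (dON > 7) next  # dipoles too far apart to bond
      e <- 27.888 * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
      HB[i, j] <- e < -0.5
    }
  }
  hb <- function(ri, rj) {
    i <- idx_of(ri); j <- idx_of(rj)
    !is.na(i) && !is.na(j) && HB[i, j]
  }
  ss <- rep("Loop", n)
  # strands: parallel / antiparallel bridge patterns between non-neighbours
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ri <- resno[i]; rj <- resno[j]
      if (rj - ri <= 2L) next
      parallel <- (hb(ri - 1L, rj) && hb(rj, ri + 1L)) ||
                  (hb(rj - 1L, ri) && hb(ri, rj + 1L))
      antipar <- (hb(ri, rj) && hb(rj, ri)) ||
                 (hb(ri - 1L, rj + 1L) && hb(rj - 1L, ri + 1L))
      if (parallel || antipar) ss[c(i, j)] <- "Strand"
    }
  }
  # alpha-helix: two consecutive 4-turns mark residues i..i+3
  for (i in seq_len(n)) {
    ri <- resno[i]
    if (hb(ri - 1L, ri + 3L) && hb(ri, ri + 4L)) {
      for (k in 0:3) {
        m <- idx_of(ri + k)
        if (!is.na(m)) ss[m] <- "Helix"
      }
    }
  }
  ss[!complete] <- "Loop"
  ss
}

#' Catalytic-site overlap
#'
#' In `exact` mode, a position overlaps the catalytic site when it is one of
#' the annotated catalytic positions. In `proximity` mode, it overlaps when
#' any of its heavy atoms lies within `radius` of any heavy atom of an
#' annotated catalytic residue.
#'
#' @param pos 1-based residue position.
#' @param catalytic_sites Integer vector of annotated catalytic positions
#'   (may be empty).
#' @param model A `structure_model`; required for `proximity` mode.
#' @param mode `"exact"` (default) or `"proximity"`.
#' @param radius Heavy-atom distance cutoff for proximity mode (Angstrom).
#' @return Logical scalar.
#' @export
catalytic_overlap <- function(pos, catalytic_sites, model = NULL,
                              mode = c("exact", "proximity"), radius = 5.0) {
  mode <- match.arg(mode)
  if (length(catalytic_sites) == 0L) return(FALSE)
  if (mode == "exact") return(pos %in% catalytic_sites)
  if (is.null(model)) stop("proximity mode requires a structure model")
  if (pos %in% catalytic_sites) return(TRUE)
  at <- model$atoms
  self <- as.matrix(at[at$resno == pos, c("x", "y", "z"), drop = FALSE])
  cat_at <- as.matrix(at[at$resno %in% catalytic_sites, c("x", "y", "z"), drop = FALSE])
  if (nrow(self) == 0L || nrow(cat_at) == 0L) return(FALSE)
  for (k in seq_len(nrow(self))) {
    d2 <- (cat_at[, 1] - self[k, 1])^2 + (cat_at[, 2] - self[k, 2])^2 +
      (cat_at[, 3] - self[k, 3])^2
    if (any(d2 <= radius^2)) return(TRUE)
  }
  FALSE
}

#' Full per-residue structural profile
#'
#' Convenience wrapper computing, for every residue of a model, the order
#' class (windowed pLDDT), contact count, SASA, RSA, burial class,
#' secondary-structure class and catalytic flag in one pass.
#'
#' @param model A `structure_model`.
#' @param catalytic_sites Integer vector of catalytic positions (default
#'   none).
#' @param window,threshold Passed to [classify_order()].
#' @param contact_radius,neighbor_exclusion Passed to [count_contacts()].
#' @param probe,n_points Passed to [compute_sasa()].
#' @return Data frame with one row per residue: `resno`, `aa`, `plddt`,
#'   `order_class`, `contact_count`, `sasa`, `rsa`, `burial_class`,
#'   `ss_class`, `catalytic`.
#' @export
residue_profile <- function(model, catalytic_sites = integer(),
                            window = 2L, threshold = 50,
                            contact_radius = 5.0, neighbor_exclusion = 2L,
                            probe = 1.4, n_points = 960L) {
  res <- model_residues(model)
  n <- nrow(res)
  # the pLDDT track indexed by residue number so windows respect numbering
  track <- rep(NA_real_, max(res$resno))
  track[res$resno] <- res$plddt
  order_class <- vapply(res$resno, function(p)
    classify_order(track, p, window = window, threshold = threshold),
    character(1))
  contacts <- vapply(res$resno, function(p)
    count_contacts(model, p, radius = contact_radius,
                   neighbor_exclusion = neighbor_exclusion), integer(1))
  sasa <- as.numeric(compute_sasa(model, probe = probe, n_points = n_points))
  rsa <- relative_accessibility(sasa, res$aa)
  data.frame(
    resno = res$resno, aa = res$aa, plddt = res$plddt,
    order_class = order_class, contact_count = contacts,
    sasa = sasa, rsa = rsa, burial_class = classify_burial(rsa),
    ss_class = assign_secondary_structure(model),
    catalytic = vapply(res$resno, catalytic_overlap, logical(1),
                       catalytic_sites = catalytic_sites),
    stringsAsFactors = FALSE
  )
}
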