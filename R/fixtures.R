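#' @title Synthetic structures and cohorts
#' @description Deterministic backbone builder (internal-coordinate chain
#'   extension from phi/psi torsions), synthetic PDB writer carrying planted
#'   pLDDT values, composite fixtures (helix bundle, extended chain,
#'   antiparallel strand pair) and a cohort simulator with planted
#'   per-feature prevalences — ground truth for every other module.
#' @name fixtures
NULL

# standard backbone geometry: bond lengths (Angstrom) and angles (degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
OMEGA_TRANS <- 180

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}
unit3 <- function(v) v / sqrt(sum(v^2))

# place atom D from reference atoms A-B-C with bond |CD|, angle B-C-D and
# torsion A-B-C-D (degrees); the NeRF internal-coordinate step
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign flip so realised IUPAC dihedrals match
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# CB from backbone frame (fixed tetrahedral placement)
place_cb <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca; a <- cross3(b, cc)
  ca + (-0.58273431 * a + 0.56802827 * b - 0.54067466 * cc)
}

#' Build a backbone from torsion-angle segments
#'
#' Places N, CA, C, O (and optionally CB) atoms sequentially by
#' internal-coordinate chain extension with standard bond geometry
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; trans peptide,
#' omega = 180 degrees). Each segment contributes `length` residues built
#' with its `phi`/`psi` torsions, and every atom of those residues carries
#' the segment's `plddt` value in the B-factor slot, emulating the
#' AlphaFold convention. Deterministic.
#'
#' @param segments Data frame with columns `length`, `phi`, `psi`, `plddt`.
#' @param sequence One-letter sequence string or vector; default poly-Ala
#'   (poly-Gly residues get no CB).
#' @param cb Place CB atoms (default `TRUE`; never on glycine).
#' @param protein_id Identifier stamped on the model.
#' @param start_resno First residue number (default 1).
#' @return A `structure_model`.
#' @export
generate_backbone <- function(segments, sequence = NULL, cb = TRUE,
                              protein_id = "SYN", start_resno = 1L) {
  stopifnot(all(c("length", "phi", "psi", "plddt") %in% names(segments)))
  if (any(!is.finite(segments$phi)) || any(!is.finite(segments$psi))) {
    stop("non-finite torsion angle in segment specification")
  }
  if (any(segments$length < 1L)) stop("segment lengths must be >= 1")
  if (any(segments$plddt < 0 | segments$plddt > 100)) stop("plddt must lie in [0, 100]")
  n <- sum(segments$length)
  phi <- rep(segments$phi, segments$length)
  psi <- rep(segments$psi, segments$length)
  plddt <- rep(segments$plddt, segments$length)
  if (is.null(sequence)) sequence <- rep("A", n)
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (length(sequence) != n) stop("sequence length must match total segment length")
  if (any(!sequence %in% names(AA1_TO_3))) stop("sequence contains non-standard residues")

  N <- CA <- Cc <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  angA <- ANGLE_N_CA_C * pi / 180
  Cc[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(angA), sin(angA), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], Cc[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], Cc[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, OMEGA_TRANS)
    Cc[i, ] <- place_atom(Cc[i - 1, ], N[i, ], CA[i, ],
                          BOND_CA_C, ANGLE_N_CA_C, phi[i])
  }
  rows <- list()
  for (i in seq_len(n)) {
    o <- place_atom(N[i, ], CA[i, ], Cc[i, ], BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
    resno <- start_resno + i - 1L
    coords <- rbind(N = N[i, ], CA = CA[i, ], C = Cc[i, ], O = o)
    elements <- c("N", "C", "C", "O")
    if (cb && sequence[i] != "G") {
      coords <- rbind(coords, CB = place_cb(N[i, ], CA[i, ], Cc[i, ]))
      elements <- c(elements, "C")
    }
    rows[[i]] <- data.frame(
      resno = resno, aa = sequence[i], elety = rownames(coords),
      element = elements, x = coords[, 1], y = coords[, 2], z = coords[, 3],
      b = plddt[i], stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new_structure_model(protein_id, atoms, source_path = NA_character_)
}

#' Write a synthetic model as a PDB file
#'
#' Thin wrapper over [write_structure()] with an optional per-residue pLDDT
#' override; every atom of a residue carries the residue's value in the
#' B-factor column, the AlphaFold convention.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @param plddt Optional numeric vector, one value per residue, replacing
#'   the stored track.
#' @return `path`, invisibly.
#' @export
write_synthetic_model <- function(model, path, plddt = NULL) {
  if (!is.null(plddt)) {
    resno <- unique(model$atoms$resno)
    if (length(plddt) != length(resno)) stop("plddt must have one value per residue")
    if (any(plddt < 0 | plddt > 100)) stop("plddt must lie in [0, 100]")
    model$atoms$b <- plddt[match(model$atoms$resno, resno)]
  }
  write_structure(model, path)
}

apply_rigid <- function(model, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rot)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

rotation_matrix <- function(rx, ry, rz) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

merge_models <- function(models, protein_id) {
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms))
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure_model(protein_id, atoms)
}

helix_axis_frame <- function(model) {
  ca <- as.matrix(model$atoms[model$atoms$elety == "CA", c("x", "y", "z")])
  centre <- colMeans(ca)
  axis <- prcomp(ca, center = TRUE)$rotation[, 1]
  e1 <- unit3(cross3(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- unit3(cross3(axis, e1))
  list(centre = centre, axis = unit3(axis), e1 = e1, e2 = e2)
}

#' Helix-bundle fixture with a buried central helix
#'
#' One ideal alpha-helix (phi = -57, psi = -47) surrounded by rings of
#' longer parallel copies, so that the interior residues of the central
#' helix are buried (low relative solvent accessibility) and contact-dense
#' — a controlled stand-in for a folded protein core. All residues are
#' alanine (CB placed) and carry the same planted pLDDT.
#'
#' @param n_core Central helix length (default 16).
#' @param n_ring Neighbour helix length (default 28).
#' @param n_neighbors Helices in the first ring (default 6).
#' @param radius First-ring axis-to-axis distance in Angstrom (default 8).
#' @param second_ring Add a second ring at twice the radius (default
#'   `TRUE`), tightening burial of the core.
#' @param plddt Planted pLDDT for every residue (default 90).
#' @param protein_id Identifier (default `"SYNBUNDLE"`).
#' @return A `structure_model`; the central helix occupies residues
#'   `1..n_core`, neighbours are numbered from 1001 upward with gaps.
#' @export
build_helix_bundle <- function(n_core = 16L, n_ring = 28L, n_neighbors = 6L,
                               radius = 8, second_ring = TRUE, plddt = 90,
                               protein_id = "SYNBUNDLE") {
  core <- generate_backbone(
    data.frame(length = n_core, phi = -57, psi = -47, plddt = plddt)
  )
  frame <- helix_axis_frame(core)
  ring_proto <- generate_backbone(
    data.frame(length = n_ring, phi = -57, psi = -47, plddt = plddt)
  )
  ring_frame <- helix_axis_frame(ring_proto)
  # align each neighbour's centre with the core centre, then push it out
  models <- list(core)
  offsets <- list()
  for (k in seq_len(n_neighbors)) {
    theta <- 2 * pi * (k - 1) / n_neighbors
    offsets[[length(offsets) + 1L]] <- radius * (cos(theta) * frame$e1 + sin(theta) * frame$e2)
  }
  if (second_ring) {
    n2 <- 2L * n_neighbors
    for (k in seq_len(n2)) {
      theta <- 2 * pi * (k - 0.5) / n2
      offsets[[length(offsets) + 1L]] <- 2 * radius * (cos(theta) * frame$e1 + sin(theta) * frame$e2)
    }
  }
  for (k in seq_along(offsets)) {
    nb <- ring_proto
    nb$atoms$resno <- nb$atoms$resno + 1000L * k
    nb <- apply_rigid(nb, shift = frame$centre - ring_frame$centre + offsets[[k]])
    models[[length(models) + 1L]] <- nb
  }
  merge_models(models, protein_id)
}

#' Extended-chain fixture
#'
#' A fully extended isolated chain (phi = psi = 180): no helix, no strand
#' partner, maximal solvent exposure. Poly-glycine by default so that the
#' backbone-only model is unambiguously `Exposed` under the Tien
#' normalisation.
#'
#' @param n Number of residues.
#' @param plddt Planted pLDDT (default 30, a disordered-region value).
#' @param sequence Sequence (default poly-Gly).
#' @param protein_id Identifier (default `"SYNCOIL"`).
#' @return A `structure_model`.
#' @export
build_extended_chain <- function(n = 30L, plddt = 30, sequence = rep("G", n),
                                 protein_id = "SYNCOIL") {
  generate_backbone(
    data.frame(length = n, phi = 180, psi = 180, plddt = plddt),
    sequence = sequence, protein_id = protein_id
  )
}

#' Antiparallel two-strand fixture
#'
#' Two beta strands (phi = -139, psi = 135) arranged antiparallel; the
#' second strand's rigid placement is refined numerically so that the
#' backbone O...N distances of the targeted bridge pairs reach hydrogen-bond
#' geometry (about 2.9 Angstrom), which the Kabsch-Sander criterion then
#' detects as antiparallel bridges. Deterministic (fixed start, derivative-
#' free refinement).
#'
#' @param n Residues per strand (default 6).
#' @param plddt Planted pLDDT (default 90).
#' @param protein_id Identifier (default `"SYNSHEET"`).
#' @return A `structure_model`; strand one is residues `1..n`, strand two
#'   `101..100+n`. The attribute `bridge_pairs` lists the residue pairs
#'   placed in hydrogen-bond register.
#' @export
build_antiparallel_pair <- function(n = 6L, plddt = 90, protein_id = "SYNSHEET") {
  strand <- function(start_resno) generate_backbone(
    data.frame(length = n, phi = -139, psi = 135, plddt = plddt),
    cb = FALSE, start_resno = start_resno
  )
  a <- strand(1L)
  b0 <- strand(101L)
  centre_b <- colMeans(as.matrix(b0$atoms[, c("x", "y", "z")]))
  # antiparallel H-bond register: residue i of strand one pairs with
  # residue n + 1 - i of strand two; both-direction bonds on even i
  pairs <- do.call(rbind, lapply(seq(2L, n - 1L, by = 2L), function(i) c(i, n + 1L - i)))
  coords_of <- function(model, resno, name) backbone_coords(model$atoms, resno, name)
  objective <- function(par) {
    b <- apply_rigid(b0, rot = rotation_matrix(par[4], par[5], par[6]),
                     shift = c(par[1], par[2], par[3]) + centre_b -
                       rotation_matrix(par[4], par[5], par[6]) %*% centre_b)
    cost <- 0
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- 100L + pairs[r, 2]
      d1 <- sqrt(sum((coords_of(a, i, "O") - coords_of(b, j, "N"))^2))
      d2 <- sqrt(sum((coords_of(a, i, "N") - coords_of(b, j, "O"))^2))
      cost <- cost + (d1 - 2.9)^2 + (d2 - 2.9)^2
    }
    xa <- as.matrix(a$atoms[, c("x", "y", "z")])
    xb <- as.matrix(b$atoms[, c("x", "y", "z")])
    for (k in seq_len(nrow(xa))) {
      d <- sqrt((xb[, 1] - xa[k, 1])^2 + (xb[, 2] - xa[k, 2])^2 + (xb[, 3] - xa[k, 3])^2)
      cost <- cost + sum(pmax(0, 2.4 - d)^2) * 10
    }
    cost
  }
  # start: strand two flipped head-to-tail beside strand one
  start <- c(0, 4.8, 0, 0, 0, pi)
  fit <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-10))
  par <- fit$par
  b <- apply_rigid(b0, rot = rotation_matrix(par[4], par[5], par[6]),
                   shift = c(par[1], par[2], par[3]) + centre_b -
                     rotation_matrix(par[4], par[5], par[6]) %*% centre_b)
  out <- merge_models(list(a, b), protein_id)
  attr(out, "bridge_pairs") <- cbind(pairs[, 1], 100L + pairs[, 2])
  out
}

#' Simulate a two-group variant cohort with planted feature prevalences
#'
#' Every cell of each group's feature matrix is an independent Bernoulli
#' draw with that group's per-feature prevalence — the generative model
#' behind a pathogenic-versus-benign comparison with known ground truth.
#' The implied true odds ratio for a feature is
#' `[p1 / (1 - p1)] / [p0 / (1 - p0)]`. Fully reproducible from `seed`.
#'
#' @param features Character vector of feature names (a registry subset).
#' @param prev_pathogenic,prev_benign Per-feature prevalences in \[0, 1\]
#'   (recycled if scalar).
#' @param n_path,n_benign Group sizes.
#' @param seed Integer seed driving all draws.
#' @return List with `feature_matrix` elements `pathogenic` and `benign`.
#' @export
simulate_cohort <- function(features, prev_pathogenic, prev_benign,
                            n_path, n_benign, seed = 1L) {
  stopifnot(n_path >= 0, n_benign >= 0)
  prev_pathogenic <- rep_len(prev_pathogenic, length(features))
  prev_benign <- rep_len(prev_benign, length(features))
  if (any(prev_pathogenic < 0 | prev_pathogenic > 1) ||
      any(prev_benign < 0 | prev_benign > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  draw <- function(n, prev, label) {
    cells <- vapply(prev, function(p) stats::rbinom(n, 1L, p), integer(n))
    if (n == 1L) cells <- matrix(cells, nrow = 1L)
    if (n == 0L) cells <- matrix(integer(0), nrow = 0L, ncol = length(features))
    colnames(cells) <- features
    df <- cbind(
      data.frame(
        protein_id = rep("SYNTHETIC", n), position = seq_len(n),
        ref_aa = rep("A", n), alt_aa = rep("V", n), dataset = rep(label, n),
        protein_class = rep(NA_character_, n),
        disease_category = rep(NA_character_, n), stringsAsFactors = FALSE
      ),
      as.data.frame(cells)
    )
    new_feature_matrix(df, registry = features)
  }
  list(
    pathogenic = draw(n_path, prev_pathogenic, "pathogenic"),
    benign = draw(n_benign, prev_benign, "benign")
  )
}

#' Synthetic end-to-end structural cohort
#'
#' Writes two synthetic models to `dir` — a high-pLDDT helix bundle
#' (`SYNBUNDLE.pdb`) whose central helix is buried, and a low-pLDDT exposed
#' coil (`SYNCOIL.pdb`) — and builds two variant tables: "pathogenic"
#' variants at interior positions of the buried central helix and "benign"
#' variants along the coil. Running [build_feature_matrix()] and
#' [compare_feature_sets()] on the result exercises the whole pipeline with
#' known ground truth: order/helix/core features should associate with the
#' pathogenic set and disorder/loop/exposed features with the benign set.
#'
#' @param dir Directory for the model files (created if needed).
#' @param n_path,n_benign Variants per group (default 40).
#' @param seed Seed for sampling positions and alternate residues.
#' @return List: `pathogenic` and `benign` variant data frames,
#'   `structures` (the model directory).
#' @export
demo_structural_cohort <- function(dir = tempfile("varscape"), n_path = 40L,
                                   n_benign = 40L, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bundle <- build_helix_bundle()
  coil <- build_extended_chain()
  write_synthetic_model(bundle, file.path(dir, "SYNBUNDLE.pdb"))
  write_synthetic_model(coil, file.path(dir, "SYNCOIL.pdb"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  core_positions <- 5:12
  coil_positions <- 3:28
  alts_path <- sample(c("E", "K", "W", "R"), n_path, replace = TRUE)
  alts_benign <- sample(c("S", "D", "N", "C"), n_benign, replace = TRUE)
  pathogenic <- data.frame(
    protein_id = "SYNBUNDLE",
    position = sample(core_positions, n_path, replace = TRUE),
    ref_aa = "A", alt_aa = alts_path, dataset = "pathogenic",
    stringsAsFactors = FALSE
  )
  benign <- data.frame(
    protein_id = "SYNCOIL",
    position = sample(coil_positions, n_benign, replace = TRUE),
    ref_aa = "G", alt_aa = alts_benign, dataset = "benign",
    stringsAsFactors = FALSE
  )
  list(pathogenic = pathogenic, benign = benign, structures = dir)
}
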