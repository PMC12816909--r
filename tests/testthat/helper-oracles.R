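# Independent oracles and fixture builders shared across the suite.

# Two-sided Fisher p by full hypergeometric enumeration computed from
# log-binomial coefficients (a code path independent of dhyper), with the
# conventional 1e-7 relative tie tolerance.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(m1 + m2, k)
  dens <- exp(logp)
  obs <- dens[match(a, support)]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

# Contact count by a plain all-pairs atom distance loop.
oracle_contacts <- function(model, pos, radius = 5.0, excl = 2L) {
  at <- model$atoms
  self <- at[at$resno == pos, , drop = FALSE]
  hits <- integer(0)
  for (i in seq_len(nrow(self))) {
    for (j in seq_len(nrow(at))) {
      if (abs(at$resno[j] - pos) <= excl) next
      d <- sqrt((at$x[j] - self$x[i])^2 + (at$y[j] - self$y[i])^2 +
                  (at$z[j] - self$z[i])^2)
      if (d <= radius) hits <- c(hits, at$resno[j])
    }
  }
  length(unique(hits))
}

# Minimal fixed-column PDB record.
pdb_line <- function(record = "ATOM", serial, name, resname, chain = "A",
                     resno, x, y, z, b = 50, element = substr(name, 1, 1),
                     altloc = " ") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, x, y, z, 1.00, b,
          element)
}

# Hand-written three-residue backbone PDB with pLDDT in the B column.
three_residue_pdb <- function(path, b_ca = c(91.2, 30, 75), b_side = b_ca) {
  lines <- character(0)
  serial <- 0L
  for (i in 1:3) {
    for (atom in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      bval <- if (atom == "CA") b_ca[i] else b_side[i]
      lines <- c(lines, pdb_line(
        serial = serial, name = atom, resname = c("ALA", "GLY", "VAL")[i],
        resno = i, x = 3.8 * i + 0.5 * serial, y = 0.3 * serial, z = 0.1 * serial,
        b = bval, element = substr(atom, 1, 1)
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Feature matrix with explicit 0/1/NA cells from a plain matrix.
make_fm <- function(mat, registry = colnames(mat), dataset = "d",
                    protein_class = NA_character_) {
  n <- nrow(mat)
  df <- cbind(
    data.frame(
      protein_id = rep("P", n), position = seq_len(n), ref_aa = rep("A", n),
      alt_aa = rep("V", n), dataset = rep(dataset, n),
      protein_class = rep_len(protein_class, n),
      disease_category = rep(NA_character_, n), stringsAsFactors = FALSE
    ),
    as.data.frame(mat)
  )
  varscape:::new_feature_matrix(df, registry = registry)
}

# Two-group matrices realising exact 2x2 counts for one feature.
fm_pair_from_counts <- function(a, b, c, d, feature = "F1") {
  path <- matrix(c(rep(1L, a), rep(0L, b)), ncol = 1,
                 dimnames = list(NULL, feature))
  ben <- matrix(c(rep(1L, c), rep(0L, d)), ncol = 1,
                dimnames = list(NULL, feature))
  list(pathogenic = make_fm(path), benign = make_fm(ben))
}
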