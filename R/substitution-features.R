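#' @title Substitution-chemistry and thresholded auxiliary features
#' @description Classify the physicochemical transition of an amino-acid
#'   substitution (size, polarity, charge, hydropathy) and threshold
#'   auxiliary scores (conservation, FoldX-style ddG, van der Waals clash)
#'   into binary features with NA propagation.
#' @name substitution-features
NULL

SUBSTITUTION_FEATURES <- c(
  "SmallToBig", "BigToSmall", "PolarToNonpolar", "NonpolarToPolar",
  "HydrophilicIntroduced", "HydrophobicIntroduced",
  "ChargedIntroduced", "PolarIntroduced"
)

#' Default amino-acid property table
#'
#' Per-residue stereochemical classes used by [classify_substitution()]:
#' side-chain size (`small`/`big`), polarity (`polar`/`nonpolar`), charge,
#' and hydropathy (`hydrophobic`/`hydrophilic`/`neutral`). Charged residues
#' are by construction polar and hydrophilic. The table can be overridden
#' with [read_property_table()].
#'
#' @return Data frame with columns `aa`, `size_class`, `polarity`,
#'   `charged`, `hydropathy_class`, one row per standard amino acid.
#' @export
default_property_table <- function() {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  small <- c("G", "A", "S", "C", "T", "P", "N", "D", "V")
  polar <- c("S", "T", "N", "Q", "Y", "C", "H", "D", "E", "K", "R")
  charged <- c("D", "E", "K", "R", "H")
  hydrophobic <- c("A", "V", "L", "I", "F", "M", "C")
  hydrophilic <- union(charged, c("N", "Q", "S", "T"))
  data.frame(
    aa = aa,
    size_class = ifelse(aa %in% small, "small", "big"),
    polarity = ifelse(aa %in% polar, "polar", "nonpolar"),
    charged = aa %in% charged,
    hydropathy_class = ifelse(aa %in% hydrophobic, "hydrophobic",
                              ifelse(aa %in% hydrophilic, "hydrophilic", "neutral")),
    stringsAsFactors = FALSE
  )
}

#' Read a user-supplied amino-acid property table
#'
#' Tab-separated with header `aa, size_class, polarity, charged,
#' hydropathy_class`; all 20 standard residues must be present and charged
#' residues must be polar and hydrophilic.
#'
#' @param path Path to the TSV file.
#' @return Validated property table (see [default_property_table()]).
#' @export
read_property_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("aa", "size_class", "polarity", "charged", "hydropathy_class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("property table missing column(s): ", paste(miss, collapse = ", "))
  tab$charged <- as.logical(tab$charged)
  missing_aa <- setdiff(names(MAX_ASA_TIEN), tab$aa)
  if (length(missing_aa)) stop("property table missing residue(s): ", paste(missing_aa, collapse = ", "))
  bad <- tab$charged & (tab$polarity != "polar" | tab$hydropathy_class != "hydrophilic")
  if (any(bad)) {
    stop("charged residues must be polar and hydrophilic; violated for: ",
         paste(tab$aa[bad], collapse = ", "))
  }
  tab
}

#' Classify the physicochemical transition of a substitution
#'
#' Returns the subset of the eight directional transition features that fire
#' for `ref_aa -> alt_aa` under a property table: size transitions
#' (`SmallToBig`, `BigToSmall`), polarity transitions (`PolarToNonpolar`,
#' `NonpolarToPolar`), and property-introduction features that fire only
#' when the reference residue lacks the property and the alternate carries
#' it (`HydrophilicIntroduced`, `HydrophobicIntroduced`,
#' `ChargedIntroduced`, `PolarIntroduced`).
#'
#' @param ref_aa,alt_aa One-letter codes; must differ and be standard.
#' @param table Property table (default [default_property_table()]).
#' @return Character vector (possibly empty) of fired feature names.
#' @export
classify_substitution <- function(ref_aa, alt_aa, table = default_property_table()) {
  if (identical(ref_aa, alt_aa)) stop("synonymous substitution: ", ref_aa, " -> ", alt_aa)
  if (!(ref_aa %in% table$aa) || !(alt_aa %in% table$aa)) {
    stop("residue(s) outside the 20-letter alphabet: ", ref_aa, " -> ", alt_aa)
  }
  r <- table[match(ref_aa, table$aa), ]
  a <- table[match(alt_aa, table$aa), ]
  fired <- character()
  if (r$size_class == "small" && a$size_class == "big") fired <- c(fired, "SmallToBig")
  if (r$size_class == "big" && a$size_class == "small") fired <- c(fired, "BigToSmall")
  if (r$polarity == "polar" && a$polarity == "nonpolar") fired <- c(fired, "PolarToNonpolar")
  if (r$polarity == "nonpolar" && a$polarity == "polar") fired <- c(fired, "NonpolarToPolar")
  if (a$hydropathy_class == "hydrophilic" && r$hydropathy_class != "hydrophilic") {
    fired <- c(fired, "HydrophilicIntroduced")
  }
  if (a$hydropathy_class == "hydrophobic" && r$hydropathy_class != "hydrophobic") {
    fired <- c(fired, "HydrophobicIntroduced")
  }
  if (a$charged && !r$charged) fired <- c(fired, "ChargedIntroduced")
  if (a$polarity == "polar" && r$polarity != "polar") fired <- c(fired, "PolarIntroduced")
  fired
}

#' Default thresholds for auxiliary-score features
#'
#' `cons_cutoff` has no universal default (conservation metrics differ in
#' scale) and must be supplied for the `Conserved` feature to be computed;
#' until then the feature is `NA`. ddG cutoffs are in kcal/mol.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(cons_cutoff = NULL, ddg_cutoff = 1.0, less_cutoff = -1.0, clash_cutoff = 0.5)
}

#' Threshold auxiliary scores into binary features
#'
#' `Conserved` fires when conservation >= `cons_cutoff`; `TotalEnergy` when
#' ddG >= `ddg_cutoff`; `LessTotalEnergy` when ddG <= `less_cutoff`;
#' `VanDerWaalsClashes` when the clash score >= `clash_cutoff`. Any missing
#' input yields `NA` for the affected features — never an error — so the
#' pipeline continues when an upstream annotation source failed.
#'
#' @param conservation Conservation score or `NA`.
#' @param ddg FoldX-style folding free-energy change (kcal/mol) or `NA`.
#' @param vdw_clash Steric-clash score or `NA`.
#' @param thresholds Named list as from [default_thresholds()].
#' @return Named integer vector over `Conserved`, `TotalEnergy`,
#'   `LessTotalEnergy`, `VanDerWaalsClashes` with values 0, 1 or `NA`.
#' @export
threshold_features <- function(conservation = NA_real_, ddg = NA_real_,
                               vdw_clash = NA_real_,
                               thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds[!vapply(thresholds, is.null, logical(1))])
  if (!is.null(th$less_cutoff) && !is.null(th$ddg_cutoff) &&
      th$less_cutoff >= th$ddg_cutoff) {
    stop("less_cutoff must be below ddg_cutoff")
  }
  flag <- function(x, cutoff, ge = TRUE) {
    if (is.null(cutoff) || is.na(x)) return(NA_integer_)
    as.integer(if (ge) x >= cutoff else x <= cutoff)
  }
  c(
    Conserved = flag(conservation, th$cons_cutoff),
    TotalEnergy = flag(ddg, th$ddg_cutoff),
    LessTotalEnergy = flag(ddg, th$less_cutoff, ge = FALSE),
    VanDerWaalsClashes = flag(vdw_clash, th$clash_cutoff)
  )
}
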