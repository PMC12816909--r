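#' @title Variant ingest and feature-matrix construction
#' @description Read, filter and label missense variant datasets from
#'   protein-level TSV or VEP-annotated VCF, attach protein-class and
#'   disease maps, and join structural plus substitution annotations into a
#'   binary variants-by-features matrix.
#' @name variant-ingest
NULL

REQUIRED_VARIANT_COLS <- c("protein_id", "position", "ref_aa", "alt_aa")
OPTIONAL_VARIANT_COLS <- c(
  "dataset", "af", "filter_status", "clin_sig", "score",
  "conservation", "ddg", "vdw_clash", "protein_class", "disease_category"
)

complete_variant_table <- function(df) {
  for (col in OPTIONAL_VARIANT_COLS) {
    if (!col %in% names(df)) {
      df[[col]] <- rep(
        if (col %in% c("af", "score", "conservation", "ddg", "vdw_clash"))
          NA_real_ else NA_character_,
        nrow(df)
      )
    }
  }
  df$position <- as.integer(df$position)
  if (any(df$position < 1L, na.rm = TRUE)) stop("variant positions must be >= 1")
  syn <- df$ref_aa == df$alt_aa
  if (any(syn, na.rm = TRUE)) stop("synonymous rows (ref_aa == alt_aa) are not missense variants")
  bad_af <- !is.na(df$af) & (df$af < 0 | df$af > 1)
  if (any(bad_af)) stop("allele frequencies outside [0, 1]")
  df[, c(REQUIRED_VARIANT_COLS, OPTIONAL_VARIANT_COLS)]
}

#' Read a variant dataset
#'
#' Two dialects are supported. `tsv`: a tab-separated protein-level table
#' with header columns `protein_id`, `position`, `ref_aa`, `alt_aa` and any
#' of `dataset`, `af`, `filter_status`, `clin_sig`, `score`, `conservation`,
#' `ddg`, `vdw_clash`, `protein_class`, `disease_category`. `vep_vcf`: a
#' VCF v4.x whose `CSQ` INFO field was written by VEP; the CSQ subfield
#' order is taken from the `##INFO=<ID=CSQ,...Format: ...>` header line
#' (never assumed). Only CSQ entries whose consequence contains
#' `missense_variant` and whose `CANONICAL` flag is `YES` are kept; the
#' protein position and residues come from the `Protein_position` and
#' `Amino_acids` subfields, and the protein id from `SWISSPROT` when
#' present, else `Feature`. Malformed CSQ entries are skipped with a count.
#'
#' @param path Input file path.
#' @param format `"tsv"` or `"vep_vcf"`.
#' @param dataset Optional dataset label stamped on every record.
#' @return Data frame of variant records, one row per missense variant.
#' @export
read_variants <- function(path, format = c("tsv", "vep_vcf"), dataset = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- if (format == "tsv") read_variants_tsv(path) else read_variants_vep_vcf(path)
  if (!is.null(dataset)) df$dataset <- dataset
  df
}

read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_VARIANT_COLS, names(df))
  if (length(miss)) stop("variant table is missing required column(s): ",
                         paste(miss, collapse = ", "))
  complete_variant_table(df)
}

read_variants_vep_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  csq_line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  if (length(csq_line) == 0L) stop("VCF has no CSQ INFO definition (not VEP-annotated?)")
  fmt <- sub('.*Format: *([^">]+).*', "\\1", csq_line[1])
  fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  need <- c("Consequence", "CANONICAL", "Protein_position", "Amino_acids")
  miss <- setdiff(need, fields)
  if (length(miss)) stop("CSQ Format lacks subfield(s): ", paste(miss, collapse = ", "))
  pid_field <- if ("SWISSPROT" %in% fields) "SWISSPROT" else if ("Feature" %in% fields)
    "Feature" else stop("CSQ Format lacks a protein identifier subfield (SWISSPROT or Feature)")

  info <- vcfR::extract.info(vcf, element = "CSQ")
  skipped <- 0L
  rows <- list()
  for (rec in info) {
    if (is.na(rec)) next
    for (entry in strsplit(rec, ",", fixed = TRUE)[[1]]) {
      parts <- strsplit(entry, "|", fixed = TRUE)[[1]]
      length(parts) <- length(fields)
      v <- setNames(parts, fields)
      if (is.na(v[["Consequence"]]) ||
          !grepl("missense_variant", v[["Consequence"]], fixed = TRUE)) next
      if (is.na(v[["CANONICAL"]]) || v[["CANONICAL"]] != "YES") next
      aas <- strsplit(v[["Amino_acids"]], "/", fixed = TRUE)[[1]]
      pos <- suppressWarnings(as.integer(sub("-.*", "", v[["Protein_position"]])))
      if (length(aas) != 2L || any(!aas %in% names(AA1_TO_3)) || is.na(pos)) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = v[[pid_field]], position = pos,
        ref_aa = aas[1], alt_aa = aas[2], stringsAsFactors = FALSE
      )
    }
  }
  if (skipped > 0L) message(skipped, " malformed CSQ entr", if (skipped == 1) "y" else "ies", " skipped")
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), position = integer(),
               ref_aa = character(), alt_aa = character(), stringsAsFactors = FALSE)
  complete_variant_table(df)
}

#' Filter a variant dataset
#'
#' Selection rules for building comparison cohorts:
#' * `clinvar_pathogenic` — keep clinical significance `Pathogenic` or
#'   `Likely pathogenic` (case-insensitive).
#' * `gnomad_benign` — keep allele frequency > `af_cutoff` (default 0.05)
#'   with `filter_status == "PASS"`.
#' * `score_top` / `score_bottom` — keep the top / bottom `q`-quantile of
#'   the `score` column (default `q = 0.05`); pass `params$cutoff` to use a
#'   fixed score threshold instead of a data-derived quantile.
#' * `none` — keep everything.
#'
#' The predicate modes are idempotent. The quantile modes are idempotent
#' only with an explicit `cutoff`: a data-derived quantile recomputed on its
#' own output selects a strictly smaller set.
#'
#' @param records Variant data frame (see [read_variants()]).
#' @param mode Filtering mode.
#' @param params Named list: `af_cutoff`, `q`, `cutoff` as applicable.
#' @return Filtered variant data frame.
#' @export
filter_dataset <- function(records,
                           mode = c("none", "clinvar_pathogenic", "gnomad_benign",
                                    "score_top", "score_bottom"),
                           params = list()) {
  mode <- match.arg(mode)
  need_col <- function(col) {
    if (!col %in% names(records) || all(is.na(records[[col]]))) {
      stop("mode '", mode, "' requires column '", col, "'")
    }
  }
  keep <- switch(mode,
    none = rep(TRUE, nrow(records)),
    clinvar_pathogenic = {
      need_col("clin_sig")
      tolower(records$clin_sig) %in% c("pathogenic", "likely pathogenic")
    },
    gnomad_benign = {
      need_col("af"); need_col("filter_status")
      af_cutoff <- params$af_cutoff %||% 0.05
      !is.na(records$af) & records$af > af_cutoff &
        !is.na(records$filter_status) & records$filter_status == "PASS"
    },
    score_top = ,
    score_bottom = {
      need_col("score")
      q <- params$q %||% 0.05
      s <- records$score
      if (mode == "score_top") {
        cutoff <- params$cutoff %||% quantile(s, 1 - q, na.rm = TRUE, names = FALSE)
        !is.na(s) & s >= cutoff
      } else {
        cutoff <- params$cutoff %||% quantile(s, q, na.rm = TRUE, names = FALSE)
        !is.na(s) & s <= cutoff
      }
    }
  )
  records[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_two_column_map <- function(path, value_name) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("map file '", path, "' needs two tab-separated columns")
  key <- as.character(tab[[1]])
  val <- as.character(tab[[2]])
  dup <- unique(key[duplicated(key)])
  conflicting <- dup[vapply(dup, function(k) length(unique(val[key == k])) > 1L, logical(1))]
  if (length(conflicting)) {
    stop("conflicting duplicate ", value_name, " map rows for: ",
         paste(conflicting, collapse = ", "))
  }
  setNames(val, key)[!duplicated(key)]
}

#' Attach protein-class and disease-category labels
#'
#' Joins PANTHER-style protein classes (keyed by protein id) and MONDO-style
#' disease categories (keyed by variant `protein_id:position:ref:alt` or by
#' protein id) onto the variant table. Unmatched entries get `NA` and are
#' later excluded from stratified — but not global — analyses. Conflicting
#' duplicate map rows are an error.
#'
#' @param records Variant data frame.
#' @param class_map Path to a two-column TSV (protein id, class), or `NULL`.
#' @param disease_map Path to a two-column TSV (variant or protein key,
#'   category), or `NULL`.
#' @return The records with `protein_class` / `disease_category` filled.
#' @export
attach_classifications <- function(records, class_map = NULL, disease_map = NULL) {
  if (!is.null(class_map)) {
    m <- read_two_column_map(class_map, "protein-class")
    records$protein_class <- unname(m[records$protein_id])
  }
  if (!is.null(disease_map)) {
    m <- read_two_column_map(disease_map, "disease")
    vkey <- paste(records$protein_id, records$position, records$ref_aa,
                  records$alt_aa, sep = ":")
    hit <- unname(m[vkey])
    fallback <- unname(m[records$protein_id])
    records$disease_category <- ifelse(is.na(hit), fallback, hit)
  }
  records
}

#' Read a catalytic-site annotation file
#'
#' Two-column TSV (protein id, residue position); positions are pooled per
#' protein.
#'
#' @param path Path to the TSV file.
#' @return Named list of integer position vectors, one entry per protein.
#' @export
read_catalytic_sites <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("catalytic-site file needs two tab-separated columns")
  split(as.integer(tab[[2]]), as.character(tab[[1]]))
}

new_feature_matrix <- function(df, registry = feature_registry()) {
  stopifnot(all(registry %in% names(df)))
  for (f in registry) {
    cells <- df[[f]]
    if (!all(cells %in% c(0L, 1L, NA_integer_))) stop("feature cells must be 0/1/NA: ", f)
    df[[f]] <- as.integer(cells)
  }
  attr(df, "registry") <- registry
  class(df) <- c("feature_matrix", "data.frame")
  df
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d variants x %d features\n",
              nrow(x), length(attr(x, "registry"))))
  NextMethod()
}

#' Build the binary feature matrix for a variant dataset
#'
#' For every variant record, the structural profile of its protein model is
#' computed at the variant position ([residue_profile()]) and combined with
#' the substitution-chemistry and thresholded auxiliary features into the
#' fixed 23-feature registry. Failures are localised: a missing model file,
#' or a model whose residue at the variant position does not match the
#' reported reference residue, yields `NA` for the structural features of
#' that variant only, and the remaining features are still computed.
#' Structural profiles are computed once per protein and reused.
#'
#' @param records Variant data frame.
#' @param structures Directory containing `<protein_id>.pdb` model files
#'   (missing files allowed), or `NULL` for no structural annotation.
#' @param catalytic_sites Named list of catalytic positions per protein id
#'   (see [read_catalytic_sites()]), or `NULL`.
#' @param property_table Amino-acid property table.
#' @param thresholds Auxiliary-score thresholds ([default_thresholds()]).
#' @param contact_min Contact count at or above which the binary `Contacts`
#'   feature fires (default 8).
#' @param ... Passed to [residue_profile()] (window, radii, quadrature).
#' @return A `feature_matrix`: the variant key columns followed by one
#'   0/1/NA column per registry feature.
#' @export
build_feature_matrix <- function(records, structures = NULL,
                                 catalytic_sites = NULL,
                                 property_table = default_property_table(),
                                 thresholds = default_thresholds(),
                                 contact_min = 8L, ...) {
  key_cols <- c("protein_id", "position", "ref_aa", "alt_aa", "dataset",
                "protein_class", "disease_category")
  records <- complete_variant_table(records)
  n <- nrow(records)
  feat <- matrix(NA_integer_, nrow = n, ncol = length(FEATURE_REGISTRY),
                 dimnames = list(NULL, FEATURE_REGISTRY))
  profiles <- list()
  mismatches <- 0L
  for (i in seq_len(n)) {
    rec <- records[i, ]
    prof <- NULL
    if (!is.null(structures)) {
      pid <- rec$protein_id
      if (!pid %in% names(profiles)) {
        file <- file.path(structures, paste0(pid, ".pdb"))
        profiles[[pid]] <- if (file.exists(file)) {
          model <- read_structure(file)
          residue_profile(model,
                          catalytic_sites = catalytic_sites[[pid]] %||% integer(),
                          ...)
        } else NA
      }
      prof <- profiles[[rec$protein_id]]
      if (is.data.frame(prof)) {
        row <- prof[match(rec$position, prof$resno), ]
        if (nrow(row) == 1L && !is.na(row$resno) && row$aa == rec$ref_aa) {
          feat[i, "OrderpLDDT"] <- as.integer(row$order_class == "Order")
          feat[i, "DisorderpLDDT"] <- as.integer(row$order_class == "Disorder")
          for (b in c("Core", "MediumBuried", "MediumExposed", "Exposed")) {
            feat[i, b] <- as.integer(row$burial_class == b)
          }
          for (s in c("Helix", "Strand", "Loop")) {
            feat[i, s] <- as.integer(row$ss_class == s)
          }
          feat[i, "Contacts"] <- as.integer(row$contact_count >= contact_min)
          feat[i, "CatalyticSite"] <- as.integer(row$catalytic)
        } else {
          mismatches <- mismatches + 1L
        }
      }
    }
    feat[i, names(threshold_features())] <- threshold_features(
      conservation = rec$conservation, ddg = rec$ddg, vdw_clash = rec$vdw_clash,
      thresholds = thresholds
    )
    fired <- classify_substitution(rec$ref_aa, rec$alt_aa, table = property_table)
    feat[i, SUBSTITUTION_FEATURES] <- as.integer(SUBSTITUTION_FEATURES %in% fired)
  }
  if (mismatches > 0L) {
    message(mismatches, " variant(s) with model/reference residue mismatch; ",
            "structural features set to NA")
  }
  out <- cbind(records[, key_cols, drop = FALSE], as.data.frame(feat))
  rownames(out) <- NULL
  new_feature_matrix(out)
}

#' Write a feature matrix as TSV
#'
#' One row per variant: the key columns followed by one 0/1/NA column per
#' feature. The companion [read_feature_matrix()] restores the object.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write.table(as.data.frame(fm), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' Every column that is not a variant key column is treated as a feature;
#' the file's column order fixes the registry, so matrices restricted to a
#' feature subset (e.g. simulated cohorts) round trip too.
#'
#' @param path Path to the TSV file.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  key_cols <- c("protein_id", "position", "ref_aa", "alt_aa", "dataset",
                "protein_class", "disease_category")
  registry <- setdiff(names(df), key_cols)
  if (length(registry) == 0L) stop("feature-matrix file has no feature columns")
  new_feature_matrix(df, registry = registry)
}

#' Write a JSON run manifest
#'
#' Records package version, thresholds, seed and dataset counts next to a
#' pipeline output so a run can be audited and reproduced.
#'
#' @param path Output JSON path.
#' @param counts Named list/vector of dataset sizes.
#' @param thresholds Thresholds used.
#' @param seed Seed used for any stochastic step (or `NA`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, counts = list(), thresholds = default_thresholds(),
                               seed = NA_integer_) {
  manifest <- list(
    package = "varscape",
    version = as.character(utils::packageVersion("varscape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    thresholds = thresholds[!vapply(thresholds, is.null, logical(1))],
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
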