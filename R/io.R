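#' Read a SNP weight table
#'
#' Reads the tab-separated weight table defining the genetic risk score: one
#' row per SNP with its risk allele and natural-log odds-ratio weight.
#' Expected columns: \code{snp_id}, \code{chrom}, \code{pos},
#' \code{risk_allele}, \code{other_allele}, \code{weight}.
#'
#' @param path path to a TSV file.
#' @return validated data frame of class \code{grs_weights}.
#' @seealso [default_weight_table()] for the bundled synthetic 30-SNP table.
#' @export
read_weight_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_weight_table(df)
}

#' Validate a SNP weight table
#'
#' Checks column presence and the table invariants: unique SNP ids, strictly
#' positive weights, risk allele distinct from the other allele.
#'
#' @param df data frame with the weight-table columns.
#' @return the data frame, with class \code{grs_weights} prepended.
#' @export
validate_weight_table <- function(df) {
  needed <- c("snp_id", "chrom", "pos", "risk_allele", "other_allele", "weight")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop_("weight table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stop_("weight table has duplicated snp_id values")
  if (!is.numeric(df$weight) || any(!is.finite(df$weight)) || any(df$weight <= 0))
    stop_("weights must be finite and strictly positive")
  if (any(df$risk_allele == df$other_allele))
    stop_("risk_allele must differ from other_allele for every SNP")
  ok_nt <- c("A", "C", "G", "T")
  if (!all(df$risk_allele %in% ok_nt) || !all(df$other_allele %in% ok_nt))
    stop_("alleles must be single nucleotides (A/C/G/T)")
  class(df) <- c("grs_weights", class(df))
  df
}

#' Bundled synthetic 30-SNP weight table
#'
#' The package ships a synthetic 30-row weight table (plausible log-odds-ratio
#' magnitudes with one dominant HLA-like effect). It is calibrated so that the
#' synthetic reference cohort's empirical 5th and 50th score centiles land
#' near the published classification thresholds 0.234 and 0.280; it is not
#' the published SNP list, which users can supply via [read_weight_table()].
#'
#' @return data frame of class \code{grs_weights} with 30 rows.
#' @export
default_weight_table <- function() {
  read_weight_table(system.file("extdata", "t1dgrs_weights_synthetic.tsv",
                                package = "grstriage", mustWork = TRUE))
}

#' Bundled synthetic per-class risk-allele frequencies
#'
#' Risk-allele frequencies used by the synthetic cohort generator:
#' \code{case_freq} for type 1 diabetes cases (enriched) and
#' \code{background_freq} for the general background population. Synthetic
#' values calibrated jointly with [default_weight_table()].
#'
#' @return data frame with columns \code{snp_id}, \code{case_freq},
#'   \code{background_freq}.
#' @export
default_allele_freqs <- function() {
  read.delim(system.file("extdata", "t1dgrs_allele_freqs_synthetic.tsv",
                         package = "grstriage", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Read a genotype dosage matrix
#'
#' Reads a TSV of risk-allele dosages: one row per child, first column
#' \code{child_id}, remaining columns named by SNP id with values 0, 1, 2 or
#' \code{"."} for missing.
#'
#' @param path path to a TSV file.
#' @param weights optional weight table; when supplied, any genotype column
#'   whose SNP id is not in the table triggers an error naming the SNP.
#' @return numeric matrix (children x SNPs) with child ids as row names.
#' @export
read_genotype_matrix <- function(path, weights = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = ".")
  if (names(df)[1] != "child_id")
    stop_("first column of a genotype matrix must be child_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df$child_id)
  bad <- m[!is.na(m) & !(m %in% c(0, 1, 2))]
  if (length(bad) > 0)
    stop_("dosages must be 0, 1, 2 or '.'; found: ", paste(unique(bad), collapse = ", "))
  if (!is.null(weights)) {
    unknown <- setdiff(colnames(m), weights$snp_id)
    if (length(unknown) > 0)
      stop_("unknown SNP id(s) not present in the weight table: ",
            paste(unknown, collapse = ", "))
  }
  m
}

#' Convert VCF genotypes to risk-allele dosages
#'
#' Reads a VCF with the \pkg{vcfR} package and converts GT fields to
#' risk-allele dosage using the weight table's \code{risk_allele}. Variants
#' are matched by ID; REF/ALT must equal the weight table's allele pair
#' exactly (either orientation). Allele mismatches are an error — no
#' strand-flipping heuristics are applied.
#'
#' @param path path to a VCF file (uncompressed or bgzipped).
#' @param weights a weight table from [read_weight_table()].
#' @return numeric dosage matrix (samples x SNPs), \code{NA} for missing GT.
#' @export
genotypes_from_vcf <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-variant VCF
  ids <- fix[, "ID"]
  keep <- which(ids %in% weights$snp_id)
  if (length(keep) == 0)
    stop_("no weight-table SNP ids found in the VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- matrix(NA_real_, nrow = ncol(gt), ncol = length(keep),
                dimnames = list(colnames(gt), ids[keep]))
  for (j in seq_along(keep)) {
    i <- keep[j]
    w <- weights[weights$snp_id == ids[i], ]
    ref <- unname(fix[i, "REF"]); alt <- unname(fix[i, "ALT"])
    pair <- sort(c(ref, alt))
    if (!identical(pair, sort(c(w$risk_allele, w$other_allele))))
      stop_("allele mismatch for ", ids[i], ": VCF ", ref, "/", alt,
            " vs weight table ", w$risk_allele, "/", w$other_allele)
    risk_is_alt <- identical(alt, w$risk_allele)
    g <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    out[, j] <- vapply(alleles, function(al) {
      if (length(al) != 2 || any(al == ".") || any(is.na(al))) return(NA_real_)
      n_alt <- sum(al == "1")
      if (risk_is_alt) n_alt else 2 - n_alt
    }, numeric(1))
  }
  out
}

#' Read a per-child phenotype table
#'
#' CSV with one row per clinic attendee. Recognised columns: \code{child_id},
#' \code{age_at_diagnosis}, \code{antibody_status}
#' (positive/negative/missing), \code{insulin_treated},
#' \code{clinically_diagnosed_t1d}, \code{parent_with_diabetes},
#' \code{hba1c_mmol_mol}, \code{mody_probability},
#' \code{parental_consanguinity} and \code{extra_pancreatic_features}
#' (semicolon-separated feature codes, empty for none). \code{"."} encodes a
#' missing value.
#'
#' @param path path to a CSV file.
#' @return data frame with typed columns.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = ".")
  if (!"child_id" %in% names(df)) stop_("phenotype table needs a child_id column")
  df$child_id <- as.character(df$child_id)
  for (col in c("insulin_treated", "clinically_diagnosed_t1d",
                "parent_with_diabetes", "parental_consanguinity")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  if ("antibody_status" %in% names(df)) {
    df$antibody_status[is.na(df$antibody_status)] <- "missing"
    bad <- setdiff(unique(df$antibody_status), c("positive", "negative", "missing"))
    if (length(bad) > 0)
      stop_("antibody_status must be positive/negative/missing; found: ",
            paste(bad, collapse = ", "))
  }
  if ("extra_pancreatic_features" %in% names(df))
    df$extra_pancreatic_features[is.na(df$extra_pancreatic_features)] <- ""
  if ("age_at_diagnosis" %in% names(df) &&
      any(df$age_at_diagnosis < 0, na.rm = TRUE))
    stop_("age_at_diagnosis must be non-negative")
  if ("hba1c_mmol_mol" %in% names(df) &&
      any(df$hba1c_mmol_mol <= 0, na.rm = TRUE))
    stop_("hba1c_mmol_mol must be positive when present")
  df
}

#' Read a gene panel table
#'
#' TSV with columns \code{gene_symbol} and \code{modes} (comma-separated
#' subset of autosomal_dominant, autosomal_recessive, mitochondrial,
#' x_linked).
#'
#' @param path path to a TSV file.
#' @return data frame of class \code{gene_panel}.
#' @export
read_gene_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_symbol", "modes") %in% names(df)))
    stop_("gene panel needs gene_symbol and modes columns")
  if (anyDuplicated(df$gene_symbol)) stop_("gene panel has duplicated gene symbols")
  ok <- c("autosomal_dominant", "autosomal_recessive", "mitochondrial", "x_linked")
  modes <- strsplit(df$modes, ",", fixed = TRUE)
  bad <- setdiff(unique(unlist(modes)), ok)
  if (length(bad) > 0)
    stop_("unknown inheritance mode(s): ", paste(bad, collapse = ", "))
  class(df) <- c("gene_panel", class(df))
  df
}

#' Bundled synthetic 50-gene monogenic diabetes panel
#'
#' A synthetic stand-in for a comprehensive dominant-plus-recessive monogenic
#' diabetes panel. Real gene symbols with field-standard inheritance modes,
#' including the recessive genes \code{WFS1} and \code{SLC19A2}; the precise
#' 50-gene composition is illustrative.
#'
#' @return data frame of class \code{gene_panel} with 50 rows.
#' @export
default_gene_panel <- function() {
  read_gene_panel(system.file("extdata", "gene_panel_synthetic.tsv",
                              package = "grstriage", mustWork = TRUE))
}

#' Read pathogenic variant calls
#'
#' CSV with columns \code{child_id}, \code{gene_symbol}, \code{zygosity}
#' (monoallelic / biallelic / mitochondrial_variant) and \code{pathogenic}
#' (logical). Biallelic covers homozygous and compound-heterozygous calls.
#'
#' @param path path to a CSV file.
#' @return data frame.
#' @export
read_variant_calls <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("child_id", "gene_symbol", "zygosity", "pathogenic")
  if (!all(needed %in% names(df)))
    stop_("variant calls need columns: ", paste(needed, collapse = ", "))
  df$child_id <- as.character(df$child_id)
  df$pathogenic <- as.logical(df$pathogenic)
  bad <- setdiff(unique(df$zygosity),
                 c("monoallelic", "biallelic", "mitochondrial_variant"))
  if (length(bad) > 0)
    stop_("unknown zygosity value(s): ", paste(bad, collapse = ", "))
  df
}

#' Literature comparison counts for the UK cohorts
#'
#' Published counts (not patient data) used for between-cohort comparisons:
#' a systematic screen of a UK paediatric clinic population (20 monogenic
#' cases of 808, 0 recessive) and routine UK diagnostic referrals (102 cases,
#' 2 recessive, no population denominator).
#'
#' @return data frame with columns \code{cohort}, \code{n_cases},
#'   \code{n_cohort}, \code{n_recessive}, \code{description}.
#' @export
uk_literature_counts <- function() {
  read.delim(system.file("extdata", "uk_literature_counts.tsv",
                         package = "grstriage", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
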