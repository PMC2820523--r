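# Core data structures: SNP panel, genotype table, sample metadata, the
# data-cleaning filters, and the pairwise mismatch kernel.
#
# Genotype calls are stored as an integer matrix (samples x markers) using
# the dosage-style encoding 0 = HOM_REF, 1 = HET, 2 = HOM_ALT, NA = missing.

CALL_HOM_REF <- 0L
CALL_HET <- 1L
CALL_HOM_ALT <- 2L

#' Construct a SNP marker panel
#'
#' A panel describes the biallelic markers a genotype table is scored on.
#'
#' @param marker_id Character vector of unique marker identifiers.
#' @param chromosome Character vector of chromosome names.
#' @param position Integer vector of 1-based physical positions (bp).
#' @param ref_allele,alt_allele Single-character reference and alternate
#'   alleles; must differ at every marker.
#'
#' @return A `data.frame` of class `snp_panel` with one row per marker.
#' @export
snp_panel <- function(marker_id, chromosome = "1", position = seq_along(marker_id),
                      ref_allele = "A", alt_allele = "T") {
  marker_id <- as.character(marker_id)
  n <- length(marker_id)
  panel <- data.frame(
    marker_id = marker_id,
    chromosome = rep_len(as.character(chromosome), n),
    position = rep_len(as.integer(position), n),
    ref_allele = rep_len(as.character(ref_allele), n),
    alt_allele = rep_len(as.character(alt_allele), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(panel$marker_id)) {
    stop("marker ids must be unique")
  }
  if (any(panel$position < 1L)) {
    stop("positions must be >= 1")
  }
  if (any(panel$ref_allele == panel$alt_allele)) {
    stop("ref and alt alleles must differ")
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Construct a genotype table
#'
#' @param calls Integer matrix (samples x markers) with entries 0 (HOM_REF),
#'   1 (HET), 2 (HOM_ALT) or NA (missing). Row names are sample ids; column
#'   names, when present, must match the panel's marker ids.
#' @param panel A [snp_panel()]; generated from the column count if omitted.
#'
#' @return An object of class `genotype_table` with elements `calls` and
#'   `panel`.
#' @export
genotype_table <- function(calls, panel = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) {
    stop("calls matrix must have sample ids as row names")
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicate sample id: ", rownames(calls)[duplicated(rownames(calls))][1])
  }
  bad <- !(calls %in% c(CALL_HOM_REF, CALL_HET, CALL_HOM_ALT) | is.na(calls))
  if (any(bad)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  if (is.null(panel)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- sprintf("m%03d", seq_len(ncol(calls)))
    panel <- snp_panel(ids)
  }
  if (nrow(panel) != ncol(calls)) {
    stop("panel has ", nrow(panel), " markers but calls has ", ncol(calls), " columns")
  }
  colnames(calls) <- panel$marker_id
  structure(list(calls = calls, panel = panel), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d samples x %d markers (%.1f%% missing, %.1f%% het)\n",
    nrow(x$calls), ncol(x$calls),
    100 * mean(is.na(x$calls)),
    100 * mean(x$calls == CALL_HET, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Sample ids of a genotype table
#' @param gt A `genotype_table`.
#' @return Character vector of sample ids, in table order.
#' @export
sample_ids <- function(gt) rownames(gt$calls)

#' Subset a genotype table by sample and/or marker
#'
#' @param gt A `genotype_table`.
#' @param samples Sample ids or indices to keep (default all).
#' @param markers Marker ids or indices to keep (default all).
#' @return A `genotype_table` restricted to the requested rows/columns,
#'   preserving order of the selection.
#' @export
subset_genotypes <- function(gt, samples = NULL, markers = NULL) {
  calls <- gt$calls
  panel <- gt$panel
  if (!is.null(samples)) {
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, panel$marker_id)
    calls <- calls[, markers, drop = FALSE]
    panel <- panel[markers, , drop = FALSE]
    class(panel) <- c("snp_panel", "data.frame")
  }
  structure(list(calls = calls, panel = panel), class = "genotype_table")
}

# ---------------------------------------------------------------------------
# File I/O

#' Read a genotype table from TSV or VCF
#'
#' The TSV dialect has marker ids in the header, sample ids in the first
#' column, and calls encoded 0 (HOM_REF), 1 (HET), 2 (HOM_ALT), with any of
#' `NA`, `N`, `.` or `./.` for missing. VCF input uses the GT field only;
#' multi-allelic records are dropped with a warning giving the count.
#'
#' @param path Path to the genotype file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

missing_codes <- c("NA", "N", ".", "./.", "")

read_genotypes_tsv <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("malformed genotype TSV (need sample id + >=1 marker): ", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals %in% missing_codes] <- NA_character_
  ok <- vals %in% c("0", "1", "2") | is.na(vals)
  if (!all(ok)) {
    bad_row <- which(!ok, arr.ind = TRUE)[1, 1]
    stop("parse error in ", path, " at data line ", bad_row,
         ": calls must be 0/1/2 or a missing code")
  }
  calls <- matrix(as.integer(vals), nrow = nrow(raw),
                  dimnames = list(ids, colnames(raw)[-1]))
  genotype_table(calls)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "ALT"]) != 1 | nchar(fix[, "REF"]) != 1
  if (any(multi)) {
    warning(sum(multi), " non-biallelic-SNP record(s) excluded")
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic SNP records in ", path)
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- CALL_HOM_REF
    out[g %in% c("0/1", "1/0")] <- CALL_HET
    out[g %in% "1/1"] <- CALL_HOM_ALT
    out
  }
  calls <- t(apply(gt_raw, 2, code))
  ids <- colnames(gt_raw)
  if (anyDuplicated(ids)) stop("duplicate sample id: ", ids[duplicated(ids)][1])
  marker_id <- fix[, "ID"]
  fallback <- is.na(marker_id) | marker_id == "."
  marker_id[fallback] <- paste0(fix[fallback, "CHROM"], ":", fix[fallback, "POS"])
  panel <- snp_panel(marker_id, chromosome = fix[, "CHROM"],
                     position = as.integer(fix[, "POS"]),
                     ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"])
  rownames(calls) <- ids
  genotype_table(calls, panel)
}

#' Write a genotype table as TSV
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  df <- data.frame(sample_id = sample_ids(gt), gt$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

valid_continents <- c("EURASIA", "NORTH_AMERICA", "OTHER")
valid_tissues <- c("FIELD_SEED_GROWN", "FIELD_MATURE", "STOCK_CENTER", "UNKNOWN")

#' Read sample metadata from TSV
#'
#' Expected columns: `sample_id`, `latitude`, `longitude`, `site_id`,
#' `continent` (EURASIA / NORTH_AMERICA / OTHER) and `tissue_source`
#' (FIELD_SEED_GROWN / FIELD_MATURE / STOCK_CENTER / UNKNOWN).
#'
#' @param path Path to the metadata TSV.
#' @return A validated `data.frame`.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_meta(meta)
}

#' Validate a sample metadata table
#' @param meta Data frame with the metadata columns (see [read_sample_meta()]).
#' @return `meta`, with columns coerced, if valid; otherwise an error.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "latitude", "longitude", "site_id", "continent", "tissue_source")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$site_id <- as.character(meta$site_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  }
  if (any(meta$latitude < -90 | meta$latitude > 90, na.rm = TRUE)) {
    stop("latitude out of [-90, 90]")
  }
  if (any(meta$longitude <= -180 | meta$longitude > 180, na.rm = TRUE)) {
    stop("longitude out of (-180, 180]")
  }
  if (!all(meta$continent %in% valid_continents)) {
    stop("continent must be one of ", paste(valid_continents, collapse = "/"))
  }
  if (!all(meta$tissue_source %in% valid_tissues)) {
    stop("tissue_source must be one of ", paste(valid_tissues, collapse = "/"))
  }
  meta
}

#' Write a sample metadata table as TSV
#' @param meta Metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Data-cleaning filters

#' Remove samples with excess missing calls
#'
#' A sample is removed when its fraction of missing calls is strictly
#' greater than `max_missing_fraction`. The default corresponds to the
#' "more than 50 of 149 markers missing" rule, expressed as a fraction so
#' it scales to panels of any size.
#'
#' @param gt A `genotype_table`.
#' @param max_missing_fraction Maximum tolerated missing fraction, in \[0, 1\].
#' @return A list with `genotypes` (survivors, order preserved) and
#'   `removed`, a data frame with columns `sample_id`, `missing_fraction`
#'   and `reason`.
#' @export
filter_samples_by_missingness <- function(gt, max_missing_fraction = 50 / 149) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(gt$calls))
  drop <- frac > max_missing_fraction
  removed <- data.frame(
    sample_id = sample_ids(gt)[drop],
    missing_fraction = unname(frac[drop]),
    reason = if (any(drop)) "excess_missing" else character(0),
    stringsAsFactors = FALSE
  )
  list(genotypes = subset_genotypes(gt, samples = which(!drop)), removed = removed)
}

#' Remove markers with excess missing or heterozygous calls
#'
#' A marker is removed when its missing fraction exceeds
#' `max_missing_fraction` OR its heterozygous fraction (of all samples)
#' exceeds `max_het_fraction`; the two symptoms are tested separately.
#' Either is typically an indicator of a poorly performing assay.
#'
#' @param gt A `genotype_table`.
#' @param max_missing_fraction,max_het_fraction Thresholds in \[0, 1\]
#'   (defaults 0.25 each).
#' @return A list with `genotypes` and a `removed` marker report
#'   (`marker_id`, `missing_fraction`, `het_fraction`, `reason`).
#' @export
filter_markers <- function(gt, max_missing_fraction = 0.25, max_het_fraction = 0.25) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            max_het_fraction >= 0, max_het_fraction <= 1)
  miss <- colMeans(is.na(gt$calls))
  # het fraction is of all samples; missing calls count as non-het
  het <- colSums(gt$calls == CALL_HET, na.rm = TRUE) / nrow(gt$calls)
  drop <- miss > max_missing_fraction | het > max_het_fraction
  reason <- ifelse(miss > max_missing_fraction,
                   ifelse(het > max_het_fraction, "excess_missing;excess_het", "excess_missing"),
                   "excess_het")
  removed <- data.frame(
    marker_id = gt$panel$marker_id[drop],
    missing_fraction = unname(miss[drop]),
    het_fraction = unname(het[drop]),
    reason = reason[drop],
    stringsAsFactors = FALSE
  )
  list(genotypes = subset_genotypes(gt, markers = which(!drop)), removed = removed)
}

#' Remove haplogroups containing blacklisted samples
#'
#' Every sample belonging to a haplogroup that contains any blacklisted
#' sample id is removed (used to strip haplogroups matching common lab
#' strains, which indicate contamination). Blacklist ids absent from the
#' data produce a warning, not an error.
#'
#' @param gt A `genotype_table`.
#' @param assignment A [qt_cluster()] haplogroup assignment covering all
#'   samples of `gt`.
#' @param blacklist_sample_ids Character vector of sample ids.
#' @return A list with `genotypes` and a `removed` report
#'   (`sample_id`, `haplogroup`, `reason`).
#' @export
remove_blacklisted_haplogroups <- function(gt, assignment, blacklist_sample_ids) {
  ids <- sample_ids(gt)
  if (!all(ids %in% names(assignment$group_of))) {
    stop("assignment does not cover all samples in the genotype table")
  }
  present <- blacklist_sample_ids %in% ids
  if (any(!present)) {
    warning("blacklist id(s) absent from data: ",
            paste(blacklist_sample_ids[!present], collapse = ", "))
  }
  bad_groups <- unique(unlist(assignment$group_of[blacklist_sample_ids[present]]))
  drop <- unname(unlist(assignment$group_of[ids])) %in% bad_groups
  removed <- data.frame(
    sample_id = ids[drop],
    haplogroup = unname(unlist(assignment$group_of[ids]))[drop],
    reason = if (any(drop)) "blacklisted_haplogroup" else character(0),
    stringsAsFactors = FALSE
  )
  list(genotypes = subset_genotypes(gt, samples = which(!drop)), removed = removed)
}

# ---------------------------------------------------------------------------
# Pairwise mismatch kernel

#' Mismatch between two call vectors
#'
#' Counts `n`, the markers informative (non-missing; heterozygous calls
#' count as missing when `het_as_missing`, the default) in both vectors,
#' and `k`, the informative markers at which the calls differ. The
#' fraction k/n is `NA` and flagged undefined when `n = 0`.
#'
#' @param h1,h2 Integer call vectors of equal length (0/1/2/NA).
#' @param het_as_missing Treat heterozygous calls as missing (default TRUE).
#' @return A list with `k`, `n`, `fraction` and `defined`.
#' @export
pairwise_mismatch <- function(h1, h2, het_as_missing = TRUE) {
  if (length(h1) != length(h2)) stop("call vectors differ in length")
  if (het_as_missing) {
    h1[h1 == CALL_HET] <- NA_integer_
    h2[h2 == CALL_HET] <- NA_integer_
  }
  inf <- !is.na(h1) & !is.na(h2)
  n <- sum(inf)
  k <- sum(h1[inf] != h2[inf])
  list(k = k, n = n,
       fraction = if (n > 0) k / n else NA_real_,
       defined = n > 0)
}

# All-pairs mismatch counts via matrix products. Returns k and n matrices
# (samples x samples). HET is masked to missing when het_as_missing.
mismatch_matrices <- function(calls, het_as_missing = TRUE) {
  if (het_as_missing) calls[calls == CALL_HET] <- NA_integer_
  inf <- !is.na(calls)
  alt <- (calls == CALL_HOM_ALT) & inf
  het <- (calls == CALL_HET) & inf
  ref <- inf & !alt & !het
  storage.mode(inf) <- "double"
  storage.mode(alt) <- "double"
  storage.mode(het) <- "double"
  storage.mode(ref) <- "double"
  n <- inf %*% t(inf)
  # a position mismatches when the two informative calls differ
  k <- alt %*% t(ref) + ref %*% t(alt) +
    het %*% t(ref) + ref %*% t(het) +
    het %*% t(alt) + alt %*% t(het)
  list(k = round(k), n = round(n))
}

# Unordered-pair mismatch table: one row per pair (i < j by input order).
pair_mismatch_table <- function(gt, het_as_missing = TRUE) {
  mm <- mismatch_matrices(gt$calls, het_as_missing)
  idx <- which(upper.tri(mm$n), arr.ind = TRUE)
  data.frame(
    i = idx[, 1], j = idx[, 2],
    k = mm$k[idx], n = mm$n[idx],
    fraction = ifelse(mm$n[idx] > 0, mm$k[idx] / mm$n[idx], NA_real_),
    stringsAsFactors = FALSE
  )
}
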