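# Per-field-site inbreeding coefficient F_IS, conversion to selfing rate,
# site-eligibility rules, locus-bootstrap confidence intervals and
# per-plant heterozygous-locus counts.

#' Multilocus F_IS within one field site
#'
#' For each locus polymorphic within the site, with within-site alt-allele
#' frequency `p` estimated from the `n` plants with non-missing calls:
#' observed heterozygosity `H_obs = n_het / n` and expected heterozygosity
#' `H_exp = 2 p (1 - p) * 2n / (2n - 1)` (small-sample correction). The
#' multilocus estimate combines loci as a ratio of sums,
#' `F_IS = 1 - sum(H_obs) / sum(H_exp)`; monomorphic loci contribute
#' nothing. Heterozygous calls are real data here (they carry the signal),
#' unlike in the mismatch statistics.
#'
#' @param gt_site A `genotype_table` restricted to one site's plants
#'   (>= 2 plants).
#' @return A list with `fis` (NA when no locus is polymorphic),
#'   `n_loci_used`, `n_plants` and `per_locus` (data frame with `marker_id`,
#'   `n`, `p_hat`, `h_obs`, `h_exp` for the polymorphic loci).
#' @export
site_fis <- function(gt_site) {
  calls <- gt_site$calls
  if (nrow(calls) < 2) stop("site F_IS needs at least 2 plants")
  n <- colSums(!is.na(calls))
  n_het <- colSums(calls == CALL_HET, na.rm = TRUE)
  n_alt <- colSums(calls == CALL_HOM_ALT, na.rm = TRUE)
  p_hat <- ifelse(n > 0, (2 * n_alt + n_het) / (2 * n), NA_real_)
  poly <- !is.na(p_hat) & p_hat > 0 & p_hat < 1 & n >= 2
  h_obs <- n_het[poly] / n[poly]
  h_exp <- 2 * p_hat[poly] * (1 - p_hat[poly]) * (2 * n[poly]) / (2 * n[poly] - 1)
  fis <- if (any(poly)) 1 - sum(h_obs) / sum(h_exp) else NA_real_
  list(
    fis = fis,
    n_loci_used = sum(poly),
    n_plants = nrow(calls),
    per_locus = data.frame(
      marker_id = gt_site$panel$marker_id[poly],
      n = n[poly], p_hat = p_hat[poly], h_obs = h_obs, h_exp = h_exp,
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' Selfing rate from the inbreeding coefficient
#'
#' At inbreeding equilibrium under uniform outcrossing,
#' `s = 2 / (1 / F_IS + 1) = 2 F_IS / (1 + F_IS)`. Non-positive `F_IS`
#' (an excess of heterozygotes) is clamped to selfing 0, and the result is
#' clamped to \[0, 1\].
#'
#' @param fis Inbreeding coefficient(s); NA propagates.
#' @return Selfing rate(s) in \[0, 1\].
#' @export
selfing_from_fis <- function(fis) {
  s <- ifelse(is.na(fis), NA_real_,
              ifelse(fis <= 0, 0, 2 * fis / (1 + fis)))
  pmin(pmax(s, 0), 1)
}

#' Field sites eligible for selfing estimation
#'
#' A site qualifies when every genotyped plant there was grown from
#' field-collected seed or sampled as a mature field plant (no stock-center
#' or unknown material) and at least `min_haplogroups` distinct haplogroups
#' occur at the site (a monomorphic site carries no information about
#' outcrossing).
#'
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param assignment A [qt_cluster()] assignment covering all samples.
#' @param min_haplogroups Minimum distinct haplogroups (default 2).
#' @return Character vector of eligible site ids.
#' @export
eligible_sites <- function(meta, assignment, min_haplogroups = 2) {
  if (!all(meta$sample_id %in% names(assignment$group_of))) {
    stop("assignment does not cover all samples in the metadata")
  }
  ok_tissue <- tapply(
    meta$tissue_source %in% c("FIELD_SEED_GROWN", "FIELD_MATURE"),
    meta$site_id, all
  )
  n_hg <- tapply(assignment$group_of[meta$sample_id], meta$site_id,
                 function(g) length(unique(g)))
  sites <- names(ok_tissue)
  sites[ok_tissue & n_hg[sites] >= min_haplogroups]
}

#' Selfing rate for one site with a locus-bootstrap confidence interval
#'
#' Point estimate via [site_fis()] and [selfing_from_fis()]; the interval
#' resamples loci with replacement, recomputes the chain per replicate and
#' takes percentile bounds. Replicates where every resampled locus is
#' monomorphic are dropped and counted; the interval is reported undefined
#' when more than half the replicates are dropped.
#'
#' @param gt_site A `genotype_table` for one site.
#' @param site_id Site label carried into the output.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param ci_level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return A one-row data frame: `site_id`, `n_plants`, `n_loci_used`,
#'   `fis`, `selfing`, `ci_low`, `ci_high`, `n_boot_used`.
#' @export
site_selfing_with_ci <- function(gt_site, site_id = "site", n_boot = 1000,
                                 ci_level = 0.95, seed = 1L) {
  est <- site_fis(gt_site)
  s_hat <- selfing_from_fis(est$fis)
  ci <- c(NA_real_, NA_real_)
  n_used <- 0L
  if (!is.na(est$fis) && n_boot > 0) {
    set.seed(seed)
    L <- ncol(gt_site$calls)
    reps <- vapply(seq_len(n_boot), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      boot <- subset_genotypes(gt_site, markers = cols)
      selfing_from_fis(site_fis(boot)$fis)
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    n_used <- length(reps)
    if (n_used >= n_boot / 2) {
      a <- (1 - ci_level) / 2
      ci <- unname(stats::quantile(reps, c(a, 1 - a), type = 7))
    }
  }
  data.frame(site_id = site_id, n_plants = est$n_plants,
             n_loci_used = est$n_loci_used, fis = est$fis, selfing = s_hat,
             ci_low = ci[1], ci_high = ci[2], n_boot_used = n_used,
             stringsAsFactors = FALSE)
}

#' Selfing estimates for many sites
#'
#' Applies the F_IS-to-selfing chain to each requested site. Sites with
#' fewer than 2 plants or no polymorphic locus yield NA estimates and are
#' kept in the output so the caller can see why they dropped out.
#'
#' @param gt A `genotype_table`.
#' @param meta Sample metadata covering the table's samples.
#' @param sites Site ids to estimate (default: all sites in `meta`).
#' @param n_boot Bootstrap replicates per site (0 = no interval).
#' @param ci_level Interval level.
#' @param seed Integer seed (one sub-seed per site).
#' @return A data frame, one row per site, as in [site_selfing_with_ci()].
#' @export
selfing_by_site <- function(gt, meta, sites = NULL, n_boot = 0,
                            ci_level = 0.95, seed = 1L) {
  if (is.null(sites)) sites <- unique(meta$site_id)
  rows <- lapply(seq_along(sites), function(i) {
    sid <- sites[i]
    ids <- meta$sample_id[meta$site_id == sid]
    ids <- ids[ids %in% sample_ids(gt)]
    if (length(ids) < 2) {
      return(data.frame(site_id = sid, n_plants = length(ids),
                        n_loci_used = 0L, fis = NA_real_, selfing = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n_boot_used = 0L,
                        stringsAsFactors = FALSE))
    }
    site_selfing_with_ci(subset_genotypes(gt, samples = ids), site_id = sid,
                         n_boot = n_boot, ci_level = ci_level,
                         seed = seed + i)
  })
  do.call(rbind, rows)
}

#' Heterozygous-locus counts per plant
#'
#' @param gt A `genotype_table`.
#' @return A list with `counts` (named integer vector, one per plant),
#'   `quantiles` (5/25/50/75/95/100th percentiles) and `fraction_at_most`,
#'   a function giving the fraction of plants with at most `t` heterozygous
#'   loci.
#' @export
het_count_distribution <- function(gt) {
  counts <- rowSums(gt$calls == CALL_HET, na.rm = TRUE)
  list(
    counts = counts,
    quantiles = stats::quantile(counts, c(0.05, 0.25, 0.5, 0.75, 0.95, 1)),
    fraction_at_most = function(t) mean(counts <= t)
  )
}
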