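# Synthetic genotype and landscape generators.
#
# Two layers: (1) a mixed-mating inbreeding-equilibrium site generator used
# for estimator-recovery tests, and (2) a two-scenario landscape generator
# contrasting smooth spatial allele-frequency gradients (Eurasia-like
# isolation by distance) with clonal haplogroup spread (North-America-like).
# All generators are fully deterministic given their seed.

#' Generate a marker panel with baseline allele frequencies
#'
#' Baseline alternate-allele frequencies are drawn uniformly on
#' `[maf_low, maf_high]`, emulating a panel ascertained for intermediate
#' minor allele frequencies (the default 0.25-0.30 band).
#'
#' @param n_markers Number of biallelic markers (default 139).
#' @param maf_low,maf_high Frequency band, `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Integer seed.
#' @return A list with `panel` (a [snp_panel()]) and `freqs`
#'   (baseline alt-allele frequency per marker).
#' @export
generate_panel <- function(n_markers = 139, maf_low = 0.25, maf_high = 0.30,
                           seed = 1L) {
  stopifnot(n_markers >= 1, maf_low > 0, maf_low <= maf_high, maf_high <= 0.5)
  set.seed(seed)
  freqs <- stats::runif(n_markers, maf_low, maf_high)
  panel <- snp_panel(sprintf("m%03d", seq_len(n_markers)),
                     chromosome = as.character(1 + (seq_len(n_markers) - 1) %% 5),
                     position = seq_len(n_markers) * 1000L)
  list(panel = panel, freqs = freqs)
}

# Draw one site's calls at inbreeding equilibrium. Each call is, with
# probability F, an "inbred" draw (homozygous, alt with prob p) and with
# probability 1-F a Hardy-Weinberg draw (het with prob 2p(1-p)).
equilibrium_calls <- function(n_plants, freqs, inbreeding_f) {
  L <- length(freqs)
  p <- matrix(freqs, nrow = n_plants, ncol = L, byrow = TRUE)
  inbred <- matrix(stats::runif(n_plants * L) < inbreeding_f, n_plants, L)
  u <- matrix(stats::runif(n_plants * L), n_plants, L)
  calls <- matrix(CALL_HOM_REF, n_plants, L)
  # inbred draw: HOM_ALT with prob p
  calls[inbred & u < p] <- CALL_HOM_ALT
  # HW draw: genotype probs p^2 / 2p(1-p) / (1-p)^2
  hw_alt <- !inbred & u < p^2
  hw_het <- !inbred & u >= p^2 & u < p^2 + 2 * p * (1 - p)
  calls[hw_alt] <- CALL_HOM_ALT
  calls[hw_het] <- CALL_HET
  storage.mode(calls) <- "integer"
  calls
}

#' Generate genotypes for one field site at inbreeding equilibrium
#'
#' Calls are drawn independently per locus and per plant: with probability
#' `inbreeding_f` an inbred draw (homozygous alt with probability `p`,
#' homozygous ref otherwise), with probability `1 - inbreeding_f` a
#' Hardy-Weinberg draw. Expected heterozygosity per locus is therefore
#' `(1 - F) * 2 p (1 - p)`.
#'
#' @param n_plants Number of plants at the site.
#' @param freqs Per-locus alt-allele frequencies in (0, 1).
#' @param inbreeding_f Equilibrium inbreeding coefficient F in \[0, 1\].
#' @param seed Integer seed.
#' @param sample_prefix Prefix for generated sample ids.
#' @param panel Optional [snp_panel()] (generated to match `freqs` if omitted).
#' @return A [genotype_table()].
#' @export
generate_equilibrium_site <- function(n_plants, freqs, inbreeding_f, seed = 1L,
                                      sample_prefix = "s", panel = NULL) {
  stopifnot(n_plants >= 1, all(freqs > 0), all(freqs < 1),
            inbreeding_f >= 0, inbreeding_f <= 1)
  set.seed(seed)
  calls <- equilibrium_calls(n_plants, freqs, inbreeding_f)
  rownames(calls) <- sprintf("%s%04d", sample_prefix, seq_len(n_plants))
  genotype_table(calls, panel)
}

#' Apply genotyping noise to a table
#'
#' Each non-missing call is independently corrupted with probability
#' `error_rate` and then set missing with probability `missing_rate`
#' (missingness applied after the error step). By default an error flips a
#' homozygote to the opposite homozygote and leaves heterozygotes alone;
#' with `error_to_het = TRUE` errors turn the call heterozygous instead.
#'
#' @param gt A `genotype_table`.
#' @param error_rate,missing_rate Per-call probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @param error_to_het Use the heterozygote error mode (default FALSE).
#' @return A `genotype_table` of the same shape.
#' @export
apply_genotyping_noise <- function(gt, error_rate = 0, missing_rate = 0,
                                   seed = 1L, error_to_het = FALSE) {
  stopifnot(error_rate >= 0, error_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  calls <- gt$calls
  present <- !is.na(calls)
  err <- present & (matrix(stats::runif(length(calls)), nrow(calls)) < error_rate)
  if (error_to_het) {
    calls[err] <- CALL_HET
  } else {
    flip <- err & calls != CALL_HET
    calls[flip] <- 2L - calls[flip]
  }
  gone <- present & (matrix(stats::runif(length(calls)), nrow(calls)) < missing_rate)
  calls[gone] <- NA_integer_
  genotype_table(calls, gt$panel)
}

#' Generate a synthetic spatial landscape of genotyped field sites
#'
#' Two scenario presets:
#'
#' * `"eurasia"` — field sites scattered over a square of side `extent_km`;
#'   per-site allele frequencies are the baseline frequencies perturbed on
#'   the logit scale by a Gaussian random field whose correlation decays as
#'   `exp(-d / frequency_gradient_scale_km)`, so expected pairwise mismatch
#'   grows smoothly with distance; genotypes are drawn at inbreeding
#'   equilibrium per site.
#' * `"north_america"` — `n_founder_clones` fully homozygous founder
#'   haplotypes; each site receives `clone_fraction` of its plants as
#'   error-perturbed copies of one founder (founder choice decays with the
#'   distance to the founder's origin) plus equilibrium draws from the
#'   baseline frequencies for the rest, mimicking continent-wide clonal
#'   haplogroup spread over weak background structure.
#'
#' Both scenarios finish with [apply_genotyping_noise()].
#'
#' @param scenario `"eurasia"` or `"north_america"`.
#' @param n_sites Number of field sites (default 50).
#' @param plants_per_site Plants per site; recycled across sites (default 20).
#' @param n_markers,maf_low,maf_high Panel spec (defaults 139 markers,
#'   0.25-0.30 band).
#' @param extent_km Side of the square study region (default 3000).
#' @param frequency_gradient_scale_km Correlation length of the allele
#'   frequency field (eurasia; default 800).
#' @param gradient_sd Standard deviation of the logit-scale perturbation
#'   (default 1).
#' @param n_founder_clones Number of founder haplotypes (north_america;
#'   default 5).
#' @param clone_fraction Fraction of plants per site copied from the site's
#'   founder (north_america; default 0.9).
#' @param inbreeding_f Equilibrium F used for non-clonal draws (default 0.95).
#' @param error_rate,missing_rate Genotyping noise (defaults 0.005, 0.02).
#' @param continent Continent label written into the metadata
#'   (defaults to match the scenario).
#' @param seed Integer master seed.
#' @return A list with `genotypes` (a [genotype_table()]), `meta` (sample
#'   metadata data frame) and `truth` (a list with the baseline frequencies,
#'   per-site frequencies, per-site F, founder haplotypes/assignments and
#'   all generator parameters) for recovery tests.
#' @export
generate_landscape <- function(scenario = c("eurasia", "north_america"),
                               n_sites = 50, plants_per_site = 20,
                               n_markers = 139, maf_low = 0.25, maf_high = 0.30,
                               extent_km = 3000,
                               frequency_gradient_scale_km = 800,
                               gradient_sd = 1,
                               n_founder_clones = 5, clone_fraction = 0.9,
                               inbreeding_f = 0.95,
                               error_rate = 0.005, missing_rate = 0.02,
                               continent = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(extent_km > 0, n_sites >= 1,
            clone_fraction >= 0, clone_fraction <= 1)
  if (is.null(continent)) {
    continent <- if (scenario == "eurasia") "EURASIA" else "NORTH_AMERICA"
  }
  pan <- generate_panel(n_markers, maf_low, maf_high, seed = seed)
  set.seed(seed + 1L)
  L <- n_markers

  # site coordinates: uniform on a lat/lon rectangle spanning ~extent_km,
  # anchored at mid latitude 45N so 1 deg lon ~ 78.6 km
  lat0 <- 45
  dlat <- extent_km / 111.32
  dlon <- extent_km / (111.32 * cos(lat0 * pi / 180))
  lat <- lat0 - dlat / 2 + stats::runif(n_sites) * dlat
  lon <- stats::runif(n_sites) * dlon - dlon / 2
  site_ids <- sprintf("site%03d", seq_len(n_sites))
  npl <- rep_len(plants_per_site, n_sites)

  dmat <- site_distance_matrix(lat, lon)
  site_f <- rep_len(inbreeding_f, n_sites)

  site_freqs <- NULL
  founders <- NULL
  founder_of_site <- NULL
  if (scenario == "eurasia") {
    # spatially autocorrelated logit-scale perturbation, shared chol factor
    if (frequency_gradient_scale_km > 0) {
      cov <- exp(-dmat / frequency_gradient_scale_km)
      cf <- chol(cov + diag(1e-8, n_sites))
      z <- t(cf) %*% matrix(stats::rnorm(n_sites * L), n_sites, L)
    } else {
      z <- matrix(stats::rnorm(n_sites * L), n_sites, L)
    }
    lo <- log(pan$freqs / (1 - pan$freqs))
    site_freqs <- 1 / (1 + exp(-(matrix(lo, n_sites, L, byrow = TRUE) + gradient_sd * z)))
    site_freqs <- pmin(pmax(site_freqs, 0.02), 0.98)
  } else {
    # founder haplotypes: fully homozygous draws from the baseline freqs
    founders <- matrix(
      ifelse(stats::runif(n_founder_clones * L) <
               rep(pan$freqs, each = n_founder_clones), CALL_HOM_ALT, CALL_HOM_REF),
      n_founder_clones, L
    )
    storage.mode(founders) <- "integer"
    # founder origins; site picks founder with probability decaying over
    # the full landscape extent, so the choice is only weakly spatial and
    # clones span the continent (the emerging-IBD regime)
    oi <- sample.int(n_sites, n_founder_clones, replace = n_founder_clones > n_sites)
    founder_of_site <- integer(n_sites)
    for (s in seq_len(n_sites)) {
      d0 <- dmat[s, oi]
      w <- exp(-d0 / max(extent_km, 1))
      founder_of_site[s] <- sample.int(n_founder_clones, 1, prob = w / sum(w))
    }
  }

  call_blocks <- vector("list", n_sites)
  meta_blocks <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    set.seed(seed + 1000L + s)
    np <- npl[s]
    if (scenario == "eurasia") {
      calls <- equilibrium_calls(np, site_freqs[s, ], site_f[s])
    } else {
      n_clone <- round(clone_fraction * np)
      calls <- matrix(NA_integer_, np, L)
      if (n_clone > 0) {
        calls[seq_len(n_clone), ] <- matrix(founders[founder_of_site[s], ],
                                            n_clone, L, byrow = TRUE)
      }
      if (n_clone < np) {
        calls[(n_clone + 1):np, ] <- equilibrium_calls(np - n_clone, pan$freqs, site_f[s])
      }
    }
    rownames(calls) <- sprintf("%s_p%03d", site_ids[s], seq_len(np))
    call_blocks[[s]] <- calls
    meta_blocks[[s]] <- data.frame(
      sample_id = rownames(calls),
      latitude = lat[s], longitude = lon[s],
      site_id = site_ids[s], continent = continent,
      tissue_source = "FIELD_SEED_GROWN",
      stringsAsFactors = FALSE
    )
  }
  gt <- genotype_table(do.call(rbind, call_blocks), pan$panel)
  gt <- apply_genotyping_noise(gt, error_rate, missing_rate, seed = seed + 2L)
  meta <- do.call(rbind, meta_blocks)
  rownames(meta) <- NULL

  truth <- list(
    scenario = scenario, seed = seed,
    baseline_freqs = pan$freqs, site_freqs = site_freqs,
    site_f = stats::setNames(site_f, site_ids),
    site_lat = stats::setNames(lat, site_ids),
    site_lon = stats::setNames(lon, site_ids),
    founders = founders,
    founder_of_site = if (!is.null(founder_of_site)) {
      stats::setNames(founder_of_site, site_ids)
    },
    clone_fraction = if (scenario == "north_america") clone_fraction,
    frequency_gradient_scale_km = if (scenario == "eurasia") frequency_gradient_scale_km,
    gradient_sd = if (scenario == "eurasia") gradient_sd,
    error_rate = error_rate, missing_rate = missing_rate
  )
  list(genotypes = gt, meta = validate_sample_meta(meta), truth = truth)
}

site_distance_matrix <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  d
}
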