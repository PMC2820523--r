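# Field-site haplogroup diversity, the global pairwise mismatch
# distribution with continent partitioning, and panmixia resampling.

#' Haplogroup diversity of one field site
#'
#' The probability that two plants drawn from the site without replacement
#' belong to different haplogroups:
#' `1 - sum(c_i (c_i - 1)) / (n (n - 1))` for haplogroup multiplicities
#' `c_i` summing to `n`. A with-replacement (Simpson) variant is available
#' by flag.
#'
#' @param group_counts Integer vector of haplogroup multiplicities at the
#'   site (sum >= 2).
#' @param with_replacement Use the Simpson form `1 - sum((c_i/n)^2)`
#'   (default FALSE).
#' @return Diversity in \[0, 1\]; NA when fewer than 2 plants.
#' @export
site_diversity <- function(group_counts, with_replacement = FALSE) {
  group_counts <- group_counts[group_counts > 0]
  n <- sum(group_counts)
  if (n < 2) return(NA_real_)
  if (with_replacement) {
    1 - sum((group_counts / n)^2)
  } else {
    1 - sum(group_counts * (group_counts - 1)) / (n * (n - 1))
  }
}

#' Per-site haplogroup diversity table
#'
#' @param meta Sample metadata.
#' @param assignment A [qt_cluster()] assignment covering the samples.
#' @param with_replacement Passed to [site_diversity()].
#' @return A data frame with `site_id`, `continent`, `n_plants`,
#'   `n_haplogroups`, `modal_fraction` and `diversity` (NA for sites with
#'   fewer than 2 plants).
#' @export
diversity_by_site <- function(meta, assignment, with_replacement = FALSE) {
  if (!all(meta$sample_id %in% names(assignment$group_of))) {
    stop("assignment does not cover all samples in the metadata")
  }
  sites <- unique(meta$site_id)
  rows <- lapply(sites, function(sid) {
    sel <- meta$site_id == sid
    groups <- assignment$group_of[meta$sample_id[sel]]
    counts <- as.integer(table(groups))
    data.frame(
      site_id = sid,
      continent = meta$continent[sel][1],
      n_plants = sum(sel),
      n_haplogroups = length(counts),
      modal_fraction = max(counts) / sum(counts),
      diversity = site_diversity(counts, with_replacement),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Fraction of sites dominated by a single haplogroup
#'
#' A site is "dominated" when its modal haplogroup exceeds
#' `dominance_threshold` of the plants there. Reported per continent and
#' overall; sites with fewer than 2 plants are excluded.
#'
#' @param site_div Output of [diversity_by_site()].
#' @param dominance_threshold Modal-frequency threshold in (0, 1)
#'   (default 0.8).
#' @return A data frame with `continent` (including an `"ALL"` row),
#'   `n_sites` and `dominated_fraction`.
#' @export
dominance_summary <- function(site_div, dominance_threshold = 0.8) {
  stopifnot(dominance_threshold > 0, dominance_threshold < 1)
  sd2 <- site_div[site_div$n_plants >= 2, , drop = FALSE]
  dom <- sd2$modal_fraction > dominance_threshold
  by_cont <- tapply(dom, sd2$continent, mean)
  n_cont <- tapply(dom, sd2$continent, length)
  data.frame(
    continent = c(names(by_cont), "ALL"),
    n_sites = c(as.integer(n_cont), nrow(sd2)),
    dominated_fraction = c(as.numeric(by_cont), mean(dom)),
    stringsAsFactors = FALSE
  )
}

# fixed-width histogram over mismatch fractions in [0, 1]
mismatch_histogram <- function(fractions, bin_width) {
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  counts <- as.integer(table(cut(fractions, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  list(breaks = breaks, counts = counts, n_pairs = length(fractions))
}

#' Pairwise mismatch distribution, partitioned by continent
#'
#' Computes the mismatch fraction for every unordered pair of plants
#' (heterozygous calls treated as missing by default), assigns each pair a
#' stratum from the continent pair — the shared continent name when both
#' plants are on the same continent, `"INTERCONTINENTAL"` otherwise — and
#' histograms each stratum plus the `"ALL"` union. Pairs with no marker
#' informative in both (undefined fraction) are excluded and counted.
#'
#' @param gt A `genotype_table`.
#' @param meta Optional sample metadata; without it all pairs land in
#'   `"ALL"`.
#' @param bin_width Histogram bin width (default one marker, `1/L`).
#' @param het_as_missing Treat heterozygous calls as missing (default TRUE).
#' @return A list with `pairs` (data frame: `id1`, `id2`, `k`, `n`,
#'   `fraction`, `stratum`), `histograms` (named list of per-stratum
#'   histograms), `n_undefined` and `bin_width`.
#' @export
mismatch_distribution <- function(gt, meta = NULL, bin_width = NULL,
                                  het_as_missing = TRUE) {
  if (nrow(gt$calls) < 2) stop("need at least 2 samples")
  if (is.null(bin_width)) bin_width <- 1 / ncol(gt$calls)
  pairs <- pair_mismatch_table(gt, het_as_missing)
  ids <- sample_ids(gt)
  pairs$id1 <- ids[pairs$i]
  pairs$id2 <- ids[pairs$j]
  if (!is.null(meta)) {
    cont <- stats::setNames(meta$continent, meta$sample_id)
    c1 <- cont[pairs$id1]
    c2 <- cont[pairs$id2]
    pairs$stratum <- ifelse(c1 == c2, c1, "INTERCONTINENTAL")
  } else {
    pairs$stratum <- "ALL"
  }
  undef <- !is.finite(pairs$fraction)
  defined <- pairs[!undef, , drop = FALSE]
  strata <- unique(defined$stratum)
  hists <- lapply(strata, function(s) {
    mismatch_histogram(defined$fraction[defined$stratum == s], bin_width)
  })
  names(hists) <- strata
  hists$ALL <- mismatch_histogram(defined$fraction, bin_width)
  list(pairs = pairs[, c("id1", "id2", "k", "n", "fraction", "stratum")],
       histograms = hists, n_undefined = sum(undef), bin_width = bin_width)
}

#' Simulate haplotypes under panmixia by per-marker resampling
#'
#' For each simulated haplotype and each marker independently, the call is
#' copied from a uniformly chosen donor haplotype (with replacement, donor
#' redrawn per marker), which destroys all linkage between markers while
#' preserving the marginal call frequencies. With `unique_only` the donor
#' pool holds one representative (the central haplotype) per haplogroup,
#' removing the weighting caused by clonally amplified haplogroups.
#'
#' @param gt A `genotype_table` providing the donor pool.
#' @param n_sim Number of simulated haplotypes (default 10000).
#' @param unique_only Use one donor per haplogroup (default FALSE).
#' @param assignment Required when `unique_only`: a [qt_cluster()] result.
#' @param seed Integer seed.
#' @param max_pairs Cap on the number of simulated pairs used for the
#'   mismatch distribution; a uniform random subset of pairs is scored when
#'   `choose(n_sim, 2)` exceeds it (default 1e5).
#' @param bin_width Histogram bin width (default `1/L`).
#' @param het_as_missing Treat heterozygous calls as missing in the
#'   simulated mismatch distribution (default TRUE).
#' @return A list with `sim_calls` (n_sim x L integer matrix), `fractions`
#'   (mismatch fractions of the scored pairs), `histogram`,
#'   `mean_fraction`, `n_pairs_scored` and `n_donors`.
#' @export
simulate_panmixia <- function(gt, n_sim = 10000, unique_only = FALSE,
                              assignment = NULL, seed = 1L, max_pairs = 1e5,
                              bin_width = NULL, het_as_missing = TRUE) {
  stopifnot(n_sim >= 2)
  if (is.null(bin_width)) bin_width <- 1 / ncol(gt$calls)
  donors <- gt$calls
  if (unique_only) {
    if (is.null(assignment)) stop("unique_only requires a haplogroup assignment")
    donors <- donors[unname(assignment$central_of), , drop = FALSE]
  }
  set.seed(seed)
  L <- ncol(donors)
  nd <- nrow(donors)
  sim <- matrix(NA_integer_, n_sim, L)
  for (j in seq_len(L)) {
    sim[, j] <- donors[sample.int(nd, n_sim, replace = TRUE), j]
  }
  rownames(sim) <- sprintf("sim%05d", seq_len(n_sim))

  total_pairs <- n_sim * (n_sim - 1) / 2
  if (total_pairs <= max_pairs) {
    mm <- mismatch_matrices(sim, het_as_missing)
    ut <- upper.tri(mm$n)
    k <- mm$k[ut]
    n <- mm$n[ut]
  } else {
    # uniform random pairs without replacement via linear pair indices
    pid <- sample(total_pairs, max_pairs)
    j <- ceiling((1 + sqrt(1 + 8 * pid)) / 2)
    i <- pid - (j - 1) * (j - 2) / 2
    h1 <- sim[i, , drop = FALSE]
    h2 <- sim[j, , drop = FALSE]
    if (het_as_missing) {
      h1[h1 == CALL_HET] <- NA_integer_
      h2[h2 == CALL_HET] <- NA_integer_
    }
    inf <- !is.na(h1) & !is.na(h2)
    n <- rowSums(inf)
    k <- rowSums(inf & (h1 != h2), na.rm = TRUE)
  }
  frac <- ifelse(n > 0, k / n, NA_real_)
  frac <- frac[!is.na(frac)]
  list(sim_calls = sim, fractions = frac,
       histogram = mismatch_histogram(frac, bin_width),
       mean_fraction = mean(frac),
       n_pairs_scored = length(frac), n_donors = nd)
}

#' Expected panmictic mismatch fraction from donor call frequencies
#'
#' Closed-form companion to [simulate_panmixia()]: with per-marker donor
#' call frequencies `f0` (HOM_REF), `f2` (HOM_ALT) and informative mass
#' `g = f0 + f2`, the expected per-pair mismatch fraction under per-marker
#' resampling is `sum(2 f0 f2) / sum(g^2)` (exact when every donor call is
#' informative, a tight approximation otherwise).
#'
#' @param gt Donor `genotype_table`.
#' @param unique_only,assignment As in [simulate_panmixia()].
#' @param het_as_missing Treat heterozygous calls as missing (default TRUE).
#' @return Expected mismatch fraction.
#' @export
expected_panmixia_mismatch <- function(gt, unique_only = FALSE,
                                       assignment = NULL,
                                       het_as_missing = TRUE) {
  donors <- gt$calls
  if (unique_only) {
    if (is.null(assignment)) stop("unique_only requires a haplogroup assignment")
    donors <- donors[unname(assignment$central_of), , drop = FALSE]
  }
  if (het_as_missing) donors[donors == CALL_HET] <- NA_integer_
  nd <- nrow(donors)
  f0 <- colSums(donors == CALL_HOM_REF, na.rm = TRUE) / nd
  f2 <- colSums(donors == CALL_HOM_ALT, na.rm = TRUE) / nd
  fh <- colSums(donors == CALL_HET, na.rm = TRUE) / nd
  g <- f0 + f2 + fh
  sum(2 * f0 * f2) / sum(g^2)
}

#' Classify plant pairs as identical, intermediate or unrelated
#'
#' A pair is `IDENTICAL` when it has zero mismatches (`k = 0`), `UNRELATED`
#' when its mismatch fraction is at least the `unrelated_quantile`-th
#' quantile of the simulated panmictic distribution (i.e. indistinguishable
#' from a random re-assortment of alleles), and `INTERMEDIATE` otherwise.
#' Fractions are over defined pairs and sum to 1.
#'
#' @param pairs Pair table from [mismatch_distribution()] (needs `k`,
#'   `fraction`).
#' @param sim_fractions Simulated panmictic mismatch fractions from
#'   [simulate_panmixia()].
#' @param unrelated_quantile Lower quantile of the simulated distribution
#'   used as the unrelatedness cut (default 0.01).
#' @return A list with `fractions` (named: identical, intermediate,
#'   unrelated), `threshold`, `n_pairs` and `class` (per-pair factor).
#' @export
classify_pairs <- function(pairs, sim_fractions, unrelated_quantile = 0.01) {
  if (length(sim_fractions) == 0) stop("simulated distribution is empty")
  thr <- unname(stats::quantile(sim_fractions, unrelated_quantile, type = 7))
  ok <- is.finite(pairs$fraction)
  k <- pairs$k[ok]
  f <- pairs$fraction[ok]
  cls <- ifelse(k == 0, "identical", ifelse(f >= thr, "unrelated", "intermediate"))
  cls <- factor(cls, levels = c("identical", "intermediate", "unrelated"))
  list(
    fractions = c(
      identical = mean(cls == "identical"),
      intermediate = mean(cls == "intermediate"),
      unrelated = mean(cls == "unrelated")
    ),
    threshold = thr, n_pairs = sum(ok), class = cls
  )
}
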