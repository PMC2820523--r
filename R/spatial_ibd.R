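# Geographic pairwise analysis: great-circle distances, multi-scale
# distance binning of pair statistics, linear and exponential curve fits,
# and pairwise-site Weir-Cockerham F_ST against log distance with
# sliding-window slopes.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere with the IUGG mean Earth radius
#' (6371.0088 km). Vectorized over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84
#'   assumed; no datum conversion).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Geographic pair table for IBD analysis
#'
#' One row per unordered pair of plants with defined mismatch fraction:
#' great-circle distance, same-haplogroup indicator and mismatch fraction.
#'
#' @param gt A `genotype_table`.
#' @param meta Sample metadata covering the table's samples.
#' @param assignment A [qt_cluster()] assignment (for the same-haplogroup
#'   indicator); optional.
#' @param het_as_missing Treat heterozygous calls as missing (default TRUE).
#' @return A data frame with `id1`, `id2`, `km`, `same_group`, `k`, `n`,
#'   `fraction`.
#' @export
ibd_pair_table <- function(gt, meta, assignment = NULL, het_as_missing = TRUE) {
  ids <- sample_ids(gt)
  m <- meta[match(ids, meta$sample_id), ]
  if (anyNA(m$sample_id)) stop("metadata does not cover all samples")
  pairs <- pair_mismatch_table(gt, het_as_missing)
  lat <- m$latitude
  lon <- m$longitude
  pairs$km <- haversine_km(lat[pairs$i], lon[pairs$i], lat[pairs$j], lon[pairs$j])
  if (!is.null(assignment)) {
    grp <- assignment$group_of[ids]
    pairs$same_group <- grp[pairs$i] == grp[pairs$j]
  } else {
    pairs$same_group <- NA
  }
  pairs$id1 <- ids[pairs$i]
  pairs$id2 <- ids[pairs$j]
  pairs[is.finite(pairs$fraction),
        c("id1", "id2", "km", "same_group", "k", "n", "fraction")]
}

#' Bin pair statistics by geographic distance
#'
#' Pairs are assigned to half-open bins `[i*w, (i+1)*w)` by the floor rule.
#' Per bin: pair count, same-haplogroup probability, and mismatch-fraction
#' quantiles at the 9th, 25th, 50th, 75th and 91st percentiles (linear
#' interpolation). Empty bins within range are kept with `n_pairs = 0` and
#' NA statistics.
#'
#' @param pairs Pair table from [ibd_pair_table()].
#' @param bin_width_km Bin width in km (presets 150, 10, 0.5).
#' @param max_distance_km Optional cap; pairs at or beyond it are dropped.
#' @return A data frame of class `binned_ibd`: `bin_low`, `bin_high`,
#'   `mid_km`, `n_pairs`, `p_same_haplogroup`, `q09`, `q25`, `q50`, `q75`,
#'   `q91`, `mean_fraction`.
#' @export
bin_pairs <- function(pairs, bin_width_km, max_distance_km = NULL) {
  stopifnot(bin_width_km > 0)
  if (!is.null(max_distance_km)) {
    pairs <- pairs[pairs$km < max_distance_km, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no pairs to bin")
  idx <- floor(pairs$km / bin_width_km)
  all_bins <- 0:max(idx)
  probs <- c(0.09, 0.25, 0.5, 0.75, 0.91)
  rows <- lapply(all_bins, function(b) {
    sel <- idx == b
    np <- sum(sel)
    if (np == 0) {
      qs <- rep(NA_real_, 5)
      ps <- NA_real_
      mf <- NA_real_
    } else {
      qs <- unname(stats::quantile(pairs$fraction[sel], probs, type = 7))
      ps <- if (all(is.na(pairs$same_group[sel]))) NA_real_ else
        mean(pairs$same_group[sel], na.rm = TRUE)
      mf <- mean(pairs$fraction[sel])
    }
    data.frame(bin_low = b * bin_width_km, bin_high = (b + 1) * bin_width_km,
               mid_km = (b + 0.5) * bin_width_km, n_pairs = np,
               p_same_haplogroup = ps,
               q09 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q91 = qs[5],
               mean_fraction = mf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("binned_ibd", "data.frame")
  out
}

# pull response values and weights out of a binned_ibd table
binned_response <- function(binned, response, weighting, min_pairs) {
  y <- binned[[response]]
  keep <- !is.na(y) & binned$n_pairs >= min_pairs
  list(x = binned$mid_km[keep], y = y[keep],
       w = if (weighting == "by_n_pairs") binned$n_pairs[keep]
           else rep(1, sum(keep)))
}

#' Weighted linear fit to binned IBD data
#'
#' Least squares of a bin response on bin midpoints, `y = m x + b`,
#' weighted by per-bin pair count by default.
#'
#' @param binned A [bin_pairs()] table.
#' @param response Column to fit (default `"p_same_haplogroup"`).
#' @param weighting `"by_n_pairs"` (default) or `"none"`.
#' @param min_pairs Bins with fewer pairs are excluded (default 5).
#' @return A list of class `curve_fit`: `form = "linear"`, `params`
#'   (named `m`, `b`), `rss`, `converged = TRUE`, `n_bins`.
#' @export
fit_linear <- function(binned, response = "p_same_haplogroup",
                       weighting = c("by_n_pairs", "none"), min_pairs = 5) {
  weighting <- match.arg(weighting)
  d <- binned_response(binned, response, weighting, min_pairs)
  if (length(d$x) < 2) stop("need at least 2 informative bins")
  fit <- stats::lm(y ~ x, data = data.frame(x = d$x, y = d$y), weights = d$w)
  co <- stats::coef(fit)
  structure(list(form = "linear",
                 params = c(m = unname(co["x"]), b = unname(co["(Intercept)"])),
                 rss = sum(d$w * stats::residuals(fit)^2),
                 converged = TRUE, n_bins = length(d$x),
                 response = response, weighting = weighting),
            class = "curve_fit")
}

#' Exponential-decay fit to binned IBD data
#'
#' Nonlinear least squares of `y = C exp(-lambda x)` (`"exp_decay"`) or the
#' saturating form `y = K - C exp(-lambda x)` (`"exp_saturating"`) on bin
#' midpoints. Initialization: `C0` from the first informative bin,
#' `lambda0` from a log-linear regression of the positive responses, `K0`
#' from the last bin. A solver failure or a negative fitted rate is
#' reported as `converged = FALSE` rather than an error, since monotone
#' increasing data genuinely cannot fit a decay.
#'
#' @param binned A [bin_pairs()] table.
#' @param form `"exp_decay"` (default) or `"exp_saturating"`.
#' @param response Column to fit (default `"q50"`, the per-bin median
#'   mismatch fraction).
#' @param weighting `"by_n_pairs"` (default) or `"none"`.
#' @param min_pairs Bins with fewer pairs are excluded (default 5).
#' @return A `curve_fit` list: `params` named (`C`, `lambda`) or
#'   (`K`, `C`, `lambda`), `rss`, `converged`, `n_bins`.
#' @export
fit_exp_decay <- function(binned, form = c("exp_decay", "exp_saturating"),
                          response = "q50",
                          weighting = c("by_n_pairs", "none"), min_pairs = 5) {
  form <- match.arg(form)
  weighting <- match.arg(weighting)
  d <- binned_response(binned, response, weighting, min_pairs)
  need <- if (form == "exp_decay") 3 else 4
  if (length(d$x) < need) stop("need at least ", need, " informative bins")
  df <- data.frame(x = d$x, y = d$y)

  pos <- d$y > 0
  lam0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y) ~ x, data = df[pos, ]))["x"]
    max(abs(sl), 1e-6)
  } else 1 / max(d$x)
  C0 <- max(d$y[1], 1e-6)
  K0 <- d$y[length(d$y)]

  res <- tryCatch({
    if (form == "exp_decay") {
      fit <- minpack.lm::nlsLM(y ~ C * exp(-lambda * x), data = df,
                               start = list(C = C0, lambda = lam0),
                               weights = d$w,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- stats::coef(fit)
      list(params = c(C = unname(co["C"]), lambda = unname(co["lambda"])),
           rss = sum(d$w * stats::residuals(fit)^2),
           converged = unname(co["lambda"]) >= 0)
    } else {
      fit <- minpack.lm::nlsLM(y ~ K - C * exp(-lambda * x), data = df,
                               start = list(K = K0, C = max(K0 - C0, 1e-6),
                                            lambda = lam0),
                               weights = d$w,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- stats::coef(fit)
      list(params = c(K = unname(co["K"]), C = unname(co["C"]),
                      lambda = unname(co["lambda"])),
           rss = sum(d$w * stats::residuals(fit)^2),
           converged = unname(co["lambda"]) >= 0)
    }
  }, error = function(e) {
    list(params = if (form == "exp_decay") c(C = NA_real_, lambda = NA_real_)
         else c(K = NA_real_, C = NA_real_, lambda = NA_real_),
         rss = NA_real_, converged = FALSE)
  })
  structure(c(res, list(form = form, n_bins = length(d$x),
                        response = response, weighting = weighting)),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("curve_fit [%s] on %s (%d bins, %s): %s; rss=%.4g; converged=%s\n",
              x$form, x$response, x$n_bins, x$weighting,
              paste(sprintf("%s=%.6g", names(x$params), x$params), collapse = ", "),
              x$rss, x$converged))
  invisible(x)
}

# Weir-Cockerham variance components for two populations at one locus.
# Inputs: per-site non-missing counts n1,n2 (plants), alt freqs p1,p2 and
# het fractions h1,h2. Returns c(a, b, c).
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(c(0, 0, 0))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

# theta for one site pair across loci: ratio of summed components
wc_theta_pair <- function(calls1, calls2) {
  stats1 <- locus_stats(calls1)
  stats2 <- locus_stats(calls2)
  ok <- stats1$n >= 2 & stats2$n >= 2
  comp <- vapply(which(ok), function(j) {
    wc_components(stats1$n[j], stats2$n[j], stats1$p[j], stats2$p[j],
                  stats1$h[j], stats2$h[j])
  }, numeric(3))
  if (length(comp) == 0) return(NA_real_)
  num <- sum(comp[1, ])
  den <- sum(comp[1, ] + comp[2, ] + comp[3, ])
  if (den == 0) NA_real_ else num / den
}

locus_stats <- function(calls) {
  n <- colSums(!is.na(calls))
  het <- colSums(calls == CALL_HET, na.rm = TRUE)
  alt <- colSums(calls == CALL_HOM_ALT, na.rm = TRUE)
  list(n = n,
       p = ifelse(n > 0, (2 * alt + het) / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_))
}

#' Pairwise Weir-Cockerham F_ST between field sites
#'
#' Per site pair, theta is the two-population Weir-Cockerham estimator
#' computed per locus and combined across loci as a ratio of summed
#' variance components. Negative estimates are retained (truncation would
#' bias the distance regressions). Sites with fewer than
#' `min_plants_per_site` genotyped plants are excluded.
#'
#' @param gt A `genotype_table`.
#' @param meta Sample metadata covering the table's samples.
#' @param min_plants_per_site Minimum plants per site (default 4).
#' @return A list with `pairs` (data frame: `site1`, `site2`, `fst`),
#'   `sites` (ids used) and `excluded` (ids dropped for size).
#' @export
pairwise_site_fst <- function(gt, meta, min_plants_per_site = 4) {
  ids <- sample_ids(gt)
  m <- meta[match(ids, meta$sample_id), ]
  if (anyNA(m$sample_id)) stop("metadata does not cover all samples")
  counts <- table(m$site_id)
  use <- names(counts)[counts >= min_plants_per_site]
  excluded <- setdiff(names(counts), use)
  if (length(use) < 2) stop("need at least 2 sites with >= ",
                            min_plants_per_site, " plants")
  site_calls <- lapply(use, function(s) gt$calls[m$site_id == s, , drop = FALSE])
  names(site_calls) <- use
  cmb <- utils::combn(use, 2)
  fst <- vapply(seq_len(ncol(cmb)), function(q) {
    wc_theta_pair(site_calls[[cmb[1, q]]], site_calls[[cmb[2, q]]])
  }, numeric(1))
  list(pairs = data.frame(site1 = cmb[1, ], site2 = cmb[2, ], fst = fst,
                          stringsAsFactors = FALSE),
       sites = use, excluded = excluded)
}

#' F_ST against log distance, with sliding-window slopes
#'
#' Ordinary least squares of pairwise site F_ST on `ln(km)`. Site pairs at
#' distance 0 are excluded (and counted). Sliding windows of `window`
#' consecutive pairs ordered by distance (step 1) each get their own slope;
#' when fewer pairs than `window` exist, only the global regression is
#' returned.
#'
#' @param fst_pairs Pair table from [pairwise_site_fst()] (`site1`,
#'   `site2`, `fst`).
#' @param meta Sample metadata (site coordinates are taken from each
#'   site's first sample).
#' @param window Window size in pairs (default 500; scale down for small
#'   simulated landscapes).
#' @return A list with `pairs` (ordered by distance: `site1`, `site2`,
#'   `fst`, `km`, `log_km`), `slope`, `intercept`, `n_zero_excluded` and
#'   `windows` (data frame: `start`, `mid_km`, `slope`).
#' @export
fst_distance_regression <- function(fst_pairs, meta, window = 500) {
  site_first <- meta[!duplicated(meta$site_id), ]
  lat <- stats::setNames(site_first$latitude, site_first$site_id)
  lon <- stats::setNames(site_first$longitude, site_first$site_id)
  p <- fst_pairs
  p$km <- haversine_km(lat[p$site1], lon[p$site1], lat[p$site2], lon[p$site2])
  zero <- p$km <= 0
  p <- p[!zero & !is.na(p$fst), , drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 site pairs at positive distance")
  p$log_km <- log(p$km)
  p <- p[order(p$km), , drop = FALSE]
  rownames(p) <- NULL
  co <- stats::coef(stats::lm(fst ~ log_km, data = p))
  windows <- data.frame(start = integer(0), mid_km = numeric(0),
                        slope = numeric(0))
  npairs <- nrow(p)
  if (npairs >= window) {
    # rolling OLS slope over `window` consecutive pairs via cumulative sums
    x <- p$log_km
    y <- p$fst
    cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
    cxx <- cumsum(c(0, x^2)); cxy <- cumsum(c(0, x * y))
    st <- seq_len(npairs - window + 1)
    en <- st + window - 1
    sx <- cx[en + 1] - cx[st]; sy <- cy[en + 1] - cy[st]
    sxx <- cxx[en + 1] - cxx[st]; sxy <- cxy[en + 1] - cxy[st]
    denom <- sxx - sx^2 / window
    slope <- ifelse(denom > 0, (sxy - sx * sy / window) / denom, NA_real_)
    mid <- vapply(st, function(s) stats::median(p$km[s:(s + window - 1)]),
                  numeric(1))
    windows <- data.frame(start = st, mid_km = mid, slope = slope)
  }
  list(pairs = p, slope = unname(co["log_km"]), intercept = unname(co["(Intercept)"]),
       n_zero_excluded = sum(zero), windows = windows)
}
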