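test_that("haversine distances match spherical geometry", {
  expect_equal(haversine_km(48, 2, 48, 2), 0)
  # half circumference and quarter circumference at the equator
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 0.1 / 20015)
  expect_equal(haversine_km(0, 0, 0, 90), pi * 6371.0088 / 2, tolerance = 0.1 / 10008)
  # symmetric and vectorized
  expect_equal(haversine_km(c(0, 10), c(0, 20), c(5, 15), c(5, 25)),
               haversine_km(c(5, 15), c(5, 25), c(0, 10), c(0, 20)))
})

test_that("distance binning follows the floor rule and conserves pairs", {
  pairs <- data.frame(
    id1 = "a", id2 = "b",
    km = c(10, 170, 320), same_group = c(TRUE, FALSE, FALSE),
    k = c(0, 5, 7), n = 10, fraction = c(0, 0.5, 0.7)
  )
  b <- bin_pairs(pairs, 150)
  expect_equal(b$bin_low, c(0, 150, 300))
  expect_equal(b$n_pairs, c(1L, 1L, 1L))
  expect_equal(sum(b$n_pairs), nrow(pairs))
  expect_equal(b$p_same_haplogroup, c(1, 0, 0))

  # all pairs at zero distance in one bin
  pairs0 <- data.frame(id1 = "a", id2 = "b", km = 0, same_group = TRUE,
                       k = 0, n = 10, fraction = 0)
  b0 <- bin_pairs(pairs0[rep(1, 5), ], 0.5)
  expect_equal(nrow(b0), 1)
  expect_equal(b0$p_same_haplogroup, 1)

  # quantiles of a hand-listed 11-value bin match direct computation
  fr <- seq(0, 1, by = 0.1)
  pairs11 <- data.frame(id1 = "a", id2 = "b", km = 1, same_group = FALSE,
                        k = 1, n = 10, fraction = fr)
  b11 <- bin_pairs(pairs11, 10)
  qs <- quantile(fr, c(0.09, 0.25, 0.5, 0.75, 0.91), type = 7)
  expect_equal(unname(unlist(b11[1, c("q09", "q25", "q50", "q75", "q91")])),
               unname(qs))
  # quantiles weakly ordered
  expect_true(all(diff(unname(unlist(b11[1, c("q09", "q25", "q50", "q75", "q91")]))) >= 0))
})

test_that("linear fits agree with the closed-form normal equations", {
  x <- seq(75, by = 150, length.out = 8)
  mk <- function(y, n) {
    b <- data.frame(bin_low = x - 75, bin_high = x + 75, mid_km = x,
                    n_pairs = n, p_same_haplogroup = y,
                    q09 = y, q25 = y, q50 = y, q75 = y, q91 = y,
                    mean_fraction = y)
    class(b) <- c("binned_ibd", "data.frame")
    b
  }
  # exact line y = 2x + 1
  f <- fit_linear(mk(2 * x + 1, 50L))
  expect_equal(unname(f$params["m"]), 2, tolerance = 1e-10)
  expect_equal(unname(f$params["b"]), 1, tolerance = 1e-10)
  expect_lt(f$rss, 1e-10)
  # constant response has slope 0
  f0 <- fit_linear(mk(rep(0.4, 8), 50L))
  expect_equal(unname(f0$params["m"]), 0, tolerance = 1e-12)

  # weighted vs unweighted on a heavy outlier bin, against the
  # normal-equations solution computed directly
  y <- 0.001 * x + 0.1
  y[8] <- 0.9
  n <- rep(10L, 8); n[8] <- 1000L
  fw <- fit_linear(mk(y, n), weighting = "by_n_pairs", min_pairs = 1)
  fu <- fit_linear(mk(y, n), weighting = "none", min_pairs = 1)
  W <- diag(as.numeric(n))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(fw$params["b"]), beta[1], tolerance = 1e-8)
  expect_equal(unname(fw$params["m"]), beta[2], tolerance = 1e-8)
  expect_gt(abs(fw$params["m"] - fu$params["m"]), 1e-5)
})

test_that("exponential fits recover noiseless parameters and refuse rising data", {
  x <- seq(5, 400, by = 10)
  mk <- function(y) {
    b <- data.frame(bin_low = x - 5, bin_high = x + 5, mid_km = x,
                    n_pairs = 50L, p_same_haplogroup = y,
                    q09 = y, q25 = y, q50 = y, q75 = y, q91 = y,
                    mean_fraction = y)
    class(b) <- c("binned_ibd", "data.frame")
    b
  }
  f <- fit_exp_decay(mk(0.8 * exp(-0.01 * x)), "exp_decay")
  expect_true(f$converged)
  expect_lt(abs(f$params[["C"]] - 0.8) / 0.8, 1e-6)
  expect_lt(abs(f$params[["lambda"]] - 0.01) / 0.01, 1e-6)

  fs <- fit_exp_decay(mk(0.35 - 0.3 * exp(-0.01 * x)), "exp_saturating")
  expect_true(fs$converged)
  expect_lt(max(abs(fs$params - c(K = 0.35, C = 0.3, lambda = 0.01)) /
                  c(0.35, 0.3, 0.01)), 1e-6)

  # strictly increasing response cannot fit a decay: converged = FALSE
  fi <- fit_exp_decay(mk(0.1 + 0.001 * x), "exp_decay")
  expect_false(fi$converged)
})

test_that("Weir-Cockerham theta matches hand-computed fixtures", {
  # locus 1, site1: 5 RR / 3 RA / 2 AA; site2: 1 RR / 1 RA / 8 AA
  s1 <- c(rep(0L, 5), rep(1L, 3), rep(2L, 2))
  s2 <- c(0L, 1L, rep(2L, 8))
  theta <- selfscape:::wc_theta_pair(matrix(s1, 10, 1), matrix(s2, 10, 1))
  expect_equal(theta, 133 / 363, tolerance = 1e-12)

  # two loci, unequal/missing-reduced sample sizes
  l1s1 <- c(rep(0L, 4), rep(1L, 2), 2L)
  l1s2 <- c(rep(0L, 2), rep(2L, 3))
  l2s1 <- c(rep(0L, 3), rep(1L, 3), 2L)
  l2s2 <- c(rep(1L, 2), rep(2L, 3))
  theta2 <- selfscape:::wc_theta_pair(cbind(l1s1, l2s1), cbind(l1s2, l2s2))
  expect_equal(theta2, 5358 / 33253, tolerance = 1e-12)

  # opposite fixation gives exactly 1; identical sites give ~ 0
  a <- matrix(0L, 6, 10); b <- matrix(2L, 6, 10)
  expect_equal(selfscape:::wc_theta_pair(a, b), 1)
})

test_that("pairwise site F_ST behaves at the null and under fixation", {
  pan <- generate_panel(50, 0.25, 0.30, seed = 131)
  # one panmictic population split into two labelled sites: theta ~ 0
  gt <- generate_equilibrium_site(400, pan$freqs, 0.5, seed = 132)
  meta <- make_meta(gt)
  meta$site_id <- rep(c("x", "y"), each = 200)
  fst <- pairwise_site_fst(gt, meta)
  expect_lt(abs(fst$pairs$fst), 0.02)
  # small sites excluded with a record
  meta$site_id[1:2] <- "tiny"
  meta$site_id[3:400] <- rep(c("x", "y"), 199)
  fst2 <- pairwise_site_fst(gt, meta, min_plants_per_site = 4)
  expect_true("tiny" %in% fst2$excluded)
})

test_that("F_ST regression recovers exact linear structure and window slopes", {
  set.seed(141)
  n_sites <- 12
  meta <- data.frame(
    sample_id = sprintf("s%02d", 1:n_sites),
    latitude = runif(n_sites, 40, 50), longitude = runif(n_sites, 0, 20),
    site_id = sprintf("site%02d", 1:n_sites),
    continent = "EURASIA", tissue_source = "FIELD_SEED_GROWN"
  )
  cmb <- combn(meta$site_id, 2)
  km <- haversine_km(meta$latitude[match(cmb[1, ], meta$site_id)],
                     meta$longitude[match(cmb[1, ], meta$site_id)],
                     meta$latitude[match(cmb[2, ], meta$site_id)],
                     meta$longitude[match(cmb[2, ], meta$site_id)])
  fst_pairs <- data.frame(site1 = cmb[1, ], site2 = cmb[2, ],
                          fst = 0.02 * log(km) - 0.03)
  reg <- fst_distance_regression(fst_pairs, meta, window = 20)
  expect_equal(reg$slope, 0.02, tolerance = 1e-10)
  expect_equal(reg$intercept, -0.03, tolerance = 1e-10)
  # every sliding-window slope equals the global slope on exact data
  expect_equal(nrow(reg$windows), choose(n_sites, 2) - 20 + 1)
  expect_true(all(abs(reg$windows$slope - 0.02) < 1e-8))
  # windows ordered by distance
  expect_true(!is.unsorted(reg$windows$mid_km))

  # shuffled response: slope t-statistic is null
  set.seed(142)
  tvals <- replicate(40, {
    shuf <- fst_pairs
    shuf$fst <- sample(shuf$fst)
    r <- fst_distance_regression(shuf, meta, window = 100)
    p <- r$pairs
    summary(lm(fst ~ log_km, data = p))$coefficients["log_km", "t value"]
  })
  expect_gte(mean(abs(tvals) < 2), 0.9)
})
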