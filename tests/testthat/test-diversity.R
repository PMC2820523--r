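test_that("site diversity equals the unordered-pair probability", {
  expect_equal(site_diversity(5), 0)            # one haplogroup
  expect_equal(site_diversity(c(1, 1)), 1)      # two singletons
  expect_equal(site_diversity(c(2, 2)), 2 / 3)  # 4 of 6 pairs differ
  expect_true(is.na(site_diversity(1)))         # undefined below 2 plants

  # exhaustive pair enumeration oracle for n <= 8
  set.seed(101)
  for (rep in 1:20) {
    counts <- table(sample(1:4, sample(2:8, 1), replace = TRUE))
    labels <- rep(seq_along(counts), counts)
    pairs <- combn(length(labels), 2)
    frac_diff <- mean(labels[pairs[1, ]] != labels[pairs[2, ]])
    expect_equal(site_diversity(as.integer(counts)), frac_diff)
    # with-replacement variant is the Simpson complement
    expect_equal(site_diversity(as.integer(counts), with_replacement = TRUE),
                 1 - sum((counts / sum(counts))^2))
  }
})

test_that("dominance summary applies the modal-frequency threshold per continent", {
  sd <- data.frame(
    site_id = c("a", "b", "c", "d"),
    continent = c("EURASIA", "EURASIA", "NORTH_AMERICA", "NORTH_AMERICA"),
    n_plants = c(10, 8, 10, 2),
    n_haplogroups = c(2, 2, 2, 2),
    modal_fraction = c(9 / 10, 4 / 8, 9 / 10, 1 / 2),
    diversity = c(0.2, 0.57, 0.2, 1)
  )
  dom <- dominance_summary(sd, 0.8)
  expect_equal(dom$dominated_fraction[dom$continent == "EURASIA"], 0.5)
  expect_equal(dom$dominated_fraction[dom$continent == "ALL"], 0.5)
  # (4,4) is never dominated at any threshold >= 0.5
  expect_equal(dominance_summary(sd[2, , drop = FALSE], 0.5)$dominated_fraction[1], 0)
})

test_that("clone-dominated landscapes are flagged dominated nearly everywhere", {
  ls <- generate_landscape("north_america", n_sites = 20, plants_per_site = 10,
                           clone_fraction = 0.9, seed = 103)
  asn <- qt_cluster(ls$genotypes)
  dom <- dominance_summary(diversity_by_site(ls$meta, asn), 0.8)
  expect_gte(dom$dominated_fraction[dom$continent == "ALL"], 0.9)
})

test_that("mismatch distribution partitions pairs by continent and conserves mass", {
  calls <- rbind(rep(0L, 10), rep(0L, 10), rep(2L, 10))
  gt <- make_gt(calls)
  meta <- make_meta(gt)
  meta$continent <- c("EURASIA", "EURASIA", "NORTH_AMERICA")
  md <- mismatch_distribution(gt, meta)
  strata <- table(md$pairs$stratum)
  expect_equal(unname(strata[["EURASIA"]]), 1)
  expect_equal(unname(strata[["INTERCONTINENTAL"]]), 2)
  # identical plants pair at fraction 0
  expect_equal(md$pairs$fraction[md$pairs$stratum == "EURASIA"], 0)
  # histogram mass conservation: per-stratum masses sum to defined pairs
  expect_equal(sum(vapply(md$histograms[c("EURASIA", "INTERCONTINENTAL")],
                          function(h) h$n_pairs, numeric(1))),
               choose(3, 2) - md$n_undefined)

  # undefined pairs are excluded and counted
  calls2 <- rbind(c(0L, NA), c(NA, 0L), c(0L, 0L))
  md2 <- mismatch_distribution(make_gt(calls2))
  expect_equal(md2$n_undefined, 1)
  expect_equal(md2$histograms$ALL$n_pairs, 2)
})

test_that("panmixia resampling reproduces donor-pool expectations", {
  # degenerate donor pool: all identical -> all simulated pairs identical
  gt <- make_gt(matrix(rep(c(0L, 2L), each = 5), 5, 2))
  pan <- simulate_panmixia(gt, n_sim = 30, seed = 1)
  expect_true(all(pan$fractions == 0))

  # two equally frequent opposite homozygote haplotypes: mean fraction ~ 0.5
  calls <- rbind(matrix(0L, 10, 40), matrix(2L, 10, 40))
  gt <- make_gt(calls)
  pan <- simulate_panmixia(gt, n_sim = 300, seed = 2)
  expect_equal(expected_panmixia_mismatch(gt), 0.5)
  expect_lt(abs(pan$mean_fraction - 0.5), 0.01)

  # same seed twice is bit-identical
  pan2 <- simulate_panmixia(gt, n_sim = 300, seed = 2)
  expect_identical(pan$sim_calls, pan2$sim_calls)
  expect_identical(pan$fractions, pan2$fractions)
})

test_that("analytic expectation matches simulation within Monte-Carlo error", {
  pan <- generate_panel(139, 0.25, 0.30, seed = 111)
  gt <- generate_equilibrium_site(60, pan$freqs, 1, seed = 112)
  expect_val <- expected_panmixia_mismatch(gt)
  means <- vapply(1:5, function(s) {
    simulate_panmixia(gt, n_sim = 200, seed = 200 + s)$mean_fraction
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expect_val), 3 * se)
})

test_that("unique_only reweights donors and is a no-op for all-singleton pools", {
  cl <- make_clone_gt(3, 10, L = 60, per_copy_error = 0, missing_rate = 0,
                      seed = 113)
  asn <- qt_cluster(cl$gt)
  expect_length(asn$extraction_order, 3)
  full <- simulate_panmixia(cl$gt, n_sim = 150, seed = 3)
  uniq <- simulate_panmixia(cl$gt, n_sim = 150, unique_only = TRUE,
                            assignment = asn, seed = 3)
  expect_equal(uniq$n_donors, 3)
  expect_equal(full$n_donors, 30)

  # all singletons: the two donor pools hold the same haplotypes
  singles <- make_clone_gt(6, 1, L = 139, per_copy_error = 0,
                           missing_rate = 0, seed = 114)
  asn1 <- qt_cluster(singles$gt)
  a <- simulate_panmixia(singles$gt, n_sim = 100, seed = 4)
  b <- simulate_panmixia(singles$gt, n_sim = 100, unique_only = TRUE,
                         assignment = asn1, seed = 4)
  expect_identical(sort(unname(asn1$central_of)), sort(sample_ids(singles$gt)))
  expect_identical(dim(a$sim_calls), dim(b$sim_calls))
})

test_that("pair classification splits identical / intermediate / unrelated", {
  # all plants identical -> everything classified identical
  gt <- make_gt(matrix(0L, 4, 20))
  md <- mismatch_distribution(gt)
  cls <- classify_pairs(md$pairs, sim_fractions = runif(200, 0.3, 0.5))
  expect_equal(unname(cls$fractions["identical"]), 1)
  expect_equal(sum(cls$fractions), 1)

  # panmictic data: identical and intermediate fractions both near zero
  pan <- generate_panel(139, 0.25, 0.30, seed = 121)
  gt <- generate_equilibrium_site(80, pan$freqs, 1, seed = 122)
  md <- mismatch_distribution(gt)
  sim <- simulate_panmixia(gt, n_sim = 300, seed = 123)
  cls <- classify_pairs(md$pairs, sim$fractions)
  expect_lt(cls$fractions[["identical"]] + cls$fractions[["intermediate"]], 0.05)
  expect_equal(sum(cls$fractions), 1)
})
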