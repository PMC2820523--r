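test_that("binomial identity tail probability matches closed forms", {
  # k = 0: the tail is everything
  expect_equal(identity_tail_probability(0, 10, 0.005), 1)
  expect_equal(identity_tail_probability(0, 139, 0.2), 1)
  # single Bernoulli
  expect_equal(identity_tail_probability(1, 1, 0.005), 0.005)
  # closed-form sum: P(X>=2), X ~ Bin(10, 0.1)
  q <- 1 - 0.9^10 - 10 * 0.1 * 0.9^9
  expect_equal(identity_tail_probability(2, 10, 0.1), q, tolerance = 1e-12)
  expect_equal(round(identity_tail_probability(2, 10, 0.1), 4), 0.2639)
  expect_error(identity_tail_probability(1, 0, 0.005), "n must be")
  expect_error(identity_tail_probability(5, 3, 0.005), "k must be")
})

test_that("pair distance transforms the tail and flags incomparable pairs", {
  p <- cluster_params()
  # identical informative vectors: distance 0 under both transforms
  h <- c(0L, 2L, 0L)
  expect_equal(pair_distance(h, h, p), 0)
  p1 <- cluster_params(distance_transform = "one_minus_tail")
  expect_equal(pair_distance(h, h, p1), 0)
  # k=1, n=139 at epsilon 0.005: q = 1 - 0.995^139, d = -log10(q)
  h1 <- rep(0L, 139)
  h2 <- c(2L, rep(0L, 138))
  q <- 1 - 0.995^139
  expect_equal(pair_distance(h1, h2, p), -log10(q), tolerance = 1e-10)
  expect_equal(round(pair_distance(h1, h2, p), 4), 0.2995)
  # no shared informative markers: infinite distance
  expect_equal(pair_distance(c(NA_integer_, 0L), c(0L, NA_integer_), p), Inf)
  # monotone non-decreasing in k at fixed n
  d <- vapply(0:20, function(k) {
    a <- rep(0L, 139); a[seq_len(k)] <- 2L
    pair_distance(rep(0L, 139), a, p)
  }, numeric(1))
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0))
})

test_that("grow_cluster walks the size-adaptive threshold rule", {
  p <- cluster_params(alpha = 0.05)
  # all candidates at distance zero join under any rule
  expect_length(grow_cluster(rep(0, 7), p), 7)
  expect_length(grow_cluster(rep(0, 7), cluster_params(threshold_rule = "size_bonferroni")), 7)
  # (0, 0, 0.4): after two inclusions m = 3, tau = 0.15 < 0.4 -> stop at 2
  expect_equal(grow_cluster(c(0, 0, 0.4), p), c(1L, 2L))
  # single candidate at 0.04 < tau(1) = 0.05 -> included
  expect_equal(grow_cluster(0.04, p), 1L)
  # ... and at 0.05 (not strictly less) -> excluded
  expect_equal(grow_cluster(0.05, p), integer(0))
  # ties broken by ascending input index
  expect_equal(grow_cluster(c(0.01, 0.01, 0.01), p)[1], 1L)
})

test_that("trivial partitions: all-identical and all-distant inputs", {
  # N identical haplotypes -> one group of N
  gt <- make_gt(matrix(rep(c(0L, 2L, 0L, 2L), each = 6), 6, 4))
  asn <- qt_cluster(gt)
  expect_length(asn$extraction_order, 1)
  expect_equal(unname(asn$sizes), 6L)

  # haplotypes differing at >= 30% of 139 markers -> all singletons
  cl <- make_clone_gt(5, 1, L = 139, min_div = 0.3, per_copy_error = 0,
                      missing_rate = 0, seed = 13)
  asn <- qt_cluster(cl$gt)
  expect_length(asn$extraction_order, 5)
  expect_true(all(asn$sizes == 1L))
})

test_that("qt_cluster equals the exhaustive oracle on small fixtures", {
  p <- cluster_params()
  # the 12-haplotype fixture: 10 copies of A (7 exact, 3 with one
  # genotyping error each) and 2 copies of B at 40 mismatches; the exact
  # copies let the cluster reach the size at which tau admits a 1-error
  # copy (d = 0.2995 < 0.05 m once m >= 6)
  set.seed(17)
  A <- sample(c(0L, 2L), 139, replace = TRUE)
  B <- A
  jb <- sample(139, 40)
  B[jb] <- 2L - B[jb]
  calls <- rbind(matrix(A, 10, 139, byrow = TRUE), B, B)
  for (i in 8:10) { j <- sample(139, 1); calls[i, j] <- 2L - calls[i, j] }
  gt <- make_gt(calls)
  asn <- qt_cluster(gt, p)
  expect_equal(sort(unname(asn$sizes), decreasing = TRUE), c(10L, 2L))
  expect_identical(assignment_groups(asn), naive_qt_cluster(gt, p))

  # randomized fixtures across parameter space, N <= 12
  for (s in 1:12) {
    set.seed(s)
    N <- sample(4:12, 1)
    base <- sample(c(0L, 2L), 30, replace = TRUE)
    calls <- matrix(base, N, 30, byrow = TRUE)
    nflip <- sample(0:6, N, replace = TRUE)
    for (i in seq_len(N)) {
      if (nflip[i] > 0) {
        j <- sample(30, nflip[i])
        calls[i, j] <- 2L - calls[i, j]
      }
    }
    calls[matrix(runif(N * 30) < 0.05, N, 30)] <- NA_integer_
    gt <- make_gt(calls)
    for (pp in list(cluster_params(),
                    cluster_params(alpha = 0.2),
                    cluster_params(epsilon = 0.02, threshold_rule = "fixed"))) {
      expect_identical(assignment_groups(qt_cluster(gt, pp)),
                       naive_qt_cluster(gt, pp))
    }
  }
})

test_that("assignments partition the input with non-increasing sizes", {
  cl <- make_clone_gt(3, 8, L = 80, per_copy_error = 0.05, seed = 23)
  asn <- qt_cluster(cl$gt)
  ids <- sample_ids(cl$gt)
  # total and single-valued
  expect_setequal(names(asn$group_of), ids)
  expect_true(all(asn$group_of %in% asn$extraction_order))
  # central haplotype is a member of its own group
  for (hg in asn$extraction_order) {
    expect_equal(unname(asn$group_of[asn$central_of[[hg]]]), hg)
  }
  # sizes non-increasing along extraction order
  expect_true(all(diff(unname(asn$sizes[asn$extraction_order])) <= 0))
  # spectrum mass equals sample count
  spec <- haplogroup_size_spectrum(asn)
  expect_equal(sum(spec$size * spec$n_groups), length(ids))
})

test_that("clustering is invariant to sample order on unambiguous structure", {
  cl <- make_clone_gt(3, 6, L = 100, per_copy_error = 0, missing_rate = 0.01,
                      seed = 29)
  asn1 <- qt_cluster(cl$gt)
  set.seed(1)
  perm <- sample(nrow(cl$gt$calls))
  gt2 <- subset_genotypes(cl$gt, samples = perm)
  asn2 <- qt_cluster(gt2)
  part1 <- lapply(assignment_groups(asn1), sort)
  part2 <- lapply(assignment_groups(asn2), sort)
  expect_setequal(part1, part2)
})

test_that("founder partitions are recovered from clone data with rare errors", {
  for (s in 1:3) {
    cl <- make_clone_gt(4, 20, per_copy_error = 0.01, seed = 40 + s)
    asn <- qt_cluster(cl$gt)
    labels <- as.integer(factor(asn$group_of[sample_ids(cl$gt)]))
    expect_equal(rand_index(cl$truth, labels), 1.0)
  }
})

test_that("assignment_table reports centers and distances consistently", {
  cl <- make_clone_gt(2, 4, L = 50, per_copy_error = 0, missing_rate = 0,
                      seed = 51)
  asn <- qt_cluster(cl$gt)
  tab <- assignment_table(asn, cl$gt)
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$is_central), 2)
  expect_true(all(tab$distance_to_central == 0))
})
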