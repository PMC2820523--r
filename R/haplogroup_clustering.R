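# Modified QT clustering of multilocus SNP haplotypes into haplogroups.
#
# Two haplotypes are "potentially identical" when their observed mismatches
# are compatible with genotyping error alone. The distance between two
# haplotypes is derived from the binomial tail probability of seeing at
# least the observed number of mismatches among the markers informative in
# both, given a per-marker discrepancy rate epsilon. Clusters are grown
# around candidate centers with a cluster-size-adaptive inclusion
# threshold; at each round the largest formable cluster is extracted.
#
# The raw tail probability is bounded by 1, which would make a threshold of
# "alpha times the cluster size" vacuous once a cluster reaches 1/alpha
# members; the default distance is therefore -log10 of the tail, which is
# unbounded and grows smoothly with the mismatch count, so large clonal
# groups tolerate a few genotyping errors while unrelated haplotypes never
# merge. The bounded transform and alternative threshold rules are kept as
# configuration for sensitivity analysis.

#' Clustering parameters
#'
#' @param epsilon Per-marker discrepancy probability under the hypothesis
#'   that two haplotypes are identical (genotyping error; default 0.005).
#' @param alpha Threshold multiplier: a candidate at distance d joins a
#'   cluster of current size m iff `d < tau(m)` (default 0.05).
#' @param threshold_rule `tau(m)`: `"size_multiplicative"` (`alpha * m`,
#'   default), `"size_bonferroni"` (`alpha / m`) or `"fixed"` (`alpha`).
#' @param distance_transform `"neg_log10_tail"` (default) or
#'   `"one_minus_tail"`.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(epsilon = 0.005, alpha = 0.05,
                           threshold_rule = c("size_multiplicative",
                                              "size_bonferroni", "fixed"),
                           distance_transform = c("neg_log10_tail",
                                                  "one_minus_tail")) {
  stopifnot(epsilon > 0, epsilon < 1, alpha > 0)
  structure(list(
    epsilon = epsilon, alpha = alpha,
    threshold_rule = match.arg(threshold_rule),
    distance_transform = match.arg(distance_transform)
  ), class = "cluster_params")
}

#' Binomial tail probability of observed mismatches under identity
#'
#' The probability of seeing `k` or more mismatches among `n` compared
#' markers if the two haplotypes are truly identical and each marker
#' independently disagrees with probability `epsilon`:
#' `P(X >= k)` for `X ~ Binomial(n, epsilon)`, evaluated via the survival
#' function for numerical stability.
#'
#' @param k Number of mismatching markers (0..n).
#' @param n Number of markers informative in both haplotypes (>= 1).
#' @param epsilon Per-marker discrepancy probability.
#' @return The upper-tail probability, vectorized over `k`/`n`.
#' @export
identity_tail_probability <- function(k, n, epsilon = 0.005) {
  if (any(n < 1)) stop("n must be >= 1 (no informative markers)")
  if (any(k < 0 | k > n)) stop("k must be in [0, n]")
  stats::pbinom(k - 1, n, epsilon, lower.tail = FALSE)
}

#' Binomial mismatch-probability distance between two haplotypes
#'
#' Computes (k, n) with [pairwise_mismatch()] (heterozygous calls treated
#' as missing) and transforms the identity tail probability `q` into a
#' distance: `-log10(q)` under the default transform, or `1 - q`. Pairs
#' with no marker informative in both (`n = 0`) get distance `Inf` and can
#' never be co-clustered.
#'
#' @param h1,h2 Integer call vectors.
#' @param params A [cluster_params()].
#' @return A non-negative distance (possibly `Inf`).
#' @export
pair_distance <- function(h1, h2, params = cluster_params()) {
  mm <- pairwise_mismatch(h1, h2, het_as_missing = TRUE)
  if (mm$n == 0) return(Inf)
  transform_tail(mm$k, mm$n, params)
}

# distance from (k, n); vectorized; n = 0 -> Inf
transform_tail <- function(k, n, params) {
  d <- rep(Inf, length(k))
  ok <- n > 0
  if (params$distance_transform == "neg_log10_tail") {
    lq <- stats::pbinom(k[ok] - 1, n[ok], params$epsilon,
                        lower.tail = FALSE, log.p = TRUE)
    d[ok] <- -lq / log(10)
  } else {
    d[ok] <- stats::pbinom(k[ok] - 1, n[ok], params$epsilon)
  }
  d
}

# inclusion thresholds tau(m) for m = 1..n_cand (m = size before each test)
threshold_seq <- function(n_cand, params) {
  m <- seq_len(n_cand)
  switch(params$threshold_rule,
    size_multiplicative = params$alpha * m,
    size_bonferroni = params$alpha / m,
    fixed = rep(params$alpha, n_cand)
  )
}

#' Grow one cluster around a center
#'
#' Candidates are proposed in order of ascending distance to the center
#' (ties broken by ascending candidate position) and included while
#' `d < tau(m)`, where `m` is the current cluster size (the center counts,
#' so the first test is against `tau(1)`); the walk stops at the first
#' failure.
#'
#' @param distances Numeric vector of candidate distances to the center.
#' @param params A [cluster_params()].
#' @return Integer indices (into `distances`) of the included candidates,
#'   in inclusion order.
#' @export
grow_cluster <- function(distances, params = cluster_params()) {
  if (length(distances) == 0) return(integer(0))
  ord <- order(distances, seq_along(distances))
  d <- distances[ord]
  ok <- d < threshold_seq(length(d), params)
  fail <- which(!ok)
  n_in <- if (length(fail)) fail[1] - 1L else length(d)
  ord[seq_len(n_in)]
}

#' Assign every sample to a haplogroup by modified QT clustering
#'
#' At each round every remaining sample is tried as a center with
#' [grow_cluster()]; the center forming the largest cluster wins (ties:
#' smallest sum of member distances to the center, then lowest input
#' index). The winning cluster is recorded as the next haplogroup and
#' removed, and the search repeats until every sample is placed. Samples
#' with identical observed call vectors are collapsed to a single
#' representative during the center search (a pure optimization; the
#' result equals the naive algorithm), and a round in which the best
#' cluster is a singleton finishes the partition in one pass since every
#' later round could also only produce singletons.
#'
#' @param gt A `genotype_table`.
#' @param params A [cluster_params()].
#' @return An object of class `haplogroup_assignment`: a list with
#'   `group_of` (named character vector, sample id -> haplogroup id),
#'   `central_of` (named character vector, haplogroup id -> central sample
#'   id), `extraction_order` (haplogroup ids in definition order) and
#'   `sizes` (named integer vector).
#' @export
qt_cluster <- function(gt, params = cluster_params()) {
  ids <- sample_ids(gt)
  N <- length(ids)
  if (N == 0) stop("genotype table has no samples")
  mm <- mismatch_matrices(gt$calls, het_as_missing = TRUE)
  dmat <- matrix(transform_tail(as.vector(mm$k), as.vector(mm$n), params), N, N)
  diag(dmat) <- 0

  # duplicate haplotypes: identical observed rows share a representative
  key <- apply(gt$calls, 1, paste, collapse = ",")
  rep_idx <- match(key, key)  # lowest input index with the same row

  # per-row candidate order (ascending distance, ties by input index),
  # computed once and filtered to the remaining set each round
  pre_ord <- lapply(seq_len(N), function(i) {
    o <- order(dmat[i, ], seq_len(N))
    o[o != i]
  })

  remaining <- rep(TRUE, N)
  group_of <- character(N)
  names(group_of) <- ids
  central <- character(0)
  extraction <- character(0)
  sizes <- integer(0)
  g <- 0L

  while (any(remaining)) {
    rem <- which(remaining)
    # one center per duplicate class: the lowest remaining index of each
    # class (identical rows give identical clusters, and the lowest index
    # is the one the naive tie-break would pick)
    centers <- rem[!duplicated(rep_idx[rem])]
    best_size <- -1L
    best_sum <- Inf
    best_center <- NA_integer_
    best_members <- integer(0)
    for (i in centers) {
      cand <- pre_ord[[i]]
      cand <- cand[remaining[cand]]
      d <- dmat[i, cand]
      ok <- d < threshold_seq(length(d), params)
      fail <- which(!ok)
      n_in <- if (length(fail)) fail[1] - 1L else length(d)
      size <- n_in + 1L
      if (size > best_size) {
        best_size <- size
        best_sum <- sum(d[seq_len(n_in)])
        best_center <- i
        best_members <- cand[seq_len(n_in)]
      } else if (size == best_size) {
        s <- sum(d[seq_len(n_in)])
        if (s < best_sum || (s == best_sum && i < best_center)) {
          best_sum <- s
          best_center <- i
          best_members <- cand[seq_len(n_in)]
        }
      }
    }
    if (best_size == 1L) {
      # no pair can co-cluster any more: all remaining are singletons,
      # emitted in input order (the tie-break order of the naive search)
      for (i in rem) {
        g <- g + 1L
        hg <- sprintf("HG%04d", g)
        group_of[i] <- hg
        central[hg] <- ids[i]
        extraction <- c(extraction, hg)
        sizes[hg] <- 1L
      }
      remaining[] <- FALSE
    } else {
      g <- g + 1L
      hg <- sprintf("HG%04d", g)
      members <- c(best_center, best_members)
      group_of[members] <- hg
      central[hg] <- ids[best_center]
      extraction <- c(extraction, hg)
      sizes[hg] <- length(members)
      remaining[members] <- FALSE
    }
  }
  structure(list(group_of = group_of, central_of = central,
                 extraction_order = extraction, sizes = sizes),
            class = "haplogroup_assignment")
}

#' @export
print.haplogroup_assignment <- function(x, ...) {
  cat(sprintf("haplogroup_assignment: %d samples in %d haplogroups (largest %d)\n",
              length(x$group_of), length(x$extraction_order), max(x$sizes)))
  invisible(x)
}

#' Haplogroup size spectrum
#'
#' @param assignment A [qt_cluster()] result.
#' @return A data frame with columns `size` and `n_groups` (descending
#'   size); `sum(size * n_groups)` equals the number of samples.
#' @export
haplogroup_size_spectrum <- function(assignment) {
  tab <- table(assignment$sizes)
  out <- data.frame(size = as.integer(names(tab)), n_groups = as.integer(tab))
  out[order(-out$size), , drop = FALSE]
}

#' Export a haplogroup assignment as a data frame
#'
#' One row per sample: `sample_id`, `haplogroup`, `is_central` and
#' `distance_to_central` under the given parameters.
#'
#' @param assignment A [qt_cluster()] result.
#' @param gt The genotype table that was clustered.
#' @param params The [cluster_params()] used.
#' @return A data frame in input-sample order.
#' @export
assignment_table <- function(assignment, gt, params = cluster_params()) {
  ids <- sample_ids(gt)
  hg <- assignment$group_of[ids]
  cen <- assignment$central_of[hg]
  d <- vapply(seq_along(ids), function(i) {
    pair_distance(gt$calls[ids[i], ], gt$calls[cen[i], ], params)
  }, numeric(1))
  data.frame(sample_id = ids, haplogroup = unname(hg),
             is_central = ids == unname(cen),
             distance_to_central = d, stringsAsFactors = FALSE)
}
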