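# Shared fixtures and independent oracles for the test suite.

# genotype_table from a plain matrix, generating sample ids as needed
make_gt <- function(mat, ids = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(nrow(mat)))
  rownames(mat) <- ids
  genotype_table(mat)
}

# minimal metadata table around a genotype table
make_meta <- function(gt, site_id = "siteA", latitude = 48, longitude = 2,
                      continent = "EURASIA", tissue = "FIELD_SEED_GROWN") {
  n <- nrow(gt$calls)
  validate_sample_meta(data.frame(
    sample_id = sample_ids(gt),
    latitude = rep_len(latitude, n), longitude = rep_len(longitude, n),
    site_id = rep_len(site_id, n), continent = rep_len(continent, n),
    tissue_source = rep_len(tissue, n), stringsAsFactors = FALSE
  ))
}

# write one small genotype fixture as equivalent TSV and VCF encodings:
# samples s1..s3, biallelic markers m1,m2 (plus a triallelic VCF record
# that readers must drop)
write_fixture_tsv <- function(path) {
  writeLines(c(
    "sample_id\tm1\tm2",
    "s1\t0\t0",
    "s2\t1\t2",
    "s3\t2\tNA"
  ), path)
  path
}

write_fixture_vcf <- function(path, include_triallelic = TRUE) {
  rows <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "m1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "m2", "G", "C", ".", "PASS", ".", "GT",
          "0/0", "1/1", "./.", sep = "\t")
  )
  if (include_triallelic) {
    rows <- c(rows, paste("1", "300", "m3", "A", "C,T", ".", "PASS", ".",
                          "GT", "0/0", "1/1", "1/1", sep = "\t"))
  }
  writeLines(rows, path)
  path
}

# Exhaustive QT clustering oracle: literally re-evaluates every remaining
# sample as a center each round using the exported per-pair primitives,
# with no deduplication or shortcut. Returns groups as a list of member-id
# vectors in extraction order.
naive_qt_cluster <- function(gt, params = cluster_params()) {
  ids <- sample_ids(gt)
  N <- length(ids)
  d <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j) d[i, j] <- pair_distance(gt$calls[i, ], gt$calls[j, ], params)
    }
  }
  tau <- function(m) switch(params$threshold_rule,
    size_multiplicative = params$alpha * m,
    size_bonferroni = params$alpha / m,
    fixed = params$alpha)
  remaining <- seq_len(N)
  groups <- list()
  while (length(remaining) > 0) {
    best <- NULL
    for (ci in remaining) {
      cand <- setdiff(remaining, ci)
      ord <- cand[order(d[ci, cand], cand)]
      members <- ci
      sumd <- 0
      m <- 1L
      for (x in ord) {
        if (d[ci, x] < tau(m)) {
          members <- c(members, x)
          sumd <- sumd + d[ci, x]
          m <- m + 1L
        } else break
      }
      if (is.null(best) ||
          length(members) > length(best$members) ||
          (length(members) == length(best$members) &&
           (sumd < best$sumd ||
            (sumd == best$sumd && ci < best$center)))) {
        best <- list(center = ci, members = members, sumd = sumd)
      }
    }
    groups[[length(groups) + 1]] <- ids[best$members]
    remaining <- setdiff(remaining, best$members)
  }
  groups
}

# qt_cluster output in the oracle's shape: member ids per group, in
# extraction order, center first
assignment_groups <- function(assignment) {
  lapply(assignment$extraction_order, function(hg) {
    members <- names(assignment$group_of)[assignment$group_of == hg]
    cen <- assignment$central_of[[hg]]
    c(cen, setdiff(members, cen))
  })
}

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    same_a <- a[i] == a[(i + 1):n]
    same_b <- b[i] == b[(i + 1):n]
    agree <- agree + sum(same_a == same_b)
  }
  agree / choose(n, 2)
}

# clone fixture: n_founders fully homozygous founders with pairwise
# divergence >= min_div, each copied `copies` times; with probability
# per_copy_error a copy carries one flipped marker
make_clone_gt <- function(n_founders, copies, L = 139, min_div = 0.3,
                          per_copy_error = 0.01, missing_rate = 0.02,
                          seed = 1) {
  set.seed(seed)
  repeat {
    founders <- matrix(sample(c(0L, 2L), n_founders * L, replace = TRUE,
                              prob = c(0.72, 0.28)), n_founders, L)
    div <- as.matrix(stats::dist(founders, method = "manhattan")) / 2 / L
    if (n_founders == 1 || min(div[upper.tri(div)]) >= min_div) break
  }
  calls <- founders[rep(seq_len(n_founders), each = copies), , drop = FALSE]
  n <- nrow(calls)
  err <- which(stats::runif(n) < per_copy_error)
  for (i in err) {
    j <- sample.int(L, 1)
    calls[i, j] <- 2L - calls[i, j]
  }
  miss <- matrix(stats::runif(n * L) < missing_rate, n, L)
  calls[miss] <- NA_integer_
  rownames(calls) <- sprintf("c%03d", seq_len(n))
  list(gt = genotype_table(calls),
       truth = rep(seq_len(n_founders), each = copies))
}
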