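# End-to-end orchestration: simulate or ingest, QC, cluster, blacklist,
# re-cluster, selfing, diversity, IBD and F_ST, from a single config, with
# a run manifest and deterministic per-stage seeds.

#' Default run configuration
#'
#' Returns the full configuration list with every tunable at its default.
#' Entries under `simulate` are passed to [generate_landscape()]; setting
#' `input$genotypes` / `input$meta` instead runs on files on disk. Unknown
#' keys in a user config are rejected by [run_pipeline()].
#'
#' @param out_dir Output directory for stage TSV/YAML files (NULL = don't
#'   write files, return results in memory only).
#' @return A nested list of parameters.
#' @export
default_config <- function(out_dir = NULL) {
  list(
    seed = 1L,
    out_dir = out_dir,
    input = list(genotypes = NULL, meta = NULL, format = "tsv"),
    simulate = list(scenario = "eurasia", n_sites = 50, plants_per_site = 20,
                    n_markers = 139, maf_low = 0.25, maf_high = 0.30,
                    extent_km = 3000, frequency_gradient_scale_km = 800,
                    gradient_sd = 1, n_founder_clones = 5, clone_fraction = 0.9,
                    inbreeding_f = 0.95, error_rate = 0.005, missing_rate = 0.02),
    qc = list(max_sample_missing = 50 / 149, max_marker_missing = 0.25,
              max_marker_het = 0.25),
    cluster = list(epsilon = 0.005, alpha = 0.05,
                   threshold_rule = "size_multiplicative",
                   distance_transform = "neg_log10_tail"),
    blacklist = character(0),
    selfing = list(min_haplogroups = 2, n_boot = 200, ci_level = 0.95),
    diversity = list(dominance_threshold = 0.8, n_sim = 10000,
                     unrelated_quantile = 0.01, max_pairs = 1e5),
    ibd = list(bin_widths_km = c(150, 10, 0.5), min_pairs = 5),
    fst = list(min_plants_per_site = 4, window = 50)
  )
}

# deep-merge user config into defaults; unknown keys are an error
merge_config <- function(user, base, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, "$", k)
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(user[[k]], base[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

# stable per-stage seed below 2^31, derived from the master seed and the
# stage name so adding a stage does not shift the others' randomness
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(NULL)
  path <- file.path(out_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest or simulate, sample/marker QC, haplogroup
#' clustering, blacklist haplogroup removal followed by re-clustering
#' (the blacklist is defined on haplogroups, so clustering must come
#' first), selfing estimation over eligible sites (aggregated both
#' plant-weighted and site-weighted), site diversity and dominance,
#' mismatch distribution with panmixia simulation and pair
#' classification, binned IBD with curve fits at each configured scale,
#' and pairwise F_ST with the log-distance regression. Geography-dependent
#' stages are skipped (with a manifest entry) when coordinates are absent.
#' Identical config + seed reproduces every output byte-for-byte.
#'
#' @param config A (partial) configuration list merged over
#'   [default_config()], or a path to a YAML file with the same structure.
#' @return A list of class `selfscape_run` with `config`, `manifest`
#'   (per-stage wall times, counts and output files) and `results`
#'   (per-stage R objects).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_config())
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("selfscape")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = list()
  )
  results <- list()
  add_stage <- function(name, t0, counts = list(), files = character(0),
                        skipped = FALSE, reason = NULL) {
    entry <- list(stage = name,
                  wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
                  counts = counts, skipped = skipped)
    if (!is.null(reason)) entry$reason <- reason
    files <- files[!vapply(files, is.null, logical(1))]
    if (length(files)) {
      entry$outputs <- as.list(tools::md5sum(unlist(files)))
    }
    manifest$stages[[name]] <<- entry
  }

  # --- ingest / simulate ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(cfg$input$genotypes)) {
    gt <- read_genotypes(cfg$input$genotypes, cfg$input$format)
    meta <- if (!is.null(cfg$input$meta)) read_sample_meta(cfg$input$meta)
    truth <- NULL
  } else {
    sim <- do.call(generate_landscape,
                   c(cfg$simulate, list(seed = stage_seed(cfg$seed, "simulate"))))
    gt <- sim$genotypes
    meta <- sim$meta
    truth <- sim$truth
  }
  f_gt <- write_stage_tsv(
    data.frame(sample_id = sample_ids(gt), gt$calls, check.names = FALSE),
    cfg$out_dir, "genotypes_raw.tsv")
  f_meta <- if (!is.null(meta)) write_stage_tsv(meta, cfg$out_dir, "meta.tsv")
  add_stage("ingest", t0,
            counts = list(n_samples = nrow(gt$calls), n_markers = ncol(gt$calls)),
            files = list(f_gt, f_meta))
  results$truth <- truth

  # --- QC ------------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fs <- filter_samples_by_missingness(gt, cfg$qc$max_sample_missing)
  fm <- filter_markers(fs$genotypes, cfg$qc$max_marker_missing, cfg$qc$max_marker_het)
  gt <- fm$genotypes
  if (!is.null(meta)) meta <- meta[meta$sample_id %in% sample_ids(gt), ]
  f1 <- write_stage_tsv(fs$removed, cfg$out_dir, "removed_samples.tsv")
  f2 <- write_stage_tsv(fm$removed, cfg$out_dir, "removed_markers.tsv")
  add_stage("qc", t0,
            counts = list(samples_removed = nrow(fs$removed),
                          markers_removed = nrow(fm$removed),
                          n_samples = nrow(gt$calls), n_markers = ncol(gt$calls)),
            files = list(f1, f2))
  results$qc <- list(removed_samples = fs$removed, removed_markers = fm$removed)

  # --- clustering (+ blacklist + re-clustering) ----------------------------
  t0 <- as.numeric(Sys.time())
  params <- cluster_params(cfg$cluster$epsilon, cfg$cluster$alpha,
                           cfg$cluster$threshold_rule,
                           cfg$cluster$distance_transform)
  assignment <- qt_cluster(gt, params)
  n_bl <- 0L
  if (length(cfg$blacklist) > 0) {
    bl <- remove_blacklisted_haplogroups(gt, assignment, cfg$blacklist)
    n_bl <- nrow(bl$removed)
    if (n_bl > 0) {
      gt <- bl$genotypes
      if (!is.null(meta)) meta <- meta[meta$sample_id %in% sample_ids(gt), ]
      assignment <- qt_cluster(gt, params)
    }
    write_stage_tsv(bl$removed, cfg$out_dir, "removed_blacklist.tsv")
  }
  atab <- assignment_table(assignment, gt, params)
  f3 <- write_stage_tsv(atab, cfg$out_dir, "haplogroups.tsv")
  add_stage("cluster", t0,
            counts = list(n_haplogroups = length(assignment$extraction_order),
                          largest = max(assignment$sizes),
                          blacklist_removed = n_bl),
            files = list(f3))
  results$assignment <- assignment
  results$size_spectrum <- haplogroup_size_spectrum(assignment)
  results$genotypes <- gt
  results$meta <- meta

  # --- selfing -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(meta)) {
    sites <- eligible_sites(meta, assignment, cfg$selfing$min_haplogroups)
    selfing <- selfing_by_site(gt, meta, sites = sites,
                               n_boot = cfg$selfing$n_boot,
                               ci_level = cfg$selfing$ci_level,
                               seed = stage_seed(cfg$seed, "selfing"))
    ok <- !is.na(selfing$selfing)
    plant_weighted <- if (any(ok))
      sum(selfing$selfing[ok] * selfing$n_plants[ok]) / sum(selfing$n_plants[ok])
      else NA_real_
    site_weighted <- if (any(ok)) mean(selfing$selfing[ok]) else NA_real_
    f4 <- write_stage_tsv(selfing, cfg$out_dir, "selfing_by_site.tsv")
    add_stage("selfing", t0,
              counts = list(n_sites_eligible = length(sites),
                            n_sites_estimated = sum(ok),
                            selfing_plant_weighted = round(plant_weighted, 6),
                            selfing_site_weighted = round(site_weighted, 6)),
              files = list(f4))
    results$selfing <- list(by_site = selfing,
                            plant_weighted = plant_weighted,
                            site_weighted = site_weighted)
  } else {
    add_stage("selfing", t0, skipped = TRUE, reason = "no metadata")
  }

  # --- diversity + panmixia ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(meta)) {
    sdiv <- diversity_by_site(meta, assignment)
    dom <- dominance_summary(sdiv, cfg$diversity$dominance_threshold)
    f5 <- write_stage_tsv(sdiv, cfg$out_dir, "site_diversity.tsv")
    f6 <- write_stage_tsv(dom, cfg$out_dir, "dominance.tsv")
  } else {
    sdiv <- NULL; dom <- NULL; f5 <- NULL; f6 <- NULL
  }
  md <- mismatch_distribution(gt, meta)
  pan <- simulate_panmixia(gt, n_sim = cfg$diversity$n_sim,
                           seed = stage_seed(cfg$seed, "panmixia"),
                           max_pairs = cfg$diversity$max_pairs)
  cls <- classify_pairs(md$pairs, pan$fractions,
                        cfg$diversity$unrelated_quantile)
  add_stage("diversity", t0,
            counts = list(n_pairs = nrow(md$pairs),
                          n_undefined_pairs = md$n_undefined,
                          frac_identical = round(cls$fractions[["identical"]], 6),
                          frac_intermediate = round(cls$fractions[["intermediate"]], 6),
                          frac_unrelated = round(cls$fractions[["unrelated"]], 6)),
            files = list(f5, f6))
  results$diversity <- list(by_site = sdiv, dominance = dom,
                            mismatch = md, panmixia = pan,
                            classification = cls)

  # --- IBD + F_ST ----------------------------------------------------------
  has_geo <- !is.null(meta) && !anyNA(meta$latitude) && !anyNA(meta$longitude)
  t0 <- as.numeric(Sys.time())
  if (has_geo) {
    ptab <- ibd_pair_table(gt, meta, assignment)
    ibd <- lapply(cfg$ibd$bin_widths_km, function(w) {
      binned <- bin_pairs(ptab, w)
      fits <- list(
        linear_same = try_fit(function(b, r, mp)
          fit_linear(b, r, min_pairs = mp),
          binned, "p_same_haplogroup", cfg$ibd$min_pairs),
        exp_same = try_fit(function(b, r, mp)
          fit_exp_decay(b, "exp_decay", r, min_pairs = mp),
          binned, "p_same_haplogroup", cfg$ibd$min_pairs),
        sat_mismatch = try_fit(function(b, r, mp)
          fit_exp_decay(b, "exp_saturating", r, min_pairs = mp),
          binned, "q50", cfg$ibd$min_pairs)
      )
      write_stage_tsv(as.data.frame(binned), cfg$out_dir,
                      sprintf("ibd_bins_%gkm.tsv", w))
      list(bin_width_km = w, binned = binned, fits = fits)
    })
    names(ibd) <- sprintf("%gkm", cfg$ibd$bin_widths_km)
    add_stage("ibd", t0, counts = list(n_pairs = nrow(ptab),
                                       n_scales = length(ibd)))
    results$ibd <- ibd

    t0 <- as.numeric(Sys.time())
    fst <- tryCatch({
      ft <- pairwise_site_fst(gt, meta, cfg$fst$min_plants_per_site)
      reg <- fst_distance_regression(ft$pairs, meta, cfg$fst$window)
      f7 <- write_stage_tsv(reg$pairs, cfg$out_dir, "fst_pairs.tsv")
      f8 <- write_stage_tsv(reg$windows, cfg$out_dir, "fst_windows.tsv")
      add_stage("fst", t0,
                counts = list(n_site_pairs = nrow(reg$pairs),
                              slope = round(reg$slope, 6),
                              n_windows = nrow(reg$windows)),
                files = list(f7, f8))
      list(table = ft, regression = reg)
    }, error = function(e) {
      add_stage("fst", t0, skipped = TRUE, reason = conditionMessage(e))
      NULL
    })
    results$fst <- fst
  } else {
    add_stage("ibd", t0, skipped = TRUE, reason = "no geography in metadata")
    add_stage("fst", as.numeric(Sys.time()), skipped = TRUE,
              reason = "no geography in metadata")
  }

  if (!is.null(cfg$out_dir)) {
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  }
  structure(list(config = cfg, manifest = manifest, results = results),
            class = "selfscape_run")
}

try_fit <- function(f, binned, response, min_pairs) {
  tryCatch(f(binned, response, min_pairs), error = function(e) NULL)
}

# md5 of the canonicalized config (written as YAML to a temp file)
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Human-readable run summary
#'
#' @param run A [run_pipeline()] result.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
summarize_run <- function(run) {
  r <- run$results
  lines <- c(
    sprintf("selfscape run (seed %s, config %s)", run$manifest$seed,
            run$manifest$config_hash),
    sprintf("samples: %d, markers: %d after QC", nrow(r$genotypes$calls),
            ncol(r$genotypes$calls)),
    sprintf("haplogroups: %d (largest %d)",
            length(r$assignment$extraction_order), max(r$assignment$sizes)),
    "haplogroup size spectrum (size x n_groups):",
    paste(sprintf("  %dx%d", r$size_spectrum$size, r$size_spectrum$n_groups),
          collapse = "")
  )
  if (!is.null(r$selfing)) {
    q <- stats::quantile(r$selfing$by_site$selfing, c(0.25, 0.5, 0.75),
                         na.rm = TRUE)
    lines <- c(lines,
      sprintf("selfing: plant-weighted %.1f%%, site-weighted %.1f%% (site quartiles %.1f/%.1f/%.1f%%)",
              100 * r$selfing$plant_weighted, 100 * r$selfing$site_weighted,
              100 * q[1], 100 * q[2], 100 * q[3]))
  }
  if (!is.null(r$diversity$dominance)) {
    dd <- r$diversity$dominance
    all_row <- dd[dd$continent == "ALL", ]
    lines <- c(lines,
      sprintf("sites dominated by one haplogroup: %.0f%% of %d",
              100 * all_row$dominated_fraction, all_row$n_sites))
    if (all(is.na(r$diversity$by_site$diversity))) {
      lines <- c(lines, "note: all site diversities undefined (degenerate input)")
    }
  }
  cf <- r$diversity$classification$fractions
  lines <- c(lines,
    sprintf("pair classes: %.1f%% identical, %.1f%% intermediate, %.1f%% unrelated",
            100 * cf[["identical"]], 100 * cf[["intermediate"]],
            100 * cf[["unrelated"]]))
  if (!is.null(r$ibd)) {
    for (nm in names(r$ibd)) {
      fit <- r$ibd[[nm]]$fits$linear_same
      if (!is.null(fit)) {
        lines <- c(lines,
          sprintf("IBD %s bins: p(same haplogroup) slope %.3g per km (n bins %d)",
                  nm, fit$params[["m"]], fit$n_bins))
      }
    }
  }
  if (!is.null(r$fst)) {
    lines <- c(lines, sprintf("F_ST ~ ln(km): slope %.4g over %d site pairs",
                              r$fst$regression$slope, nrow(r$fst$regression$pairs)))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.selfscape_run <- function(x, ...) {
  summarize_run(x)
  invisible(x)
}
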