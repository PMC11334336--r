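#' Pipeline configuration
#'
#' Bundles every tunable of the survey/microcosm analysis. The master seed
#' propagates to each stochastic stage through [child_seed()], so stages are
#' individually reproducible.
#'
#' @param gradient_variable gradient column: `"latitude"` (survey),
#'   `"temperature"` or `"SWC"` (microcosm).
#' @param split_point gradient value splitting low and high groups
#'   (32 degrees N for the survey).
#' @param prevalence_threshold occupancy fraction for [prevalence_filter()].
#' @param n_perm permutations for ANOSIM/Mantel/dbRDA (paper: 999).
#' @param protest_perm permutations for PROTEST (paper: 1000).
#' @param n_null null matrices for NST.
#' @param nmds_starts random NMDS starts.
#' @param window_size moving-window width; `NULL` uses the initial
#'   low-gradient group size.
#' @param rmt_scan threshold grid for [rmt_threshold()].
#' @param positive_only admit only positive correlations as network edges.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gradient_variable = "latitude", split_point = 32,
                            prevalence_threshold = 0.3, n_perm = 999L,
                            protest_perm = 1000L, n_null = 1000L,
                            nmds_starts = 20L, window_size = NULL,
                            rmt_scan = seq(0.30, 0.98, by = 0.01),
                            positive_only = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# One predator arm: filtered tables -> block -> RMT -> meta net -> site metrics.
network_arm <- function(prey_f, pred_f, cfg) {
  blk <- spearman_block(prey_f, pred_f)
  scan <- tryCatch(rmt_threshold(blk, scan = cfg$rmt_scan), error = function(e) {
    if (is.null(e$scan)) stop(e)
    # strongly structured data can reject Poisson everywhere; fall back to
    # the best-fitting evaluable threshold so the pipeline stays auditable
    tab <- e$scan
    if (all(is.na(tab$p_poisson))) stop(e)
    best <- which.max(replace(tab$p_poisson, is.na(tab$p_poisson), -1))
    warning("RMT scan found no Poisson-consistent threshold; ",
            "using best-fitting threshold ", tab$threshold[best])
    structure(list(scan = tab, chosen_threshold = tab$threshold[best]),
              class = "rmt_scan")
  })
  meta <- build_meta_network(blk, scan$chosen_threshold,
                             positive_only = cfg$positive_only)
  list(block = blk, rmt = scan, meta = meta,
       site_metrics = site_subnetworks(meta, prey_f, pred_f))
}

#' Run the full survey analysis
#'
#' Orchestrates rarefaction, prevalence filtering, richness trends, NMDS and
#' ANOSIM by latitude group, distance decay, the two predator-prey network
#' arms (Spearman + RMT threshold + per-site metrics), NST, the
#' moving-window hierarchical partitioning, Procrustes/PROTEST with residual
#' trends, best-subset OLS of bacterial richness, Mantel tests and
#' variation partitioning. A missing virus table skips the V-B stages.
#'
#' @param data list with `metadata`, `bacteria`, `protist` and optionally
#'   `virus` (as from [simulate_survey()], or read from TSV).
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, every stage output is
#'   written as TSV/JSON plus a `manifest.json` of active settings.
#' @return a result bundle (named list of stage outputs).
#' @export
run_survey <- function(data, config = pipeline_config(), outdir = NULL) {
  cfg <- config
  md <- data$metadata
  g <- md[[cfg$gradient_variable]]
  has_virus <- !is.null(data$virus)
  if (!has_virus) message("virus table missing: skipping V-B stages")

  kingdoms <- c("bacteria", "protist", if (has_virus) "virus")
  rare <- list()
  for (k in kingdoms) {
    tab <- harmonize_sites(data[[k]], md)$table
    rare[[k]] <- rarefy(tab, "min", seed = child_seed(cfg$seed,
                                                      paste0("rarefy_", k)))
  }
  shared <- Reduce(intersect, lapply(rare, sample_ids))
  rare <- lapply(rare, subset_asv, samples = shared)
  md <- md[match(shared, md$site_id), ]
  g <- md[[cfg$gradient_variable]]
  filt <- lapply(rare, prevalence_filter, threshold = cfg$prevalence_threshold)

  # alpha diversity trends
  trends <- lapply(rare, function(tab) fit_gradient_trend(richness(tab), g))

  # beta diversity: NMDS, ANOSIM by gradient group, distance decay
  groups <- ifelse(g < cfg$split_point, "low", "high")
  dists <- lapply(filt, community_distance, metric = "bray_curtis",
                  transform = "hellinger")
  ords <- lapply(names(dists), function(k) {
    nmds(dists[[k]], k = 2L, n_starts = cfg$nmds_starts,
         seed = child_seed(cfg$seed, paste0("nmds_", k)))
  })
  names(ords) <- names(dists)
  anosims <- lapply(names(dists), function(k) {
    anosim_test(dists[[k]], groups, n_perm = cfg$n_perm,
                seed = child_seed(cfg$seed, paste0("anosim_", k)))
  })
  names(anosims) <- names(dists)
  ddr <- if (cfg$gradient_variable == "latitude") {
    distance_decay(dists$bacteria, geographic_distance(md), groups)
  }

  # trophic networks
  arms <- list(PB = network_arm(filt$bacteria, filt$protist, cfg))
  if (has_virus) arms$VB <- network_arm(filt$bacteria, filt$virus, cfg)

  # assembly stochasticity and the moving window
  presence <- (rare$bacteria$counts > 0L) * 1L
  nst_all <- nst(presence, null_config(n_null = cfg$n_null,
                                       seed = child_seed(cfg$seed, "nst")))
  pg <- predictor_groups(md, arms$PB$site_metrics,
                         if (has_virus) arms$VB$site_metrics)
  window <- moving_window(presence, dists$bacteria, pg, g,
                          w = cfg$window_size, split = cfg$split_point,
                          nst_config = null_config(
                            n_null = min(cfg$n_null, 100L),
                            seed = child_seed(cfg$seed, "window_nst")))

  # community congruence
  congr <- lapply(names(arms), function(p) {
    pred_k <- if (p == "VB") "virus" else "protist"
    pr <- protest(ords$bacteria$coordinates, ords[[pred_k]]$coordinates,
                  n_perm = cfg$protest_perm,
                  seed = child_seed(cfg$seed, paste0("protest_", p)))
    list(protest = pr, residual_trend = residual_gradient(pr, g))
  })
  names(congr) <- names(arms)

  # drivers of richness and composition
  Xall <- do.call(cbind, pg)
  ols <- ols_best_subset(richness(rare$bacteria), Xall)
  mantels <- lapply(names(arms), function(p) {
    pred_k <- if (p == "VB") "virus" else "protist"
    mantel_test(dists$bacteria, dists[[pred_k]], n_perm = cfg$n_perm,
                seed = child_seed(cfg$seed, paste0("mantel_", p)))
  })
  names(mantels) <- names(arms)
  biotic <- do.call(cbind, pg[intersect(c("PB", "VB"), names(pg))])
  vpa <- variation_partition(dists$bacteria,
                             list(climatic = pg$climatic,
                                  edaphic = pg$edaphic, biotic = biotic))
  dbr <- dbrda(dists$bacteria, vif_prune(Xall)$X, n_perm = cfg$n_perm,
               seed = child_seed(cfg$seed, "dbrda"))

  bundle <- list(config = cfg, metadata = md, rarefied = rare,
                 filtered = filt, richness_trends = trends,
                 ordinations = ords, anosim = anosims, ddr = ddr,
                 networks = arms, nst = nst_all, moving_window = window,
                 congruence = congr, ols = ols, mantel = mantels,
                 vpa = vpa, dbrda = dbr)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Run the microcosm analysis
#'
#' Same stages as the survey on one experimental arm, with the gradient
#' covariate swapped to temperature or soil water content; the moving window
#' is replaced by per-level summaries when the design has five or fewer
#' levels, and trend fits target the manipulated gradient.
#'
#' @param data list as from [simulate_microcosm()].
#' @param config a [pipeline_config()] with `gradient_variable` set to
#'   `"temperature"` or `"SWC"`.
#' @param outdir optional output directory.
#' @return a result bundle.
#' @export
run_microcosm <- function(data, config = pipeline_config(
                            gradient_variable = "temperature",
                            split_point = 15),
                          outdir = NULL) {
  cfg <- config
  if (!cfg$gradient_variable %in% c("temperature", "SWC")) {
    stop("microcosm gradient must be temperature or SWC")
  }
  arm <- if (cfg$gradient_variable == "temperature") "temperature" else
    "moisture"
  keep <- data$metadata$treatment == arm
  md <- data$metadata[keep, ]
  g <- md[[cfg$gradient_variable]]
  if (length(unique(g)) < 3L) stop("fewer than 3 gradient levels")
  sub <- list(metadata = md)
  for (k in intersect(c("bacteria", "protist", "virus"), names(data))) {
    if (!is.null(data[[k]])) {
      sub[[k]] <- subset_asv(data[[k]], samples = md$site_id)
    }
  }
  bundle <- run_survey(sub, cfg)
  # per-level summaries instead of the (short) moving window
  metrics <- do.call(rbind, lapply(bundle$networks, `[[`, "site_metrics"))
  lev <- lapply(split(seq_along(g), g), function(idx) {
    ids <- md$site_id[idx]
    row <- c(level = g[idx[1L]],
             richness = mean(richness(bundle$rarefied$bacteria)[ids]))
    for (p in unique(metrics$pair)) {
      m <- metrics[metrics$pair == p & metrics$site_id %in% ids, ]
      row <- c(row, stats::setNames(c(mean(m$E), mean(m$C)),
                                    paste0(p, c("_E", "_C"))))
    }
    row
  })
  bundle$level_summaries <- as.data.frame(do.call(rbind, lev))
  bundle$network_trends <- lapply(split(metrics, metrics$pair), function(m) {
    m <- m[match(md$site_id, m$site_id), ]
    list(edges = fit_gradient_trend(m$E, g),
         connectance = fit_gradient_trend(m$C, g))
  })
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# Serialize a result bundle as plain TSV/JSON plus a settings manifest.
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  j <- function(x, f) jsonlite::write_json(x, file.path(outdir, f),
                                           auto_unbox = TRUE, digits = NA,
                                           force = TRUE, pretty = TRUE)
  cfg <- bundle$config
  cfg$rmt_scan <- range(cfg$rmt_scan)
  j(cfg, "manifest.json")
  write_site_metadata(bundle$metadata, file.path(outdir, "metadata_used.tsv"))
  j(lapply(bundle$richness_trends, function(t)
    t[c("model", "R2", "AIC", "p_overall")]), "richness_trends.json")
  for (k in names(bundle$ordinations)) {
    o <- bundle$ordinations[[k]]
    write_tsv(data.frame(site_id = rownames(o$coordinates), o$coordinates),
              file.path(outdir, sprintf("nmds_%s.tsv", k)))
  }
  j(bundle$anosim, "anosim.json")
  if (!is.null(bundle$ddr)) j(bundle$ddr, "distance_decay.json")
  for (p in names(bundle$networks)) {
    arm <- bundle$networks[[p]]
    write_tsv(arm$site_metrics,
              file.path(outdir, sprintf("site_metrics_%s.tsv", p)))
    write_network(arm$meta, file.path(outdir, sprintf("network_%s", p)))
    write_tsv(arm$rmt$scan, file.path(outdir, sprintf("rmt_scan_%s.tsv", p)))
  }
  j(bundle$nst[c("ST", "NST", "determinism", "n_null", "seed")], "nst.json")
  write_tsv(bundle$moving_window, file.path(outdir, "moving_window.tsv"))
  for (p in names(bundle$congruence)) {
    co <- bundle$congruence[[p]]
    write_tsv(data.frame(site_id = names(co$protest$residuals),
                         residual = unname(co$protest$residuals)),
              file.path(outdir, sprintf("procrustes_residuals_%s.tsv", p)))
    j(list(m2 = co$protest$m2, R2 = co$protest$R2, p = co$protest$p,
           n_perm = co$protest$n_perm,
           residual_trend = co$residual_trend[
             c("model", "R2", "p_overall")]),
      sprintf("procrustes_%s.json", p))
  }
  j(bundle$ols[c("terms", "beta", "R2", "AIC", "p_terms", "method")],
    "ols_richness.json")
  j(bundle$mantel, "mantel.json")
  write_tsv(data.frame(component = rownames(bundle$vpa), bundle$vpa),
            file.path(outdir, "vpa.tsv"))
  j(bundle$dbrda, "dbrda.json")
  if (!is.null(bundle$level_summaries)) {
    write_tsv(bundle$level_summaries, file.path(outdir, "level_summaries.tsv"))
  }
  invisible(outdir)
}
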