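#' Simulation configuration for survey- and microcosm-like datasets
#'
#' Defines the stated world of the generator: a cross-latitude paddy-soil
#' survey (default 73 sites over 19.27-47.41 degrees N) with kingdom-specific
#' richness shapes (bacteria decreasing, protists peaking near 32 N, viruses
#' weakly increasing), covariates tied to latitude (MAT strongly negative,
#' SWC tracking MAP at r ~ 0.66), log-normal latent abundances thinned by a
#' Gaussian niche filter on the gradient, multinomial sequencing noise, and
#' planted predator-prey pairs whose latent profiles are correlated with
#' their prey's.
#'
#' @param n_sites number of survey sites.
#' @param latitude_range numeric length-2, degrees N.
#' @param n_asv_pool named pool sizes per kingdom.
#' @param depth multinomial sequencing depth per sample.
#' @param n_true_links planted predator-prey pairs per predator kingdom.
#' @param link_strength latent-scale correlation of planted pairs, in (0, 1].
#' @param filter_strength weight in `[0, 1]` of the niche filter on occupancy
#'   (0 = neutral occupancy, 1 = fully environment-determined).
#' @param niche_width Gaussian niche tolerance, in gradient units.
#' @param driver covariate driving the niche filter (`"latitude"`, `"MAT"`,
#'   `"temperature"`, `"SWC"`).
#' @param covariate_noise multiplier on every covariate noise SD (0 gives
#'   noise-free covariates, e.g. MAT exactly affine in latitude).
#' @param abund_sdlog SD of the per-ASV log-normal baseline.
#' @param site_noise_sdlog SD of site-level log-abundance noise.
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 73L,
                       latitude_range = c(19.27, 47.41),
                       n_asv_pool = c(bacteria = 260L, protist = 120L,
                                      virus = 80L),
                       depth = 10000L,
                       n_true_links = c(PB = 20L, VB = 20L),
                       link_strength = 0.9,
                       filter_strength = 0.5,
                       niche_width = 6,
                       driver = "latitude",
                       covariate_noise = 1,
                       abund_sdlog = 1,
                       site_noise_sdlog = 0.6,
                       seed = 1L) {
  stopifnot(n_sites >= 1L, all(n_asv_pool > 0L), depth >= 0L,
            link_strength > 0, link_strength <= 1,
            filter_strength >= 0, filter_strength <= 1)
  structure(list(n_sites = as.integer(n_sites),
                 latitude_range = latitude_range,
                 n_asv_pool = n_asv_pool, depth = as.integer(depth),
                 n_true_links = n_true_links, link_strength = link_strength,
                 filter_strength = filter_strength, niche_width = niche_width,
                 driver = driver, covariate_noise = covariate_noise,
                 abund_sdlog = abund_sdlog,
                 site_noise_sdlog = site_noise_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Accepts a YAML mapping whose keys mirror the arguments of [sim_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in c("n_asv_pool", "n_true_links")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(sim_config, vals)
}

# Occupancy base probability per kingdom along the normalized gradient
# position t in [0, 1]; encodes the latitudinal richness shapes.
occupancy_base <- function(kingdom, t) {
  switch(kingdom,
         bacteria = 0.80 - 0.30 * t,
         protist  = 0.75 - 0.25 * (2 * (t - 0.45))^2,
         virus    = 0.45 + 0.20 * t,
         stop("unknown kingdom"))
}

#' Simulate site metadata along a latitudinal gradient
#'
#' Latitudes are uniform over the configured range; MAT declines with
#' latitude (~0.75 degC per degree, noise SD 2, giving r < -0.9); MAP also
#' declines with latitude and SWC is generated from MAP so that their
#' Pearson correlation targets ~0.66; pH and C:N carry weak positive
#' latitude trends; remaining edaphic variables are latitude-independent.
#'
#' @param config a [sim_config()].
#' @param seed seed (defaults to the config's).
#' @return metadata `data.frame` with the package's fixed column schema.
#' @export
simulate_metadata <- function(config = sim_config(), seed = config$seed) {
  n <- config$n_sites
  lo <- config$latitude_range[1L]; hi <- config$latitude_range[2L]
  cv <- config$covariate_noise
  with_seed(seed, {
    lat <- sort(stats::runif(n, lo, hi))
    if (n >= 2L) { lat[1L] <- lo; lat[n] <- hi }  # pin the stated span
    lon <- stats::runif(n, 95, 124.41)
    elev <- pmax(0, stats::rnorm(n, 200, 150 * cv))
    MAT <- 38.5 - 0.75 * lat + stats::rnorm(n, 0, 2 * cv)
    MAP <- pmax(50, 2200 - 40 * lat + stats::rnorm(n, 0, 150 * cv))
    MTCM <- 1.6 * MAT - 18 + stats::rnorm(n, 0, 2 * cv)
    PSCV <- 40 + 1.2 * lat + stats::rnorm(n, 0, 8 * cv)
    SWC <- pmin(95, pmax(1, 10 + 0.01 * MAP + stats::rnorm(n, 0, 4.1 * cv)))
    pH <- pmin(13.5, pmax(0.5, 5.2 + 0.04 * lat + stats::rnorm(n, 0, 0.5 * cv)))
    SOM <- pmax(0.2, stats::rnorm(n, 3, 1 * cv))
    TN <- pmax(0.02, stats::rnorm(n, 0.2, 0.05 * cv))
    TC <- pmax(0.2, TN * stats::rnorm(n, 10, 1.5 * cv))
    NO3 <- pmax(0.1, stats::rnorm(n, 20, 8 * cv))
    NH4 <- pmax(0.1, stats::rnorm(n, 5, 2 * cv))
    AP <- pmax(0.5, stats::rnorm(n, 25, 10 * cv))
    C_N <- pmax(2, 10 + 0.05 * lat + stats::rnorm(n, 0, 1.5 * cv))
    validate_metadata(data.frame(
      site_id = sprintf("S%03d", seq_len(n)), latitude = lat, longitude = lon,
      elevation = elev, MAT = MAT, MAP = MAP, MTCM = MTCM, PSCV = PSCV,
      pH = pH, SWC = SWC, SOM = SOM, TN = TN, TC = TC, NO3 = NO3, NH4 = NH4,
      AP = AP, C_N = C_N, stringsAsFactors = FALSE))
  })
}

# Latent community for one kingdom: occupancy z (sites x pool) thinned by a
# Gaussian niche filter on the driver, latent abundance z * exp(a_j + e_ij).
simulate_latent <- function(kingdom, gradient, config, seed) {
  n <- length(gradient)
  pool <- config$n_asv_pool[[kingdom]]
  w <- config$filter_strength
  tol <- config$niche_width
  rng <- range(gradient)
  t_pos <- if (diff(rng) > 0) (gradient - rng[1L]) / diff(rng) else rep(0.5, n)
  with_seed(seed, {
    base <- occupancy_base(kingdom, t_pos)
    # niche optima over an interval widened by one tolerance on each side,
    # so edge sites are not systematically depauperate
    u <- stats::runif(pool, rng[1L] - tol, rng[2L] + tol)
    niche <- exp(-outer(gradient, u, "-")^2 / (2 * tol^2))
    p_occ <- base * ((1 - w) + w * niche)
    z <- matrix(stats::rbinom(n * pool, 1L, p_occ), n, pool)
    a <- stats::rnorm(pool, 0, config$abund_sdlog)
    e <- matrix(stats::rnorm(n * pool, 0, config$site_noise_sdlog), n, pool)
    lat_ab <- z * exp(rep(a, each = n) + e)
    empty <- rowSums(lat_ab) == 0
    if (any(empty)) lat_ab[empty, sample.int(pool, 1L)] <- 1  # avoid dead site
    lat_ab
  })
}

# Multinomial read sampling from latent profiles.
draw_counts <- function(latent, depth, kingdom, ids, seed) {
  if (depth <= 0L) stop("sequencing depth must be positive")
  counts <- with_seed(seed, {
    t(apply(latent, 1L, function(lam) {
      stats::rmultinom(1L, depth, lam / sum(lam))[, 1L]
    }))
  })
  dimnames(counts) <- list(ids,
                           sprintf("%s_%04d", toupper(substr(kingdom, 1, 1)),
                                   seq_len(ncol(latent))))
  tab <- asv_table(counts, kingdom)
  attr(tab, "latent") <- latent
  tab
}

#' Simulate the three kingdom community tables
#'
#' Draws, for each kingdom, per-ASV log-normal latent abundances thinned by
#' kingdom-specific occupancy probabilities along the driver gradient, then
#' multinomial read counts at the configured depth. The latent matrix is
#' attached as attribute `"latent"` for link planting.
#'
#' @param metadata output of [simulate_metadata()] (or microcosm metadata).
#' @param config a [sim_config()].
#' @param seed seed (defaults to the config's).
#' @return named list of three `asv_table`s: bacteria, protist, virus.
#' @export
simulate_communities <- function(metadata, config = sim_config(),
                                 seed = config$seed) {
  g <- metadata[[config$driver]]
  if (is.null(g)) stop("driver column not found in metadata: ", config$driver)
  out <- list()
  for (k in c("bacteria", "protist", "virus")) {
    lat_ab <- simulate_latent(k, g, config, child_seed(seed, paste0("lat_", k)))
    out[[k]] <- draw_counts(lat_ab, config$depth, k, metadata$site_id,
                            child_seed(seed, paste0("cnt_", k)))
  }
  out
}

#' Plant predator-prey links between two community tables
#'
#' Rewrites the latent profiles of selected predator ASVs so that, across
#' sites, each tracks a chosen prey ASV: the predator copies the prey's
#' occupancy with probability `link_strength` and, where present, its
#' log-latent abundance is a `link_strength`-weighted mixture of the prey's
#' standardized log-latent profile and independent noise. Predator counts are
#' then re-drawn multinomially, so sequencing noise attenuates but does not
#' erase the association.
#'
#' @param prey an `asv_table` carrying a `"latent"` attribute.
#' @param predator an `asv_table` carrying a `"latent"` attribute.
#' @param config a [sim_config()]; `link_strength` may also be a per-sample
#'   vector via `strength`.
#' @param n_links number of planted pairs (defaults per config).
#' @param strength scalar or per-sample link strength, overriding the config.
#' @param seed seed.
#' @return list with `table` (the rewritten predator `asv_table`) and
#'   `links` (data.frame: predator_asv, prey_asv, strength).
#' @export
plant_trophic_links <- function(prey, predator, config = sim_config(),
                                n_links = NULL, strength = NULL,
                                seed = config$seed) {
  if (!identical(sample_ids(prey), sample_ids(predator))) {
    stop("prey and predator tables must share sample ids")
  }
  lat_prey <- attr(prey, "latent"); lat_pred <- attr(predator, "latent")
  if (is.null(lat_prey) || is.null(lat_pred)) {
    stop("tables must carry latent attributes (generate with simulate_communities)")
  }
  key <- if (predator$kingdom == "virus") "VB" else "PB"
  if (is.null(n_links)) n_links <- config$n_true_links[[key]]
  rho <- if (is.null(strength)) config$link_strength else strength
  n <- nrow(lat_prey)
  rho <- rep_len(rho, n)
  if (n_links > min(ncol(lat_prey), ncol(lat_pred))) {
    stop("more links requested than available ASV pairs")
  }
  with_seed(seed, {
    occ_prey <- colMeans(lat_prey > 0)
    # prey partners must be variable and prevalent enough to survive filtering
    eligible <- which(occ_prey >= 0.4 & occ_prey <= 0.95)
    if (length(eligible) < n_links) eligible <- order(-occ_prey)[seq_len(n_links)]
    prey_idx <- sample(eligible, n_links)
    pred_idx <- sample(ncol(lat_pred), n_links)
    for (j in seq_len(n_links)) {
      x <- lat_prey[, prey_idx[j]]
      pres <- x > 0
      zx <- numeric(n)
      if (sum(pres) > 1L) zx[pres] <- scale(log(x[pres]))[, 1L]
      copy <- stats::rbinom(n, 1L, rho) == 1L
      occ_new <- ifelse(copy, pres, stats::rbinom(n, 1L, mean(pres)) == 1L)
      eps <- stats::rnorm(n)
      y <- rho * zx + sqrt(pmax(0, 1 - rho^2)) * eps
      lat_pred[, pred_idx[j]] <- ifelse(occ_new, exp(y), 0)
    }
    empty <- rowSums(lat_pred) == 0
    if (any(empty)) lat_pred[empty, 1L] <- 1
    tab <- draw_counts(lat_pred, config$depth, predator$kingdom,
                       sample_ids(predator), child_seed(seed, "replant"))
    links <- data.frame(predator_asv = asv_ids(tab)[pred_idx],
                        prey_asv = asv_ids(prey)[prey_idx],
                        strength = mean(rho), stringsAsFactors = FALSE)
    list(table = tab, links = links)
  })
}

#' Simulate a full survey dataset
#'
#' Metadata plus three kingdom tables with planted protist-bacteria and
#' virus-bacteria links.
#'
#' @param config a [sim_config()].
#' @return list: `metadata`, `bacteria`, `protist`, `virus`, `links`
#'   (list with `PB` and `VB` registries).
#' @export
simulate_survey <- function(config = sim_config()) {
  md <- simulate_metadata(config)
  comm <- simulate_communities(md, config)
  pb <- plant_trophic_links(comm$bacteria, comm$protist, config,
                            seed = child_seed(config$seed, "links_PB"))
  vb <- plant_trophic_links(comm$bacteria, comm$virus, config,
                            seed = child_seed(config$seed, "links_VB"))
  list(metadata = md, bacteria = comm$bacteria, protist = pb$table,
       virus = vb$table, links = list(PB = pb$links, VB = vb$links))
}

#' Simulate a microcosm experiment dataset
#'
#' Fixed factorial design: five temperatures (5, 10, 15, 20, 25 degC) with
#' eight replicates at 13.7% soil water content, plus four soil water
#' contents (10, 15, 20, 25%) with eight replicates at 20 degC — 72 units in
#' all. Communities are driven by the temperature column; planted link
#' strength can vary along temperature (default a quadratic peak at 15 degC,
#' emulating mid-temperature intensification of protist grazing).
#'
#' @param config a [sim_config()]; `n_sites`, `latitude_range` and `driver`
#'   are ignored (the design is fixed).
#' @param pb_profile function mapping temperature to protist-bacteria link
#'   strength in (0, 1]; default quadratic peaking at 15 degC.
#' @return list: `metadata` (with `temperature` and treatment columns),
#'   `bacteria`, `protist`, `virus`, `links`.
#' @export
simulate_microcosm <- function(config = sim_config(),
                               pb_profile = function(tc)
                                 0.9 - 0.5 * ((tc - 15) / 10)^2) {
  temps <- c(5, 10, 15, 20, 25); swcs <- c(10, 15, 20, 25); reps <- 8L
  design <- rbind(
    data.frame(treatment = "temperature",
               temperature = rep(temps, each = reps),
               SWC = 13.7),
    data.frame(treatment = "moisture", temperature = 20,
               SWC = rep(swcs, each = reps)))
  n <- nrow(design)  # 72 experimental units
  md <- with_seed(child_seed(config$seed, "microcosm_md"), data.frame(
    site_id = sprintf("M%03d", seq_len(n)),
    treatment = design$treatment,
    temperature = design$temperature,
    latitude = 22.45, longitude = 112.41, elevation = 50,
    MAT = design$temperature, MAP = 1600, MTCM = 11, PSCV = 65,
    pH = stats::rnorm(n, 6.5, 0.1), SWC = design$SWC,
    SOM = 1.4, TN = 0.1, TC = 1, NO3 = 82.9, NH4 = 4.1, AP = 39.4,
    C_N = stats::rnorm(n, 10, 0.5), stringsAsFactors = FALSE))
  cfg <- config
  cfg$n_sites <- n
  cfg$driver <- "temperature"
  comm <- simulate_communities(md, cfg, seed = child_seed(cfg$seed, "micro"))
  rho <- pmin(1, pmax(0.05, pb_profile(md$temperature)))
  pb <- plant_trophic_links(comm$bacteria, comm$protist, cfg, strength = rho,
                            seed = child_seed(cfg$seed, "micro_PB"))
  vb <- plant_trophic_links(comm$bacteria, comm$virus, cfg,
                            strength = pmin(1, 1 - 0.02 * md$temperature),
                            seed = child_seed(cfg$seed, "micro_VB"))
  list(metadata = md, bacteria = comm$bacteria, protist = pb$table,
       virus = vb$table, links = list(PB = pb$links, VB = vb$links))
}

#' Write a simulated dataset to a directory as TSV
#'
#' Emits the same TSV dialects read by [read_asv_table()] and
#' [read_site_metadata()], plus `true_links_PB.tsv` / `true_links_VB.tsv`
#' registries. With a fixed seed the bytes are identical across runs.
#'
#' @param sim output of [simulate_survey()] or [simulate_microcosm()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_site_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  for (k in c("bacteria", "protist", "virus")) {
    write_asv_table(sim[[k]], file.path(dir, paste0(k, ".tsv")))
  }
  for (p in names(sim$links)) {
    write_tsv(sim$links[[p]], file.path(dir, sprintf("true_links_%s.tsv", p)))
  }
  invisible(dir)
}
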