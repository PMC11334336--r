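as_tab <- function(m, kingdom = "bacteria") {
  dimnames(m) <- list(sprintf("s%02d", seq_len(nrow(m))),
                      sprintf("x%02d", seq_len(ncol(m))))
  storage.mode(m) <- "integer"
  asv_table(m, kingdom)
}

test_that("spearman block handles monotonicity, reversal and ties", {
  # filler columns keep row sums constant so relative abundances stay
  # proportional to counts
  prey <- as_tab(cbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1),
                       c(2, 4, 4, 8, 6), c(10, 8, 8, 4, 6)))
  pred <- as_tab(cbind(c(2, 4, 6, 8, 10), c(1, 3, 3, 5, 4),
                       c(13, 9, 7, 3, 2)), "protist")
  blk <- spearman_block(prey, pred)
  expect_equal(blk$rho["x01", "x01"], 1)   # monotone copy
  expect_equal(blk$rho["x01", "x02"], -1)  # reversed ranks
  # x=(1,2,2,4,3)-ranked vs y=(1,3,3,5,4): identical average ranks -> rho = 1
  expect_equal(blk$rho["x02", "x03"], 1)

  constant <- as_tab(cbind(rep(3, 5), rep(2, 5)), "protist")
  expect_warning(blk2 <- spearman_block(prey, constant), "constant")
  expect_equal(unname(blk2$rho[1, ]), rep(0, 4))
})

test_that("bipartite embedding spectrum equals the eigen oracle", {
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(12 * 7), 12, 7)
    A[abs(A) < 0.8] <- 0
    act <- A[rowSums(A != 0) > 0, colSums(A != 0) > 0, drop = FALSE]
    M <- rbind(cbind(matrix(0, nrow(act), nrow(act)), act),
               cbind(t(act), matrix(0, ncol(act), ncol(act))))
    expect_equal(trophgrad:::embedded_spectrum(A),
                 sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
                 tolerance = 1e-8)
  }
})

test_that("meta-network counts follow C = E/N^2", {
  blk <- structure(list(predator_ids = c("p1", "p2"), prey_ids = c("b1", "b2"),
                        rho = matrix(c(0.9, -0.8, 0.85, 0.7), 2, 2,
                                     dimnames = list(c("p1", "p2"),
                                                     c("b1", "b2")))),
                   class = "correlation_block")
  full <- build_meta_network(blk, 0.5)
  expect_identical(c(full$E, full$N), c(4L, 4L))
  expect_equal(full$C, 0.25)
  none <- build_meta_network(blk, 0.95)
  expect_identical(none$E, 0L)
  expect_equal(none$C, 0)
  one <- build_meta_network(blk, 0.88)
  expect_identical(c(one$E, one$N), c(1L, 2L))
  expect_equal(one$C, 1 / 4)
  pos <- build_meta_network(blk, 0.75, positive_only = TRUE)
  expect_identical(pos$E, 2L)  # the -0.8 and the 0.7 entries drop out
})

test_that("site subnetworks induce on present ASVs", {
  # bipartite path b1 - p1 - b2 (predator p1 linked to both prey)
  rho <- matrix(c(0.9, 0.9, 0.1), 1, 3,
                dimnames = list("p1", c("b1", "b2", "b3")))
  blk <- structure(list(predator_ids = "p1", prey_ids = c("b1", "b2", "b3"),
                        rho = rho), class = "correlation_block")
  meta <- build_meta_network(blk, 0.5)
  prey <- as_tab(rbind(c(5, 5, 5), c(5, 5, 5), c(0, 5, 5)))
  colnames(prey$counts) <- c("b1", "b2", "b3")
  pred <- as_tab(rbind(5, 5, 0), "protist")
  colnames(pred$counts) <- "p1"
  ms <- site_subnetworks(meta, prey, pred)
  # site 1: everything present -> equals the meta-network
  expect_identical(ms$E[1], meta$E)
  expect_identical(ms$N[1], meta$N)
  expect_equal(ms$C[1], meta$C)
  # site 3 lacks the middle node p1 -> no edges, no connected nodes
  expect_identical(c(ms$E[3], ms$N[3]), c(0L, 0L))
  expect_equal(ms$C[3], 0)
})

test_that("edge count is monotone non-increasing in threshold and sites
           never exceed the meta-network", {
  cfg <- small_config(seed = 8)
  md <- simulate_metadata(cfg)
  comm <- simulate_communities(md, cfg)
  bb <- prevalence_filter(rarefy(comm$bacteria, seed = 1))
  pp <- prevalence_filter(rarefy(comm$protist, seed = 2))
  blk <- spearman_block(bb, pp)
  Es <- vapply(seq(0.1, 0.9, 0.1),
               function(s) build_meta_network(blk, s)$E, 0L)
  expect_true(all(diff(Es) <= 0))
  meta <- build_meta_network(blk, 0.4)
  ms <- site_subnetworks(meta, bb, pp)
  expect_true(all(ms$E <= meta$E))
  expect_true(all(ms$N <= meta$N))
  expect_true(all(ms$C >= 0 & ms$C <= 1))
  expect_true(all(ms$E <= ms$N^2))
})

test_that("rmt threshold isolates planted structure from noise", {
  cfg <- sim_config(seed = 17, filter_strength = 0,
                    n_asv_pool = c(bacteria = 120L, protist = 60L,
                                   virus = 20L))
  md <- simulate_metadata(cfg)
  comm <- simulate_communities(md, cfg)
  pb <- plant_trophic_links(comm$bacteria, comm$protist, cfg, seed = 99)
  bb <- prevalence_filter(rarefy(comm$bacteria, seed = 1))
  pp <- prevalence_filter(rarefy(pb$table, seed = 2))
  blk <- spearman_block(bb, pp)
  scan <- rmt_threshold(blk)
  expect_true(scan$chosen_threshold >= 0.30 && scan$chosen_threshold <= 0.98)
  # the Wigner surmise reference at u = 1 is the closed form (pi/2)e^(-pi/4)
  expect_equal((pi / 2) * exp(-pi / 4), 0.71616, tolerance = 1e-4)
  # the chosen threshold removes nearly all of the correlation mass
  frac_excluded <- mean(abs(blk$rho) < scan$chosen_threshold)
  expect_gt(frac_excluded, 0.99)
  # planted pairs dominate the surviving edges
  net <- build_meta_network(blk, scan$chosen_threshold)
  expect_gte(sum(pb$links$predator_asv %in%
                   net$predator_ids[rowSums(net$adjacency) > 0]), 15)
})

test_that("threshold sensitivity correlates metrics across prevalence levels", {
  cfg <- small_config(seed = 5)
  md <- simulate_metadata(cfg)
  comm <- simulate_communities(md, cfg)
  pb <- plant_trophic_links(comm$bacteria, comm$protist, cfg, seed = 7)
  bb <- rarefy(comm$bacteria, seed = 1)
  pp <- rarefy(pb$table, seed = 2)
  expect_error(threshold_sensitivity(bb, pp, prevalence_levels = 0.3),
               "at least 2")
  # identical levels give correlation 1 by construction
  same <- threshold_sensitivity(bb, pp, prevalence_levels = c(0.3, 0.3),
                                threshold = 0.4)
  expect_true(all(same$rho[!is.na(same$rho)] == 1))
  sens <- threshold_sensitivity(bb, pp, prevalence_levels = c(0.2, 0.3, 0.4),
                                threshold = 0.4)
  expect_identical(nrow(sens), 6L)
})

test_that("per-site E correlates across prevalence levels on planted data", {
  hits <- vapply(1:20, function(s) {
    cfg <- small_config(seed = s + 300)
    md <- simulate_metadata(cfg)
    comm <- simulate_communities(md, cfg)
    pb <- plant_trophic_links(comm$bacteria, comm$protist, cfg, seed = s)
    bb <- rarefy(comm$bacteria, seed = 1)
    pp <- rarefy(pb$table, seed = 2)
    sens <- threshold_sensitivity(bb, pp,
                                  prevalence_levels = c(0.2, 0.3, 0.4),
                                  threshold = 0.5)
    all(sens$rho[sens$metric == "E"] > 0.5, na.rm = TRUE)
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("network export writes an edge list and GraphML", {
  rho <- matrix(c(0.9, -0.95, 0.2, 0.1), 2, 2,
                dimnames = list(c("p1", "p2"), c("b1", "b2")))
  blk <- structure(list(predator_ids = c("p1", "p2"),
                        prey_ids = c("b1", "b2"), rho = rho),
                   class = "correlation_block")
  net <- build_meta_network(blk, 0.5)
  prefix <- file.path(withr::local_tempdir(), "net")
  write_network(net, prefix)
  edges <- read.delim(paste0(prefix, "_edges.tsv"))
  expect_identical(nrow(edges), 2L)
  expect_setequal(edges$sign, c("positive", "negative"))
  expect_true(any(grepl("graphml", readLines(paste0(prefix, ".graphml")))))
})
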