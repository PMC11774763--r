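identity_ensemble <- function(net, n = 5) {
  structure(list(networks = rep(list(net), n), algorithm = "ms",
                 config = list(), master_seed = 1, seeds = NULL,
                 traces = NULL),
            class = "null_ensemble")
}

test_that("Spearman correlations hit their closed-form extremes and the oracle", {
  net <- generate_synthetic(20, 0.3, seed = 1)
  expect_equal(strength_spearman(net, identity_ensemble(net))$rho, rep(1, 5))

  # reversed ranks -> rho = -1: build a null whose strengths invert the order
  s <- strengths(net)$strength
  rev_net <- net
  ord <- order(s)
  perm <- integer(20)
  perm[ord] <- rev(ord)
  rev_net$weights <- net$weights[perm, perm]
  rho <- strength_spearman(net, identity_ensemble(rev_net, 1))$rho
  expect_equal(rho, -1)

  # rank-then-Pearson brute force on small fixtures
  for (seed in 1:5) {
    a <- random_small_net(8, 0.6, seed = seed)
    b <- random_small_net(8, 0.6, seed = seed + 50)
    got <- strength_spearman(a, identity_ensemble(b, 1))$rho
    want <- cor(rank(strengths(a)$strength), rank(strengths(b)$strength))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("KS statistics match the step-function oracle and its extremes", {
  net <- generate_synthetic(20, 0.3, seed = 2)
  expect_equal(strength_ks(net, identity_ensemble(net))$ks, rep(0, 5))

  lo <- net_from_edges(3, list(c(1, 2, 0.1), c(2, 3, 0.2)))
  hi <- net_from_edges(3, list(c(1, 2, 100), c(2, 3, 200)))
  expect_equal(strength_ks(lo, identity_ensemble(hi, 1))$ks, 1)

  for (seed in 1:5) {
    a <- random_small_net(8, 0.6, seed = seed)
    b <- random_small_net(8, 0.6, seed = seed + 50)
    got <- strength_ks(a, identity_ensemble(b, 1))$ks
    want <- oracle_ks(strengths(a)$strength, strengths(b)$strength)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("KS is invariant under a common strictly monotone transform", {
  a <- random_small_net(10, 0.5, seed = 7)
  b <- random_small_net(10, 0.5, seed = 8)
  sa <- strengths(a)$strength
  sb <- strengths(b)$strength
  expect_equal(oracle_ks(sa, sb), oracle_ks(log(sa), log(sb)))
  expect_equal(oracle_ks(sa, sb), oracle_ks(sa^3, sb^3))
})

test_that("CLES equals brute-force pair counting and the U identity", {
  r <- mwu_cles(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r$cles, 100)
  r2 <- mwu_cles(rep(1, 4), rep(1, 4))
  expect_equal(r2$cles, 50)

  set.seed(9)
  for (i in 1:50) {
    a <- round(runif(6), 2)
    b <- round(runif(6), 2)
    got <- mwu_cles(a, b)
    expect_equal(got$cles, oracle_cles(a, b))
    expect_equal(got$cles, 100 * got$u / 36)
  }
  expect_error(mwu_cles(numeric(0), 1:3), "nonempty")
})

test_that("morphospace composes per-null metrics and collapses for identical copies", {
  net <- generate_synthetic(25, 0.25, seed = 4)
  ms0 <- morphospace(net, identity_ensemble(net, 4))
  expect_equal(ms0$summary$ensemble_var_cpl, 0)
  expect_equal(ms0$summary$ensemble_var_clu, 0)
  expect_equal(ms0$summary$ensemble_mean_cpl, ms0$reference$cpl)

  ens <- generate_ensemble(net, "ms", n_nulls = 6, seed = 5)
  cfg <- metric_config()
  msp <- morphospace(net, ens, cfg)
  for (i in c(1, 4, 6)) {
    expect_equal(msp$points$cpl[i],
                 characteristic_path_length(ens$networks[[i]], cfg))
    expect_equal(msp$points$clustering[i], mean_clustering(ens$networks[[i]]))
  }
  expect_equal(msp$summary$ensemble_mean_cpl, mean(msp$points$cpl))
  expect_equal(msp$summary$ensemble_var_cpl, var(msp$points$cpl))
})

test_that("subsample convergence is zero at full size, deterministic, and shrinks", {
  net <- generate_synthetic(25, 0.25, seed = 6)
  ens <- generate_ensemble(net, "ms", n_nulls = 30, seed = 7)
  msp <- morphospace(net, ens)
  traj <- subsample_convergence(msp, c(5, 15, 30), n_resamples = 200, seed = 1)
  expect_s3_class(traj, "convergence_trajectory")
  at_full <- traj[traj$sample_size == 30, ]
  expect_true(all(at_full$rel_diff == 0))
  expect_true(all(traj$rel_diff >= 0))
  # monotone trend in expectation: smallest size has the largest mean error
  for (stat in unique(traj$statistic)) {
    tr <- traj[traj$statistic == stat, ]
    expect_gt(tr$rel_diff[tr$sample_size == 5],
              tr$rel_diff[tr$sample_size == 30])
  }
  traj2 <- subsample_convergence(msp, c(5, 15, 30), n_resamples = 200, seed = 1)
  expect_identical(traj, traj2)
  expect_error(subsample_convergence(msp, 31), "exceeds")
})

test_that("ensemble comparison reports shapes and a 50% self-CLES", {
  net <- generate_synthetic(30, 0.2, seed = 8)
  cfg <- annealing_config(n_stages = 10)
  ens <- list(ms = generate_ensemble(net, "ms", n_nulls = 8, seed = 9),
              rs = generate_ensemble(net, "rs", n_nulls = 8, seed = 9),
              sa = generate_ensemble(net, "sa", n_nulls = 8, annealing = cfg,
                                     seed = 9))
  rep <- compare_ensembles(net, ens)
  expect_equal(nrow(rep$per_null), 24)
  expect_equal(nrow(rep$pairwise), 6)  # 3 pairs x 2 metrics
  self <- mwu_cles(rep$per_null$rho[rep$per_null$algorithm == "sa"],
                   rep$per_null$rho[rep$per_null$algorithm == "sa"])
  expect_equal(self$cles, 50)
  # values recomputable from library calls
  expect_equal(rep$per_null$rho[rep$per_null$algorithm == "rs"],
               strength_spearman(net, ens$rs)$rho)
})

test_that("tidiers and plots cover the main result types", {
  net <- generate_synthetic(20, 0.3, seed = 10)
  ens <- generate_ensemble(net, "sa", n_nulls = 3,
                           annealing = annealing_config(n_stages = 5),
                           seed = 11)
  td <- tidy(ens)
  expect_true(all(c("null", "final_energy", "stages_run") %in% names(td)))
  expect_equal(nrow(td), 3)
  gl <- glance(ens)
  expect_equal(gl$n_nulls, 3)

  tr <- ens$traces[[1]]
  expect_equal(nrow(tidy(tr)), tr$stages_run)
  expect_equal(glance(tr)$final_energy, tr$final_energy)

  msp <- morphospace(net, ens)
  expect_equal(nrow(tidy(msp)), 3)
  expect_true("reference_cpl" %in% names(glance(msp)))

  curve <- normalized_rich_club(net, ens)
  expect_s3_class(autoplot(curve), "ggplot")
  expect_s3_class(autoplot(msp), "ggplot")
  expect_s3_class(autoplot(tr), "ggplot")
  traj <- subsample_convergence(msp, c(2, 3), n_resamples = 20, seed = 1)
  expect_s3_class(autoplot(traj), "ggplot")

  hr <- identify_hubs(net)
  expect_true(is.numeric(glance(hr)$p_R))
})
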