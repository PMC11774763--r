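test_that("mse energy matches hand-computed values per objective", {
  s <- function(...) tibble::tibble(node = seq_along(c(...)), strength = c(...))
  expect_equal(mse_energy(s(1, 2, 3), s(1, 2, 3)), 0)
  expect_equal(mse_energy(s(3, 1, 2), s(1, 3, 2)), 8 / 3)

  din <- tibble::tibble(node = 1:2, s_in = c(0, 2), s_out = c(1, 1))
  dcur <- tibble::tibble(node = 1:2, s_in = c(1, 1), s_out = c(2, 0))
  # in-error 1.0 and out-error 1.0 sum for the directed objective
  expect_equal(mse_energy(din, dcur), 2)
  expect_equal(mse_energy(din, dcur, objective = "dir_alt"), 1)

  sg <- tibble::tibble(node = 1:2, s_pos = c(1, 1), s_neg = c(2, 2))
  sg2 <- tibble::tibble(node = 1:2, s_pos = c(2, 2), s_neg = c(2, 2))
  expect_equal(mse_energy(sg, sg2), 1)

  expect_error(mse_energy(s(1, 2), s(1, 2, 3)), "lengths")
  expect_error(mse_energy(s(1, 2), din, objective = "und"), "missing")
})

test_that("the Metropolis criterion accepts downhill always and uphill by exp(-dE/T)", {
  expect_true(metropolis_accept(2, 1, 0.001, 0.999999))
  T <- 1.7
  dE <- T * log(2)  # acceptance probability exactly 1/2
  expect_true(metropolis_accept(1, 1 + dE, T, 0.4))
  expect_false(metropolis_accept(1, 1 + dE, T, 0.6))
  expect_false(metropolis_accept(1, 2, 1e-12, 1e-6))
  expect_error(metropolis_accept(1, 2, 0, 0.5), "positive")
})

test_that("rank matching places the large weight on the high-residual pair", {
  # path a-b-c with weights 1 and 10: strengths (1, 11, 10); the b-c edge has
  # the larger expected magnitude and must receive the weight 10
  net <- net_from_edges(3, list(c(1, 2, 1), c(2, 3, 10)))
  out <- rubinov_sporns(net, net, seed = 1)
  expect_equal(out$weights[2, 3], 10)
  expect_equal(out$weights[1, 2], 1)

  single <- net_from_edges(2, list(c(1, 2, 3.5)))
  expect_equal(rubinov_sporns(single, single, seed = 1)$weights[1, 2], 3.5)
})

test_that("compiled rank matching agrees exactly with the R reference", {
  for (seed in 1:5) {
    net <- random_small_net(8, 0.5, seed = seed)
    sc <- maslov_sneppen_und(net, preserve_connectedness = FALSE,
                             seed = seed + 40)$network
    et <- edge_table(sc)
    w_desc <- sort(sorted_weights(net), decreasing = TRUE)
    s_tgt <- strengths(net)$strength

    set.seed(seed + 7)
    tk <- runif(nrow(et))
    got <- strengthnulls:::cpp_rs_place(n_nodes(net), et$i - 1L, et$j - 1L,
                                        w_desc, s_tgt, tk)
    set.seed(seed + 7)
    tk2 <- runif(nrow(et))
    want <- strengthnulls:::.rs_place_reference(n_nodes(net), et$i, et$j,
                                                w_desc, s_tgt, tk2)
    expect_equal(got, want)
  }
})

test_that("rank matching conserves weights and improves strength fit over rewiring", {
  net <- generate_synthetic(60, 0.2, seed = 5)
  sc <- maslov_sneppen_und(net, seed = 6)$network
  rs <- rubinov_sporns(net, sc, seed = 7)
  expect_identical(sorted_weights(rs), sorted_weights(net))
  expect_identical((rs$weights != 0), (sc$weights != 0))
  rho_rs <- cor(strengths(net)$strength, strengths(rs)$strength,
                method = "spearman")
  rho_ms <- cor(strengths(net)$strength, strengths(sc)$strength,
                method = "spearman")
  expect_gt(rho_rs, rho_ms)
  expect_error(rubinov_sporns(net, generate_synthetic(60, 0.2, seed = 99)),
               "degree sequence|weight multiset")
})

test_that("signed rank matching preserves per-sign weight multisets", {
  net <- generate_synthetic(40, 0.25, signed = TRUE, seed = 8)
  sc <- switch_signed(net, seed = 9)$network
  rs <- rubinov_sporns(net, sc, seed = 10)
  w_ref <- sorted_weights(net)
  w_out <- sorted_weights(rs)
  expect_identical(w_out, w_ref)
  expect_equal(degrees(rs)$k_pos, degrees(net)$k_pos)
  expect_equal(degrees(rs)$k_neg, degrees(net)$k_neg)
})

test_that("annealing lowers the energy and keeps topology and weights intact", {
  net <- generate_synthetic(50, 0.2, seed = 1)
  sc <- maslov_sneppen_und(net, seed = 2)$network
  fit <- simulated_annealing(net, sc, annealing_config(seed = 3))
  tr <- fit$trace
  expect_lte(tr$final_energy, tr$initial_energy)
  expect_lt(tr$final_energy, 0.01 * tr$initial_energy)
  expect_equal(tr$final_energy, tr$stage_energies[tr$stages_run])
  expect_equal(tr$stages_run, 100)
  expect_identical((fit$network$weights != 0), (sc$weights != 0))
  expect_identical(sorted_weights(fit$network), sorted_weights(net))
  rho <- cor(strengths(net)$strength, strengths(fit$network)$strength,
             method = "spearman")
  expect_gte(rho, 0.99)
})

test_that("uniform weights give zero energy from the start", {
  net <- generate_synthetic(20, 0.3, weight_dist = "uniform",
                            dist_params = list(min = 1, max = 1), seed = 4)
  expect_true(all(sorted_weights(net) == 1))
  sc <- maslov_sneppen_und(net, seed = 5)$network
  fit <- simulated_annealing(net, sc, annealing_config(n_stages = 5, seed = 6))
  expect_equal(fit$trace$initial_energy, 0)
  expect_equal(fit$trace$final_energy, 0)
  expect_equal(strengths(fit$network)$strength, strengths(net)$strength)
})

test_that("the energy threshold stops the schedule early", {
  net <- generate_synthetic(50, 0.2, seed = 1)
  sc <- maslov_sneppen_und(net, seed = 2)$network
  fit <- simulated_annealing(
    net, sc, annealing_config(energy_threshold = 1e-4, max_stages = 1000,
                              seed = 9))
  expect_lt(fit$trace$stages_run, 1000)
  expect_lte(fit$trace$final_energy, 1e-4)
})

test_that("directed annealing variants honor their objectives", {
  net <- generate_synthetic(40, 0.15, directed = TRUE, seed = 11)
  sc <- maslov_sneppen_dir(net, seed = 12)$network
  fit <- simulated_annealing(net, sc, annealing_config(seed = 13))
  expect_lt(fit$trace$final_energy, 0.05 * fit$trace$initial_energy)

  alt <- simulated_annealing_dir_alt(net, sc, annealing_config(seed = 14))
  expect_equal(strengths(alt$network)$s_out, strengths(net)$s_out,
               tolerance = 1e-12)
  expect_identical(sorted_weights(alt$network), sorted_weights(net))
  # in-strength error must improve on the scaffold's
  e_scaffold <- mse_energy(strengths(net), strengths(sc), objective = "dir_alt")
  e_alt <- mse_energy(strengths(net), strengths(alt$network),
                      objective = "dir_alt")
  expect_lt(e_alt, e_scaffold)
  expect_error(simulated_annealing_dir_alt(net, generate_synthetic(
    40, 0.15, directed = TRUE, seed = 77)), "degree|out-strength|weight")
})

test_that("signed annealing keeps sign-class structure while fitting both strengths", {
  net <- generate_synthetic(40, 0.25, signed = TRUE, seed = 15)
  sc <- switch_signed(net, seed = 16)$network
  fit <- simulated_annealing(net, sc, annealing_config(seed = 17))
  expect_equal(degrees(fit$network)$k_pos, degrees(net)$k_pos)
  expect_equal(degrees(fit$network)$k_neg, degrees(net)$k_neg)
  expect_identical(sorted_weights(fit$network), sorted_weights(net))
  expect_lt(fit$trace$final_energy, 0.05 * fit$trace$initial_energy)
  st <- strengths(net); sn <- strengths(fit$network)
  expect_gt(cor(st$s_pos, sn$s_pos, method = "spearman"), 0.95)
  expect_gt(cor(st$s_neg, sn$s_neg, method = "spearman"), 0.95)
})

test_that("annealing config validates its invariants", {
  expect_error(annealing_config(n_stages = 0), "n_stages")
  expect_error(annealing_config(T0 = -1), "T0")
  expect_error(annealing_config(cooling_factor = 1.5), "cooling_factor")
  expect_error(annealing_config(energy_threshold = 0), "positive")
  expect_error(simulated_annealing(
    generate_synthetic(10, 0.5, seed = 1),
    generate_synthetic(10, 0.5, seed = 1),
    annealing_config(objective = "dir")), "does not match")
})

test_that("ensembles share scaffolds across algorithms under one master seed", {
  net <- generate_synthetic(40, 0.2, seed = 19)
  cfg <- annealing_config(n_stages = 10)
  e_ms <- generate_ensemble(net, "ms", n_nulls = 4, seed = 77)
  e_rs <- generate_ensemble(net, "rs", n_nulls = 4, seed = 77)
  e_sa <- generate_ensemble(net, "sa", n_nulls = 4, annealing = cfg, seed = 77)
  for (i in 1:4) {
    topo <- (e_ms$networks[[i]]$weights != 0)
    expect_identical((e_rs$networks[[i]]$weights != 0), topo)
    expect_identical((e_sa$networks[[i]]$weights != 0), topo)
    expect_identical(sorted_weights(e_rs$networks[[i]]), sorted_weights(net))
    expect_identical(sorted_weights(e_sa$networks[[i]]), sorted_weights(net))
  }
  expect_error(generate_ensemble(generate_synthetic(10, 0.5, directed = TRUE,
                                                    seed = 1),
                                 "rs", n_nulls = 2),
               "undirected")
})

test_that("derived per-null seeds are valid and index-dependent only", {
  s <- vapply(1:100, derive_seed, integer(1), master_seed = 42)
  expect_true(all(s >= 1 & s < 2^31))
  expect_equal(length(unique(s)), 100)
  expect_identical(derive_seed(42, 7), derive_seed(42, 7))
  expect_false(derive_seed(42, 7) == derive_seed(43, 7))
})
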