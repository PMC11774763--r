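test_that("construction validates the network invariants", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 2
  w[2, 3] <- w[3, 2] <- 3
  net <- weighted_network(w)
  expect_s3_class(net, "weighted_network")
  expect_equal(n_nodes(net), 3)
  expect_equal(edge_count(net), 2)

  expect_error(weighted_network(matrix(1, 2, 3)), "square")
  expect_error(weighted_network(diag(3)), "diagonal")
  bad <- w; bad[1, 2] <- 5
  expect_error(weighted_network(bad), "symmetric")
  bad <- w; bad[1, 2] <- bad[2, 1] <- -1
  expect_error(weighted_network(bad), "negative")
  bad <- w; bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(weighted_network(bad), "NaN")
  expect_error(weighted_network(matrix(0, 3, 3)), "no edges")
})

test_that("strengths and degrees follow the network kind", {
  tri <- triangle_net()
  expect_equal(strengths(tri)$strength, c(2, 2, 2))
  expect_equal(degrees(tri)$degree, c(2, 2, 2))

  st <- star_net(3)
  expect_equal(degrees(st)$degree, c(3, 1, 1, 1))

  d <- matrix(0, 2, 2); d[1, 2] <- 5
  dn <- weighted_network(d, directed = TRUE)
  expect_equal(strengths(dn)$s_out, c(5, 0))
  expect_equal(strengths(dn)$s_in, c(0, 5))

  s <- matrix(0, 2, 2); s[1, 2] <- s[2, 1] <- -2
  sn <- weighted_network(s, signed = TRUE)
  expect_equal(strengths(sn)$s_pos, c(0, 0))
  expect_equal(strengths(sn)$s_neg, c(2, 2))
})

test_that("strengths/degrees match brute-force summation on random fixtures", {
  for (seed in 1:10) {
    net <- random_small_net(8, 0.5, seed = seed)
    expect_equal(strengths(net)$strength, oracle_strengths(net$weights))
    expect_equal(degrees(net)$degree,
                 oracle_strengths((net$weights != 0) * 1))
  }
  # signed partition identity: k_pos + k_neg equals the binary degree
  snet <- generate_synthetic(20, 0.3, signed = TRUE, seed = 4)
  dg <- degrees(snet)
  expect_equal(dg$k_pos + dg$k_neg, rowSums(snet$weights != 0))
  # directed strength balance
  dnet <- generate_synthetic(20, 0.2, directed = TRUE, seed = 5)
  st <- strengths(dnet)
  expect_equal(sum(st$s_in), sum(st$s_out))
})

test_that("dense and edge-list round trips are lossless", {
  dir <- withr::local_tempdir()
  cases <- list(
    und = generate_synthetic(12, 0.4, seed = 1),
    dir = generate_synthetic(12, 0.3, directed = TRUE, seed = 2),
    sgn = generate_synthetic(12, 0.4, signed = TRUE, seed = 3)
  )
  for (nm in names(cases)) {
    net <- cases[[nm]]
    for (fmt in c("dense", "edgelist")) {
      p <- file.path(dir, paste0(nm, ".", fmt))
      write_network(net, p, format = fmt)
      back <- read_network(p, format = fmt, directed = net$directed,
                           signed = net$signed)
      expect_identical(back$weights, net$weights,
                       label = paste(nm, fmt, "weights"))
    }
  }
})

test_that("edge lists are symmetrized and reject duplicates and self-loops", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "el.tsv")
  writeLines(c("source\ttarget\tweight", "0\t1\t2.0", "1\t2\t3.0"), p)
  net <- read_network(p, format = "edgelist")
  expect_equal(net$weights[1, 2], 2)
  expect_equal(net$weights[2, 1], 2)
  expect_equal(net$weights[2, 3], 3)
  expect_equal(net$weights[3, 2], 3)

  writeLines(c("0\t1\t2.0", "1\t0\t3.0"), p)
  expect_error(read_network(p, format = "edgelist"), "duplicate")
  writeLines(c("1\t1\t2.0"), p)
  expect_error(read_network(p, format = "edgelist"), "self-loop")
})

test_that("dense reader rejects malformed matrices", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  writeLines(c("0,1,2", "1,0,3"), p)
  expect_error(read_network(p), "square")
  writeLines(c("0,NaN", "NaN,0"), p)
  expect_error(read_network(p), "NaN|non-numeric")
  # whitespace-delimited dialect autodetected
  writeLines(c("0 1", "1 0"), p)
  expect_equal(read_network(p)$weights[1, 2], 1)
  # header row becomes labels
  writeLines(c("a,b", "0,1", "1,0"), p)
  expect_equal(read_network(p)$labels, c("a", "b"))
})

test_that("synthetic generator hits the requested density and is deterministic", {
  a <- generate_synthetic(50, 0.2, seed = 7)
  b <- generate_synthetic(50, 0.2, seed = 7)
  expect_identical(a$weights, b$weights)
  expect_equal(edge_count(a), round(0.2 * 50 * 49 / 2))

  full <- generate_synthetic(10, 1.0, seed = 1)
  expect_equal(degrees(full)$degree, rep(9, 10))

  sparse <- generate_synthetic(200, 0.05, connected = TRUE, seed = 11)
  expect_true(is_connected(sparse))
  dirnet <- generate_synthetic(40, 0.1, directed = TRUE, connected = TRUE,
                               seed = 12)
  expect_true(is_connected(dirnet))
  expect_error(generate_synthetic(100, 0.001, connected = TRUE, seed = 1),
               "too low")
})

test_that("log-normal weights match the analytic mean at large edge counts", {
  net <- generate_synthetic(150, 0.9, weight_dist = "lognormal",
                            dist_params = list(meanlog = 0, sdlog = 1),
                            connected = FALSE, seed = 21)
  w <- sorted_weights(net)
  expect_gt(length(w), 1e4)
  analytic_mean <- exp(0.5)
  analytic_sd <- sqrt((exp(1) - 1) * exp(1))
  se <- analytic_sd / sqrt(length(w))
  expect_lt(abs(mean(w) - analytic_mean), 3 * se)
})

test_that("ensemble round trip preserves networks, seeds and manifest", {
  dir <- withr::local_tempdir()
  net <- generate_synthetic(20, 0.3, seed = 1)
  ens <- generate_ensemble(net, "sa", n_nulls = 3,
                           annealing = annealing_config(n_stages = 5),
                           seed = 99)
  write_ensemble(ens, file.path(dir, "ens"))
  expect_true(file.exists(file.path(dir, "ens", "manifest.json")))
  expect_length(list.files(file.path(dir, "ens"), pattern = "^null_.*csv$"), 3)
  back <- read_ensemble(file.path(dir, "ens"))
  expect_equal(back$algorithm, "sa")
  expect_equal(length(back$networks), 3)
  for (i in 1:3) {
    expect_identical(back$networks[[i]]$weights, ens$networks[[i]]$weights)
  }
  expect_equal(vapply(back$traces, `[[`, numeric(1), "final_energy"),
               vapply(ens$traces, `[[`, numeric(1), "final_energy"))
})
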