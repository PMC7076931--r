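test_that("community_spec validates parameters", {
  expect_error(community_spec(0, "pln"), "S")
  expect_error(community_spec(10, "pln", sigma = 0), "sigma")
  expect_error(community_spec(10, "nb", k = -1), "m and k")
  expect_error(community_spec(10, "mixture",
                              components = list(list(mu = 0, sigma = 1,
                                                     weight = 0.6))),
               "sum to 1")
})

test_that("simulate_sad is seeded, zero-truncated and tracks its rates", {
  spec <- community_spec(500, "pln", mu = 1, sigma = 1.2)
  a <- simulate_sad(spec, seed = 4)
  b <- simulate_sad(spec, seed = 4)
  expect_identical(as.integer(a), as.integer(b))
  expect_true(all(a >= 1))
  # degenerate sigma: counts are Poisson(e^mu = 1) conditioned positive
  d <- simulate_sad(community_spec(20000, "pln", mu = 0, sigma = 1e-8),
                    seed = 5)
  em <- mean(as.integer(d))
  expect_lt(abs(em - 1 / (1 - exp(-1))), 0.02)  # E[N | N>0] = 1/(1-e^-1)
  # latent rates recover mu: mean log lambda ~ mu within 3 SE
  spec2 <- community_spec(2000, "pln", mu = 1, sigma = 1.5)
  s2 <- simulate_sad(spec2, seed = 6)
  lam <- attr(s2, "lambda")
  expect_equal(length(lam), 2000)
  expect_lt(abs(mean(log(lam)) - 1), 3 * 1.5 / sqrt(2000))
})

test_that("simulate_otu_table hits depth exactly and is mean-unbiased", {
  comm <- setNames(c(50, 30, 15, 5), paste0("o", 1:4))
  tab <- simulate_otu_table(comm, n_samples = 6, depth = 500, seed = 1)
  expect_equal(unname(rowSums(tab$counts)), rep(500, 6))
  # overdispersion = 0: per-OTU mean proportions match community proportions
  sims <- vapply(1:100, function(s)
    colMeans(simulate_otu_table(comm, 2, 1000, overdispersion = 0,
                                seed = s)$counts / 1000), numeric(4))
  p <- comm / sum(comm)
  se <- sqrt(p * (1 - p) / (1000 * 200))
  expect_true(all(abs(rowMeans(sims)[names(comm)] - p) < 3.5 * se))
})

test_that("plant_cooccurrence preserves depth and plants signed structure", {
  fx <- make_network_fixture(seed = 11)
  expect_identical(rowSums(fx$planted$counts), rowSums(fx$unplanted$counts))
  rel <- fx$planted$counts / rowSums(fx$planted$counts)
  for (i in seq_len(nrow(fx$pairs))) {
    r <- cor(rel[, fx$pairs$otuA[i]], rel[, fx$pairs$otuB[i]])
    if (fx$pairs$sign[i] == "positive") expect_gt(r, 0.8) else expect_lt(r, 0)
  }
  # strength 0 leaves the table unchanged
  tab <- fx$unplanted
  pairs0 <- data.frame(otuA = "otu00001", otuB = "otu00002",
                       sign = "positive", strength = 0)
  expect_identical(plant_cooccurrence(tab, pairs0, seed = 1)$counts,
                   tab$counts)
  bad <- data.frame(otuA = "nope", otuB = "otu00002", sign = "positive",
                    strength = 1)
  expect_error(plant_cooccurrence(tab, bad, seed = 1), "unknown OTU")
})

test_that("simulate_env reproduces richness exactly at zero noise and plants
           a correlated decoy pair", {
  rich <- c(10, 20, 30, 25, 15)
  env <- simulate_env(5, c("a", "b"), c(a = 1), rich, noise_sd = 0, seed = 1)
  expect_equal(env$a, rich)
  env2 <- simulate_env(60, paste0("p", 1:8), c(p8 = 2, p7 = -1),
                       rnorm(60, 100, 10), noise_sd = 1, seed = 2)
  cp <- attr(env2, "correlated_pair")
  expect_gt(abs(cor(env2[[cp[1]]], env2[[cp[2]]])), 0.6)
  # the linear predictor reproduces richness up to the stated noise
  rich2 <- rnorm(60, 100, 10)
  env3 <- simulate_env(60, paste0("p", 1:8), c(p8 = 2, p7 = -1), rich2,
                       noise_sd = 1, seed = 3)
  resid <- rich2 - (2 * env3$p8 - env3$p7)
  expect_lt(sd(resid), 1.5)
  expect_gt(sd(resid), 0.5)
  # determinism
  r2 <- rnorm(60, 100, 10)
  e1 <- simulate_env(60, paste0("p", 1:8), c(p1 = 1), r2, 0.5, seed = 7)
  e2 <- simulate_env(60, paste0("p", 1:8), c(p1 = 1), r2, 0.5, seed = 7)
  expect_identical(e1, e2)
})

test_that("generated SADs are right-skewed (median < mean) when heavy", {
  skew_ok <- vapply(1:50, function(s) {
    a <- simulate_sad(community_spec(400, "pln", mu = 1, sigma = 1.5),
                      seed = s)
    median(as.integer(a)) < mean(as.integer(a))
  }, logical(1))
  expect_true(all(skew_ok))
  skew_nb <- vapply(1:50, function(s) {
    a <- simulate_sad(community_spec(400, "nb", m = 20, k = 0.5), seed = s)
    median(as.integer(a)) < mean(as.integer(a))
  }, logical(1))
  expect_true(all(skew_nb))
})

test_that("well-separated mixtures produce multimodal octave histograms", {
  # both humps interior: a component at mu ~ 0 piles species into octaves
  # 0-1 almost evenly, which the prominence rule scores as one flat mode
  comps <- list(list(mu = 1.2, sigma = 0.7, weight = 0.5),
                list(mu = 7.2, sigma = 0.7, weight = 0.5))
  hits <- vapply(1:50, function(s) {
    a <- simulate_sad(community_spec(600, "mixture", components = comps),
                      seed = s)
    m <- count_modes(octave_bin(a))
    !is.na(m) && m >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("make_fixture bundles are valid and byte-identically reproducible", {
  cfg <- fixture_config()
  # shrink for test runtime
  cfg$domains <- lapply(cfg$domains, function(d) {
    d$S <- max(80, d$S %/% 10); d$samples_per_site <- 2; d$depth <- 800; d
  })
  b <- make_fixture(cfg, seed = 3)
  for (tab in b$tables) expect_silent(validate_otu_table(tab))
  expect_identical(sort(names(b$tables)),
                   c("archaea", "bacteria", "eukarya"))
  # ground-truth ids resolve
  pp <- b$truth$planted_pairs
  expect_true(all(c(pp$otuA, pp$otuB) %in%
                    colnames(b$tables[[cfg$planted_pairs$domain]]$counts)))
  expect_true(all(rownames(b$env) %in%
                    b$tables$bacteria$metadata$sample_id))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(make_fixture(cfg, seed = 3), d1)
  write_fixture(make_fixture(cfg, seed = 3), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})
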