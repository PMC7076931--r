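test_that("pln_pmf matches the adaptive-quadrature oracle on the grid", {
  for (mu in c(-1, 0, 1, 3)) for (sigma in c(0.5, 1, 2)) {
    p <- pln_pmf(c(0L, 1L, 5L, 50L, 500L), mu, sigma)
    o <- vapply(c(0, 1, 5, 50, 500), pln_oracle, numeric(1),
                mu = mu, sigma = sigma)
    expect_true(all(abs(p - o) < 1e-8),
                info = sprintf("mu=%g sigma=%g", mu, sigma))
  }
  expect_error(pln_pmf(1, 0, -1), "sigma")
})

test_that("pln_pmf degenerate limit and normalization", {
  expect_equal(pln_pmf(2, 0, 1e-6), exp(-1) / 2, tolerance = 1e-4)
  expect_equal(sum(pln_pmf(0:5000, 1, 1.5)), 1, tolerance = 1e-6)
})

test_that("nb_pmf closed form, Poisson limit and normalization", {
  expect_equal(nb_pmf(0, m = 2, k = 1), 1 / 3, tolerance = 1e-12)
  # dual route: hand-rolled log-space formula vs stats::dnbinom
  ns <- 0:50
  expect_equal(nb_pmf(ns, m = 7.3, k = 0.42),
               dnbinom(ns, size = 0.42, mu = 7.3), tolerance = 1e-12)
  expect_true(all(abs(nb_pmf(0:10, m = 1, k = 1e6) - dpois(0:10, 1)) < 1e-4))
  expect_equal(sum(nb_pmf(0:100000, 5, 0.5)), 1, tolerance = 1e-10)
  expect_error(nb_pmf(1, -1, 1))
})

test_that("zero truncation renormalizes and rejects n = 0", {
  expect_error(truncated_pmf(0, "nb", m = 2, k = 1), "undefined")
  # hand case: nb(1; 2, 1) / (1 - nb(0)) = (1/3 * 2/3) / (2/3) = 1/3
  expect_equal(truncated_pmf(1, "nb", m = 2, k = 1), 1 / 3,
               tolerance = 1e-12)
  expect_equal(sum(truncated_pmf(1:100000, "nb", m = 5, k = 0.5)), 1,
               tolerance = 1e-9)
  expect_equal(sum(truncated_pmf(1:3000, "pln", mu = 0.5, sigma = 1)), 1,
               tolerance = 1e-6)
})

test_that("fit_sad recovers truncated-PLN parameters and honours contracts", {
  av <- simulate_sad(community_spec(2000, "pln", mu = 1, sigma = 1.5),
                     seed = 1)
  f <- fit_sad(av, "pln")
  expect_true(f$converged)
  expect_gt(f$params[["mu"]], 0.9); expect_lt(f$params[["mu"]], 1.1)
  expect_gt(f$params[["sigma"]], 1.4); expect_lt(f$params[["sigma"]], 1.6)
  expect_equal(f$AIC, 2 * 2 - 2 * f$logLik)
  # optimizer contract: the optimum beats every deterministic start
  x <- as.integer(av); u <- sort(unique(x)); w <- tabulate(match(x, u))
  ll <- function(mu, sg) sum(w * (pln_pmf(u, mu, sg, log = TRUE) -
                                    log1p(-pln_pmf(0L, mu, sg))))
  starts <- list(c(mean(log(x)), sd(log(x))),
                 c(mean(log(x)) - 0.5, sd(log(x)) * 1.5))
  for (s in starts) expect_gte(f$logLik, ll(s[1], s[2]))
  # small-data rule
  small <- fit_sad(abundance_vector(c(a = 3L, b = 1L, c = 9L)), "pln")
  expect_false(small$converged)
  expect_true(is.na(small$AIC))
  expect_error(fit_sad(integer(0), "pln"), "empty")
})

test_that("akaike_weights: symmetry, direct formula, NA propagation", {
  mkfit <- function(fam, aic, conv = TRUE) {
    structure(list(family = fam, params = c(1, 1), logLik = (2 * 2 - aic) / 2,
                   n_params = 2L, AIC = if (conv) aic else NA_real_,
                   converged = conv, n_species = 100L, truncated = TRUE,
                   group = "g"), class = "sad_fit")
  }
  eq <- akaike_weights(mkfit("pln", 100), mkfit("nb", 100))
  expect_equal(eq$wPLN, 0.5); expect_equal(eq$wNB, 0.5)
  w <- akaike_weights(mkfit("pln", 100), mkfit("nb", 110))
  expect_lt(abs(w$wPLN - 0.99331), 5e-6)   # printed precision
  expect_lt(abs(w$wNB - 0.00669), 5e-6)
  expect_equal(w$wPLN + w$wNB, 1)
  # invariance under adding a constant to both AICs
  w2 <- akaike_weights(mkfit("pln", 1100), mkfit("nb", 1110))
  expect_equal(w2$wPLN, w$wPLN)
  nac <- akaike_weights(mkfit("pln", 100), mkfit("nb", 90, conv = FALSE))
  expect_true(is.na(nac$wPLN) && is.na(nac$wNB))
  expect_error(akaike_weights(mkfit("nb", 1), mkfit("nb", 2)), "PLN")
})

test_that("octave_bin uses floor(log2 n) and conserves species", {
  h <- octave_bin(c(1, 1, 2, 3, 4, 8))
  expect_equal(h$count, c(2, 2, 1, 1))
  expect_equal(sum(h$count), attr(h, "n_species"))
  singles <- octave_bin(rep(1, 7))
  expect_equal(singles$octave, 0)
  expect_equal(singles$count, 7)
  expect_error(octave_bin(integer(0)), "empty")
})

test_that("count_modes follows the prominence rule", {
  expect_equal(count_modes(c(0.1, 0.4, 0.3, 0.15, 0.05)), 1)
  expect_equal(count_modes(c(0.3, 0.1, 0.05, 0.25, 0.3)), 2)
  expect_equal(count_modes(rep(0.2, 5)), 1)       # plateau counts once
  expect_true(is.na(count_modes(c(0.5, 0.5))))    # too few octaves
  # a bump below the prominence threshold does not count
  # (normalized: peak 0.203 over flanking min 0.182, prominence 0.021 < 0.05)
  expect_equal(count_modes(c(0.5, 0.28, 0.26, 0.29, 0.1),
                           min_prominence = 0.05), 1)
})

test_that("fit_sad_suite selects the generating family and emits curves", {
  # PLN ground truth, two clear-scale groups
  cfg <- fixture_config()
  cfg$regions <- list(north = c("n1", "n2"), south = c("s1", "s2"))
  cfg$domains <- list(
    bacteria = list(S = 1200, samples_per_site = 4, depth = 4000,
                    overdispersion = 0.15,
                    sad = list(north = list(model = "pln", mu = 0.5, sigma = 2),
                               south = list(model = "pln", mu = 0.5, sigma = 2))))
  cfg$planted_pairs <- NULL
  b <- make_fixture(cfg, seed = 21)
  suite <- fit_sad_suite(b$tables$bacteria, "regional")
  expect_true(all(suite$comparisons$wPLN > 0.95))
  # NB ground truth
  cfg$domains$bacteria$sad <- list(north = list(model = "nb", m = 20, k = 0.5),
                                   south = list(model = "nb", m = 20, k = 0.5))
  b2 <- make_fixture(cfg, seed = 22)
  suite2 <- fit_sad_suite(b2$tables$bacteria, "regional")
  expect_true(all(suite2$comparisons$wNB > 0.95))
  # fitted octave proportions sum to 1 (cutoff at 1 - 1e-9)
  oct <- suite$octaves
  for (g in unique(oct$group)) {
    expect_equal(sum(oct$fitted_pln[oct$group == g], na.rm = TRUE), 1,
                 tolerance = 1e-6)
    expect_equal(sum(oct$observed_proportion[oct$group == g]), 1,
                 tolerance = 1e-8)
  }
  # local scale pools by site
  local <- fit_sad_suite(subset_otu_table(
    b$tables$bacteria, samples = b$tables$bacteria$metadata$site == "n1"),
    "local")
  expect_equal(local$comparisons$group, "n1")
})

test_that("PLN beats NB in likelihood on PLN data (sanity, 50 seeds)", {
  wins <- vapply(1:50, function(s) {
    av <- simulate_sad(community_spec(1500, "pln", mu = 0.5, sigma = 1.5),
                       seed = 400 + s)
    fit_sad(av, "pln")$logLik >= fit_sad(av, "nb")$logLik
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
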