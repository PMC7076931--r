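test_that("mic trivial cases: monotone 1, constant 0, symmetry, guards", {
  x <- seq_len(100)
  expect_equal(mic(x, exp(0.1 * x)), 1, tolerance = 1e-9)
  expect_equal(mic(x, rep(3.5, 100)), 0)
  set.seed(1)
  a <- rnorm(30); b <- rnorm(30)
  expect_identical(mic(a, b), mic(b, a))
  expect_error(mic(1:3, 1:3), "at least 4")
  expect_error(mic(1:10, 1:9), "equal length")
})

test_that("mic is invariant under strictly monotone transforms", {
  set.seed(2)
  for (n in c(12, 40)) {
    x <- rnorm(n); y <- x + rnorm(n, 0, 0.6)
    m0 <- mic(x, y)
    expect_equal(mic(exp(x), y), m0, tolerance = 1e-12)
    expect_equal(mic(x, rank(y)), m0, tolerance = 1e-12)
    expect_equal(mic(-x, y^3 + 2), m0, tolerance = 1e-12)
  }
})

test_that("mic equals the exhaustive both-axes oracle for n <= 12", {
  set.seed(5)
  for (r in 1:15) {
    n <- sample(6:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(mic(x, y, b_max = 6), mic_exhaustive_oracle(x, y, 6),
                 tolerance = 1e-9)
  }
  # tied values cannot be split by grid lines
  for (r in 1:5) {
    x <- sample(1:4, 10, TRUE); y <- sample(1:3, 10, TRUE)
    expect_equal(mic(x, y, b_max = 6), mic_exhaustive_oracle(x, y, 6),
                 tolerance = 1e-9)
  }
})

test_that("mic dominates any fixed equipartition grid", {
  set.seed(6)
  for (r in 1:10) {
    x <- rnorm(50); y <- 0.5 * x + rnorm(50)
    B <- 50^0.6
    m <- mic(x, y)
    for (nx in 2:floor(B / 2)) {
      ny <- floor(B / nx)
      expect_gte(m + 1e-9, mic_equipartition_grid(x, y, nx, ny))
    }
  }
})

test_that("pairwise_mic returns all unordered pairs with signs", {
  fx <- make_network_fixture(n_background = 4, n_positive = 1,
                             n_negative = 1, n_samples = 20, depth = 2000,
                             seed = 3)
  res <- pairwise_mic(fx$planted)
  k <- ncol(fx$planted$counts)
  expect_equal(nrow(res), k * (k - 1) / 2)
  rk <- paste(res$otuA, res$otuB)
  pos <- fx$pairs[fx$pairs$sign == "positive", ]
  i <- match(paste(pos$otuA, pos$otuB), rk)
  expect_gt(res$mic[i], 0.8)
  expect_identical(res$sign[i], "positive")
  neg <- fx$pairs[fx$pairs$sign == "negative", ]
  j <- match(paste(neg$otuA, neg$otuB), rk)
  expect_identical(res$sign[j], "negative")
  # duplicated OTU column gives mic 1 with its twin
  tab <- fx$planted
  cnt <- cbind(tab$counts, zzdup = tab$counts[, 1])
  tab2 <- otu_table(cnt, tab$metadata$site, tab$metadata$region,
                    tab$metadata$domain)
  res2 <- pairwise_mic(tab2)
  twin <- res2[res2$otuB == "zzdup" & res2$otuA == colnames(tab$counts)[1], ]
  expect_equal(twin$mic, 1, tolerance = 1e-9)
  expect_error(pairwise_mic(subset_otu_table(tab, samples = 1:3)),
               "at least 4 samples")
})

test_that("permutation p-values: bounds, floor for perfect pairs,
           near-uniform under independence", {
  fx <- make_network_fixture(n_background = 4, n_positive = 1,
                             n_negative = 0, n_samples = 24, depth = 3000,
                             strength = 3, seed = 9)
  tab <- fx$planted
  # identical column pair: no null can exceed mic = 1, p = 1/(n_perm+1)
  cnt <- cbind(tab$counts, zzdup = tab$counts[, 1])
  tab2 <- otu_table(cnt, tab$metadata$site, tab$metadata$region,
                    tab$metadata$domain)
  p <- permutation_pvalues(tab2, data.frame(otuA = colnames(tab$counts)[1],
                                            otuB = "zzdup"),
                           n_perm = 199, seed = 1)
  expect_equal(p, 1 / 200)
  expect_error(permutation_pvalues(tab2, data.frame(otuA = "a", otuB = "b"),
                                   n_perm = 50), "n_perm")
  # independent OTUs: p approximately uniform over many pairs
  set.seed(10)
  m <- matrix(rpois(30 * 25, 40), 30, 25,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("o%02d", 1:25)))
  ind <- otu_table(m, "A", "r1", "bacteria")
  pairs <- as.data.frame(t(combn(colnames(m), 2)))
  names(pairs) <- c("otuA", "otuB")
  pv <- permutation_pvalues(ind, pairs[1:200, ], n_perm = 99, seed = 2)
  expect_true(all(pv > 0 & pv <= 1))
  ks <- max(abs(sort(pv) - seq_along(pv) / length(pv)))
  expect_lt(ks, 0.1)
})

test_that("BH adjustment: hand case, monotonicity, edge cases", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(0.04, 5)), rep(0.04, 5))
  set.seed(3)
  p <- runif(50)
  adj <- adjust_pvalues(p)
  expect_identical(adj, p.adjust(p, "BH"))   # independent implementation
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_identical(adjust_pvalues(p, "bonferroni"), p.adjust(p, "bonferroni"))
})

test_that("build_network filters edges and excludes isolated OTUs", {
  res <- data.frame(otuA = c("a", "a", "b"), otuB = c("b", "c", "c"),
                    mic = c(0.95, 0.85, 0.5),
                    sign = c("positive", "negative", "positive"),
                    p = c(0.001, 0.2, 0.001), p_adj = c(0.001, 0.3, 0.001))
  net <- build_network(res)
  expect_equal(net$topology$n_edges, 1)
  expect_setequal(net$nodes$otu, c("a", "b"))  # c is isolated, excluded
  # no pair passes
  none <- build_network(transform(res, p_adj = 1))
  expect_equal(none$topology$n_nodes, 0)
  expect_equal(none$topology$n_components, 0)
  expect_true(is.na(none$topology$characteristic_path_length))
  # thresholds wide open: complete graph
  all_net <- build_network(transform(res, p_adj = 0.5), mic_threshold = 0,
                           p_threshold = 1)
  expect_equal(all_net$topology$n_edges, 3)
  expect_equal(all_net$topology$avg_neighbours, 2)
})

test_that("edge sets shrink monotonically as thresholds tighten", {
  fx <- make_network_fixture(seed = 13)
  res <- pairwise_mic(fx$planted)
  res$p_adj <- res$p <- 0.0005
  sizes <- vapply(c(0, 0.5, 0.8, 0.95),
                  function(th) nrow(build_network(res, th)$edges), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("topology follows NetworkAnalyzer conventions", {
  mknet <- function(a, b) {
    ids <- sort(unique(c(a, b)))
    build_network(data.frame(otuA = a, otuB = b, mic = 0.9,
                             sign = "positive", p = 1e-3, p_adj = 1e-3))
  }
  tri <- mknet(c("a", "b", "c"), c("b", "c", "a"))$topology
  expect_equal(tri$clustering_coefficient, 1)
  expect_equal(tri$characteristic_path_length, 1)
  expect_equal(tri$diameter, 1)
  expect_equal(tri$n_components, 1)
  expect_equal(tri$avg_neighbours, 2)
  path4 <- mknet(c("a", "b", "c"), c("b", "c", "d"))$topology
  expect_equal(path4$clustering_coefficient, 0)
  expect_equal(path4$diameter, 3)
  expect_equal(path4$characteristic_path_length, 10 / 6, tolerance = 1e-12)
  two <- mknet(c("a", "c"), c("b", "d"))$topology
  expect_equal(two$n_components, 2)
  expect_equal(two$avg_neighbours, 1)
})

test_that("cooccurrence_null_test is seeded and detects planted structure", {
  fx <- make_network_fixture(n_background = 5, n_positive = 2,
                             n_negative = 1, n_samples = 24, depth = 3000,
                             seed = 17)
  r1 <- cooccurrence_null_test(fx$planted, n_perm = 99, seed = 4)
  r2 <- cooccurrence_null_test(fx$planted, n_perm = 99, seed = 4)
  expect_identical(r1, r2)
  expect_equal(r1$p, 1 / 100)     # heavily planted: minimum attainable
  expect_gte(r1$observed, 2)
  r3 <- cooccurrence_null_test(fx$unplanted, n_perm = 99, seed = 4)
  expect_gt(r3$p, 0.05)
})

test_that("network writers emit TSV, SIF and GraphML", {
  res <- data.frame(otuA = c("a", "b"), otuB = c("b", "c"), mic = c(0.9, 0.85),
                    sign = c("positive", "negative"),
                    p = 1e-3, p_adj = 1e-3)
  net <- build_network(res)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, "tsv")
  expect_equal(nrow(read.delim(tsv)), 2)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(net, sif, "sif")
  expect_setequal(readLines(sif), c("a cooccurs_pos b", "b cooccurs_neg c"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
})
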