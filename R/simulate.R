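# Synthetic-data generator: communities with known SAD family, a multinomial
# sequencing layer, planted co-occurring OTU pairs, and environmental
# covariates with known effects on richness. Everything downstream is
# testable against this ground truth without any sequencing data.

#' Specify a generative community
#'
#' @param S number of species in the regional pool (`>= 1`).
#' @param model `"pln"`, `"nb"` or `"mixture"` (mixture of PLN components).
#' @param mu,sigma PLN parameters (`sigma > 0`).
#' @param m,k NB mean and dispersion (`> 0`).
#' @param components for mixtures: list of `list(mu=, sigma=, weight=)`;
#'   weights must sum to 1.
#' @return a `community_spec`.
#' @export
community_spec <- function(S, model = c("pln", "nb", "mixture"),
                           mu = 0, sigma = 1, m = 10, k = 1,
                           components = NULL) {
  model <- match.arg(model)
  if (S < 1) stop("S must be >= 1")
  if (model == "pln" && sigma <= 0) stop("sigma must be > 0")
  if (model == "nb" && (m <= 0 || k <= 0)) stop("m and k must be > 0")
  if (model == "mixture") {
    if (is.null(components) || length(components) < 1)
      stop("mixture requires components")
    wsum <- sum(vapply(components, `[[`, numeric(1), "weight"))
    if (abs(wsum - 1) > 1e-8) stop("mixture weights must sum to 1")
    if (any(vapply(components, `[[`, numeric(1), "sigma") <= 0))
      stop("sigma must be > 0 in every component")
  }
  structure(list(S = as.integer(S), model = model, mu = mu, sigma = sigma,
                 m = m, k = k, components = components),
            class = "community_spec")
}

#' Draw a species abundance vector from a community spec
#'
#' Every family is sampled as Poisson counts over latent per-species rates:
#' PLN draws `lambda_i ~ LogNormal(mu, sigma)`, NB draws
#' `lambda_i ~ Gamma(k, k/m)` (the gamma-Poisson construction of the
#' negative binomial), and mixtures assign species to lognormal components
#' by weight. Zero draws are discarded: the community is defined over
#' observed species. The full latent rate vector is kept as attribute
#' `"lambda"` (named for all S species) — downstream table simulation
#' samples from these rates, which is what keeps the pooled SAD within the
#' generating family under multinomial sequencing effort.
#'
#' @param spec a [community_spec()].
#' @param seed optional integer seed.
#' @return an [abundance_vector()] named `otu00001..`, with attribute
#'   `lambda`.
#' @export
simulate_sad <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  .with_seed(seed, {
    S <- spec$S
    lambda <- switch(spec$model,
      pln = rlnorm(S, spec$mu, spec$sigma),
      nb = stats::rgamma(S, shape = spec$k, rate = spec$k / spec$m),
      mixture = {
        w <- vapply(spec$components, `[[`, numeric(1), "weight")
        comp <- sample.int(length(w), S, replace = TRUE, prob = w)
        mus <- vapply(spec$components, `[[`, numeric(1), "mu")[comp]
        sds <- vapply(spec$components, `[[`, numeric(1), "sigma")[comp]
        rlnorm(S, mus, sds)
      })
    names(lambda) <- sprintf("otu%05d", seq_len(S))
    n <- rpois(S, lambda)
    names(n) <- names(lambda)
    keep <- n > 0
    if (!any(keep)) stop("all species drew zero counts; increase mu/m or S")
    av <- abundance_vector(n[keep], group = "community", group_by = "community")
    attr(av, "lambda") <- lambda
    av
  })
}

#' Simulate an OTU table by (over-dispersed) multinomial resampling
#'
#' Emulates the sequencing layer: per sample, the community's relative
#' abundances are perturbed by lognormal noise with log-sd `overdispersion`,
#' renormalized, and a multinomial of size `depth` is drawn. With
#' `overdispersion = 0` the expected per-OTU proportions equal the community
#' proportions.
#'
#' @param community an [abundance_vector()] (named).
#' @param n_samples number of samples (`>= 1`).
#' @param depth reads per sample (`>= 1`).
#' @param overdispersion lognormal log-sd of per-sample proportion noise.
#' @param seed optional integer seed.
#' @param site,region,domain metadata labels for the generated samples.
#' @param sample_prefix prefix for generated sample ids.
#' @return an `otu_table`.
#' @export
simulate_otu_table <- function(community, n_samples, depth,
                               overdispersion = 0, seed = NULL,
                               site = "site1", region = "region1",
                               domain = "bacteria",
                               sample_prefix = paste0(site, "_s")) {
  if (n_samples < 1 || depth < 1) stop("n_samples and depth must be >= 1")
  if (is.null(names(community))) stop("community must be a named vector")
  .with_seed(seed, {
    p <- community / sum(community)
    S <- length(p)
    cnt <- matrix(0L, n_samples, S,
                  dimnames = list(sprintf("%s%02d", sample_prefix,
                                          seq_len(n_samples)),
                                  names(community)))
    for (i in seq_len(n_samples)) {
      q <- if (overdispersion > 0) {
        w <- p * exp(rnorm(S, 0, overdispersion))
        w / sum(w)
      } else p
      cnt[i, ] <- rmultinom(1, depth, q)[, 1]
    }
    otu_table(cnt, site, region, domain)
  })
}

#' Plant co-occurring OTU pairs into a table
#'
#' For each pair, every sample's counts of both OTUs are rescaled by a shared
#' latent lognormal factor (log-sd `strength`); for negative pairs the second
#' OTU gets the reciprocal factor. Rows are then rescaled to their original
#' depth and re-rounded by largest remainders, so per-sample totals are
#' preserved exactly. `strength = 0` leaves the table unchanged.
#'
#' @param table an `otu_table`.
#' @param pairs data.frame with columns `otuA`, `otuB`, `sign`
#'   (`"positive"`/`"negative"`) and `strength` (lognormal log-sd, `>= 0`).
#' @param seed optional integer seed.
#' @return an `otu_table` with the same shape and per-sample totals.
#' @export
plant_cooccurrence <- function(table, pairs, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  need <- c("otuA", "otuB", "sign", "strength")
  if (!all(need %in% names(pairs)))
    stop("pairs needs columns ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(c(pairs$otuA, pairs$otuB)), colnames(table$counts))
  if (length(unknown) > 0)
    stop("unknown OTU id(s): ", paste(unknown, collapse = ", "))
  if (!all(pairs$sign %in% c("positive", "negative")))
    stop("sign must be 'positive' or 'negative'")
  .with_seed(seed, {
    cnt <- table$counts
    x <- matrix(as.double(cnt), nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
    tot <- rowSums(cnt)
    for (j in seq_len(nrow(pairs))) {
      s <- pairs$strength[j]
      f <- rlnorm(nrow(x), 0, s)   # rlnorm(.,0,0) == 1, so strength 0 is a no-op
      a <- pairs$otuA[j]; b <- pairs$otuB[j]
      x[, a] <- x[, a] * f
      x[, b] <- x[, b] * (if (pairs$sign[j] == "positive") f else 1 / f)
    }
    for (i in seq_len(nrow(x))) {
      if (sum(x[i, ]) == 0) next
      x[i, ] <- .round_to_total(x[i, ] * tot[i] / sum(x[i, ]), tot[i])
    }
    storage.mode(x) <- "integer"
    otu_table(x, table$metadata$site, table$metadata$region,
              table$metadata$domain, taxonomy = table$taxonomy)
  })
}

# largest-remainder rounding to an exact integer total (deterministic ties)
.round_to_total <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    frac <- x - fl
    idx <- order(-frac, seq_along(x))[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Simulate environmental covariates with known effects on richness
#'
#' Constructs a covariate table such that the linear predictor of
#' `true_effects` reproduces the supplied `richness` vector up to Gaussian
#' noise of sd `noise_sd`: decoy and secondary true predictors are drawn
#' N(0,1), and the first true predictor is solved for. The first two decoy
#' predictors are built mutually correlated (rho = 0.85) to exercise
#' covariate pruning.
#'
#' @param n_samples number of rows.
#' @param predictors character vector of column names.
#' @param true_effects named numeric vector of coefficients; names must be a
#'   subset of `predictors`.
#' @param richness numeric response vector of length `n_samples`.
#' @param noise_sd Gaussian noise sd.
#' @param seed optional integer seed.
#' @param sample_ids optional row names.
#' @return data.frame of covariates with attributes `true_effects` and
#'   `correlated_pair`.
#' @export
simulate_env <- function(n_samples, predictors, true_effects, richness,
                         noise_sd = 0, seed = NULL, sample_ids = NULL) {
  if (length(richness) != n_samples)
    stop("richness must have length n_samples")
  if (!all(names(true_effects) %in% predictors))
    stop("true_effects names must be among predictors")
  if (length(true_effects) < 1) stop("need at least one true effect")
  .with_seed(seed, {
    env <- as.data.frame(matrix(rnorm(n_samples * length(predictors)),
                                n_samples, length(predictors),
                                dimnames = list(NULL, predictors)))
    decoys <- setdiff(predictors, names(true_effects))
    corr_pair <- NULL
    if (length(decoys) >= 2) {
      corr_pair <- decoys[1:2]
      env[[corr_pair[2]]] <- 0.85 * env[[corr_pair[1]]] +
        sqrt(1 - 0.85^2) * rnorm(n_samples)
    }
    tr <- names(true_effects)
    eps <- if (noise_sd > 0) rnorm(n_samples, 0, noise_sd) else 0
    others <- if (length(tr) > 1)
      as.matrix(env[, tr[-1], drop = FALSE]) %*% true_effects[tr[-1]]
    else 0
    env[[tr[1]]] <- (richness - others - eps) / true_effects[tr[1]]
    if (!is.null(sample_ids)) rownames(env) <- sample_ids
    attr(env, "true_effects") <- true_effects
    attr(env, "correlated_pair") <- corr_pair
    env
  })
}

#' Default configuration for the two-region, nine-site synthetic bundle
#'
#' Emulates the study layout at desk scale: regions `vestfold_hills` (sites
#' AF, HV, OW, RL, TR) and `windmill_islands` (BP, HI, MP, RR); three domains
#' with very different richness; right-skewed SADs; per-domain sequencing
#' depths 10000 / 2000 / 5000.
#'
#' @return nested list of generator settings.
#' @export
fixture_config <- function() {
  list(
    regions = list(
      vestfold_hills = c("AF", "HV", "OW", "RL", "TR"),
      windmill_islands = c("BP", "HI", "MP", "RR")),
    domains = list(
      bacteria = list(S = 2500, samples_per_site = 8, depth = 10000,
                      overdispersion = 0.3,
                      sad = list(vestfold_hills = list(model = "pln", mu = 1,
                                                       sigma = 2),
                                 windmill_islands = list(model = "pln", mu = 1,
                                                         sigma = 2.4))),
      eukarya = list(S = 300, samples_per_site = 4, depth = 2000,
                     overdispersion = 0.3,
                     sad = list(vestfold_hills = list(model = "nb", m = 25,
                                                      k = 0.5),
                                windmill_islands = list(model = "pln", mu = 1.5,
                                                        sigma = 1.8))),
      archaea = list(S = 120, samples_per_site = 4, depth = 5000,
                     overdispersion = 0.3,
                     sad = list(vestfold_hills = list(model = "pln", mu = 2,
                                                      sigma = 1.8),
                                windmill_islands = list(model = "pln", mu = 2,
                                                        sigma = 2)))),
    planted_pairs = list(domain = "bacteria", region = "vestfold_hills",
                         n_positive = 5, n_negative = 2, strength = 1.5),
    env = list(
      predictors = c("pH", "conductivity", "TC", "TN", "TP", "P", "Cu", "Al",
                     "Al2O3", "TiO2", "CECCa", "CECNa", "NO2_NO3", "DMF",
                     "gravel", "mud"),
      true_effects = c(TP = 120, Cu = -90, gravel = 60),
      noise_sd = 40)
  )
}

#' Assemble the full synthetic fixture bundle
#'
#' Builds one regional community per domain x region, draws per-site sample
#' tables from it, plants co-occurring pairs into the configured table, and
#' constructs an environment table whose known effects explain per-sample
#' bacterial Chao1 richness. All randomness flows from `seed` through
#' deterministic per-stage sub-seeds.
#'
#' @param config a list shaped like [fixture_config()].
#' @param seed master integer seed.
#' @return a `fixture_bundle`: list with `tables` (one `otu_table` per
#'   domain), `env` (data.frame) and `truth` (SAD model per region x domain,
#'   planted pairs, true env effects).
#' @export
make_fixture <- function(config = fixture_config(), seed = 1) {
  tables <- list()
  truth <- list(sad = list(), planted_pairs = NULL, env_effects = NULL)
  stage <- 0L
  for (dom in names(config$domains)) {
    dc <- config$domains[[dom]]
    site_tabs <- list()
    for (reg in names(config$regions)) {
      sadc <- dc$sad[[reg]]
      spec <- do.call(community_spec, c(list(S = dc$S), sadc))
      stage <- stage + 1L
      comm <- simulate_sad(spec, seed = .sub_seed(seed, stage))
      rates <- attr(comm, "lambda")  # sample from latent rates, not counts
      truth$sad[[paste(dom, reg, sep = ".")]] <-
        c(list(domain = dom, region = reg), sadc)
      for (site in config$regions[[reg]]) {
        stage <- stage + 1L
        site_tabs[[site]] <- simulate_otu_table(
          rates, dc$samples_per_site, dc$depth,
          overdispersion = dc$overdispersion, seed = .sub_seed(seed, stage),
          site = site, region = reg, domain = dom,
          sample_prefix = paste0(dom, "_", site, "_s"))
      }
    }
    tables[[dom]] <- combine_otu_tables(site_tabs)
  }
  pp <- config$planted_pairs
  if (!is.null(pp) && (pp$n_positive + pp$n_negative) > 0) {
    tab <- tables[[pp$domain]]
    in_reg <- tab$metadata$region == pp$region
    sub <- tab$counts[in_reg, , drop = FALSE]
    # plant on mid-rank OTUs: abundant enough to survive the filter and the
    # top-N network screen, but individually minor so their shared factors
    # do not couple the rest of the table through the compositional
    # normalization
    rank <- names(sort(colSums(sub), decreasing = TRUE))
    npair <- pp$n_positive + pp$n_negative
    top <- rank[seq(11L, 10L + 2L * npair)]
    pairs <- data.frame(
      otuA = top[seq(1, 2 * npair, by = 2)],
      otuB = top[seq(2, 2 * npair, by = 2)],
      sign = rep(c("positive", "negative"), c(pp$n_positive, pp$n_negative)),
      strength = pp$strength, stringsAsFactors = FALSE)
    stage <- stage + 1L
    planted <- plant_cooccurrence(subset_otu_table(tab, samples = in_reg),
                                  pairs, seed = .sub_seed(seed, stage))
    rest <- subset_otu_table(tab, samples = !in_reg)
    tables[[pp$domain]] <- combine_otu_tables(list(planted, rest))
    truth$planted_pairs <- pairs
  }
  envc <- config$env
  rich <- sample_chao1(tables$bacteria)
  stage <- stage + 1L
  env <- simulate_env(length(rich), envc$predictors, envc$true_effects,
                      as.numeric(rich), noise_sd = envc$noise_sd,
                      seed = .sub_seed(seed, stage), sample_ids = names(rich))
  env$region <- tables$bacteria$metadata$region[
    match(rownames(env), tables$bacteria$metadata$sample_id)]
  truth$env_effects <- as.list(envc$true_effects)
  structure(list(tables = tables, env = env, truth = truth,
                 seed = seed, config = config),
            class = "fixture_bundle")
}

#' Write a fixture bundle to disk (QIIME-classic TSV + CSV + JSON truth)
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_all <- list()
  for (dom in names(bundle$tables)) {
    tab <- bundle$tables[[dom]]
    write_otu_table(tab, file.path(dir, paste0("otu_table_", dom, ".tsv")))
    meta_all[[dom]] <- tab$metadata
  }
  meta <- do.call(rbind, c(meta_all, make.row.names = FALSE))
  write.table(meta, file.path(dir, "sample_metadata.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  env <- cbind(sample_id = rownames(bundle$env), bundle$env)
  write.table(env, file.path(dir, "env_table.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Build a compact single-region fixture for network testing
#'
#' The community has two tiers: abundant "background" OTUs carrying most of
#' the reads, and minor planted OTUs (about 1% of reads each) that receive
#' the shared latent co-occurrence factors. Keeping planted OTUs minor stops
#' their fluctuations from propagating through the compositional
#' normalization into spurious correlations among the rest. An unplanted
#' twin drawn from the same community supports null calibration.
#'
#' @param n_background abundant background OTUs.
#' @param n_samples samples.
#' @param depth reads per sample.
#' @param n_positive,n_negative planted pair counts.
#' @param strength lognormal log-sd of the shared latent factor.
#' @param overdispersion per-sample lognormal proportion noise.
#' @param seed master seed.
#' @return list with `planted` (`otu_table`), `unplanted` (`otu_table`) and
#'   `pairs` (the planted pair table).
#' @export
make_network_fixture <- function(n_background = 10, n_samples = 40,
                                 depth = 8000, n_positive = 5, n_negative = 2,
                                 strength = 1.5, overdispersion = 0.15,
                                 seed = 1) {
  npair <- n_positive + n_negative
  n_otus <- n_background + 2L * npair
  comm <- .with_seed(.sub_seed(seed, 1L), {
    bg <- rlnorm(n_background, meanlog = 6, sdlog = 0.4)
    minor <- rlnorm(2L * npair, meanlog = 4, sdlog = 0.2)
    setNames(pmax(1L, as.integer(round(c(minor, bg)))),
             sprintf("otu%05d", seq_len(n_otus)))
  })
  av <- abundance_vector(comm, group = "network", group_by = "community")
  base <- simulate_otu_table(av, n_samples, depth,
                             overdispersion = overdispersion,
                             seed = .sub_seed(seed, 2L), site = "netsite",
                             region = "netregion", domain = "bacteria")
  ids <- sprintf("otu%05d", seq_len(2L * npair))
  pairs <- data.frame(
    otuA = ids[seq(1, 2 * npair, by = 2)],
    otuB = ids[seq(2, 2 * npair, by = 2)],
    sign = rep(c("positive", "negative"), c(n_positive, n_negative)),
    strength = strength, stringsAsFactors = FALSE)
  planted <- plant_cooccurrence(base, pairs, seed = .sub_seed(seed, 3L))
  unplanted <- simulate_otu_table(av, n_samples, depth,
                                  overdispersion = overdispersion,
                                  seed = .sub_seed(seed, 4L), site = "netsite",
                                  region = "netregion", domain = "bacteria")
  list(planted = planted, unplanted = unplanted, pairs = pairs)
}
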