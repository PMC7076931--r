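# End-to-end orchestration: simulate (or load) -> rarefy -> filter -> SAD
# fits -> diversity -> co-occurrence network -> richness models, from a
# single config with one master seed split deterministically per stage.

#' Default pipeline configuration
#'
#' All knobs in one list. `input_dir = NULL` simulates the bundled synthetic
#' fixture; otherwise OTU tables, metadata and environment tables are read
#' from the directory (same layout [write_fixture()] produces).
#'
#' @param seed master seed.
#' @param input_dir optional directory of input tables.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, input_dir = NULL) {
  structure(list(
    seed = seed,
    input_dir = input_dir,
    fixture = fixture_config(),
    rarefy_depths = list(bacteria = 8000, eukarya = 1500, archaea = 4000),
    filter_threshold_pct = 0.001,
    sad_scale = "regional",
    sad_truncated = TRUE,
    mic = list(alpha = 0.6, c = 15, mic_threshold = 0.8, p_threshold = 0.001,
               n_perm = 999, max_otus = 40,
               adjust_method = "benjamini_hochberg",
               network_domain = "bacteria", network_region = "vestfold_hills",
               null_test = TRUE, null_n_perm = 199),
    model_families = list(bacteria = "negative_binomial", eukarya = "gaussian",
                          archaea = "gaussian"),
    chao1_variant = "bias_corrected"
  ), class = "pipeline_config")
}

#' Read a pipeline config from JSON (or YAML when available)
#'
#' Fields present in the file override the defaults of [pipeline_config()].
#'
#' @param path path to a `.json` (or `.yaml`/`.yml`) config file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  cfg
}

.validate_config <- function(config) {
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config validation: seed must be a single integer")
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop("config validation: input_dir does not exist: ", config$input_dir)
  invisible(config)
}

.stage <- function(name, log, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(name, sprintf("%.1fs", proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Writes per-stage outputs (TSV/JSON) plus a run manifest to `out_dir`.
#' Reruns with the same config and seed produce byte-identical outputs.
#'
#' @param config a `pipeline_config` (or path to a config file).
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message("[sadmine] ", paste(...))
  seed <- as.integer(config$seed)

  bundle <- .stage("input", log, {
    if (is.null(config$input_dir)) {
      b <- make_fixture(config$fixture, seed = seed)
      write_fixture(b, file.path(out_dir, "fixture"))
      b
    } else {
      md <- read_sample_metadata(file.path(config$input_dir,
                                           "sample_metadata.csv"))
      tabs <- list()
      for (f in list.files(config$input_dir, pattern = "^otu_table_.*\\.tsv$")) {
        dom <- sub("^otu_table_(.*)\\.tsv$", "\\1", f)
        tabs[[dom]] <- read_otu_table(file.path(config$input_dir, f), md)
      }
      env <- read_env_table(file.path(config$input_dir, "env_table.csv"))
      env$region <- md$region[match(rownames(env), md$sample_id)]
      list(tables = tabs, env = env, truth = NULL)
    }
  })

  rarefied <- .stage("rarefy", log, {
    out <- list()
    for (dom in names(bundle$tables)) {
      depth <- config$rarefy_depths[[dom]]
      out[[dom]] <- if (is.null(depth)) bundle$tables[[dom]]
        else suppressWarnings(rarefy(bundle$tables[[dom]], depth,
                                     seed = .sub_seed(seed, 101L)))
    }
    out
  })

  # the >0.001% screen applies to the network input only; SAD fits and
  # diversity use all rarefied OTUs
  filtered <- .stage("filter", log, {
    out <- list()
    for (dom in names(rarefied)) {
      per_region <- lapply(sort(unique(rarefied[[dom]]$metadata$region)),
        function(reg) filter_rel_abundance(
          subset_otu_table(rarefied[[dom]],
                           samples = rarefied[[dom]]$metadata$region == reg),
          config$filter_threshold_pct))
      out[[dom]] <- combine_otu_tables(per_region)
    }
    out
  })

  sad <- .stage("sadfit", log, {
    rows <- list(); octs <- list()
    for (dom in names(rarefied)) {
      suite <- fit_sad_suite(rarefied[[dom]], scale = config$sad_scale,
                             truncated = config$sad_truncated)
      suite$comparisons$domain <- dom
      suite$octaves$domain <- dom
      rows[[dom]] <- suite$comparisons
      octs[[dom]] <- suite$octaves
    }
    comp <- do.call(rbind, c(rows, make.row.names = FALSE))
    oct <- do.call(rbind, c(octs, make.row.names = FALSE))
    write_results(comp[, c("domain", "group", "wPLN", "wNB", "delta_AIC",
                           "n_species")],
                  file.path(out_dir, "sad_weights.tsv"), "tsv")
    write_results(oct, file.path(out_dir, "sad_octaves.tsv"), "tsv")
    list(comparisons = comp, octaves = oct)
  })

  div <- .stage("diversity", log, {
    ch <- list()
    for (dom in names(rarefied))
      ch[[dom]] <- data.frame(
        domain = dom,
        sample_id = rownames(rarefied[[dom]]$counts),
        site = rarefied[[dom]]$metadata$site,
        region = rarefied[[dom]]$metadata$region,
        chao1 = unname(sample_chao1(rarefied[[dom]], config$chao1_variant)),
        stringsAsFactors = FALSE)
    chao <- do.call(rbind, c(ch, make.row.names = FALSE))
    write_results(chao, file.path(out_dir, "chao1.tsv"), "tsv")
    corr <- cross_domain_correlations(rarefied)
    if (!is.null(corr))
      write_results(corr, file.path(out_dir, "richness_correlations.tsv"),
                    "tsv")
    list(chao1 = chao, correlations = corr)
  })

  net <- .stage("network", log, {
    mc <- config$mic
    dom <- mc$network_domain
    tab <- filtered[[dom]]
    tab <- subset_otu_table(tab,
                            samples = tab$metadata$region == mc$network_region,
                            drop_empty_otus = TRUE)
    res <- pairwise_mic(tab, config$filter_threshold_pct,
                        alpha = mc$alpha, c = mc$c, max_otus = mc$max_otus)
    cand <- which(res$mic > mc$mic_threshold)
    res$p <- NA_real_; res$p_adj <- NA_real_
    if (length(cand) > 0) {
      pv <- permutation_pvalues(attr(res, "table"), res[cand, ],
                                n_perm = mc$n_perm,
                                seed = .sub_seed(seed, 201L),
                                alpha = mc$alpha, c = mc$c)
      res$p[cand] <- pv
      res$p_adj[cand] <- adjust_pvalues(pv, mc$adjust_method)
    }
    domains <- setNames(rep(tab$metadata$domain[1], ncol(tab$counts)),
                        colnames(tab$counts))
    network <- build_network(res, mc$mic_threshold, mc$p_threshold,
                             domains = domains)
    write_results(as.data.frame(res), file.path(out_dir, "mic_pairs.tsv"),
                  "tsv")
    write_network(network, file.path(out_dir, "network_edges.tsv"), "tsv")
    write_network(network, file.path(out_dir, "network.sif"), "sif")
    write_results(network$topology, file.path(out_dir, "network_topology.json"),
                  "json")
    nt <- NULL
    if (isTRUE(mc$null_test)) {
      nt <- cooccurrence_null_test(attr(res, "table"), mc$mic_threshold,
                                   n_perm = mc$null_n_perm,
                                   seed = .sub_seed(seed, 202L),
                                   alpha = mc$alpha, c = mc$c)
      write_results(list(p = nt$p, observed = nt$observed),
                    file.path(out_dir, "network_null_test.json"), "json")
    }
    list(results = res, network = network, null_test = nt)
  })

  models <- .stage("models", log, {
    env <- bundle$env
    pruned <- prune_covariates(env[, setdiff(names(env), "region"),
                                   drop = FALSE])
    penv <- pruned$env
    penv$region <- factor(env$region)
    # env rows describe soil samples keyed by the (bacterial) sample ids;
    # the other domains are subsamples of the same soils, so pair their
    # samples to env rows by site + within-site rank
    soil_key <- function(tab) {
      md <- tab$metadata
      paste(md$site, stats::ave(seq_along(md$site), md$site, FUN = seq_along),
            sep = "#")
    }
    env_key <- soil_key(bundle$tables$bacteria)[
      match(rownames(penv), bundle$tables$bacteria$metadata$sample_id)]
    fits <- list()
    for (dom in names(rarefied)) {
      fam <- config$model_families[[dom]] %||% "gaussian"
      rich <- sample_chao1(rarefied[[dom]], config$chao1_variant)
      dk <- soil_key(rarefied[[dom]])
      hit <- match(dk, env_key)
      keep <- !is.na(hit)
      if (sum(keep) < 10) next
      fits[[dom]] <- suppressMessages(
        stepwise_aic(rich[keep], penv[hit[keep], , drop = FALSE], fam))
    }
    summary <- summarize_best_models(fits)
    write_results(summary, file.path(out_dir, "model_summary.tsv"), "tsv")
    write_results(pruned$removed, file.path(out_dir, "pruned_covariates.tsv"),
                  "tsv")
    list(fits = fits, summary = summary, pruned = pruned$removed)
  })

  manifest <- list(package = "sadmine",
                   version = as.character(utils::packageVersion("sadmine")),
                   seed = seed,
                   config = config[setdiff(names(config), "fixture")],
                   stages = c("input", "rarefy", "filter", "sadfit",
                              "diversity", "network", "models"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done")
  invisible(list(bundle = bundle, rarefied = rarefied, filtered = filtered,
                 sad = sad, diversity = div, network = net, models = models))
}

#' Command-line entry point
#'
#' Subcommands map 1:1 to module operations: `simulate`, `rarefy`, `sadfit`,
#' `chao1`, `network`, `model`, `all`. Run via the bundled launcher:
#' `Rscript inst/cli/sadmine.R <subcommand> --help`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sadmine <command> [options]",
    "commands:",
    "  simulate  --out DIR [--seed N]        write the synthetic fixture",
    "  rarefy    --in DIR --out DIR --depth N [--seed N]",
    "  sadfit    --in DIR --out DIR [--scale regional|local]",
    "  chao1     --in DIR --out DIR",
    "  network   --in DIR --out DIR [--mic-threshold X] [--p-threshold X]",
    "            [--n-perm N] [--seed N]",
    "  model     --in DIR --out DIR [--family gaussian|negative_binomial]",
    "  all       --out DIR [--config FILE] [--seed N]   full pipeline",
    sep = "\n")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- .parse_cli_opts(args[-1])
  status <- tryCatch({
    switch(cmd,
      simulate = {
        b <- make_fixture(seed = as.integer(opt$seed %||% 1))
        write_fixture(b, opt$out)
      },
      all = {
        cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
               else pipeline_config(seed = as.integer(opt$seed %||% 1))
        if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
        run_pipeline(cfg, opt$out)
      },
      rarefy = {
        tabs <- .cli_read_tables(opt$`in`)
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        for (dom in names(tabs)) {
          r <- rarefy(tabs[[dom]], as.integer(opt$depth),
                      seed = as.integer(opt$seed %||% 1))
          write_otu_table(r, file.path(opt$out,
                                       paste0("otu_table_", dom, ".tsv")))
        }
      },
      sadfit = {
        tabs <- .cli_read_tables(opt$`in`)
        rows <- lapply(names(tabs), function(dom) {
          s <- fit_sad_suite(tabs[[dom]], scale = opt$scale %||% "regional")
          s$comparisons$domain <- dom
          s$comparisons
        })
        write_results(do.call(rbind, rows),
                      file.path(opt$out, "sad_weights.tsv"), "tsv")
      },
      chao1 = {
        tabs <- .cli_read_tables(opt$`in`)
        rows <- lapply(names(tabs), function(dom)
          data.frame(domain = dom,
                     sample_id = rownames(tabs[[dom]]$counts),
                     chao1 = unname(sample_chao1(tabs[[dom]]))))
        write_results(do.call(rbind, rows), file.path(opt$out, "chao1.tsv"),
                      "tsv")
      },
      network = {
        tabs <- .cli_read_tables(opt$`in`)
        tab <- tabs[[1]]
        res <- pairwise_mic(tab, max_otus = 40)
        thr <- as.numeric(opt$`mic-threshold` %||% 0.8)
        cand <- which(res$mic > thr)
        res$p <- NA_real_; res$p_adj <- NA_real_
        if (length(cand) > 0) {
          pv <- permutation_pvalues(attr(res, "table"), res[cand, ],
                                    n_perm = as.integer(opt$`n-perm` %||% 999),
                                    seed = as.integer(opt$seed %||% 1))
          res$p[cand] <- pv
          res$p_adj[cand] <- adjust_pvalues(pv)
        }
        net <- build_network(res, thr,
                             as.numeric(opt$`p-threshold` %||% 0.001))
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        write_network(net, file.path(opt$out, "network_edges.tsv"), "tsv")
        write_results(net$topology,
                      file.path(opt$out, "network_topology.json"), "json")
      },
      model = {
        tabs <- .cli_read_tables(opt$`in`)
        env <- read_env_table(file.path(opt$`in`, "env_table.csv"))
        md <- read_sample_metadata(file.path(opt$`in`, "sample_metadata.csv"))
        env$region <- factor(md$region[match(rownames(env), md$sample_id)])
        fits <- list()
        for (dom in names(tabs)) {
          rich <- sample_chao1(tabs[[dom]])
          shared <- intersect(names(rich), rownames(env))
          if (length(shared) < 10) next
          pr <- prune_covariates(env[shared, setdiff(names(env), "region")])
          penv <- pr$env
          penv$region <- env$region[match(shared, rownames(env))]
          fits[[dom]] <- stepwise_aic(rich[shared], penv,
                                      opt$family %||% "gaussian")
        }
        write_results(summarize_best_models(fits),
                      file.path(opt$out, "model_summary.tsv"), "tsv")
      },
      { cat(usage, "\n"); stop("unknown command: ", cmd) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}

.cli_read_tables <- function(dir) {
  if (is.null(dir) || !dir.exists(dir)) stop("--in directory not found")
  md_path <- file.path(dir, "sample_metadata.csv")
  md <- if (file.exists(md_path)) read_sample_metadata(md_path) else NULL
  files <- list.files(dir, pattern = "^otu_table_.*\\.tsv$")
  if (length(files) == 0) stop("no otu_table_*.tsv in ", dir)
  tabs <- lapply(files, function(f) read_otu_table(file.path(dir, f), md))
  names(tabs) <- sub("^otu_table_(.*)\\.tsv$", "\\1", files)
  tabs
}
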