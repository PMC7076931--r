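# Co-occurrence networks from maximal-information-coefficient associations:
# pairwise MIC on relative abundances, permutation significance,
# Benjamini-Hochberg correction, edge filtering (MIC > 0.8, adjusted
# p <= 0.001) and NetworkAnalyzer-convention topology summaries.

#' Maximal information coefficient of two vectors
#'
#' Maximum over grid shapes `(nx, ny)` with `nx * ny <= B(n) = n^alpha` of
#' the grid mutual information normalized by `log2(min(nx, ny))`. For
#' `n <= exact_n` the search over grids is exhaustive (complete enumeration
#' of row partitions plus an exact column dynamic program); for larger n the
#' published heuristic is used: equipartition one axis, optimize the other
#' by dynamic programming over at most `c * nx` clump boundaries, applied
#' symmetrically with the max taken.
#'
#' @param x,y numeric vectors of equal length `n >= 4`; ties allowed.
#' @param alpha grid-budget exponent, `B(n) = n^alpha` (default 0.6).
#' @param c clump factor (default 15).
#' @param b_max optional hard cap on the grid budget B (overrides `n^alpha`).
#' @param exact force exhaustive (`TRUE`) or heuristic (`FALSE`) search;
#'   default `NULL` chooses exhaustive for `n <= 16`.
#' @return MIC score in `[0, 1]`.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15, b_max = NULL, exact = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (is.null(exact)) exact <- n <= 16
  mic_cpp(as.numeric(x), as.numeric(y), alpha, as.integer(c),
          if (is.null(b_max)) -1 else as.numeric(b_max), isTRUE(exact))
}

.rel_abundance <- function(table) {
  tot <- rowSums(table$counts)
  tot[tot == 0] <- 1
  table$counts / tot
}

#' Pairwise MIC between all OTUs of a table
#'
#' Computes MIC on per-sample relative abundances for every unordered OTU
#' pair surviving the relative-abundance screen. Edge sign comes from the
#' Pearson correlation of the same relative abundances (zero correlation
#' gives a positive sign with a warning).
#'
#' @param table an `otu_table` with `>= 4` samples.
#' @param min_rel_abundance_pct OTU screen passed to
#'   [filter_rel_abundance()] (default 0.001, i.e. >0.001%).
#' @param alpha,c MIC parameters, see [mic()].
#' @param max_otus optional cap: keep only the `max_otus` most abundant OTUs
#'   after the screen (runtime guard for desk-scale tables; `NULL` = no cap).
#' @return data.frame of class `mic_results`: `otuA`, `otuB`, `mic`, `sign`;
#'   `p` and `p_adj` columns are added by [permutation_pvalues()] /
#'   [adjust_pvalues()].
#' @export
pairwise_mic <- function(table, min_rel_abundance_pct = 0.001,
                         alpha = 0.6, c = 15, max_otus = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (nrow(table$counts) < 4) stop("need at least 4 samples")
  tab <- filter_rel_abundance(table, min_rel_abundance_pct)
  if (!is.null(max_otus) && ncol(tab$counts) > max_otus) {
    keep <- names(sort(colSums(tab$counts), decreasing = TRUE))[
      seq_len(max_otus)]
    tab <- subset_otu_table(tab, otus = sort(keep))
  }
  rel <- .rel_abundance(tab)
  k <- ncol(rel)
  if (k < 2) stop("fewer than 2 OTUs after filtering")
  idx <- combn(k, 2)
  mics <- mic_pairwise_cpp(rel, idx[1, ], idx[2, ], alpha, as.integer(c),
                           -1, nrow(rel) <= 16)
  pear <- vapply(seq_len(ncol(idx)), function(j) {
    a <- rel[, idx[1, j]]; b <- rel[, idx[2, j]]
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }, numeric(1))
  if (any(pear == 0))
    warning("zero Pearson correlation for ", sum(pear == 0),
            " pair(s); sign set to positive")
  out <- data.frame(otuA = colnames(rel)[idx[1, ]],
                    otuB = colnames(rel)[idx[2, ]],
                    mic = mics,
                    sign = ifelse(pear < 0, "negative", "positive"),
                    stringsAsFactors = FALSE)
  attr(out, "table") <- tab
  attr(out, "mic_params") <- list(alpha = alpha, c = c)
  class(out) <- c("mic_results", "data.frame")
  out
}

#' Permutation p-values for MIC associations
#'
#' The null is generated by permuting each OTU's sample order independently;
#' `p = (b + 1) / (n_perm + 1)` with `b` the number of null MIC values
#' `>=` the observed one, so p is never 0 and never exceeds 1.
#'
#' @param table the `otu_table` the MIC values were computed on (relative
#'   abundances are recomputed internally).
#' @param pairs data.frame with `otuA`, `otuB` (typically a subset of
#'   [pairwise_mic()] rows — in the pipeline, the MIC-screened candidates).
#' @param n_perm number of permutations, `>= 99` (default 999).
#' @param seed optional integer seed.
#' @param alpha,c MIC parameters.
#' @return numeric vector of p-values, one per pair row.
#' @export
permutation_pvalues <- function(table, pairs, n_perm = 999, seed = NULL,
                                alpha = 0.6, c = 15) {
  stopifnot(inherits(table, "otu_table"))
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (nrow(pairs) == 0) return(numeric(0))
  rel <- .rel_abundance(table)
  ai <- match(pairs$otuA, colnames(rel))
  bi <- match(pairs$otuB, colnames(rel))
  if (anyNA(ai) || anyNA(bi)) stop("pair OTU ids not in table")
  .with_seed(seed,
    mic_perm_pvalues_cpp(rel, ai, bi, alpha, as.integer(c),
                         as.integer(n_perm), nrow(rel) <= 16))
}

#' Adjust p-values for multiple testing
#'
#' Step-up Benjamini-Hochberg (default) or Bonferroni; adjusted values are
#' monotone in the raw values and capped at 1.
#'
#' @param p numeric vector of p-values.
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @return adjusted p-values in the original order.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  m <- length(p)
  if (m == 0) return(p)
  if (method == "bonferroni") return(pmin(1, p * m))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Build a co-occurrence network from MIC results
#'
#' Edges require `mic > mic_threshold` and adjusted `p <= p_threshold` (rows
#' lacking an adjusted p never become edges); OTUs without any passing edge
#' are excluded from the node set.
#'
#' @param results a `mic_results` data.frame carrying `mic`, `sign` and
#'   (for candidate rows) `p_adj`.
#' @param mic_threshold minimum MIC, strict (default 0.8).
#' @param p_threshold maximum adjusted p (default 0.001).
#' @param domains optional named character vector OTU id -> domain label.
#' @return a `cooccurrence_network`: list with `nodes` (otu, domain,
#'   degree), `edges` and `topology` (see [topology_stats()]).
#' @export
build_network <- function(results, mic_threshold = 0.8, p_threshold = 0.001,
                          domains = NULL) {
  need <- c("otuA", "otuB", "mic", "sign")
  if (!all(need %in% names(results)))
    stop("results needs columns ", paste(need, collapse = ", "))
  pa <- if ("p_adj" %in% names(results)) results$p_adj else
    rep(NA_real_, nrow(results))
  pass <- results$mic > mic_threshold & !is.na(pa) & pa <= p_threshold
  edges <- results[pass, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$otuA, edges$otuB)))
  deg <- table(factor(c(edges$otuA, edges$otuB), levels = ids))
  nodes <- data.frame(otu = ids,
                      domain = if (is.null(domains))
                                 rep(NA_character_, length(ids))
                               else unname(domains[ids]),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = as.data.frame(edges),
                        mic_threshold = mic_threshold,
                        p_threshold = p_threshold),
                   class = "cooccurrence_network")
  net$topology <- topology_stats(net)
  net
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("otuA", "otuB"), drop = FALSE], directed = FALSE,
    vertices = net$nodes$otu)
}

#' Topology summary of a co-occurrence network
#'
#' Conventions follow the undirected NetworkAnalyzer treatment: the
#' clustering coefficient is the mean over nodes of the local clustering
#' coefficient with degree-<2 nodes contributing 0; the characteristic path
#' length averages shortest paths over connected pairs only; the diameter is
#' the longest finite shortest path; average neighbours = 2 E / N. An empty
#' network reports 0 nodes/edges/components and NA for the metrics.
#'
#' @param net a `cooccurrence_network`.
#' @return list: `n_nodes`, `n_edges`, `clustering_coefficient`,
#'   `avg_neighbours`, `characteristic_path_length`, `diameter`,
#'   `n_components`.
#' @export
topology_stats <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nn <- nrow(net$nodes); ne <- nrow(net$edges)
  if (nn == 0)
    return(list(n_nodes = 0L, n_edges = 0L,
                clustering_coefficient = NA_real_, avg_neighbours = NA_real_,
                characteristic_path_length = NA_real_, diameter = NA_real_,
                n_components = 0L))
  g <- .as_igraph(net)
  cc <- mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  list(n_nodes = as.integer(nn), n_edges = as.integer(ne),
       clustering_coefficient = cc,
       avg_neighbours = 2 * ne / nn,
       characteristic_path_length = igraph::mean_distance(g, directed = FALSE),
       diameter = igraph::diameter(g, directed = FALSE),
       n_components = igraph::components(g)$no)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  t <- x$topology
  cat("cooccurrence_network:", t$n_nodes, "nodes,", t$n_edges, "edges,",
      t$n_components, "components\n")
  cat("  clustering coefficient =", signif(t$clustering_coefficient, 3),
      "| avg neighbours =", signif(t$avg_neighbours, 3),
      "| char path length =", signif(t$characteristic_path_length, 3),
      "| diameter =", t$diameter, "\n")
  invisible(x)
}

#' Do OTUs co-occur more than expected by chance?
#'
#' Test statistic: the number of unordered OTU pairs with MIC above
#' `mic_threshold` (the binding edge filter on a fixed table; the
#' permutation-p filter cannot be recomputed inside the null without nested
#' permutations). The null rebuilds the statistic on tables where every
#' OTU's sample order is permuted independently; `p = (b+1)/(n_perm+1)`.
#'
#' @param table an `otu_table` (already screened; all its OTUs are used).
#' @param mic_threshold edge threshold (default 0.8).
#' @param n_perm permutations (default 999).
#' @param seed optional integer seed.
#' @param alpha,c MIC parameters.
#' @param max_otus optional abundance cap as in [pairwise_mic()].
#' @return list: `p`, `observed` edge-count, `null_counts`.
#' @export
cooccurrence_null_test <- function(table, mic_threshold = 0.8, n_perm = 999,
                                   seed = NULL, alpha = 0.6, c = 15,
                                   max_otus = NULL) {
  stopifnot(inherits(table, "otu_table"))
  tab <- table
  if (!is.null(max_otus) && ncol(tab$counts) > max_otus) {
    keep <- names(sort(colSums(tab$counts), decreasing = TRUE))[
      seq_len(max_otus)]
    tab <- subset_otu_table(tab, otus = sort(keep))
  }
  rel <- .rel_abundance(tab)
  res <- .with_seed(seed,
    mic_null_edges_cpp(rel, alpha, as.integer(c), mic_threshold,
                       as.integer(n_perm), nrow(rel) <= 16))
  list(p = res$p, observed = res$observed, null_counts = res$null_counts)
}

#' Write a network as edge-list TSV, Cytoscape SIF or GraphML
#'
#' @param net a `cooccurrence_network`.
#' @param path output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooccurrence_network"))
  if (format == "tsv") {
    cols <- intersect(c("otuA", "otuB", "mic", "sign", "p", "p_adj"),
                      names(net$edges))
    write.table(net$edges[, cols, drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    rel <- ifelse(net$edges$sign == "negative", "cooccurs_neg", "cooccurs_pos")
    writeLines(paste(net$edges$otuA, rel, net$edges$otuB), path)
  } else {
    g <- .as_igraph(net)
    igraph::V(g)$domain <- ifelse(is.na(net$nodes$domain), "unknown",
                                  net$nodes$domain)
    if (nrow(net$edges) > 0) {
      igraph::E(g)$mic <- net$edges$mic
      igraph::E(g)$sign <- net$edges$sign
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
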