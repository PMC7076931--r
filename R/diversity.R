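# Chao1 richness, individual-based rarefaction (q = 0) and cross-domain
# richness correlations.

#' Chao1 richness estimate
#'
#' Classic: `S_obs + F1^2 / (2 F2)`; bias-corrected (default, the vegan
#' convention): `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where F1 and F2 are
#' singleton and doubleton counts. When `F2 = 0` the classic form falls back
#' to the bias-corrected one with a message.
#'
#' @param sample_counts integer vector of per-OTU counts `>= 0` for one
#'   sample (or pooled group).
#' @param variant `"bias_corrected"` or `"classic"`.
#' @return a `chao1_estimate`: list with `S_obs`, `F1`, `F2`, `chao1`,
#'   `variant`.
#' @export
chao1 <- function(sample_counts, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  x <- sample_counts
  if (any(!is.finite(x) | x < 0 | x != round(x)))
    stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("all-zero count vector")
  S <- sum(x > 0)
  F1 <- sum(x == 1)
  F2 <- sum(x == 2)
  if (variant == "classic" && F2 == 0) {
    message("F2 = 0: classic Chao1 falls back to the bias-corrected form")
    variant <- "bias_corrected"
  }
  est <- if (variant == "classic") S + F1^2 / (2 * F2)
         else S + F1 * (F1 - 1) / (2 * (F2 + 1))
  structure(list(S_obs = S, F1 = F1, F2 = F2, chao1 = est, variant = variant),
            class = "chao1_estimate")
}

#' @export
print.chao1_estimate <- function(x, ...) {
  cat("Chao1 (", x$variant, "): ", signif(x$chao1, 6),
      "  [S_obs = ", x$S_obs, ", F1 = ", x$F1, ", F2 = ", x$F2, "]\n",
      sep = "")
  invisible(x)
}

#' Per-sample Chao1 richness for an OTU table
#'
#' @param table an `otu_table`.
#' @param variant passed to [chao1()].
#' @return named numeric vector of Chao1 estimates, one per sample.
#' @export
sample_chao1 <- function(table, variant = "bias_corrected") {
  stopifnot(inherits(table, "otu_table"))
  vapply(seq_len(nrow(table$counts)),
         function(i) chao1(table$counts[i, ], variant)$chao1,
         numeric(1)) |>
    setNames(rownames(table$counts))
}

#' Individual-based rarefaction curve (q = 0)
#'
#' Expected richness in a uniform subsample of `m` reads:
#' `E[S_m] = sum_i (1 - C(N - n_i, m) / C(N, m))`, evaluated with log-gamma
#' arithmetic.
#'
#' @param pooled_counts integer vector of per-OTU counts (zeros allowed,
#'   ignored).
#' @param depths integer subsample sizes, each `<= sum(pooled_counts)`.
#' @return a `rarefaction_curve`: data.frame with `depth` and
#'   `expected_richness`.
#' @export
rarefaction_curve <- function(pooled_counts, depths) {
  x <- pooled_counts[pooled_counts > 0]
  if (length(x) == 0) stop("no positive counts")
  N <- sum(x)
  if (any(depths < 1 | depths != round(depths))) stop("depths must be integers >= 1")
  if (any(depths > N)) stop("depth exceeds total reads (", N, ")")
  es <- vapply(depths, function(m) {
    # log C(N-n_i, m) - log C(N, m); C(N-n_i, m) = 0 when m > N - n_i
    ok <- (N - x) >= m
    p <- numeric(length(x))
    p[ok] <- exp(lchoose(N - x[ok], m) - lchoose(N, m))
    sum(1 - p)
  }, numeric(1))
  structure(data.frame(depth = as.integer(depths), expected_richness = es),
            S_obs = length(x), class = c("rarefaction_curve", "data.frame"))
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' `t = R sqrt(n-2) / sqrt(1-R^2)` on `n - 2` degrees of freedom. Used for
#' cross-domain comparisons of pooled Chao1 richness.
#'
#' @param x,y paired numeric vectors of equal length `n >= 3`.
#' @return list with `R`, `P`, `n` (`R = NA` with a warning when either
#'   vector has zero variance).
#' @export
richness_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(R = NA_real_, P = NA_real_, n = n))
  }
  R <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(R) >= 1) return(list(R = R, P = 0, n = n))
  tstat <- R * sqrt(n - 2) / sqrt(1 - R^2)
  list(R = R, P = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Cross-domain Chao1 richness correlations
#'
#' Computes per-sample Chao1 within each domain table, pairs samples across
#' domains by a shared location key derived from the sample id (site plus
#' trailing sample index), and reports Pearson R and P for every domain
#' pair. Samples without a partner are dropped, with the count reported.
#'
#' @param tables named list of `otu_table`s (one per domain).
#' @param key_fun function mapping sample ids + metadata to a pairing key;
#'   the default pairs by `site` and within-site sample rank.
#' @return data.frame: domainA, domainB, n, R, P, dropped.
#' @export
cross_domain_correlations <- function(tables, key_fun = NULL) {
  if (is.null(key_fun))
    key_fun <- function(tab) {
      md <- tab$metadata
      idx <- stats::ave(seq_along(md$site), md$site, FUN = seq_along)
      paste(md$site, idx, sep = "#")
    }
  rich <- lapply(tables, function(tab)
    setNames(sample_chao1(tab), key_fun(tab)))
  doms <- names(tables)
  rows <- list()
  for (i in seq_along(doms)) for (j in seq_along(doms)) {
    if (j <= i) next
    a <- rich[[i]]; b <- rich[[j]]
    shared <- intersect(names(a), names(b))
    dropped <- (length(a) - length(shared)) + (length(b) - length(shared))
    if (dropped > 0)
      message(doms[i], " vs ", doms[j], ": dropped ", dropped,
              " unpaired sample(s)")
    if (length(shared) < 3) next
    cc <- richness_correlation(a[shared], b[shared])
    rows[[length(rows) + 1L]] <- data.frame(
      domainA = doms[i], domainB = doms[j], n = cc$n, R = cc$R, P = cc$P,
      dropped = dropped, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
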