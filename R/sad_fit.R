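# Maximum-likelihood fitting of species abundance distributions and model
# comparison by Akaike weights: the core niche-vs-neutral inference. The
# Poisson-lognormal (PLN) stands in for niche-structured communities, the
# negative binomial (NB) for the neutral comparator. Fits are zero-truncated
# by default: only observed species enter an abundance vector, so the
# likelihood conditions on n >= 1.

#' Fit a species abundance distribution by maximum likelihood
#'
#' Maximizes the (zero-truncated) log-likelihood of a PLN or NB family over
#' a pooled abundance vector with Nelder-Mead, using three deterministic
#' moment-based starts. Scale parameters are optimized on the log scale.
#' Vectors with fewer than 5 species return `converged = FALSE` (fitting is
#' not meaningful on such small data sets), as do optimizer failures and
#' fits whose Hessian is not positive definite at the optimum.
#'
#' @param abundances integer vector of per-species counts `>= 1` (an
#'   [abundance_vector()] or plain vector).
#' @param family `"pln"` or `"nb"`.
#' @param truncated fit the zero-truncated likelihood (default `TRUE`,
#'   matching the observed-species convention; `FALSE` fits the untruncated
#'   family).
#' @return an object of class `sad_fit`: list with `family`, `params`
#'   (named: `mu`,`sigma` or `m`,`k`), `logLik`, `n_params` (2), `AIC`
#'   (`NA` when unconverged), `converged`, `n_species`, `truncated`.
#' @export
fit_sad <- function(abundances, family = c("pln", "nb"), truncated = TRUE) {
  family <- match.arg(family)
  x <- as.integer(abundances)
  if (length(x) == 0L) stop("empty abundance vector")
  if (any(x < 1)) stop("abundances must be >= 1")
  group <- attr(abundances, "group")
  res <- list(family = family, params = c(NA_real_, NA_real_),
              logLik = NA_real_, n_params = 2L, AIC = NA_real_,
              converged = FALSE, n_species = length(x), truncated = truncated,
              group = group)
  names(res$params) <- if (family == "pln") c("mu", "sigma") else c("m", "k")
  class(res) <- "sad_fit"
  if (length(x) < 5L) return(res)

  u <- sort(unique(x))
  w <- tabulate(match(x, u))
  nll <- if (family == "pln") {
    function(th) {
      mu <- th[1]; sigma <- exp(th[2])
      if (!is.finite(sigma) || sigma <= 0 || sigma > 50) return(1e10)
      lp <- pln_pmf(u, mu, sigma, log = TRUE)
      if (truncated) lp <- lp - log1p(-exp(pln_pmf(0L, mu, sigma, log = TRUE)))
      v <- -sum(w * lp)
      if (!is.finite(v)) 1e10 else v
    }
  } else {
    function(th) {
      m <- exp(th[1]); k <- exp(th[2])
      if (!is.finite(m) || !is.finite(k) || k < 1e-8 || m < 1e-8 ||
          k > 1e8 || m > 1e12) return(1e10)
      lp <- nb_pmf(u, m, k, log = TRUE)
      if (truncated) lp <- lp - log1p(-exp(nb_pmf(0L, m, k, log = TRUE)))
      v <- -sum(w * lp)
      if (!is.finite(v)) 1e10 else v
    }
  }

  starts <- .sad_starts(x, family)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10) return(res)
  opt_ok <- best$convergence == 0
  # polish + curvature check at the optimum (the polish pass may stop on
  # maxit without that signalling failure of the overall fit)
  H <- tryCatch(optim(best$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE),
                error = function(e) NULL)
  if (!is.null(H) && H$value <= best$value) best <- H
  # curvature check: reject saddle points (negative curvature) but tolerate
  # the flat ridge the truncated NB develops as k -> 0 (its log-series
  # limit), where the supremum sits on the parameter boundary
  hess_ok <- FALSE
  if (!is.null(H) && all(is.finite(H$hessian))) {
    ev <- eigen(H$hessian, symmetric = TRUE, only.values = TRUE)$values
    hess_ok <- min(ev) > -1e-6 * max(1, abs(max(ev)))
  }
  # NB boundary convergence: as k -> 0 the truncated NB tends to its
  # log-series limit along a flat ridge whose supremum sits on the
  # parameter boundary; the achieved likelihood is a valid sup for AIC
  # comparison even though the curvature test is meaningless there.
  at_boundary <- family == "nb" && exp(best$par[2]) < 1e-6
  conv <- (opt_ok && hess_ok) || (at_boundary && is.finite(best$value))
  th <- best$par
  res$params[] <- if (family == "pln") c(th[1], exp(th[2]))
                  else c(exp(th[1]), exp(th[2]))
  res$logLik <- -best$value
  res$converged <- conv
  res$AIC <- if (conv) 2 * res$n_params - 2 * res$logLik else NA_real_
  res
}

# three deterministic starts from moment estimates plus fixed perturbations
.sad_starts <- function(x, family) {
  if (family == "pln") {
    m1 <- mean(log(x)); s1 <- sd(log(x))
    if (!is.finite(s1) || s1 < 0.1) s1 <- 0.5
    list(c(m1, log(s1)),
         c(m1 - 0.5, log(s1 * 1.5)),
         c(m1 + 0.5, log(max(s1 * 0.6, 0.2))))
  } else {
    m0 <- mean(x)
    v0 <- var(x)
    k0 <- if (is.finite(v0) && v0 > m0) m0^2 / (v0 - m0) else 1
    k0 <- min(max(k0, 1e-3), 1e3)
    list(c(log(m0), log(k0)),
         c(log(m0 * 0.5), log(k0 * 2)),
         c(log(m0 * 2), log(max(k0 * 0.5, 1e-3))))
  }
}

#' @export
print.sad_fit <- function(x, ...) {
  cat("sad_fit [", toupper(x$family), "] ",
      paste(names(x$params), "=", signif(x$params, 4), collapse = ", "),
      "\n  logLik = ", signif(x$logLik, 8), ", AIC = ", signif(x$AIC, 8),
      ", converged = ", x$converged, ", S = ", x$n_species, "\n", sep = "")
  invisible(x)
}

#' Akaike weights for a PLN fit vs an NB fit
#'
#' `delta_i = AIC_i - min(AIC)`; `w_i = exp(-delta_i/2) / sum exp(-delta_j/2)`.
#' If either fit failed to converge both weights are `NA` (the Table-S4
#' convention for small data sets).
#'
#' @param fit_pln,fit_nb `sad_fit` objects for the same abundance vector.
#' @return a `model_comparison` list: `group`, `wPLN`, `wNB`, `delta_AIC`
#'   (AIC_PLN - AIC_NB), `converged`.
#' @export
akaike_weights <- function(fit_pln, fit_nb) {
  stopifnot(inherits(fit_pln, "sad_fit"), inherits(fit_nb, "sad_fit"))
  if (fit_pln$family != "pln" || fit_nb$family != "nb")
    stop("expected one PLN fit and one NB fit, in that order")
  if (!identical(fit_pln$group, fit_nb$group))
    stop("fits are for different groups: ", fit_pln$group, " vs ", fit_nb$group)
  out <- list(group = fit_pln$group, wPLN = NA_real_, wNB = NA_real_,
              delta_AIC = NA_real_, converged = FALSE)
  class(out) <- "model_comparison"
  if (!fit_pln$converged || !fit_nb$converged) return(out)
  aic <- c(fit_pln$AIC, fit_nb$AIC)
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w <- w / sum(w)
  out$wPLN <- w[1]; out$wNB <- w[2]
  out$delta_AIC <- aic[1] - aic[2]
  out$converged <- TRUE
  out
}

#' Bin abundances into octave classes
#'
#' Species with abundance `n` fall in octave `floor(log2(n))`: octave 0 holds
#' singletons, octave 1 abundances 2-3, octave 2 abundances 4-7, and so on.
#'
#' @param abundances integer vector `>= 1`.
#' @return an `octave_histogram`: data.frame with `octave` (0..max) and
#'   `count`, attribute `n_species`.
#' @export
octave_bin <- function(abundances) {
  x <- as.integer(abundances)
  if (length(x) == 0L) stop("empty abundance vector")
  if (any(x < 1)) stop("abundances must be >= 1")
  oct <- floor(log2(x))
  counts <- tabulate(oct + 1L, nbins = max(oct) + 1L)
  structure(data.frame(octave = seq_along(counts) - 1L, count = counts),
            n_species = length(x), class = c("octave_histogram", "data.frame"))
}

#' Count modes of an octave histogram
#'
#' Operationalizes visual multimodality: the number of local maxima of the
#' proportion-normalized histogram whose prominence (height above the higher
#' of the two flanking minima; for boundary peaks, the single flanking
#' minimum) exceeds `min_prominence`. Plateaus of equal values count once.
#'
#' @param hist an `octave_histogram`, or a numeric vector of octave counts or
#'   proportions.
#' @param min_prominence prominence threshold as a proportion (default 0.05).
#' @return integer mode count, or `NA` when fewer than 3 octaves.
#' @export
count_modes <- function(hist, min_prominence = 0.05) {
  p <- if (inherits(hist, "octave_histogram")) hist$count else as.numeric(hist)
  if (length(p) < 3L) return(NA_integer_)
  p <- p / sum(p)
  # compress plateaus (runs of equal values)
  r <- rle(p)$values
  k <- length(r)
  if (k == 1L) return(1L)
  is_peak <- logical(k)
  for (i in seq_len(k)) {
    up <- i == 1L || r[i] > r[i - 1L]
    down <- i == k || r[i] > r[i + 1L]
    is_peak[i] <- up && down
  }
  peaks <- which(is_peak)
  if (length(peaks) == 0L) return(0L)
  nmodes <- 0L
  for (j in seq_along(peaks)) {
    i <- peaks[j]
    lmin <- if (j == 1L) {
      if (i == 1L) NA_real_ else min(r[1:(i - 1L)])
    } else min(r[(peaks[j - 1L] + 1L):(i - 1L)])
    rmin <- if (j == length(peaks)) {
      if (i == k) NA_real_ else min(r[(i + 1L):k])
    } else min(r[(i + 1L):(peaks[j + 1L] - 1L)])
    flank <- max(lmin, rmin, na.rm = TRUE)  # higher flanking minimum
    if (!is.finite(flank)) flank <- 0
    if (r[i] - flank > min_prominence) nmodes <- nmodes + 1L
  }
  nmodes
}

#' Expected octave proportions under a fitted (truncated) SAD
#'
#' The mass of octave r is the zero-truncated pmf summed over
#' `n in [2^r, 2^(r+1))`. For the PLN this sum is evaluated as a
#' Gauss-Hermite quadrature of Poisson CDF differences over the lognormal
#' rate (the per-n sum telescopes inside the integral, so octaves far in the
#' tail cost no more than early ones); for the NB the CDF difference is
#' closed form. Octaves accumulate until cumulative mass exceeds `1 - 1e-9`.
#'
#' @param fit a converged `sad_fit`.
#' @param max_octave hard cap on the octave index (default 40).
#' @return data.frame with `octave` and `proportion` (zero rows when the fit
#'   did not converge).
#' @keywords internal
expected_octave_proportions <- function(fit, max_octave = 40L) {
  if (!inherits(fit, "sad_fit") || !fit$converged)
    return(data.frame(octave = integer(0), proportion = numeric(0)))
  octave_cdf_mass <- if (fit$family == "pln") {
    mu <- fit$params[["mu"]]; sigma <- fit$params[["sigma"]]
    gh <- gauss_hermite(200L)
    lam <- exp(mu + sqrt(2) * sigma * gh$nodes)
    wts <- gh$weights / sqrt(pi)
    p0 <- sum(wts * dpois(0, lam))
    function(lo, hi)
      sum(wts * (stats::ppois(hi, lam) - stats::ppois(lo - 1, lam))) / (1 - p0)
  } else {
    m <- fit$params[["m"]]; k <- fit$params[["k"]]
    p0 <- nb_pmf(0L, m, k)
    function(lo, hi)
      (stats::pnbinom(hi, size = k, mu = m) -
         stats::pnbinom(lo - 1, size = k, mu = m)) / (1 - p0)
  }
  props <- numeric(0)
  cum <- 0
  for (r in 0:max_octave) {
    mass <- octave_cdf_mass(2^r, 2^(r + 1) - 1)
    props <- c(props, mass)
    cum <- cum + mass
    if (cum > 1 - 1e-9) break
  }
  data.frame(octave = seq_along(props) - 1L, proportion = props)
}

#' Fit PLN and NB SADs to every group of an OTU table
#'
#' Pools abundances at the requested scale (region or site), fits both
#' families per group, combines them into Akaike weights, and emits
#' observed + fitted octave curves.
#'
#' @param table an `otu_table`.
#' @param scale `"regional"` (pool by region) or `"local"` (pool by site).
#' @param truncated zero-truncated likelihoods (default `TRUE`).
#' @return list with `comparisons` (data.frame: group, domain, scale,
#'   n_species, wPLN, wNB, delta_AIC, and the fitted parameters) and
#'   `octaves` (long data.frame: group, octave, observed_proportion,
#'   fitted_pln, fitted_nb).
#' @export
fit_sad_suite <- function(table, scale = c("regional", "local"),
                          truncated = TRUE) {
  scale <- match.arg(scale)
  group_by <- if (scale == "regional") "region" else "site"
  pools <- pool_abundances(table, group_by)
  comp_rows <- list()
  oct_rows <- list()
  for (g in names(pools)) {
    av <- pools[[g]]
    fp <- fit_sad(av, "pln", truncated = truncated)
    fn <- fit_sad(av, "nb", truncated = truncated)
    wc <- akaike_weights(fp, fn)
    comp_rows[[g]] <- data.frame(
      group = g, domain = attr(av, "domain") %||% NA_character_,
      scale = scale, n_species = length(av),
      wPLN = wc$wPLN, wNB = wc$wNB, delta_AIC = wc$delta_AIC,
      pln_mu = fp$params[["mu"]], pln_sigma = fp$params[["sigma"]],
      nb_m = fn$params[["m"]], nb_k = fn$params[["k"]],
      pln_converged = fp$converged, nb_converged = fn$converged,
      stringsAsFactors = FALSE)
    obs <- octave_bin(av)
    ep <- expected_octave_proportions(fp)
    en <- expected_octave_proportions(fn)
    octs <- 0:max(max(obs$octave), nrow(ep) - 1L, nrow(en) - 1L)
    getp <- function(df, o) ifelse(o < nrow(df), df$proportion[o + 1L], NA_real_)
    oct_rows[[g]] <- data.frame(
      group = g, octave = octs,
      observed_proportion = ifelse(octs <= max(obs$octave),
                                   obs$count[match(octs, obs$octave)] /
                                     attr(obs, "n_species"), 0),
      fitted_pln = if (nrow(ep)) getp(ep, octs) else NA_real_,
      fitted_nb = if (nrow(en)) getp(en, octs) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(comparisons = do.call(rbind, c(comp_rows, make.row.names = FALSE)),
       octaves = do.call(rbind, c(oct_rows, make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
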