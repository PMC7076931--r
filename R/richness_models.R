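# Explaining Chao1 richness from environmental covariates: prune
# co-correlated predictors, fit Gaussian or negative-binomial models with
# optional fixed-df natural-spline terms, select by stepwise AIC with forced
# terms, and report deviance explained.

#' Prune co-correlated environmental covariates
#'
#' Iterates numeric columns in lexicographic order; whenever a later column
#' has `|Pearson R| > r_threshold` with an already-kept earlier column, the
#' later one is dropped. Constant columns are excluded (with a warning)
#' before any correlation is computed.
#'
#' @param env data.frame of covariates (non-numeric columns pass through
#'   untouched and are never pruned).
#' @param r_threshold strict correlation threshold (default 0.6).
#' @return list with `env` (pruned data.frame) and `removed` (data.frame:
#'   `removed`, `correlated_with`, `r`).
#' @export
prune_covariates <- function(env, r_threshold = 0.6) {
  num_cols <- names(env)[vapply(env, is.numeric, logical(1))]
  if (length(num_cols) < 2) stop("need at least 2 numeric columns")
  consts <- num_cols[vapply(num_cols, function(cn)
    sd(env[[cn]], na.rm = TRUE) == 0 || all(is.na(env[[cn]])), logical(1))]
  if (length(consts) > 0) {
    warning("excluding constant column(s): ", paste(consts, collapse = ", "))
    num_cols <- setdiff(num_cols, consts)
  }
  ord <- sort(num_cols)
  kept <- character(0)
  removed <- data.frame(removed = character(0), correlated_with = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (cn in ord) {
    hit <- FALSE
    for (kc in kept) {
      r <- suppressWarnings(cor(env[[cn]], env[[kc]],
                                use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > r_threshold) {
        removed <- rbind(removed, data.frame(removed = cn,
                                             correlated_with = kc, r = r,
                                             stringsAsFactors = FALSE))
        hit <- TRUE
        break
      }
    }
    if (!hit) kept <- c(kept, cn)
  }
  drop_cols <- union(consts, removed$removed)
  list(env = env[, setdiff(names(env), drop_cols), drop = FALSE],
       removed = removed)
}

# term labels: "x" is linear, "s(x)" a df-3 natural cubic spline
.term_formula <- function(term, spline_df = 3) {
  m <- regmatches(term, regexec("^s\\((.+)\\)$", term))[[1]]
  if (length(m) == 2) sprintf("splines::ns(%s, df = %d)", m[2], spline_df)
  else term
}

.term_predictor <- function(term) sub("^s\\((.+)\\)$", "\\1", term)

#' Fit a richness model (Gaussian or negative binomial)
#'
#' Gaussian-identity fits via least squares; negative binomial log-link via
#' IRLS alternated with ML estimation of the dispersion (MASS::glm.nb, whose
#' AIC counts the dispersion as a parameter). Spline terms are unpenalized
#' natural cubic bases with fixed df. Under the NB family a non-integer
#' response (Chao1 is real-valued) is rounded to the nearest integer with a
#' message.
#'
#' @param response numeric vector.
#' @param env data.frame of covariates (numeric or factor/character).
#' @param terms character vector of term labels: a column name for a linear
#'   term, `"s(name)"` for a df-`spline_df` natural spline. Empty vector
#'   fits the intercept-only model.
#' @param family `"gaussian"` or `"negative_binomial"`.
#' @param spline_df spline degrees of freedom (default 3).
#' @return a `model_fit`: list with `family`, `terms`, `coefficients`,
#'   `logLik`, `AIC`, `null_deviance`, `deviance`, `deviance_explained`,
#'   `pseudo_r2` (squared response-fitted correlation), `fit` (the
#'   underlying glm object), `converged`.
#' @export
fit_model <- function(response, env, terms = character(0),
                      family = c("gaussian", "negative_binomial"),
                      spline_df = 3) {
  family <- match.arg(family)
  y <- response
  if (family == "negative_binomial") {
    if (any(y < 0)) stop("negative response not allowed under NB")
    if (any(y != round(y))) {
      message("rounding non-integer response to the nearest integer for NB")
      y <- round(y)
    }
  }
  dat <- cbind(.response = y, env)
  rhs <- if (length(terms) == 0) "1"
         else paste(vapply(terms, .term_formula, character(1),
                           spline_df = spline_df), collapse = " + ")
  fml <- as.formula(paste(".response ~", rhs))
  fit <- if (family == "gaussian")
    glm(fml, data = dat, family = gaussian())
  else
    suppressWarnings(MASS::glm.nb(fml, data = dat))
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient fit; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  n_coef <- length(coef(fit)) + (family == "negative_binomial")
  if (length(y) <= n_coef)
    stop("more coefficients than observations")
  structure(list(
    family = family, terms = terms, coefficients = coef(fit),
    logLik = as.numeric(logLik(fit)), AIC = AIC(fit),
    null_deviance = fit$null.deviance, deviance = fit$deviance,
    deviance_explained = 1 - fit$deviance / fit$null.deviance,
    pseudo_r2 = if (sd(fitted(fit)) > 0) cor(y, fitted(fit))^2 else 0,
    fit = fit, converged = isTRUE(fit$converged) || family == "gaussian"),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit [", x$family, "] terms:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept)",
      "\n  AIC =", signif(x$AIC, 8),
      "| deviance explained =", sprintf("%.1f%%", 100 * x$deviance_explained),
      "| pseudo-R2 =", signif(x$pseudo_r2, 3), "\n")
  invisible(x)
}

#' Stepwise AIC model selection with forced terms
#'
#' Starts from the saturated model (all numeric covariates as linear terms
#' plus forced terms) and repeatedly evaluates all single-term drops and
#' adds — adds consider both the linear and the spline form of absent
#' predictors — accepting the move with the lowest AIC when it improves by
#' more than 1e-10. Ties break toward fewer terms, then lexicographically.
#' Forced terms (e.g. `region`) are never dropped.
#'
#' @param response numeric vector.
#' @param env pruned covariate data.frame; may include factor columns for
#'   forced terms.
#' @param family `"gaussian"` or `"negative_binomial"`.
#' @param forced_terms term labels always kept (default `"region"` if such a
#'   column exists, otherwise none).
#' @param direction currently `"both"` (drops and adds each step).
#' @param use_splines offer `s(x)` forms as add candidates (default TRUE).
#' @param spline_df spline df (default 3).
#' @return a `stepwise_result`: list with `selected` (a `model_fit`), `path`
#'   (data.frame of accepted steps with AICs) and `forced_terms`.
#' @export
stepwise_aic <- function(response, env,
                         family = c("gaussian", "negative_binomial"),
                         forced_terms = intersect("region", names(env)),
                         direction = "both", use_splines = TRUE,
                         spline_df = 3) {
  family <- match.arg(family)
  num_preds <- names(env)[vapply(env, is.numeric, logical(1))]
  # non-numeric columns (e.g. region when not forced) compete as plain
  # categorical terms; spline forms only make sense for numeric predictors
  cat_preds <- setdiff(names(env), num_preds)
  preds <- sort(setdiff(c(num_preds, cat_preds), forced_terms))
  spline_ok <- setdiff(num_preds, forced_terms)
  fit1 <- function(terms) tryCatch(
    fit_model(response, env, terms, family, spline_df = spline_df),
    error = function(e) NULL)
  current_terms <- c(forced_terms, preds)
  current <- fit1(current_terms)
  if (is.null(current)) {
    # saturated model may be rank deficient; fall back to forced-only start
    current_terms <- forced_terms
    current <- fit1(current_terms)
    if (is.null(current)) stop("no valid start model")
  }
  path <- data.frame(step = 0L, action = "start",
                     term = paste(current_terms, collapse = "+"),
                     AIC = current$AIC, stringsAsFactors = FALSE)
  repeat {
    moves <- list()
    droppable <- setdiff(current_terms, forced_terms)
    for (tm in droppable)
      moves[[length(moves) + 1L]] <-
        list(action = "drop", term = tm,
             terms = setdiff(current_terms, tm))
    in_model <- vapply(current_terms, .term_predictor, character(1))
    absent <- setdiff(preds, in_model)
    for (p in absent) {
      cand <- c(p, if (use_splines && p %in% spline_ok) paste0("s(", p, ")"))
      for (tm in cand)
        moves[[length(moves) + 1L]] <-
          list(action = "add", term = tm,
               terms = c(current_terms, tm))
    }
    if (length(moves) == 0) break
    aics <- vapply(moves, function(mv) {
      f <- fit1(mv$terms)
      if (is.null(f) || !f$converged) Inf else f$AIC
    }, numeric(1))
    best_aic <- min(aics)
    if (!(best_aic < current$AIC - 1e-10)) break
    tied <- which(aics <= best_aic + 1e-10)
    if (length(tied) > 1) {
      sizes <- vapply(moves[tied], function(mv) length(mv$terms), integer(1))
      tied <- tied[sizes == min(sizes)]
      labs <- vapply(moves[tied], `[[`, character(1), "term")
      tied <- tied[order(labs)][1]
    }
    mv <- moves[[tied[1]]]
    current_terms <- mv$terms
    current <- fit1(current_terms)
    path <- rbind(path, data.frame(step = nrow(path), action = mv$action,
                                   term = mv$term, AIC = current$AIC,
                                   stringsAsFactors = FALSE))
  }
  structure(list(selected = current, path = path,
                 forced_terms = forced_terms),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("stepwise_aic:", nrow(x$path) - 1L, "accepted step(s); final AIC =",
      signif(x$selected$AIC, 8), "\n")
  print(x$selected)
  invisible(x)
}

#' Summarize selected richness models across domains
#'
#' One row per domain: ordered predictors of the selected model, family,
#' pseudo-R-squared and percent deviance explained.
#'
#' @param fits named list of `stepwise_result` (or `model_fit`) objects, one
#'   per domain.
#' @return data.frame: `response`, `predictors`, `distribution`, `r2`,
#'   `deviance_explained_pct`.
#' @export
summarize_best_models <- function(fits) {
  rows <- lapply(names(fits), function(dom) {
    f <- fits[[dom]]
    mf <- if (inherits(f, "stepwise_result")) f$selected else f
    data.frame(response = paste0(dom, " Chao1"),
               predictors = paste(mf$terms, collapse = ", "),
               distribution = ifelse(mf$family == "negative_binomial",
                                     "Negative binomial", "Gaussian"),
               r2 = mf$pseudo_r2,
               deviance_explained_pct = 100 * mf$deviance_explained,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
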