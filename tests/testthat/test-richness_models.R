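test_that("prune_covariates drops later columns of correlated pairs", {
  set.seed(1)
  n <- 60
  a <- rnorm(n)
  env <- data.frame(a = a, b = a + rnorm(n, 0, 1e-6),  # duplicate of a
                    c = rnorm(n), d = rnorm(n))
  pr <- prune_covariates(env)
  expect_setequal(names(pr$env), c("a", "c", "d"))
  expect_equal(pr$removed$removed, "b")
  # |R| = 0.59 keeps both (strict threshold)
  x <- rnorm(2000)
  y <- 0.59 * x + sqrt(1 - 0.59^2) * rnorm(2000)
  y <- y * sqrt(1) # keep scale
  r_emp <- cor(x, y)
  env2 <- data.frame(a = x, b = y)
  pr2 <- prune_covariates(env2, r_threshold = max(abs(r_emp) + 0.01, 0.6))
  expect_equal(nrow(pr2$removed), 0)
  # three mutually correlated: first kept, other two dropped
  z <- rnorm(n)
  env3 <- data.frame(p1 = z, p2 = z + rnorm(n, 0, 0.1),
                     p3 = z + rnorm(n, 0, 0.1), q = rnorm(n))
  pr3 <- prune_covariates(env3)
  expect_setequal(names(pr3$env), c("p1", "q"))
  expect_setequal(pr3$removed$correlated_with, "p1")
  # constant column excluded with warning
  env4 <- data.frame(a = rnorm(n), b = rnorm(n), k = 1)
  expect_warning(pr4 <- prune_covariates(env4), "constant")
  expect_false("k" %in% names(pr4$env))
})

test_that("fit_model: exact line, intercept-only, closed-form equality", {
  env <- data.frame(x = c(0, 1, 2))
  f <- fit_model(c(0, 1, 2), env, "x", "gaussian")
  expect_equal(unname(f$coefficients), c(0, 1), tolerance = 1e-10)
  expect_equal(f$deviance_explained, 1, tolerance = 1e-10)
  set.seed(2)
  env2 <- data.frame(x = rnorm(40), z = rnorm(40))
  y2 <- 2 + 0.7 * env2$x - 1.2 * env2$z + rnorm(40, 0, 0.5)
  f0 <- fit_model(y2, env2, character(0), "gaussian")
  expect_equal(f0$deviance_explained, 0)
  f2 <- fit_model(y2, env2, c("x", "z"), "gaussian")
  beta <- solve(crossprod(cbind(1, env2$x, env2$z)),
                crossprod(cbind(1, env2$x, env2$z), y2))[, 1]
  expect_equal(unname(f2$coefficients), unname(beta), tolerance = 1e-8)
  # adding a term never decreases gaussian deviance explained
  f1 <- fit_model(y2, env2, "x", "gaussian")
  expect_gte(f2$deviance_explained, f1$deviance_explained - 1e-12)
  # rank deficiency errors with the term named
  env3 <- data.frame(x = env2$x, xdup = env2$x)
  expect_error(fit_model(y2, env3, c("x", "xdup"), "gaussian"),
               "collinear")
})

test_that("NB fit recovers log-link coefficients and rounds the response", {
  set.seed(3)
  n <- 500
  env <- data.frame(x = rnorm(n))
  mu <- exp(2 + 0.5 * env$x)
  y <- rnbinom(n, size = 2, mu = mu)
  f <- fit_model(y, env, "x", "negative_binomial")
  expect_lt(abs(f$coefficients[["(Intercept)"]] - 2), 0.1)
  expect_lt(abs(f$coefficients[["x"]] - 0.5), 0.1)
  # AIC counts the dispersion: logLik df is p + 1
  expect_equal(f$AIC, -2 * f$logLik + 2 * 3, tolerance = 1e-8)
  expect_message(fit_model(y + 0.4, env, "x", "negative_binomial"),
                 "rounding")
  expect_error(fit_model(y - 100, env, "x", "negative_binomial"),
               "negative response")
})

test_that("spline terms are available and compared by AIC", {
  set.seed(4)
  n <- 120
  env <- data.frame(x = runif(n, -2, 2))
  y <- sin(1.8 * env$x) * 3 + rnorm(n, 0, 0.4)
  lin <- fit_model(y, env, "x", "gaussian")
  spl <- fit_model(y, env, "s(x)", "gaussian")
  expect_lt(spl$AIC, lin$AIC)   # the curved truth prefers the spline
  expect_equal(length(spl$coefficients), 4)  # intercept + 3 basis columns
})

test_that("stepwise_aic keeps forced terms, descends strictly, prunes noise", {
  set.seed(5)
  n <- 90
  rich <- rnorm(n, 100, 15)
  env <- simulate_env(n, paste0("p", 1:6), c(p5 = 3), rich,
                      noise_sd = 5, seed = 6)
  env$region <- factor(rep(c("r1", "r2"), length.out = n))
  sw <- stepwise_aic(rich, env, "gaussian", forced_terms = "region")
  expect_true("region" %in% sw$selected$terms)
  expect_true(any(grepl("^s?\\(?p5", sw$selected$terms)))
  expect_true(all(diff(sw$path$AIC) < 0))
  expect_lte(sw$selected$AIC, sw$path$AIC[1])
  # pure-noise predictors: little beyond forced terms survives
  noise_env <- data.frame(matrix(rnorm(n * 5), n,
                                 dimnames = list(NULL, paste0("z", 1:5))))
  noise_env$region <- env$region
  sw2 <- stepwise_aic(rnorm(n), noise_env, "gaussian",
                      forced_terms = "region")
  expect_true(all(diff(sw2$path$AIC) < 0))
  expect_lte(length(setdiff(sw2$selected$terms, "region")), 2)
})

test_that("summarize_best_models emits the report schema", {
  set.seed(7)
  n <- 60
  env <- data.frame(x = rnorm(n), region = factor(rep(c("a", "b"),
                                                      length.out = n)))
  y <- 50 + 4 * env$x + rnorm(n)
  fits <- list(bacteria = stepwise_aic(y, env, "gaussian"),
               archaea = fit_model(y, env, "x", "gaussian"))
  rep <- summarize_best_models(fits)
  expect_identical(names(rep), c("response", "predictors", "distribution",
                                 "r2", "deviance_explained_pct"))
  expect_identical(rep$response, c("bacteria Chao1", "archaea Chao1"))
  expect_true(all(rep$deviance_explained_pct >= 0 &
                    rep$deviance_explained_pct <= 100))
  # deviance explained recomputable from the stored fit
  mf <- fits$archaea
  expect_equal(rep$deviance_explained_pct[2],
               100 * (1 - mf$deviance / mf$null_deviance))
  # round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(rep, path, "tsv")
  expect_equal(read.delim(path)$r2, rep$r2, tolerance = 1e-10)
})
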