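# statistical inference: screening, PCA, regressions, selection, diagnostics

test_that("Pearson screening drops by priority and reports partners", {
  d <- make_exact_corr_pair(95, 0.94, seed = 1)
  names(d) <- c("habitat_cover", "mean_patch_size")
  set.seed(2)
  d$n_patches <- rnorm(95)
  rep <- pearson_screen(d, threshold = 0.70,
                        drop_priority = "mean_patch_size")
  expect_identical(rep$dropped$variable, "mean_patch_size")
  expect_identical(rep$dropped$partner, "habitat_cover")
  expect_equal(rep$dropped$r, 0.94, tolerance = 1e-10)
  expect_setequal(rep$retained, c("habitat_cover", "n_patches"))
  r <- cor(d[rep$retained])
  expect_true(all(abs(r[upper.tri(r)]) <= 0.70))

  # nothing to drop
  set.seed(3)
  clean <- as.data.frame(matrix(rnorm(300), ncol = 3))
  rep2 <- pearson_screen(clean)
  expect_identical(nrow(rep2$dropped), 0L)
  expect_identical(rep2$retained, names(clean))

  # duplicated column: exactly one of the two goes
  dup <- data.frame(u = clean[[1]], v = clean[[1]], w = clean[[2]])
  rep3 <- pearson_screen(dup)
  expect_identical(nrow(rep3$dropped), 1L)
  expect_identical(length(rep3$retained), 2L)

  const <- data.frame(a = clean[[1]], b = rep(1, 100))
  expect_error(pearson_screen(const), regexp = "b",
               class = "betascape_screening_error")
})

test_that("standardization yields exact z-scores and is idempotent", {
  set.seed(4)
  d <- data.frame(a = rnorm(40, 5, 3), b = runif(40) * 100)
  z <- standardize_predictors(d)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(vapply(z, sd, numeric(1)) - 1)), 1e-12)
  z2 <- standardize_predictors(z)
  expect_lt(max(abs(as.matrix(z2) - as.matrix(z))), 1e-12)
  expect_error(standardize_predictors(data.frame(a = rep(2, 5))),
               class = "betascape_domain_error")
})

test_that("PCA variance explained follows the correlation eigenstructure", {
  set.seed(5)
  x <- rnorm(60)
  perfect <- data.frame(a = x, b = 2 * x)
  p <- pca_landscapes(standardize_predictors(perfect))
  expect_equal(p$var_explained[1], 100, tolerance = 1e-9)

  d <- make_exact_corr_pair(80, 0.6, seed = 6)
  p2 <- pca_landscapes(standardize_predictors(d))
  expect_equal(p2$var_explained, c(80, 20), tolerance = 1e-9)
  expect_equal(sum(p2$var_explained), 100, tolerance = 1e-12)
  expect_true(all(diff(p2$var_explained) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(p2$loadings), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the unit-interval squeeze matches its closed form", {
  expect_equal(squeeze_unit_interval(0, 100), 0.005)
  expect_equal(squeeze_unit_interval(1, 100), 0.995)
  expect_equal(squeeze_unit_interval(0.5, 7), 0.5)
  expect_equal(squeeze_unit_interval(0.5, 10000), 0.5)
  y <- squeeze_unit_interval(c(0, 0.2, 1))
  expect_true(all(y > 0 & y < 1))
  expect_error(squeeze_unit_interval(c(0.5, 1.2)),
               class = "betascape_domain_error")
})

test_that("beta regression recovers simulated parameters", {
  set.seed(7)
  n <- 1000
  x <- rnorm(n)
  mu <- 1 / (1 + exp(-(0 + 0.3 * x)))
  phi <- 30
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y <- pmin(pmax(y, 1e-9), 1 - 1e-9)
  fit <- fit_beta_regression(y, cbind(x = x))
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients$estimate[2] - 0.3), 0.05)
  expect_lt(abs(fit$phi - 30) / 30, 0.15)
  expect_identical(nrow(fit$coefficients), 2L)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$log_lik)

  # ML beats the generating parameters on the same data
  ll_true <- sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  expect_gte(fit$log_lik, ll_true - 1e-8)

  # stationarity: analytic score (independent derivation) ~ 0 at the optimum
  est <- fit$coefficients$estimate
  X <- cbind(1, x)
  eta <- drop(X %*% est)
  mu_hat <- 1 / (1 + exp(-eta))
  phi_hat <- fit$phi
  ystar <- log(y / (1 - y))
  mustar <- digamma(mu_hat * phi_hat) - digamma((1 - mu_hat) * phi_hat)
  score_beta <- crossprod(X, phi_hat * (ystar - mustar) * mu_hat * (1 - mu_hat))
  score_phi <- sum(mu_hat * (ystar - mustar) + log(1 - y) -
                     digamma((1 - mu_hat) * phi_hat) + digamma(phi_hat))
  expect_lt(max(abs(c(score_beta, score_phi))) / n, 1e-6)
})

test_that("intercept-only beta regression centres symmetric data", {
  set.seed(8)
  half <- runif(300, 0.02, 0.48)
  y <- c(half, 1 - half)
  fit <- fit_beta_regression(y)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[1]), 2 * co$se[1])
  expect_error(fit_beta_regression(c(0, 0.5, 1)),
               class = "betascape_domain_error")
})

test_that("Gaussian fits equal the closed-form least-squares solution", {
  set.seed(9)
  n <- 60
  X <- cbind(a = rnorm(n), b = runif(n))
  y <- 2 + 1.5 * X[, 1] - 0.7 * X[, 2] + rnorm(n, sd = 0.4)
  fit <- fit_gaussian(y, X)
  closed <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_lt(max(abs(fit$coefficients$estimate - closed)), 1e-10)
  expect_equal(fit$aic, AIC(lm(y ~ X)), tolerance = 1e-8)
  expect_equal(fit$coefficients$p,
               unname(summary(lm(y ~ X))$coefficients[, 4]), tolerance = 1e-10)

  # exact linear response
  y_lin <- 1 + 3 * X[, 1]
  fit_lin <- fit_gaussian(y_lin, X)
  expect_equal(fit_lin$r2, 1, tolerance = 1e-9)
  expect_lt(max(abs(fit_lin$residuals)), 1e-10)

  # permutation invariance
  perm <- sample(n)
  fit_p <- fit_gaussian(y[perm], X[perm, ])
  expect_equal(fit_p$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(fit_p$aic, fit$aic, tolerance = 1e-10)

  expect_error(fit_gaussian(y, cbind(X, X[, 1])),
               class = "betascape_domain_error")
})

test_that("all-subsets enumeration, marginality and ranking behave", {
  set.seed(10)
  d <- data.frame(y = runif(50, 0.2, 0.8), a = rnorm(50), b = rnorm(50),
                  c = rnorm(50))
  tab <- all_subsets(d, "y", c("a", "b", "c"), family = "gaussian")
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$delta_aic) >= 0))
  expect_true(tab$best[1])

  tab_i <- all_subsets(d, "y", c("a", "b"), family = "gaussian",
                       interaction = c("a", "b"))
  expect_identical(nrow(tab_i), 5L)
  with_int <- grepl("a:b", tab_i$model)
  expect_true(all(grepl("(^|\\+ )a( |$)", tab_i$model[with_int]) &
                    grepl("b", sub("a:b", "", tab_i$model[with_int]))))

  # beta family on the same layout
  tab_b <- all_subsets(d, "y", c("a", "b", "c"), family = "beta_logit")
  expect_identical(nrow(tab_b), 8L)
  expect_true(all(tab_b$converged))
})

test_that("all-subsets recovers strong true predictors with correct signs", {
  set.seed(11)
  found <- replicate(20, {
    n <- 95
    d <- data.frame(dist = rnorm(n), patches = rnorm(n), cover = rnorm(n),
                    n1 = rnorm(n), n2 = rnorm(n))
    eta <- -0.4 + 0.5 * d$dist - 0.5 * d$patches - 0.5 * d$cover
    mu <- 1 / (1 + exp(-eta))
    d$y <- rbeta(n, mu * 40, (1 - mu) * 40)
    tab <- all_subsets(d, "y", c("dist", "patches", "cover", "n1", "n2"),
                       family = "beta_logit")
    eff <- selection_effects(tab, 1)
    g <- function(t) if (t %in% eff$term) eff$estimate[eff$term == t] else NA
    !is.na(g("dist")) && g("dist") > 0 &&
      !is.na(g("patches")) && g("patches") < 0 &&
      !is.na(g("cover")) && g("cover") < 0
  })
  expect_gte(mean(found), 0.9)
})

test_that("VIF matches its closed form", {
  d <- make_exact_corr_pair(60, 0.9, seed = 12)
  v <- vif(d)
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-9)

  # design orthogonal after centring: all VIF 1, and adding another
  # orthogonal column changes nothing
  set.seed(13)
  raw <- matrix(rnorm(120), ncol = 3)
  p1 <- raw[, 1] - mean(raw[, 1])
  p2 <- residuals(lm(raw[, 2] ~ p1))
  p3 <- residuals(lm(raw[, 3] ~ p1 + p2))
  X <- cbind(p = p1, q = p2, r = p3)
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(vif(X[, 1:2]))[1:2], unname(vif(X))[1:2],
               tolerance = 1e-9)

  # perfect collinearity reported as Inf
  Z <- cbind(a = rnorm(20))
  expect_true(is.infinite(vif(cbind(Z, b = 2 * Z[, 1]))[1]))
})

test_that("Moran's I matches an independent reference and detects structure", {
  set.seed(13)
  n <- 40
  xy <- matrix(runif(2 * n, 0, 10), ncol = 2)
  e <- rnorm(n)
  mi <- morans_i(e, xy)
  expect_equal(mi$expected, -1 / (n - 1))
  # literal Cliff-Ord moments written out independently (double sums)
  W <- 1 / as.matrix(dist(xy)); diag(W) <- 0
  z <- e - mean(e)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  I_ref <- (n / sum(W)) * num / sum(z^2)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  V_ref <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - (1 / (n - 1))^2
  expect_equal(mi$observed, I_ref, tolerance = 1e-10)
  expect_equal(mi$sd, sqrt(V_ref), tolerance = 1e-10)
  z_score <- (I_ref - (-1 / (n - 1))) / sqrt(V_ref)
  expect_equal(mi$p_value, 2 * pnorm(-abs(z_score)), tolerance = 1e-10)

  # a smooth spatial gradient is flagged
  grad <- xy[, 1] + 0.5 * xy[, 2]
  mg <- morans_i(grad + rnorm(n, sd = 0.1), xy)
  expect_gt(mg$observed, 0)
  expect_lt(mg$p_value, 0.05)

  expect_error(morans_i(rep(1, 10), xy[1:10, ]),
               class = "betascape_domain_error")
  expect_error(morans_i(rnorm(4), xy[1:4, ]),
               class = "betascape_domain_error")
})
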