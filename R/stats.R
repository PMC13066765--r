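#' Pearson correlation screening of predictors
#'
#' Iteratively, while any pair has |r| above the threshold, drops one member
#' of the most correlated offending pair: the member appearing earliest in
#' `drop_priority`, or (when neither is named) the later column in table
#' order. All drops are reported with the partner that triggered them.
#'
#' @param table numeric data frame of candidate predictors (>= 2 columns,
#'   >= 3 rows).
#' @param threshold absolute-correlation retention bound (default 0.70).
#' @param drop_priority character vector of variables to sacrifice first
#'   (default `"mean_patch_size"`, the habitat-amount proxy conventionally
#'   removed in favour of habitat cover).
#' @return A `screen_report` list: `r_matrix` (initial correlations),
#'   `dropped` (data frame `variable`, `partner`, `r`), `retained` (names).
#' @export
pearson_screen <- function(table, threshold = 0.70,
                           drop_priority = "mean_patch_size") {
  table <- as.data.frame(table)
  if (ncol(table) < 2 || nrow(table) < 3) {
    stop_betascape("betascape_screening_error",
                   "need >= 2 columns and >= 3 rows to screen")
  }
  const <- names(table)[vapply(table, function(v) sd(v, na.rm = TRUE) == 0,
                               logical(1))]
  if (length(const)) {
    stop_betascape("betascape_screening_error",
                   "constant column(s), correlation undefined: %s",
                   paste(const, collapse = ", "))
  }
  r0 <- cor(table, use = "pairwise.complete.obs")
  cur <- table
  dropped <- data.frame(variable = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (ncol(cur) < 2) break
    r <- cor(cur, use = "pairwise.complete.obs")
    diag(r) <- NA
    mx <- max(abs(r), na.rm = TRUE)
    if (mx <= threshold) break
    ij <- which(abs(r) == mx, arr.ind = TRUE)[1, ]
    pair <- colnames(r)[ij]
    pr <- match(pair, drop_priority)
    victim <- if (all(is.na(pr))) {
      pair[which.max(match(pair, names(table)))]   # later column in table order
    } else {
      pair[which.min(replace(pr, is.na(pr), Inf))]
    }
    partner <- setdiff(pair, victim)
    dropped <- rbind(dropped, data.frame(variable = victim, partner = partner,
                                         r = r[ij[1], ij[2]],
                                         stringsAsFactors = FALSE))
    cur <- cur[, setdiff(names(cur), victim), drop = FALSE]
  }
  structure(list(r_matrix = r0, dropped = dropped, retained = names(cur)),
            class = "screen_report")
}

#' Standardize columns to zero mean and unit (sample) variance
#'
#' @param table numeric data frame; every column must be non-constant.
#' @return Data frame of z-scores.
#' @export
standardize_predictors <- function(table) {
  table <- as.data.frame(table)
  out <- lapply(names(table), function(nm) {
    v <- table[[nm]]
    s <- sd(v)
    if (is.na(s) || s == 0) {
      stop_betascape("betascape_domain_error", "constant column: %s", nm)
    }
    (v - mean(v)) / s
  })
  names(out) <- names(table)
  as.data.frame(out)
}

#' Principal component analysis of the landscape environmental space
#'
#' Eigendecomposition of the (standardized) predictor table via
#' [stats::prcomp()]. Variance explained is reported over *all* `p` axes
#' (zero-variance axes as 0%), so percentages are non-increasing and sum
#' to 100.
#'
#' @param table numeric data frame (standardize first; see
#'   [standardize_predictors()]).
#' @return A `pca_result` list: `loadings` (variables x axes), `var_explained`
#'   (percent per axis), `sdev`.
#' @export
pca_landscapes <- function(table) {
  table <- as.data.frame(table)
  p <- ncol(table)
  fit <- prcomp(table, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  ev <- c(ev, rep(0, p - length(ev)))
  loadings <- matrix(0, nrow = p, ncol = p,
                     dimnames = list(names(table), paste0("PC", seq_len(p))))
  loadings[, seq_len(ncol(fit$rotation))] <- fit$rotation
  structure(list(loadings = loadings,
                 var_explained = 100 * ev / sum(ev),
                 sdev = sqrt(ev)),
            class = "pca_result")
}

#' Squeeze a unit-interval response strictly inside (0, 1)
#'
#' Smithson-Verkuilen transform `y' = (y * (n - 1) + 0.5) / n`, needed because
#' observed beta-diversity values may touch 0 or 1 while the beta likelihood
#' requires the open interval. `y = 0.5` is a fixed point for any `n`.
#'
#' @param y values in `[0, 1]`.
#' @param n sample size (default `length(y)`).
#' @return Transformed values strictly in (0, 1).
#' @export
squeeze_unit_interval <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1)) {
    stop_betascape("betascape_domain_error", "y must lie in [0, 1]")
  }
  (y * (n - 1) + 0.5) / n
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Beta regression by maximum likelihood (logit link, mean-precision form)
#'
#' Density \eqn{\Gamma(\phi) / (\Gamma(\mu\phi)\Gamma((1-\mu)\phi))
#' y^{\mu\phi - 1} (1 - y)^{(1-\mu)\phi - 1}} with
#' \eqn{\mu = \mathrm{logistic}(X\beta)}, fitted by BFGS on \eqn{(\beta,
#' \log\phi)} with analytic gradient. Standard errors come from the observed
#' information; p-values are Wald z. AIC counts all `length(beta) + 1`
#' parameters (precision included). Pseudo-R2 is the squared Pearson
#' correlation between the linear predictor and `logit(y)`.
#'
#' @param y response strictly in (0, 1) (see [squeeze_unit_interval()]).
#' @param design numeric matrix/data frame of predictors (no intercept
#'   column; one is added). May have zero columns (intercept-only model).
#' @return A `betascape_fit` list: `coefficients` (data frame with `term`,
#'   `estimate`, `se`, `z`, `p`), `phi`, `log_lik`, `aic`, `r2`, `residuals`,
#'   `fitted`, `linpred`, `converged`, `family`, `n`.
#' @export
fit_beta_regression <- function(y, design = NULL) {
  if (any(y <= 0 | y >= 1)) {
    stop_betascape("betascape_domain_error",
                   "beta regression needs y strictly inside (0, 1)")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(if (is.null(design)) {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  } else design))
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop_betascape("betascape_domain_error", "design matrix is rank deficient")
  }
  ly <- logit(y)
  l1y <- log(1 - y)

  nll <- function(par) {
    eta <- drop(X %*% par[1:p])
    mu <- inv_logit(eta)
    phi <- exp(par[p + 1])
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * l1y)
  }
  grad <- function(par) {
    eta <- drop(X %*% par[1:p])
    mu <- inv_logit(eta)
    phi <- exp(par[p + 1])
    ystar <- ly
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    d_beta <- -drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
    d_phi <- -sum(mu * (ystar - mustar) + l1y - digamma((1 - mu) * phi) +
                    digamma(phi)) * phi
    c(d_beta, d_phi)
  }

  beta0 <- qr.solve(X, ly)
  mu0 <- inv_logit(drop(X %*% beta0))
  res_var <- var(y - mu0)
  phi0 <- max(1, mean(mu0 * (1 - mu0)) / max(res_var, 1e-8) - 1)
  opt <- optim(c(beta0, log(phi0)), nll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  converged <- opt$convergence == 0

  H <- tryCatch(optimHess(opt$par, nll, grad), error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)[1:p]
      se <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }
  est <- opt$par[1:p]
  z <- est / se
  eta <- drop(X %*% est)
  mu <- inv_logit(eta)
  r2 <- if (p > 1) cor(eta, ly)^2 else 0
  ll <- -opt$value
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = est, se = se,
                              z = z, p = 2 * pnorm(-abs(z)),
                              stringsAsFactors = FALSE),
    phi = exp(opt$par[p + 1]),
    log_lik = ll,
    aic = 2 * (p + 1) - 2 * ll,
    r2 = r2,
    residuals = y - mu,
    fitted = mu,
    linpred = eta,
    converged = converged,
    family = "beta_logit",
    n = n
  ), class = "betascape_fit")
}

#' Gaussian (ordinary least squares) regression
#'
#' OLS with t-based p-values and adjusted R2. AIC counts the residual
#' variance as an estimated parameter (`2 * (p + 1) - 2 * logLik` with the
#' Gaussian ML log-likelihood), matching `stats::AIC` on `lm` fits.
#'
#' @param y numeric response.
#' @param design predictors (no intercept column), possibly zero columns.
#' @return A `betascape_fit` (see [fit_beta_regression()]); `phi` is `NA`.
#' @export
fit_gaussian <- function(y, design = NULL) {
  X <- cbind(`(Intercept)` = 1, as.matrix(if (is.null(design)) {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  } else design))
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    stop_betascape("betascape_domain_error",
                   "rank-deficient design: collinear terms %s",
                   paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))
  }
  if (n <= p) {
    stop_betascape("betascape_domain_error", "need n > number of parameters")
  }
  est <- qr.coef(qx, y)
  fitted <- drop(X %*% est)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  df_res <- n - p
  se <- sqrt(diag(chol2inv(qr.R(qx))) * rss / df_res)
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df_res)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj_r2 <- if (p > 1) 1 - (1 - r2) * (n - 1) / df_res else r2
  ll <- -n / 2 * (log(2 * pi) + log(sigma2_ml) + 1)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = est, se = se,
                              z = tval, p = pval, stringsAsFactors = FALSE),
    phi = NA_real_,
    log_lik = ll,
    aic = 2 * (p + 1) - 2 * ll,
    r2 = adj_r2,
    residuals = res,
    fitted = fitted,
    linpred = fitted,
    converged = TRUE,
    family = "gaussian",
    n = n
  ), class = "betascape_fit")
}

#' All-subsets (dredge-style) model selection by AIC
#'
#' Fits every subset of the candidate predictors (intercept always included)
#' and, when an interaction pair is supplied, additionally each subset
#' containing both main effects with the interaction term (marginality: the
#' interaction never enters without its mains). Models are ranked by AIC
#' ascending, ties broken by fewer parameters then lexicographic term order;
#' `delta_aic` is relative to the rank-1 model and the "best set" is
#' `delta_aic <= 2`. Predictors are standardized internally so effects are
#' comparable standardized effect sizes; beta-family responses are squeezed
#' off the boundary with [squeeze_unit_interval()]. Rows with missing values
#' in any candidate predictor or the response are dropped (count in
#' `attr(, "n_dropped_rows")`).
#'
#' @param data data frame holding the response and predictors.
#' @param response response column name.
#' @param predictors character vector of candidate predictor columns
#'   (<= 12).
#' @param family `"beta_logit"` or `"gaussian"`.
#' @param interaction optional length-2 character vector naming the
#'   interaction pair (e.g. `c("habitat_cover", "n_patches")`).
#' @return A `selection_table` data frame: `rank`, `model`, `k`, `aic`,
#'   `delta_aic`, `r2`, `converged`, `best`; fitted models in
#'   `attr(, "fits")` (named by `model`), failures in `attr(, "failed")`.
#' @export
all_subsets <- function(data, response, predictors,
                        family = c("beta_logit", "gaussian"),
                        interaction = NULL) {
  family <- match.arg(family)
  if (length(predictors) > 12) {
    stop_betascape("betascape_config_error",
                   "exhaustive enumeration bound: <= 12 candidate terms")
  }
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2, all(interaction %in% predictors))
  }
  cols <- c(response, predictors)
  cc <- complete.cases(data[, cols, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- data[cc, cols, drop = FALSE]
  y <- d[[response]]
  Z <- standardize_predictors(d[predictors])
  if (family == "beta_logit") y <- squeeze_unit_interval(y)

  k <- length(predictors)
  subsets <- lapply(0:(2^k - 1), function(mask) {
    predictors[bitwAnd(mask, bitwShiftL(1, seq_len(k) - 1)) > 0]
  })
  specs <- lapply(subsets, function(s) list(terms = s, interaction = FALSE))
  if (!is.null(interaction)) {
    with_both <- Filter(function(s) all(interaction %in% s), subsets)
    specs <- c(specs, lapply(with_both,
                             function(s) list(terms = s, interaction = TRUE)))
  }

  int_name <- if (!is.null(interaction)) {
    paste(interaction, collapse = ":")
  } else NULL
  fits <- list(); rows <- list(); failed <- character()
  for (spec in specs) {
    terms <- spec$terms
    X <- if (length(terms)) as.matrix(Z[terms]) else NULL
    label_terms <- terms
    if (spec$interaction) {
      X <- cbind(X, Z[[interaction[1]]] * Z[[interaction[2]]])
      colnames(X)[ncol(X)] <- int_name
      label_terms <- c(terms, int_name)
    }
    label <- if (length(label_terms)) paste(sort(label_terms), collapse = " + ")
             else "(intercept)"
    fit <- tryCatch(
      if (family == "beta_logit") fit_beta_regression(y, X)
      else fit_gaussian(y, X),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      failed <- c(failed, label)
      next
    }
    fits[[label]] <- fit
    n_par <- nrow(fit$coefficients) + 1   # + phi or sigma2
    rows[[label]] <- data.frame(model = label, k = n_par, aic = fit$aic,
                                r2 = fit$r2, converged = fit$converged,
                                stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic, tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$best <- tab$delta_aic <= 2
  tab <- tab[, c("rank", "model", "k", "aic", "delta_aic", "r2",
                 "converged", "best")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "failed") <- failed
  attr(tab, "n_dropped_rows") <- n_dropped
  attr(tab, "response") <- response
  attr(tab, "family") <- family
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Terms and standardized effects of a ranked model in a selection table
#'
#' @param tab a `selection_table` from [all_subsets()].
#' @param rank model rank (default 1, the AIC-best model).
#' @return Data frame `term`, `estimate`, `se`, `p` (intercept excluded).
#' @export
selection_effects <- function(tab, rank = 1) {
  label <- tab$model[tab$rank == rank]
  fit <- attr(tab, "fits")[[label]]
  co <- fit$coefficients
  co[co$term != "(Intercept)", c("term", "estimate", "se", "p")]
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor `j` on all others (with
#' intercept). Perfect collinearity yields `Inf`.
#'
#' @param design numeric matrix/data frame of >= 2 predictors.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) {
    stop_betascape("betascape_domain_error", "VIF needs >= 2 predictors")
  }
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Moran's I spatial autocorrelation of model residuals
#'
#' Inverse-distance weights `w_ij = 1 / d_ij` (`w_ii = 0`, row-unnormalized);
#' statistic \eqn{I = (n / \sum w) \sum_{ij} w_{ij} (e_i - \bar e)(e_j - \bar
#' e) / \sum (e_i - \bar e)^2}, expectation \eqn{-1/(n-1)}, variance under the
#' normality assumption, two-sided normal-approximation p-value. Coincident
#' coordinates (zero distances) are perturbed by a documented epsilon of
#' `1e-6 *` the maximum pairwise distance.
#'
#' @param residuals numeric vector (n >= 5) with positive variance.
#' @param coords two-column coordinate matrix.
#' @return List: `observed`, `expected`, `sd`, `p_value`.
#' @export
morans_i <- function(residuals, coords) {
  n <- length(residuals)
  if (n < 5) {
    stop_betascape("betascape_domain_error", "Moran's I needs n >= 5")
  }
  e <- residuals - mean(residuals)
  if (sum(e^2) == 0) {
    stop_betascape("betascape_domain_error", "zero residual variance")
  }
  D <- as.matrix(dist(as.matrix(coords)))
  eps <- 1e-6 * max(D)
  zero_off <- D == 0 & row(D) != col(D)
  if (any(zero_off)) D[zero_off] <- eps
  W <- 1 / D
  diag(W) <- 0
  S0 <- sum(W)
  I <- (n / S0) * drop(crossprod(e, W %*% e)) / sum(e^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VarI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  sdI <- sqrt(VarI)
  list(observed = I, expected = EI, sd = sdI,
       p_value = 2 * pnorm(-abs((I - EI) / sdI)))
}
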