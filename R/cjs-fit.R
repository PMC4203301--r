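# Cormack-Jolly-Seber likelihood, fitting, goodness of fit and QAICc.

# Build the n x (T-1) matrices of survival and recapture probabilities from
# a coefficient vector. P[, j] is the recapture probability at occasion
# j + 1. Cells before an individual's first capture are unused.
cjs_prob_matrices <- function(beta, ctx) {
  n <- ctx$data$n; Tm1 <- ctx$data$T - 1L
  Phi <- matrix(0.5, n, Tm1)
  P <- matrix(0.5, n, Tm1)
  kphi <- ncol(ctx$dphi$X)
  eta_phi <- as.vector(ctx$dphi$X %*% beta[seq_len(kphi)])
  Phi[cbind(ctx$dphi$i, ctx$dphi$j)] <- invlogit(eta_phi)
  if (is.null(ctx$fixed_p)) {
    eta_p <- as.vector(ctx$dp$X %*% beta[kphi + seq_len(ncol(ctx$dp$X))])
    P[cbind(ctx$dp$i, ctx$dp$j)] <- invlogit(eta_p)
  } else {
    fp <- rep_len(ctx$fixed_p, Tm1)
    P <- matrix(fp, n, Tm1, byrow = TRUE)
  }
  list(Phi = Phi, P = P)
}

# negative log-likelihood of the CJS model conditioned on first release.
# Known-alive intervals contribute log(phi) plus the Bernoulli detection
# term; the tail after the last detection contributes log(chi), with
# chi_j = (1 - phi_j) + phi_j (1 - p_{j+1}) chi_{j+1}.
cjs_nll <- function(beta, ctx) {
  pm <- cjs_prob_matrices(beta, ctx)
  Phi <- pm$Phi; P <- pm$P
  data <- ctx$data
  n <- data$n; Tm1 <- data$T - 1L
  eps <- 1e-12
  Phi <- pmin(pmax(Phi, eps), 1 - eps)
  P <- pmin(pmax(P, eps), 1 - eps)
  # known-alive part
  A <- ctx$alive_mask                      # n x (T-1): first <= j <= last-1
  Y <- data$ch[, -1, drop = FALSE]         # detection at occasion j+1
  ll <- sum((log(Phi) + Y * log(P) + (1 - Y) * log(1 - P))[A])
  # tail: chi at the last detection occasion
  chi <- rep(1, n)
  chi_at_last <- rep(1, n)
  need <- data$last <= Tm1                # last == T contributes log(1)
  for (j in Tm1:1) {
    chi <- (1 - Phi[, j]) + Phi[, j] * (1 - P[, j]) * chi
    hit <- data$last == j
    if (any(hit)) chi_at_last[hit] <- chi[hit]
  }
  ll <- ll + sum(log(pmax(chi_at_last[need], eps)))
  -ll
}

# -2 log likelihood of the saturated model: within each release cohort
# (same first occasion) the distinct post-release histories are multinomial,
# so the saturated fit assigns each pattern its observed frequency. Used as
# the reference point for the reported deviance (the MARK QDeviance
# convention); only deviance differences on the same data are meaningful.
cjs_saturated_neg2ll <- function(data) {
  pat <- paste(data$first, apply(data$ch, 1, paste, collapse = ""))
  O <- table(pat)
  coh <- table(data$first)[sub(" .*", "", names(O))]
  -2 * sum(O * log(as.numeric(O) / as.numeric(coh)))
}

make_cjs_context <- function(data, spec, fixed_p = NULL) {
  dphi <- build_design(data, spec$phi, "phi")
  dp <- if (is.null(fixed_p)) build_design(data, spec$p, "p") else NULL
  Tm1 <- data$T - 1L
  alive_mask <- matrix(FALSE, data$n, Tm1)
  for (i in seq_len(data$n)) {
    if (data$last[i] > data$first[i]) {
      alive_mask[i, seq(data$first[i], data$last[i] - 1L)] <- TRUE
    }
  }
  list(data = data, spec = spec, dphi = dphi, dp = dp, fixed_p = fixed_p,
       alive_mask = alive_mask)
}

#' Fit a Cormack-Jolly-Seber survival/recapture model
#'
#' Maximizes the CJS likelihood conditioned on first release with a logit
#' link, by quasi-Newton optimization with random multi-starts on the logit
#' scale. The reported `deviance` is -2 log L-hat minus the saturated-model
#' value (release-cohort history multinomial), the convention under which
#' the bootstrap variance-inflation ratio is calibrated near 1; `neg2loglik`
#' is the raw -2 log L-hat used by [qaicc()]. Only differences between
#' models fitted to the same data are meaningful, which is all that model
#' selection uses.
#'
#' The parameter count `k` is the number of design columns, minus one per
#' survival age-class block with year-dependent survival when recapture is
#' also year-dependent (the terminal phi x p product is then confounded),
#' minus any coefficient driven to the logit boundary (|estimate| > 15,
#' flagged non-estimable).
#'
#' @param data a [capture_data()].
#' @param spec a [parse_model()] result or a notation string.
#' @param fixed_p optional fixed recapture probability (scalar or length
#'   T-1 vector, probability scale). Fixed recapture contributes no
#'   parameters to `k`.
#' @param n_starts random multi-starts (default 5; the first start is at 0).
#' @param control passed to [stats::optim()] (BFGS).
#' @return object of class `cjs_fit`: coefficients, conditional SEs and
#'   covariance, `deviance`, `k`, `n_eff` (total releases), `converged`,
#'   `boundary` flags, and the fitted probability matrices.
#' @export
fit_cjs <- function(data, spec, fixed_p = NULL, n_starts = 5,
                    control = list(maxit = 500, reltol = 1e-10)) {
  if (is.character(spec)) spec <- parse_model(spec)
  ctx <- make_cjs_context(data, spec, fixed_p)
  k_free <- ncol(ctx$dphi$X) + if (is.null(fixed_p)) ncol(ctx$dp$X) else 0L
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    init <- if (s == 1) rep(0, k_free) else stats::rnorm(k_free, 0, 1)
    opt <- try(stats::optim(init, cjs_nll, ctx = ctx, method = "BFGS",
                            control = control), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
  }
  if (is.null(best)) stopf("CJS optimization failed in all starts")
  beta <- best$par
  nms <- c(colnames(ctx$dphi$X),
           if (is.null(fixed_p)) colnames(ctx$dp$X))
  names(beta) <- nms
  H <- try(stats::optimHess(beta, cjs_nll, ctx = ctx), silent = TRUE)
  vc <- matrix(NA_real_, k_free, k_free, dimnames = list(nms, nms))
  if (!inherits(H, "try-error")) {
    vci <- try(solve(H), silent = TRUE)
    if (!inherits(vci, "try-error")) vc <- vci
  }
  se <- sqrt(pmax(diag(vc), 0))
  # boundary (separated) estimates are flagged but still counted in k: they
  # consume a degree of freedom even though their MLE is infinite
  boundary <- abs(beta) > 15
  # the terminal phi x p product is confounded only when recapture is
  # year-dependent AND every survival class covering the last interval is
  # year-dependent (a constant class identifies p_T and frees the rest)
  ht <- ctx$dphi$has_t
  if (!is.null(fixed_p)) {
    conf <- 0L
  } else {
    conf <- if (ctx$dp$has_t$any && ht$blocks_with_t == ht$n_blocks &&
                  ht$n_blocks > 0) 1L else 0L
  }
  k <- k_free - conf
  pm <- cjs_prob_matrices(beta, ctx)
  structure(list(
    spec = spec, notation = spec$notation, coef = beta, se = se, vcov = vc,
    neg2loglik = 2 * best$value,
    deviance = 2 * best$value - cjs_saturated_neg2ll(data),
    logLik = -best$value,
    k = as.integer(k), n_eff = n_releases(data),
    converged = best$convergence == 0, boundary = boundary,
    confounded = conf, fixed_p = fixed_p,
    Phi = pm$Phi, P = pm$P, data = data
  ), class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("<cjs_fit> %s  deviance %.2f  k %d  n_eff %d  %s\n",
              x$notation, x$deviance, x$k, x$n_eff,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Coefficient table of a fitted CJS model
#' @param fit a [fit_cjs()] result.
#' @return data.frame `term, beta, se, lo95, hi95, boundary`.
#' @export
coef_table <- function(fit) {
  data.frame(term = names(fit$coef), beta = unname(fit$coef),
             se = unname(fit$se),
             lo95 = unname(fit$coef - 1.96 * fit$se),
             hi95 = unname(fit$coef + 1.96 * fit$se),
             boundary = unname(fit$boundary),
             stringsAsFactors = FALSE)
}

#' Simulate detection histories from CJS probability matrices
#'
#' Given per-individual survival and recapture probability matrices and
#' first-release occasions, draws Bernoulli survival through each interval
#' and Bernoulli detection while alive. Used by the parametric bootstrap
#' and by power simulations.
#'
#' @param Phi,P n x (T-1) probability matrices (`P[, j]` applies at occasion
#'   j + 1).
#' @param first integer vector of release occasions.
#' @return 0/1 history matrix with the same release structure.
#' @export
simulate_cjs_histories <- function(Phi, P, first) {
  n <- nrow(Phi); Tm1 <- ncol(Phi)
  ch <- matrix(0L, n, Tm1 + 1L)
  ch[cbind(seq_len(n), first)] <- 1L
  alive <- rep(TRUE, n)
  started <- rep(FALSE, n)
  for (j in seq_len(Tm1)) {
    started <- started | first == j
    act <- started & alive
    if (!any(act)) next
    surv <- stats::runif(n) < Phi[, j]
    alive[act] <- surv[act]
    det <- act & alive & (stats::runif(n) < P[, j])
    ch[det, j + 1L] <- 1L
  }
  ch
}

#' Bootstrap goodness of fit: the variance inflation factor c-hat
#'
#' Simulates `n_boot` datasets from the fitted model (same release
#' structure), refits the same model to each, and divides the observed
#' deviance by the mean bootstrap deviance. Values below 1 are truncated to
#' 1 for QAICc use (mild underdispersion is treated as sampling noise).
#'
#' @param fit a converged [fit_cjs()].
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return object of class `chat`: list `c_hat`, `c_hat_raw`, `n_boot`,
#'   `boot_deviances`, `n_failed`, `seed`.
#' @export
bootstrap_chat <- function(fit, n_boot = 100, seed = 1L) {
  if (!fit$converged) stopf("c-hat bootstrap requires a converged fit")
  set.seed(seed)
  data <- fit$data
  devs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ch_b <- simulate_cjs_histories(fit$Phi, fit$P, data$first)
    data_b <- capture_data(ch_b, age_at_first = data$age_at_first,
                           sex = data$sex, ind_cov = data$ind_cov,
                           year_cov = data$year_cov)
    fb <- try(fit_cjs(data_b, fit$spec, fixed_p = fit$fixed_p, n_starts = 1),
              silent = TRUE)
    if (!inherits(fb, "try-error") && fb$converged) devs[b] <- fb$deviance
  }
  n_failed <- sum(is.na(devs))
  if (n_failed > 0.2 * n_boot) {
    stopf("%d/%d bootstrap refits failed", n_failed, n_boot)
  }
  raw <- fit$deviance / mean(devs, na.rm = TRUE)
  structure(list(c_hat = max(1, raw), c_hat_raw = raw, n_boot = n_boot,
                 boot_deviances = devs, n_failed = n_failed, seed = seed),
            class = "chat")
}

#' @export
print.chat <- function(x, ...) {
  cat(sprintf("c-hat = %.3f (raw %.3f; %d bootstrap replicates, %d failed)\n",
              x$c_hat, x$c_hat_raw, x$n_boot, x$n_failed))
  invisible(x)
}

#' Quasi-likelihood AICc
#'
#' `QAICc = deviance / c_hat + 2k + 2k(k + 1) / (n_eff - k - 1)`, with
#' `n_eff` the total number of release events (the standard
#' capture-recapture effective sample size).
#'
#' @param fit a [fit_cjs()] result, or a deviance value if `k` is given.
#' @param c_hat variance inflation factor (default 1).
#' @param n_eff effective sample size; defaults to the fit's release count.
#' @param k parameter count; defaults to the fit's `k`.
#' @return QAICc value.
#' @export
qaicc <- function(fit, c_hat = 1, n_eff = NULL, k = NULL) {
  if (inherits(fit, "cjs_fit")) {
    dev <- fit$neg2loglik
    if (is.null(n_eff)) n_eff <- fit$n_eff
    if (is.null(k)) k <- fit$k
  } else {
    dev <- fit
    if (is.null(n_eff) || is.null(k)) stopf("supply n_eff and k with a raw deviance")
  }
  if (n_eff <= k + 1) stopf("n_eff must exceed k + 1")
  dev / c_hat + 2 * k + 2 * k * (k + 1) / (n_eff - k - 1)
}
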