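# model notation parsing, covariate transforms, CJS likelihood/fitting,
# goodness of fit, QAICc

test_that("model notation parses into cub/adult/recapture structures", {
  s <- parse_model("Phi(a2-t/.) p(t)")
  expect_true(s$phi$age_split)
  expect_equal(s$phi$cub, "t")
  expect_equal(s$phi$adult, character(0))
  expect_equal(s$p$terms, "t")
  s2 <- parse_model("Phi(a2-t/sex + popsize) p(t)")
  expect_setequal(s2$phi$adult, c("sex", "popsize"))
  s3 <- parse_model("Phi(a2-t/sex*C) p(t)")
  expect_setequal(s3$phi$adult, c("sex", "C", "sex:C"))
  expect_error(parse_model("Phi(a2-t) p(t)"), "cub.*adult|adult")
  expect_error(parse_model("nonsense"), "parse")
  # constant model has 2 parameters
  d <- sim_const_cjs(n = 40, T = 4, seed = 1)
  f <- fit_cjs(d, "Phi(.) p(.)", n_starts = 1)
  expect_equal(f$k, 2L)
})

test_that("standardize centers to mean 0 and SD 0.5 and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-0.5, 0, 0.5))
  set.seed(2); x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 0.5, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(1, 5)), "variance")
})

test_that("coccidial transform is log1p then month-wise scaling", {
  counts <- c(0, 10, 100, 0, 5, 50)
  month <- c("May", "May", "May", "Jun", "Jun", "Jun")
  got <- transform_coccidia(counts, month)
  # independent two-step oracle
  lx <- log(counts + 1)
  want <- numeric(6)
  for (m in c("May", "Jun")) {
    i <- month == m
    want[i] <- (lx[i] - mean(lx[i])) / (2 * sd(lx[i]))
  }
  expect_equal(got, want, tolerance = 1e-12)
  # zero count contributes log term 0; equal counts within month -> zeros
  expect_equal(transform_coccidia(c(7, 7, 7), rep("Aug", 3)), rep(0, 3))
  expect_error(transform_coccidia(c(-1, 2), c("a", "a")), "negative")
})

test_that("mean imputation fills by column mean and keeps a mask", {
  x <- cbind(a = c(1, NA, 3), b = c(2, 2, NA))
  got <- impute_missing(x)
  expect_equal(got[, "a"], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(unname(got[2, "a"]), 2)
  expect_equal(unname(got[3, "b"]), 2)
  expect_equal(sum(attr(got, "imputed")), 2)
  full <- cbind(a = 1:3, b = 4:6)
  expect_equal(unname(impute_missing(full)), unname(full), ignore_attr = TRUE)
  expect_error(impute_missing(cbind(a = c(NA, NA))), "fully missing")
})

test_that("degenerate all-detected data drives phi and p to 1", {
  ch <- matrix(1L, 10, 3)
  d <- capture_data(ch, age_at_first = "adult")
  f <- fit_cjs(d, "Phi(.) p(.)", n_starts = 1)
  expect_gt(plogis(f$coef[1]), 0.999)
  expect_gt(plogis(f$coef[2]), 0.999)
})

test_that("constant-model MLE matches a 200x200 grid-search oracle", {
  d <- sim_const_cjs(n = 30, T = 5, phi = 0.75, p = 0.55, seed = 5)
  f <- fit_cjs(d, "Phi(.) p(.)", n_starts = 2)
  grid <- seq(-3, 3, length.out = 200)
  best <- c(NA, NA); bestv <- Inf
  for (a in grid) for (b in grid) {
    v <- oracle_const_cjs_nll(plogis(a), plogis(b), d$ch, d$first)
    if (v < bestv) { bestv <- v; best <- c(a, b) }
  }
  # optimizer at least as good as the grid, and close in probability scale
  expect_lte(f$neg2loglik / 2, bestv + 1e-6)
  expect_lt(abs(plogis(f$coef[1]) - plogis(best[1])), 0.02)
  expect_lt(abs(plogis(f$coef[2]) - plogis(best[2])), 0.02)
  # the package nll agrees with the independent transcription everywhere
  for (a in c(-1, 0, 1)) for (b in c(-0.5, 0.5)) {
    ctx <- hfcsurv:::make_cjs_context(d, parse_model("Phi(.) p(.)"), NULL)
    expect_equal(hfcsurv:::cjs_nll(c(a, b), ctx),
                 oracle_const_cjs_nll(plogis(a), plogis(b), d$ch, d$first),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to individual order and nesting never raises deviance", {
  d <- sim_const_cjs(n = 120, T = 6, seed = 9)
  f1 <- fit_cjs(d, "Phi(.) p(.)", n_starts = 1)
  set.seed(1)
  perm <- sample(d$n)
  d2 <- capture_data(d$ch[perm, ], age_at_first = d$age_at_first[perm],
                     sex = d$sex[perm])
  f2 <- fit_cjs(d2, "Phi(.) p(.)", n_starts = 1)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-6)
  # nested models: adding year dependence cannot increase the deviance
  f3 <- fit_cjs(d, "Phi(t) p(.)", n_starts = 2)
  expect_lte(f3$deviance, f1$deviance + 1e-4)
})

test_that("an individual never seen again adds exactly its unobserved-fate term", {
  d <- sim_const_cjs(n = 80, T = 5, seed = 11)
  spec <- parse_model("Phi(.) p(.)")
  beta <- c(0.4, -0.2)
  ctx1 <- hfcsurv:::make_cjs_context(d, spec, NULL)
  nll1 <- hfcsurv:::cjs_nll(beta, ctx1)
  # append one individual released at occasion 2, never redetected
  ch2 <- rbind(d$ch, ghost = c(0L, 1L, 0L, 0L, 0L))
  d2 <- capture_data(ch2, age_at_first = "adult")
  ctx2 <- hfcsurv:::make_cjs_context(d2, spec, NULL)
  nll2 <- hfcsurv:::cjs_nll(beta, ctx2)
  phi <- plogis(beta[1]); p <- plogis(beta[2])
  chi <- 1
  for (j in 3:1) chi <- (1 - phi) + phi * (1 - p) * chi  # occasions 3..5
  expect_equal(nll2 - nll1, -log(chi), tolerance = 1e-10)
})

test_that("terminal phi*p confounding is counted once and shows profile flatness", {
  set.seed(13)
  n <- 150; T <- 4
  first <- sample(1:2, n, TRUE)
  ch <- simulate_cjs_histories(matrix(0.7, n, T - 1), matrix(0.6, n, T - 1), first)
  d <- capture_data(ch, age_at_first = "adult")
  f <- fit_cjs(d, "Phi(t) p(t)", n_starts = 2)
  expect_equal(f$k, 2 * T - 3)    # 6 coefficients, 1 confounded
  # profile flatness: moving the last phi and compensating p leaves nll flat
  ctx <- hfcsurv:::make_cjs_context(d, parse_model("Phi(t) p(t)"), NULL)
  beta <- f$coef
  nll0 <- hfcsurv:::cjs_nll(beta, ctx)
  # indexes: phi block is (Intercept), t2, t3; p block (Intercept), t2, t3
  phiT <- plogis(beta[1] + beta[3])
  pT <- plogis(beta[4] + beta[6])
  for (delta in c(-0.5, 0.5)) {
    phi_new <- plogis(qlogis(phiT) + delta)
    p_new <- phiT * pT / phi_new
    b2 <- beta
    b2[3] <- qlogis(phi_new) - beta[1]
    b2[6] <- qlogis(p_new) - beta[4]
    expect_equal(hfcsurv:::cjs_nll(b2, ctx), nll0, tolerance = 1e-6)
  }
})

test_that("age-split designs put covariates on the right intervals", {
  # cubs get their first interval in the cub class, adults afterwards
  set.seed(3)
  n <- 400; T <- 6
  first <- sample(1:(T - 2), n, TRUE)
  phi_cub <- 0.55; phi_ad <- 0.85
  Phi <- matrix(phi_ad, n, T - 1)
  Phi[cbind(seq_len(n), first)] <- phi_cub
  ch <- simulate_cjs_histories(Phi, matrix(0.7, n, T - 1), first)
  d <- capture_data(ch, age_at_first = "cub")
  f <- fit_cjs(d, "Phi(a2-./.) p(.)", n_starts = 2)
  expect_lt(abs(plogis(f$coef["phi:cub:(Intercept)"]) - phi_cub), 0.08)
  expect_lt(abs(plogis(f$coef["phi:ad:(Intercept)"]) - phi_ad), 0.06)
})

test_that("individual and year covariates with fixed recapture are recovered", {
  set.seed(21)
  n <- 800; T <- 8
  x <- rnorm(n, 0, 0.5)                    # standardized-scale covariate
  yr <- rnorm(T - 1, 0, 0.5)
  first <- sample(1:(T - 2), n, TRUE)
  b_x <- 0.8; b_yr <- 0.6
  Phi <- plogis(outer(b_x * x, b_yr * yr, "+") + 0.8)
  ch <- simulate_cjs_histories(Phi, matrix(0.65, n, T - 1), first)
  d <- capture_data(ch, age_at_first = "adult",
                    ind_cov = data.frame(x = x),
                    year_cov = data.frame(z = yr))
  f <- fit_cjs(d, "Phi(x + z) p(.)", n_starts = 2)
  expect_lt(abs(f$coef["phi:x"] - b_x), 0.3)
  expect_lt(abs(f$coef["phi:z"] - b_yr), 0.3)
  # fixed recapture: same structure, p pinned at truth, excluded from k
  ff <- fit_cjs(d, "Phi(x + z) p(.)", fixed_p = 0.65, n_starts = 2)
  expect_equal(ff$k, 3L)
  expect_lt(abs(ff$coef["phi:x"] - b_x), 0.3)
})

test_that("QAICc arithmetic is exact and limits to QAIC", {
  expect_equal(qaicc(100, c_hat = 1, n_eff = 50, k = 3), 100 + 6 + 24 / 46)
  expect_equal(qaicc(100, c_hat = 2, n_eff = 50, k = 3), 50 + 6 + 24 / 46)
  expect_equal(qaicc(100, c_hat = 1, n_eff = 1e12, k = 3), 106,
               tolerance = 1e-9)
  expect_error(qaicc(100, c_hat = 1, n_eff = 4, k = 3), "exceed")
})

test_that("bootstrap c-hat is calibrated, detects overdispersion, and is deterministic", {
  d <- sim_const_cjs(n = 150, T = 6, seed = 31)
  f <- fit_cjs(d, "Phi(.) p(.)", n_starts = 1)
  c1 <- bootstrap_chat(f, n_boot = 30, seed = 4)
  c2 <- bootstrap_chat(f, n_boot = 30, seed = 4)
  expect_identical(c1$c_hat, c2$c_hat)
  # a single replicate is noisy; the multi-seed calibration lives in the
  # acceptance suite
  expect_lt(abs(c1$c_hat_raw - 1), 0.3)
  # overdispersed data: clone each history (paired identical fates)
  dd <- capture_data(d$ch[rep(seq_len(d$n), each = 2), ],
                     age_at_first = "adult")
  fo <- fit_cjs(dd, "Phi(.) p(.)", n_starts = 1)
  co <- bootstrap_chat(fo, n_boot = 30, seed = 5)
  expect_gt(co$c_hat_raw, c1$c_hat_raw)
})

test_that("covariate slope recovery is nearly unbiased across a small grid", {
  # 2 effect sizes x 2 sample sizes, 6 replicates each (reduced grid)
  for (b in c(0.5, 1.0)) for (n in c(200, 400)) {
    err <- vapply(1:6, function(r) {
      set.seed(1000 * b + n + r)
      x <- rnorm(n, 0, 0.5)
      first <- sample(1:3, n, TRUE)
      Phi <- matrix(plogis(0.8 + b * x), n, 5)
      ch <- simulate_cjs_histories(Phi, matrix(0.6, n, 5), first)
      d <- capture_data(ch, age_at_first = "adult",
                        ind_cov = data.frame(x = x))
      fit_cjs(d, "Phi(x) p(.)", n_starts = 1)$coef["phi:x"] - b
    }, numeric(1))
    expect_lt(abs(median(err)), 0.35)
  }
})

test_that("MARK-style .inp round-trips with frequency expansion", {
  f <- tempfile(fileext = ".inp")
  writeLines(c("/* comment */ 101100 2;", "110000 1;"), f)
  ch <- read_inp(f)
  expect_equal(nrow(ch), 3)
  expect_equal(unname(ch[1, ]), c(1, 0, 1, 1, 0, 0))
  expect_equal(unname(ch[3, ]), c(1, 1, 0, 0, 0, 0))
  f2 <- tempfile(fileext = ".inp")
  write_inp(ch, f2)
  expect_equal(read_inp(f2), ch, ignore_attr = TRUE)
  writeLines("xyz 1;", f2)
  expect_error(read_inp(f2), "malformed")
})
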