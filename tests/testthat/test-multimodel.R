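# Delta/weight arithmetic, evidence ratios, model averaging, VIF screen,
# local-vs-general comparison

test_that("rank_models computes Delta, weights and plausibility", {
  q <- c(A = 110, B = 112, C = 130)
  s <- rank_models(q + 0, names = names(q))
  expect_equal(s$delta, c(0, 2, 20))
  expect_equal(sum(s$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(s$weight) <= 0))      # weight monotone in Delta
  expect_equal(s$plausible, c(TRUE, TRUE, FALSE))
  expect_equal(rank_models(5)$weight, 1)
  expect_error(rank_models(c(1, NA)), "NA")
})

test_that("evidence ratios follow the Delta identity and invert", {
  s <- rank_models(c(100, 103.98), names = c("a", "b"))
  expect_equal(evidence_ratio(s, "a", "b"), exp(0.5 * 3.98))
  expect_equal(evidence_ratio(s, "a", "b") * evidence_ratio(s, "b", "a"), 1)
  expect_equal(evidence_ratio(s, "a", "a"), 1)
  # survives underflow via the identity
  s2 <- rank_models(c(0, 4000), names = c("a", "b"))
  expect_true(is.finite(evidence_ratio(s2, "b", "a")))
})

test_that("model averaging: natural vs zero, importance, unconditional SE", {
  # two models, equal weights, term only in the first
  s <- rank_models(c(100, 100), names = c("with", "without"))
  est <- c(1.0, NA); ses <- c(0.5, NA)
  nat <- model_average(s, "x", est, ses, "natural")
  zer <- model_average(s, "x", est, ses, "zero")
  expect_equal(nat$beta, 1.0)
  expect_equal(zer$beta, 0.5)
  expect_equal(nat$relative_importance, 0.5)
  # natural SE folds no selection spread here (single containing model)
  expect_equal(nat$se, 0.5)
  # zero method: se = sum w sqrt(var + (b - bbar)^2)
  expect_equal(zer$se, 0.5 * sqrt(0.25 + 0.25) + 0.5 * sqrt(0 + 0.25))
  # term in all models: natural == zero
  est2 <- c(0.8, 0.4); ses2 <- c(0.2, 0.3)
  cols <- c("beta", "se", "lo95", "hi95", "relative_importance")
  expect_equal(model_average(s, "x", est2, ses2, "natural")[, cols],
               model_average(s, "x", est2, ses2, "zero")[, cols],
               tolerance = 1e-12)
  expect_error(model_average(s, "x", c(NA, NA), c(NA, NA), "natural"),
               "absent")
})

test_that("4-model synthetic set matches a hand computation of the unconditional SE", {
  q <- c(m1 = 200, m2 = 201, m3 = 203, m4 = 215)   # m4 implausible
  s <- rank_models(q + 0, names = names(q))
  est <- c(0.9, 0.5, NA, 2.0)
  ses <- c(0.30, 0.40, NA, 0.10)
  # hand computation over the plausible set {m1, m2, m3}
  w <- exp(-0.5 * c(0, 1, 3)); w <- w / sum(w)
  win <- w[1:2] / sum(w[1:2])
  b_nat <- sum(win * est[1:2])
  se_nat <- sum(win * sqrt(ses[1:2]^2 + (est[1:2] - b_nat)^2))
  nat <- model_average(s, "x", est, ses, "natural")
  expect_equal(nat$beta, b_nat, tolerance = 1e-10)
  expect_equal(nat$se, se_nat, tolerance = 1e-10)
  b_zero <- sum(w * c(est[1:2], 0))
  se_zero <- sum(w * sqrt(c(ses[1:2], 0)^2 + (c(est[1:2], 0) - b_zero)^2))
  zer <- model_average(s, "x", est, ses, "zero")
  expect_equal(zer$beta, b_zero, tolerance = 1e-10)
  expect_equal(zer$se, se_zero, tolerance = 1e-10)
  # identity: zero = natural x importance (renormalized in the plausible set)
  expect_equal(zer$beta, nat$beta * nat$relative_importance, tolerance = 1e-12)
  # adding an implausible model does not change the averages
  s5 <- rank_models(c(q, m5 = 230), names = c(names(q), "m5"))
  nat5 <- model_average(s5, "x", c(est, 5), c(ses, 1), "natural")
  expect_equal(nat5$beta, nat$beta, tolerance = 1e-12)
  expect_equal(nat5$se, nat$se, tolerance = 1e-12)
})

test_that("relative importance sums plausible containing weights", {
  q <- c(100, 100, 100, 120)
  tt <- list(c("x", "z"), c("z"), c("x"), c("x"))
  s <- rank_models(q, names = paste0("m", 1:4))
  # weights are over the full considered set, so the implausible model's
  # (tiny) weight stays in the denominator
  w1 <- 1 / (3 + exp(-10))
  expect_equal(relative_importance(s, "x", tt), 2 * w1, tolerance = 1e-12)
  expect_equal(relative_importance(s, "z", tt), 2 * w1, tolerance = 1e-12)
  expect_equal(relative_importance(s, "absent", tt), 0)
})

test_that("zero = natural x importance on randomized synthetic model sets", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(3:8, 1)
    q <- 100 + c(0, cumsum(abs(rnorm(m - 1, 1, 2))))
    s <- rank_models(q, names = paste0("m", seq_len(m)))
    has <- runif(m) < 0.6
    if (!any(has & s$plausible)) has[1] <- TRUE
    est <- ifelse(has, rnorm(m), NA)
    ses <- ifelse(has, runif(m, 0.1, 1), NA)
    nat <- model_average(s, "x", est, ses, "natural")
    zer <- model_average(s, "x", est, ses, "zero")
    expect_equal(zer$beta, nat$beta * nat$relative_importance,
                 tolerance = 1e-10)
  }
})

test_that("VIF screen matches a direct R^2 oracle and drops collinear columns", {
  set.seed(8)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  v <- vif_screen(X, threshold = 5)
  expect_setequal(v$retained, colnames(X))
  # oracle VIFs via lm
  for (j in seq_len(ncol(X))) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v$vif[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # orthogonal columns -> VIF 1
  Q <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(unname(vif_screen(Q)$vif), rep(1, 3), tolerance = 1e-3)
  # duplicated column -> infinite VIF, one copy dropped first
  XD <- cbind(X, c1_dup = X[, "c1"])
  vd <- vif_screen(XD, threshold = 5)
  expect_true(is.infinite(max(vd$vif_initial)))
  expect_length(vd$dropped, 1)
  expect_true(vd$dropped %in% c("c1", "c1_dup"))
  # correlated design: iterative drop until all below threshold
  Z <- X
  Z[, 2] <- X[, 1] + rnorm(200, 0, 0.2)
  vz <- vif_screen(Z, threshold = 5)
  expect_true(all(vz$vif <= 5))
})

test_that("identical fits differ in QAICc only by the parameter-count terms", {
  dev <- 500; n <- 400
  q1 <- qaicc(dev, c_hat = 1, n_eff = n, k = 5)
  q2 <- qaicc(dev, c_hat = 1, n_eff = n, k = 8)
  expect_equal(q2 - q1, 2 * 3 + 2 * 8 * 9 / (n - 9) - 2 * 5 * 6 / (n - 6))
})

test_that("local vs general comparison separates its generating worlds", {
  # reduced replicate counts: 6 replicates per world, majority criterion
  wins_general <- 0; wins_local <- 0
  n_rep <- 6
  for (r in seq_len(n_rep)) {
    # general world: survival depends on f-like genome-wide signal
    sim <- simulate_population(scenario("general_effect", seed = 7000 + r,
                                        n_years = 8, n_founders = 120,
                                        n_loci = 12, max_cubs_per_year = 70))
    d <- sim$captures
    prof <- het_profile(sim$genotypes)
    d2 <- hfcsurv:::attach_sh_covariates(d, prof, sim$pedigree, sim$genotypes)
    slh <- hfcsurv:::slh_for_role(hfcsurv:::slh_matrix(sim$genotypes),
                                  sim$pedigree, rownames(d2$ch), "SH_Ind")
    lg <- compare_local_general(d2, slh, "SH_Ind", n_starts = 1)
    if (lg$table$model[1] == "multilocus") wins_general <- wins_general + 1

    sim <- simulate_population(scenario("local_effect", seed = 7100 + r,
                                        n_years = 8, n_founders = 120,
                                        n_loci = 12, max_cubs_per_year = 70,
                                        beta = c(Twt = 0.66, locus1 = 2.5)))
    d <- sim$captures
    prof <- het_profile(sim$genotypes)
    d2 <- hfcsurv:::attach_sh_covariates(d, prof, sim$pedigree, sim$genotypes)
    slh <- hfcsurv:::slh_for_role(hfcsurv:::slh_matrix(sim$genotypes),
                                  sim$pedigree, rownames(d2$ch), "SH_Ind")
    lg <- compare_local_general(d2, slh, "SH_Ind", n_starts = 1)
    if (lg$table$model[1] == "single_locus") wins_local <- wins_local + 1
  }
  expect_gte(wins_general, ceiling(0.8 * n_rep))
  # the single-locus world must favor the single-locus model more often
  # than the general world does
  expect_gt(wins_local, n_rep - wins_general)
})
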