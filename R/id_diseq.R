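#' Identity disequilibrium: the g2 statistic
#'
#' g2 measures the excess covariance in heterozygosity across loci created
#' by variance in inbreeding: in a population where some individuals are
#' more inbred than others, heterozygosity is correlated between unlinked
#' loci, and multilocus marker heterozygosity carries information about the
#' genome-wide inbreeding coefficient. g2 = 0 under no inbreeding variance.
#'
#' The point estimate follows the multilocus estimator of David et al.
#' (2007) for data with missing genotypes: a ratio of unbiased moment
#' estimators,
#' \deqn{\hat g_2 = \frac{\sum_{j \ne k} \sum_i h_{ij} h_{ik} / n_{jk}}
#'                       {\sum_{j \ne k} \sum_{i \ne i'} h_{ij} h_{i'k} / m_{jk}} - 1}
#' where `h` is the 0/1 heterozygosity indicator, `n_jk` counts individuals
#' typed at both loci of a pair and `m_jk` counts ordered pairs of distinct
#' individuals typed at `j` and `k` respectively; missing calls drop out of
#' both moments. The numerator estimates the mean within-individual
#' cross-locus joint heterozygosity, the denominator the product of the
#' locus heterozygosities under independence.
#'
#' The standard error is a bootstrap over individuals; the p-value is a
#' permutation test whose null shuffles each locus's heterozygosity column
#' independently across individuals, which destroys between-locus
#' correlation while preserving each locus's heterozygosity and
#' missingness. Both resamples use `n_iter` iterations.
#'
#' @param g a [genotype_table()].
#' @param n_iter bootstrap/permutation iterations (default 1000).
#' @param seed integer seed, recorded in the result.
#' @return object of class `g2_result`: list with `g2`, `se`, `p_value`,
#'   `n_iter`, `seed`, `boot` (bootstrap estimates), `perm` (null
#'   estimates).
#' @export
g2_stat <- function(g, n_iter = 1000, seed = 1L) {
  h <- slh_matrix(g)
  poly <- apply(h, 2, function(x) any(x == 1, na.rm = TRUE) && any(!is.na(x)))
  if (ncol(h) < 2) stopf("g2 undefined for one locus")
  if (sum(poly) < 2) stopf("g2 requires at least 2 polymorphic loci")
  if (nrow(h) < 10) warnf("g2 on fewer than 10 individuals is unreliable")
  obs <- g2_point(h)
  set.seed(seed)
  n <- nrow(h)
  boot <- vapply(seq_len(n_iter), function(b) {
    g2_point(h[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1))
  perm <- vapply(seq_len(n_iter), function(b) {
    hp <- apply(h, 2, function(col) col[sample.int(n)])
    g2_point(hp)
  }, numeric(1))
  structure(list(
    g2 = obs,
    se = stats::sd(boot, na.rm = TRUE),
    p_value = mean(perm >= obs, na.rm = TRUE),
    n_iter = n_iter, seed = seed, boot = boot, perm = perm
  ), class = "g2_result")
}

#' @export
print.g2_result <- function(x, ...) {
  cat(sprintf("g2 = %.4g (SE %.3g), permutation P = %.3g [%d iterations, seed %d]\n",
              x$g2, x$se, x$p_value, x$n_iter, x$seed))
  invisible(x)
}

# vectorized point estimate on a 0/1/NA heterozygosity matrix
g2_point <- function(h) {
  t_mat <- !is.na(h)
  hh <- h
  hh[!t_mat] <- 0
  storage.mode(hh) <- "double"
  tm <- t_mat * 1
  # within-individual cross products per locus pair
  S_w <- crossprod(hh)            # sum_i h_ij h_ik
  N_w <- crossprod(tm)            # n_jk
  ch <- colSums(hh)
  ct <- colSums(tm)
  S_b <- outer(ch, ch) - S_w      # sum_{i != i'} h_ij h_i'k
  N_b <- outer(ct, ct) - N_w      # m_jk
  off <- upper.tri(S_w) | lower.tri(S_w)
  ok <- off & N_w > 0 & N_b > 0
  num <- sum(S_w[ok] / N_w[ok])
  den <- sum(S_b[ok] / N_b[ok])
  if (den <= 0) return(NA_real_)
  num / den - 1
}

#' Heterozygosity-heterozygosity correlation (HHC)
#'
#' Splits the marker panel at random into two halves, computes each
#' individual's proportion of typed loci heterozygous in each half, and
#' correlates the two (Spearman). Repeated over random splits; a positive
#' mean HHC indicates that heterozygosity is correlated across marker
#' subsets, i.e. identity disequilibrium.
#'
#' @param g a [genotype_table()].
#' @param n_splits number of random splits (default 100).
#' @param split_sizes two integers summing to the number of loci; default
#'   splits as evenly as possible (e.g. 17/18 for a 35-locus panel).
#' @param seed integer seed.
#' @return object of class `hhc_result`: list with `coefficients` (length
#'   `n_splits`), `mean`, `sd`, `min`, `max`, `seed`.
#' @export
hhc <- function(g, n_splits = 100, split_sizes = NULL, seed = 1L) {
  L <- n_loc(g)
  if (L < 2) stopf("HHC requires at least 2 loci")
  if (is.null(split_sizes)) split_sizes <- c(floor(L / 2), ceiling(L / 2))
  if (sum(split_sizes) != L) stopf("split sizes must sum to the number of loci (%d)", L)
  h <- slh_matrix(g)
  set.seed(seed)
  co <- vapply(seq_len(n_splits), function(s) {
    half1 <- sample.int(L, split_sizes[1])
    m1 <- rowMeans(h[, half1, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(h[, -half1, drop = FALSE], na.rm = TRUE)
    ok <- is.finite(m1) & is.finite(m2)
    suppressWarnings(stats::cor(m1[ok], m2[ok], method = "spearman"))
  }, numeric(1))
  structure(list(coefficients = co, mean = mean(co, na.rm = TRUE),
                 sd = stats::sd(co, na.rm = TRUE),
                 min = min(co, na.rm = TRUE), max = max(co, na.rm = TRUE),
                 n_splits = n_splits, split_sizes = split_sizes, seed = seed),
            class = "hhc_result")
}

#' @export
print.hhc_result <- function(x, ...) {
  cat(sprintf("HHC over %d random %d/%d splits: mean %.3f (SD %.3f, range %.3f..%.3f)\n",
              x$n_splits, x$split_sizes[1], x$split_sizes[2],
              x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Expected correlation between standardized heterozygosity and inbreeding
#'
#' Under the classic inbreeding model the expected heterozygosity of an
#' individual with inbreeding coefficient `f` is proportional to `(1 - f)`,
#' so for standardized heterozygosity (population mean 1) the expected
#' Pearson correlation with `f` is
#' \deqn{r = -\frac{\sigma(f)}{(1 - E(f))\,\sigma(H)}}
#' with `E(f)` and `sigma(f)` the mean and SD of the inbreeding coefficient
#' and `sigma(H)` the SD of standardized heterozygosity. The correlation is
#' never positive: inbreeding can only depress heterozygosity.
#'
#' @param e_f mean inbreeding coefficient.
#' @param sd_f SD of the inbreeding coefficient (>= 0).
#' @param sd_h SD of standardized heterozygosity (> 0).
#' @return data.frame `e_f, sd_f, sd_h, r_expected` with `r_expected <= 0`
#'   (clamped at -1).
#' @export
expected_r_sh_f <- function(e_f, sd_f, sd_h) {
  if (sd_h <= 0) stopf("sd_h must be positive")
  if (sd_f < 0) stopf("sd_f must be nonnegative")
  r <- -sd_f / ((1 - e_f) * sd_h)
  r <- max(r, -1)
  data.frame(e_f = e_f, sd_f = sd_f, sd_h = sd_h, r_expected = r)
}

#' Observed rank correlation between heterozygosity and inbreeding
#'
#' @param profiles data.frame from [het_profile()] (needs `individual`,
#'   `sh`).
#' @param inbreeding data.frame from [inbreeding_records()] (needs `id`,
#'   `f`).
#' @return list `rho`, `p_value`, `n` (Spearman with mid-ranks; two-sided).
#' @export
observed_r_sh_f <- function(profiles, inbreeding) {
  m <- merge(profiles[, c("individual", "sh")],
             inbreeding[, c("id", "f")],
             by.x = "individual", by.y = "id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stopf("need at least 3 paired observations")
  if (stats::sd(m$f) == 0 || stats::sd(m$sh) == 0) {
    warnf("zero variance in f or SH; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(m)))
  }
  ct <- suppressWarnings(
    stats::cor.test(m$sh, m$f, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}
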