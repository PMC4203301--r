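# QAICc model ranking, Akaike weights, model averaging and the
# local-vs-general (single-locus vs multilocus) comparison.

#' Rank models by QAICc
#'
#' Computes, for a set of models, the QAICc difference from the top model
#' (Delta), the relative Akaike weight
#' `w = exp(-0.5 Delta) / sum(exp(-0.5 Delta))` over all considered models,
#' and a plausibility flag (`Delta < 7`).
#'
#' @param qaicc numeric vector of QAICc values (or a list of [fit_cjs()]
#'   objects with a `c_hat`).
#' @param names model names/notations.
#' @param k,deviance optional columns carried into the table.
#' @param plausible_delta plausibility threshold (default 7).
#' @return object of class `model_set`: data.frame
#'   `model, k, deviance, qaicc, delta, weight, plausible`, ordered by
#'   Delta then name.
#' @export
rank_models <- function(qaicc, names = NULL, k = NA, deviance = NA,
                        plausible_delta = 7) {
  if (is.list(qaicc) && all(vapply(qaicc, inherits, logical(1), "cjs_fit"))) {
    stopf("pass QAICc values; use qaicc() on each fit first")
  }
  q <- as.numeric(qaicc)
  if (anyNA(q)) stopf("NaN/NA QAICc value(s)")
  if (is.null(names)) names <- paste0("model", seq_along(q))
  delta <- q - min(q)
  w <- exp(-0.5 * delta)
  w <- w / sum(w)
  out <- data.frame(model = names, k = k, deviance = deviance, qaicc = q,
                    delta = delta, weight = w,
                    plausible = delta < plausible_delta,
                    stringsAsFactors = FALSE)
  out <- out[order(out$delta, out$model), ]
  rownames(out) <- NULL
  class(out) <- c("model_set", "data.frame")
  out
}

#' Evidence ratio between two models
#'
#' The ratio of Akaike weights, computed through the Delta identity
#' `exp(0.5 (Delta_b - Delta_a))` for numerical stability when weights
#' underflow.
#'
#' @param set a [rank_models()] result.
#' @param a,b model names.
#' @return numeric evidence ratio (support for `a` relative to `b`).
#' @export
evidence_ratio <- function(set, a, b) {
  ia <- match(a, set$model); ib <- match(b, set$model)
  if (is.na(ia) || is.na(ib)) stopf("model not in set")
  exp(0.5 * (set$delta[ib] - set$delta[ia]))
}

#' Relative importance of a term
#'
#' The summed Akaike weight of the plausible models that contain the term
#' (weights taken over the full considered set).
#'
#' @param set a [rank_models()] result.
#' @param term term name.
#' @param terms_by_model list (aligned with `set$model`) of character
#'   vectors naming each model's terms; or a logical vector of containment.
#' @return numeric in \[0, 1\].
#' @export
relative_importance <- function(set, term, terms_by_model) {
  contains <- containment(set, term, terms_by_model)
  sum(set$weight[contains & set$plausible])
}

containment <- function(set, term, terms_by_model) {
  if (is.logical(terms_by_model)) return(terms_by_model)
  if (length(terms_by_model) != nrow(set)) {
    stopf("terms_by_model must align with the model set")
  }
  vapply(terms_by_model, function(tt) term %in% tt, logical(1))
}

#' Model-averaged coefficient for a term
#'
#' Averages a coefficient over the plausible model set (`Delta < 7`), with
#' weights renormalized within that set. Two conventions:
#' \describe{
#'   \item{natural}{average only over plausible models containing the term,
#'     weighted by their renormalized weights (i.e. divided by the summed
#'     weight of the containing models).}
#'   \item{zero}{substitute an estimate (and SE) of zero in plausible models
#'     not containing the term. The zero-method estimate equals the natural
#'     estimate times the term's relative importance computed within the
#'     plausible set.}
#' }
#' The unconditional standard error follows Burnham & Anderson:
#' `se = sum_i w_i sqrt(var_i + (beta_i - beta_bar)^2)` over the averaged
#' set, which folds model-selection uncertainty into the SE.
#'
#' @param set a [rank_models()] result.
#' @param term term name.
#' @param estimates,ses numeric vectors aligned with `set$model` (NA where
#'   the term is absent).
#' @param method `"natural"` or `"zero"`.
#' @return data.frame `term, method, beta, se, lo95, hi95,
#'   relative_importance`.
#' @export
model_average <- function(set, term, estimates, ses,
                          method = c("natural", "zero")) {
  method <- match.arg(method)
  if (length(estimates) != nrow(set) || length(ses) != nrow(set)) {
    stopf("estimates/ses must align with the model set")
  }
  pl <- set$plausible
  has <- !is.na(estimates)
  if (!any(has & pl) && method == "natural") {
    stopf("term '%s' absent from every plausible model", term)
  }
  w_pl <- set$weight[pl] / sum(set$weight[pl])   # renormalized within set
  est_pl <- estimates[pl]
  se_pl <- ses[pl]
  has_pl <- has[pl]
  imp <- sum(w_pl[has_pl])
  if (method == "natural") {
    w <- w_pl[has_pl] / sum(w_pl[has_pl])
    e <- est_pl[has_pl]
    s <- se_pl[has_pl]
  } else {
    w <- w_pl
    e <- ifelse(has_pl, est_pl, 0)
    s <- ifelse(has_pl, se_pl, 0)
  }
  beta <- sum(w * e)
  se <- sum(w * sqrt(s^2 + (e - beta)^2))
  data.frame(term = term, method = method, beta = beta, se = se,
             lo95 = beta - 1.96 * se, hi95 = beta + 1.96 * se,
             relative_importance = imp, stringsAsFactors = FALSE)
}

#' Variance inflation factor screen
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column `j` on the others.
#' Columns above the threshold are dropped iteratively, highest first;
#' perfectly collinear columns report `Inf` and go first.
#'
#' @param x numeric design matrix (>= 2 columns).
#' @param threshold drop columns with VIF above this (default 5).
#' @return list `retained` (colnames kept), `dropped`, `vif` (final VIFs of
#'   retained columns), `vif_initial`.
#' @export
vif_screen <- function(x, threshold = 5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2) stopf("VIF needs at least 2 columns")
  vifs <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      fit <- stats::lm.fit(cbind(1, m[, -j, drop = FALSE]), m[, j])
      ssr <- sum(fit$residuals^2)
      sst <- sum((m[, j] - mean(m[, j]))^2)
      if (sst == 0) return(Inf)
      r2 <- 1 - ssr / sst
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- x
  dropped <- character(0)
  v0 <- stats::setNames(vifs(keep), colnames(keep))
  repeat {
    v <- vifs(keep)
    if (ncol(keep) <= 1 || max(v) <= threshold) break
    worst <- which.max(v)
    dropped <- c(dropped, colnames(keep)[worst])
    keep <- keep[, -worst, drop = FALSE]
  }
  list(retained = colnames(keep), dropped = dropped,
       vif = stats::setNames(vifs(keep), colnames(keep)),
       vif_initial = v0)
}

#' Single-locus vs multilocus survival model comparison
#'
#' Fits two first-year-survival models with the CJS engine and compares
#' them by QAICc: (1) a "local" model with every retained single-locus
#' heterozygosity indicator (SLH) plus its interaction with summer
#' rainfall, and (2) a "general" model with multilocus standardized
#' heterozygosity (SH) plus its rainfall interaction. Both include the
#' climate main effects. A lower QAICc for the multilocus model supports
#' genome-wide (inbreeding) effects; a win for the single-locus model
#' supports local/direct effects.
#'
#' Loci are screened before fitting: loci with fewer than `min_het`
#' heterozygous individuals are excluded, as are loci failing the
#' [vif_screen()] collinearity check; missing SLH values are mean-imputed
#' ([impute_missing()]).
#'
#' @param data a [capture_data()] whose `ind_cov` contains the multilocus
#'   measure named by `sh_term` and whose `year_cov` contains `SR` and
#'   `Twt`.
#' @param slh matrix of 0/1/NA single-locus heterozygosity indicators
#'   (individuals x loci, aligned with `data`).
#' @param sh_term name of the multilocus covariate in `data$ind_cov`
#'   (e.g. `"SH_Ind"`, `"SH_Mat"`, `"SH_Pat"`).
#' @param min_het heterozygote-count screen (default 7).
#' @param vif_threshold collinearity screen (default 5).
#' @param c_hat variance inflation factor for QAICc (default 1).
#' @param n_starts optimizer starts per model.
#' @return list with `table` (a two-row [rank_models()] set), `fits`,
#'   `excluded_loci`.
#' @export
compare_local_general <- function(data, slh, sh_term, min_het = 7,
                                  vif_threshold = 5, c_hat = 1,
                                  n_starts = 2) {
  slh <- as.matrix(slh)
  if (is.null(colnames(slh))) colnames(slh) <- paste0("L", seq_len(ncol(slh)))
  het_n <- colSums(slh == 1, na.rm = TRUE)
  low <- colnames(slh)[het_n < min_het]
  slh1 <- slh[, het_n >= min_het, drop = FALSE]
  if (ncol(slh1) < 2) stopf("fewer than 2 loci survive the heterozygote screen")
  slh1 <- impute_missing(slh1)
  vs <- vif_screen(slh1, threshold = vif_threshold)
  excluded <- list(low_het = low, collinear = vs$dropped)
  slh2 <- slh1[, vs$retained, drop = FALSE]
  colnames(slh2) <- paste0("slh_", colnames(slh2))
  data_l <- data
  data_l$ind_cov <- cbind(data$ind_cov, as.data.frame(slh2))
  terms_l <- c(colnames(slh2), paste0(colnames(slh2), ":SR"), "SR", "Twt")
  terms_g <- c(sh_term, paste0(sh_term, ":SR"), "SR", "Twt")
  note_l <- paste0("Phi(a2-", paste(terms_l, collapse = " + "), "/sex) p(t)")
  note_g <- paste0("Phi(a2-", paste(terms_g, collapse = " + "), "/sex) p(t)")
  fit_l <- fit_cjs(data_l, note_l, n_starts = n_starts)
  fit_g <- fit_cjs(data, note_g, n_starts = n_starts)
  q <- c(single_locus = qaicc(fit_l, c_hat),
         multilocus = qaicc(fit_g, c_hat))
  tab <- rank_models(q, names = names(q), k = c(fit_l$k, fit_g$k),
                     deviance = c(fit_l$deviance, fit_g$deviance))
  list(table = tab, fits = list(single_locus = fit_l, multilocus = fit_g),
       excluded_loci = excluded)
}
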