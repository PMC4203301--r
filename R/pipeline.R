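# End-to-end orchestration: multistep reduced-model search, covariate HFC
# model sets with model averaging, inbreeding summaries, identity
# disequilibrium block, and the local-vs-general comparison.

add_adult_term <- function(spec, term) {
  if (spec$phi$age_split) {
    spec$phi$adult <- unique(c(spec$phi$adult, parse_terms(term, term)))
  } else {
    spec$phi$terms <- unique(c(spec$phi$terms, parse_terms(term, term)))
  }
  spec$notation <- deparse_spec(spec)
  spec
}

deparse_spec <- function(spec) {
  one <- function(st) {
    if (st$age_split) {
      paste0("a2-", paste(if (length(st$cub)) st$cub else ".", collapse = " + "),
             "/", paste(if (length(st$adult)) st$adult else ".", collapse = " + "))
    } else {
      paste(if (length(st$terms)) st$terms else ".", collapse = " + ")
    }
  }
  paste0("Phi(", one(spec$phi), ") p(", one(spec$p), ")")
}

#' Multistep reduced-model search
#'
#' Reproduces the classic four-stage search for a parsimonious
#' survival/recapture structure before any genetic covariates are
#' considered: (1) age structure (two age classes, year dependence per
#' class), (2) a sex effect on adult survival (and on recapture), (3) a
#' cohort-size effect, (4) a population-size effect. The best structure by
#' QAICc is carried forward at each stage.
#'
#' Cohort size (cub releases per year) is derived from the data if absent;
#' the population-size stage is skipped unless `popsize` is present in
#' `data$year_cov`.
#'
#' @param data a [capture_data()].
#' @param c_hat variance inflation factor applied in QAICc (default 1).
#' @param n_starts optimizer starts per model.
#' @param out_dir optional directory for per-stage CSVs
#'   (`stage_<name>.csv`, columns model, k, QDeviance, Delta, omega).
#' @return list `stages` (named list of [rank_models()] tables), `fits`
#'   (top fit per stage), `reduced` (final reduced-model fit).
#' @export
run_reduced_model_search <- function(data, c_hat = 1, n_starts = 2,
                                     out_dir = NULL) {
  if (is.null(data$year_cov)) data$year_cov <- data.frame(row.names = seq_len(data$T - 1))
  if (!"cohort_size" %in% names(data$year_cov)) {
    cs <- tabulate(data$first[data$age_at_first == "cub"], nbins = data$T)
    data$year_cov$cohort_size <- standardize(cs[seq_len(data$T - 1)] + 0)
  }
  if ("popsize" %in% names(data$year_cov) &&
      stats::sd(data$year_cov$popsize) > 0 &&
      (abs(mean(data$year_cov$popsize)) > 1 || stats::sd(data$year_cov$popsize) > 1)) {
    data$year_cov$popsize <- standardize(data$year_cov$popsize)
  }
  fit_set <- function(notations) {
    fits <- lapply(notations, function(nt) fit_cjs(data, nt, n_starts = n_starts))
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!any(ok)) stopf("no converged models in stage")
    fits <- fits[ok]
    q <- vapply(fits, qaicc, numeric(1), c_hat = c_hat)
    tab <- rank_models(q, names = vapply(fits, `[[`, "", "notation"),
                       k = vapply(fits, `[[`, 0L, "k"),
                       deviance = vapply(fits, `[[`, 0, "deviance"))
    list(tab = tab, fits = fits, top = fits[[which.min(q)]])
  }
  stages <- list(); fits <- list()
  # stage 1: age structure
  s <- fit_set(c("Phi(a2-t/.) p(t)", "Phi(a2-t/t) p(t)",
                 "Phi(a2-./.) p(t)", "Phi(.) p(t)"))
  stages$age <- s$tab; fits$age <- s$top
  # stage 2: sex on adult survival; also sex-dependent recapture
  base <- s$top$spec
  with_sex <- add_adult_term(base, "sex")
  sex_p <- with_sex
  sex_p$p <- list(age_split = FALSE, terms = c("sex", "t", "sex:t"))
  sex_p$notation <- deparse_spec(sex_p)
  s <- fit_set(unique(c(with_sex$notation, base$notation, sex_p$notation)))
  stages$sex <- s$tab; fits$sex <- s$top
  # stage 3: cohort size
  base <- s$top$spec
  s <- fit_set(unique(c(base$notation,
                        add_adult_term(base, "sex*cohort_size")$notation)))
  stages$cohort <- s$tab; fits$cohort <- s$top
  # stage 4: population size
  base <- s$top$spec
  if ("popsize" %in% names(data$year_cov)) {
    s <- fit_set(unique(c(add_adult_term(base, "popsize")$notation,
                          base$notation)))
    stages$popsize <- s$tab; fits$popsize <- s$top
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(stages)) {
      tab <- stages[[nm]]
      names(tab) <- c("model", "k", "QDeviance", "QAICc", "Delta", "omega",
                      "plausible")
      utils::write.csv(tab, file.path(out_dir, paste0("stage_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  # the reduced model used downstream is the sex-stage winner refit on the
  # final search outcome
  list(stages = stages, fits = fits, reduced = s$top)
}

# candidate model list for one heterozygosity measure: climate mains always
# included; the SH main may add a quadratic and up to `max_int`
# SH x climate interactions (hierarchical)
candidate_models <- function(sh_term, extra = character(0), max_int = 2) {
  climates <- c("SR", "Tsm", "Twt")
  ints <- paste0(sh_term, ":", climates)
  int_sets <- list(character(0))
  for (k in seq_len(max_int)) {
    cmb <- utils::combn(ints, k, simplify = FALSE)
    int_sets <- c(int_sets, cmb)
  }
  models <- list(c(climates, extra))           # no-SH climate model
  for (quad in c(FALSE, TRUE)) {
    for (is in int_sets) {
      tt <- c(sh_term, if (quad) paste0(sh_term, "^2"), is, climates, extra)
      models[[length(models) + 1]] <- tt
    }
  }
  models
}

#' Covariate model set for one heterozygosity measure
#'
#' Fits the combinatorial candidate list for one multilocus measure on
#' first-year (cub) survival, with the reduced structure on adults and
#' recapture fixed at the reduced model's occasion-specific estimates, and
#' returns the ranked set plus model-averaged estimates for every term
#' under both the natural and zero conventions.
#'
#' @param data a [capture_data()] whose `ind_cov` contains `sh_term` (and
#'   any `extra` covariates) and whose `year_cov` contains `SR`, `Tsm`,
#'   `Twt`.
#' @param sh_term covariate name (`"SH_Ind"`, `"SH_Mat"`, `"SH_Pat"`).
#' @param fixed_p recapture probabilities fixed from the reduced model
#'   (scalar or per-occasion vector).
#' @param c_hat QAICc variance inflation factor.
#' @param extra extra always-included cub terms (e.g. a rare-allele score).
#' @param max_int maximum number of SH x climate interactions per model.
#' @param n_starts optimizer starts per model.
#' @return list `set` (a [rank_models()] table), `terms_by_model`,
#'   `averaged` (data.frame over all terms x both methods), `fits`.
#' @export
run_sh_model_set <- function(data, sh_term, fixed_p, c_hat = 1,
                             extra = character(0), max_int = 2,
                             n_starts = 2) {
  cand <- candidate_models(sh_term, extra = extra, max_int = max_int)
  notes <- vapply(cand, function(tt) {
    paste0("Phi(a2-", paste(tt, collapse = " + "), "/sex) p(.)")
  }, character(1))
  fits <- lapply(notes, function(nt) {
    fit_cjs(data, nt, fixed_p = fixed_p, n_starts = n_starts)
  })
  q <- vapply(fits, qaicc, numeric(1), c_hat = c_hat)
  set <- rank_models(q, names = notes,
                     k = vapply(fits, `[[`, 0L, "k"),
                     deviance = vapply(fits, `[[`, 0, "deviance"))
  ord <- match(set$model, notes)
  fits <- fits[ord]; cand <- cand[ord]
  all_terms <- unique(unlist(cand))
  avg <- do.call(rbind, lapply(all_terms, function(tm) {
    est <- vapply(fits, function(f) {
      cn <- paste0("phi:cub:", tm)
      if (cn %in% names(f$coef)) unname(f$coef[cn]) else NA_real_
    }, numeric(1))
    ses <- vapply(fits, function(f) {
      cn <- paste0("phi:cub:", tm)
      if (cn %in% names(f$coef)) unname(f$se[cn]) else NA_real_
    }, numeric(1))
    rbind(model_average(set, tm, est, ses, "natural"),
          model_average(set, tm, est, ses, "zero"))
  }))
  list(set = set, terms_by_model = cand, averaged = avg, fits = fits)
}

#' Inbreeding summary at the three pedigree-restriction levels
#'
#' For each restriction level, reports sample size, mean `f` with 95
#' percent CI, mean standardized heterozygosity of inbred versus outbred
#' individuals, and a Mann-Whitney test between them.
#'
#' @param p a [pedigree()].
#' @param profiles [het_profile()] output for the same individuals.
#' @param inds candidate ids (default: all with a heterozygosity profile).
#' @return data.frame, one row per restriction level.
#' @export
inbreeding_summary <- function(p, profiles, inds = profiles$individual) {
  lev <- c("both_parents", "ge1_grandparent", "all4_grandparents")
  out <- lapply(lev, function(lv) {
    rec <- inbreeding_records(p, intersect(inds, p$id), lv)
    m <- merge(rec, profiles, by.x = "id", by.y = "individual")
    fin <- mean_ci95(m$f)
    shi <- m$sh[m$inbred == 1]; sho <- m$sh[m$inbred == 0]
    wt <- if (length(shi) >= 1 && length(sho) >= 1) {
      suppressWarnings(stats::wilcox.test(shi, sho))
    } else NULL
    data.frame(level = lv, n = nrow(m), n_inbred = length(shi),
               mean_f = fin[1], f_lo = fin[2], f_hi = fin[3],
               sh_inbred = if (length(shi)) mean(shi) else NA_real_,
               sh_outbred = if (length(sho)) mean(sho) else NA_real_,
               U = if (is.null(wt)) NA_real_ else unname(wt$statistic),
               p_value = if (is.null(wt)) NA_real_ else wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full heterozygosity-fitness analysis
#'
#' Orchestrates the complete analysis on consistent genotype, pedigree and
#' capture inputs: (a) heterozygosity profiles; (b) inbreeding at the three
#' restriction levels; (c) the identity-disequilibrium block (g2, HHC,
#' expected vs observed correlation between SH and f); (d) covariate CJS
#' model sets for own, maternal and paternal heterozygosity with climate
#' mains, interactions and quadratics (recapture fixed from the reduced
#' model; the paternal set also carries the rare-allele score); (e)
#' model-averaged estimates under both conventions; (f) the
#' local-vs-general single-locus comparison. All randomness is governed by
#' `seed` and recorded in the manifest.
#'
#' @param genotypes a [genotype_table()].
#' @param ped a [pedigree()].
#' @param captures a [capture_data()] of known-age individuals (row names =
#'   ids present in the pedigree).
#' @param seed integer seed.
#' @param c_hat `"bootstrap"` (default, `n_boot` replicates on the reduced
#'   model) or a fixed numeric value.
#' @param n_boot bootstrap replicates for c-hat.
#' @param n_iter_g2 iterations for g2/HHC resampling.
#' @param roles which heterozygosity measures to model.
#' @param local_general fit the single-locus vs multilocus comparison
#'   (slower; default TRUE).
#' @param coccidia optional data.frame `id, count, month` of gut-parasite
#'   counts; when supplied, a parasite-controlled subset model set is run
#'   for each role; when absent that block is skipped without altering
#'   other outputs.
#' @param max_int,n_starts passed to [run_sh_model_set()].
#' @param out_dir optional output directory for CSV reports and the run
#'   manifest.
#' @return a list with components `profiles`, `marker_summary`,
#'   `inbreeding`, `id_diseq`, `reduced`, `c_hat`, `sh_sets`,
#'   `local_general`, `coccidia_sets`, `manifest`.
#' @export
run_hfc_analysis <- function(genotypes, ped, captures, seed = 1L,
                             c_hat = "bootstrap", n_boot = 100,
                             n_iter_g2 = 1000,
                             roles = c("SH_Ind", "SH_Mat", "SH_Pat"),
                             local_general = TRUE, coccidia = NULL,
                             max_int = 2, n_starts = 2, out_dir = NULL) {
  ids <- rownames(captures$ch)
  orphans <- setdiff(ids, ped$id)
  if (length(orphans)) {
    stopf("capture ids missing from pedigree: %s",
          paste(utils::head(orphans, 5), collapse = ", "))
  }
  set.seed(seed)
  # (a) heterozygosity profiles and marker summary
  prof <- het_profile(genotypes)
  msum <- marker_summary(genotypes)
  # (b) inbreeding
  inb <- inbreeding_summary(ped, prof, inds = ids)
  rec_bp <- inbreeding_records(ped, intersect(ids, ped$id), "both_parents")
  # (c) identity disequilibrium
  g2r <- g2_stat(genotypes, n_iter = n_iter_g2, seed = seed)
  hhcr <- hhc(genotypes, n_splits = min(100, n_iter_g2), seed = seed + 1L)
  obs_r <- observed_r_sh_f(prof, rec_bp)
  merged <- merge(prof, rec_bp, by.x = "individual", by.y = "id")
  exp_r <- expected_r_sh_f(mean(merged$f), stats::sd(merged$f),
                           stats::sd(merged$sh))
  # covariates on the capture data from observed genotypes + pedigree
  captures <- attach_sh_covariates(captures, prof, ped, genotypes)
  # reduced model and c-hat
  red <- run_reduced_model_search(captures, n_starts = n_starts)
  chat_obj <- NULL
  if (identical(c_hat, "bootstrap")) {
    chat_obj <- bootstrap_chat(red$reduced, n_boot = n_boot, seed = seed + 2L)
    c_hat <- chat_obj$c_hat
  }
  # occasion-specific recapture fixed from the reduced model
  fixed_p <- colMeans(red$reduced$P)
  # (d, e) covariate model sets per role
  sh_sets <- list()
  for (role in roles) {
    extra <- if (role == "SH_Pat") "rare_pat" else character(0)
    sh_sets[[role]] <- run_sh_model_set(captures, role, fixed_p = fixed_p,
                                        c_hat = c_hat, extra = extra,
                                        max_int = max_int,
                                        n_starts = n_starts)
  }
  # coccidia-controlled subset
  cocc_sets <- NULL
  if (!is.null(coccidia)) {
    cv <- transform_coccidia(coccidia$count, coccidia$month)
    cc <- stats::setNames(cv, coccidia$id)[rownames(captures$ch)]
    keep <- !is.na(cc)
    sub <- subset_capture_data(captures, keep)
    sub$ind_cov$coccidia <- cc[keep]
    cocc_sets <- lapply(stats::setNames(roles, roles), function(role) {
      run_sh_model_set(sub, role, fixed_p = fixed_p, c_hat = c_hat,
                       extra = "coccidia", max_int = max_int,
                       n_starts = n_starts)
    })
  }
  # (f) local vs general
  lg <- NULL
  if (local_general) {
    slh_all <- slh_matrix(genotypes)
    lg <- lapply(stats::setNames(roles, roles), function(role) {
      slh <- slh_for_role(slh_all, ped, rownames(captures$ch), role)
      try(compare_local_general(captures, slh, role, c_hat = c_hat,
                                n_starts = n_starts), silent = TRUE)
    })
  }
  manifest <- list(
    seed = seed, c_hat = c_hat, n_boot = n_boot, n_iter_g2 = n_iter_g2,
    roles = roles, max_int = max_int,
    n_individuals = captures$n, n_occasions = captures$T,
    package_version = as.character(utils::packageVersion("hfcsurv")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  res <- list(profiles = prof, marker_summary = msum, inbreeding = inb,
              id_diseq = list(g2 = g2r, hhc = hhcr, observed_r = obs_r,
                              expected_r = exp_r),
              reduced = red, c_hat = c_hat, chat = chat_obj,
              sh_sets = sh_sets, local_general = lg,
              coccidia_sets = cocc_sets, manifest = manifest)
  if (!is.null(out_dir)) write_hfc_report(res, out_dir)
  res
}

# map each capture-data individual to its own / dam / sire heterozygosity
attach_sh_covariates <- function(captures, prof, ped, genotypes) {
  ids <- rownames(captures$ch)
  sh <- stats::setNames(prof$sh, prof$individual)
  pi <- match(ids, ped$id)
  dam <- ped$dam[pi]; sire <- ped$sire[pi]
  raw <- data.frame(SH_Ind = unname(sh[ids]),
                    SH_Mat = unname(sh[dam]),
                    SH_Pat = unname(sh[sire]))
  rare <- rep(NA_real_, length(ids))
  gset <- genotypes$individuals
  for (r in seq_along(ids)) {
    if (!is.na(sire[r]) && sire[r] %in% gset) {
      rare[r] <- rare_allele_score(genotypes, sire[r])$score
    }
  }
  raw$rare_pat <- rare
  raw <- impute_missing(raw)
  raw <- as.data.frame(apply(raw, 2, standardize))
  rownames(raw) <- ids
  old <- captures$ind_cov
  if (!is.null(old)) {
    # freshly computed observed-genotype covariates replace any same-named
    # columns already present (e.g. generator truth values)
    old <- old[, setdiff(names(old), names(raw)), drop = FALSE]
  }
  captures$ind_cov <- if (is.null(old) || ncol(old) == 0) raw else cbind(old, raw)
  for (v in c("SR", "Tsm", "Twt")) {
    if (!is.null(captures$year_cov) && v %in% names(captures$year_cov)) next
    stopf("year covariate '%s' required in captures$year_cov", v)
  }
  captures
}

slh_for_role <- function(slh_all, ped, ids, role) {
  pi <- match(ids, ped$id)
  src <- switch(role, SH_Ind = ids, SH_Mat = ped$dam[pi], SH_Pat = ped$sire[pi])
  out <- matrix(NA_real_, length(ids), ncol(slh_all),
                dimnames = list(ids, colnames(slh_all)))
  hit <- !is.na(src) & src %in% rownames(slh_all)
  out[hit, ] <- slh_all[src[hit], , drop = FALSE]
  out
}

subset_capture_data <- function(data, keep) {
  capture_data(data$ch[keep, , drop = FALSE],
               age_at_first = data$age_at_first[keep],
               sex = data$sex[keep],
               ind_cov = data$ind_cov[keep, , drop = FALSE],
               year_cov = data$year_cov)
}

write_hfc_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$profiles, file.path(out_dir, "het_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(res$marker_summary, file.path(out_dir, "marker_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$inbreeding, file.path(out_dir, "inbreeding_summary.csv"),
                   row.names = FALSE)
  idd <- res$id_diseq
  jsonlite::write_json(list(
    g2 = list(g2 = idd$g2$g2, se = idd$g2$se, p = idd$g2$p_value,
              n_iter = idd$g2$n_iter, seed = idd$g2$seed),
    hhc = list(mean = idd$hhc$mean, sd = idd$hhc$sd,
               min = idd$hhc$min, max = idd$hhc$max),
    observed_r = idd$observed_r, expected_r = as.list(idd$expected_r)),
    file.path(out_dir, "id_diseq.json"), auto_unbox = TRUE, digits = NA)
  for (role in names(res$sh_sets)) {
    s <- res$sh_sets[[role]]
    utils::write.csv(s$set, file.path(out_dir, paste0("models_", role, ".csv")),
                     row.names = FALSE)
    utils::write.csv(s$averaged,
                     file.path(out_dir, paste0("averaged_", role, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$local_general)) {
    for (role in names(res$local_general)) {
      lgr <- res$local_general[[role]]
      if (!inherits(lgr, "try-error")) {
        utils::write.csv(lgr$table,
                         file.path(out_dir, paste0("local_general_", role, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
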