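# Seeded synthetic population generator: pedigree with incestuous matings,
# microsatellite genotypes with typing error, climate series, and capture
# histories from a covariate-dependent CJS process -- with full ground truth.

#' Simulation configuration
#'
#' Defaults emulate a high-density badger-type study system: ~19 social
#' groups, 35 microsatellite loci averaging ~4.5 alleles, 97 percent typing
#' completeness with allelic dropout and false-allele rates of 0.005, 5
#' percent incestuous (first-order relative) matings, ~50 percent
#' extra-group paternity, 24 annual occasions, cub survival ~0.68 and adult
#' survival ~0.82 on average with interannual variation in the cub class
#' and a small male survival deficit in adults.
#'
#' Covariate effects on first-year survival are given in `beta`, named on
#' the logit scale over standardized predictors: available names are
#' `SH_Ind`, `SH_Mat`, `SH_Pat` (standardized true multilocus
#' heterozygosity of the cub / dam / sire), `f` (raw pedigree inbreeding
#' coefficient), `locus1` (centered heterozygosity indicator of the first
#' locus), climate terms `SR`, `Tsm`, `Twt`, quadratics like `SH_Pat^2`,
#' and `:`-interactions like `SH_Pat:SR`.
#'
#' @param seed integer seed (mandatory).
#' @param n_founders,n_years,n_groups,n_loci,mean_alleles population and
#'   panel structure.
#' @param incest_rate probability a mating is between first-order
#'   relatives.
#' @param extra_group_rate probability a non-incestuous sire is drawn from
#'   outside the dam's group.
#' @param completeness fraction of genotype calls retained.
#' @param eps1,eps2 per-allele allelic-dropout and false-allele rates.
#' @param breed_prob annual breeding probability of an adult female.
#' @param max_cubs_per_year cap on annual cub production (computational
#'   carrying capacity).
#' @param cub_intercept,adult_intercept,sex_adult,year_sd logit-scale
#'   survival parameters (year effects are N(0, year_sd) on cub survival).
#' @param beta named numeric vector of covariate effects on cub survival.
#' @param sh_sd reference SD used to standardize true SH in the generator.
#' @param p_mean,p_year_sd recapture probability: yearly logits are
#'   N(logit(p_mean), p_year_sd).
#' @param climate list of `c(mean, sd)` for `SR` (summer rainfall, mm),
#'   `Tsm` (summer mean temperature, C), `Twt` (winter mean temperature,
#'   C).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_founders = 150, n_years = 24, n_groups = 19,
                       n_loci = 35, mean_alleles = 4.5,
                       incest_rate = 0.05, extra_group_rate = 0.5,
                       completeness = 0.97, eps1 = 0.005, eps2 = 0.005,
                       breed_prob = 0.6, max_cubs_per_year = 80,
                       cub_intercept = logit(0.68),
                       adult_intercept = 1.49, sex_adult = -0.33,
                       year_sd = 0.5,
                       beta = c(Twt = 0.66),
                       sh_sd = 0.15,
                       p_mean = 0.75, p_year_sd = 0.3,
                       climate = list(SR = c(400, 60), Tsm = c(14, 0.8),
                                      Twt = c(4.5, 1.2))) {
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  if (n_years < 2) stopf("n_years must be >= 2")
  for (r in c(incest_rate, extra_group_rate, completeness, eps1, eps2,
              breed_prob, p_mean)) {
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Named simulation scenarios
#'
#' @param name one of `"null"` (no heterozygosity or inbreeding effect on
#'   survival), `"general_effect"` (survival declines with the true
#'   inbreeding coefficient), `"local_effect"` (survival depends on
#'   heterozygosity at a single causal locus), `"paternal_x_rain"`
#'   (a positive paternal-heterozygosity x summer-rainfall interaction,
#'   coefficient 1.0, with no individual or maternal effect).
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
scenario <- function(name = c("null", "general_effect", "local_effect",
                              "paternal_x_rain"), seed, ...) {
  name <- match.arg(name)
  beta <- switch(name,
    null = c(Twt = 0.66),
    general_effect = c(Twt = 0.66, f = -6),
    local_effect = c(Twt = 0.66, locus1 = 1.0),
    paternal_x_rain = c(Twt = 0.66, SR = 0.3, SH_Pat = 0.3, "SH_Pat:SR" = 1.0))
  args <- list(...)
  if (!is.null(args$beta)) { beta <- args$beta; args$beta <- NULL }
  cfg <- do.call(sim_config, c(list(seed = seed, beta = beta), args))
  cfg$scenario <- name
  # detectable inbreeding variance for the general-effect world
  if (name == "general_effect") cfg$incest_rate <- max(cfg$incest_rate, 0.10)
  cfg
}

#' Simulate a yearly climate series
#'
#' Gaussian year values around configured means; returned unstandardized
#' (standardization against the study-period mean and SD is the analysis
#' pipeline's job).
#'
#' @param n_years number of years.
#' @param climate list of `c(mean, sd)` per variable (see [sim_config()]).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return data.frame `year, SR, Tsm, Twt`.
#' @export
simulate_climate <- function(n_years,
                             climate = list(SR = c(400, 60), Tsm = c(14, 0.8),
                                            Twt = c(4.5, 1.2)),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(year = seq_len(n_years))
  for (v in names(climate)) {
    out[[v]] <- stats::rnorm(n_years, climate[[v]][1], climate[[v]][2])
  }
  out
}

# generator-side standardization: fixed reference moments, not the sample
std_ref <- function(x, mean, sd) (x - mean) / (2 * sd)

#' Simulate a full synthetic population
#'
#' Runs the stated demographic world forward: founders with
#' Dirichlet-drawn allele frequencies; yearly within/between-group pair
#' formation with a configured incest rate; Mendelian transmission; cub
#' survival Bernoulli on the logit linear predictor built from `beta` and
#' the standardized covariates; adult survival with a sex effect; yearly
#' detection given alive; then genotyping error (allelic dropout, false
#' alleles) and completeness thinning on the emitted genotypes.
#'
#' @param config a [sim_config()] or [scenario()].
#' @return list with elements
#'   \item{pedigree}{a [pedigree()] of every individual (founders
#'     included).}
#'   \item{genotypes}{observed [genotype_table()] (with typing error).}
#'   \item{captures}{a [capture_data()] of known-age individuals (cubs
#'     first detected in their birth year); `ind_cov` carries the
#'     generator-standardized true covariates, `year_cov` the standardized
#'     climate and population size.}
#'   \item{truth}{ground truth: true genotypes, true `f` per individual,
#'     survival/recapture parameters, climate, year effects, realized
#'     incest fraction.}
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  n_years <- config$n_years
  # marker panel
  n_alleles <- pmax(2L, 2L + stats::rpois(L, max(0, config$mean_alleles - 2)))
  freqs <- lapply(n_alleles, function(k) {
    w <- stats::rgamma(k, 1)
    stats::setNames(w / sum(w), as.character(100 + seq_len(k)))
  })
  exp_het <- vapply(freqs, function(p) 1 - sum(p^2), numeric(1))
  clim <- simulate_climate(n_years, config$climate)
  year_eff <- stats::rnorm(n_years, 0, config$year_sd)
  p_year <- invlogit(stats::rnorm(n_years, logit(config$p_mean), config$p_year_sd))

  n_max <- config$n_founders + n_years * config$max_cubs_per_year + 8
  id <- character(n_max); dam <- rep(NA_character_, n_max); sire <- rep(NA_character_, n_max)
  sexv <- character(n_max); grp <- integer(n_max); born <- integer(n_max)
  a1 <- matrix(NA_character_, n_max, L); a2 <- matrix(NA_character_, n_max, L)
  K <- matrix(0, n_max, n_max)   # kinship, built tabularly as rows are added
  fvec <- numeric(n_max)
  alive <- logical(n_max)
  sh_true <- numeric(n_max)
  ch <- matrix(0L, n_max, n_years)
  n <- 0L

  draw_founder_genotype <- function() {
    g1 <- character(L); g2 <- character(L)
    for (l in seq_len(L)) {
      al <- sample(names(freqs[[l]]), 2, replace = TRUE, prob = freqs[[l]])
      g1[l] <- al[1]; g2[l] <- al[2]
    }
    list(g1, g2)
  }
  add_ind <- function(iid, d, s, sx, g, by, g1, g2) {
    n <<- n + 1L
    id[n] <<- iid; dam[n] <<- d; sire[n] <<- s; sexv[n] <<- sx
    grp[n] <<- g; born[n] <<- by
    a1[n, ] <<- g1; a2[n, ] <<- g2
    di <- if (is.na(d)) NA_integer_ else match(d, id[seq_len(n - 1L)])
    si <- if (is.na(s)) NA_integer_ else match(s, id[seq_len(n - 1L)])
    if (!is.na(di) && !is.na(si)) {
      prev <- seq_len(n - 1L)
      K[n, prev] <<- 0.5 * (K[di, prev] + K[si, prev])
      K[prev, n] <<- K[n, prev]
      fvec[n] <<- K[di, si]
    } else {
      fvec[n] <<- 0
    }
    K[n, n] <<- 0.5 * (1 + fvec[n])
    sh_true[n] <<- mean(a1[n, ] != a2[n, ]) / mean(exp_het)
    alive[n] <<- TRUE
    n
  }

  for (i in seq_len(config$n_founders)) {
    g <- draw_founder_genotype()
    add_ind(sprintf("F%03d", i), NA, NA,
            if (stats::runif(1) < 0.5) "F" else "M",
            sample.int(config$n_groups, 1), -1L, g[[1]], g[[2]])
  }

  n_incest_matings <- 0L; n_matings <- 0L; n_rel_available <- 0L
  cub_counter <- 0L
  sh_std <- function(i) std_ref(sh_true[i], 1, config$sh_sd)
  clim_std <- lapply(c("SR", "Tsm", "Twt"), function(v) {
    std_ref(clim[[v]], config$climate[[v]][1], config$climate[[v]][2])
  })
  names(clim_std) <- c("SR", "Tsm", "Twt")

  cov_value <- function(nm, ci, di, si, y) {
    if (grepl(":", nm, fixed = TRUE)) {
      ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
      return(cov_value(ab[1], ci, di, si, y) * cov_value(ab[2], ci, di, si, y))
    }
    if (grepl("\\^2$", nm)) return(cov_value(sub("\\^2$", "", nm), ci, di, si, y)^2)
    switch(nm,
           SH_Ind = sh_std(ci), SH_Mat = sh_std(di), SH_Pat = sh_std(si),
           f = fvec[ci],
           locus1 = as.numeric(a1[ci, 1] != a2[ci, 1]) - 0.5,
           SR = clim_std$SR[y], Tsm = clim_std$Tsm[y], Twt = clim_std$Twt[y],
           stopf("unknown beta name '%s'", nm))
  }

  pop_size <- integer(n_years)
  for (y in seq_len(n_years)) {
    cur <- seq_len(n)
    ad_f <- cur[alive[cur] & sexv[cur] == "F" & born[cur] <= y - 2L]
    ad_m <- cur[alive[cur] & sexv[cur] == "M" & born[cur] <= y - 2L]
    cubs_y <- integer(0)
    if (length(ad_f) && length(ad_m)) {
      mums <- ad_f[stats::runif(length(ad_f)) < config$breed_prob]
      if (length(mums) * 2 > config$max_cubs_per_year) {
        mums <- sample(mums, config$max_cubs_per_year %/% 2)
      }
      for (mi in mums) {
        # sire choice: incestuous (first-order relative) with configured
        # probability, else extra-group or within-group
        sons <- !is.na(dam[ad_m]) & dam[ad_m] == id[mi]
        fullsib <- !is.na(dam[mi]) & !is.na(sire[mi]) &
          !is.na(dam[ad_m]) & !is.na(sire[ad_m]) &
          dam[ad_m] == dam[mi] & sire[ad_m] == sire[mi]
        rel1 <- ad_m[sons | fullsib]
        rel1 <- unique(c(rel1,
                         if (!is.na(sire[mi])) match(sire[mi], id[seq_len(n)])))
        rel1 <- rel1[!is.na(rel1) & alive[rel1] & born[rel1] <= y - 2L]
        fa <- NULL
        if (length(rel1)) n_rel_available <- n_rel_available + 1L
        if (length(rel1) && stats::runif(1) < config$incest_rate) {
          fa <- if (length(rel1) == 1) rel1 else sample(rel1, 1)
          n_incest_matings <- n_incest_matings + 1L
        } else {
          out_g <- ad_m[grp[ad_m] != grp[mi]]
          in_g <- ad_m[grp[ad_m] == grp[mi]]
          pool <- if (length(out_g) && (stats::runif(1) < config$extra_group_rate ||
                                          !length(in_g))) out_g else in_g
          if (!length(pool)) pool <- ad_m
          fa <- if (length(pool) == 1) pool else sample(pool, 1)
        }
        n_matings <- n_matings + 1L
        litter <- 1L + stats::rbinom(1, 2, 0.25)
        for (cc in seq_len(litter)) {
          if (n >= n_max) break
          cub_counter <- cub_counter + 1L
          pick <- function(i) {
            g1 <- character(L)
            from1 <- stats::runif(L) < 0.5
            ifelse(from1, a1[i, ], a2[i, ])
          }
          ci <- add_ind(sprintf("C%05d", cub_counter), id[mi], id[fa],
                        if (stats::runif(1) < 0.5) "F" else "M",
                        grp[mi], y, pick(mi), pick(fa))
          cubs_y <- c(cubs_y, ci)
        }
      }
    }
    cur <- seq_len(n)
    pop_size[y] <- sum(alive[cur])
    if (pop_size[y] == 0) {
      stopf("population extinct in year %d; raise survival or founders", y)
    }
    # detection at occasion y
    det <- cur[alive[cur] & stats::runif(length(cur)) < p_year[y]]
    ch[det, y] <- 1L
    # survival over interval y -> y+1
    if (y < n_years) {
      for (i in cur[alive[cur]]) {
        if (born[i] == y) {
          di <- match(dam[i], id[cur]); si <- match(sire[i], id[cur])
          lp <- config$cub_intercept + year_eff[y]
          for (nm in names(config$beta)) {
            lp <- lp + config$beta[[nm]] * cov_value(nm, i, di, si, y)
          }
        } else {
          sx <- if (sexv[i] == "F") -0.5 else 0.5
          lp <- config$adult_intercept + config$sex_adult * sx
        }
        if (stats::runif(1) > invlogit(lp)) alive[i] <- FALSE
      }
    }
  }

  keep <- seq_len(n)
  ped <- pedigree(id[keep], dam[keep], sire[keep],
                  cohort = ifelse(born[keep] > 0, born[keep], NA),
                  sex = sexv[keep], group = as.character(grp[keep]))
  true_geno <- genotype_table(id[keep], paste0("Mel-", 100 + seq_len(L)),
                              a1[keep, , drop = FALSE], a2[keep, , drop = FALSE])
  obs <- corrupt_genotypes(true_geno, config$eps1, config$eps2,
                           config$completeness, freqs)

  # known-age capture data: cubs detected in their birth year
  is_cub_known <- born[keep] >= 1L & ch[cbind(keep, pmax(born[keep], 1L))] == 1L
  ka <- keep[is_cub_known]
  first_det <- born[ka]
  ch_ka <- ch[ka, , drop = FALSE]
  # detections before the birth year are impossible by construction
  rownames(ch_ka) <- id[ka]
  dam_i <- match(dam[ka], id[keep]); sire_i <- match(sire[ka], id[keep])
  ind_cov <- data.frame(
    SH_Ind = std_ref(sh_true[ka], 1, config$sh_sd),
    SH_Mat = std_ref(sh_true[dam_i], 1, config$sh_sd),
    SH_Pat = std_ref(sh_true[sire_i], 1, config$sh_sd),
    f = fvec[ka],
    locus1 = as.numeric(a1[ka, 1] != a2[ka, 1]) - 0.5,
    row.names = id[ka]
  )
  year_cov <- data.frame(
    SR = clim_std$SR[seq_len(n_years - 1)],
    Tsm = clim_std$Tsm[seq_len(n_years - 1)],
    Twt = clim_std$Twt[seq_len(n_years - 1)],
    popsize = pop_size[seq_len(n_years - 1)]
  )
  captures <- capture_data(ch_ka, age_at_first = "cub", sex = sexv[ka],
                           ind_cov = ind_cov, year_cov = year_cov)
  truth <- list(
    config = config,
    genotypes_true = true_geno,
    allele_freqs = freqs,
    f = stats::setNames(fvec[keep], id[keep]),
    sh_true = stats::setNames(sh_true[keep], id[keep]),
    year_effects = year_eff, p_year = p_year,
    climate = clim, pop_size = pop_size,
    realized_incest = if (n_matings) n_incest_matings / n_matings else NA_real_,
    incest_given_available = if (n_rel_available) {
      n_incest_matings / n_rel_available
    } else NA_real_,
    n_matings = n_matings, n_rel_available = n_rel_available
  )
  list(pedigree = ped, genotypes = obs, captures = captures, truth = truth)
}

# apply allelic dropout (eps1), false alleles (eps2) and completeness
# thinning to a true genotype table
corrupt_genotypes <- function(g, eps1, eps2, completeness, freqs) {
  a1 <- g$a1; a2 <- g$a2
  n <- nrow(a1); L <- ncol(a1)
  for (l in seq_len(L)) {
    all_alleles <- names(freqs[[l]])
    if (eps1 > 0) {
      het <- which(a1[, l] != a2[, l])
      d1 <- het[stats::runif(length(het)) < eps1]
      a1[d1, l] <- a2[d1, l]                      # allele 1 drops out
      het <- which(a1[, l] != a2[, l])
      d2 <- het[stats::runif(length(het)) < eps1]
      a2[d2, l] <- a1[d2, l]
    }
    if (eps2 > 0 && length(all_alleles) > 1) {
      for (slot in 1:2) {
        m <- if (slot == 1) a1 else a2
        fa <- which(stats::runif(n) < eps2)
        for (i in fa) {
          others <- setdiff(all_alleles, m[i, l])
          m[i, l] <- if (length(others) == 1) others else sample(others, 1)
        }
        if (slot == 1) a1[, l] <- m[, l] else a2[, l] <- m[, l]
      }
    }
  }
  drop <- matrix(stats::runif(n * L) > completeness, n, L)
  a1[drop] <- NA_character_; a2[drop] <- NA_character_
  genotype_table(g$individuals, g$loci, a1, a2)
}

#' Write a simulated population as an analysis-ready fixture directory
#'
#' Emits the exact plain-text formats the analysis readers consume:
#' `pedigree.csv`, `genotypes.genepop`, `captures.inp`, `ind_cov.csv`,
#' `year_cov.csv` and `truth.json` (scalar ground truth only).
#'
#' @param sim a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.genepop"))
  write_inp(sim$captures$ch, file.path(dir, "captures.inp"))
  ic <- cbind(id = rownames(sim$captures$ind_cov), sim$captures$ind_cov)
  utils::write.csv(ic, file.path(dir, "ind_cov.csv"), row.names = FALSE)
  utils::write.csv(cbind(year = seq_len(nrow(sim$captures$year_cov)),
                         sim$captures$year_cov),
                   file.path(dir, "year_cov.csv"), row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(seed = tr$config$seed,
                            scenario = tr$config$scenario %||% "custom",
                            beta = as.list(tr$config$beta),
                            realized_incest = tr$realized_incest,
                            p_year = tr$p_year,
                            year_effects = tr$year_effects),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
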