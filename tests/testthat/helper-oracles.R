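# Fixture builders and independent oracle implementations. Every oracle here
# is deliberately naive (loops, enumeration, Monte Carlo) and shares no code
# with the package internals it checks.

# random genotype table: independent loci, Dirichlet-ish frequencies
random_genotype_table <- function(n = 10, L = 5, k_alleles = 4,
                                  miss_rate = 0, seed = 1) {
  set.seed(seed)
  alleles <- as.character(100 + seq_len(k_alleles))
  a1 <- matrix(NA_character_, n, L)
  a2 <- matrix(NA_character_, n, L)
  for (l in seq_len(L)) {
    w <- rgamma(k_alleles, 1); p <- w / sum(w)
    a1[, l] <- sample(alleles, n, TRUE, prob = p)
    a2[, l] <- sample(alleles, n, TRUE, prob = p)
  }
  if (miss_rate > 0) {
    m <- matrix(runif(n * L) < miss_rate, n, L)
    # keep every individual typed somewhere and every locus typed
    m[, 1] <- FALSE; m[1, ] <- FALSE
    a1[m] <- NA; a2[m] <- NA
  }
  genotype_table(sprintf("i%02d", seq_len(n)), sprintf("L%02d", seq_len(L)),
                 a1, a2)
}

# spreadsheet-style recomputation of SH / HL / IR from first principles
oracle_het_measures <- function(g) {
  n <- length(g$individuals); L <- length(g$loci)
  # population allele frequencies by direct tally
  freqs <- lapply(seq_len(L), function(l) {
    al <- c(g$a1[, l], g$a2[, l]); al <- al[!is.na(al)]
    table(al) / length(al)
  })
  pop_oh <- sapply(seq_len(L), function(l) {
    het <- 0; tot <- 0
    for (i in seq_len(n)) {
      if (is.na(g$a1[i, l])) next
      tot <- tot + 1
      if (g$a1[i, l] != g$a2[i, l]) het <- het + 1
    }
    het / tot
  })
  eh <- sapply(freqs, function(p) 1 - sum(p^2))
  out <- data.frame(individual = g$individuals, sh = NA_real_,
                    hl = NA_real_, ir = NA_real_)
  for (i in seq_len(n)) {
    typed <- which(!is.na(g$a1[i, ]))
    het <- g$a1[i, typed] != g$a2[i, typed]
    out$sh[i] <- mean(het) / mean(pop_oh[typed])
    out$hl[i] <- sum(eh[typed][!het]) / sum(eh[typed])
    sumf <- 0
    for (l in typed) {
      sumf <- sumf + freqs[[l]][[g$a1[i, l]]] + freqs[[l]][[g$a2[i, l]]]
    }
    out$ir[i] <- (2 * sum(!het) - sumf) / (2 * length(typed) - sumf)
  }
  out
}

# brute-force transcription of the g2 double-sum estimator: plain loops over
# individuals and ordered locus pairs, typed-pair normalization
oracle_g2 <- function(g) {
  h <- matrix(NA_real_, length(g$individuals), length(g$loci))
  for (i in seq_len(nrow(h))) for (l in seq_len(ncol(h))) {
    if (!is.na(g$a1[i, l])) h[i, l] <- as.numeric(g$a1[i, l] != g$a2[i, l])
  }
  n <- nrow(h); L <- ncol(h)
  num <- 0; den <- 0
  for (j in seq_len(L)) for (k in seq_len(L)) {
    if (j == k) next
    sw <- 0; nw <- 0
    for (i in seq_len(n)) {
      if (!is.na(h[i, j]) && !is.na(h[i, k])) {
        sw <- sw + h[i, j] * h[i, k]; nw <- nw + 1
      }
    }
    sb <- 0; nb <- 0
    for (i in seq_len(n)) for (i2 in seq_len(n)) {
      if (i == i2) next
      if (!is.na(h[i, j]) && !is.na(h[i2, k])) {
        sb <- sb + h[i, j] * h[i2, k]; nb <- nb + 1
      }
    }
    if (nw > 0 && nb > 0) {
      num <- num + sw / nw
      den <- den + sb / nb
    }
  }
  num / den - 1
}

# gene-dropping Monte Carlo kinship: propagate unique founder alleles,
# estimate P(random allele of a IBD random allele of b)
oracle_kinship_gd <- function(ped, a, b, ndrops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  ord <- order(gen_depth(ped))
  di <- match(ped$dam, ped$id); si <- match(ped$sire, ped$id)
  A1 <- matrix(0L, n, ndrops); A2 <- matrix(0L, n, ndrops)
  cnt <- 0L
  for (i in ord) {
    if (is.na(di[i]) || is.na(si[i])) {
      A1[i, ] <- cnt + 1L; A2[i, ] <- cnt + 2L; cnt <- cnt + 2L
    } else {
      pick1 <- runif(ndrops) < 0.5
      A1[i, ] <- ifelse(pick1, A1[di[i], ], A2[di[i], ])
      pick2 <- runif(ndrops) < 0.5
      A2[i, ] <- ifelse(pick2, A1[si[i], ], A2[si[i], ])
    }
  }
  ia <- match(a, ped$id); ib <- match(b, ped$id)
  ga <- ifelse(runif(ndrops) < 0.5, A1[ia, ], A2[ia, ])
  gb <- ifelse(runif(ndrops) < 0.5, A1[ib, ], A2[ib, ])
  p_hat <- mean(ga == gb)
  list(estimate = p_hat, se = sqrt(p_hat * (1 - p_hat) / ndrops))
}

gen_depth <- function(ped) {
  di <- match(ped$dam, ped$id); si <- match(ped$sire, ped$id)
  g <- rep(0L, nrow(ped))
  repeat {
    gnew <- g
    for (i in seq_len(nrow(ped))) {
      pd <- if (is.na(di[i])) -1L else g[di[i]]
      ps <- if (is.na(si[i])) -1L else g[si[i]]
      gnew[i] <- max(pd, ps) + 1L
    }
    if (identical(gnew, g)) break
    g <- gnew
  }
  g
}

# tabular additive-relationship kinship (independent of the recursive engine)
oracle_kinship_tabular <- function(ped, a, b) {
  ord <- order(gen_depth(ped))
  n <- nrow(ped)
  K <- matrix(0, n, n)
  di <- match(ped$dam, ped$id); si <- match(ped$sire, ped$id)
  done <- integer(0)
  for (i in ord) {
    for (j in done) {
      kij <- 0
      if (!is.na(di[i])) kij <- kij + 0.5 * K[di[i], j]
      if (!is.na(si[i])) kij <- kij + 0.5 * K[si[i], j]
      K[i, j] <- K[j, i] <- kij
    }
    fi <- if (!is.na(di[i]) && !is.na(si[i])) K[di[i], si[i]] else 0
    K[i, i] <- 0.5 * (1 + fi)
    done <- c(done, i)
  }
  K[match(a, ped$id), match(b, ped$id)]
}

# random pedigree with known structure and randomized missingness
random_pedigree <- function(n_founders = 10, n_gen = 3, kids_per_gen = 12,
                            seed = 1) {
  set.seed(seed)
  id <- sprintf("P%03d", seq_len(n_founders))
  dam <- rep(NA_character_, n_founders)
  sire <- rep(NA_character_, n_founders)
  sex <- sample(c("F", "M"), n_founders, TRUE)
  for (g in seq_len(n_gen)) {
    fem <- id[sex == "F"]; mal <- id[sex == "M"]
    if (!length(fem) || !length(mal)) break
    for (k in seq_len(kids_per_gen)) {
      nid <- sprintf("P%03d", length(id) + 1L)
      id <- c(id, nid)
      dam <- c(dam, sample(fem, 1)); sire <- c(sire, sample(mal, 1))
      sex <- c(sex, sample(c("F", "M"), 1))
    }
  }
  pedigree(id, dam, sire, sex = sex)
}

# tiny CJS dataset from known constants
sim_const_cjs <- function(n = 200, T = 6, phi = 0.7, p = 0.6, seed = 1,
                          age = "adult") {
  set.seed(seed)
  first <- sample(seq_len(T - 2), n, replace = TRUE)
  ch <- simulate_cjs_histories(matrix(phi, n, T - 1), matrix(p, n, T - 1),
                               first)
  capture_data(ch, age_at_first = age)
}

# direct CJS log-likelihood for constant phi/p via per-history enumeration
# (independent transcription used by the grid-search oracle)
oracle_const_cjs_nll <- function(phi, p, ch, first) {
  T <- ncol(ch)
  ll <- 0
  chi <- numeric(T)
  chi[T] <- 1
  for (j in (T - 1):1) chi[j] <- (1 - phi) + phi * (1 - p) * chi[j + 1]
  for (i in seq_len(nrow(ch))) {
    f <- first[i]
    l <- max(which(ch[i, ] == 1))
    if (l > f) {
      for (j in f:(l - 1)) {
        ll <- ll + log(phi) + ifelse(ch[i, j + 1] == 1, log(p), log(1 - p))
      }
    }
    ll <- ll + log(chi[l])
  }
  -as.numeric(ll)
}
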