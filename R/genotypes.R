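#' Genotype tables for diploid microsatellite panels
#'
#' A `genotype_table` holds unordered diploid allele calls for a set of
#' individuals scored at a panel of codominant loci (typically
#' microsatellites), with explicit missing calls. It is the substrate for
#' all heterozygosity measures ([het_profile()]), allele frequencies,
#' per-locus marker summaries and identity-disequilibrium statistics.
#'
#' @param individuals character vector of unique individual identifiers.
#' @param loci character vector of unique locus names.
#' @param a1,a2 character (or coercible) matrices, individuals x loci, giving
#'   the two allele labels of each call; `NA` in either slot marks the whole
#'   call as missing. The pair is unordered: (120,124) and (124,120) are the
#'   same genotype and are stored in a canonical order.
#' @return An object of class `genotype_table` with elements `individuals`,
#'   `loci`, `a1`, `a2` (canonically ordered allele matrices).
#' @export
genotype_table <- function(individuals, loci, a1, a2) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  if (anyDuplicated(individuals)) {
    stopf("duplicate individual id(s): %s",
          paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  }
  if (anyDuplicated(loci)) stopf("duplicate locus name(s)")
  a1 <- matrix(as.character(a1), length(individuals), length(loci))
  a2 <- matrix(as.character(a2), length(individuals), length(loci))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  # canonical unordered pair: lexicographically smaller label first
  swap <- !miss & (a1 > a2)
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci (%.1f%% typed)\n",
              length(x$individuals), length(x$loci),
              100 * mean(!is.na(x$a1))))
  invisible(x)
}

n_ind <- function(g) length(g$individuals)
n_loc <- function(g) length(g$loci)

typed_matrix <- function(g) !is.na(g$a1)

# per-(individual, locus) heterozygosity indicator; NA where missing
slh_matrix <- function(g) {
  h <- (g$a1 != g$a2) * 1L
  dimnames(h) <- list(g$individuals, g$loci)
  h
}

#' Read genotypes from GENEPOP or long-format CSV
#'
#' @param path file path.
#' @param format `"genepop"` (2- or 3-digit allele codes, all-zero allele code
#'   = missing) or `"long_csv"` (columns `individual,locus,allele1,allele2`,
#'   empty/NA allele = missing call).
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("genepop", "long_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  switch(format,
         genepop = read_genepop(path),
         long_csv = read_long_csv(path))
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stopf("malformed GENEPOP file: fewer than 3 lines")
  # line 1 is a title; locus names follow (one per line or comma-separated)
  # until the first 'Pop' line
  i <- 2
  loci <- character(0)
  while (i <= length(lines) && !grepl("^\\s*pop\\s*$", lines[i], ignore.case = TRUE)) {
    loci <- c(loci, trimws(strsplit(lines[i], ",")[[1]]))
    i <- i + 1
  }
  if (i > length(lines)) stopf("malformed GENEPOP file: no 'Pop' line")
  loci <- loci[nzchar(loci)]
  ids <- character(0)
  rows1 <- list()
  rows2 <- list()
  for (j in seq(i, length(lines))) {
    ln <- lines[j]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stopf("malformed GENEPOP file at line %d: no comma separator", j)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != length(loci)) {
      stopf("malformed GENEPOP file at line %d: %d genotypes for %d loci",
            j, length(toks), length(loci))
    }
    w <- nchar(toks)
    if (any(w %% 2 != 0 | !grepl("^[0-9]+$", toks))) {
      stopf("malformed GENEPOP file at line %d: non-numeric or odd-width genotype", j)
    }
    half <- w %/% 2
    al1 <- as.integer(substr(toks, 1, half))
    al2 <- as.integer(substr(toks, half + 1, w))
    al1[al1 == 0L] <- NA_integer_
    al2[al2 == 0L] <- NA_integer_
    ids <- c(ids, id)
    rows1[[length(rows1) + 1L]] <- al1
    rows2[[length(rows2) + 1L]] <- al2
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate individual id in GENEPOP file: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genotype_table(ids, loci, do.call(rbind, rows1), do.call(rbind, rows2))
}

read_long_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("individual", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stopf("long CSV must have columns %s", paste(need, collapse = ","))
  }
  df$allele1[df$allele1 == ""] <- NA_character_
  df$allele2[df$allele2 == ""] <- NA_character_
  # a call missing either allele is wholly missing
  miss <- is.na(df$allele1) | is.na(df$allele2)
  df$allele1[miss] <- NA_character_
  df$allele2[miss] <- NA_character_
  ids <- unique(df$individual)        # order of first appearance
  loci <- unique(df$locus)
  a1 <- matrix(NA_character_, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  # canonical order within the row so that duplicated rows with swapped
  # alleles denote the same unordered pair
  lo <- ifelse(miss, NA, pmin(df$allele1, df$allele2))
  hi <- ifelse(miss, NA, pmax(df$allele1, df$allele2))
  for (r in seq_len(nrow(df))) {
    i <- df$individual[r]; l <- df$locus[r]
    if (!is.na(a1[i, l])) {
      if (!identical(a1[i, l], lo[r]) || !identical(a2[i, l], hi[r])) {
        stopf("conflicting duplicate rows for individual %s locus %s", i, l)
      }
      next
    }
    a1[i, l] <- lo[r]; a2[i, l] <- hi[r]
  }
  genotype_table(ids, loci, a1, a2)
}

#' Write a genotype table
#'
#' @param g a [genotype_table()].
#' @param path output file.
#' @param format `"genepop"` (allele labels must be integers < 1000) or
#'   `"long_csv"`.
#' @param title GENEPOP title line.
#' @export
write_genotypes <- function(g, path, format = c("genepop", "long_csv"),
                            title = "hfcsurv genotypes") {
  format <- match.arg(format)
  if (format == "long_csv") {
    df <- data.frame(
      individual = rep(g$individuals, times = n_loc(g)),
      locus = rep(g$loci, each = n_ind(g)),
      allele1 = as.vector(g$a1),
      allele2 = as.vector(g$a2),
      stringsAsFactors = FALSE
    )
    df$allele1[is.na(df$allele1)] <- ""
    df$allele2[is.na(df$allele2)] <- ""
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  al <- suppressWarnings(as.integer(c(g$a1, g$a2)))
  if (anyNA(al[!is.na(c(g$a1, g$a2))])) {
    stopf("GENEPOP output requires integer allele labels")
  }
  width <- if (max(al, na.rm = TRUE) > 99) 3L else 2L
  fmt <- function(x) {
    x <- suppressWarnings(as.integer(x))
    x[is.na(x)] <- 0L
    formatC(x, width = width, flag = "0")
  }
  geno <- matrix(paste0(fmt(g$a1), fmt(g$a2)), n_ind(g), n_loc(g))
  lines <- c(title, g$loci, "Pop",
             paste0(g$individuals, " , ",
                    apply(geno, 1, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed by counting two allele copies per typed
#' individual; missing calls contribute nothing.
#'
#' @param g a [genotype_table()].
#' @return named list, one named numeric vector of frequencies per locus
#'   (each sums to 1).
#' @export
allele_frequencies <- function(g) {
  out <- vector("list", n_loc(g))
  names(out) <- g$loci
  for (l in seq_len(n_loc(g))) {
    al <- c(g$a1[, l], g$a2[, l])
    al <- al[!is.na(al)]
    if (length(al) == 0) stopf("locus %s has zero typed individuals", g$loci[l])
    tab <- table(al)
    out[[l]] <- as.numeric(tab) / length(al)
    names(out[[l]]) <- names(tab)
  }
  out
}

# per-locus observed heterozygosity across all genotyped individuals
locus_obs_het <- function(g) {
  h <- slh_matrix(g)
  colMeans(h, na.rm = TRUE)
}

# expected heterozygosity 1 - sum p^2, optionally with the small-sample
# (unbiased, 2n/(2n-1)) correction
locus_exp_het <- function(g, unbiased = TRUE) {
  fr <- allele_frequencies(g)
  nt <- colSums(typed_matrix(g))
  vapply(seq_along(fr), function(l) {
    he <- 1 - sum(fr[[l]]^2)
    if (unbiased && nt[l] > 0) he <- he * (2 * nt[l]) / (2 * nt[l] - 1)
    he
  }, numeric(1))
}

#' Multilocus heterozygosity profile (SH, HL, IR)
#'
#' Computes, for each individual, the three standard microsatellite
#' diversity measures, over typed loci only:
#' \describe{
#'   \item{SH}{standardized heterozygosity: the proportion of the
#'     individual's typed loci that are heterozygous, divided by the mean
#'     population observed heterozygosity of exactly those loci. Mean SH of
#'     fully typed individuals is 1 by construction.}
#'   \item{HL}{homozygosity by locus: `sum(E_hom) / (sum(E_hom) + sum(E_het))`
#'     where `E` is the expected heterozygosity (`1 - sum p^2`) of each typed
#'     locus, split by whether the individual is homozygous there. 0 for a
#'     fully heterozygous individual, 1 for a fully homozygous one.}
#'   \item{IR}{internal relatedness: `(2H - sum f) / (2N - sum f)` with `H`
#'     the number of homozygous typed loci, `N` the number of typed loci and
#'     `sum f` the summed population frequencies of the individual's 2N
#'     allele copies. -1 and +1 at the fully outbred / fully inbred
#'     extremes of the classic two-allele case.}
#' }
#' Allele frequencies and population heterozygosities are always taken from
#' the full table. An undefined IR (zero denominator) is returned as `NA`
#' with a warning, never as silent `NaN`.
#'
#' @param g a [genotype_table()].
#' @param individual optional single id; default all individuals.
#' @return data.frame with columns `individual, sh, hl, ir, n_typed`. The
#'   per-locus 0/1/NA heterozygosity indicators are available via
#'   `attr(, "slh")`.
#' @export
het_profile <- function(g, individual = NULL) {
  h <- slh_matrix(g)
  typed <- typed_matrix(g)
  oh <- locus_obs_het(g)
  eh <- locus_exp_het(g, unbiased = FALSE)
  fr <- allele_frequencies(g)
  ids <- g$individuals
  if (!is.null(individual)) {
    if (!individual %in% ids) stopf("unknown individual: %s", individual)
    ids <- individual
  }
  res <- data.frame(individual = ids, sh = NA_real_, hl = NA_real_,
                    ir = NA_real_, n_typed = NA_integer_,
                    stringsAsFactors = FALSE)
  for (r in seq_along(ids)) {
    i <- match(ids[r], g$individuals)
    tl <- which(typed[i, ])
    if (length(tl) == 0) stopf("individual %s typed at zero loci", ids[r])
    hi <- h[i, tl]
    res$n_typed[r] <- length(tl)
    denom_sh <- mean(oh[tl])
    res$sh[r] <- if (denom_sh > 0) mean(hi) / denom_sh else NA_real_
    e <- eh[tl]
    tot <- sum(e)
    res$hl[r] <- if (tot > 0) sum(e[hi == 0]) / tot else NA_real_
    # IR: summed frequencies of the individual's allele copies
    sf <- 0
    for (l in tl) {
      sf <- sf + fr[[l]][[g$a1[i, l]]] + fr[[l]][[g$a2[i, l]]]
    }
    nhom <- sum(hi == 0)
    den <- 2 * length(tl) - sf
    if (abs(den) < 1e-12) {
      warnf("IR undefined for individual %s (zero denominator)", ids[r])
      res$ir[r] <- NA_real_
    } else {
      res$ir[r] <- (2 * nhom - sf) / den
    }
  }
  attr(res, "slh") <- if (is.null(individual)) h else h[individual, , drop = FALSE]
  res
}

#' Rare-allele carriage score
#'
#' The number of allele copies an individual carries whose population
#' frequency is below `threshold`, divided by the number of allele copies it
#' was typed for (2 x typed loci; a homozygous rare genotype counts twice).
#' Used as a control when modelling paternal heterozygosity effects, to
#' separate rare-allele carriage (e.g. via immigrant fathers) from
#' heterozygosity itself.
#'
#' @param g a [genotype_table()].
#' @param individual individual id.
#' @param threshold frequency below which an allele counts as rare
#'   (default 0.05, i.e. rarer than 5 percent).
#' @return data.frame `individual, score, n_rare, n_alleles_typed`.
#' @export
rare_allele_score <- function(g, individual, threshold = 0.05) {
  i <- match(individual, g$individuals)
  if (is.na(i)) stopf("unknown individual: %s", individual)
  fr <- allele_frequencies(g)
  tl <- which(typed_matrix(g)[i, ])
  if (length(tl) == 0) stopf("individual %s typed at zero loci", individual)
  n_rare <- 0L
  for (l in tl) {
    n_rare <- n_rare + (fr[[l]][[g$a1[i, l]]] < threshold) +
      (fr[[l]][[g$a2[i, l]]] < threshold)
  }
  data.frame(individual = individual, score = n_rare / (2 * length(tl)),
             n_rare = as.integer(n_rare),
             n_alleles_typed = 2L * length(tl), stringsAsFactors = FALSE)
}

#' Per-locus marker summary
#'
#' @param g a [genotype_table()].
#' @return data.frame `locus, n_alleles, n_typed, obs_het, exp_het`
#'   (`exp_het` is the unbiased small-sample-corrected estimator), with an
#'   attribute `"means"`: unweighted across-locus means of the three
#'   statistics with 95 percent CIs (mean +/- 1.96 SE across loci).
#' @export
marker_summary <- function(g) {
  if (n_loc(g) < 1) stopf("no loci")
  fr <- allele_frequencies(g)
  out <- data.frame(
    locus = g$loci,
    n_alleles = vapply(fr, length, integer(1)),
    n_typed = colSums(typed_matrix(g)),
    obs_het = locus_obs_het(g),
    exp_het = locus_exp_het(g, unbiased = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "means") <- rbind(
    n_alleles = mean_ci95(out$n_alleles),
    obs_het = mean_ci95(out$obs_het),
    exp_het = mean_ci95(out$exp_het)
  )
  out
}
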