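#' Pedigrees and pedigree inbreeding
#'
#' A `pedigree` is a data.frame-backed record of parent links plus cohort,
#' sex and social-group metadata. Unknown parents are `NA`; founders
#' (both parents unknown) are assumed unrelated and non-inbred, the standard
#' assumption when working with wild pedigrees where parentage links are
#' inevitably incomplete.
#'
#' @param id,dam,sire character vectors; `NA` in `dam`/`sire` = unknown.
#' @param cohort integer birth year (optional, `NA` allowed).
#' @param sex,group optional metadata vectors.
#' @return object of class `pedigree` (a data.frame with columns
#'   `id, dam, sire, cohort, sex, group`).
#' @export
pedigree <- function(id, dam = NA, sire = NA, cohort = NA, sex = NA, group = NA) {
  id <- as.character(id)
  n <- length(id)
  df <- data.frame(
    id = id,
    dam = as.character(rep_len(dam, n)),
    sire = as.character(rep_len(sire, n)),
    cohort = rep_len(cohort, n),
    sex = rep_len(sex, n),
    group = rep_len(group, n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$id)) stopf("duplicate id(s) in pedigree")
  known <- c(df$dam, df$sire)
  known <- known[!is.na(known)]
  orphan <- setdiff(known, df$id)
  if (length(orphan)) {
    stopf("parent id(s) not present as records: %s",
          paste(utils::head(orphan, 5), collapse = ", "))
  }
  class(df) <- c("pedigree", "data.frame")
  check_acyclic(df)
  df
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals (%d founders)\n",
              nrow(x), sum(is.na(x$dam) & is.na(x$sire))))
  NextMethod()
}

#' Read / write a pedigree CSV (`id,dam,sire,cohort,sex,group`, empty = unknown)
#' @param path file path.
#' @rdname pedigree_io
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  for (col in c("dam", "sire", "sex", "group")) {
    if (col %in% names(df)) df[[col]][df[[col]] == ""] <- NA
  }
  pedigree(df$id, df$dam, df$sire,
           cohort = if ("cohort" %in% names(df)) as.integer(df$cohort) else NA,
           sex = df$sex %||% NA, group = df$group %||% NA)
}

#' @param p a [pedigree()].
#' @rdname pedigree_io
#' @export
write_pedigree <- function(p, path) {
  df <- as.data.frame(p)
  df[is.na(df)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# topological generation index; errors on cycles naming one offending id
check_acyclic <- function(p) {
  idx <- stats::setNames(seq_len(nrow(p)), p$id)
  gen <- rep(NA_integer_, nrow(p))
  state <- integer(nrow(p)) # 0 untouched, 1 in progress, 2 done
  depth <- function(i, path) {
    if (state[i] == 1L) {
      stopf("pedigree cycle detected involving id %s (path: %s)",
            p$id[i], paste(p$id[path], collapse = " -> "))
    }
    if (state[i] == 2L) return(gen[i])
    state[i] <<- 1L
    d <- 0L
    for (par in c(p$dam[i], p$sire[i])) {
      if (!is.na(par)) d <- max(d, depth(idx[[par]], c(path, i)) + 1L)
    }
    gen[i] <<- d
    state[i] <<- 2L
    d
  }
  for (i in seq_len(nrow(p))) if (state[i] == 0L) depth(i, integer(0))
  invisible(gen)
}

# Memoized recursive kinship engine. Returns a closure phi(a, b) on row
# indices; standard recursion: phi(x,x) = (1 + f_x)/2 with f_x the kinship
# of x's parents, and phi(x,y) recurses through the parents of whichever
# argument is in the later generation (founders contribute 0).
kinship_engine <- function(p) {
  idx <- stats::setNames(seq_len(nrow(p)), p$id)
  gen <- check_acyclic(p)
  dam <- match(p$dam, p$id)
  sire <- match(p$sire, p$id)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(a, b) {
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste0(a, ":", b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      fa <- if (is.na(dam[a]) || is.na(sire[a])) 0 else phi(dam[a], sire[a])
      0.5 * (1 + fa)
    } else {
      # recurse through the later-generation member so ancestors terminate
      x <- if (gen[a] >= gen[b]) a else b
      y <- if (gen[a] >= gen[b]) b else a
      if (is.na(dam[x]) && is.na(sire[x])) {
        0 # founder unrelated to everyone else
      } else {
        pd <- if (is.na(dam[x])) 0 else phi(dam[x], y)
        ps <- if (is.na(sire[x])) 0 else phi(sire[x], y)
        0.5 * (pd + ps)
      }
    }
    memo[[key]] <- val
    val
  }
  list(phi = phi, idx = idx)
}

#' Pedigree kinship coefficient
#'
#' Probability that an allele drawn at random from `a` is identical by
#' descent with one drawn at random from `b`, with founders treated as
#' unrelated and non-inbred. `kinship(a, a) = (1 + f_a) / 2`.
#'
#' @param p a [pedigree()].
#' @param a,b individual ids.
#' @return numeric kinship in \[0, 1\].
#' @export
kinship <- function(p, a, b) {
  eng <- kinship_engine(p)
  ia <- eng$idx[[as.character(a)]]
  ib <- eng$idx[[as.character(b)]]
  if (is.null(ia) || is.null(ib)) stopf("id not in pedigree")
  eng$phi(ia, ib)
}

#' Pedigree inbreeding coefficient
#'
#' `f` of an individual is the kinship of its parents; 0 whenever either
#' parent is unknown (undetected inbreeding through missing links is exactly
#' what the dataset-restriction rules of [restrict_pedigree()] guard
#' against).
#'
#' @param p a [pedigree()].
#' @param ind one or more ids; default all.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding_f <- function(p, ind = p$id) {
  eng <- kinship_engine(p)
  ind <- as.character(ind)
  dam <- p$dam[match(ind, p$id)]
  sire <- p$sire[match(ind, p$id)]
  if (anyNA(match(ind, p$id))) stopf("id not in pedigree")
  out <- vapply(seq_along(ind), function(r) {
    if (is.na(dam[r]) || is.na(sire[r])) return(0)
    eng$phi(eng$idx[[dam[r]]], eng$idx[[sire[r]]])
  }, numeric(1))
  stats::setNames(out, ind)
}

#' Restrict a set of individuals by pedigree completeness
#'
#' Deeper pedigrees detect more inbreeding: restricting the analysis set to
#' individuals with more complete ancestry trades sample size against bias
#' in `f`.
#'
#' @param p a [pedigree()].
#' @param inds candidate ids (default all).
#' @param level `"both_parents"` (dam and sire known),
#'   `"ge1_grandparent"` (both parents known and at least one of the four
#'   grandparent slots known) or `"all4_grandparents"` (all four known).
#' @return character vector of retained ids (order preserved).
#' @export
restrict_pedigree <- function(p, inds = p$id,
                              level = c("both_parents", "ge1_grandparent",
                                        "all4_grandparents")) {
  level <- match.arg(level)
  inds <- as.character(inds)
  i <- match(inds, p$id)
  if (anyNA(i)) stopf("id(s) not in pedigree")
  dam <- p$dam[i]; sire <- p$sire[i]
  keep <- !is.na(dam) & !is.na(sire)
  if (level != "both_parents") {
    gp_known <- function(par) {
      j <- match(par, p$id)
      cbind(!is.na(p$dam[j]), !is.na(p$sire[j]))
    }
    gk <- cbind(gp_known(dam), gp_known(sire))
    gk[is.na(gk)] <- FALSE
    nk <- rowSums(gk)
    keep <- keep & if (level == "ge1_grandparent") nk >= 1 else nk == 4
  }
  inds[keep]
}

#' Classify individuals as inbred or outbred
#'
#' The conventional first-order threshold: offspring of matings at least as
#' close as half-sib/grand-parental (`f >= 0.125`) are coded inbred (1),
#' all others outbred (0).
#'
#' @param f numeric vector of inbreeding coefficients in \[0, 1).
#' @param threshold inbred cut point, default 0.125 (inclusive).
#' @return integer vector of 0/1 codes.
#' @export
classify_inbred <- function(f, threshold = 0.125) {
  if (any(f < 0, na.rm = TRUE)) stopf("negative inbreeding coefficient")
  as.integer(f >= threshold)
}

#' Inbreeding records at a restriction level
#'
#' @param p a [pedigree()].
#' @param inds candidate ids (default all).
#' @param level see [restrict_pedigree()].
#' @return data.frame `id, f, restriction_level, inbred` for the individuals
#'   that satisfy the restriction.
#' @export
inbreeding_records <- function(p, inds = p$id, level = "both_parents") {
  keep <- restrict_pedigree(p, inds, level)
  f <- inbreeding_f(p, keep)
  data.frame(id = keep, f = unname(f), restriction_level = level,
             inbred = classify_inbred(f), stringsAsFactors = FALSE)
}
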