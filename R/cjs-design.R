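#' Capture-mark-recapture data container
#'
#' Holds annual detection histories conditioned on first capture, the
#' individual-level covariates used in survival models, and interval-level
#' (year) covariates. Years run birth-cohort style: occasion `j` is the
#' trapping year `j`, and interval `j` spans occasion `j` to `j + 1`; a
#' year-level covariate attaches to the interval that starts in that year.
#'
#' @param ch 0/1 matrix, individuals x occasions (`T >= 2` columns); row
#'   names are individual ids. Every row must contain at least one 1.
#' @param age_at_first `"cub"` or `"adult"`: age class at first capture.
#'   An individual first caught as a cub spends its first interval in the
#'   cub class and all later intervals in the adult class; an individual
#'   first caught as an adult is always adult.
#' @param sex optional vector (`"F"`/`"M"` or a numeric code). Internally
#'   coded -0.5/+0.5 so that main effects are averaged over the sexes.
#' @param ind_cov optional data.frame of static individual covariates
#'   (rows aligned with `ch`).
#' @param year_cov optional data.frame of interval covariates with
#'   `ncol(ch) - 1` rows (e.g. summer rainfall, winter temperature,
#'   population size).
#' @return object of class `capture_data`.
#' @export
capture_data <- function(ch, age_at_first = "cub", sex = NULL,
                         ind_cov = NULL, year_cov = NULL) {
  ch <- as.matrix(ch)
  storage.mode(ch) <- "integer"
  if (ncol(ch) < 2) stopf("need at least 2 occasions")
  if (!all(ch %in% c(0L, 1L))) stopf("detection matrix must be 0/1")
  first <- apply(ch, 1, function(x) which(x == 1L)[1])
  if (anyNA(first)) stopf("individual(s) with all-zero history")
  n <- nrow(ch)
  if (is.null(rownames(ch))) rownames(ch) <- paste0("ind", seq_len(n))
  age_at_first <- rep_len(as.character(age_at_first), n)
  if (!all(age_at_first %in% c("cub", "adult"))) {
    stopf("age_at_first must be 'cub' or 'adult'")
  }
  sex_num <- if (is.null(sex)) rep(0, n) else {
    if (is.character(sex) || is.factor(sex)) {
      s <- as.character(sex)
      ifelse(s %in% c("F", "f", "female"), -0.5, 0.5)
    } else as.numeric(sex)
  }
  if (!is.null(ind_cov)) {
    ind_cov <- as.data.frame(ind_cov)
    if (nrow(ind_cov) != n) stopf("ind_cov must have one row per individual")
  }
  if (!is.null(year_cov)) {
    year_cov <- as.data.frame(year_cov)
    if (nrow(year_cov) != ncol(ch) - 1) {
      stopf("year_cov must have T-1 = %d rows", ncol(ch) - 1)
    }
  }
  structure(list(ch = ch, first = first, last = apply(ch, 1, function(x) max(which(x == 1L))),
                 age_at_first = age_at_first, sex = sex_num,
                 ind_cov = ind_cov, year_cov = year_cov,
                 n = n, T = ncol(ch)),
            class = "capture_data")
}

#' @export
print.capture_data <- function(x, ...) {
  cat(sprintf("<capture_data> %d individuals, %d occasions, %d releases\n",
              x$n, x$T, n_releases(x)))
  invisible(x)
}

# effective sample size: total release events = detections at occasions 1..T-1
n_releases <- function(data) sum(data$ch[, -data$T, drop = FALSE])

#' Read / write MARK-style .inp encounter histories
#'
#' Each line is `"<history> <frequency>;"`; frequencies > 1 are expanded to
#' individual rows. Comment lines (`/* ... */`) are ignored.
#'
#' @param path file path.
#' @return for `read_inp`, a 0/1 history matrix suitable for
#'   [capture_data()].
#' @rdname inp_io
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("/\\*.*?\\*/", "", lines)
  lines <- trimws(gsub(";", "", lines))
  lines <- lines[nzchar(lines)]
  hist <- character(0)
  freq <- integer(0)
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\\s+")[[1]]
    if (length(parts) < 2 || !grepl("^[01]+$", parts[1])) {
      stopf("malformed .inp line %d: '%s'", k, lines[k])
    }
    hist <- c(hist, parts[1])
    freq <- c(freq, as.integer(parts[2]))
  }
  rows <- rep(seq_along(hist), freq)
  ch <- do.call(rbind, lapply(hist[rows], function(h) {
    as.integer(strsplit(h, "")[[1]])
  }))
  rownames(ch) <- paste0("ind", seq_len(nrow(ch)))
  ch
}

#' @param ch 0/1 history matrix.
#' @rdname inp_io
#' @export
write_inp <- function(ch, path) {
  h <- apply(ch, 1, paste, collapse = "")
  writeLines(paste0(h, " 1;"), path)
  invisible(path)
}

#' Standardize a predictor to mean 0, SD 2
#'
#' The 2-SD convention makes coefficients of continuous predictors
#' comparable with those of (-0.5, +0.5)-coded binary predictors, which
#' matters when model-averaging main effects in the presence of
#' interactions.
#'
#' @param x numeric vector with nonzero variance.
#' @return `(x - mean(x)) / (2 * sd(x))`.
#' @export
standardize <- function(x) {
  if (stats::sd(x, na.rm = TRUE) == 0) stopf("cannot standardize a zero-variance vector")
  (x - mean(x, na.rm = TRUE)) / (2 * stats::sd(x, na.rm = TRUE))
}

#' Transform parasite (coccidial oocyst) counts into a survival covariate
#'
#' Counts are `log(x + 1)` transformed, then centered and scaled to SD 2
#' within each sampling month (seasonal shedding makes raw counts
#' incomparable across months), then pooled. A month where all transformed
#' counts are equal contributes zeros.
#'
#' @param counts nonnegative numeric vector.
#' @param month month label per count.
#' @return numeric covariate vector.
#' @export
transform_coccidia <- function(counts, month) {
  if (any(counts < 0, na.rm = TRUE)) stopf("negative parasite count")
  lx <- log(counts + 1)
  out <- numeric(length(lx))
  for (m in unique(month)) {
    i <- which(month == m)
    s <- stats::sd(lx[i], na.rm = TRUE)
    out[i] <- if (is.na(s) || s == 0) 0 else (lx[i] - mean(lx[i], na.rm = TRUE)) / (2 * s)
  }
  out
}

#' Column-mean imputation of missing covariates
#'
#' @param x numeric matrix or data.frame; each column must have at least one
#'   observed value.
#' @return completed matrix with attribute `"imputed"` (logical mask of
#'   filled cells).
#' @export
impute_missing <- function(x) {
  x <- as.matrix(x)
  mask <- is.na(x)
  for (j in seq_len(ncol(x))) {
    if (all(mask[, j])) stopf("column %s fully missing", colnames(x)[j] %||% j)
    x[mask[, j], j] <- mean(x[, j], na.rm = TRUE)
  }
  attr(x, "imputed") <- mask
  x
}

#' Parse MARK-style model notation
#'
#' Notation like `"Phi(a2-t/sex) p(t)"`: the survival (`Phi`) and recapture
#' (`p`) structures each take either a flat term list or an age-class split
#' `a2-<cub terms>/<adult terms>`. Terms are `+`-separated; `.` is the
#' intercept-only structure, `t` a year factor, `a*b` expands to
#' `a + b + a:b`, and `x^2` is a quadratic. Any other token names a
#' covariate of the data.
#'
#' @param notation model string.
#' @return object of class `cjs_spec` with elements `phi` and `p`, each a
#'   list `(age_split, cub, adult, terms)`.
#' @export
parse_model <- function(notation) {
  s <- trimws(notation)
  m <- regmatches(s, regexec("^Phi\\s*\\((.*?)\\)\\s*[pP]\\s*\\((.*?)\\)\\s*$", s))[[1]]
  if (length(m) != 3) {
    stopf("cannot parse model notation '%s' (expected \"Phi(...) p(...)\")", notation)
  }
  structure(list(phi = parse_structure(m[2], notation),
                 p = parse_structure(m[3], notation),
                 notation = s),
            class = "cjs_spec")
}

parse_structure <- function(txt, notation) {
  txt <- trimws(txt)
  if (grepl("^a2\\s*-", txt)) {
    body <- sub("^a2\\s*-\\s*", "", txt)
    halves <- strsplit(body, "/")[[1]]
    if (length(halves) != 2) {
      stopf("age-split structure needs '<cub>/<adult>' in '%s'", notation)
    }
    list(age_split = TRUE,
         cub = parse_terms(halves[1], notation),
         adult = parse_terms(halves[2], notation))
  } else {
    list(age_split = FALSE, terms = parse_terms(txt, notation))
  }
}

parse_terms <- function(txt, notation) {
  toks <- trimws(strsplit(txt, "\\+")[[1]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0 || identical(toks, ".")) return(character(0))
  out <- character(0)
  for (tk in toks) {
    if (tk == ".") next
    if (grepl("\\*", tk)) {
      ab <- trimws(strsplit(tk, "\\*")[[1]])
      if (length(ab) != 2) stopf("bad interaction token '%s' in '%s'", tk, notation)
      out <- c(out, ab[1], ab[2], paste0(ab[1], ":", ab[2]))
    } else {
      out <- c(out, tk)
    }
  }
  unique(out)
}

#' @export
print.cjs_spec <- function(x, ...) {
  cat("<cjs_spec>", x$notation, "\n")
  invisible(x)
}

# --- design construction -----------------------------------------------------

# value of a single term for given (individual, interval-or-occasion) rows
term_values <- function(term, data, i_idx, j_idx) {
  if (grepl(":", term, fixed = TRUE)) {
    ab <- strsplit(term, ":", fixed = TRUE)[[1]]
    return(term_values(ab[1], data, i_idx, j_idx) *
             term_values(ab[2], data, i_idx, j_idx))
  }
  if (grepl("\\^2$", term)) {
    return(term_values(sub("\\^2$", "", term), data, i_idx, j_idx)^2)
  }
  if (term == "sex") return(data$sex[i_idx])
  if (!is.null(data$ind_cov) && term %in% names(data$ind_cov)) {
    return(data$ind_cov[[term]][i_idx])
  }
  if (!is.null(data$year_cov) && term %in% names(data$year_cov)) {
    return(data$year_cov[[term]][j_idx])
  }
  stopf("unknown model term '%s' (not sex, t, an individual covariate or a year covariate)",
        term)
}

# design block for one class subset of long rows: intercept + term columns
design_block <- function(terms, data, i_idx, j_idx, prefix) {
  n <- length(i_idx)
  cols <- list()
  cols[[paste0(prefix, "(Intercept)")]] <- rep(1, n)
  for (term in terms) {
    if (term == "t") {
      lev <- sort(unique(j_idx))
      for (l in lev[-1]) {
        cols[[paste0(prefix, "t", l)]] <- as.numeric(j_idx == l)
      }
    } else if (grepl("(^t:|:t$)", term)) {
      other <- sub("(^t:|:t$)", "", term)
      ov <- term_values(other, data, i_idx, j_idx)
      lev <- sort(unique(j_idx))
      for (l in lev[-1]) {
        cols[[paste0(prefix, other, ":t", l)]] <- ov * (j_idx == l)
      }
    } else {
      cols[[paste0(prefix, term)]] <- term_values(term, data, i_idx, j_idx)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# long-format design for survival (type "phi": rows are intervals
# first..T-1 per individual) or recapture (type "p": rows are occasions
# first+1..T, indexed by the preceding interval j = occasion - 1)
build_design <- function(data, struct, type) {
  Tm1 <- data$T - 1L
  i_idx <- integer(0); j_idx <- integer(0)
  for (i in seq_len(data$n)) {
    if (data$first[i] > Tm1) next  # released at the final occasion: no interval
    js <- seq(data$first[i], Tm1)
    i_idx <- c(i_idx, rep.int(i, length(js)))
    j_idx <- c(j_idx, js)
  }
  # for p rows, j indexes the interval preceding the occasion (occasion j+1)
  if (!struct$age_split) {
    X <- design_block(struct$terms, data, i_idx, j_idx,
                      prefix = paste0(type, ":"))
    return(list(X = X, i = i_idx, j = j_idx,
                cub_rows = rep(FALSE, length(i_idx)),
                has_t = list(any = "t" %in% struct$terms,
                             blocks_with_t = as.integer("t" %in% struct$terms),
                             n_blocks = 1L)))
  }
  # cub class: the first interval of an individual first caught as a cub
  cub_rows <- (j_idx == data$first[i_idx]) & (data$age_at_first[i_idx] == "cub")
  if (type == "p") {
    # recapture occasions after first capture are all adult for known-age
    # animals; the a2 split on p collapses accordingly
    cub_rows <- rep(FALSE, length(i_idx))
  }
  Xc <- if (any(cub_rows)) {
    design_block(struct$cub, data, i_idx[cub_rows], j_idx[cub_rows],
                 prefix = paste0(type, ":cub:"))
  } else NULL
  Xa <- if (any(!cub_rows)) {
    design_block(struct$adult, data, i_idx[!cub_rows], j_idx[!cub_rows],
                 prefix = paste0(type, ":ad:"))
  } else NULL
  p_c <- if (is.null(Xc)) 0L else ncol(Xc)
  p_a <- if (is.null(Xa)) 0L else ncol(Xa)
  X <- matrix(0, length(i_idx), p_c + p_a)
  cn <- character(0)
  if (p_c) { X[cub_rows, seq_len(p_c)] <- Xc; cn <- c(cn, colnames(Xc)) }
  if (p_a) { X[!cub_rows, p_c + seq_len(p_a)] <- Xa; cn <- c(cn, colnames(Xa)) }
  colnames(X) <- cn
  blocks_with_t <- (p_c > 0 && "t" %in% struct$cub) + (p_a > 0 && "t" %in% struct$adult)
  list(X = X, i = i_idx, j = j_idx, cub_rows = cub_rows,
       has_t = list(any = blocks_with_t > 0, blocks_with_t = blocks_with_t,
                    n_blocks = (p_c > 0) + (p_a > 0)))
}
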