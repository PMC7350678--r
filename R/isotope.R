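# Natural-abundance and tracer-purity correction.
#
# Heavy isotopes occur naturally (13C at ~1.1%, 15N, 18O, 34S, 2H), so the
# measured intensity at mass shift M+i mixes tracer-derived labelling with
# natural background.  The measured vector relates linearly to the true
# labelled-atom counts: measured = CM %*% true, where column j of the
# correction matrix CM is the mass-shift distribution of a molecule with
# exactly j tracer atoms nominally labelled.  Inverting this system under a
# non-negativity constraint (Lawson-Hanson NNLS) recovers the
# tracer-derived mass-isotopomer distribution.
#
# The model is the classical low-resolution one: every atom contributes
# independently, so the molecule's shift distribution is the convolution of
# per-atom shift polynomials.  With `tracer_only = TRUE` (default) only the
# tracer element's natural abundance is modelled -- appropriate for
# high-resolution analysers that mass-resolve non-tracer isotopes away, and
# the regime in which a 3-carbon molecule shows ~3% natural M+1 and a
# 10-carbon molecule ~10%.

#' Parse an elemental sum formula
#'
#' Understands strings such as `"C10H16N5O13P3"` (ATP) or `"C10H17N3O6S"`
#' (glutathione): repeated `<ElementSymbol><count>` pieces, a missing count
#' meaning 1.  Only C, H, N, O, P and S are allowed; formulas containing
#' other elements (Si, Cl, Br, ...) cannot be corrected and raise an error.
#' P has no stable heavy isotope and contributes nothing, but is parsed.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C10H16N5O13P3")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- stringr::str_trim(text)
  m <- stringr::str_match_all(text, "([A-Z][a-z]?)(\\d*)")[[1]]
  if (nrow(m) == 0 || paste(m[, 1], collapse = "") != text) {
    abort(sprintf("cannot parse formula '%s'", text))
  }
  elements <- m[, 2]
  allowed <- c("C", "H", "N", "O", "P", "S")
  bad <- setdiff(elements, allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "unsupported element(s) %s in formula '%s' (only C, H, N, O, P, S can be corrected)",
      paste(bad, collapse = ", "), text))
  }
  counts <- as.integer(ifelse(m[, 3] == "", 1L, m[, 3]))
  out <- tapply(counts, factor(elements, levels = allowed), sum)
  out[is.na(out)] <- 0L
  setNames(as.integer(out), allowed)
}

#' Default natural-abundance table
#'
#' Heavy-isotope abundances per element as (mass shift in Da -> fraction);
#' the light isotope carries the remainder.  Carbon is pinned at 1.1% for
#' 13C; the others follow standard terrestrial values: 2H 0.0115%, 15N
#' 0.364%, 17O 0.038% and 18O 0.205%, 33S 0.75% and 34S 4.21%.  Phosphorus
#' is monoisotopic.  Override entries to explore other assumptions.
#'
#' @return Named list; each element is a numeric vector of abundances named
#'   by mass shift.
#' @export
default_isotope_table <- function() {
  list(
    C = c("1" = 0.011),
    H = c("1" = 0.000115),
    N = c("1" = 0.00364),
    O = c("1" = 0.00038, "2" = 0.00205),
    P = numeric(0),
    S = c("1" = 0.0075, "2" = 0.0421)
  )
}

#' Tracer specification
#'
#' @param element `"C13"`, `"N15"` or `"H2"` -- the heavy isotope fed in the
#'   tracing experiment.
#' @param purity Isotopic purity of the tracer in (0, 1]: the probability
#'   that a nominally labelled position actually carries the heavy isotope.
#' @return List with `element` (the element symbol), `isotope` (the input
#'   name) and `purity`.
#' @export
tracer_spec <- function(element = c("C13", "N15", "H2"), purity = 1) {
  element <- match.arg(element)
  stopifnot(is.numeric(purity), length(purity) == 1, purity > 0, purity <= 1)
  list(element = c(C13 = "C", N15 = "N", H2 = "H")[[element]],
       isotope = element, purity = purity)
}

# polynomial (coef vector over shifts 0..k) multiplication
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

poly_power <- function(p, n) {
  out <- 1
  while (n > 0) {
    if (n %% 2 == 1) out <- poly_mult(out, p)
    p <- poly_mult(p, p)
    n <- n %/% 2
  }
  out
}

# per-atom shift polynomial for one atom of `element` at natural abundance
atom_poly <- function(element, isotopes) {
  ab <- isotopes[[element]]
  if (is.null(ab) || length(ab) == 0) return(1)
  shifts <- as.integer(names(ab))
  p <- numeric(max(shifts) + 1)
  p[1] <- 1 - sum(ab)
  p[shifts + 1] <- ab
  p
}

#' Mass-shift distribution of a partially labelled molecule
#'
#' Computes the probability distribution over mass shifts (M+0, M+1, ...)
#' for a molecule with `labelled` tracer atoms nominally heavy.  Each
#' labelled position is heavy with probability `tracer$purity` and light
#' otherwise; the remaining tracer-element atoms pick up heavy isotopes at
#' natural abundance (binomial); and, unless `tracer_only`, all other
#' elements contribute their natural heavy isotopes too, convolved in as
#' independent per-atom polynomials (so +2 isotopes such as 18O and 34S are
#' handled exactly).
#'
#' With `labelled = 0` this is the plain natural-abundance isotope pattern:
#' for C3 at 1.1% 13C the M+1 fraction is `3 * 0.011 * 0.989^2` = 3.2%, for
#' C10 it is 10.0%.
#'
#' @param formula Formula string or parsed [parse_formula()] vector.
#' @param tracer A [tracer_spec()].
#' @param labelled Number of nominally labelled tracer atoms (0 ..
#'   tracer-atom count).
#' @param isotopes Abundance table, see [default_isotope_table()].
#' @param tracer_only If `TRUE` (default) ignore natural isotopes of
#'   non-tracer elements, as resolved away on high-resolution instruments.
#' @return Numeric probability vector over shifts `0..k` (element `i` is
#'   shift `i - 1`); sums to 1.
#' @examples
#' natural_distribution("C3", labelled = 0)
#' @export
natural_distribution <- function(formula, tracer = tracer_spec("C13"),
                                 labelled = 0,
                                 isotopes = default_isotope_table(),
                                 tracer_only = TRUE) {
  if (is.character(formula)) formula <- parse_formula(formula)
  n_tr <- formula[[tracer$element]]
  if (labelled > n_tr) {
    abort(sprintf("labelled atoms (%d) exceed %s count (%d) in the formula",
                  labelled, tracer$element, n_tr))
  }
  p <- 1
  if (labelled > 0) {
    p <- poly_mult(p, poly_power(c(1 - tracer$purity, tracer$purity), labelled))
  }
  if (n_tr - labelled > 0) {
    p <- poly_mult(p, poly_power(atom_poly(tracer$element, isotopes),
                                 n_tr - labelled))
  }
  if (!tracer_only) {
    for (el in setdiff(names(formula), tracer$element)) {
      if (formula[[el]] > 0) {
        p <- poly_mult(p, poly_power(atom_poly(el, isotopes), formula[[el]]))
      }
    }
  }
  p <- as.numeric(p)
  while (length(p) > 1 && p[length(p)] == 0) p <- p[-length(p)]
  p
}

#' Build the natural-abundance correction matrix
#'
#' Column `j` (for `j = 0 .. n` tracer atoms) holds the mass-shift
#' distribution of the molecule with `j` nominally labelled atoms,
#' truncated to the observed shifts `0..max_shift`.  Columns therefore sum
#' to at most 1; the shortfall is the probability mass pushed beyond the
#' truncation.
#'
#' @inheritParams natural_distribution
#' @param max_shift Largest observed mass shift (rows are `0..max_shift`);
#'   defaults to the tracer-atom count.
#' @return Numeric matrix of dimension `(max_shift + 1) x (n_tracer + 1)`
#'   with dimnames `M+i` / `x0..xn`.
#' @export
build_correction_matrix <- function(formula, tracer = tracer_spec("C13"),
                                    max_shift = NULL,
                                    isotopes = default_isotope_table(),
                                    tracer_only = TRUE) {
  if (is.character(formula)) formula <- parse_formula(formula)
  n_tr <- formula[[tracer$element]]
  if (n_tr == 0) {
    abort(sprintf("formula contains no %s; cannot correct a %s tracer",
                  tracer$element, tracer$isotope))
  }
  max_shift <- max_shift %||% n_tr
  cm <- matrix(0, nrow = max_shift + 1, ncol = n_tr + 1,
               dimnames = list(paste0("M+", 0:max_shift),
                               paste0("x", 0:n_tr)))
  for (j in 0:n_tr) {
    d <- natural_distribution(formula, tracer, labelled = j,
                              isotopes = isotopes, tracer_only = tracer_only)
    k <- min(length(d), max_shift + 1)
    cm[1:k, j + 1] <- d[1:k]
  }
  cm
}

#' Non-negative least squares (Lawson--Hanson)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` with the classical
#' active-set algorithm.  Small dense problems only (correction matrices
#' are at most 31 x 31).
#'
#' @param A Numeric matrix.
#' @param b Numeric vector, `length(b) == nrow(A)`.
#' @return List with `x` (the non-negative solution) and `residual`
#'   (`||Ax - b||_2`).
#' @export
nnls_solve <- function(A, b) {
  stopifnot(is.matrix(A), length(b) == nrow(A))
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  tol <- 1e-10 * max(abs(crossprod(A, b)), 1)
  iter <- 0
  while (any(!passive) && max(w[!passive]) > tol && iter < 30 * n) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { z <- numeric(n); break }
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
  }
  list(x = as.numeric(x), residual = sqrt(sum((A %*% x - b)^2)))
}

#' Correct a measured isotopologue vector
#'
#' Recovers the tracer-derived labelled-atom distribution from a measured
#' intensity vector by solving `measured = CM %*% corrected` under
#' non-negativity.  Missing entries enter the solver as 0 (with a warning);
#' an all-zero measurement returns all zeros.
#'
#' @param measured Numeric vector of intensities for shifts
#'   `0..(nrow(cm) - 1)`; `NA` allowed.
#' @param cm Correction matrix from [build_correction_matrix()].
#' @return Numeric vector of corrected intensities (length `ncol(cm)`), with
#'   attribute `"residual"` (the NNLS residual norm) and `"had_missing"`.
#' @export
correct_mid <- function(measured, cm) {
  stopifnot(is.matrix(cm))
  if (length(measured) != nrow(cm)) {
    abort(sprintf("measured vector has length %d but the matrix has %d rows",
                  length(measured), nrow(cm)))
  }
  had_missing <- anyNA(measured)
  if (had_missing) {
    warn("missing isotopologue intensities treated as 0 for correction")
    measured[is.na(measured)] <- 0
  }
  if (all(measured == 0)) {
    out <- numeric(ncol(cm))
    attr(out, "residual") <- 0
    attr(out, "had_missing") <- had_missing
    return(out)
  }
  fit <- nnls_solve(cm, measured)
  out <- fit$x
  attr(out, "residual") <- fit$residual
  attr(out, "had_missing") <- had_missing
  out
}

#' Read a compound-to-formula table
#'
#' Two columns, compound and sum formula, as CSV or XLSX.  Extra columns are
#' ignored.
#'
#' @param path File path, or a data frame with two columns.
#' @return Named character vector formula-by-compound.
#' @export
read_formula_table <- function(path) {
  raw <- if (is.data.frame(path)) {
    path
  } else if (tolower(tools::file_ext(path)) %in% c("xls", "xlsx")) {
    readxl::read_excel(path, sheet = 1, col_types = "text")
  } else {
    readr::read_delim(path, delim = sniff_delim(path),
                      col_types = readr::cols(.default = "c"),
                      show_col_types = FALSE)
  }
  if (ncol(raw) < 2) abort("formula table needs columns: compound, formula")
  setNames(stringr::str_trim(as.character(raw[[2]])),
           stringr::str_trim(as.character(raw[[1]])))
}

#' Natural-abundance correction of grouped tracing data
#'
#' Applies [correct_mid()] per (base compound, sample): builds each
#' compound's correction matrix from its sum formula and replaces the
#' measured isotopologue intensities by corrected ones, with corrected
#' fractions alongside.  Compounds without a formula are left uncorrected
#' with a warning.
#'
#' @param grouped Output of [group_isotopologues()].
#' @param formulas Named character vector (compound -> formula), a data
#'   frame, or a file path accepted by [read_formula_table()].
#' @param tracer A [tracer_spec()].
#' @param isotopes Abundance table.
#' @param tracer_only See [natural_distribution()].
#' @return Tibble like `grouped` (all shifts `0..max` present per compound)
#'   with columns `intensity` (corrected), `fraction` (corrected relative
#'   distribution), `residual` and `corrected` (logical).
#' @export
correct_isotopologues <- function(grouped, formulas,
                                  tracer = tracer_spec("C13"),
                                  isotopes = default_isotope_table(),
                                  tracer_only = TRUE) {
  if (is.data.frame(formulas) ||
      (is.character(formulas) && is.null(names(formulas)))) {
    formulas <- read_formula_table(formulas)
  }
  bases <- unique(grouped$base_compound)
  no_formula <- setdiff(bases, names(formulas))
  if (length(no_formula) > 0) {
    warn(sprintf("no sum formula for: %s; left uncorrected",
                 paste(no_formula, collapse = ", ")))
  }
  meta_cols <- setdiff(names(grouped),
                       c("base_compound", "shift", "sample_id", "intensity",
                         "rt", "fraction"))
  pieces <- lapply(bases, function(bc) {
    sub <- filter(grouped, base_compound == bc)
    max_shift <- max(sub$shift)
    if (!bc %in% names(formulas)) {
      res <- sub %>%
        group_by(base_compound, sample_id) %>%
        mutate(fraction = {
          tot <- sum(intensity, na.rm = TRUE)
          if (tot > 0) ifelse(is.na(intensity), 0, intensity / tot) else NA_real_
        }) %>%
        ungroup() %>%
        mutate(residual = NA_real_, corrected = FALSE)
      return(res)
    }
    n_tr <- parse_formula(formulas[[bc]])[[tracer$element]]
    if (max_shift > n_tr) {
      abort(sprintf(
        "'%s' shows M+%d but its formula has only %d %s atoms",
        bc, max_shift, n_tr, tracer$element))
    }
    cm <- build_correction_matrix(formulas[[bc]], tracer,
                                  max_shift = max_shift,
                                  isotopes = isotopes,
                                  tracer_only = tracer_only)
    purrr::map_dfr(unique(sub$sample_id), function(sid) {
      rows <- filter(sub, sample_id == sid)
      measured <- rep(NA_real_, max_shift + 1)
      measured[rows$shift + 1] <- rows$intensity
      corr <- suppressWarnings(correct_mid(measured, cm))
      tot <- sum(corr)
      out <- tibble(
        base_compound = bc, sample_id = sid,
        shift = 0:(ncol(cm) - 1), intensity = as.numeric(corr),
        fraction = if (tot > 0) as.numeric(corr) / tot else NA_real_,
        residual = attr(corr, "residual"), corrected = TRUE
      )
      for (col in meta_cols) out[[col]] <- rows[[col]][1]
      out
    })
  })
  bind_rows(pieces)
}
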