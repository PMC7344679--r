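# Monoisotopic atomic masses (Da), IUPAC values; the adduct shifts below are
# derived from these at load time rather than hard-coded.
MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12,
  N  = 14.003074,
  O  = 15.994915,
  Na = 22.98976928,
  S  = 31.97207100,
  P  = 30.97376163
)
ELECTRON_MASS <- 0.00054858
PROTON_MASS <- MONOISOTOPIC_MASS[["H"]] - ELECTRON_MASS

# Parse an elemental formula string like "C15H14O6" into a named count
# vector. Supported elements are those of MONOISOTOPIC_MASS; anything else,
# or any unconsumed text, is an error.
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula))
    stop("empty or invalid formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: ", formula)
  el <- sub("[0-9]*$", "", tokens)
  ct <- sub("^[A-Za-z]+", "", tokens)
  ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
  unknown <- setdiff(el, names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element(s) in formula ", formula, ": ",
         paste(unknown, collapse = ", "))
  if (any(ct <= 0L)) stop("element counts must be positive in ", formula)
  counts <- tapply(ct, factor(el, levels = unique(el)), sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times monoisotopic atomic mass over the formula's elements
#' (C, H, N, O, P, S, Na supported).
#'
#' @param formula elemental formula string, e.g. `"C15H14O6"`.
#' @return mass in Dalton.
#' @examples
#' formula_monoisotopic_mass("H2O")      # 18.01056
#' formula_monoisotopic_mass("C15H14O6") # catechin, 290.07904
#' @export
formula_monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * MONOISOTOPIC_MASS[names(counts)])
}

#' Supported ionization adducts
#'
#' The singly charged adducts considered during annotation: `M+H`, `M+Na`,
#' `M+NH4` in positive mode; `M-H`, `M+AcOH-H` (acetate) in negative mode;
#' and `M+` in positive mode for intrinsically charged cations (flavylium
#' anthocyanins), whose database formula already describes the cation so the
#' only shift is the electron deficit. Mass shifts are computed from the
#' monoisotopic table, including the electron mass.
#'
#' @return data.frame with columns `adduct`, `mode`, `mass_shift` (Da) and
#'   `intrinsic` (logical: applies only to intrinsically charged compounds).
#' @export
adduct_table <- function() {
  amass <- function(f) formula_monoisotopic_mass(f)
  data.frame(
    adduct = c("M+H", "M+Na", "M+NH4", "M-H", "M+AcOH-H", "M+"),
    mode = c("positive", "positive", "positive", "negative", "negative",
             "positive"),
    mass_shift = c(
      PROTON_MASS,
      amass("Na") - ELECTRON_MASS,
      amass("NH4") - ELECTRON_MASS,
      -PROTON_MASS,
      amass("C2H4O2") - PROTON_MASS,
      -ELECTRON_MASS),
    intrinsic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Theoretical m/z of an adduct ion
#'
#' @param neutral_mass monoisotopic mass of the (neutral or, for `M+`,
#'   cationic) formula in Da; must be positive.
#' @param adduct adduct name from [adduct_table()].
#' @param mode optional ionization mode; if given, a mode-inconsistent adduct
#'   is an error.
#' @return m/z in Thomson (singly charged).
#' @export
adduct_mz <- function(neutral_mass, adduct, mode = NULL) {
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0))
    stop("neutral_mass must be positive")
  tab <- adduct_table()
  i <- match(adduct, tab$adduct)
  if (is.na(i)) stop("unknown adduct: ", adduct)
  if (!is.null(mode) && tab$mode[i] != mode)
    stop("adduct ", adduct, " is not a ", mode, "-mode species")
  neutral_mass + tab$mass_shift[i]
}

#' Annotate features by exact-mass adduct matching
#'
#' For every feature, finds all (compound, adduct) pairs whose theoretical
#' m/z lies within `tol_ppm` of the observed m/z, restricted to adducts of
#' the table's ionization mode. Neutral compounds are matched through the
#' neutral adducts; intrinsically charged compounds only through `M+`.
#' ppm error is `(observed - theoretical) / theoretical * 1e6`. Each feature
#' then receives an MSI confidence level via [assign_msi_level()].
#'
#' @param table a `feature_table` (its `mode` selects the adduct set).
#' @param db compound database data.frame (see [read_compound_db()]).
#' @param tol_ppm maximum absolute ppm error (default 5).
#' @return an `annotation_result`: list with `candidates` (one row per match,
#'   sorted by |ppm error| within feature) and `msi_levels` (one row per
#'   feature: `feature_id`, `mz`, `msi_level`).
#' @export
annotate_features <- function(table, db, tol_ppm = 5.0) {
  stopifnot(inherits(table, "feature_table"), tol_ppm >= 0)
  adducts <- adduct_table()
  adducts <- adducts[adducts$mode == table$mode, , drop = FALSE]
  # theoretical m/z for every admissible (compound, adduct) pair
  theo <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    mass <- formula_monoisotopic_mass(db$formula[i])
    ok <- if (db$intrinsic_charge[i] == 1) adducts$intrinsic else !adducts$intrinsic
    ad <- adducts[ok, , drop = FALSE]
    if (!nrow(ad)) return(NULL)
    data.frame(compound = db$name[i], formula = db$formula[i],
               compound_class = db$compound_class[i],
               adduct = ad$adduct, theoretical_mz = mass + ad$mass_shift)
  }))
  cand <- vector("list", n_features(table))
  for (k in seq_len(n_features(table))) {
    if (is.null(theo)) { cand[[k]] <- NULL; next }
    ppm <- (table$mz[k] - theo$theoretical_mz) / theo$theoretical_mz * 1e6
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) next
    hit <- hit[order(abs(ppm[hit]))]
    cand[[k]] <- data.frame(feature_id = table$feature_id[k],
                            theo[hit, , drop = FALSE],
                            ppm_error = ppm[hit], row.names = NULL)
  }
  candidates <- do.call(rbind, cand)
  if (is.null(candidates))
    candidates <- data.frame(feature_id = character(0), compound = character(0),
                             formula = character(0), compound_class = character(0),
                             adduct = character(0), theoretical_mz = numeric(0),
                             ppm_error = numeric(0))
  msi <- vapply(seq_len(n_features(table)), function(k) {
    assign_msi_level(candidates[candidates$feature_id == table$feature_id[k], ,
                                drop = FALSE])
  }, integer(1))
  structure(list(candidates = candidates,
                 msi_levels = data.frame(feature_id = table$feature_id,
                                         mz = table$mz, msi_level = msi),
                 tol_ppm = tol_ppm),
            class = "annotation_result")
}

#' MSI confidence level of a candidate set
#'
#' Level 2: all candidates share a single molecular formula. Level 3:
#' multiple formulas, but all within a single compound class. Level 4:
#' no candidates, or candidates spanning multiple classes (unknown).
#'
#' @param candidates data.frame with columns `formula` and `compound_class`
#'   (possibly zero rows).
#' @return integer 2, 3 or 4.
#' @export
assign_msi_level <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(4L)
  if (length(unique(candidates$formula)) == 1L) return(2L)
  if (length(unique(candidates$compound_class)) == 1L) return(3L)
  4L
}
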