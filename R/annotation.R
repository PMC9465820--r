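# Monoisotopic masses of the most abundant isotopes (Da), CODATA/IUPAC.
.monoisotopic_masses <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Se = 79.9165213, Fe = 55.9349375,
  Mg = 23.9850417, Ca = 39.96259098, I = 126.904473, Br = 78.9183371
)

.proton_mass <- 1.007276466812

#' Parse an elemental formula into element counts
#' @noRd
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(integer(0))
  if (!grepl("^([A-Z][a-z]?[0-9]*)*$", formula))
    stop("cannot parse formula: ", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]*$", "", tokens)
  n <- as.integer(sub("^[A-Z][a-z]?", "", tokens))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Compose a formula string from element counts (Hill order)
#' @noRd
compose_formula <- function(counts) {
  counts <- counts[counts > 0]
  el <- names(counts)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (counts[[e]] > 1L) counts[[e]] else ""), character(1)),
    collapse = "")
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums most-abundant-isotope masses times element counts. The supported
#' element set covers common metabolite formulas (C, H, N, O, P, S plus
#' halogens, Na, K, Se, Fe, Mg, Ca); unknown symbols are refused.
#'
#' @param formula character vector of formulas (e.g. `"C6H12O6"`); an empty
#'   string has mass 0.
#' @return numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' formula_mass("H2O")  # 18.0106
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    if (length(counts) == 0) return(0)
    unknown <- setdiff(names(counts), names(.monoisotopic_masses))
    if (length(unknown))
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    sum(.monoisotopic_masses[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a reference metabolite mass list
#'
#' Expects a TSV with columns `id`, `name`, `formula` and optionally
#' `keto_acid` (logical flag for alpha-keto acids eligible for
#' phenylhydrazone derivatization). Neutral monoisotopic masses are computed
#' from the formulas. A small bundled list is available via
#' `system.file("extdata", "reference_metabolites.tsv",
#' package = "mixdeconv")`.
#'
#' @param path TSV file path.
#' @return data.frame of class `reference_mass_list`: `id`, `name`,
#'   `formula`, `mass`, `keto_acid`, `derivative`.
#' @export
read_reference_masses <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "formula") %in% names(d)))
  if (is.null(d$keto_acid)) d$keto_acid <- FALSE
  d$keto_acid <- as.logical(d$keto_acid)
  d$mass <- formula_mass(d$formula)
  d$derivative <- FALSE
  class(d) <- c("reference_mass_list", "data.frame")
  d
}

#' Add phenylhydrazone derivatives of alpha-keto acids
#'
#' Alpha-keto acids are stabilized during extraction by reaction with
#' phenylhydrazine, shifting the detectable species by `+C6H8N2 - H2O`
#' (+90.0582 Da). For every entry flagged `keto_acid`, a derivative entry is
#' appended with the adjusted formula, recomputed mass, and identifier
#' prefixed `PHderiv_`.
#'
#' @param entries a `reference_mass_list` data.frame (see
#'   [read_reference_masses()]).
#' @return the list with derivative rows appended.
#' @export
derivatize_keto_acids <- function(entries) {
  stopifnot(all(c("id", "formula") %in% names(entries)))
  if (is.null(entries$keto_acid) || !any(entries$keto_acid))
    return(entries)
  add <- parse_formula("C6H8N2")
  sub <- parse_formula("H2O")
  flagged <- entries[which(entries$keto_acid), ]
  deriv <- flagged
  deriv$formula <- vapply(flagged$formula, function(f) {
    counts <- parse_formula(f)
    all_el <- union(union(names(counts), names(add)), names(sub))
    full <- stats::setNames(integer(length(all_el)), all_el)
    full[names(counts)] <- counts
    full[names(add)] <- full[names(add)] + add
    full[names(sub)] <- full[names(sub)] - sub
    if (any(full < 0))
      stop("derivative of ", f, " has a negative element count")
    compose_formula(full)
  }, character(1), USE.NAMES = FALSE)
  deriv$id <- paste0("PHderiv_", flagged$id)
  deriv$name <- paste0("PHderiv_", flagged$name)
  deriv$mass <- formula_mass(deriv$formula)
  deriv$derivative <- TRUE
  deriv$keto_acid <- FALSE
  out <- rbind(entries, deriv)
  rownames(out) <- NULL
  out
}

#' Annotate measured ions by accurate mass
#'
#' Matches measured m/z values against a reference mass list under an adduct
#' rule (default deprotonation, `[M-H]-`, expected m/z = neutral mass minus
#' the proton mass). All references within the mass tolerance are reported,
#' sorted by absolute error; multiple matches are preserved. The comparison
#' is strict (`|error| < tolerance`) by default.
#'
#' @param mz numeric vector of measured m/z values (named, or names are
#'   generated).
#' @param references a `reference_mass_list` (after optional
#'   [derivatize_keto_acids()]).
#' @param tolerance mass tolerance in m/z units (default 0.003).
#' @param adduct `"M-H"`, `"M+H"` or `"none"` (neutral-mass matching).
#' @param inclusive if TRUE, matches at exactly the tolerance are kept.
#' @return data.frame of class `annotation_table`: one row per (ion, match)
#'   pair plus one row with `NA` match columns per unmatched ion; columns
#'   `ion`, `mz`, `id`, `name`, `formula`, `expected_mz`, `mass_error`,
#'   `adduct`.
#' @export
annotate_ions <- function(mz, references, tolerance = 0.003,
                          adduct = c("M-H", "M+H", "none"),
                          inclusive = FALSE) {
  adduct <- match.arg(adduct)
  stopifnot(tolerance > 0, "mass" %in% names(references))
  expected <- switch(adduct,
                     "M-H" = references$mass - .proton_mass,
                     "M+H" = references$mass + .proton_mass,
                     "none" = references$mass)
  ion <- names(mz)
  if (is.null(ion)) ion <- sprintf("ion%04d", seq_along(mz))
  rows <- lapply(seq_along(mz), function(i) {
    err <- mz[i] - expected
    hit <- if (inclusive) abs(err) <= tolerance else abs(err) < tolerance
    if (!any(hit)) {
      return(data.frame(ion = ion[i], mz = unname(mz[i]), id = NA_character_,
                        name = NA_character_, formula = NA_character_,
                        expected_mz = NA_real_, mass_error = NA_real_,
                        adduct = adduct))
    }
    idx <- which(hit)[order(abs(err[hit]))]
    data.frame(ion = ion[i], mz = unname(mz[i]), id = references$id[idx],
               name = references$name[idx],
               formula = references$formula[idx],
               expected_mz = expected[idx], mass_error = err[idx],
               adduct = adduct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}
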