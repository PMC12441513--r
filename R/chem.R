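# Elemental-formula arithmetic, monoisotopic masses, adduct m/z and ppm error.
#
# All downstream mass arithmetic in the package funnels through this file so
# that a single set of isotope-mass constants governs every theoretical value.

# Monoisotopic (most abundant isotope) masses, Da. CODATA/AME values; carbon-12
# is exact by definition. Extend here to support further elements.
.ISOTOPE_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.00307400443,
  O  = 15.99491461956,
  S  = 31.97207117,
  P  = 30.97376199842,
  Na = 22.98976928,
  K  = 38.9637064864,
  Cl = 34.968852682
)

# Proton mass (H atom minus one electron); electron mass, Da.
.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990907

#' Parse an elemental formula string
#'
#' Parses Hill-notation formula strings such as `"C21H18O11"` into a named
#' integer vector of element counts. Omitted counts mean 1 (`"H2O"` is
#' `c(H = 2, O = 1)`). Parentheses, isotope labels and charges are not part of
#' the accepted grammar.
#'
#' @param text A single formula string.
#' @return A named integer vector of class `elemental_formula`, ordered in
#'   Hill convention (C, H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C21H18O11")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (text == "") {
    return(as_formula(integer(0)))
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(text)) {
    stop("cannot parse formula '", text, "': unexpected characters", call. = FALSE)
  }
  elems <- sub("[0-9]+$", "", matched)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", matched)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(elems, names(.ISOTOPE_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s) in formula '", text, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tapply(counts, elems, sum)
  as_formula(stats::setNames(as.integer(out), names(out)))
}

# Internal constructor: validates, drops zeros, applies Hill order.
as_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (any(counts < 0L)) {
    stop("formula has negative element count(s): ",
         paste(names(counts)[counts < 0L], collapse = ", "), call. = FALSE)
  }
  rest <- sort(setdiff(names(counts), c("C", "H")))
  ord <- c(intersect(c("C", "H"), names(counts)), rest)
  counts <- counts[ord]
  structure(as.integer(counts), names = ord, class = "elemental_formula")
}

#' Serialize an elemental formula to Hill notation
#'
#' @param f A formula (named counts vector or string).
#' @return A single string; parsing it back reproduces `f`.
#' @export
format_formula <- function(f) {
  f <- as_elemental(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "  (", sprintf("%.5f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

# Accept either a formula string or an elemental_formula / named vector.
as_elemental <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (inherits(f, "elemental_formula")) return(f)
  if (!is.null(names(f))) return(as_formula(stats::setNames(as.integer(f), names(f))))
  stop("not an elemental formula: ", deparse(substitute(f)), call. = FALSE)
}

#' Add or subtract elemental formulas
#'
#' Element-wise formula arithmetic. Subtraction that would drive any element
#' count negative is an error (the transformation is chemically impossible for
#' that parent).
#'
#' @param f1,f2 Formulas (strings or `elemental_formula` objects).
#' @return An `elemental_formula`.
#' @examples
#' formula_add("C15H10O5", "C6H8O6")      # aglycone + glucuronide
#' formula_subtract("C21H18O11", "C6H8O6")
#' @export
formula_add <- function(f1, f2) {
  f1 <- as_elemental(f1); f2 <- as_elemental(f2)
  all_el <- union(names(f1), names(f2))
  v1 <- stats::setNames(integer(length(all_el)), all_el)
  v1[names(f1)] <- unclass(f1)
  v1[names(f2)] <- v1[names(f2)] + unclass(f2)
  as_formula(v1)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  f1 <- as_elemental(f1); f2 <- as_elemental(f2)
  all_el <- union(names(f1), names(f2))
  v1 <- stats::setNames(integer(length(all_el)), all_el)
  v1[names(f1)] <- unclass(f1)
  v1[names(f2)] <- v1[names(f2)] - unclass(f2)
  as_formula(v1)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#'
#' @param f Formula (string or `elemental_formula`).
#' @return Mass in Da (full double precision; format to 4 dp for display).
#' @examples
#' monoisotopic_mass("C21H18O11")  # 446.0849 (baicalin)
#' @export
monoisotopic_mass <- function(f) {
  f <- as_elemental(f)
  if (length(f) == 0) return(0)
  sum(unclass(f) * .ISOTOPE_MASS[names(f)])
}

# The five supported electrospray adducts. Mass deltas are derived once from
# the isotope-mass table with electron correction (see adduct_table test):
#   [M+H]+       +proton
#   [M+NH4]+     +NH3 + proton
#   [M+H-H2O]+   +proton - H2O
#   [M-H]-       -proton
#   [M+HCOO]-    +HCOOH - proton
.ADDUCTS <- data.frame(
  name = c("[M+H]+", "[M+NH4]+", "[M+H-H2O]+", "[M-H]-", "[M+HCOO]-"),
  polarity = c("positive", "positive", "positive", "negative", "negative"),
  charge = c(1L, 1L, 1L, -1L, -1L),
  stringsAsFactors = FALSE
)
.ADDUCTS$mass_delta <- c(
  .PROTON_MASS,
  .PROTON_MASS + 3 * .ISOTOPE_MASS[["H"]] + .ISOTOPE_MASS[["N"]],
  .PROTON_MASS - (2 * .ISOTOPE_MASS[["H"]] + .ISOTOPE_MASS[["O"]]),
  -.PROTON_MASS,
  -.PROTON_MASS + (2 * .ISOTOPE_MASS[["H"]] + .ISOTOPE_MASS[["C"]] +
                     2 * .ISOTOPE_MASS[["O"]])
)

#' Supported electrospray adducts
#'
#' The five adducts used throughout: `[M+H]+`, `[M+NH4]+`, `[M+H-H2O]+` in
#' positive mode and `[M-H]-`, `[M+HCOO]-` in negative mode. Mass deltas are
#' electron-corrected (proton mass 1.00727646688 Da).
#'
#' @return A data frame with columns `name`, `polarity`, `charge`, `mass_delta`.
#' @export
adduct_table <- function() .ADDUCTS

# Normalise the unicode/typographic dashes that appear in printed tables.
normalize_adduct_name <- function(name) {
  name <- gsub("–|−|—", "-", name)
  gsub("[[:space:]]", "", name)
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (>= 0).
#' @param adduct Adduct name, one of `adduct_table()$name`.
#' @return m/z of the charged species.
#' @examples
#' adduct_mz(monoisotopic_mass("C21H18O11"), "[M-H]-")   # 445.0776
#' adduct_mz(monoisotopic_mass("C15H10O5"), "[M+H]+")    # 271.0601
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass >= 0))
  adduct <- normalize_adduct_name(adduct)
  i <- match(adduct, .ADDUCTS$name)
  if (any(is.na(i))) {
    stop("unsupported adduct '", paste(adduct[is.na(i)], collapse = "', '"),
         "'; supported: ", paste(.ADDUCTS$name, collapse = ", "), call. = FALSE)
  }
  (neutral_mass + .ADDUCTS$mass_delta[i]) / abs(.ADDUCTS$charge[i])
}

#' Adduct polarity lookup
#' @param adduct Adduct name.
#' @return `"positive"` or `"negative"`.
#' @export
adduct_polarity <- function(adduct) {
  adduct <- normalize_adduct_name(adduct)
  i <- match(adduct, .ADDUCTS$name)
  if (any(is.na(i))) {
    stop("unsupported adduct '", paste(adduct[is.na(i)], collapse = "', '"), "'",
         call. = FALSE)
  }
  .ADDUCTS$polarity[i]
}

#' Signed mass error in parts per million
#'
#' Sign convention: `(measured - theoretical) / theoretical * 1e6`.
#'
#' @param measured,theoretical m/z values; `theoretical` must be > 0.
#' @return Signed ppm error.
#' @examples
#' ppm_error(445.0777, 445.0776)  # +0.22 ppm (baicalin worked example)
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0", call. = FALSE)
  (measured - theoretical) / theoretical * 1e6
}

#' @rdname ppm_error
#' @param tol_ppm Tolerance in ppm.
#' @return `within_ppm()`: logical, `|error| <= tol_ppm`.
#' @export
within_ppm <- function(measured, theoretical, tol_ppm = 5) {
  abs(ppm_error(measured, theoretical)) <= tol_ppm
}
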