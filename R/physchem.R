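# Predicted molecular weight from average residue masses.

# Average (isotope-abundance weighted) residue masses in Da, Expasy values;
# average because the comparison target is SDS-PAGE-scale kDa.
AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

#' Predicted molecular weight of a protein
#'
#' Sum of average residue masses plus one water. Additive:
#' `MW(ab) = MW(a) + MW(b) - water`.
#'
#' @param p A [protein_sequence()].
#' @param allow_ambiguous If `TRUE`, `X` residues contribute the mean of the
#'   20 residue masses; otherwise they are an error.
#' @return Mass in Dalton. The rounded kDa value is attached as attribute
#'   `"kDa"`.
#' @export
molecular_weight <- function(p, allow_ambiguous = FALSE) {
  stopifnot(inherits(p, "protein_sequence"))
  res <- strsplit(p$residues, "")[[1]]
  n_x <- sum(res == "X")
  if (n_x > 0 && !allow_ambiguous)
    stop("sequence '", p$id, "' contains ambiguous residue X ",
         "(set allow_ambiguous = TRUE to use the mean residue mass)")
  mw <- sum(AVG_RESIDUE_MASS[res[res != "X"]]) +
    n_x * mean(AVG_RESIDUE_MASS) + WATER_MASS
  structure(unname(mw), kDa = round(mw / 1000))
}
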