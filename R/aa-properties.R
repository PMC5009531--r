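# Five physicochemical descriptors per standard amino acid: steric parameter
# (graph shape index), polarizability, volume, hydrophobicity, isoelectric
# point. Classic parameter set used throughout sequence-based structure
# predictors; shipped inline so the package carries no binary data.
.aap_raw <- local({
  m <- matrix(c(
    # steric, polarizability, volume, hydrophobicity, isoelectric point
    1.28, 0.05, 1.00,  0.31,  6.11, # A
    1.77, 0.13, 2.43,  1.54,  6.35, # C
    1.60, 0.11, 2.78, -0.77,  2.95, # D
    1.56, 0.15, 3.78, -0.64,  3.09, # E
    2.94, 0.29, 5.89,  1.79,  5.67, # F
    0.00, 0.00, 0.00,  0.00,  6.07, # G
    2.99, 0.23, 4.66,  0.13,  7.69, # H
    4.19, 0.19, 4.00,  1.80,  6.04, # I
    1.89, 0.22, 4.77, -0.99,  9.99, # K
    2.59, 0.19, 4.00,  1.70,  6.04, # L
    2.35, 0.22, 4.43,  1.23,  5.71, # M
    1.60, 0.13, 2.95, -0.60,  6.52, # N
    2.67, 0.00, 2.72,  0.72,  6.80, # P
    1.56, 0.18, 3.95, -0.22,  5.65, # Q
    2.34, 0.29, 6.13, -1.01, 10.74, # R
    1.31, 0.06, 1.60, -0.04,  5.70, # S
    3.03, 0.11, 2.60,  0.26,  5.60, # T
    3.67, 0.14, 3.00,  1.22,  6.02, # V
    3.21, 0.41, 8.08,  2.25,  5.94, # W
    2.94, 0.30, 6.47,  1.39,  5.66  # Y
  ), nrow = 20, byrow = TRUE,
  dimnames = list(AA20, c("steric", "polarizability", "volume",
                          "hydrophobicity", "isoelectric")))
  m
})

#' Amino-acid property table
#'
#' Returns the five physicochemical descriptors used in residue encoding --
#' steric parameter (graph shape index), polarizability, volume,
#' hydrophobicity and isoelectric point -- for the 20 standard amino acids,
#' each column min-max normalized to `[0, 1]` over the 20 residues so that
#' every descriptor attains both 0 and 1 (polarizability shares its minimum
#' between glycine and proline in the source parameter set).
#'
#' @param normalized Logical; return min-max normalized values (default) or
#'   the raw descriptor values in their native units.
#' @return A tibble with columns `aa`, `steric`, `polarizability`, `volume`,
#'   `hydrophobicity`, `isoelectric`; one row per standard amino acid.
#' @examples
#' aa_property_table()
#' @export
aa_property_table <- function(normalized = TRUE) {
  m <- .aap_raw
  if (normalized) {
    m <- apply(m, 2, function(x) (x - min(x)) / (max(x) - min(x)))
  }
  tibble::as_tibble(m) |>
    dplyr::mutate(aa = AA20, .before = 1)
}

# Normalized AAP matrix keyed by residue letter, with an 'X' row holding the
# column means (unknown residue convention).
.aap_matrix <- function() {
  m <- apply(.aap_raw, 2, function(x) (x - min(x)) / (max(x) - min(x)))
  rownames(m) <- AA20
  rbind(m, X = colMeans(m))
}
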