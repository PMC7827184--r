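#' Amino-acid alphabet in PSI-BLAST column order
#'
#' The 20 standard residues in the column order used by PSI-BLAST's ASCII
#' PSSM output (`ARNDCQEGHILKMFPSTWYV`). All feature encoders index residues
#' by this order, never alphabetically, and PSSM objects carry it explicitly.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
pssm_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# internal constant (avoids repeated function calls in hot loops)
.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Physicochemical property table for the 20 amino acids
#'
#' Versioned per-residue scales and class assignments used by
#' [physicochemical_features()]:
#'
#' * `volume`: residue volume in cubic Angstrom (Zamyatnin).
#' * `hydrophobicity`: Kyte-Doolittle hydropathy index.
#' * `flexibility`: Bhaskaran-Ponnuswamy average flexibility index.
#' * `chemical_class`: 1 aliphatic, 2 aromatic, 3 sulfur-containing,
#'   4 hydroxyl, 5 basic, 6 acidic, 7 amide.
#' * `size_class`: 1 tiny, 2 small, 3 large (Livingstone-Barton style).
#' * `polarity`: 0 nonpolar, 1 polar.
#' * `hbond`: hydrogen-bonding capability; 0 none, 1 donor only,
#'   2 acceptor only, 3 donor and acceptor.
#' * `hydrophobicity_label`: 1 hydrophobic, 2 neutral, 3 hydrophilic.
#'
#' The table is data, not code: swapping in an alternative set of scales only
#' requires passing a different data frame with the same columns.
#'
#' @param version Table version string; only `"1.0"` ships with the package.
#' @return A data frame with one row per residue (rownames = one-letter code)
#'   and the columns listed above, plus an attribute `version`.
#' @export
physchem_table <- function(version = "1.0") {
  if (!identical(version, "1.0")) {
    stop("unknown physchem table version: ", version)
  }
  aa <- .AA
  volume <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
              Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
              L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
              S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  hydrophobicity <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                      L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  flexibility <- c(A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346,
                   Q = 0.493, E = 0.497, G = 0.544, H = 0.323, I = 0.462,
                   L = 0.365, K = 0.466, M = 0.295, F = 0.314, P = 0.509,
                   S = 0.507, T = 0.444, W = 0.305, Y = 0.420, V = 0.386)
  chem <- c(A = 1, R = 5, N = 7, D = 6, C = 3, Q = 7, E = 6, G = 1, H = 5,
            I = 1, L = 1, K = 5, M = 3, F = 2, P = 1, S = 4, T = 4, W = 2,
            Y = 2, V = 1)
  size <- c(A = 1, R = 3, N = 2, D = 2, C = 1, Q = 3, E = 3, G = 1, H = 3,
            I = 3, L = 3, K = 3, M = 3, F = 3, P = 2, S = 1, T = 1, W = 3,
            Y = 3, V = 2)
  polarity <- c(A = 0, R = 1, N = 1, D = 1, C = 0, Q = 1, E = 1, G = 0,
                H = 1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 1,
                T = 1, W = 0, Y = 1, V = 0)
  hbond <- c(A = 0, R = 1, N = 3, D = 2, C = 3, Q = 3, E = 2, G = 0, H = 3,
             I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 3, T = 3, W = 1,
             Y = 3, V = 0)
  hlabel <- c(A = 1, R = 3, N = 3, D = 3, C = 1, Q = 3, E = 3, G = 2, H = 2,
              I = 1, L = 1, K = 3, M = 1, F = 1, P = 2, S = 2, T = 2, W = 2,
              Y = 2, V = 1)
  tab <- data.frame(
    volume = volume[aa],
    hydrophobicity = hydrophobicity[aa],
    flexibility = flexibility[aa],
    chemical_class = chem[aa],
    size_class = size[aa],
    polarity = polarity[aa],
    hbond = hbond[aa],
    hydrophobicity_label = hlabel[aa],
    row.names = aa
  )
  attr(tab, "version") <- version
  tab
}
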