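# IUPAC diploid-consensus conventions shared across the package.
#
# A two-fold ambiguity code contributes both alleles at dosage 1 each;
# three/four-fold codes (B, D, H, V), 'N' and '-' are missing at that site.
# This matches the diploid consensus semantics of RAD assemblers.

.BASES <- c("A", "C", "G", "T")

# first/second allele carried by each consensus character (NA = missing)
.IUPAC_A1 <- c(A = "A", C = "C", G = "G", T = "T",
               R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
               N = NA, `-` = NA, B = NA, D = NA, H = NA, V = NA)
.IUPAC_A2 <- c(A = "A", C = "C", G = "G", T = "T",
               R = "G", Y = "T", S = "G", W = "T", K = "T", M = "C",
               N = NA, `-` = NA, B = NA, D = NA, H = NA, V = NA)

# unordered base pair -> consensus character ("AG" -> "R", "AA" -> "A")
.IUPAC_PAIR <- c(AA = "A", CC = "C", GG = "G", TT = "T",
                 AC = "M", AG = "R", AT = "W",
                 CG = "S", CT = "Y", GT = "K")

#' Encode a pair of haploid alleles as an IUPAC consensus character
#'
#' @param a1,a2 character vectors of bases in `A`, `C`, `G`, `T`; `NA`
#'   propagates to `N`.
#' @return character vector of consensus characters.
#' @keywords internal
iupac_from_pair <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  out <- unname(.IUPAC_PAIR[paste0(lo, hi)])
  out[is.na(a1) | is.na(a2)] <- "N"
  out
}

# character matrix (samples x positions) -> two integer allele-code matrices
# (1..4 index into .BASES, NA = missing)
.allele_codes <- function(mat) {
  a1 <- .IUPAC_A1[mat]
  a2 <- .IUPAC_A2[mat]
  c1 <- match(a1, .BASES)
  c2 <- match(a2, .BASES)
  dim(c1) <- dim(mat)
  dim(c2) <- dim(mat)
  dimnames(c1) <- dimnames(mat)
  dimnames(c2) <- dimnames(mat)
  list(c1 = c1, c2 = c2)
}

# per-column allele counts: 4 x ncol matrix of counts of A,C,G,T among the
# 2 * n_called alleles in each column
.column_allele_counts <- function(codes) {
  nc <- ncol(codes$c1)
  out <- matrix(0L, nrow = 4L, ncol = nc)
  for (b in 1:4) {
    out[b, ] <- colSums(codes$c1 == b, na.rm = TRUE) +
      colSums(codes$c2 == b, na.rm = TRUE)
  }
  out
}

# TRUE for columns where > max_samples samples carry a heterozygous code
.column_het_counts <- function(codes) {
  het <- codes$c1 != codes$c2
  colSums(het, na.rm = TRUE)
}
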