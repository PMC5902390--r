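# Grantham physicochemical distance (Grantham, Science 185:862-864, 1974).
#
# D(i,j) = rho * sqrt(alpha*(c_i-c_j)^2 + beta*(p_i-p_j)^2 + gamma*(v_i-v_j)^2)
# with c = composition (atomic weight ratio of hetero elements), p = polarity,
# v = molecular volume; rho scales the mean over the 190 unordered pairs to 100.

GRANTHAM_PROPERTIES <- data.frame(
  aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
         "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c  = c(1.42, 0.65, 0.00, 0.39, 0.71, 0.00, 0.00, 0.74, 0.00, 0.00,
         0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0.00, 0.13),
  p  = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
         6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v  = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
         136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE
)

GRANTHAM_WEIGHTS <- c(alpha = 1.833, beta = 0.1018, gamma = 0.000399)

.grantham_raw <- function(i, j) {
  w <- GRANTHAM_WEIGHTS
  p <- GRANTHAM_PROPERTIES
  sqrt(w[["alpha"]] * (p$c[i] - p$c[j])^2 +
       w[["beta"]]  * (p$p[i] - p$p[j])^2 +
       w[["gamma"]] * (p$v[i] - p$v[j])^2)
}

# rho fixed by the normalisation: mean over all 190 unordered pairs = 100.
.grantham_rho <- local({
  idx <- utils::combn(20L, 2L)
  100 / mean(.grantham_raw(idx[1, ], idx[2, ]))
})

# round half away from zero, the convention of the published integer matrix
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Grantham distance between two amino acids
#'
#' Physicochemical distance combining side-chain composition, polarity and
#' molecular volume. Large values (e.g. Asp/Ala = 126) flag radical
#' substitutions; small values (Leu/Ile = 5) conservative ones. The score is
#' symmetric, zero on identity, and reported as an integer as in the
#' published matrix.
#'
#' @param aa1,aa2 amino acids in one- or three-letter code.
#' @return integer Grantham score.
#' @examples
#' grantham("Asp", "Ala")  # 126
#' grantham("I", "T")      # 89
#' @export
grantham <- function(aa1, aa2) {
  i <- match(aa_one(aa1), GRANTHAM_PROPERTIES$aa)
  j <- match(aa_one(aa2), GRANTHAM_PROPERTIES$aa)
  as.integer(round_half_away(.grantham_rho * .grantham_raw(i, j)))
}

#' Full 20 x 20 Grantham distance matrix
#'
#' @param codes `"one"` (default) or `"three"` letter dimnames.
#' @return symmetric integer matrix with zero diagonal.
#' @export
grantham_matrix <- function(codes = c("one", "three")) {
  codes <- match.arg(codes)
  aas <- sort(GRANTHAM_PROPERTIES$aa)
  m <- outer(aas, aas, function(a, b) {
    mapply(grantham, a, b)
  })
  storage.mode(m) <- "integer"
  lab <- if (codes == "three") aa_three(aas) else aas
  dimnames(m) <- list(lab, lab)
  m
}
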