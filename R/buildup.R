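#' Geometric-progression (GP) buildup factor
#'
#' Evaluates the five-parameter GP fitting function for a point-isotropic
#' buildup factor at optical depth `x` (mean free paths):
#' \deqn{B(x) = 1 + (b-1)\frac{K^x - 1}{K - 1}, \qquad K \ne 1}
#' \deqn{B(x) = 1 + (b-1)\,x, \qquad K = 1}
#' with
#' \deqn{K(x) = c\,x^a + d\,\frac{\tanh(x/x_K - 2) - \tanh(-2)}{1 - \tanh(-2)}.}
#' The linear branch is taken when `|K - 1| < 1e-9`.
#'
#' @param coeffs list with components `b`, `c`, `a`, `xK`, `d`
#'   (e.g. from [lookup_gp()]).
#' @param x optical depth in mean free paths, `x >= 0` (vectorized).
#' @return buildup factor(s), always `>= 1`; `B(0) = 1`.
#' @export
gp_buildup <- function(coeffs, x) {
  if (any(x < 0)) stop("optical depth x must be non-negative")
  b <- coeffs$b; cc <- coeffs$c; a <- coeffs$a; xK <- coeffs$xK; d <- coeffs$d
  B <- numeric(length(x))
  pos <- x > 0
  B[!pos] <- 1
  if (any(pos)) {
    xp <- x[pos]
    t2 <- tanh(-2)
    K <- cc * xp^a + d * (tanh(xp / xK - 2) - t2) / (1 - t2)
    lin <- abs(K - 1) < 1e-9
    Bv <- numeric(length(xp))
    Bv[lin] <- 1 + (b - 1) * xp[lin]
    Bv[!lin] <- 1 + (b - 1) * (K[!lin]^xp[!lin] - 1) / (K[!lin] - 1)
    B[pos] <- Bv
  }
  pmax(B, 1)
}

#' Two-region effective buildup factor (Kalos rule)
#'
#' Composes the buildup of two stacked material layers, numbered from the
#' source toward the detector, into a single effective factor. With
#' \eqn{B_1, B_2} the single-material GP buildup factors and effective
#' atomic numbers \eqn{Z_1 > Z_2} (high-Z layer first, e.g. a steel capsule
#' in water):
#' \deqn{B = B_2(l_2) + \frac{B_1(l_1)-1}{B_2(l_1)-1}\left[B_2(l_1+l_2) - B_2(l_2)\right]}
#' and for \eqn{Z_2 > Z_1}:
#' \deqn{B = B_2(l_2) + \left[B_2(l_1+l_2) - B_2(l_2)\right]
#'   \left\{\frac{B_1(l_1)-1}{B_2(l_1)-1} e^{-1.7 l_2}
#'   + \frac{(\mu_C/\mu)_1}{(\mu_C/\mu)_2}\left(1 - e^{-l_2}\right)\right\}.}
#' Equal effective Z collapses to the single-material GP factor at
#' \eqn{l_1 + l_2}. For `l1 < 1e-6` mfp the indeterminate ratio is bypassed
#' and the water-side factor `B2(l2)` is returned (the correct limit).
#'
#' @param mat1,mat2 [material()] objects for the source-side and
#'   detector-side layers; both must carry GP data at `E`.
#' @param l1,l2 optical thicknesses in mean free paths, `>= 0`.
#' @param E photon energy in MeV.
#' @return effective buildup factor, `>= 1`.
#' @export
kalos_two_region <- function(mat1, l1, mat2, l2, E) {
  if (l1 < 0 || l2 < 0) stop("optical thicknesses must be non-negative")
  g2 <- lookup_gp(mat2, E)
  if (l1 < 1e-6) return(gp_buildup(g2, l2))
  if (identical(mat1$name, mat2$name) || mat1$effective_Z == mat2$effective_Z)
    return(gp_buildup(g2, l1 + l2))
  g1 <- lookup_gp(mat1, E)
  if (l2 < 1e-12) return(gp_buildup(g1, l1))
  B1l1 <- gp_buildup(g1, l1)
  B2l1 <- gp_buildup(g2, l1)
  B2l2 <- gp_buildup(g2, l2)
  B2tot <- gp_buildup(g2, l1 + l2)
  ratio <- (B1l1 - 1) / (B2l1 - 1)
  if (mat1$effective_Z > mat2$effective_Z) {
    B <- B2l2 + ratio * (B2tot - B2l2)
  } else {
    cf1 <- lookup_compton_fraction(mat1, E)
    cf2 <- lookup_compton_fraction(mat2, E)
    B <- B2l2 + (B2tot - B2l2) *
      (ratio * exp(-1.7 * l2) + (cf1 / cf2) * (1 - exp(-l2)))
  }
  max(B, 1)
}

#' Effective buildup factor along a multi-layer ray path
#'
#' Layers thinner than 1e-4 mfp (e.g. millimetre air channels) are dropped,
#' adjacent same-material segments are merged, then: a single remaining layer
#' uses the GP factor directly; two layers use the Kalos two-region rule;
#' more than two layers are collapsed by a left fold from the source side,
#' replacing the two segments nearest the source by a pseudo-layer of the
#' second segment's material with the combined optical thickness (a
#' documented approximation). An empty path gives 1.
#'
#' @param path a `layer_path` from [trace_ray()] with optical thicknesses
#'   attached, or any data.frame-like with columns `material`
#'   (list of [material()]) and `optical` (mfp).
#' @param E photon energy in MeV.
#' @return effective buildup factor, `>= 1`.
#' @export
effective_buildup <- function(path, E) {
  mats <- path$material
  l <- path$optical
  keep <- l >= 1e-4
  mats <- mats[keep]; l <- l[keep]
  n <- length(l)
  if (n == 0L) return(1)
  # merge adjacent same-material segments
  if (n > 1L) {
    nm <- vapply(mats, function(m) m$name, "")
    grp <- cumsum(c(TRUE, nm[-1] != nm[-n]))
    l <- as.numeric(tapply(l, grp, sum))
    mats <- mats[!duplicated(grp)]
    n <- length(l)
  }
  if (n == 1L) return(gp_buildup(lookup_gp(mats[[1]], E), l))
  while (n > 2L) {
    l <- c(l[1] + l[2], l[-(1:2)])
    mats <- mats[-1]
    n <- n - 1L
  }
  kalos_two_region(mats[[1]], l[1], mats[[2]], l[2], E)
}
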