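#' Kors ECG-to-VCG regression matrix
#'
#' Returns the published Kors regression coefficients mapping the eight
#' independent leads of the standard 12-lead ECG (I, II, V1-V6) to the three
#' orthogonal vectorcardiogram components. Row order is (x, y, z) with x the
#' anterior-posterior axis, z the long axis of the body, and the xy-plane the
#' transverse plane.
#'
#' Coefficients from Kors et al., Eur Heart J 11:1083-1092 (1990),
#' regression method (the matrix is embedded as constants because no
#' standard R package exports it).
#'
#' @return A `lead_transform` object: a 3 x 8 numeric matrix with dimnames
#'   `c("x","y","z")` by `c("I","II","V1".."V6")` and a `name` attribute.
#' @export
#' @examples
#' kors_matrix()
kors_matrix <- function() {
  m <- rbind(
    x = c(I = 0.38, II = -0.07, V1 = -0.13, V2 = 0.05, V3 = -0.01,
          V4 = 0.14, V5 = 0.06, V6 = 0.54),
    y = c(I = -0.07, II = 0.93, V1 = 0.06, V2 = -0.02, V3 = -0.05,
          V4 = 0.06, V5 = -0.17, V6 = 0.13),
    z = c(I = 0.11, II = -0.23, V1 = -0.43, V2 = -0.06, V3 = -0.14,
          V4 = -0.20, V5 = -0.11, V6 = 0.31))
  lead_transform(m, name = "kors")
}

#' Construct a lead transform
#'
#' A lead transform maps the 8 independent ECG leads (I, II, V1-V6) to the
#' three VCG components by left-multiplication.
#'
#' @param matrix 3 x 8 numeric matrix with finite entries.
#' @param name Label for the transform.
#' @return A `lead_transform` object.
#' @export
lead_transform <- function(matrix, name = "custom") {
  matrix <- as.matrix(matrix)
  if (!identical(dim(matrix), c(3L, 8L))) {
    stop("lead transform must be a 3 x 8 matrix", call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    stop("lead transform entries must be finite", call. = FALSE)
  }
  rownames(matrix) <- c("x", "y", "z")
  colnames(matrix) <- independent_leads()
  structure(matrix, name = name, class = c("lead_transform", "matrix", "array"))
}

#' Lead-field matrix: the Moore-Penrose pseudo-inverse of the Kors matrix
#'
#' The forward model projects the net cardiac dipole onto the 8 independent
#' leads with the pseudo-inverse of the Kors matrix, so that the Kors
#' transform applied to a simulated ECG recovers the source dipole exactly
#' (the Kors matrix has full row rank, hence K %*% pinv(K) = I3).
#'
#' @param transform A `lead_transform`; defaults to [kors_matrix()].
#' @return An 8 x 3 numeric matrix mapping a dipole (x,y,z) to the leads
#'   I, II, V1-V6.
#' @export
lead_field_matrix <- function(transform = kors_matrix()) {
  lf <- MASS::ginv(unclass(transform))
  dimnames(lf) <- list(independent_leads(), c("x", "y", "z"))
  lf
}

independent_leads <- function() c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

`%||%` <- function(a, b) if (is.null(a)) b else a

all_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", "V1", "V2", "V3", "V4", "V5", "V6")
}
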