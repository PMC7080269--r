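#' Modified Beer-Lambert law conversion matrix
#'
#' The fixed 2x3 matrix mapping optical-density changes at 780, 805 and
#' 830 nm to concentration changes of deoxy- and oxy-hemoglobin
#' (rows: dHbR, dHbO; units mM*cm).
#'
#' @return A 2x3 numeric matrix with dimnames.
#' @export
#' @examples
#' mbll_matrix() %*% c(1, 0, 0)
mbll_matrix <- function() {
  matrix(c(1.8545, -0.2394, -1.0947,
           -1.4887, 0.5970, 1.4847),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("HbR", "HbO"), c("OD780", "OD805", "OD830")))
}

# Moore-Penrose right inverse of the conversion matrix: the forward map used
# by the generator to synthesize optical densities from planted hemoglobin
# trajectories, so that od_to_hemoglobin() recovers them exactly.
mbll_forward_matrix <- function() {
  m <- mbll_matrix()
  a <- t(m) %*% solve(m %*% t(m))
  dimnames(a) <- list(c("OD780", "OD805", "OD830"), c("HbR", "HbO"))
  a
}

#' Convert optical densities to hemoglobin concentration changes
#'
#' Applies the modified Beer-Lambert law pointwise: each triplet of
#' optical-density changes at (780, 805, 830) nm is mapped through the fixed
#' 2x3 conversion matrix to (dHbR, dHbO) in mM*cm.
#'
#' @param od780,od805,od830 Numeric vectors or channels-by-samples matrices of
#'   optical-density changes, co-sampled and of equal dimension.
#' @return A list with elements `hbr` and `hbo` of the same shape as the
#'   inputs.
#' @export
#' @examples
#' od_to_hemoglobin(1, 0, 0)   # first column of the conversion matrix
od_to_hemoglobin <- function(od780, od805, od830) {
  if (!all(dim2(od780) == dim2(od805)) || !all(dim2(od780) == dim2(od830)))
    stop("the three optical-density series must have identical dimensions")
  m <- mbll_matrix()
  list(hbr = m[1, 1] * od780 + m[1, 2] * od805 + m[1, 3] * od830,
       hbo = m[2, 1] * od780 + m[2, 2] * od805 + m[2, 3] * od830)
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)
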