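#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between the interiors of two level-set
#' fields (or two logical masks).
#'
#' @param a,b `level_set`s on one grid, or logical arrays.
#' @return scalar in \[0, 1\] (1 when both are empty).
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (is.logical(a)) a else interior_mask(a)
  mb <- if (is.logical(b)) b else interior_mask(b)
  s <- sum(ma) + sum(mb)
  if (s == 0) return(1)
  2 * sum(ma & mb) / s
}

#' Interface cells of a level-set field
#'
#' Cells whose sign differs from at least one axis neighbor — a discrete
#' covering of the zero level set, also used as the "boundary voxel" count
#' when scoring interaction effort.
#'
#' @param phi a `level_set` (or logical mask).
#' @param interior_only count only the interior-side cells. Default FALSE
#'   (both sides).
#' @return integer vector of cell indices.
#' @export
interface_cells <- function(phi, interior_only = FALSE) {
  m <- if (is.logical(phi)) phi else interior_mask(phi)
  edge <- array(FALSE, dim(m))
  for (a in seq_along(dim(m))) {
    edge <- edge | (m != axshift(m, a, 1L)) | (m != axshift(m, a, -1L))
  }
  if (interior_only) edge <- edge & m
  which(edge)
}

#' Symmetric Hausdorff distance between two zero level sets
#'
#' Brute-force maximum over each interface cell of the distance to the
#' nearest interface cell of the other field, in physical units.
#'
#' @param a,b `level_set`s on one grid.
#' @return scalar distance (Inf when either interface is empty).
#' @export
hausdorff_interface <- function(a, b) {
  check_same_grid(a, b)
  ia <- interface_cells(a)
  ib <- interface_cells(b)
  if (length(ia) == 0L || length(ib) == 0L) return(Inf)
  pa <- sweep(arrayInd(ia, dim(a$values)), 2, a$grid$spacing, `*`)
  pb <- sweep(arrayInd(ib, dim(b$values)), 2, b$grid$spacing, `*`)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}
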