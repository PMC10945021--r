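#' Euclidean projection onto the l1 ball
#'
#' Exact sort-based projection of a vector onto `{u : sum(|u|) <= radius}`
#' (the algorithm of Duchi et al.: sort the magnitudes, find the largest
#' feasible support, soft-threshold). Returns `v` unchanged when it is
#' already inside the ball.
#'
#' @param v Numeric vector with finite entries.
#' @param radius Positive scalar, the l1 radius.
#' @return Numeric vector of the same length, the closest point (in the
#'   Euclidean sense) of the l1 ball to `v`.
#' @examples
#' project_l1_ball(c(3, 0), 1)       # c(1, 0)
#' project_l1_ball(c(1, 1), 1)       # c(0.5, 0.5)
#' project_l1_ball(c(0.2, -0.1), 1)  # unchanged, already inside
#' @export
project_l1_ball <- function(v, radius) {
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stopf("project_l1_ball: input must be finite numeric")
  }
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stopf("project_l1_ball: radius must be a positive finite scalar")
  }
  .project_l1_ball_cpp(as.numeric(v), radius)
}

#' Bilevel projection onto the l1,1 ball of a weight matrix
#'
#' Enforces the structured-sparsity constraint `sum_i ||W[i, ]||_1 <= eta`
#' in two stages: (1) the vector of per-row l1 norms is projected onto the
#' l1 ball of radius `eta`, allocating a budget to each feature row; (2)
#' each row is projected onto the l1 ball of its allocated budget. Rows
#' whose budget is zero become exactly zero, which removes the corresponding
#' input gene from the network (feature deselection).
#'
#' Rows of `W` index input features (genes); this operator is intended for
#' the first encoder layer, whose rows are the fan-out weights of each gene.
#'
#' Note the bilevel operator is not in general the exact Euclidean
#' projection onto the l1,1 ball (which, since the l1,1 norm of a matrix is
#' the l1 norm of its vectorization, is plain entrywise soft-thresholding):
#' the two coincide whenever they keep the same rows alive, but the bilevel
#' allocation can zero a row that the exact projection would retain. The
#' bilevel form is preferred precisely because it deselects whole rows.
#'
#' @param W Numeric matrix, features in rows.
#' @param eta Positive scalar constraint radius; smaller values force
#'   stronger sparsity.
#' @return Matrix of the same shape with `sum(abs(.)) <= eta` and zeroed-out
#'   deselected rows.
#' @examples
#' project_l11_bilevel(rbind(c(2, 0), c(0, 2)), 2)  # rows halved
#' @export
project_l11_bilevel <- function(W, eta) {
  if (!is.matrix(W) || !is.numeric(W) || anyNA(W) || any(!is.finite(W))) {
    stopf("project_l11_bilevel: W must be a finite numeric matrix")
  }
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0) {
    stopf("project_l11_bilevel: eta must be a positive finite scalar")
  }
  out <- .project_l11_bilevel_cpp(W, eta)
  dimnames(out) <- dimnames(W)
  out
}

#' Fraction of input features kept by a sparse first layer
#'
#' @param W First encoder layer weight matrix (genes in rows).
#' @param tol Row l1 norms at or below `tol` count as deselected.
#' @return Fraction in `[0, 1]` of rows with nonzero l1 norm.
#' @export
selected_feature_fraction <- function(W, tol = 1e-12) {
  if (!is.matrix(W)) stopf("selected_feature_fraction: W must be a matrix")
  mean(rowSums(abs(W)) > tol)
}

## Support (selected-feature) indicator of the first layer.
feature_support <- function(W, tol = 1e-12) {
  rowSums(abs(W)) > tol
}
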