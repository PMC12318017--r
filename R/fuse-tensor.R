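#' Tensor fusion by mode-n products
#'
#' Applies projection matrices along each mode of a 3-way feature array
#' (athletes x modalities x time-windows): `T = X x1 W1 x2 W2 x3 W3`.
#' Identity projections return the input; products along distinct modes
#' commute.
#'
#' @param X numeric 3-dimensional array.
#' @param W1,W2,W3 projection matrices; `ncol(Wk)` must equal `dim(X)[k]`.
#'   `NULL` leaves a mode untouched.
#' @return list of class `tf_tensor`: `tensor` (the projected array),
#'   `dims_in`, `dims_out`.
#' @export
tensor_fuse <- function(X, W1 = NULL, W2 = NULL, W3 = NULL) {
  if (length(dim(X)) != 3) {
    tf_validation_error("X must be a 3-mode array", "X")
  }
  Ws <- list(W1, W2, W3)
  out <- X
  for (mode in 1:3) {
    W <- Ws[[mode]]
    if (is.null(W)) next
    if (ncol(W) != dim(out)[mode]) {
      tf_validation_error(sprintf(
        "mode-%d dimension mismatch: ncol(W%d) = %d but dim(X)[%d] = %d",
        mode, mode, ncol(W), mode, dim(out)[mode]), paste0("W", mode))
    }
    out <- mode_n_product(out, W, mode)
  }
  structure(list(tensor = out, dims_in = dim(X), dims_out = dim(out)),
            class = "tf_tensor")
}

mode_n_product <- function(X, W, mode) {
  d <- dim(X)
  perm <- c(mode, setdiff(1:3, mode))
  Xm <- matrix(aperm(X, perm), nrow = d[mode])     # mode-n unfolding
  Ym <- W %*% Xm
  d_out <- d
  d_out[mode] <- nrow(W)
  aperm(array(Ym, d_out[perm]), order(perm))
}
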