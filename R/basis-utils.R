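# Internal B-spline / penalty primitives shared by the hazard fitter and the
# cumulative-effect designs. P-splines: equally spaced knots, cubic B-splines,
# difference penalty (Eilers & Marx style).

# Knot vector for k cubic B-spline basis functions on [xlim[1], xlim[2]].
ps_knots <- function(xlim, k, degree = 3) {
  stopifnot(k > degree, diff(xlim) > 0)
  nseg <- k - degree
  h <- diff(xlim) / nseg
  seq(xlim[1] - degree * h, xlim[2] + degree * h, length.out = nseg + 2 * degree + 1)
}

# Evaluate the k basis functions at x; rows sum to 1 inside the data range.
ps_eval <- function(x, knots, degree = 3) {
  x <- pmin(pmax(x, knots[degree + 1]), knots[length(knots) - degree])
  splines::splineDesign(knots, x, ord = degree + 1)
}

# Difference penalty matrix D'D of the given order for k coefficients.
diff_penalty <- function(k, order = 2) {
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

# Sum-to-zero reparameterization: given the constraint row vector C (usually
# column means of the basis over the fit data), return Z with C %*% Z = 0 so
# the smooth is identifiable next to an intercept.
constraint_null <- function(C) {
  qr.Q(qr(matrix(C, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}

# Moore-Penrose pseudo-inverse via eigen decomposition (symmetric psd input).
sym_pinv <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0) & e$values > 0
  if (!any(pos)) return(S * 0)
  V <- e$vectors[, pos, drop = FALSE]
  V %*% (t(V) / e$values[pos])
}
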