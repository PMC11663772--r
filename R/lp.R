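# Dense two-phase primal simplex for the small linear programs arising in
# the successive linearization of the concave feature-selection program.
# Bland's anti-cycling rule makes every solve deterministic and finite.
# Problems are ~10^2 variables/constraints, so a tableau implementation is
# adequate and has no external dependencies.

# Solve: min cost'x  s.t.  A x <= b, x >= 0.
# Returns list(x, fval, status) with status "optimal", "infeasible",
# "unbounded" or "maxiter".
lp_solve <- function(cost, A, b, tol = 1e-9, max_pivots = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cost) == n, length(b) == m)
  sgn <- ifelse(b < 0, -1, 1)
  A1 <- A * sgn
  b1 <- b * sgn
  S <- diag(sgn, m) # slack block after row scaling
  art_rows <- which(sgn < 0)
  n_art <- length(art_rows)
  Aart <- matrix(0, m, n_art)
  if (n_art) Aart[cbind(art_rows, seq_len(n_art))] <- 1
  Tab <- cbind(A1, S, Aart)
  rhs <- b1
  basis <- integer(m)
  basis[sgn > 0] <- n + which(sgn > 0)
  basis[art_rows] <- n + m + seq_len(n_art)
  nv <- ncol(Tab)

  pivot <- function(lv, e) {
    p <- Tab[lv, ]
    pr <- rhs[lv] / p[e]
    p <- p / p[e]
    f <- Tab[, e]
    Tab <<- Tab - outer(f, p)
    rhs <<- rhs - f * pr
    Tab[lv, ] <<- p
    rhs[lv] <<- pr
    basis[lv] <<- e
  }

  run_phase <- function(cvec, allowed, budget) {
    pivots <- 0L
    repeat {
      r <- cvec - as.vector(crossprod(cvec[basis], Tab))
      enter <- which(r < -tol & allowed)
      if (!length(enter)) return("optimal")
      e <- min(enter) # Bland
      col <- Tab[, e]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratios <- rhs[pos] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      lv <- cand[which.min(basis[cand])] # Bland on ties
      pivot(lv, e)
      pivots <- pivots + 1L
      if (pivots > budget) return("maxiter")
    }
  }

  allowed <- rep(TRUE, nv)
  if (n_art) {
    c1 <- c(rep(0, n + m), rep(1, n_art))
    st <- run_phase(c1, allowed, max_pivots)
    if (st != "optimal") return(list(x = NULL, fval = NA_real_, status = st))
    if (sum(rhs[basis > n + m]) > 1e-7)
      return(list(x = NULL, fval = NA_real_, status = "infeasible"))
    # drive remaining zero-level artificials out of the basis where possible
    for (i in which(basis > n + m)) {
      cols <- which(abs(Tab[i, seq_len(n + m)]) > tol)
      if (length(cols)) pivot(i, min(cols))
    }
    allowed[(n + m + 1):nv] <- FALSE
  }
  c2 <- c(cost, rep(0, nv - n))
  st <- run_phase(c2, allowed, max_pivots)
  if (st != "optimal") return(list(x = NULL, fval = NA_real_, status = st))
  x <- numeric(nv)
  x[basis] <- rhs
  x <- x[seq_len(n)]
  list(x = x, fval = sum(cost * x), status = "optimal")
}
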