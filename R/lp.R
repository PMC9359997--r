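# Dense two-phase primal simplex for the small linear programs FBA needs:
#   maximize c'x  subject to  A x = b,  0 <= x <= u.
# Full tableau with Bland's anti-cycling rule: slow but guaranteed to
# terminate, and robust on the degenerate desk-scale problems this package
# solves (no general-purpose LP package is available to it).

lp_max <- function(cc, A, b, u, tol = 1e-9, max_iter = 100000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(u) == n, all(u >= -tol))
  u <- pmax(u, 0)
  neg <- b < 0
  A[neg, ] <- -A[neg, ]
  b[neg] <- -b[neg]

  # tableau variables: x (1..n), bound slacks s (n+1..2n),
  # artificials for the equality rows (2n+1..2n+m)
  N <- 2L * n + m
  tab <- matrix(0, m + n, N + 1L)
  tab[seq_len(m), seq_len(n)] <- A
  tab[seq_len(m), 2L * n + seq_len(m)] <- diag(m)
  tab[seq_len(m), N + 1L] <- b
  tab[m + seq_len(n), seq_len(n)] <- diag(n)
  tab[m + seq_len(n), n + seq_len(n)] <- diag(n)
  tab[m + seq_len(n), N + 1L] <- u
  basis <- c(2L * n + seq_len(m), n + seq_len(n))
  active <- rep(TRUE, m + n)  # rows dropped when found redundant

  pivot <- function(i, j) {
    tab[i, ] <<- tab[i, ] / tab[i, j]
    piv_row <- tab[i, ]
    for (k in which(active)) if (k != i && abs(tab[k, j]) > 0)
      tab[k, ] <<- tab[k, ] - tab[k, j] * piv_row
    basis[i] <<- j
  }

  do_phase <- function(obj, allowed) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      act <- which(active)
      cb <- obj[basis[act]]
      red <- obj - as.vector(cb %*% tab[act, seq_len(N), drop = FALSE])
      red[basis[act]] <- 0
      red[!allowed] <- -Inf
      enter <- which(red > tol)
      if (!length(enter)) return("optimal")
      j <- min(enter)                      # Bland: smallest entering index
      col <- tab[act, j]
      ok <- col > tol
      if (!any(ok)) return("unbounded")
      ratios <- tab[act, N + 1L][ok] / col[ok]
      rmin <- min(ratios)
      cand <- which(ok)[abs(ratios - rmin) <= tol * max(1, abs(rmin))]
      i <- act[cand[which.min(basis[act][cand])]]  # Bland: smallest leaving
      pivot(i, j)
    }
  }

  # phase 1: drive the artificials to zero
  st <- do_phase(c(rep(0, 2L * n), rep(-1, m)), rep(TRUE, N))
  if (st == "unbounded") stop("phase-1 LP unbounded (internal error)")
  act <- which(active)
  infeas <- sum(tab[act[basis[act] > 2L * n], N + 1L])
  if (infeas > 1e-7) return(list(status = "infeasible"))

  # pivot out degenerate basic artificials, or drop redundant rows
  for (i in act[basis[act] > 2L * n]) {
    j <- which(abs(tab[i, seq_len(2L * n)]) > tol)
    if (length(j)) pivot(i, min(j)) else active[i] <- FALSE
  }

  # phase 2: the real objective; artificials may not re-enter
  st <- do_phase(c(cc, rep(0, n + m)), c(rep(TRUE, 2L * n), rep(FALSE, m)))
  if (st == "unbounded") return(list(status = "unbounded"))

  x <- numeric(N)
  act <- which(active)
  x[basis[act]] <- tab[act, N + 1L]
  list(status = "optimal", x = x[seq_len(n)], value = sum(cc * x[seq_len(n)]))
}
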