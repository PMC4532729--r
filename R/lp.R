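# Small dense two-phase simplex.  The systems in this package are tiny
# (tens of columns), so a textbook tableau with Bland's rule is entirely
# adequate and keeps the package free of external solver dependencies.

# minimize (or maximize) obj'x  s.t.  Aeq x = beq, Age x >= bge, lo <= x <= hi
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Age = NULL, bge = NULL,
                     lo, hi, maximize = FALSE, tol = 1e-9) {
  m <- length(lo)
  stopifnot(length(hi) == m, all(is.finite(lo)), all(is.finite(hi)),
            all(hi >= lo - tol), length(obj) == m)
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, m); beq <- numeric(0) }
  if (is.null(Age)) { Age <- matrix(0, 0, m); bge <- numeric(0) }
  ne <- nrow(Aeq); ng <- nrow(Age)
  u <- hi - lo
  # columns: y (m) | surplus s (ng) | upper-bound slack t (m)
  nc <- m + ng + m
  A <- matrix(0, ne + ng + m, nc)
  b <- numeric(ne + ng + m)
  if (ne) { A[seq_len(ne), seq_len(m)] <- Aeq; b[seq_len(ne)] <- beq - Aeq %*% lo }
  if (ng) {
    A[ne + seq_len(ng), seq_len(m)] <- Age
    A[cbind(ne + seq_len(ng), m + seq_len(ng))] <- -1
    b[ne + seq_len(ng)] <- bge - Age %*% lo
  }
  A[cbind(ne + ng + seq_len(m), seq_len(m))] <- 1
  A[cbind(ne + ng + seq_len(m), m + ng + seq_len(m))] <- 1
  b[ne + ng + seq_len(m)] <- u
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  nr <- nrow(A)
  # artificials for eq/ge rows; bound rows start with t basic unless flipped
  art_rows <- c(seq_len(ne + ng), (ne + ng + seq_len(m))[flip[ne + ng + seq_len(m)]])
  n_art <- length(art_rows)
  tab <- cbind(A, matrix(0, nr, n_art), b)
  basis <- integer(nr)
  for (i in seq_len(m)) if (!flip[ne + ng + i]) basis[ne + ng + i] <- m + ng + i
  for (k in seq_along(art_rows)) { tab[art_rows[k], nc + k] <- 1; basis[art_rows[k]] <- nc + k }
  ncol_tot <- nc + n_art

  pivot <- function(tab, pr, pc) {
    tab[pr, ] <- tab[pr, ] / tab[pr, pc]
    for (i in seq_len(nrow(tab))) if (i != pr && abs(tab[i, pc]) > 0)
      tab[i, ] <- tab[i, ] - tab[i, pc] * tab[pr, ]
    tab
  }
  run <- function(tab, basis, cost, allowed) {
    repeat {
      cb <- cost[basis]
      rc <- cost - as.vector(cb %*% tab[, seq_len(ncol_tot), drop = FALSE])
      cand <- which(rc < -tol & allowed)
      if (!length(cand)) return(list(tab = tab, basis = basis, status = "optimal"))
      pc <- cand[1]                                   # Bland
      pos <- which(tab[, pc] > tol)
      if (!length(pos)) return(list(tab = tab, basis = basis, status = "unbounded"))
      ratio <- tab[pos, ncol_tot + 1] / tab[pos, pc]
      pr <- pos[ratio == min(ratio)]
      pr <- pr[which.min(basis[pr])]                  # Bland tie-break
      tab <- pivot(tab, pr, pc)
      basis[pr] <- pc
    }
  }
  allowed <- rep(TRUE, ncol_tot)
  if (n_art) {
    cost1 <- c(rep(0, nc), rep(1, n_art))
    r <- run(tab, basis, cost1, allowed)
    tab <- r$tab; basis <- r$basis
    val1 <- sum(cost1[basis] * tab[, ncol_tot + 1])
    if (val1 > 1e-7) return(list(status = "infeasible", x = NULL, value = NA))
    # pivot out any basic artificials (rows may be redundant)
    for (i in which(basis > nc)) {
      j <- which(abs(tab[i, seq_len(nc)]) > tol)[1]
      if (!is.na(j)) { tab <- pivot(tab, i, j); basis[i] <- j }
    }
    allowed[nc + seq_len(n_art)] <- FALSE
  }
  cost2 <- c(if (maximize) -obj else obj, rep(0, ng + m), rep(0, n_art))
  r <- run(tab, basis, cost2, allowed)
  if (r$status != "optimal") return(list(status = r$status, x = NULL, value = NA))
  tab <- r$tab; basis <- r$basis
  y <- numeric(nc)
  y[basis[basis <= nc]] <- tab[basis <= nc, ncol_tot + 1]
  x <- y[seq_len(m)] + lo
  list(status = "optimal", x = x,
       value = sum(obj * x))
}
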