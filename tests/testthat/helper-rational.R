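# Exact rational Gaussian elimination, used as an independent oracle for
# vertex enumeration on small load systems.  Rationals are (num, den) pairs
# held in doubles; all inputs here are 0/1 matrices and small-denominator
# right-hand sides, so magnitudes stay far below 2^53.

rgcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  if (a == 0) 1 else a
}

rsimp <- function(n, d) {
  if (d < 0) { n <- -n; d <- -d }
  g <- rgcd(n, d)
  c(n / g, d / g)
}

radd <- function(x, y) rsimp(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
rsub <- function(x, y) radd(x, c(-y[1], y[2]))
rmul <- function(x, y) rsimp(x[1] * y[1], x[2] * y[2])
rdiv <- function(x, y) { stopifnot(y[1] != 0); rsimp(x[1] * y[2], x[2] * y[1]) }

# Solve A x = b exactly.  A: integer matrix (rows >= cols allowed); b: list of
# rationals.  Returns list of rationals, NULL if inconsistent, NA if rank
# deficient in the unknowns.
rat_solve <- function(A, b) {
  nr <- nrow(A); nc <- ncol(A)
  M <- lapply(seq_len(nr), function(i)
    c(lapply(A[i, ], function(v) c(v, 1)), list(b[[i]])))
  piv_cols <- integer(0); piv_rows <- integer(0)
  row <- 1
  for (col in seq_len(nc)) {
    pr <- NA
    for (i in row:nr) if (M[[i]][[col]][1] != 0) { pr <- i; break }
    if (is.na(pr)) next
    tmp <- M[[row]]; M[[row]] <- M[[pr]]; M[[pr]] <- tmp
    pv <- M[[row]][[col]]
    for (i in seq_len(nr)) {
      if (i == row || M[[i]][[col]][1] == 0) next
      f <- rdiv(M[[i]][[col]], pv)
      for (j in col:(nc + 1))
        M[[i]][[j]] <- rsub(M[[i]][[j]], rmul(f, M[[row]][[j]]))
    }
    piv_cols <- c(piv_cols, col); piv_rows <- c(piv_rows, row)
    row <- row + 1
    if (row > nr) break
  }
  if (length(piv_cols) < nc) return(NA)          # underdetermined
  for (i in seq_len(nr)) {
    if (i %in% piv_rows) next
    if (M[[i]][[nc + 1]][1] != 0) return(NULL)   # inconsistent
  }
  x <- vector("list", nc)
  for (k in seq_along(piv_cols))
    x[[piv_cols[k]]] <- rdiv(M[[piv_rows[k]]][[nc + 1]],
                             M[[piv_rows[k]]][[piv_cols[k]]])
  x
}

# Independent vertex enumeration for {A x = b, 0 <= x <= 1} over rationals.
# b given as num/den integer vectors.
rational_vertices <- function(A, b_num, b_den) {
  m <- ncol(A)
  d <- m - qr(A)$rank
  b <- lapply(seq_along(b_num), function(i) rsimp(b_num[i], b_den[i]))
  verts <- list()
  push <- function(x) {
    xv <- vapply(x, function(r) r[1] / r[2], numeric(1))
    verts[[length(verts) + 1]] <<- xv
  }
  check_push <- function(x) {
    for (r in x) if (r[1] < 0 || r[1] > r[2]) return()
    push(x)
  }
  if (d == 0) {
    x <- rat_solve(A, b)
    if (!is.null(x) && !identical(x, NA)) check_push(x)
  } else {
    subsets <- utils::combn(m, d)
    grid <- as.matrix(expand.grid(rep(list(0:1), d)))
    for (ci in seq_len(ncol(subsets))) {
      S <- subsets[, ci]
      free <- setdiff(seq_len(m), S)
      for (g in seq_len(nrow(grid))) {
        vals <- grid[g, ]
        rhs <- b
        for (i in seq_along(rhs)) {
          pin <- sum(A[i, S] * vals)
          rhs[[i]] <- rsub(rhs[[i]], c(pin, 1))
        }
        xf <- rat_solve(A[, free, drop = FALSE], rhs)
        if (is.null(xf) || identical(xf, NA)) next
        x <- vector("list", m)
        for (k in seq_along(S)) x[[S[k]]] <- c(vals[k], 1)
        for (k in seq_along(free)) x[[free[k]]] <- xf[[k]]
        check_push(x)
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, m))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 12)), , drop = FALSE]
}

# Order vertex rows canonically (after rounding away solver fuzz) so two
# enumerations can be compared as sets.
sort_rows <- function(V, digits = 9) {
  if (!nrow(V)) return(V)
  V <- round(V, digits)
  V[do.call(order, as.data.frame(V)), , drop = FALSE]
}
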