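# Exact rational arithmetic on (numerator, denominator) pairs stored as
# doubles. Networks here are tiny (< 15 species, < 15 reactions) and all
# intermediate integers stay far below 2^53, so doubles are exact.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b == 0, 0, a %% b)
    a <- t
  }
  a
}

# normalize: positive denominator, reduced terms
rat <- function(num, den = rep(1, length(num))) {
  if (any(den == 0)) stop("rational with zero denominator", call. = FALSE)
  s <- sign(den)
  num <- num * s; den <- den * s
  g <- .gcd(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

rat_add <- function(x, y) rat(x$num * y$den + y$num * x$den, x$den * y$den)
rat_sub <- function(x, y) rat(x$num * y$den - y$num * x$den, x$den * y$den)
rat_mul <- function(x, y) rat(x$num * y$num, x$den * y$den)
rat_div <- function(x, y) {
  if (any(y$num == 0)) stop("rational division by zero", call. = FALSE)
  rat(x$num * y$den, x$den * y$num)
}
rat_neg <- function(x) rat(-x$num, x$den)
rat_is_zero <- function(x) x$num == 0
rat_value <- function(x) x$num / x$den

rat_format <- function(x) {
  ifelse(x$den == 1, as.character(x$num), paste0(x$num, "/", x$den))
}

rat_elt <- function(x, i) list(num = x$num[i], den = x$den[i])

rat_replace <- function(x, i, value) {
  x$num[i] <- value$num
  x$den[i] <- value$den
  x
}

# Reduced row echelon form of a rational matrix stored as parallel
# numerator/denominator matrices. Returns pivot columns alongside.
rat_rref <- function(num, den) {
  nr <- nrow(num); nc <- ncol(num)
  pivots <- integer(0)
  r <- 1L
  for (j in seq_len(nc)) {
    if (r > nr) break
    piv <- which(num[r:nr, j] != 0)
    if (length(piv) == 0) next
    i <- r + piv[1] - 1L
    if (i != r) {
      num[c(i, r), ] <- num[c(r, i), ]
      den[c(i, r), ] <- den[c(r, i), ]
    }
    # scale row r so entry (r, j) is 1
    p <- rat(num[r, j], den[r, j])
    row <- rat_div(rat(num[r, ], den[r, ]), p)
    num[r, ] <- row$num; den[r, ] <- row$den
    for (k in seq_len(nr)) {
      if (k == r || num[k, j] == 0) next
      f <- rat(num[k, j], den[k, j])
      upd <- rat_sub(rat(num[k, ], den[k, ]), rat_mul(f, rat(num[r, ], den[r, ])))
      num[k, ] <- upd$num; den[k, ] <- upd$den
    }
    pivots <- c(pivots, j)
    r <- r + 1L
  }
  list(num = num, den = den, pivots = pivots)
}
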