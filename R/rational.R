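#' Exact rational numbers
#'
#' A small vectorized exact-rational class used for every probability the
#' package computes. Offspring and recombination-product distributions are
#' kept as ratios of integers throughout; conversion to double happens only
#' at display or sampling time. Numerators and denominators are stored as
#' doubles but restricted to the exactly-representable integer range
#' (|x| < 2^53); any operation that would leave that range aborts rather
#' than silently losing exactness.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), recycled against `num`.
#' @return A `rational` vector.
#' @examples
#' rational(1, 2) + rational(1, 3)
#' sum(rational(c(1, 1, 1), c(4, 4, 2))) == rational(1)
#' @export
rational <- function(num, den = 1) {
  if (!is.numeric(num) || !is.numeric(den)) {
    stop("num and den must be numeric", call. = FALSE)
  }
  n <- max(length(num), length(den))
  num <- rep_len(as.numeric(num), n)
  den <- rep_len(as.numeric(den), n)
  if (any(den == 0)) stop("zero denominator", call. = FALSE)
  if (any(num != trunc(num)) || any(den != trunc(den))) {
    stop("num and den must be integer-valued", call. = FALSE)
  }
  .rat_check(num, den)
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- .gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

.rat_check <- function(num, den) {
  if (any(abs(num) >= 2^53) || any(abs(den) >= 2^53)) {
    stop("rational overflow: magnitude exceeds exactly-representable range",
         call. = FALSE)
  }
  invisible(NULL)
}

# vectorized Euclid; both args non-negative
.gcd <- function(a, b) {
  while (any(b > 0)) {
    live <- b > 0
    r <- a
    r[live] <- a[live] %% b[live]
    a[live] <- b[live]
    b <- r
    b[!live] <- 0
  }
  a
}

#' Coerce to rational
#'
#' Accepts `rational` vectors (returned unchanged), integer-valued numerics,
#' strings of the form `"a/b"` or `"a"`, and general doubles (converted by
#' continued-fraction approximation, exact for any value that has a small
#' denominator such as 0.9 = 9/10).
#'
#' @param x object to coerce.
#' @param tol accuracy for continued-fraction conversion of doubles.
#' @return A `rational` vector.
#' @export
as_rational <- function(x, tol = 1e-12) {
  if (inherits(x, "rational")) return(x)
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)
    num <- suppressWarnings(
      vapply(parts, function(p) as.numeric(p[[1]]), numeric(1)))
    den <- suppressWarnings(vapply(parts, function(p) {
      if (length(p) == 1L) 1 else as.numeric(p[[2]])
    }, numeric(1)))
    if (any(is.na(num)) || any(is.na(den))) {
      stop("cannot parse rational from string", call. = FALSE)
    }
    return(rational(num, den))
  }
  if (!is.numeric(x)) stop("cannot coerce to rational", call. = FALSE)
  if (all(x == trunc(x))) return(rational(x, 1))
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    cf <- .contfrac(x[i], tol)
    num[i] <- cf[1]
    den[i] <- cf[2]
  }
  rational(num, den)
}

.contfrac <- function(x, tol) {
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0
  r <- x
  for (iter in 1:64) {
    a <- floor(r)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (abs(x - h / k) < tol || r == a || k > 1e15) {
      return(c(sign * h, k))
    }
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    r <- 1 / (r - a)
  }
  c(sign * h1, k1)
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) {
  structure(list(num = x$num[i], den = x$den[i]), class = "rational")
}

#' @export
`[[.rational` <- function(x, i) {
  structure(list(num = x$num[[i]], den = x$den[[i]]), class = "rational")
}

#' @export
`[<-.rational` <- function(x, i, value) {
  value <- as_rational(value)
  x$num[i] <- value$num
  x$den[i] <- value$den
  x
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), as_rational)
  structure(list(num = unlist(lapply(parts, function(p) p$num)),
                 den = unlist(lapply(parts, function(p) p$den))),
            class = "rational")
}

#' @export
rep.rational <- function(x, ...) {
  idx <- rep(seq_along(x$num), ...)
  x[idx]
}

#' @export
as.numeric.rational <- function(x, ...) x$num / x$den

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
as.character.rational <- function(x, ...) format(x)

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    e1 <- as_rational(e1)
    return(switch(.Generic,
                  "-" = rational(-e1$num, e1$den),
                  "+" = e1,
                  stop("unsupported unary operator for rational: ", .Generic,
                       call. = FALSE)))
  }
  e1 <- as_rational(e1)
  e2 <- as_rational(e2)
  n <- max(length(e1), length(e2))
  a <- e1[rep_len(seq_along(e1$num), n)]
  b <- e2[rep_len(seq_along(e2$num), n)]
  switch(.Generic,
    "+" = {
      .rat_check(a$num * b$den + b$num * a$den, a$den * b$den)
      rational(a$num * b$den + b$num * a$den, a$den * b$den)
    },
    "-" = {
      .rat_check(a$num * b$den - b$num * a$den, a$den * b$den)
      rational(a$num * b$den - b$num * a$den, a$den * b$den)
    },
    "*" = {
      .rat_check(a$num * b$num, a$den * b$den)
      rational(a$num * b$num, a$den * b$den)
    },
    "/" = {
      if (any(b$num == 0)) stop("division by zero rational", call. = FALSE)
      .rat_check(a$num * b$den, a$den * b$num)
      rational(a$num * b$den, a$den * b$num)
    },
    "==" = a$num * b$den == b$num * a$den,
    "!=" = a$num * b$den != b$num * a$den,
    "<"  = a$num * b$den <  b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">"  = a$num * b$den >  b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop("unsupported operator for rational: ", .Generic, call. = FALSE)
  )
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  x <- c.rational(...)
  switch(.Generic,
    "sum" = {
      acc <- rational(0)
      for (i in seq_along(x)) acc <- acc + x[i]
      acc
    },
    "prod" = {
      acc <- rational(1)
      for (i in seq_along(x)) acc <- acc * x[i]
      acc
    },
    "min" = x[which.min(as.numeric(x))],
    "max" = x[which.max(as.numeric(x))],
    "range" = c(x[which.min(as.numeric(x))], x[which.max(as.numeric(x))]),
    stop("unsupported summary for rational: ", .Generic, call. = FALSE)
  )
}

#' Is a rational within the closed unit interval?
#' @param x rational vector.
#' @return logical vector.
#' @keywords internal
.rat_in_unit <- function(x) {
  x >= rational(0) & x <= rational(1)
}
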