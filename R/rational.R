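#' @useDynLib gemverify, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Exact rational vectors
#'
#' `vrat()` builds a vector of exact rationals from integer-valued numerators
#' and denominators. All arithmetic on `vrat` vectors is performed over p/q
#' fractions with no rounding: feasibility statements made with them are exact,
#' not tolerance checks. A denominator of 0 encodes an infinite bound
#' (numerator +1 or -1) and is only meaningful where bounds are expected.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (recycled), default 1.
#' @return An object of class `vrat`.
#' @examples
#' vrat(1, 3) + vrat(1, 6)   # 1/2, exactly
#' @export
vrat <- function(num = numeric(), den = 1) {
  if (length(den) == 1L && length(num) != 1L) den <- rep(den, length(num))
  if (length(num) != length(den)) stop("num and den lengths differ")
  r <- cpp_rat_reduce(as.numeric(num), as.numeric(den))
  new_vrat(r$num, r$den, names(num))
}

new_vrat <- function(num, den, nm = NULL) {
  structure(list(num = num, den = den, names = nm), class = "vrat")
}

#' @export
is_vrat <- function(x) inherits(x, "vrat")

#' Coerce to an exact rational vector
#'
#' Numeric input must be integer-valued (use [rationalize()] to convert decimal
#' text or IEEE doubles explicitly); character input accepts `"p/q"`, integer
#' and decimal literals (including exponents), mapped digit-exactly.
#'
#' @param x numeric, character, or `vrat`.
#' @return A `vrat` vector.
#' @export
as_vrat <- function(x) {
  if (is_vrat(x)) return(x)
  if (is.character(x)) return(rat_parse(x))
  if (is.numeric(x)) {
    if (any(!is.finite(x) | x != floor(x)))
      stop("as_vrat() accepts only integer-valued numerics; use rationalize() for fractional values")
    return(vrat(x, rep(1, length(x))))
  }
  stop("cannot coerce ", class(x)[1], " to vrat")
}

#' Parse rational literals
#'
#' Accepts `"p/q"`, plain integers, decimal literals, scientific notation
#' (`"1e6"`, `"2.5e-3"`), and the infinities `"Inf"`/`"-Inf"`/`"INF"`.
#' Decimal text is mapped to the exact fraction its digits denote
#' (`"0.1"` becomes 1/10), never routed through binary floating point.
#'
#' @param text character vector.
#' @return A `vrat` vector.
#' @export
rat_parse <- function(text) {
  text <- trimws(as.character(text))
  n <- length(text)
  num <- numeric(n); den <- numeric(n)
  for (i in seq_len(n)) {
    s <- text[i]
    if (grepl("^[+-]?(inf|Inf|INF|Infinity)$", s)) {
      num[i] <- if (startsWith(s, "-")) -1 else 1
      den[i] <- 0
      next
    }
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed rational literal: ", s)
      p <- suppressWarnings(as.numeric(parts[1])); q <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(p) || is.na(q) || p != floor(p) || q != floor(q))
        stop("malformed rational literal: ", s)
      num[i] <- p; den[i] <- q
      next
    }
    m <- regmatches(s, regexec("^([+-]?)([0-9]*)(?:\\.([0-9]*))?(?:[eE]([+-]?[0-9]+))?$", s))[[1]]
    if (length(m) == 0 || (m[3] == "" && m[4] == ""))
      stop("malformed numeric literal: '", s, "'")
    sign <- if (m[2] == "-") -1 else 1
    digits <- paste0(m[3], m[4])
    if (nchar(digits) > 17) {
      digits <- sub("^0+", "", digits)
      if (nchar(digits) > 17) stop("numeric literal has too many significant digits for exact conversion: ", s)
    }
    p <- as.numeric(if (digits == "") "0" else digits)
    dec <- nchar(m[4])
    ex <- if (m[5] == "") 0L else as.integer(m[5])
    pow <- ex - dec
    if (pow >= 0) { num[i] <- sign * p * 10^pow; den[i] <- 1 }
    else { num[i] <- sign * p; den[i] <- 10^(-pow) }
    if (abs(num[i]) > 2^53 || den[i] > 2^53)
      stop("numeric literal exceeds exact integer range: ", s)
  }
  r <- cpp_rat_reduce(num, den)
  new_vrat(r$num, r$den, names(text))
}

#' Convert a value to an exact rational
#'
#' Two conversion modes, chosen explicitly because they answer different
#' questions. `decimal_text` maps the printed digits exactly (`"0.1"` is
#' 1/10) and is what an SBML reader must use to avoid manufacturing numerical
#' error at parse time. `float_bits` maps the IEEE-754 value exactly (the
#' double `0.1` is 3602879701896397/36028797018963968) and is what a
#' verification of a floating-point flux vector must use.
#'
#' @param x character (for `decimal_text`) or numeric (for `float_bits`).
#' @param mode one of `"decimal_text"`, `"float_bits"`.
#' @return A `vrat` vector.
#' @export
rationalize <- function(x, mode = c("decimal_text", "float_bits")) {
  mode <- match.arg(mode)
  if (mode == "decimal_text") {
    if (!is.character(x)) x <- format(x, digits = 17, scientific = FALSE, trim = TRUE)
    rat_parse(x)
  } else {
    if (!is.numeric(x)) stop("float_bits mode requires numeric input")
    if (any(!is.finite(x))) stop("float_bits rationalization requires finite values")
    r <- cpp_float_to_rat(as.numeric(x))
    new_vrat(r$num, r$den, names(x))
  }
}

rat_recycle <- function(a, b) {
  la <- length(a$num); lb <- length(b$num)
  if (la == lb) return(list(a = a, b = b))
  if (la == 1L) a <- new_vrat(rep(a$num, lb), rep(a$den, lb))
  else if (lb == 1L) b <- new_vrat(rep(b$num, la), rep(b$den, la))
  else stop("vrat length mismatch: ", la, " vs ", lb)
  list(a = a, b = b)
}

#' @export
Ops.vrat <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(new_vrat(-e1$num, e1$den, e1$names))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for vrat")
  }
  a <- as_vrat(e1); b <- as_vrat(e2)
  r <- rat_recycle(a, b); a <- r$a; b <- r$b
  nm <- if (!is.null(a$names)) a$names else b$names
  op <- match(.Generic, c("+", "-", "*", "/"))
  if (!is.na(op)) {
    out <- cpp_rat_elem(op, a$num, a$den, b$num, b$den)
    return(new_vrat(out$num, out$den, nm))
  }
  cmp <- cpp_rat_compare(a$num, a$den, b$num, b$den)
  switch(.Generic,
    "==" = cmp == 0L, "!=" = cmp != 0L,
    "<" = cmp < 0L, "<=" = cmp <= 0L,
    ">" = cmp > 0L, ">=" = cmp >= 0L,
    stop(.Generic, " not defined for vrat"))
}

#' @export
length.vrat <- function(x) length(x$num)

#' @export
names.vrat <- function(x) x$names

#' @export
`names<-.vrat` <- function(x, value) { x$names <- value; x }

#' @export
`[.vrat` <- function(x, i) {
  if (is.character(i)) {
    if (is.null(x$names)) stop("vrat has no names")
    i <- match(i, x$names)
    if (anyNA(i)) stop("unknown vrat name")
  }
  new_vrat(x$num[i], x$den[i], if (is.null(x$names)) NULL else x$names[i])
}

#' @export
`[<-.vrat` <- function(x, i, value) {
  value <- as_vrat(value)
  if (is.character(i)) i <- match(i, x$names)
  x$num[i] <- value$num; x$den[i] <- value$den
  x
}

#' @export
c.vrat <- function(...) {
  parts <- lapply(list(...), as_vrat)
  nms <- unlist(lapply(parts, function(p) if (is.null(p$names)) rep("", length(p$num)) else p$names))
  if (all(nms == "")) nms <- NULL
  new_vrat(unlist(lapply(parts, function(p) p$num)),
           unlist(lapply(parts, function(p) p$den)), nms)
}

#' @export
`[[.vrat` <- function(x, i) {
  if (identical(i, "num") || identical(i, "den") || identical(i, "names"))
    return(.subset2(x, i))
  out <- x[i]
  out$names <- NULL  # [[ drops names, matching base semantics
  out
}

#' @export
rep.vrat <- function(x, ...) {
  idx <- rep(seq_along(x$num), ...)
  x[idx]
}

#' Exact sum of a rational vector
#' @param x a `vrat` vector.
#' @return Length-1 `vrat`.
#' @export
rat_sum <- function(x) {
  x <- as_vrat(x)
  r <- cpp_rat_sum(x$num, x$den)
  new_vrat(r$num, r$den)
}

#' @export
abs.vrat <- function(x) new_vrat(abs(x$num), x$den, x$names)

rat_sign <- function(x) sign(x$num)

rat_is_finite <- function(x) x$den != 0

rat_zero <- function(n = 1L) new_vrat(rep(0, n), rep(1, n))

rat_min <- function(x) {
  stopifnot(length(x) > 0)
  m <- x[1L]
  for (i in seq_along(x$num)[-1L]) if (isTRUE(x[i] < m)) m <- x[i]
  m
}

rat_max <- function(x) {
  stopifnot(length(x) > 0)
  m <- x[1L]
  for (i in seq_along(x$num)[-1L]) if (isTRUE(x[i] > m)) m <- x[i]
  m
}

#' Format rationals as "p/q" strings
#' @param x a `vrat` vector.
#' @return Character vector; integers render without a denominator.
#' @export
rat_format <- function(x) {
  x <- as_vrat(x)
  out <- ifelse(x$den == 0, ifelse(x$num > 0, "Inf", "-Inf"),
                ifelse(x$den == 1, sprintf("%.0f", x$num),
                       paste0(sprintf("%.0f", x$num), "/", sprintf("%.0f", x$den))))
  names(out) <- x$names
  out
}

#' @export
format.vrat <- function(x, ...) rat_format(x)

#' @export
as.character.vrat <- function(x, ...) rat_format(x)

#' @export
as.double.vrat <- function(x, ...) {
  out <- ifelse(x$den == 0, ifelse(x$num > 0, Inf, -Inf), x$num / x$den)
  names(out) <- x$names
  out
}

#' @export
print.vrat <- function(x, ...) {
  cat("<vrat[", length(x), "]> ", paste(rat_format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

# --- exact rational matrices -------------------------------------------------

#' Exact rational matrix
#'
#' Thin container pairing numerator and denominator matrices; used for
#' stoichiometric matrices and null-space bases where entries must stay exact.
#'
#' @param num,den integer-valued matrices of equal shape.
#' @param dimnames optional dimnames.
#' @return An object of class `ratmat`.
#' @export
ratmat <- function(num, den = NULL, dimnames = NULL) {
  num <- as.matrix(num)
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  den <- as.matrix(den)
  stopifnot(all(dim(num) == dim(den)))
  r <- cpp_rat_reduce(as.numeric(num), as.numeric(den))
  structure(list(num = matrix(r$num, nrow(num), ncol(num)),
                 den = matrix(r$den, nrow(num), ncol(num)),
                 dimnames = dimnames), class = "ratmat")
}

#' @export
dim.ratmat <- function(x) dim(x$num)

#' @export
dimnames.ratmat <- function(x) x$dimnames

#' @export
as.matrix.ratmat <- function(x, ...) {
  m <- x$num / ifelse(x$den == 0, NA, x$den)
  dimnames(m) <- x$dimnames
  m
}

#' @export
print.ratmat <- function(x, ...) {
  d <- dim(x$num)
  cat("<ratmat ", d[1], " x ", d[2], ">\n", sep = "")
  if (prod(d) > 0 && prod(d) <= 400) {
    m <- matrix(rat_format(new_vrat(as.numeric(x$num), as.numeric(x$den))), d[1], d[2])
    dimnames(m) <- x$dimnames
    print(m, quote = FALSE)
  }
  invisible(x)
}

ratmat_col <- function(x, j) new_vrat(x$num[, j], x$den[, j], x$dimnames[[1]])

ratmat_row <- function(x, i) new_vrat(x$num[i, ], x$den[i, ], x$dimnames[[2]])

ratmat_from_cols <- function(cols, dimnames = NULL, nrow = 0) {
  if (length(cols) == 0)
    return(ratmat(matrix(0, nrow, 0), matrix(1, nrow, 0), dimnames))
  n <- length(cols[[1]])
  num <- vapply(cols, function(v) v$num, numeric(n))
  den <- vapply(cols, function(v) v$den, numeric(n))
  if (n == 1) { num <- matrix(num, 1); den <- matrix(den, 1) }
  ratmat(num, den, dimnames)
}

#' Exact matrix-vector product
#' @param A a `ratmat`.
#' @param x a `vrat` of length `ncol(A)`.
#' @return `vrat` of length `nrow(A)`, computed with no rounding.
#' @export
rat_matvec <- function(A, x) {
  stopifnot(inherits(A, "ratmat"))
  x <- as_vrat(x)
  if (ncol(A$num) != length(x)) stop("rat_matvec dimension mismatch")
  r <- cpp_rat_matvec(A$num, A$den, x$num, x$den)
  new_vrat(r$num, r$den, A$dimnames[[1]])
}

#' Exact reduced row-echelon form
#' @param A a `ratmat`.
#' @return List with the `ratmat` `rref` and integer `pivots` (pivot columns).
#' @export
rat_rref <- function(A) {
  stopifnot(inherits(A, "ratmat"))
  r <- cpp_rat_rref(A$num, A$den)
  list(rref = structure(list(num = r$num, den = r$den, dimnames = A$dimnames),
                        class = "ratmat"),
       pivots = r$pivots)
}
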