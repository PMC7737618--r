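## Shared internal helpers: coordinate flattening, seeded RNG scope,
## condition constructors, hybrid-36 encoding for PDB field overflow.

#' @importFrom stats rnorm runif sd quantile median coef nls.control
#' @importFrom utils read.csv read.delim write.csv head tail
NULL

AVOGADRO <- 6.02214076e23

## Flattening convention used everywhere (PCA vectors, ENM modes,
## pathway arithmetic): (x1,y1,z1,x2,y2,z2,...).
flatten_xyz <- function(m) as.vector(t(m))

unflatten_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

## Evaluate `expr` under a local RNG seed, restoring global RNG state.
## All public generators route through this: no global random state leaks.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_elevator("invalid_seed", "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Classed conditions so callers (and the CLI) can map failures to
## machine-readable error classes.
stop_elevator <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("elevator_", class), "elevator_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_elevator <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("elevator_", class), "elevator_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_elevator("numeric", "%s contains non-finite values", what)
  invisible(x)
}

## Rotation matrix about a unit axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * tcrossprod(u)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop_elevator("numeric", "zero vector cannot be normalized")
  v / n
}

## --- hybrid-36 encoding (atom serials > 99999, residue numbers > 9999) ---
## Width-4 numbers 1..9999 are plain decimal; 10000.. map to A000..ZZZZ
## (upper case), then a000..zzzz (lower case), per the fixed-column
## convention used by large-structure PDB files.

.h36_digits_upper <- c(0:9, LETTERS)
.h36_digits_lower <- c(0:9, letters)

hy36encode <- function(n, width) {
  stopifnot(width %in% c(4L, 5L))
  base_ <- 36L
  dec_max <- 10L^width - 1L
  if (n >= 0 && n <= dec_max) return(formatC(n, width = width))
  upper_span <- 26L * base_^(width - 1L)
  v <- n - (dec_max + 1L)
  if (v < upper_span) {
    digs <- .h36_digits_upper
    v <- v + 10L * base_^(width - 1L)  # first digit starts at 'A'
  } else {
    v <- v - upper_span
    if (v >= upper_span)
      stop_elevator("overflow", "value %d exceeds hybrid-36 range", n)
    digs <- .h36_digits_lower
    v <- v + 10L * base_^(width - 1L)
  }
  out <- character(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- digs[(v %% base_) + 1L]
    v <- v %/% base_
  }
  paste(out, collapse = "")
}

hy36decode <- function(s) {
  s <- trimws(s)
  if (grepl("^-?[0-9]+$", s)) return(as.integer(s))
  width <- nchar(s)
  base_ <- 36L
  first <- substr(s, 1L, 1L)
  digs <- if (first %in% LETTERS) .h36_digits_upper else .h36_digits_lower
  v <- 0L
  for (i in seq_len(width)) {
    d <- match(substr(s, i, i), digs) - 1L
    if (is.na(d)) stop_elevator("parse", "invalid hybrid-36 field '%s'", s)
    v <- v * base_ + d
  }
  dec_max <- 10L^width - 1L
  offset0 <- 10L * base_^(width - 1L)
  if (first %in% LETTERS) {
    as.integer(v - offset0 + dec_max + 1L)
  } else {
    as.integer(v - offset0 + 26L * base_^(width - 1L) + dec_max + 1L)
  }
}
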