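# The 25 integer combination functions used at each slot of the liability
# chain. All functions are total: every pair of integers maps to an integer,
# undefined cases map to 0, and results saturate at the 32-bit two's
# complement range so that chained evaluation can never overflow.

.sat_max <- 2^31 - 1
.sat_min <- -(2^31 - 1) # symmetric; R reserves -2^31 for NA_integer_

.fn_names <- c(
  "ADD", "SUB", "MULT", "DIV", "MOD", "MOD2",
  "GT", "LT", "AND", "OR", "XOR",
  "BITA", "BITO", "BITX",
  "ABS", "NOT", "FAC", "LEFT", "RIGHT",
  "POW", "LOG", "PER", "CHS",
  "MIN", "MAX"
)

.fn_groups <- rep(
  c("Basic", "Logical", "Bitwise", "Unary", "Large", "Miscellaneous"),
  times = c(6, 5, 3, 5, 4, 2)
)

.fn_symbols <- c(
  ADD = "+", SUB = "-", MULT = "*", DIV = "/", MOD = "%", MOD2 = "%2",
  GT = ">", LT = "<", AND = "&&", OR = "||", XOR = "^^",
  BITA = "&", BITO = "|", BITX = "^",
  ABS = "ABS", NOT = "~", FAC = "!", LEFT = "LEFT", RIGHT = "RIGHT",
  POW = "POW", LOG = "LOG", PER = "P", CHS = "C",
  MIN = "MIN", MAX = "MAX"
)

#' Catalogue of the 25 combination functions
#'
#' Lists the integer-valued functions available at each of the six slots of
#' the hierarchical liability chain, in the canonical order used by the
#' bitstring encoding of the search module (`ADD` = index 0 through
#' `MAX` = index 24).
#'
#' @return A tibble with one row per function and columns `index` (0--24),
#'   `name`, `symbol` (the operator-style alias, accepted anywhere a function
#'   name is) and `group` (`Basic`, `Logical`, `Bitwise`, `Unary`, `Large` or
#'   `Miscellaneous`).
#' @examples
#' math_functions()
#' @export
math_functions <- function() {
  tibble::tibble(
    index = 0:24,
    name = .fn_names,
    symbol = unname(.fn_symbols),
    group = .fn_groups
  )
}

#' Normalise a function name
#'
#' Accepts the canonical names case-insensitively as well as the
#' operator-style symbols (`"+"`, `"^^"`, ...).
#'
#' @param name Character vector of function names or symbols.
#' @param slot Optional label (e.g. `"f1"`) used in error messages to name
#'   the offending chain slot.
#' @return Character vector of canonical upper-case names.
#' @export
fn_canonical <- function(name, slot = NULL) {
  up <- toupper(as.character(name))
  out <- ifelse(up %in% .fn_names, up, NA_character_)
  sym_idx <- match(as.character(name), .fn_symbols)
  out[is.na(out) & !is.na(sym_idx)] <- .fn_names[sym_idx[is.na(out) & !is.na(sym_idx)]]
  if (anyNA(out)) {
    bad <- unique(name[is.na(out)])
    where <- if (is.null(slot)) "" else paste0(" in slot ", slot)
    stop(
      "Unknown combination function", where, ": ",
      paste(sQuote(bad), collapse = ", "),
      ". See math_functions() for the 25 available functions.",
      call. = FALSE
    )
  }
  out
}

.clamp <- function(x) pmin(pmax(x, .sat_min), .sat_max)

# Saturating integer power with exact results below the cap.
.pow <- function(a, b) {
  r <- numeric(length(a))
  r[b < 0] <- 0
  zb <- b >= 0
  r[zb & a == 0] <- ifelse(b[zb & a == 0] == 0, 1, 0)
  one <- zb & abs(a) == 1
  r[one] <- ifelse(a[one] == 1, 1, ifelse(b[one] %% 2 == 0, 1, -1))
  big <- zb & abs(a) >= 2
  if (any(big)) {
    ab <- a[big]
    bb <- b[big]
    over <- bb * log2(abs(ab)) > 31
    v <- numeric(length(ab))
    v[!over] <- round(ab[!over]^bb[!over])
    neg <- ab < 0 & bb %% 2 == 1
    v[over] <- ifelse(neg[over], .sat_min, .sat_max)
    r[big] <- v
  }
  r
}

# Falling factorial a!/(a-b)! for 0 <= b <= a, else 0; saturating.
.per <- function(a, b) {
  ok <- b >= 0 & a >= b
  r <- numeric(length(a))
  if (any(ok)) {
    lg <- lgamma(a[ok] + 1) - lgamma(a[ok] - b[ok] + 1)
    v <- ifelse(lg > log(.sat_max), .sat_max, round(exp(lg)))
    r[ok] <- v
  }
  r
}

.chs <- function(a, b) {
  ok <- b >= 0 & a >= b
  r <- numeric(length(a))
  r[ok] <- pmin(round(choose(a[ok], b[ok])), .sat_max)
  r
}

.fac <- function(a, b) {
  r <- numeric(length(a))
  small <- a >= 0 & a <= 12
  r[small] <- factorial(a[small])
  r[a > 12] <- .sat_max
  r
}

.bitop <- function(op) {
  function(a, b) op(as.integer(a), as.integer(b))
}

.fn_impl <- list(
  ADD = function(a, b) a + b,
  SUB = function(a, b) a - b,
  MULT = function(a, b) a * b,
  DIV = function(a, b) ifelse(b == 0, 0, trunc(a / b)),
  MOD = function(a, b) ifelse(b == 0, 0, a - floor(a / b) * b),
  MOD2 = function(a, b) (a + b) %% 2,
  GT = function(a, b) as.numeric(a > b),
  LT = function(a, b) as.numeric(a < b),
  AND = function(a, b) as.numeric(a != 0 & b != 0),
  OR = function(a, b) as.numeric(a != 0 | b != 0),
  XOR = function(a, b) as.numeric(xor(a != 0, b != 0)),
  BITA = .bitop(bitwAnd),
  BITO = .bitop(bitwOr),
  BITX = .bitop(bitwXor),
  ABS = function(a, b) abs(a),
  NOT = function(a, b) -(a + 1),
  FAC = .fac,
  LEFT = function(a, b) a,
  RIGHT = function(a, b) b,
  POW = .pow,
  LOG = function(a, b) ifelse(abs(a) >= 1, floor(log2(abs(a))), 0),
  PER = .per,
  CHS = .chs,
  MIN = function(a, b) pmin(a, b),
  MAX = function(a, b) pmax(a, b)
)

#' Apply one of the 25 combination functions
#'
#' Evaluates `f(a, b)` elementwise with total integer semantics: division and
#' modulus by zero give 0, factorial/permutation/choose outside their domain
#' give 0, and every result saturates at the 32-bit two's complement range.
#' Unary functions (`ABS`, `NOT`, `FAC`, `LOG`) act on the left operand and
#' ignore the right; `LEFT` and `RIGHT` are the two operand selectors.
#'
#' @param name A function name or symbol (see [math_functions()]).
#' @param a,b Integer vectors (recycled to a common length).
#' @param slot Optional slot label for error messages.
#' @return A numeric vector of integer-valued results.
#' @examples
#' fn_apply("ADD", 2, 2)
#' fn_apply("MOD2", 0:2, 1)
#' fn_apply("CHS", 2, 1)
#' @export
fn_apply <- function(name, a, b, slot = NULL) {
  name <- fn_canonical(name, slot = slot)
  stopifnot(length(name) == 1L)
  n <- max(length(a), length(b))
  a <- .clamp(rep_len(as.numeric(a), n))
  b <- .clamp(rep_len(as.numeric(b), n))
  .clamp(.fn_impl[[name]](a, b))
}
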