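# Finite discrete distributions over integers, represented as two-column
# tibbles (value, prob). These carry the per-locus genotype/environment
# distributions and every intermediate distribution of the liability chain.

#' Construct a discrete distribution
#'
#' @param value Integer support values (must be distinct).
#' @param prob Probabilities; non-negative, summing to 1.
#' @return A tibble with columns `value` (sorted increasing) and `prob`.
#' @examples
#' discrete_dist(c(0, 1, 2), c(0.25, 0.5, 0.25))
#' @export
discrete_dist <- function(value, prob) {
  stopifnot(length(value) == length(prob))
  if (anyDuplicated(value)) {
    stop("Support values must be distinct.", call. = FALSE)
  }
  if (any(prob < 0)) {
    stop("Probabilities must be non-negative.", call. = FALSE)
  }
  if (abs(sum(prob) - 1) > 1e-9) {
    stop("Probabilities must sum to 1 (got ", format(sum(prob)), ").", call. = FALSE)
  }
  o <- order(value)
  tibble::tibble(value = as.numeric(value)[o], prob = as.numeric(prob)[o])
}

#' Genotype distribution under Hardy-Weinberg equilibrium
#'
#' Genotypes are coded 0, 1, 2 as counts of the minor allele. The default
#' allele frequency 0.5 gives the 0.25 / 0.5 / 0.25 distribution used for
#' every functional locus.
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @return A [discrete_dist()] over {0, 1, 2}.
#' @export
dist_genotype <- function(maf = 0.5) {
  stopifnot(maf > 0, maf <= 0.5)
  discrete_dist(0:2, c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
}

#' Environmental factor distribution
#'
#' The environmental exposure is coded on the five-point scale -2..2 and is
#' uniform by default.
#'
#' @param prob Five probabilities for the values -2, -1, 0, 1, 2.
#' @return A [discrete_dist()] over {-2, ..., 2}.
#' @export
dist_environment <- function(prob = rep(0.2, 5)) {
  stopifnot(length(prob) == 5)
  discrete_dist(-2:2, prob)
}

is_discrete_dist <- function(x) {
  is.data.frame(x) && all(c("value", "prob") %in% names(x)) && nrow(x) >= 1
}

#' Exact output distribution of a combination function
#'
#' Pushes two independent discrete distributions through one of the 25
#' combination functions: `P(out = x)` is the sum of `P_a(u) * P_b(v)` over
#' all pairs `(u, v)` with `f(u, v) = x`.
#'
#' @param name Function name or symbol.
#' @param dist_a,dist_b Discrete distributions (tibbles with `value`, `prob`).
#' @param slot Optional slot label for error messages.
#' @return A [discrete_dist()] over the reachable outputs.
#' @examples
#' g <- dist_genotype()
#' fn_push("MOD2", g, g) # {0: 0.5, 1: 0.5}
#' @export
fn_push <- function(name, dist_a, dist_b, slot = NULL) {
  stopifnot(is_discrete_dist(dist_a), is_discrete_dist(dist_b))
  na <- nrow(dist_a)
  nb <- nrow(dist_b)
  a <- rep(dist_a$value, times = nb)
  b <- rep(dist_b$value, each = na)
  p <- rep(dist_a$prob, times = nb) * rep(dist_b$prob, each = na)
  out <- fn_apply(name, a, b, slot = slot)
  agg <- rowsum(p, group = out) # rows in increasing numeric order of `out`
  discrete_dist(as.numeric(rownames(agg)), as.numeric(agg))
}
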