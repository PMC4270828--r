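# Entropy-based interaction metrics. All information quantities are plug-in
# (maximum-likelihood) estimates from empirical contingency tables, in bits.

#' Shannon entropy of a count vector
#'
#' @param counts Non-negative counts with positive total; `0 log 0` is 0.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(1000, 1000)) # 1 bit
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("Counts must be non-negative.", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("Counts must have a positive total.", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# joint cell index of several discrete columns, as a single 0-based integer
.cell_code <- function(cols) {
  code <- rep(0L, length(cols[[1]]))
  for (x in cols) {
    u <- sort(unique(x))
    code <- code * length(u) + (match(x, u) - 1L)
  }
  code
}

#' Plug-in mutual information between variables and a class label
#'
#' `I(X1, ..., Xk ; Y) = H(X) + H(Y) - H(X, Y)` from the empirical joint
#' contingency table, in bits.
#'
#' @param data A data frame.
#' @param vars Character vector of column names forming the joint variable.
#' @param class Name of the class column (default `"Class"`).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(data, vars, class = "Class") {
  x <- .cell_code(data[vars])
  y <- match(data[[class]], sort(unique(data[[class]]))) - 1L
  kx <- max(x) + 1L
  ky <- max(y) + 1L
  n <- length(x)
  ent <- function(tab) {
    p <- tab[tab > 0] / n
    -sum(p * log2(p))
  }
  ent(tabulate(x + 1L, kx)) + ent(tabulate(y + 1L, ky)) -
    ent(tabulate(x * ky + y + 1L, kx * ky))
}

#' Main-effect, pairwise and pure three-way interaction information
#'
#' Decomposes the information that a triple of variants carries about
#' case-control status. The pure three-way interaction information
#' \deqn{IG(A;B;C;Y) = I(A,B,C;Y) - I(A,B;Y) - I(A,C;Y) - I(B,C;Y)
#'       + I(A;Y) + I(B;Y) + I(C;Y)}
#' is the synergy left after subtracting all one-way (main) effects and
#' two-way synergies; it can be negative (redundancy). Pairwise synergies
#' are `IG(Xi;Xj;Y) = I(Xi,Xj;Y) - I(Xi;Y) - I(Xj;Y)`.
#'
#' @param data A case-control data frame.
#' @param loci Character vector of three distinct variant column names.
#' @param class Name of the 0/1 class column.
#' @return An object of class `interaction_info` with elements `main_ig`
#'   (named length-3), `pairwise_ig` (named length-3), `threeway_ig`,
#'   `degenerate` (loci with a single observed genotype) and `n`.
#' @examples
#' ig <- interaction_information(parity_dataset(), c("TF1", "TF2", "enhancer"))
#' ig$threeway_ig # 1 bit: purely three-way epistatic signal
#' @export
interaction_information <- function(data, loci = c("TF1", "TF2", "enhancer"),
                                    class = "Class") {
  stopifnot(length(loci) == 3, !anyDuplicated(loci))
  missing <- setdiff(c(loci, class), names(data))
  if (length(missing)) {
    stop("Column(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  degenerate <- loci[vapply(loci, function(v) length(unique(data[[v]])) < 2,
                            logical(1))]
  mi <- function(vars) mutual_information(data, vars, class)
  main <- vapply(loci, function(v) mi(v), numeric(1))
  pairs <- utils::combn(loci, 2, simplify = FALSE)
  pair_joint <- vapply(pairs, mi, numeric(1))
  pair_ig <- vapply(seq_along(pairs), function(i) {
    pair_joint[i] - main[pairs[[i]][1]] - main[pairs[[i]][2]]
  }, numeric(1))
  names(pair_ig) <- vapply(pairs, paste, character(1), collapse = ":")
  three <- mi(loci) - sum(pair_joint) + sum(main)
  structure(
    list(
      loci = loci, main_ig = main, pairwise_ig = pair_ig,
      threeway_ig = three, degenerate = degenerate, n = nrow(data)
    ),
    class = "interaction_info"
  )
}

#' @export
print.interaction_info <- function(x, ...) {
  cat("Interaction information (bits), n =", x$n, "\n")
  cat("  main effects:     ",
      paste(sprintf("%s=%.4f", names(x$main_ig), x$main_ig), collapse = "  "),
      "\n")
  cat("  pairwise synergy: ",
      paste(sprintf("%s=%.4f", names(x$pairwise_ig), x$pairwise_ig),
            collapse = "  "), "\n")
  cat("  pure three-way:   ", sprintf("%.4f", x$threeway_ig), "\n")
  if (length(x$degenerate)) {
    cat("  [degenerate loci: ", paste(x$degenerate, collapse = ", "), "]\n")
  }
  invisible(x)
}

#' @rdname interaction_information
#' @param x An `interaction_info` object.
#' @param ... Unused.
#' @method tidy interaction_info
#' @export
tidy.interaction_info <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$main_ig), names(x$pairwise_ig),
             paste(x$loci, collapse = ":")),
    order = rep(c(1L, 2L, 3L), c(3L, 3L, 1L)),
    ig = c(unname(x$main_ig), unname(x$pairwise_ig), x$threeway_ig)
  )
}

#' @rdname interaction_information
#' @param object An `interaction_info` object.
#' @method autoplot interaction_info
#' @export
autoplot.interaction_info <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$ig,
                                  fill = factor(.data$order))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_grey(name = "order", start = 0.7, end = 0.2) +
    ggplot2::labs(x = NULL, y = "information gain (bits)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
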