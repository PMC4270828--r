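# Multifactor dimensionality reduction (MDR): pools k-locus genotype
# combinations into high-risk / low-risk groups by comparing each cell's
# case:control ratio with the overall ratio, and the two permutation tests
# used to validate fitted models.

# per-cell counts -> high-risk labels and training accuracy.
# cases_k/ctrl_k are counts per cell; ratio = n_cases / n_controls overall.
# Ties (cell ratio equal to overall) are high-risk; cells with no cases and
# some controls are low-risk; empty cells never contribute to accuracy.
.mdr_counts_accuracy <- function(cases_k, ctrl_k, n_cases, n_controls) {
  high <- cases_k * n_controls >= ctrl_k * n_cases & (cases_k + ctrl_k) > 0
  acc <- (sum(cases_k[high]) + sum(ctrl_k[!high])) /
    (n_cases + n_controls)
  list(high = high, accuracy = acc)
}

#' Fit an MDR classifier
#'
#' Labels each observed k-locus genotype combination high-risk when its
#' case:control ratio is at least the overall case:control ratio of the
#' dataset (ties high-risk), low-risk otherwise; unobserved combinations are
#' low-risk. Subjects in high-risk cells are predicted cases. The reported
#' accuracy is training accuracy on the full dataset.
#'
#' @param data A case-control data frame.
#' @param loci Character vector of k >= 1 variant column names.
#' @param class Name of the 0/1 class column.
#' @return An object of class `mdr_model`: the per-cell table, the
#'   threshold ratio and the training accuracy.
#' @examples
#' fit <- mdr(parity_dataset(), c("TF1", "TF2", "enhancer"))
#' fit$accuracy # 1: genotype combinations separate cases perfectly
#' @export
mdr <- function(data, loci, class = "Class") {
  stopifnot(length(loci) >= 1)
  missing <- setdiff(c(loci, class), names(data))
  if (length(missing)) {
    stop("Column(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[class]]
  n_cases <- sum(y == 1)
  n_controls <- sum(y == 0)
  cells <- dplyr::count(data[c(loci, class)], dplyr::across(dplyr::all_of(loci)),
                        wt = NULL, name = "n_total")
  cases <- dplyr::count(data[y == 1, loci, drop = FALSE],
                        dplyr::across(dplyr::all_of(loci)), name = "n_cases")
  cells <- dplyr::left_join(cells, cases, by = loci)
  cells$n_cases[is.na(cells$n_cases)] <- 0L
  cells$n_controls <- cells$n_total - cells$n_cases
  cells$n_total <- NULL
  lab <- .mdr_counts_accuracy(cells$n_cases, cells$n_controls,
                              n_cases, n_controls)
  cells$risk <- ifelse(lab$high, "high", "low")
  structure(
    list(
      loci = loci, cells = tibble::as_tibble(cells),
      threshold_ratio = n_cases / n_controls,
      accuracy = lab$accuracy,
      n_cases = n_cases, n_controls = n_controls
    ),
    class = "mdr_model"
  )
}

#' @export
print.mdr_model <- function(x, ...) {
  cat("MDR model on (", paste(x$loci, collapse = ", "), ")\n", sep = "")
  cat("  ", nrow(x$cells), " observed genotype combinations, ",
      sum(x$cells$risk == "high"), " high-risk\n", sep = "")
  cat("  threshold case:control ratio ", signif(x$threshold_ratio, 4),
      ", training accuracy ", signif(x$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname mdr
#' @param x,object An `mdr_model`.
#' @param ... Unused.
#' @method tidy mdr_model
#' @export
tidy.mdr_model <- function(x, ...) x$cells

#' @rdname mdr
#' @method glance mdr_model
#' @export
glance.mdr_model <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    threshold_ratio = x$threshold_ratio,
    n_cells = nrow(x$cells),
    n_high_risk = sum(x$cells$risk == "high"),
    n = x$n_cases + x$n_controls
  )
}

#' @rdname mdr
#' @param newdata Data frame with the model's locus columns.
#' @export
predict.mdr_model <- function(object, newdata, ...) {
  key <- do.call(paste, c(newdata[object$loci], sep = "\r"))
  cell_key <- do.call(paste, c(object$cells[object$loci], sep = "\r"))
  risk <- object$cells$risk[match(key, cell_key)]
  as.integer(!is.na(risk) & risk == "high") # unseen cells are low-risk
}

# Shared machinery for the permutation tests: work on integer cell codes so
# each permutation is a couple of tabulate() calls.
.perm_setup <- function(data, loci, class) {
  codes <- lapply(data[loci], function(x) match(x, sort(unique(x))) - 1L)
  sizes <- vapply(data[loci], function(x) length(unique(x)), integer(1))
  k <- prod(sizes)
  ci <- rep(1L, nrow(data))
  for (i in seq_along(codes)) ci <- (ci - 1L) * sizes[i] + codes[[i]] + 1L
  list(ci = ci, codes = codes, sizes = sizes, k = k,
       y = as.integer(data[[class]]))
}

.perm_accuracy <- function(ci, y, k, n_cases, n_controls) {
  cases_k <- tabulate(ci[y == 1L], nbins = k)
  ctrl_k <- tabulate(ci[y == 0L], nbins = k)
  .mdr_counts_accuracy(cases_k, ctrl_k, n_cases, n_controls)$accuracy
}

#' Permutation tests for an MDR model
#'
#' Both tests use the k-locus MDR training accuracy as the statistic and the
#' add-one estimator `p = (1 + #permutations >= observed) / (n_perm + 1)`.
#'
#' `mdr_permutation_test(type = "standard")` tests the null hypothesis of no
#' genotype-status association by shuffling the case-control labels.
#'
#' `type = "epistasis"` is the explicit test of epistasis: each variant's
#' genotype column is shuffled independently within cases and within
#' controls. This preserves every marginal genotype-status association
#' (allele and genotype frequency differences) while destroying
#' inter-variant interactions, so significance is evidence of epistasis
#' beyond independent main effects.
#'
#' @param data A case-control data frame.
#' @param loci Variant columns defining the MDR model.
#' @param n_perm Number of permutations (default 1000).
#' @param type `"standard"` or `"epistasis"`.
#' @param class Name of the 0/1 class column.
#' @param seed Optional integer seed.
#' @return Object of class `mdr_perm_test` with `statistic` (observed
#'   accuracy), `p.value`, `n_perm`, `type` and the permuted statistics.
#' @export
mdr_permutation_test <- function(data, loci, n_perm = 1000,
                                 type = c("standard", "epistasis"),
                                 class = "Class", seed = NULL) {
  type <- match.arg(type)
  stopifnot(n_perm >= 1)
  s <- .perm_setup(data, loci, class)
  n_cases <- sum(s$y == 1L)
  n_controls <- sum(s$y == 0L)
  observed <- .perm_accuracy(s$ci, s$y, s$k, n_cases, n_controls)
  case_rows <- which(s$y == 1L)
  ctrl_rows <- which(s$y == 0L)
  perm_stat <- with_seed_(seed, vapply(seq_len(n_perm), function(i) {
    if (type == "standard") {
      yp <- sample(s$y)
      .perm_accuracy(s$ci, yp, s$k, n_cases, n_controls)
    } else {
      ci <- rep(1L, length(s$y))
      for (j in seq_along(s$codes)) {
        cj <- s$codes[[j]]
        cj[case_rows] <- cj[case_rows][sample.int(length(case_rows))]
        cj[ctrl_rows] <- cj[ctrl_rows][sample.int(length(ctrl_rows))]
        ci <- (ci - 1L) * s$sizes[j] + cj + 1L
      }
      .perm_accuracy(ci, s$y, s$k, n_cases, n_controls)
    }
  }, numeric(1)))
  structure(
    list(
      statistic = observed,
      p.value = (1 + sum(perm_stat >= observed)) / (n_perm + 1),
      n_perm = n_perm, type = type, loci = loci, perm_stat = perm_stat
    ),
    class = "mdr_perm_test"
  )
}

#' @export
print.mdr_perm_test <- function(x, ...) {
  lab <- if (x$type == "standard") {
    "standard permutation test (label shuffling)"
  } else {
    "explicit test of epistasis (within-class genotype shuffling)"
  }
  cat(lab, "\n  loci: ", paste(x$loci, collapse = ", "), "\n", sep = "")
  cat("  observed MDR accuracy ", signif(x$statistic, 4),
      ", p = ", format.pval(x$p.value, digits = 3),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @rdname mdr_permutation_test
#' @param x An `mdr_perm_test`.
#' @param ... Unused.
#' @method tidy mdr_perm_test
#' @export
tidy.mdr_perm_test <- function(x, ...) {
  tibble::tibble(
    type = x$type, statistic = x$statistic, p.value = x$p.value,
    n_perm = x$n_perm
  )
}
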