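# The hierarchical liability model: six genetic variants (two transcription
# factors, an enhancer, a promoter, a coding variant, a microRNA variant)
# and an environmental factor, combined by a fixed chain of six functions:
#
#   r1 = f1(TF1, enhancer); r2 = f2(r1, TF2); r3 = f3(r2, promoter);
#   r4 = f4(r3, coding);    r5 = f5(r4, microRNA);
#   liability = f6(r5, environment)

.locus_names <- c("TF1", "TF2", "enhancer", "promoter", "coding",
                  "microRNA", "environment")

# second operand fed into each of the six chain slots (first is TF1)
.chain_operands <- c("enhancer", "TF2", "promoter", "coding",
                     "microRNA", "environment")

#' Default locus distributions
#'
#' Each of the six genetic variants is biallelic with equal allele
#' frequencies, giving Hardy-Weinberg genotype probabilities 0.25 / 0.5 /
#' 0.25; the environmental factor is uniform over -2..2.
#'
#' @return Named list of [discrete_dist()] objects, one per locus.
#' @export
default_loci <- function() {
  g <- dist_genotype()
  loci <- c(
    stats::setNames(rep(list(g), 6), .locus_names[1:6]),
    list(environment = dist_environment())
  )
  loci
}

#' Define a hierarchical liability model
#'
#' @param functions Character vector of six function names (or symbols), one
#'   per chain slot `f1`..`f6`. A single name is recycled to all six slots.
#' @param loci Named list of locus distributions as produced by
#'   [default_loci()]. Genetic loci must have support {0, 1, 2}; the
#'   environment must have support {-2, ..., 2}.
#' @return An object of class `hierarchy_model`.
#' @examples
#' m <- hierarchy_model("ADD")                  # purely additive
#' m4 <- hierarchy_model(c("XOR", "XOR", "ADD", "ADD", "ADD", "ADD"))
#' @export
hierarchy_model <- function(functions = "ADD", loci = default_loci()) {
  if (length(functions) == 1) functions <- rep(functions, 6)
  if (length(functions) != 6) {
    stop("`functions` must name six chain slots f1..f6.", call. = FALSE)
  }
  functions <- vapply(
    seq_along(functions),
    function(i) fn_canonical(functions[[i]], slot = paste0("f", i)),
    character(1)
  )
  if (!all(.locus_names %in% names(loci))) {
    stop(
      "`loci` must contain distributions named ",
      paste(.locus_names, collapse = ", "), ".",
      call. = FALSE
    )
  }
  loci <- loci[.locus_names]
  for (nm in .locus_names[1:6]) {
    if (!setequal(loci[[nm]]$value, 0:2)) {
      stop("Genetic locus ", sQuote(nm), " must have support {0, 1, 2}.",
           call. = FALSE)
    }
  }
  if (!setequal(loci$environment$value, -2:2)) {
    stop("Locus 'environment' must have support {-2, ..., 2}.", call. = FALSE)
  }
  structure(
    list(functions = stats::setNames(functions, paste0("f", 1:6)), loci = loci),
    class = "hierarchy_model"
  )
}

#' @export
print.hierarchy_model <- function(x, ...) {
  cat("Hierarchical liability model\n")
  cat("  chain: ", paste0(
    "f", 1:6, "=", x$functions,
    collapse = "  "
  ), "\n", sep = "")
  cat("  wiring: ((((TF1 f1 enhancer) f2 TF2) f3 promoter) f4 coding)",
      "f5 microRNA) f6 environment\n")
  invisible(x)
}

#' Evaluate the liability chain per subject
#'
#' @param model A [hierarchy_model()].
#' @param data A data frame with integer columns `TF1`, `TF2`, `enhancer`,
#'   `promoter`, `coding`, `microRNA` (values 0/1/2) and `environment`
#'   (values -2..2).
#' @return Numeric vector of liability values, one per row of `data`.
#' @examples
#' m <- hierarchy_model("ADD")
#' liability(m, data.frame(
#'   TF1 = 2, TF2 = 2, enhancer = 2, promoter = 2, coding = 2,
#'   microRNA = 2, environment = 2
#' )) # 14
#' @export
liability <- function(model, data) {
  stopifnot(inherits(model, "hierarchy_model"))
  missing <- setdiff(.locus_names, names(data))
  if (length(missing)) {
    stop("`data` is missing locus column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in .locus_names) {
    ok <- data[[nm]] %in% model$loci[[nm]]$value
    if (!all(ok)) {
      stop(
        "Locus ", sQuote(nm), " has out-of-range value(s): ",
        paste(unique(data[[nm]][!ok]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  r <- as.numeric(data$TF1)
  for (i in 1:6) {
    r <- fn_apply(model$functions[[i]], r,
                  as.numeric(data[[.chain_operands[i]]]),
                  slot = paste0("f", i))
  }
  r
}

#' Exact liability distribution of a model
#'
#' Pushes the seven independent locus distributions through the function
#' chain, giving the exact finite distribution of the liability: the
#' probability of each output value is the sum, over all input combinations
#' that the chain maps to that value, of the product of the per-locus
#' probabilities. If `prevalence` is supplied, a disease threshold is
#' selected with [select_threshold()].
#'
#' @param model A [hierarchy_model()].
#' @param prevalence Optional target disease prevalence in (0, 1).
#' @return An object of class `liability_dist` with elements `dist` (a
#'   [discrete_dist()] tibble), and, when `prevalence` is given, `threshold`
#'   (disease is liability >= threshold), `achieved_prevalence` and
#'   `target_prevalence`.
#' @examples
#' ld <- liability_distribution(hierarchy_model("ADD"), prevalence = 0.1)
#' ld$threshold
#' @export
liability_distribution <- function(model, prevalence = NULL) {
  stopifnot(inherits(model, "hierarchy_model"))
  d <- model$loci$TF1
  for (i in 1:6) {
    d <- fn_push(model$functions[[i]], d, model$loci[[.chain_operands[i]]],
                 slot = paste0("f", i))
  }
  out <- list(dist = d, threshold = NULL, achieved_prevalence = NULL,
              target_prevalence = prevalence)
  if (!is.null(prevalence)) {
    th <- select_threshold(d, prevalence)
    out$threshold <- th$threshold
    out$achieved_prevalence <- th$achieved_prevalence
  }
  structure(out, class = "liability_dist")
}

#' @export
print.liability_dist <- function(x, ...) {
  cat("Exact liability distribution: ", nrow(x$dist), " support values in [",
      min(x$dist$value), ", ", max(x$dist$value), "]\n", sep = "")
  if (!is.null(x$threshold)) {
    cat("  disease threshold: liability >= ", x$threshold,
        " (achieved prevalence ", signif(x$achieved_prevalence, 4),
        ", target ", x$target_prevalence, ")\n", sep = "")
  }
  invisible(x)
}

#' Select a disease threshold for a target prevalence
#'
#' Disease corresponds to the upper tail of the liability distribution.
#' Among the support values `t` (excluding the minimum, whose tail
#' probability is 1 and therefore yields no two-class split), the threshold
#' chosen is the one whose achieved prevalence `P(X >= t)` is closest to the
#' target; ties are broken toward the smaller achieved prevalence.
#'
#' @param dist A [discrete_dist()] tibble.
#' @param target_prevalence Target prevalence in (0, 1).
#' @return List with `threshold` and `achieved_prevalence`.
#' @examples
#' select_threshold(discrete_dist(0:1, c(0.9, 0.1)), 0.1)
#' @export
select_threshold <- function(dist, target_prevalence) {
  stopifnot(is_discrete_dist(dist))
  if (!(target_prevalence > 0 && target_prevalence < 1)) {
    stop("`target_prevalence` must be strictly between 0 and 1.", call. = FALSE)
  }
  if (nrow(dist) < 2) {
    stop("Degenerate liability distribution: no threshold achieves a ",
         "two-class split.", call. = FALSE)
  }
  # tail probabilities P(X >= t) for each support value t, by decreasing t
  o <- order(dist$value, decreasing = TRUE)
  tail_p <- cumsum(dist$prob[o])
  cand_t <- dist$value[o]
  keep <- cand_t > min(dist$value) # exclude the all-case split
  cand_t <- cand_t[keep]
  tail_p <- tail_p[keep]
  dd <- abs(tail_p - target_prevalence)
  # candidates are ordered by increasing tail_p (decreasing t), so the first
  # minimiser has the smaller achieved prevalence
  i <- which.min(dd)
  list(threshold = cand_t[i], achieved_prevalence = tail_p[i])
}

#' @rdname liability_distribution
#' @param object A `liability_dist`.
#' @param ... Unused.
#' @method autoplot liability_dist
#' @export
autoplot.liability_dist <- function(object, ...) {
  p <- ggplot2::ggplot(object$dist, ggplot2::aes(x = .data$value, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey35", width = 0.8) +
    ggplot2::labs(x = "liability", y = "probability")
  if (!is.null(object$threshold)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$threshold - 0.5, linetype = "dashed", colour = "red"
    ) +
      ggplot2::labs(
        subtitle = sprintf(
          "disease: liability >= %s (prevalence %.4g)",
          format(object$threshold), object$achieved_prevalence
        )
      )
  }
  p
}
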