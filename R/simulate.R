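# Population simulation, case-control sampling, noise SNPs and the
# tab-delimited dataset format of the MDR software family.

with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# reproducible stream of derived seeds, all < 2^31
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(withr::with_seed(as.integer(seed), sample.int(2^31 - 2, n)))
}

#' Simulate a population from a hierarchical liability model
#'
#' Draws `n` subjects i.i.d. from the locus distributions, evaluates the
#' liability chain for each, and assigns disease status by comparing the
#' liability with the threshold selected on the *exact* liability
#' distribution (never re-estimated from the sample).
#'
#' @param model A [hierarchy_model()].
#' @param n Population size.
#' @param prevalence Target disease prevalence in (0, 1); the achieved
#'   prevalence is the closest value the discrete distribution admits.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per subject: the seven locus columns,
#'   `liability` and `status` (1 = case). Attributes `threshold` and
#'   `achieved_prevalence` record the disease definition.
#' @examples
#' pop <- simulate_population(hierarchy_model("ADD"), 1000, seed = 1)
#' mean(pop$status)
#' @export
simulate_population <- function(model, n, prevalence = 0.1, seed = NULL) {
  stopifnot(inherits(model, "hierarchy_model"), n >= 1)
  ld <- liability_distribution(model, prevalence = prevalence)
  pop <- with_seed_(seed, {
    cols <- lapply(model$loci, function(d) {
      sample(d$value, n, replace = TRUE, prob = d$prob)
    })
    tibble::as_tibble(cols)
  })
  pop$liability <- liability(model, pop)
  pop$status <- as.integer(pop$liability >= ld$threshold)
  attr(pop, "threshold") <- ld$threshold
  attr(pop, "achieved_prevalence") <- ld$achieved_prevalence
  pop
}

#' Sample a case-control dataset from a simulated population
#'
#' Samples without replacement within each status class. The environmental
#' factor, the liability and the status-defining threshold are dropped from
#' the output, mimicking a genetic study in which only genotypes are
#' measured; the six functional genotype columns are retained and a final
#' `Class` column holds the 0/1 control/case label.
#'
#' @param population Output of [simulate_population()].
#' @param n_cases,n_controls Requested class sizes.
#' @param seed Optional integer seed.
#' @return A tibble of `n_cases + n_controls` rows (cases first) with the six
#'   genotype columns and `Class`.
#' @export
sample_case_control <- function(population, n_cases, n_controls, seed = NULL) {
  stopifnot(n_cases >= 0, n_controls >= 0)
  cases <- which(population$status == 1)
  controls <- which(population$status == 0)
  if (length(cases) < n_cases || length(controls) < n_controls) {
    stop(
      "Population has ", length(cases), " cases and ", length(controls),
      " controls; cannot sample ", n_cases, " cases and ", n_controls,
      " controls.",
      call. = FALSE
    )
  }
  idx <- with_seed_(seed, c(
    cases[sample.int(length(cases), n_cases)],
    controls[sample.int(length(controls), n_controls)]
  ))
  out <- population[idx, .locus_names[1:6]]
  attr(out, "threshold") <- NULL
  attr(out, "achieved_prevalence") <- NULL
  out$Class <- rep(c(1L, 0L), c(n_cases, n_controls))
  out
}

#' Append unassociated noise SNPs to a dataset
#'
#' Each added SNP gets a minor-allele frequency drawn uniformly from
#' `maf_range` and genotypes (minor-allele counts 0/1/2) drawn under
#' Hardy-Weinberg equilibrium, independently of disease status.
#'
#' @param dataset A case-control tibble with a final `Class` column.
#' @param k Number of SNPs to add (0 returns the dataset unchanged).
#' @param maf_range Length-2 numeric, `0 < low <= high <= 0.5`.
#' @param seed Optional integer seed.
#' @return The dataset with `k` columns `N1..Nk` inserted before `Class`.
#' @export
add_noise_snps <- function(dataset, k, maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot("Class" %in% names(dataset), k >= 0)
  if (k == 0) return(dataset)
  if (length(maf_range) != 2 || maf_range[1] <= 0 ||
      maf_range[1] > maf_range[2] || maf_range[2] > 0.5) {
    stop("`maf_range` must satisfy 0 < low <= high <= 0.5.", call. = FALSE)
  }
  n <- nrow(dataset)
  snps <- with_seed_(seed, {
    maf <- stats::runif(k, maf_range[1], maf_range[2])
    cols <- lapply(maf, function(p) {
      sample(0:2, n, replace = TRUE,
             prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    })
    stats::setNames(cols, paste0("N", seq_len(k)))
  })
  dplyr::bind_cols(
    dataset[setdiff(names(dataset), "Class")],
    tibble::as_tibble(snps),
    dataset["Class"]
  )
}

#' Write / read a case-control dataset in MDR text format
#'
#' The format is tab-delimited text with a header row of variant names
#' followed by a final `Class` column, one subject per row; the de-facto
#' input format of the MDR software family. Writing then reading is
#' lossless, and a fixed dataset always produces byte-identical files.
#'
#' @param dataset A case-control tibble (genotype columns plus `Class`).
#' @param path File path.
#' @return `write_mdr` returns `path` invisibly; `read_mdr` returns the
#'   dataset as a tibble of integer columns.
#' @export
write_mdr <- function(dataset, path) {
  stopifnot(names(dataset)[ncol(dataset)] == "Class")
  lines <- c(
    paste(names(dataset), collapse = "\t"),
    do.call(paste, c(unname(as.list(dataset)), sep = "\t"))
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname write_mdr
#' @export
read_mdr <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!"Class" %in% names(d) || names(d)[ncol(d)] != "Class") {
    stop("Malformed dataset file: final column must be 'Class'.", call. = FALSE)
  }
  out <- d
  for (j in names(d)) {
    v <- suppressWarnings(as.integer(d[[j]]))
    bad <- which(is.na(v) | (j != "Class" & !(v %in% 0:2)) |
                   (j == "Class" & !(v %in% 0:1)))
    if (length(bad)) {
      stop(
        "Invalid value ", sQuote(d[[j]][bad[1]]), " in column ", sQuote(j),
        " at line ", bad[1] + 1L, " of ", path,
        " (genotypes must be 0/1/2, Class must be 0/1).",
        call. = FALSE
      )
    }
    out[[j]] <- v
  }
  out
}
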