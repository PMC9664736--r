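#' Describe the chromosomes a constraint model is built over
#'
#' A genome configuration records the chromosomes in play, their lengths,
#' whether each is autosomal or the X chromosome, and the pseudoautosomal
#' regions (PAR) on X. Constraint is modeled separately for autosomes and
#' for X (whose hemizygosity changes the observable variation), and PAR
#' intervals -- which recombine with Y and behave autosomally -- are
#' excluded from the X model. The Y chromosome is never modeled.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Integer vector of chromosome lengths (bases), parallel to
#'   `chrom`.
#' @param chrom_class Optional character vector, `"autosome"` or `"X"` per
#'   chromosome. Defaults to `"X"` for names ending in `"X"`, autosome
#'   otherwise. Names ending in `"Y"` are rejected.
#' @param par Optional tibble with columns `start`, `end` giving 0-based
#'   half-open PAR intervals on the X chromosome.
#' @param build Free-text genome build label carried into output manifests.
#'
#' @return An object of class `genome_config`: a list with a `chroms`
#'   tibble (`chrom`, `length`, `chrom_class`), a `par` tibble and the
#'   `build` label.
#' @export
genome_config <- function(chrom, length, chrom_class = NULL, par = NULL,
                          build = "synthetic") {
  stopifnot(is.character(chrom), base::length(chrom) == base::length(length))
  if (anyDuplicated(chrom) > 0) {
    rlang::abort("duplicated chromosome names in genome configuration")
  }
  if (any(grepl("Y$", chrom))) {
    rlang::abort("the Y chromosome is excluded from constraint modeling; drop it before building a genome_config")
  }
  if (is.null(chrom_class)) {
    chrom_class <- ifelse(grepl("X$", chrom), "X", "autosome")
  }
  stopifnot(all(chrom_class %in% c("autosome", "X")))
  chroms <- tibble::tibble(
    chrom = chrom,
    length = as.integer(length),
    chrom_class = chrom_class
  )
  if (any(chroms$length <= 0L)) rlang::abort("chromosome lengths must be positive")
  if (is.null(par)) {
    par <- tibble::tibble(start = integer(), end = integer())
  }
  par <- tibble::as_tibble(par)
  if (nrow(par) > 0) {
    if (!any(chroms$chrom_class == "X")) {
      rlang::abort("PAR intervals supplied but no X chromosome declared")
    }
    x_len <- chroms$length[chroms$chrom_class == "X"][1]
    stopifnot(all(par$end > par$start), all(par$start >= 0), all(par$end <= x_len))
    ord <- order(par$start)
    par <- par[ord, ]
    if (nrow(par) > 1 && any(par$start[-1] < par$end[-nrow(par)])) {
      rlang::abort("PAR intervals overlap each other")
    }
  }
  structure(
    list(chroms = chroms, par = par, build = build),
    class = "genome_config"
  )
}

#' @export
print.genome_config <- function(x, ...) {
  cat("<genome_config> build:", x$build, "\n")
  print(x$chroms)
  if (nrow(x$par) > 0) {
    cat("PAR intervals on X:\n")
    print(x$par)
  }
  invisible(x)
}

chrom_class_of <- function(genome, chrom) {
  cls <- genome$chroms$chrom_class[match(chrom, genome$chroms$chrom)]
  if (anyNA(cls)) {
    rlang::abort(paste0(
      "chromosome(s) absent from genome configuration: ",
      paste(unique(chrom[is.na(cls)]), collapse = ", ")
    ))
  }
  cls
}
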