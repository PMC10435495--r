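#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm phyper fisher.test p.adjust quantile median sd
#'   rnorm runif rmultinom setNames
#' @importFrom utils read.table write.table
#' @importFrom methods is
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-artifact child seed from a single root seed
#'
#' All generators in the synthetic-data module draw their randomness from a
#' child seed computed by a fixed schedule, so adding a new generator never
#' perturbs the artifacts produced by earlier ones. Child seeds stay within
#' the 32-bit signed integer range.
#'
#' @param seed Integer root seed.
#' @param artifact One of `"universe"`, `"de"`, `"sequences"`, `"ct"`,
#'   `"transcriptome"`, `"radial"`, `"chromatogram"`, `"fractions"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "de")
child_seed <- function(seed, artifact) {
  offsets <- c(universe = 1, de = 2, sequences = 3, ct = 4,
               transcriptome = 5, radial = 6, chromatogram = 7, fractions = 8)
  artifact <- match.arg(artifact, names(offsets))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # multiplicative hash mod a Mersenne prime keeps children well separated
  as.integer((abs(as.double(seed)) * 48271 + offsets[[artifact]] * 16807) %%
               2147483647) + 1L
}

# Normalise a character vector of gene identifiers: strip whitespace,
# collapse duplicates with a warning (identifiers compared case-sensitively).
clean_ids <- function(x, what = "gene set") {
  x <- trimws(as.character(x))
  x <- x[nzchar(x)]
  if (anyDuplicated(x)) {
    warning(sprintf("duplicate identifiers in %s collapsed (%d removed)",
                    what, sum(duplicated(x))), call. = FALSE)
    x <- unique(x)
  }
  x
}

stop_invalid <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
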