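#' Convert concentrations to molar
#'
#' All internal computations in this package are carried out in molar units;
#' efficiency in particular is unit-sensitive because it is a ratio of
#' logarithms referenced to a 1 M standard state.  File readers and
#' user-facing helpers therefore require an explicit unit declaration and
#' convert on ingest rather than guessing.
#'
#' @param x numeric vector of concentrations.
#' @param unit character; one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`
#'   (the micro sign spellings `"µM"`/`"μM"` are accepted).
#'   Either a single unit for all values or one per value.
#' @return numeric vector in molar.
#' @examples
#' to_molar(174, "uM")
#' to_molar(c(29, 140), "nM")
#' @export
to_molar <- function(x, unit) {
  if (missing(unit)) stop("concentration unit must be declared explicitly")
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  unit <- gsub("µ|μ", "u", unit)
  if (!all(unit %in% names(scale))) {
    bad <- setdiff(unique(unit), names(scale))
    stop("unknown concentration unit: ", paste(bad, collapse = ", "))
  }
  if (!(length(unit) == 1L || length(unit) == length(x)))
    stop("'unit' must have length 1 or length(x)")
  x * unname(scale[unit])
}

# internal: positivity / domain guards used throughout
check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("'", name, "' must be strictly positive and finite (got ",
         paste(utils::head(signif(x, 6), 3), collapse = ", "), ")",
         call. = FALSE)
  invisible(x)
}

check_probability <- function(x, name, open = TRUE) {
  bad <- !is.finite(x) | if (open) x <= 0 | x >= 1 else x < 0 | x > 1
  if (any(bad))
    stop("'", name, "' must lie ", if (open) "strictly inside (0, 1)"
         else "in [0, 1]", " (got ",
         paste(signif(x[bad][seq_len(min(3, sum(bad)))], 6), collapse = ", "),
         ")", call. = FALSE)
  invisible(x)
}

# internal: evaluate expr with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
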