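# Shared constants and small helpers.

# Elementary charge in coulomb (CODATA exact value).
.ELEMENTARY_CHARGE <- 1.602176634e-19

#' Bondi van der Waals radii by element
#'
#' Radii (Angstrom) assigned to atoms on structure read, used by the pore
#' profiler and the SASA module.  The set follows Bondi's compilation with
#' the common extension for potassium; unknown elements raise an error at
#' read time rather than defaulting silently.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' bondi_radii()[["O"]]
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, K = 2.75,
    MG = 1.73, CA = 2.31, ZN = 1.39, FE = 2.05)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Write a data.frame as TSV with a header line; units belong in the
# column names (e.g. "min_distance_A", "time_ns").
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
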