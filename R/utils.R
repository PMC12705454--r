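#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Round half away from zero (the convention of printed clinical tables,
#' where e.g. 28.65 -> 28.7), to `digits` decimals.
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_prob_vector <- function(p, name, tol = 1e-8) {
  stop_if(any(!is.finite(p)) || any(p < 0) || any(p > 1),
          sprintf("'%s' must contain probabilities in [0, 1]", name))
  stop_if(abs(sum(p) - 1) > tol,
          sprintf("'%s' must sum to 1 (got %.6f)", name, sum(p)))
  invisible(p)
}

#' Validate an expression matrix: numeric genes x samples with unique,
#' non-missing dimnames and finite values.
#' @noRd
check_expression <- function(x, min_samples = 2) {
  stop_if(!is.matrix(x) || !is.numeric(x), "expression must be a numeric matrix")
  stop_if(is.null(rownames(x)) || is.null(colnames(x)),
          "expression must have gene rownames and sample colnames")
  stop_if(anyDuplicated(rownames(x)) > 0, "duplicate gene ids")
  stop_if(anyDuplicated(colnames(x)) > 0, "duplicate sample ids")
  stop_if(any(!is.finite(x)), "expression contains non-finite values")
  stop_if(ncol(x) < min_samples,
          sprintf("need at least %d samples", min_samples))
  invisible(x)
}
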