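# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent child seeds from a master seed
#'
#' A single master seed spawns one child seed per iteration so that repeated
#' sweeps are both reproducible and mutually independent.
#'
#' @param master_seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# First calendar year of an age-decade label such as "40-49".
decade_start <- function(decade) {
  suppressWarnings(as.numeric(sub("[^0-9].*$", "", as.character(decade))))
}

# Validate a single non-negative count.
check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be an integer >= %s (got %s)", name, min,
                 paste(x, collapse = ",")), call. = FALSE)
  }
  as.integer(x)
}
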