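# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stop_if <- function(cond, msg, call. = FALSE) {
  if (isTRUE(cond)) stop(msg, call. = call.)
  invisible(NULL)
}

#' @keywords internal
#' @noRd
check_prob <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          sprintf("`%s` must be a single probability in [0, 1]", name))
  invisible(x)
}

#' @keywords internal
#' @noRd
check_count <- function(x, name, min = 1L) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
            x != round(x),
          sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Derive a stream-specific RNG seed from a master seed; keeps results
# independent across generators while remaining a pure function of the
# master seed.  Constant kept small so seed + offset stays < 2^31.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  offs <- c(landscape = 101L, coverage = 211L, genotypes = 307L,
            expression = 401L, ltr = 503L, pipeline = 601L)
  stopifnot(stream %in% names(offs))
  (as.integer(seed) %% 2000000000L) + offs[[stream]]
}

# Dosage class labels: copies of CC : copies of EE at a tetraploid locus.
DOSAGE_LEVELS <- c("4:0", "3:1", "2:2", "1:3", "0:4")

#' @keywords internal
#' @noRd
dosage_copies <- function(dosage) {
  m <- matrix(c(4L, 0L, 3L, 1L, 2L, 2L, 1L, 3L, 0L, 4L),
              ncol = 2L, byrow = TRUE,
              dimnames = list(DOSAGE_LEVELS, c("cc", "ee")))
  stop_if(!all(dosage %in% DOSAGE_LEVELS),
          sprintf("dosage must be one of: %s",
                  paste(DOSAGE_LEVELS, collapse = ", ")))
  m[dosage, , drop = FALSE]
}
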