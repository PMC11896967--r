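`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar positive / non-negative checks used by constructors
.check_num <- function(x, name, min = -Inf, max = Inf, len = NULL) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  if (!is.null(len) && length(x) != len)
    stop(sprintf("'%s' must have length %d", name, len), call. = FALSE)
  if (any(x < min) || any(x > max))
    stop(sprintf("'%s' must lie in [%s, %s]", name, min, max), call. = FALSE)
  invisible(x)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# set the RNG only when a seed is supplied; otherwise draw from the
# current stream so that one top-level seed governs a whole run
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
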