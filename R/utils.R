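# Internal helpers shared across modules.

# round() in R rounds half to even; prevalence tables use the conventional
# "half away from zero" rendering.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Stop with a message assembled from parts, without the call.
stop_cpep <- function(...) {
  rlang::abort(paste0(...), class = "cpepgrs_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cpep("`", name, "` must be a single finite number.")
  }
  if (x < lower || x > upper || (strict_upper && x >= upper)) {
    stop_cpep("`", name, "` = ", x, " is outside the allowed range [",
              lower, ", ", upper, if (strict_upper) ")" else "]", ".")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x)) stop_cpep("`", name, "` must be a whole number.")
  invisible(as.integer(x))
}

# Collapse a character vector for error messages, truncating long lists.
fmt_ids <- function(ids, max = 10L) {
  if (length(ids) > max) {
    paste0(paste(head(ids, max), collapse = ", "), ", ... (",
           length(ids), " total)")
  } else {
    paste(ids, collapse = ", ")
  }
}

# Derive a stream-specific seed from a base seed; keeps values < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1009) %% 2147483647)
}
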