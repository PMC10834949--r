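# internal helpers: argument checks and seed plumbing

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    abort(sprintf("`%s` must be a non-missing numeric value.", name))
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    cmp <- if (strict_lower) ">" else ">="
    abort(sprintf("`%s` must be %s %g and <= %g.", name, cmp, lower, upper))
  }
  invisible(x)
}

check_columns <- function(data, cols, name = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Deterministic stage/sub-seed derivation: one user seed fans out to
# per-stage seeds so subset runs reproduce full-run results. Kept below
# 2^31 - 1 so the result is a valid integer seed.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 69069 + h * 2654435) %% 2147483629)
}
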