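# internal helpers shared across modules

# overflow-safe log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# normalize unicode minus signs (en dash, minus sign, hyphen variants) that
# appear in pasted numeric tables, then parse as double
normalize_minus <- function(x) {
  gsub("‒|–|—|−", "-", x)
}

parse_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(as.numeric(normalize_minus(trimws(as.character(x)))))
}

abort_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "solcycle_domain_error")
}

abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "solcycle_validation_error")
}

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "solcycle_config_error")
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    bad <- x[!is.finite(x) | x <= 0][1]
    abort_domain("`%s` must be strictly positive and finite (got %s)", name, format(bad))
  }
  invisible(x)
}

check_finite <- function(x, name) {
  if (any(!is.finite(x))) {
    abort_domain("`%s` must be finite", name)
  }
  invisible(x)
}
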