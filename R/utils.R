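# internal helpers shared across modules

# Deterministic 31-bit seed derived from a base seed plus string labels, so
# per-pair randomness (PRESSO resampling, weighted-median bootstrap) is
# reproducible and independent of pair enumeration order.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad_arg <- function(msg) rlang::abort(msg, class = "mrscreen_error")

assert_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop_bad_arg(sprintf(
      "`%s` must be a single number in %s0, 1%s, got %s",
      name, if (open_left) "(" else "[", if (open_right) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

two_sided_normal_p <- function(z) 2 * stats::pnorm(-abs(z))

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  out <- DNA_COMPLEMENT[toupper(a)]
  out[is.na(out)] <- NA_character_
  unname(out)
}

is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 %in% names(DNA_COMPLEMENT)) & !is.na(a2) & complement_allele(a1) == a2
}
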