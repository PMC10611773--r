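#' @keywords internal
"_PACKAGE"

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when a == b
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp requires a >= b", call. = FALSE)
  if (b == a) return(-Inf)
  a + log1p(-exp(b - a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrbridge <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrbridge_error")))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(COMPLEMENT[x])

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
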