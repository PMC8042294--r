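# internal validation / small-numerics helpers

`%||%` <- rlang::`%||%`

stop_bad_config <- function(msg) {
  abort(msg, class = "mireqtl_config_error")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_bad_config(sprintf("`%s` must be a single finite number in [%s, %s]",
                            name, format(lower), format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x != as.integer(x)) {
    stop_bad_config(sprintf("`%s` must be an integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}

# Storey q-values with a fixed pi0 tuning parameter. Kept deliberately simple:
# pi0 is estimated at a single lambda and the step-up is BH scaled by pi0.
storey_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pi0 <- max(pi0, 1 / m)
  pmin(1, pi0 * p.adjust(p, method = "BH"))
}

adjust_pvalues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (method == "BH") p.adjust(p, method = "BH") else storey_qvalue(p)
}

# p-value for a heritability LRT at the boundary: 50:50 mixture of a point
# mass at zero and chi-square(1), or a plain chi-square(1) reference.
lrt_pvalue <- function(lrt, null_dist = c("mixture", "chisq1")) {
  null_dist <- match.arg(null_dist)
  p <- if (null_dist == "mixture") {
    ifelse(lrt <= 0, 1, 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE))
  } else {
    ifelse(lrt <= 0, 1, pchisq(lrt, df = 1, lower.tail = FALSE))
  }
  pmin(p, 1)
}
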