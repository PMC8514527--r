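# shared internal helpers and canonical factor levels

RCP_LEVELS <- c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5")
PERIOD_LEVELS <- c("mid", "end")
GLOBAL_ID <- "GLOBAL"
MONTH_COLS <- sprintf("t%02d", 1:12)

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_climmort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort_climmort("%s is missing required column(s): %s",
                   what, paste(miss, collapse = ", "))
  }
  invisible(df)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_climmort("'%s' must be a single finite number", name)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) ||
      x > upper) {
    abort_climmort("'%s' = %g is outside its valid range", name, x)
  }
  invisible(x)
}

# two-sided p-value and conventional significance stars on a t reference
p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01  ~ "**",
    p < 0.05  ~ "*",
    TRUE      ~ ""
  )
}

# quantile of the CI reference distribution: standard normal, or t on
# `df` degrees of freedom (G - 1 for G clusters)
ci_quantile <- function(level, quantile = c("z", "t"), df = Inf) {
  quantile <- match.arg(quantile)
  if (level <= 0 || level >= 1) {
    abort_climmort("confidence level must be strictly between 0 and 1")
  }
  p <- (1 + level) / 2
  if (quantile == "z") qnorm(p) else qt(p, df = df)
}
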