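# Internal helpers shared across modules.

# Evaluate `expr` with a temporarily seeded RNG, restoring any prior
# .Random.seed afterwards so package functions never leak RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if
      (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Stage-tagged message on stderr; suppressible via option.
log_msg <- function(stage, ...) {
  if (isTRUE(getOption("epiremod.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_missing_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, colnames(df))
  if (length(miss) > 0L)
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false discovery rate adjustment. Reimplemented explicitly (rather
#' than delegating to \code{stats::p.adjust}) so the monotone step-up
#' construction is part of the tested surface; agreement with
#' \code{p.adjust(method = "BH")} is asserted in the test suite.
#'
#' @param p numeric vector of p-values in (0, 1]; NAs are propagated.
#' @return numeric vector of adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0L) return(q)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(pv[o] * m / seq(m, 1L)))[ro]
  q
}
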