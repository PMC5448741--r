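# internal RNG and validation helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so package functions never
# disturb the user's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' All stochastic stages of the pipeline (cohort generation, bootstrap
#' standard errors, bootstrap AUC tests, model comparison) draw their own
#' seed from one master seed plus a stage tag, so any stage can be re-run
#' in isolation with the exact random stream it saw inside the pipeline.
#' The derivation is a 31-adic string hash of the tag folded into the
#' master seed modulo the Mersenne prime 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param tag Character stage label, e.g. `"rank"` or `"auc_k6"`.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1, is.finite(master), length(tag) == 1)
  m <- 2147483647
  h <- as.double(master) %% m
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Truncated normal draws via inverse-CDF; vectorized over mean.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_binary_labels <- function(labels) {
  if (anyNA(labels)) stop_domain("labels contain NA")
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) stop_domain("labels must be coded 0/1")
  if (length(u) < 2) stop_domain("both label classes must be present")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
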