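#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

#' Default node labels for the seven analysis variables
#'
#' Five visual-analog EMA items (0-100), one 7-point Likert item for the
#' duration of the last social contact, and the actigraphy-derived
#' physical-activity summary (mean ENMO, milligravity).
#'
#' @return Character vector of length 7.
#' @export
ema_nodes <- function() {
  c("loneliness", "worry", "restriction", "info_seeking",
    "social_contact", "stress", "physical_activity")
}
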