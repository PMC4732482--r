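# Internal helpers: classed error conditions and seed handling.

trout_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "troutherm_error")))
}

config_error <- function(msg) trout_error(msg, "troutherm_config_error")
geometry_error <- function(msg) trout_error(msg, "troutherm_geometry_error")
data_error <- function(msg) trout_error(msg, "troutherm_data_error")
design_error <- function(msg) trout_error(msg, "troutherm_design_error")
domain_error <- function(msg) trout_error(msg, "troutherm_domain_error")
param_error <- function(msg) trout_error(msg, "troutherm_parameter_error")
io_error <- function(msg) trout_error(msg, "troutherm_io_error")

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# seed = NULL means "consume the current RNG stream" so that composite
# simulations can be driven by a single top-level seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Lognormal meanlog/sdlog such that the distribution has the requested
# arithmetic mean and coefficient of variation.
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
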