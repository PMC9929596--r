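# Shared test helpers: random valid parameter draws and small utilities.

# Random strictly positive parameter set with a guaranteed positive-fat
# steady state (aF*umax > gammaE).
random_op_params <- function(n = Inf) {
  repeat {
    q <- list(aF = exp(stats::runif(1, -4, 0)),
              gammaF = exp(stats::runif(1, -4, 0)),
              gammaE = exp(stats::runif(1, -5, -1)),
              aL = exp(stats::runif(1, -1, 1)),
              gammaL = exp(stats::runif(1, -1, 1)),
              KL = exp(stats::runif(1, -2, 2)),
              umax = exp(stats::runif(1, -1, 2)),
              n = n)
    if (q$aF * q$umax > q$gammaE) return(validate_op_params(q))
  }
}

# Replace named fields of an op_params object and revalidate.
tweak_params <- function(p, ...) {
  validate_op_params(utils::modifyList(as.list(p), list(...)))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)
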