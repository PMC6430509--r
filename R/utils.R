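## Internal helpers shared across modules.

#' @importFrom methods is new validObject slot
#' @importFrom stats coef confint cor fitted lm p.adjust pt qt resid
#'   rgamma rmultinom rnorm runif sd setNames predict var
NULL

## Classed condition so callers/tests can catch specific failure modes,
## e.g. expect_error(..., class = "zeroOrNegativePartError").
sbiError <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "soilSBIError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Geometric mean in log space; x must be strictly positive.
gmean <- function(x) exp(mean(log(x)))

is_wholenumber <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

## Relative closure tolerance used throughout.
CLOSURE_TOL <- 1e-9
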