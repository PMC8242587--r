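#' @importFrom rlang %||% .data
#' @importFrom stats cor cor.test median p.adjust quantile rbeta rexp rgamma
#'   rlnorm rnorm rpois sd var
NULL

# stop() wrapper that keeps call noise out of user-facing errors
abort_ip <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Dirichlet draws, one column per sample
rdirichlet_cols <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha), nrow = k)
  sweep(g, 2, colSums(g), "/")
}

# columnwise z-score guard: returns NA sd columns untouched flagging
safe_scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  list(z = (m - mu) / s, sd = s, mean = mu)
}
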