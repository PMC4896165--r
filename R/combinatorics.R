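#' Count graphical log-linear models on P factors
#'
#' With the intercept and all main effects always present, a graphical model
#' is determined by its undirected graph, so the model space has
#' `2^(P(P-1)/2)` members.
#'
#' @param P Number of factors (at least 1).
#' @param exact If `TRUE`, return the exact integer as a decimal character
#'   string (arbitrary precision); otherwise a double, which is itself exact
#'   for every `P` with `P(P-1)/2 <= 1023` because the value is a power of
#'   two.
#' @return A double, or a character string when `exact = TRUE`.
#' @examples
#' count_graphical_models(6)   # 32768
#' count_graphical_models(10)  # 2^45
#' @export
count_graphical_models <- function(P, exact = FALSE) {
  if (length(P) != 1 || is.na(P) || P < 1 || P != floor(P)) {
    abort("`P` must be a single integer >= 1")
  }
  H <- P * (P - 1) / 2
  if (exact) return(big_pow2(H))
  2^H
}

#' Count the cells of a contingency table
#'
#' @param spec A [factor_spec()] (or bare integer vector of level counts).
#' @param exact If `TRUE`, return the exact product as a decimal string.
#' @return A double (`prod(M_p)`), or a character string when `exact = TRUE`.
#' @examples
#' count_cells(factor_spec(LETTERS[1:10], 2))  # 1024
#' @export
count_cells <- function(spec, exact = FALSE) {
  m <- as.integer(spec)
  if (length(m) < 1 || any(is.na(m)) || any(m < 2)) {
    abort("spec must give at least one factor with >= 2 levels")
  }
  if (exact) return(big_prod(m))
  prod(as.numeric(m))
}

# ---- minimal exact decimal arithmetic (digit vectors, least significant
# first); only multiplication by small integers is ever needed ----

big_mul_small <- function(d, m) {
  x <- d * m
  carry <- 0
  for (i in seq_along(x)) {
    x[i] <- x[i] + carry
    carry <- x[i] %/% 10
    x[i] <- x[i] %% 10
  }
  while (carry > 0) {
    x <- c(x, carry %% 10)
    carry <- carry %/% 10
  }
  x
}

big_to_string <- function(d) paste(rev(d), collapse = "")

big_pow2 <- function(k) {
  d <- 1
  if (k > 0) for (i in seq_len(k)) d <- big_mul_small(d, 2)
  big_to_string(d)
}

big_prod <- function(ms) {
  d <- 1
  for (m in ms) d <- big_mul_small(d, m)
  big_to_string(d)
}
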