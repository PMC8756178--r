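#' Multi-instance pooling of micro-pKa values
#'
#' A molecule is a "bag" of ionizable atoms ("instances"). Only the
#' molecule-level macro-pKa is observable, but it is tied to the per-site
#' micro-pKa values by an exact algebra: the most-acidic macro-pKa is
#' \deqn{pKa = -\log_{10} \sum_{i \in P} 10^{-pKa_i}}
#' over the acidic site set P, and the most-basic macro-pKa is
#' \deqn{pKa = \log_{10} \sum_{i \in Q} 10^{pKa_i}}
#' over the basic site set Q. Non-site atoms are masked (+Inf for the acidic
#' model, -Inf for the basic model) so they contribute exactly zero to the
#' sum. These two functions are the bridge that lets a per-atom model be
#' trained against molecule-level labels.
#'
#' The pooled value is always at least as extreme as the most extreme site:
#' `pool_acidic(v) <= min(v)` and `pool_basic(v) >= max(v)`, with equality
#' exactly when the bag has a single site.
#'
#' @param masked a `micro_pka` object from [apply_mask()].
#' @return a `macro_pka` object: list with `value` (finite scalar, or `NA`
#'   with `no_site = TRUE` when the site set is empty), `mode`, and
#'   `contributing_sites` (integer vector of 1-based atom indices).
#' @seealso [apply_mask()], [duality_check()]
#' @examples
#' m <- apply_mask(c(4, 4), sites = 1:2, mode = "acidic")
#' pool_acidic(m)$value  # 4 - log10(2)
#' @name mil_pooling
NULL

#' Mask non-ionizable atoms in a raw per-atom pKa vector
#'
#' Atoms outside the site set are masked with +Inf (acidic) or -Inf (basic),
#' which makes their term \eqn{10^{\mp pKa}} exactly zero in the pooled sum.
#' Internally the pooling skips masked entries rather than exponentiating
#' infinities, which is mathematically identical and keeps gradients clean.
#'
#' @param raw numeric vector of per-atom raw pKa predictions, length N.
#' @param sites integer vector of 1-based site atom indices (the set P or Q).
#' @param mode `"acidic"` or `"basic"`.
#' @return a `micro_pka` object: list with `values` (masked vector), `raw`,
#'   `sites`, `mode`.
#' @export
apply_mask <- function(raw, sites, mode = c("acidic", "basic")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(raw))
  sites <- as.integer(sites)
  if (anyNA(sites) || any(sites < 1L) || any(sites > length(raw)))
    stop("site index out of range 1..", length(raw))
  sites <- sort(unique(sites))
  fill <- if (mode == "acidic") Inf else -Inf
  values <- rep(fill, length(raw))
  values[sites] <- raw[sites]
  structure(
    list(values = values, raw = as.numeric(raw), sites = sites, mode = mode),
    class = "micro_pka"
  )
}

# Shared stable log10-sum-exp: sign = -1 pools acidic (softmin), +1 basic
# (softmax). Shift by the extreme value so every exponent is <= 0; exact for
# the whole pKa range seen in practice (about -10 to 40).
pool_log10sum <- function(v, sign) {
  if (length(v) == 0L) return(NA_real_)
  m <- if (sign < 0) min(v) else max(v)
  m + sign * log10(sum(10^(sign * (v - m))))
}

macro_pka_result <- function(value, mode, sites) {
  structure(
    list(
      value = value,
      mode = mode,
      contributing_sites = sites,
      no_site = length(sites) == 0L
    ),
    class = "macro_pka"
  )
}

#' @rdname mil_pooling
#' @export
pool_acidic <- function(masked) {
  stopifnot(inherits(masked, "micro_pka"))
  if (masked$mode != "acidic") stop("pool_acidic() needs mode = 'acidic'")
  v <- masked$values[masked$sites]
  macro_pka_result(pool_log10sum(v, -1), "acidic", masked$sites)
}

#' @rdname mil_pooling
#' @export
pool_basic <- function(masked) {
  stopifnot(inherits(masked, "micro_pka"))
  if (masked$mode != "basic") stop("pool_basic() needs mode = 'basic'")
  v <- masked$values[masked$sites]
  macro_pka_result(pool_log10sum(v, +1), "basic", masked$sites)
}

#' Pool a plain numeric vector of site micro-pKa values
#'
#' Convenience wrapper used throughout the package when the site bookkeeping
#' is already done: pools all entries of `v` as sites of the given mode.
#'
#' @param v numeric vector of site micro-pKa values (may be empty).
#' @param mode `"acidic"` or `"basic"`.
#' @return scalar macro-pKa, or `NA_real_` for an empty bag.
#' @export
pool_sites <- function(v, mode = c("acidic", "basic")) {
  mode <- match.arg(mode)
  pool_log10sum(as.numeric(v), if (mode == "acidic") -1 else +1)
}

#' Softmin/softmax weight of each site in the pooled macro value
#'
#' The derivative of the macro-pKa with respect to each site's micro-pKa:
#' \eqn{10^{\mp pKa_i} / \sum_j 10^{\mp pKa_j}}. Weights are non-negative and
#' sum to 1; during training they route the learning signal to sites in
#' proportion to their dominance.
#'
#' @param v numeric vector of site micro-pKa values.
#' @inheritParams pool_sites
#' @return numeric vector of weights, same length as `v`.
#' @export
pool_weights <- function(v, mode = c("acidic", "basic")) {
  mode <- match.arg(mode)
  if (length(v) == 0L) return(numeric(0))
  s <- if (mode == "acidic") -1 else +1
  m <- if (s < 0) min(v) else max(v)
  w <- 10^(s * (v - m))
  w / sum(w)
}

#' Verify the sign duality of the two pooling modes
#'
#' Checks numerically that `pool_basic(v) == -pool_acidic(-v)`, a regression
#' guard for the sign convention of the stable pooling.
#'
#' @param v numeric vector of finite micro-pKa values (may be empty).
#' @param tol numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
duality_check <- function(v, tol = 1e-9) {
  b <- pool_sites(v, "basic")
  a <- pool_sites(-v, "acidic")
  if (is.na(b) && is.na(a)) return(TRUE)
  isTRUE(abs(b - (-a)) <= tol)
}

#' @export
print.macro_pka <- function(x, ...) {
  if (x$no_site) {
    cat(sprintf("<macro_pka %s: no ionizable site>\n", x$mode))
  } else {
    cat(sprintf("<macro_pka %s: %.4f over %d site(s)>\n",
                x$mode, x$value, length(x$contributing_sites)))
  }
  invisible(x)
}

#' @export
print.micro_pka <- function(x, ...) {
  cat(sprintf("<micro_pka %s: N=%d, %d site(s)>\n",
              x$mode, length(x$values), length(x$sites)))
  invisible(x)
}
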