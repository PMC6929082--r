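# Internal helpers shared across modules.

#' Root mean square
#' @noRd
rms <- function(x) sqrt(mean(x^2))

#' Population standard deviation (n denominator)
#' @noRd
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Derive a child RNG seed from a master seed and a string tag
#'
#' Deterministic, stays below 2^31 so it is always a valid R integer seed.
#' @noRd
derive_seed <- function(master_seed, tag) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(paste0("#", tag))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Seeded k-fold partition of n items
#'
#' Returns a list of `k` disjoint index vectors covering 1..n.
#' @noRd
make_folds <- function(n, k, seed) {
  stopifnot(n >= k)
  idx <- with_seed(seed, sample.int(n))
  fold_id <- rep_len(seq_len(k), n) # fold sizes within 1 of each other
  unname(split(idx, fold_id))
}

#' Truncated normal draws via inverse-CDF (exact, vectorised)
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- pmin(pmax(mean, lower), upper) # sd == 0 entries collapse to the mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(lower, mean[pos], sd[pos])
    phi <- stats::pnorm(upper, mean[pos], sd[pos])
    out[pos] <- stats::qnorm(runif(sum(pos), plo, phi), mean[pos], sd[pos])
  }
  out
}

#' Assert a scalar finite number
#' @noRd
check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, format(min)))
  }
  invisible(x)
}
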