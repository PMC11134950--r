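#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their spec and do not
#' disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for axial fiber orientations via the
#' angle-doubling trick: sample on the full circle with mean `2*mu` and halve.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0); 0 is uniform on the circle, `Inf`
#'   collapses on `mu`.
#' @return angles in radians, wrapped to `[0, 2*pi)`.
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) {
    return(stats::runif(n, 0, 2 * pi))
  }
  if (is.infinite(kappa)) {
    return(rep(mu %% (2 * pi), n))
  }
  if (kappa > 500) {
    # wrapped-normal limit, sd = 1/sqrt(kappa)
    return((mu + stats::rnorm(n, 0, 1 / sqrt(kappa))) %% (2 * pi))
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      out[i] <- (sign(u3 - 0.5) * acos(f) + mu) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Shift a matrix by whole pixels, padding with a fill value
#' @keywords internal
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr)
  cs <- seq_len(nc)
  r_src <- rs - dr
  c_src <- cs - dc
  rk <- r_src >= 1 & r_src <= nr
  ck <- c_src >= 1 & c_src <= nc
  out[rs[rk], cs[ck]] <- m[r_src[rk], c_src[ck]]
  out
}

#' Eight-neighbour offsets (row, col)
#' @keywords internal
neighbour_offsets <- function() {
  cbind(
    dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
    dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
  )
}

# named-stop helper for invariant checks
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
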