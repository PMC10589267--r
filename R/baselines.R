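# Classical shimming baselines with exact acquisition accounting, and the
# successive-parabolic-interpolation convergence-order experiment.

# wrap either a virtual spectrometer (objective = summed FWHM over
# channels) or a plain function(action) -> value into a counting objective
make_objective <- function(sp) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  env$best_fwhm <- NULL
  if (inherits(sp, "virtual_spectrometer")) {
    env$eval <- function(a) {
      specs <- acquire(sp, a)
      env$count <- env$count + 1L
      fws <- vapply(specs, function(s) {
        w <- try(fwhm(s), silent = TRUE)
        if (inherits(w, "try-error")) NA_real_ else as.numeric(w)
      }, numeric(1))
      if (is.null(env$best_fwhm) ||
          (all(is.finite(fws)) && sum(fws) < sum(env$best_fwhm)))
        env$best_fwhm <- fws
      sum(fws)
    }
  } else if (is.function(sp)) {
    env$eval <- function(a) {
      env$count <- env$count + 1L
      sp(a)
    }
  } else stop("sp must be a virtual_spectrometer or a function")
  env
}

# vertex of the parabola through (x1,f1),(x2,f2),(x3,f3); NA if colinear
# or concave
parabola_vertex <- function(x, f) {
  d21 <- (f[2] - f[1]) / (x[2] - x[1])
  d32 <- (f[3] - f[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])          # half the 2nd derivative
  if (!is.finite(curv) || curv <= 0) return(NA_real_)
  (x[1] + x[2]) / 2 - d21 / (2 * curv)
}

#' Per-shim parabolic-interpolation baseline
#'
#' Sequential one-shim-at-a-time optimization in channel-major order: for
#' every shim, acquire the objective at three bracket offsets, fit a
#' parabola, move the shim to the parabola's minimum, and spend one
#' verification acquisition. The theoretical minimum is `m*n*3` bracket
#' acquisitions plus one check per shim — 48 for two channels of six
#' shims. Shims whose three points are colinear (or fit a concave
#' parabola) are left unchanged and logged as stuck.
#'
#' @param sp a [virtual_spectrometer()] (objective: summed FWHM over both
#'   channels), or a function `action -> value` for analytic stubs.
#' @param brackets either a numeric vector of 3 offsets shared by all
#'   shims, or a matrix `(m*n) x 3` of per-shim bracket offsets (mA,
#'   relative to the current action).
#' @param n_shims number of shims (inferred from a spectrometer).
#' @param start starting action (default zero).
#' @return object of class `baseline_report`: `method`, `acquisitions`,
#'   `theoretical_min`, `best_action`, `best_fwhm` (per channel, when a
#'   spectrometer was used), `stuck` (indices of shims left unchanged),
#'   `objective_trace`.
#' @export
run_parabola_baseline <- function(sp, brackets = c(-10, 0, 10),
                                  n_shims = NULL, start = NULL) {
  if (inherits(sp, "virtual_spectrometer")) n_shims <- sp$m * sp$n
  if (is.null(n_shims)) stop("n_shims required for a function objective")
  if (!is.matrix(brackets))
    brackets <- matrix(rep(brackets, each = n_shims), n_shims, 3)
  stopifnot(nrow(brackets) == n_shims, ncol(brackets) == 3)
  obj <- make_objective(sp)
  a <- if (is.null(start)) numeric(n_shims) else start
  stuck <- integer(0)
  trace <- numeric(0)
  for (j in seq_len(n_shims)) {
    xs <- a[j] + brackets[j, ]
    fs <- vapply(xs, function(x) {
      aj <- a; aj[j] <- x; obj$eval(aj)
    }, numeric(1))
    v <- parabola_vertex(xs, fs)
    if (is.na(v)) {
      stuck <- c(stuck, j)
      trace <- c(trace, min(fs))
      next
    }
    v <- min(max(v, min(xs)), max(xs))      # stay inside the bracket
    a[j] <- v
    trace <- c(trace, obj$eval(a))           # verification acquisition
  }
  structure(list(method = "parabola", acquisitions = obj$count,
                 theoretical_min = 4L * n_shims,
                 best_action = a, best_fwhm = obj$best_fwhm,
                 stuck = stuck, objective_trace = trace),
            class = "baseline_report")
}

#' Nelder-Mead simplex baseline on the joint shim space
#'
#' Standard reflection / expansion / contraction / shrink iterations over
#' all `m*n` shims jointly; the objective is the summed FWHM of both
#' channels. Initialization costs `(m*n) + 1` acquisitions (one per
#' vertex); every subsequent objective evaluation is counted as one
#' acquisition.
#'
#' @param sp spectrometer or analytic objective function.
#' @param init_vertices matrix `(d+1) x d` of initial vertex actions. A
#'   zero-extent polytope is flagged as degenerate and returned without
#'   optimization.
#' @param max_acq acquisition budget (stops when exceeded).
#' @param tol stop when the simplex's objective spread falls below `tol`.
#' @return a `baseline_report` with `degenerate` flag, the best vertex and
#'   the acquisition count (`init_acquisitions` = d + 1 of them).
#' @export
run_simplex_baseline <- function(sp, init_vertices, max_acq = 200,
                                 tol = 1e-8) {
  V <- as.matrix(init_vertices)
  d <- ncol(V)
  stopifnot(nrow(V) == d + 1)
  obj <- make_objective(sp)
  fv <- apply(V, 1, obj$eval)
  init_acq <- obj$count
  degenerate <- max(apply(V, 2, function(col) diff(range(col)))) == 0
  if (!degenerate) {
    al <- 1; ga <- 2; rh <- 0.5; sg <- 0.5
    while (obj$count < max_acq && (max(fv) - min(fv)) > tol) {
      o <- order(fv); V <- V[o, , drop = FALSE]; fv <- fv[o]
      centroid <- colMeans(V[seq_len(d), , drop = FALSE])
      xr <- centroid + al * (centroid - V[d + 1, ])
      fr <- obj$eval(xr)
      if (fr < fv[1]) {
        xe <- centroid + ga * (xr - centroid)
        fe <- obj$eval(xe)
        if (fe < fr) { V[d + 1, ] <- xe; fv[d + 1] <- fe }
        else { V[d + 1, ] <- xr; fv[d + 1] <- fr }
      } else if (fr < fv[d]) {
        V[d + 1, ] <- xr; fv[d + 1] <- fr
      } else {
        xc <- centroid + rh * (V[d + 1, ] - centroid)
        fc <- obj$eval(xc)
        if (fc < fv[d + 1]) { V[d + 1, ] <- xc; fv[d + 1] <- fc }
        else {
          for (i in 2:(d + 1)) {
            V[i, ] <- V[1, ] + sg * (V[i, ] - V[1, ])
            fv[i] <- obj$eval(V[i, ])
          }
        }
      }
    }
  }
  best <- which.min(fv)
  structure(list(method = "simplex", acquisitions = obj$count,
                 init_acquisitions = init_acq,
                 theoretical_min = d + 1L,
                 best_action = V[best, ], best_value = fv[best],
                 best_fwhm = obj$best_fwhm, degenerate = degenerate),
            class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf("<baseline_report> %s: %d acquisitions (theoretical min %d)\n",
              x$method, x$acquisitions, x$theoretical_min))
  invisible(x)
}

#' Successive parabolic interpolation in one dimension
#'
#' Repeatedly fits a parabola through the three most recent points and
#' jumps to its vertex (the oldest point is discarded). Returns the iterate
#' trace. Stops at `maxit`, when two successive iterates coincide, or
#' errors when the three points become colinear (the method's known
#' failure mode).
#'
#' @param f objective function of one variable.
#' @param brackets three starting points.
#' @param maxit maximum iterations.
#' @return numeric vector of iterates.
#' @export
spi_minimize <- function(f, brackets = c(-1, 0.5, 1), maxit = 100) {
  stopifnot(length(brackets) == 3)
  pts <- as.numeric(brackets)
  fv <- vapply(pts, f, numeric(1))
  trace <- numeric(0)
  for (k in seq_len(maxit)) {
    x1 <- pts[1]; x2 <- pts[2]; x3 <- pts[3]
    f1 <- fv[1]; f2 <- fv[2]; f3 <- fv[3]
    denom <- (x2 - x1) * (f2 - f3) - (x2 - x3) * (f2 - f1)
    if (!is.finite(denom) || denom == 0)
      stop("successive parabolic interpolation stalled (colinear points) ",
           "at iteration ", k)
    xn <- x2 - 0.5 * ((x2 - x1)^2 * (f2 - f3) -
                      (x2 - x3)^2 * (f2 - f1)) / denom
    if (!is.finite(xn)) stop("non-finite iterate at iteration ", k)
    trace <- c(trace, xn)
    if (k >= 2 && xn == trace[k - 1]) break
    pts <- c(x2, x3, xn)
    fv <- c(fv[2], fv[3], f(xn))
  }
  trace
}

#' Empirical convergence order of successive parabolic interpolation
#'
#' Runs [spi_minimize()] on a smooth one-dimensional objective and
#' estimates the order q from the error recursion
#' `log e_{k+1} ~ q * log e_k` by a least-squares fit through the origin
#' over the superlinear regime (errors between `regime[1]` and
#' `regime[2]`, strictly decreasing). For objectives with a non-vanishing
#' third derivative at the minimum the estimate is close to the
#' theoretical superlinear order 1.325.
#'
#' The default objective `x^2 + x^3/3` has its minimum exactly at zero
#' (so floating point resolves many superlinear iterations) and
#' `f''' != 0` there. Two degenerate classes are detected and flagged
#' rather than fitted: exactly quadratic objectives (solved by the first
#' parabolic fit) and objectives whose third derivative vanishes at the
#' minimum — symmetric ones such as `cosh`, or flat ones such as `x^4` —
#' which converge with a different order.
#'
#' @param f objective; default `function(x) x^2 + x^3/3`.
#' @param brackets three starting points (default `c(-1, 0.5, 1)`).
#' @param x_star true minimizer; located with [stats::optimize()] at tight
#'   tolerance when NULL.
#' @param regime numeric length-2: error band used for the fit.
#' @param maxit iteration cap.
#' @return list with `order` (NA for flagged degenerate cases), `errors`,
#'   `trace`, `exact_quadratic` flag, and `n_fit` (pairs used).
#' @export
estimate_convergence_order <- function(f = function(x) x^2 + x^3 / 3,
                                       brackets = c(-1, 0.5, 1),
                                       x_star = NULL,
                                       regime = c(1e-30, 1e-2),
                                       maxit = 100) {
  trace <- spi_minimize(f, brackets, maxit)
  if (is.null(x_star)) {
    n <- length(trace)
    if (n >= 2 && abs(trace[n] - trace[n - 1]) < 1e-12) {
      # the sequence converged: its own limit is the sharpest x* available
      x_star <- trace[n]
    } else {
      x_star <- stats::optimize(f, range(c(brackets, trace)),
                                tol = .Machine$double.eps^0.5)$minimum
    }
  }
  e <- abs(trace - x_star)
  exact_quadratic <- length(trace) >= 2 &&
    isTRUE(e[1] <= max(1e-12, 1e-12 * max(abs(brackets))))
  if (exact_quadratic)
    return(list(order = NA_real_, errors = e, trace = trace,
                exact_quadratic = TRUE, n_fit = 0L))
  keep <- e > regime[1] & e < regime[2]
  pair <- which(keep[-length(e)] & keep[-1] & e[-1] < e[-length(e)])
  if (length(pair) < 3)
    return(list(order = NA_real_, errors = e, trace = trace,
                exact_quadratic = FALSE, n_fit = length(pair)))
  lek <- log(e[pair]); lek1 <- log(e[pair + 1])
  q <- sum(lek * lek1) / sum(lek * lek)
  list(order = q, errors = e, trace = trace, exact_quadratic = FALSE,
       n_fit = length(pair))
}
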