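#' Uniform bin grid over the coordination coordinate
#'
#' Even partition of the coordinate into `N` non-overlapping regions of
#' width `ds`, used for the propagator / rate-matrix construction. This is
#' a finer discretisation than the coordination states themselves.
#'
#' @param lower,upper range of s covered by the grid
#' @param ds bin width (used if `n_bins` is NULL)
#' @param n_bins number of bins (>= 3); overrides `ds`
#' @return object of class `bin_grid` with `edges`, `centers`, `ds`
#' @export
bin_grid <- function(lower, upper, ds = 0.1, n_bins = NULL) {
  stopifnot(upper > lower)
  if (is.null(n_bins)) n_bins <- max(3L, round((upper - lower) / ds))
  n_bins <- as.integer(n_bins)
  if (n_bins < 3) stop("need at least 3 bins")
  edges <- seq(lower, upper, length.out = n_bins + 1)
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 ds = (upper - lower) / n_bins),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d bins of width %.4g on [%.3f, %.3f]\n",
              length(x$centers), x$ds, x$edges[1],
              x$edges[length(x$edges)]))
  invisible(x)
}

#' Empirical propagator over a bin grid
#'
#' Column-stochastic matrix of conditional probabilities
#' `P[j, i] = Prob(region j at lag | region i at 0)`, counted from every
#' frame pair `(t, t + lag)` within each trajectory segment. Many short
#' replica segments may be pooled, which is how rare-event regimes are
#' harvested: starting points spread over all bins, independent replicas.
#'
#' @param segments a [coord_series()] or list of them
#' @param grid a [bin_grid()]
#' @param lag lag time, ps; must be an integer multiple of each segment's dt
#' @return object of class `propagator`: list with `grid`, `lag`, `P`
#'   (columns of unsupported bins are NA), `counts`, `supported`
#' @export
estimate_propagator <- function(segments, grid, lag) {
  if (inherits(segments, "coord_series")) segments <- list(segments)
  stopifnot(inherits(grid, "bin_grid"), length(segments) >= 1, lag > 0)
  n <- length(grid$centers)
  counts <- matrix(0, n, n)
  for (seg in segments) {
    stopifnot(inherits(seg, "coord_series"))
    k <- lag / seg$dt
    if (abs(k - round(k)) > 1e-8 * max(1, k)) {
      stop("lag must be an integer multiple of the segment timestep")
    }
    k <- as.integer(round(k))
    m <- length(seg$values)
    if (m <= k) next
    b <- findInterval(seg$values, grid$edges, rightmost.closed = TRUE)
    b[b < 1 | b > n] <- NA
    from <- b[1:(m - k)]
    to <- b[(k + 1):m]
    ok <- !is.na(from) & !is.na(to)
    if (!any(ok)) next
    tab <- table(factor(to[ok], levels = 1:n), factor(from[ok], levels = 1:n))
    counts <- counts + unclass(tab)
  }
  colsum <- colSums(counts)
  supported <- colsum > 0
  P <- counts
  P[, supported] <- sweep(counts[, supported, drop = FALSE], 2,
                          colsum[supported], "/")
  P[, !supported] <- NA
  dimnames(P) <- NULL
  structure(list(grid = grid, lag = lag, P = P, counts = counts,
                 supported = supported),
            class = "propagator")
}

#' @export
print.propagator <- function(x, ...) {
  cat(sprintf("<propagator> %d bins, lag %.4g ps, %d supported columns, %g transitions\n",
              length(x$grid$centers), x$lag, sum(x$supported), sum(x$counts)))
  invisible(x)
}

#' Rate matrix from a propagator by matrix logarithm
#'
#' Inverts `P = exp(lag * R)` for the continuous-time generator `R`
#' (ps^-1, column convention: `R[j, i]` is the i -> j rate, columns sum to
#' zero). The logarithm is taken by eigendecomposition of the propagator
#' restricted to its largest contiguous supported block; the principal
#' branch requires all eigenvalues to have positive real part, which holds
#' when the lag is short enough. Imaginary residue and small negative
#' off-diagonals (statistical noise) are cleaned when below
#' `cleanup_tol` times the dominant off-diagonal scale, then the diagonal is
#' reset so columns sum to zero; larger residue raises an error advising a
#' smaller lag or coarser bins. With well-tuned `ds` and lag the result is
#' essentially tridiagonal; the off-tridiagonal mass fraction is reported as
#' a diagnostic.
#'
#' @param prop a propagator from [estimate_propagator()]
#' @param cleanup_tol residue tolerance as a fraction of the dominant
#'   off-diagonal rate (default 0.05, matching the <= 5 percent
#'   off-tridiagonal mass expected of a tuned discretisation; use a strict
#'   value like 1e-6 for exact analytic propagators)
#' @return object of class `rate_matrix`: list with `R`, `grid`, `lag`,
#'   `bins` (indices of the supported block), `diagnostics` (imag/negative
#'   residue fractions, off-tridiagonal mass fraction)
#' @export
rate_matrix <- function(prop, cleanup_tol = 0.05) {
  stopifnot(inherits(prop, "propagator"))
  sup <- prop$supported
  r <- rle(sup)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0) stop("propagator has no supported bins")
  len <- r$lengths[runs]
  k <- runs[which.max(len)]
  bins <- starts[k]:ends[k]
  if (length(bins) < 2) stop("supported bin range too small")
  P <- prop$P[bins, bins, drop = FALSE]
  # renormalise within the block (mass leaking outside the block is dropped)
  cs <- colSums(P)
  if (any(cs <= 0)) stop("propagator block has an empty column")
  P <- sweep(P, 2, cs, "/")
  e <- eigen(P)
  lam <- e$values
  if (any(Re(lam) <= 0)) {
    stop("propagator eigenvalues with non-positive real part: ",
         "matrix logarithm ill-defined; use a smaller lag or coarser bins")
  }
  L <- e$vectors %*% diag(log(lam), nrow = length(lam)) %*% solve(e$vectors)
  R <- Re(L) / prop$lag
  offdiag <- abs(R); diag(offdiag) <- 0
  scale <- max(offdiag)
  if (scale <= 0) scale <- .Machine$double.eps
  imag_resid <- max(abs(Im(L))) / prop$lag / scale
  neg <- R; diag(neg) <- 0
  neg_resid <- max(0, -min(neg)) / scale
  if (imag_resid > cleanup_tol || neg_resid > cleanup_tol) {
    stop(sprintf(paste0(
      "matrix-logarithm residue too large (imag %.2g, negative %.2g of the ",
      "dominant rate): use a smaller lag or coarser bins"),
      imag_resid, neg_resid))
  }
  od <- R; diag(od) <- 0
  od[od < 0] <- 0
  R <- od
  diag(R) <- -colSums(od)
  n <- nrow(R)
  tri <- abs(row(R) - col(R)) == 1
  off_mass <- sum(od)
  offtri_frac <- if (off_mass > 0) sum(od[!tri & od > 0]) / off_mass else 0
  structure(list(R = R, grid = prop$grid, lag = prop$lag, bins = bins,
                 diagnostics = list(imag_residual = imag_resid,
                                    negative_residual = neg_resid,
                                    offtridiagonal_fraction = offtri_frac)),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<rate_matrix> %d bins, lag %.4g ps; off-tridiagonal mass %.2f%%\n",
    nrow(x$R), x$lag, 100 * d$offtridiagonal_fraction))
  invisible(x)
}

#' Position-dependent diffusion profile
#'
#' `D(s)` (ps^-1) with a per-point uncertainty `dD`, defined on half-grid
#' points between adjacent bins.
#'
#' @param s coordinate values (half-grid points)
#' @param D diffusion coefficient, ps^-1 (>= 0 or NA where unsupported)
#' @param dD uncertainty, ps^-1 (defaults to 0)
#' @return object of class `diffusion_profile`
#' @export
diffusion_profile <- function(s, D, dD = 0) {
  stopifnot(is.numeric(s), is.numeric(D), length(s) == length(D))
  if (length(dD) == 1) dD <- rep(dD, length(s))
  stopifnot(length(dD) == length(s))
  if (any(D < 0, na.rm = TRUE) || any(dD < 0, na.rm = TRUE)) {
    stop("D and dD must be non-negative")
  }
  structure(list(s = as.numeric(s), D = as.numeric(D), dD = as.numeric(dD)),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  ok <- is.finite(x$D)
  cat(sprintf(
    "<diffusion_profile> %d points (%d supported), D in [%.3g, %.3g] ps^-1\n",
    length(x$s), sum(ok), min(x$D[ok]), max(x$D[ok])))
  invisible(x)
}

# interpolant for D given a diffusion_profile, a constant, or a function
diffusion_fun <- function(D) {
  if (inherits(D, "diffusion_profile")) {
    ok <- is.finite(D$D)
    if (sum(ok) < 2) {
      if (sum(ok) == 1) {
        val <- D$D[ok]
        return(function(s) rep(val, length(s)))
      }
      stop("diffusion profile has no supported points")
    }
    approxfun(D$s[ok], D$D[ok], rule = 2)
  } else if (is.function(D)) {
    D
  } else if (is.numeric(D) && length(D) == 1) {
    function(s) rep(as.numeric(D), length(s))
  } else {
    stop("D must be a diffusion_profile, a function, or a single number")
  }
}

#' Diffusion coefficients from a rate matrix
#'
#' Under the symmetric (detailed-balance-exact) discretisation of the 1D
#' Smoluchowski generator, `R[i+1, i] = D_{i+1/2} / ds^2 *
#' exp(-beta (F_{i+1} - F_i) / 2)`, the half-grid diffusion follows from the
#' geometric mean of the two opposing rates:
#' `D_{i+1/2} = ds^2 sqrt(R[i+1, i] R[i, i+1])`, in which the equilibrium
#' populations cancel. Pairs with a vanishing rate are unsupported (NA).
#'
#' @param R a `rate_matrix` (or plain generator matrix, column convention)
#' @param ds bin width; taken from the rate matrix grid if missing
#' @return a [diffusion_profile()] on the half-grid points
#' @export
diffusion_from_rates <- function(R, ds = NULL) {
  if (inherits(R, "rate_matrix")) {
    centers <- R$grid$centers[R$bins]
    if (is.null(ds)) ds <- R$grid$ds
    M <- R$R
  } else {
    M <- R
    stopifnot(!is.null(ds))
    centers <- seq_len(nrow(M))  # index grid
  }
  n <- nrow(M)
  up <- M[cbind(2:n, 1:(n - 1))]     # rate i -> i+1
  down <- M[cbind(1:(n - 1), 2:n)]   # rate i+1 -> i
  D <- ds^2 * sqrt(pmax(up, 0) * pmax(down, 0))
  # a single vanishing rate leaves the point unsupported; both vanishing
  # means genuinely no exchange (D = 0)
  D[xor(up <= 0, down <= 0)] <- NA
  shalf <- (centers[-n] + centers[-1]) / 2
  diffusion_profile(shalf, D)
}

#' Detailed-balance error estimate of the diffusion
#'
#' Detailed balance requires `P_i R[j,i] = P_j R[i,j]` at equilibrium, so the
#' half-grid diffusion can be computed twice: from the uphill rate and the
#' population ratio (`D1`) and from the downhill rate and the inverse ratio
#' (`D2`). Exactly balanced rates give `D1 = D2`; on real data the reported
#' value is the mean `(D1 + D2)/2` and the uncertainty the half-difference
#' `|D1 - D2|/2`.
#'
#' @param R a `rate_matrix` or plain generator matrix (column convention)
#' @param populations equilibrium populations `P_i` on the (supported) bin
#'   centers, e.g. `exp(-beta F_i)`; any positive scaling
#' @param ds bin width; taken from the rate matrix grid if missing
#' @return a [diffusion_profile()] with `D`, `dD`; attributes `D1`, `D2` and
#'   `db_residual` (max relative detailed-balance violation)
#' @export
diffusion_error <- function(R, populations, ds = NULL) {
  if (inherits(R, "rate_matrix")) {
    centers <- R$grid$centers[R$bins]
    if (is.null(ds)) ds <- R$grid$ds
    M <- R$R
  } else {
    M <- R
    stopifnot(!is.null(ds))
    centers <- seq_len(nrow(M))
  }
  n <- nrow(M)
  stopifnot(length(populations) == n, all(populations > 0))
  p <- populations / sum(populations)
  up <- M[cbind(2:n, 1:(n - 1))]
  down <- M[cbind(1:(n - 1), 2:n)]
  ratio <- sqrt(p[1:(n - 1)] / p[2:n])
  D1 <- ds^2 * up * ratio
  D2 <- ds^2 * down / ratio
  bad <- up <= 0 | down <= 0
  D <- (D1 + D2) / 2
  dD <- abs(D1 - D2) / 2
  D[bad] <- NA
  dD[bad] <- NA
  flux_up <- p[1:(n - 1)] * up
  flux_down <- p[2:n] * down
  db <- abs(flux_up - flux_down) / pmax(flux_up, .Machine$double.eps)
  shalf <- (centers[-n] + centers[-1]) / 2
  out <- diffusion_profile(shalf, pmax(D, 0), pmax(dD, 0))
  attr(out, "D1") <- D1
  attr(out, "D2") <- D2
  attr(out, "db_pair_residual") <- ifelse(bad, NA, db)
  attr(out, "db_residual") <- suppressWarnings(max(db[!bad], na.rm = TRUE))
  out
}

# matrix exponential of a tridiagonal generator with positive off-diagonals
# (similar to a symmetric matrix, so the eigendecomposition is real/stable)
expm_birth_death <- function(up, down, tau) {
  n <- length(up) + 1
  phi <- c(1, cumprod(sqrt(up / down)))
  off <- sqrt(up * down)
  S <- diag(-(c(up, 0) + c(0, down)))
  S[cbind(2:n, 1:(n - 1))] <- off
  S[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(S, symmetric = TRUE)
  M <- e$vectors %*% (exp(tau * e$values) * t(e$vectors))
  sweep(sweep(M, 1, phi, "*"), 2, phi, "/")
}

# largest contiguous block of supported propagator columns
supported_block <- function(supported) {
  r <- rle(supported)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0) stop("propagator has no supported bins")
  k <- runs[which.max(r$lengths[runs])]
  starts[k]:ends[k]
}

#' Maximum-likelihood tridiagonal rate matrix from a propagator
#'
#' Point estimate of the nearest-neighbour (birth-death) generator: the up
#' and down rates maximise the multinomial likelihood of the observed
#' transition counts under `P = exp(lag R)`. Unlike the raw matrix
#' logarithm, the fit remains well-posed when fast propagator modes have
#' decayed below the sampling noise, and it imposes no detailed-balance
#' constraint, so the residual asymmetry of the fitted rates can serve as an
#' error estimate. A mild smoothness penalty on `log(up_i down_i)` (second
#' differences) suppresses the adjacent-rate seesaw degeneracy.
#'
#' @param prop a propagator from [estimate_propagator()]
#' @param lambda smoothness penalty weight (default 50)
#' @param init optional initial rate guess (scalar or vector, ps^-1)
#' @return object of class `rate_matrix` (same shape as [rate_matrix()]
#'   returns) with diagnostics `nll` and `convergence`
#' @export
fit_rate_matrix <- function(prop, lambda = 50, init = NULL) {
  stopifnot(inherits(prop, "propagator"))
  bins <- supported_block(prop$supported)
  if (length(bins) < 3) stop("supported bin range too small")
  cnt <- prop$counts[bins, bins, drop = FALSE]
  n <- nrow(cnt)
  tau <- prop$lag
  if (is.null(init)) {
    # short-displacement moment initialisation
    ds <- prop$grid$ds
    init <- pmax(colSums(cnt * abs(outer(seq_len(n), seq_len(n), "-"))) /
                   pmax(colSums(cnt), 1), 0.05) / (2 * tau)
    init <- pmax(pmin(init, 10 / tau), 0.01 / tau)
  }
  init <- rep_len(init, n - 1)
  nll <- function(p) {
    u <- exp(p[1:(n - 1)])
    d <- exp(p[n:(2 * n - 2)])
    P <- expm_birth_death(u, d, tau)
    P[P < 1e-300] <- 1e-300
    v <- -sum(cnt * log(P))
    if (lambda > 0 && n > 3) {
      v <- v + lambda * sum(diff(diff((p[1:(n - 1)] + p[n:(2 * n - 2)]) / 2))^2)
    }
    v
  }
  o <- stats::optim(log(c(init, init)), nll, method = "L-BFGS-B",
                    control = list(maxit = 1500))
  u <- exp(o$par[1:(n - 1)])
  d <- exp(o$par[n:(2 * n - 2)])
  R <- matrix(0, n, n)
  R[cbind(2:n, 1:(n - 1))] <- u
  R[cbind(1:(n - 1), 2:n)] <- d
  diag(R) <- -colSums(R)
  structure(list(R = R, grid = prop$grid, lag = tau, bins = bins,
                 diagnostics = list(nll = o$value,
                                    convergence = o$convergence,
                                    offtridiagonal_fraction = 0)),
            class = "rate_matrix")
}

#' Fine-grid Smoluchowski likelihood estimate of D(s)
#'
#' Fits the observed propagator with the package's own discrete
#' Smoluchowski generator evaluated on a grid several times finer than the
#' observation bins, with `D(s)` parameterised by log-linear interpolation
#' between knots and the free-energy profile held fixed. Because the model
#' reproduces the continuous within-bin dynamics, it avoids the
#' coarse-binning bias that limits bin-level generator estimates, at the
#' cost of requiring `F(s)`.
#'
#' @param prop a propagator from [estimate_propagator()]
#' @param profile an [fe_profile()] (the fixed free energy)
#' @param knot_spacing spacing of D knots in s-units (default 0.25)
#' @param n_fine number of fine cells (default 4 per observation bin,
#'   capped at 200)
#' @param lambda smoothness penalty on second differences of log D
#'   (default 10; second differences leave log-linear ramps unpenalised
#'   while damping the adjacent-knot seesaw the likelihood alone does not
#'   resolve)
#' @param D_init initial D guess, ps^-1 (default 0.15)
#' @param min_count minimum pair count for a column to enter the fit
#' @param start_density optional fine-resolution density of the observed
#'   starting frames (function of s); defaults to the Boltzmann weight of
#'   `profile`. Supplying the empirical density matters where the data are
#'   harvested transients rather than equilibrium samples
#' @return list with `knots`, `D` (at the knots), `fitted` (function of s),
#'   `convergence`, `supported` (logical per knot: data coverage)
#' @export
fit_diffusion_smol <- function(prop, profile, knot_spacing = 0.25,
                               n_fine = NULL, lambda = 10, D_init = 0.15,
                               min_count = 50, start_density = NULL) {
  stopifnot(inherits(prop, "propagator"), inherits(profile, "fe_profile"))
  grid <- prop$grid
  nb <- length(grid$centers)
  cnt <- prop$counts
  use_col <- colSums(cnt) >= min_count
  if (sum(use_col) < 3) stop("too few populated propagator columns")
  rng <- c(grid$edges[1], grid$edges[nb + 1])
  if (is.null(n_fine)) n_fine <- min(4L * nb, 200L)
  dsf <- (rng[2] - rng[1]) / n_fine
  cf <- seq(rng[1] + dsf / 2, rng[2] - dsf / 2, length.out = n_fine)
  Ffun <- profile_fun(profile)
  Fc <- Ffun(cf)
  beta <- profile$beta
  bin_of <- findInterval(cf, grid$edges, rightmost.closed = TRUE)
  wq <- if (is.null(start_density)) {
    exp(-beta * (Fc - min(Fc)))
  } else {
    pmax(start_density(cf), 0)
  }
  phi <- exp(-beta * (Fc - min(Fc)) / 2)
  knots <- seq(rng[1], rng[2], by = knot_spacing)
  if (knots[length(knots)] < rng[2] - 1e-9) knots <- c(knots, rng[2])
  nk <- length(knots)
  cols <- which(use_col)
  W <- vapply(cols, function(i) {
    v <- wq * (bin_of == i)
    if (sum(v) <= 0) v <- exp(-beta * (Fc - min(Fc))) * (bin_of == i)
    v / sum(v)
  }, numeric(n_fine))
  cnt_use <- cnt[, cols, drop = FALSE]
  sh <- (cf[-n_fine] + cf[-1]) / 2
  dF2 <- beta * diff(Fc) / 2
  model_P <- function(logDk) {
    Df <- exp(approx(knots, logDk, xout = sh, rule = 2)$y)
    up <- Df / dsf^2 * exp(-dF2)
    down <- Df / dsf^2 * exp(dF2)
    off <- sqrt(up * down)
    S <- diag(-(c(up, 0) + c(0, down)))
    S[cbind(2:n_fine, 1:(n_fine - 1))] <- off
    S[cbind(1:(n_fine - 1), 2:n_fine)] <- off
    e <- eigen(S, symmetric = TRUE)
    Etau <- e$vectors %*% (exp(prop$lag * e$values) * t(e$vectors))
    M <- sweep(Etau %*% sweep(W, 1, phi, "/"), 1, phi, "*")
    rowsum(M, bin_of)
  }
  nll <- function(p) {
    P <- model_P(p)
    P[P < 1e-300] <- 1e-300
    -sum(cnt_use * log(P)) + lambda * sum(diff(diff(p))^2)
  }
  o <- stats::optim(rep(log(D_init), nk), nll, method = "L-BFGS-B",
                    lower = log(1e-4), upper = log(10),
                    control = list(maxit = 500))
  Dk <- exp(o$par)
  # a knot is supported when populated data bins lie within one spacing
  covered <- grid$centers[use_col]
  supported <- vapply(knots, function(k) {
    any(abs(covered - k) <= knot_spacing)
  }, logical(1))
  list(knots = knots, D = Dk,
       fitted = approxfun(knots, Dk, rule = 2),
       convergence = o$convergence, supported = supported)
}

#' Estimate D(s) from trajectory segments (propagator route)
#'
#' Full pipeline for the position-dependent diffusion coefficient: bin the
#' segments, count the propagator at the given lag, estimate the generator,
#' and convert adjacent rates to half-grid diffusion coefficients with the
#' detailed-balance error estimate. Three generator estimators are
#' available: `"smoluchowski"` (default; fine-grid likelihood fit of
#' [fit_diffusion_smol()], needs `profile`) for the D point values,
#' `"bins"` (tridiagonal bin-level likelihood, [fit_rate_matrix()]) and
#' `"logm"` (raw matrix logarithm, [rate_matrix()]). The per-point
#' uncertainty `dD` and the detailed-balance residual always come from the
#' unconstrained bin-level rates (the two detailed-balance-equivalent
#' estimates D1/D2), whatever the point estimator.
#'
#' @param segments a [coord_series()] or list of them
#' @param grid a [bin_grid()]
#' @param lag lag time, ps
#' @param profile [fe_profile()] for the equilibrium populations (required
#'   for the default method)
#' @param method generator estimator, see Details
#' @param cleanup_tol passed to [rate_matrix()] for `method = "logm"`
#' @param min_count minimum adjacent-column pair count for a half-grid
#'   point to be reported as supported
#' @param ... further arguments to [fit_diffusion_smol()]
#' @return a [diffusion_profile()] on the half-grid points; attributes
#'   `rate_matrix`, `diagnostics` (detailed-balance residual, fit
#'   convergence), and for the default method `smol_fit`
#' @export
estimate_diffusion <- function(segments, grid, lag, profile = NULL,
                               method = c("smoluchowski", "bins", "logm"),
                               cleanup_tol = 0.05, min_count = 100, ...) {
  method <- match.arg(method)
  if (method == "smoluchowski" && is.null(profile)) method <- "bins"
  prop <- estimate_propagator(segments, grid, lag)
  rm_ <- if (method == "logm") rate_matrix(prop, cleanup_tol = cleanup_tol)
         else fit_rate_matrix(prop)
  if (!is.null(profile)) {
    # bin-averaged Boltzmann weight (the center value misstates the
    # population of bins where F is steep within the bin)
    Ffun <- profile_fun(profile)
    pops <- vapply(rm_$bins, function(i) {
      x <- seq(grid$edges[i], grid$edges[i + 1], length.out = 21)
      mean(exp(-profile$beta * (Ffun(x) - min(profile$F))))
    }, numeric(1))
  } else {
    occ <- colSums(prop$counts)[rm_$bins]
    pops <- pmax(occ, 0.5)
  }
  out <- diffusion_error(rm_, pops)
  smol <- NULL
  if (method == "smoluchowski") {
    # empirical density of the starting frames at fine resolution, so the
    # within-bin start distribution matches the data (harvested transients
    # are not equilibrium samples in steep regions)
    if (inherits(segments, "coord_series")) segments <- list(segments)
    vals <- unlist(lapply(segments, `[[`, "values"))
    br <- seq(grid$edges[1], grid$edges[length(grid$edges)],
              length.out = 201)
    h <- hist(vals[vals >= br[1] & vals <= br[201]], breaks = br,
              plot = FALSE)
    dens <- approxfun((br[-1] + br[-201]) / 2, h$counts, rule = 2)
    smol <- fit_diffusion_smol(prop, profile, start_density = dens, ...)
    out$D <- smol$fitted(out$s)
  }
  # support mask: both adjacent columns need enough pairs
  cc <- colSums(prop$counts)[rm_$bins]
  n <- length(cc)
  weak <- pmin(cc[-n], cc[-1]) < min_count
  out$D[weak] <- NA
  out$dD[weak] <- NA
  db_pairs <- attr(out, "db_pair_residual")
  db_sup <- suppressWarnings(max(db_pairs[!weak], na.rm = TRUE))
  attr(out, "db_residual") <- db_sup
  attr(out, "rate_matrix") <- rm_
  attr(out, "smol_fit") <- smol
  attr(out, "diagnostics") <- c(rm_$diagnostics,
                                list(db_residual = db_sup))
  out
}
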