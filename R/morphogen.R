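#' Parameters of the SHH diffusion-degradation model
#'
#' The model describes a morphogen (SHH) secreted at rate `s0` inside a
#' posterior source region of size theta, diffusing with constant `D` and
#' degraded linearly at rate `gamma` along the A-P axis of a blastema of
#' size L, with zero-flux (Neumann) boundaries at both ends. Only the
#' combinations s0/gamma (plateau concentration) and the decay length
#' beta^-1 = sqrt(D/gamma) enter the steady state, so those are the primary
#' parameters. Target-gene (*Ptch1*) activation is a Hill function of the
#' local concentration with half-max `K` and coefficient `h`.
#'
#' The source size scales with blastema size as theta = theta_k * L^theta_alpha
#' (default 2.1 * L^0.69, L and theta in micrometres).
#'
#' @param s0_over_gamma Plateau concentration s0/gamma (dimensionless units;
#'   default 1).
#' @param beta_inv Decay length sqrt(D/gamma) in micrometres (default 300).
#' @param K Hill half-max concentration (default 0.25).
#' @param h Hill coefficient (default 4).
#' @param theta_k,theta_alpha Allometric law for the source size, theta in
#'   micrometres for L in micrometres.
#' @param D,gamma Optional diffusion constant and degradation rate; if both
#'   are given they must satisfy beta_inv = sqrt(D/gamma).
#' @return Object of class `morphogen_params`.
#' @export
morphogen_params <- function(s0_over_gamma = 1, beta_inv = 300,
                             K = 0.25, h = 4,
                             theta_k = 2.1, theta_alpha = 0.69,
                             D = NULL, gamma = NULL) {
  stopifnot(beta_inv > 0, K > 0, h > 0, s0_over_gamma > 0,
            theta_k > 0)
  if (!is.null(D) && !is.null(gamma)) {
    if (abs(sqrt(D / gamma) - beta_inv) > 1e-9 * beta_inv) {
      stop("beta_inv must equal sqrt(D/gamma)")
    }
  }
  structure(list(s0_over_gamma = s0_over_gamma, beta_inv = beta_inv,
                 K = K, h = h, theta_k = theta_k,
                 theta_alpha = theta_alpha, D = D, gamma = gamma),
            class = "morphogen_params")
}

#' Source size theta for a given blastema size
#' @param params A `morphogen_params` object.
#' @param L Blastema size in micrometres.
#' @return theta in micrometres.
#' @export
source_size <- function(params, L) params$theta_k * L^params$theta_alpha

#' Closed-form steady-state morphogen profile
#'
#' Solves D S'' - gamma S + s0 1\[x <= theta\] = 0 on \[0, L\] with zero-flux
#' ends. With beta = sqrt(gamma/D), the piecewise solution continuous and
#' differentiable at x = theta is
#' \deqn{S(x) = (s_0/\gamma) (1 - A \cosh(\beta x)), \quad 0 \le x \le \theta}
#' \deqn{S(x) = (s_0/\gamma) B \cosh(\beta (L - x)), \quad \theta \le x \le L}
#' with A = sinh(beta (L - theta)) / sinh(beta L) and
#' B = sinh(beta theta) / sinh(beta L).
#'
#' @param params A `morphogen_params` object.
#' @param L Blastema size in micrometres; must exceed the source size.
#' @param grid_step Grid spacing in micrometres.
#' @param theta Optional source size override in micrometres; by default
#'   computed from the allometric law in `params`.
#' @return Object of class `morphogen_profile`: list with `x` (grid, 0 =
#'   posterior end), `S` (concentration), `ptch1` (Hill activation in
#'   \[0, 1\]), `L`, `theta` and the parameters used.
#' @examples
#' p <- morphogen_params()
#' prof <- steady_state_profile(p, L = 2500)
#' prof$S[which.min(abs(prof$x - prof$theta))]  # ~0.48 at the source edge
#' @export
steady_state_profile <- function(params, L, grid_step = 1, theta = NULL) {
  stopifnot(inherits(params, "morphogen_params"), L > 0, grid_step > 0)
  if (is.null(theta)) theta <- source_size(params, L)
  if (theta <= 0) stop("source size must be positive")
  if (theta >= L) stop("source size theta (", signif(theta, 4),
                       " um) must be smaller than blastema size L (", L, " um)")
  beta <- 1 / params$beta_inv
  x <- seq(0, L, by = grid_step)
  A <- sinh(beta * (L - theta)) / sinh(beta * L)
  B <- sinh(beta * theta) / sinh(beta * L)
  S <- ifelse(x <= theta,
              params$s0_over_gamma * (1 - A * cosh(beta * x)),
              params$s0_over_gamma * B * cosh(beta * (L - x)))
  structure(list(x = x, S = S,
                 ptch1 = ptch1_profile(S, params$K, params$h),
                 L = L, theta = theta, params = params),
            class = "morphogen_profile")
}

#' Finite-difference steady-state oracle
#'
#' Solves the same boundary-value problem as [steady_state_profile()] by a
#' sparse second-order finite-difference discretisation (ghost-point Neumann
#' ends), independent of the closed form. Used to validate the analytic
#' solution.
#'
#' @inheritParams steady_state_profile
#' @param tol Maximum admissible residual of the discrete equations.
#' @return A `morphogen_profile` (same structure as the closed form).
#' @export
numeric_steady_state <- function(params, L, grid_step = 1, theta = NULL,
                                 tol = 1e-8) {
  stopifnot(inherits(params, "morphogen_params"), L > 0)
  if (grid_step > params$beta_inv / 10) {
    stop("grid_step must be <= beta_inv/10 for an accurate solution")
  }
  if (is.null(theta)) theta <- source_size(params, L)
  if (theta >= L) stop("source size must be smaller than L")
  x <- seq(0, L, by = grid_step)
  n <- length(x)
  beta2 <- 1 / params$beta_inv^2
  hh <- grid_step^2
  # (1/h^2) tridiagonal Laplacian with reflecting ends, minus beta^2 I;
  # units scaled by gamma: S'' / beta^-2 ... solve (D/gamma) S'' - S = -(s0/gamma) 1[x<=theta]
  main <- rep(-2 / hh / beta2 - 1, n)
  off <- rep(1 / hh / beta2, n - 1)
  offu <- off
  offl <- off
  # ghost-point Neumann: S_{-1} = S_1 and S_{n+1} = S_{n-1}
  offu[1] <- 2 / hh / beta2
  offl[n - 1] <- 2 / hh / beta2
  M <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(offl, main, offu))
  # fractional source coverage of each node's cell [x - h/2, x + h/2]
  # (clipped to [0, L]) keeps second-order accuracy at the source edge
  cell_lo <- pmax(x - grid_step / 2, 0)
  cell_hi <- pmin(x + grid_step / 2, L)
  frac <- pmax(0, pmin(theta, cell_hi) - cell_lo) / (cell_hi - cell_lo)
  rhs <- -params$s0_over_gamma * frac
  S <- as.numeric(Matrix::solve(M, rhs))
  resid <- max(abs(as.numeric(M %*% S) - rhs))
  if (resid > tol) stop("finite-difference solve residual ", resid,
                        " exceeds tolerance ", tol)
  structure(list(x = x, S = S,
                 ptch1 = ptch1_profile(S, params$K, params$h),
                 L = L, theta = theta, params = params),
            class = "morphogen_profile")
}

#' Hill activation of a target gene from a morphogen concentration
#'
#' @param S Non-negative concentration vector.
#' @param K Half-maximal concentration.
#' @param h Hill coefficient.
#' @return Activation in \[0, 1\]: S^h / (K^h + S^h).
#' @export
ptch1_profile <- function(S, K, h) {
  if (any(S < -1e-12)) stop("concentrations must be non-negative")
  S <- pmax(S, 0)
  S^h / (K^h + S^h)
}

#' Anterior boundary of the activated target-gene domain
#'
#' Finds the smallest position anterior to the source edge (x > theta) where
#' the activation profile falls through `level`, by linear interpolation
#' between grid points. At level 0.5 this is where S = K.
#'
#' @param profile A `morphogen_profile`.
#' @param level Activation threshold in (0, 1).
#' @return Position in micrometres, or `numeric(0)` if the profile never
#'   crosses the level anterior to the source.
#' @export
anterior_boundary <- function(profile, level = 0.5) {
  stopifnot(level > 0, level < 1)
  sel <- profile$x >= profile$theta
  x <- profile$x[sel]
  p <- profile$ptch1[sel]
  below <- which(p < level)
  if (length(below) == 0L) return(numeric(0))
  i <- below[1]
  if (i == 1L) return(x[1])
  x0 <- x[i - 1]; x1 <- x[i]
  p0 <- p[i - 1]; p1 <- p[i]
  x0 + (level - p0) / (p1 - p0) * (x1 - x0)
}

#' Size invariance of the morphogen signalling range
#'
#' For each blastema size L, computes the source size theta(L), the anterior
#' activation boundary, and their distance (the model analogue of the
#' measured gap between the anterior ends of the *Shh* and *Ptch1* domains).
#' Because the decay length beta^-1 is a physical constant independent of L,
#' this distance is nearly constant even as L varies several-fold.
#'
#' @param params A `morphogen_params` object.
#' @param L_values Blastema sizes in micrometres.
#' @param level Activation threshold defining the boundary.
#' @param grid_step Grid spacing in micrometres.
#' @return A data.frame with columns `L`, `theta`, `boundary`, `distance`,
#'   with attribute `range` = max(distance) - min(distance).
#' @export
diffusion_range_invariance <- function(params, L_values, level = 0.5,
                                       grid_step = 1) {
  rows <- lapply(L_values, function(L) {
    prof <- steady_state_profile(params, L, grid_step = grid_step)
    b <- anterior_boundary(prof, level)
    if (length(b) == 0L) b <- NA_real_
    data.frame(L = L, theta = prof$theta, boundary = b,
               distance = b - prof$theta)
  })
  out <- do.call(rbind, rows)
  attr(out, "range") <- max(out$distance, na.rm = TRUE) -
    min(out$distance, na.rm = TRUE)
  out
}
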