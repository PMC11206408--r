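#' Analytic test surfaces
#'
#' Energy surfaces with closed-form gradients, used to exercise the biased
#' sampler, WHAM reconstruction and nudged-elastic-band optimization on
#' problems whose answers are known independently.
#'
#' `double_well_1d()` builds a C1 piecewise-cosine double well with minima
#' at `-separation/2` (energy 0) and `+separation/2` (energy `offset`) and
#' an interior maximum of height `barrier` at 0, continued by harmonic
#' walls outside the wells.
#'
#' `gaussian_sum_2d()` is a sum of isotropic 2-D Gaussians
#' `sum_i A_i exp(-|r - c_i|^2 / (2 w_i^2))`; wells have negative
#' amplitude, barriers positive.
#'
#' @param barrier Barrier height, kcal mol^-1, measured from the reactant
#'   (left) minimum.
#' @param separation Distance between the two minima, A.
#' @param offset Energy of the product (right) minimum relative to the
#'   reactant minimum, kcal mol^-1 (negative = exergonic).
#' @return An object of class `spla2_surface` with elements `dim`,
#'   `energy(x)`, `gradient(x)`, `domain` and `params`.
#' @examples
#' s <- double_well_1d(barrier = 17, separation = 3, offset = -7.9)
#' eval_surface(s, 0)$energy   # 17
#' @export
double_well_1d <- function(barrier, separation = 3, offset = 0) {
  stopifnot(barrier > 0, separation > 0, offset < barrier)
  a <- separation / 2
  w <- pi / a
  c_l <- barrier * w^2 / 2          # curvature-matched harmonic walls
  c_r <- (barrier - offset) * w^2 / 2
  energy <- function(x) {
    ifelse(x < -a, 0.5 * c_l * (x + a)^2,
    ifelse(x < 0, barrier / 2 * (1 - cos(w * (x + a))),
    ifelse(x < a, offset + (barrier - offset) / 2 * (1 + cos(w * x)),
           offset + 0.5 * c_r * (x - a)^2)))
  }
  gradient <- function(x) {
    ifelse(x < -a, c_l * (x + a),
    ifelse(x < 0, barrier / 2 * w * sin(w * (x + a)),
    ifelse(x < a, -(barrier - offset) / 2 * w * sin(w * x),
           c_r * (x - a))))
  }
  structure(list(dim = 1L, energy = energy,
                 gradient = function(x) matrix(gradient(x), ncol = 1),
                 domain = cbind(lower = -2.5 * a, upper = 2.5 * a),
                 family = "double_well_1d",
                 params = list(barrier = barrier, separation = separation,
                               offset = offset)),
            class = "spla2_surface")
}

#' @rdname double_well_1d
#' @param amplitudes Gaussian amplitudes, kcal mol^-1 (negative = well).
#' @param centers 2-column matrix of Gaussian centers.
#' @param widths Gaussian widths (standard deviations), one per term.
#' @param domain 2 x 2 matrix `rbind(x = , y = )` of lower/upper bounds.
#' @export
gaussian_sum_2d <- function(amplitudes, centers, widths, domain = NULL) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, length(amplitudes) == nrow(centers),
            length(widths) == nrow(centers), all(widths > 0))
  if (is.null(domain)) {
    pad <- 3 * max(widths)
    domain <- cbind(lower = apply(centers, 2, min) - pad,
                    upper = apply(centers, 2, max) + pad)
  }
  energy <- function(x) {
    x <- rbind(x)
    out <- numeric(nrow(x))
    for (i in seq_along(amplitudes)) {
      d2 <- (x[, 1] - centers[i, 1])^2 + (x[, 2] - centers[i, 2])^2
      out <- out + amplitudes[i] * exp(-d2 / (2 * widths[i]^2))
    }
    out
  }
  gradient <- function(x) {
    x <- rbind(x)
    g <- matrix(0, nrow(x), 2)
    for (i in seq_along(amplitudes)) {
      dx <- x[, 1] - centers[i, 1]
      dy <- x[, 2] - centers[i, 2]
      e <- amplitudes[i] * exp(-(dx^2 + dy^2) / (2 * widths[i]^2))
      g[, 1] <- g[, 1] - e * dx / widths[i]^2
      g[, 2] <- g[, 2] - e * dy / widths[i]^2
    }
    g
  }
  structure(list(dim = 2L, energy = energy, gradient = gradient,
                 domain = domain, family = "gaussian_sum_2d",
                 params = list(amplitudes = amplitudes, centers = centers,
                               widths = widths)),
            class = "spla2_surface")
}

#' Default 2-D benchmark surface
#'
#' Three Gaussian wells plus one Gaussian barrier arranged to give two
#' minima separated by a single saddle, a minimal stand-in for a
#' two-collective-variable reaction landscape. Its stationary points are
#' not hard-coded anywhere: locate them with [find_stationary_points()].
#'
#' @return A `spla2_surface`.
#' @export
default_test_surface <- function() {
  gaussian_sum_2d(
    amplitudes = c(-12, -10, -3, 6),
    centers = rbind(c(0, 0), c(2.4, 1.6), c(1.3, 1.1), c(1.1, 0.35)),
    widths = c(0.75, 0.75, 0.6, 0.55),
    domain = cbind(lower = c(-2, -2), upper = c(4.4, 3.6))
  )
}

#' Evaluate a surface at a point
#'
#' @param surface A `spla2_surface`.
#' @param point Numeric coordinate vector of length `surface$dim`.
#' @return List with `energy` (scalar) and `gradient` (length-`dim`
#'   vector), both analytic.
#' @export
eval_surface <- function(surface, point) {
  stopifnot(inherits(surface, "spla2_surface"),
            length(point) == surface$dim)
  p <- matrix(point, nrow = 1)
  list(energy = as.numeric(surface$energy(p)),
       gradient = as.numeric(surface$gradient(p)))
}

#' Locate stationary points by dense grid search plus Newton refinement
#'
#' Scans `|grad|^2` on a dense grid over the surface domain, takes local
#' minima of the gradient norm as candidates, refines each with damped
#' Newton steps on the gradient (finite-difference Hessian of the analytic
#' gradient) and classifies the survivors by Hessian signature.
#'
#' @param surface A `spla2_surface`.
#' @param n_grid Grid points per axis.
#' @param grad_tol Gradient-norm acceptance tolerance.
#' @return Tibble with the point coordinates, `energy`, gradient norm and
#'   `type` (`"minimum"`, `"saddle"`, `"maximum"`).
#' @export
find_stationary_points <- function(surface, n_grid = 201, grad_tol = 1e-8) {
  dom <- surface$domain
  if (surface$dim == 1L) {
    xs <- seq(dom[1, 1], dom[1, 2], length.out = n_grid)
    g <- as.numeric(surface$gradient(matrix(xs, ncol = 1)))
    cand <- xs[which(diff(sign(g)) != 0)]
    pts <- lapply(cand, function(x0) newton_refine(surface, x0, grad_tol))
  } else {
    xs <- seq(dom[1, 1], dom[1, 2], length.out = n_grid)
    ys <- seq(dom[2, 1], dom[2, 2], length.out = n_grid)
    grid <- as.matrix(expand.grid(x = xs, y = ys))
    gr <- surface$gradient(grid)
    gn <- matrix(gr[, 1]^2 + gr[, 2]^2, n_grid, n_grid)
    cand_idx <- which(local_minimum_2d(gn), arr.ind = TRUE)
    pts <- lapply(seq_len(nrow(cand_idx)), function(i) {
      newton_refine(surface, c(xs[cand_idx[i, 1]], ys[cand_idx[i, 2]]),
                    grad_tol)
    })
  }
  pts <- purrr::compact(pts)
  if (length(pts) == 0) return(tibble::tibble())
  out <- dplyr::bind_rows(pts)
  # deduplicate refined points that collapsed onto the same solution
  out <- out[order(out$energy), ]
  keep <- rep(TRUE, nrow(out))
  coords <- as.matrix(out[, seq_len(surface$dim), drop = FALSE])
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in (i + 1):nrow(out)) {
        if (keep[j] &&
            sqrt(sum((coords[i, ] - coords[j, ])^2)) < 1e-4) keep[j] <- FALSE
      }
    }
  }
  tibble::as_tibble(out[keep, ])
}

newton_refine <- function(surface, x0, grad_tol, max_iter = 60) {
  x <- as.numeric(x0)
  d <- surface$dim
  for (it in seq_len(max_iter)) {
    g <- as.numeric(surface$gradient(matrix(x, nrow = 1)))
    if (sqrt(sum(g^2)) < grad_tol) break
    H <- fd_hessian(surface, x)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
    x <- x - step
    dom <- surface$domain
    if (any(x < dom[, 1] - 0.5) || any(x > dom[, 2] + 0.5)) return(NULL)
  }
  g <- as.numeric(surface$gradient(matrix(x, nrow = 1)))
  gn <- sqrt(sum(g^2))
  if (gn > 1e-6) return(NULL)
  H <- fd_hessian(surface, x)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  n_neg <- sum(ev < -1e-8)
  type <- if (n_neg == 0) "minimum" else if (n_neg == d) "maximum" else
    "saddle"
  out <- as.list(x)
  names(out) <- c("x", "y", "z")[seq_len(d)]
  tibble::as_tibble(c(out, list(
    energy = as.numeric(surface$energy(matrix(x, nrow = 1))),
    grad_norm = gn, type = type)))
}

# central-difference Hessian of the analytic gradient
fd_hessian <- function(surface, x, h = 1e-5) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (k in seq_len(d)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    H[, k] <- (as.numeric(surface$gradient(matrix(xp, nrow = 1))) -
               as.numeric(surface$gradient(matrix(xm, nrow = 1)))) / (2 * h)
  }
  (H + t(H)) / 2
}

local_minimum_2d <- function(m) {
  n <- nrow(m); p <- ncol(m)
  big <- max(m) + 1
  pad <- matrix(big, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- m
  res <- matrix(TRUE, n, p)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    res <- res & (m <= pad[(2 + di):(n + 1 + di), (2 + dj):(p + 1 + dj)])
  }
  # exclude the domain boundary ring: gradient-norm minima there are
  # usually artefacts of the window, not stationary points
  res[c(1, n), ] <- FALSE
  res[, c(1, p)] <- FALSE
  res
}
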