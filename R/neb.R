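#' Climbing-image nudged elastic band on an analytic surface
#'
#' Relaxes a chain of images between two fixed endpoints under NEB forces:
#' the true force perpendicular to the path plus a spring force along the
#' upwind (improved) tangent. Once the force norm drops below
#' `10 * f_tol`, the highest-energy image switches to climbing mode - it
#' feels the inverted parallel component of the true force and no spring -
#' so it converges onto the saddle point. The optimizer is FIRE-style
#' damped dynamics with an adaptive timestep.
#'
#' @param surface A `spla2_surface`.
#' @param start,end Endpoint coordinates ((approximate) minima); endpoints
#'   never move.
#' @param n_images Number of images including the endpoints (>= 5).
#' @param spring_k Spring constant, energy length^-2.
#' @param max_steps Optimization step budget.
#' @param f_tol Convergence threshold on the largest NEB force component
#'   norm, energy length^-1.
#' @param climb Activate the climbing image.
#' @return An object of class `neb_path`: list with `images` (matrix,
#'   one row per image), `energies`, `converged`, `max_perp_force`,
#'   `climbing_index`, `steps`.
#' @examples
#' s <- double_well_1d(barrier = 5, separation = 3)
#' p <- neb_optimize(s, start = -1.5, end = 1.5, n_images = 11)
#' max(p$energies)  # ~5
#' @export
neb_optimize <- function(surface, start, end, n_images = 16, spring_k = 1,
                         max_steps = 20000, f_tol = 1e-4, climb = TRUE) {
  stopifnot(inherits(surface, "spla2_surface"), n_images >= 5)
  d <- surface$dim
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == d, length(end) == d)
  alpha_mix <- seq(0, 1, length.out = n_images)
  images <- outer(1 - alpha_mix, start) + outer(alpha_mix, end)
  inner <- 2:(n_images - 1)
  # FIRE parameters
  dt <- 0.02; dt_max <- 0.2; alpha <- 0.1
  n_pos <- 0L
  v <- matrix(0, n_images, d)
  climbing_on <- FALSE
  climb_idx <- NA_integer_
  forces <- function(images, climbing_idx) {
    e <- as.numeric(surface$energy(images))
    g <- surface$gradient(images)
    f <- matrix(0, n_images, d)
    for (i in inner) {
      tau <- neb_tangent(images, e, i)
      gi <- g[i, ]
      if (!is.na(climbing_idx) && i == climbing_idx) {
        f[i, ] <- -gi + 2 * sum(gi * tau) * tau
      } else {
        d_fwd <- sqrt(sum((images[i + 1, ] - images[i, ])^2))
        d_bwd <- sqrt(sum((images[i, ] - images[i - 1, ])^2))
        f_spring <- spring_k * (d_fwd - d_bwd)
        f_perp <- -(gi - sum(gi * tau) * tau)
        f[i, ] <- f_perp + f_spring * tau
      }
    }
    list(f = f, e = e, g = g)
  }
  fr <- forces(images, NA_integer_)
  steps <- 0L
  repeat {
    steps <- steps + 1L
    fmax <- max(sqrt(rowSums(fr$f^2)))
    if (climb && !climbing_on && fmax < 10 * f_tol) {
      climbing_on <- TRUE
      climb_idx <- inner[which.max(fr$e[inner])]
      fr <- forces(images, climb_idx)
      v[] <- 0
      next
    }
    if (fmax < f_tol || steps >= max_steps) break
    # FIRE update on the interior images
    p_power <- sum(v * fr$f)
    if (p_power > 0) {
      n_pos <- n_pos + 1L
      fn <- sqrt(sum(fr$f^2)); vn <- sqrt(sum(v^2))
      if (fn > 0) v <- (1 - alpha) * v + alpha * vn * fr$f / fn
      if (n_pos > 5L) {
        dt <- min(dt * 1.1, dt_max)
        alpha <- alpha * 0.99
      }
    } else {
      v[] <- 0
      dt <- dt * 0.5
      alpha <- 0.1
      n_pos <- 0L
    }
    v <- v + dt * fr$f
    step <- dt * v
    limit <- 0.1
    sn <- sqrt(rowSums(step^2))
    too_big <- sn > limit
    if (any(too_big)) step[too_big, ] <- step[too_big, ] * limit / sn[too_big]
    images[inner, ] <- images[inner, ] + step[inner, , drop = FALSE]
    fr <- forces(images, if (climbing_on) climb_idx else NA_integer_)
    if (climbing_on) {
      new_idx <- inner[which.max(fr$e[inner])]
      if (new_idx != climb_idx) {
        climb_idx <- new_idx
        fr <- forces(images, climb_idx)
      }
    }
  }
  fmax <- max(sqrt(rowSums(fr$f^2)))
  structure(list(images = images, energies = fr$e,
                 spring_k = spring_k,
                 converged = fmax < f_tol,
                 max_perp_force = fmax,
                 climbing_index = climb_idx,
                 steps = steps),
            class = "neb_path")
}

# improved (upwind) tangent of Henkelman & Jonsson type
neb_tangent <- function(images, e, i) {
  t_fwd <- images[i + 1, ] - images[i, ]
  t_bwd <- images[i, ] - images[i - 1, ]
  if (e[i + 1] > e[i] && e[i] > e[i - 1]) {
    tau <- t_fwd
  } else if (e[i + 1] < e[i] && e[i] < e[i - 1]) {
    tau <- t_bwd
  } else {
    dmax <- max(abs(e[i + 1] - e[i]), abs(e[i - 1] - e[i]))
    dmin <- min(abs(e[i + 1] - e[i]), abs(e[i - 1] - e[i]))
    if (e[i + 1] > e[i - 1]) {
      tau <- t_fwd * dmax + t_bwd * dmin
    } else {
      tau <- t_fwd * dmin + t_bwd * dmax
    }
  }
  tau / sqrt(sum(tau^2))
}

#' Check a candidate saddle point by finite-difference Hessian
#'
#' @param surface A `spla2_surface`.
#' @param point Candidate coordinates.
#' @param fd_step Central-difference step.
#' @param f_tol Gradient-norm acceptance tolerance.
#' @return List of class `saddle_report`: `location`, `energy`,
#'   `grad_norm`, `eigenvalues` (all, ascending), `n_negative`, `passes`
#'   (gradient below tolerance and exactly one negative eigenvalue).
#' @examples
#' s <- gaussian_sum_2d(c(-1, -1), rbind(c(-1, 0), c(1, 0)), c(0.5, 0.5))
#' verify_saddle(s, c(0, 0))
#' @export
verify_saddle <- function(surface, point, fd_step = 1e-5, f_tol = 1e-4) {
  point <- as.numeric(point)
  g <- as.numeric(surface$gradient(matrix(point, nrow = 1)))
  H <- fd_hessian(surface, point, h = fd_step)
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  gn <- sqrt(sum(g^2))
  n_neg <- sum(ev < -1e-8)
  structure(list(location = point,
                 energy = as.numeric(surface$energy(matrix(point, nrow = 1))),
                 grad_norm = gn,
                 eigenvalues = ev,
                 n_negative = n_neg,
                 passes = gn < f_tol && n_neg == 1L),
            class = "saddle_report")
}

#' Project an optimized path onto collective variables
#'
#' Evaluates each CV function along the image chain and pairs it with the
#' image energies, giving the minimum-energy-profile curves plotted in
#' reaction-path figures (e.g. `CV = d1 + d2` sums of distances).
#'
#' @param path A `neb_path`.
#' @param cv_functions Named list of functions, each mapping an image
#'   coordinate vector to a scalar.
#' @return Tibble with `image`, `energy` and one column per CV.
#' @export
project_path <- function(path, cv_functions) {
  stopifnot(inherits(path, "neb_path"))
  if (is.function(cv_functions)) cv_functions <- list(cv = cv_functions)
  out <- tibble::tibble(image = seq_len(nrow(path$images)),
                        energy = path$energies)
  for (nm in names(cv_functions)) {
    out[[nm]] <- apply(path$images, 1, cv_functions[[nm]])
  }
  out
}
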