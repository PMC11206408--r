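#' Sample umbrella windows on an analytic 1-D surface
#'
#' Metropolis Monte Carlo with Gaussian proposals on the biased potential
#' `U_i(x) = F(x) + k_i/2 (x - x0_i)^2`. Only the stationary distribution
#' matters for free-energy reconstruction, so a Markov chain sampler is
#' sufficient; an initial `burn_in` fraction of each chain is dropped
#' (production convention 0.2, mirroring a 2.5/12.5 ps discard).
#'
#' @param surface A 1-D `spla2_surface`.
#' @param metadata Tibble with `bias_center` and `force_constant` columns
#'   (e.g. from [read_umbrella_metadata()] or [window_metadata()]).
#' @param n_steps Total Metropolis steps per window (before burn-in).
#' @param step_size Gaussian proposal standard deviation, A. The default
#'   (`NULL`) uses optimal Metropolis scaling per window,
#'   `2.4 sqrt(RT / k)` - about 2.4 times the stationary spread of the
#'   harmonic bias - which keeps the integrated autocorrelation time near
#'   its minimum; pass a number to fix the step instead.
#' @param temperature Temperature, K.
#' @param burn_in Fraction of each chain discarded from the front.
#' @param seed Integer seed; the run is a pure function of its arguments.
#' @param dt Time spacing attached to retained samples, ps (extraction
#'   cadence; default 0.005 ps = 5 fs).
#' @return List of [umbrella_window()] objects with acceptance rates in
#'   attribute `"acceptance"`.
#' @export
sample_biased_windows <- function(surface, metadata, n_steps = 12500,
                                  step_size = NULL,
                                  temperature = spla2_constants$temperature_K,
                                  burn_in = 0.2, seed = 1, dt = 0.005) {
  stopifnot(inherits(surface, "spla2_surface"), surface$dim == 1L)
  if (!is.null(step_size) && step_size <= 0) {
    stop("validation error: step_size must be > 0", call. = FALSE)
  }
  if (temperature <= 0) stop("validation error: temperature must be > 0",
                             call. = FALSE)
  stopifnot(burn_in >= 0, burn_in < 1)
  rt <- rt_kcal(temperature)
  withr::with_seed(seed, {
    purrr::pmap(
      list(metadata$bias_center, metadata$force_constant,
           seq_len(nrow(metadata))),
      function(center, k, i) {
        u <- function(x) surface$energy(matrix(x, ncol = 1)) +
          0.5 * k * (x - center)^2
        step <- if (is.null(step_size)) {
          if (k > 0) 2.4 * sqrt(rt / k) else 0.5 # no bias scale to match
        } else step_size
        x <- center
        ux <- u(x)
        prop <- stats::rnorm(n_steps, sd = step)
        logu <- log(stats::runif(n_steps))
        xs <- numeric(n_steps)
        acc <- 0L
        for (s in seq_len(n_steps)) {
          xn <- x + prop[s]
          un <- u(xn)
          if (logu[s] < (ux - un) / rt) {
            x <- xn; ux <- un; acc <- acc + 1L
          }
          xs[s] <- x
        }
        keep <- xs[(floor(n_steps * burn_in) + 1L):n_steps]
        w <- umbrella_window(keep, center, k, discard_fraction = 0,
                             times = dt * seq_along(keep))
        attr(w, "acceptance") <- acc / n_steps
        w
      })
  })
}

#' Build an umbrella metadata table in memory
#'
#' @param bias_centers Window centers, A.
#' @param force_constant Harmonic force constant(s), kcal mol^-1 A^-2.
#' @return Tibble with the columns [read_umbrella_metadata()] produces.
#' @export
window_metadata <- function(bias_centers, force_constant = 100) {
  stopifnot(all(force_constant > 0))
  tibble::tibble(
    data_path = sprintf("window_%03d.dat", seq_along(bias_centers)),
    bias_center = as.numeric(bias_centers),
    force_constant = rep_len(as.numeric(force_constant),
                             length(bias_centers))
  )
}
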