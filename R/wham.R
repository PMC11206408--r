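#' Umbrella-sampling windows
#'
#' Container for one biased simulation: the collective-variable samples and
#' the harmonic bias that produced them. `discard_fraction` drops the front
#' of the series as equilibration when the window is analysed.
#'
#' @param values Numeric CV samples (A), or a tibble with a `value` column.
#' @param bias_center Harmonic bias center, A.
#' @param force_constant Bias force constant, kcal mol^-1 A^-2. Zero is
#'   allowed for an unbiased window; metadata files require > 0.
#' @param discard_fraction Fraction in `[0, 1)` discarded from the front.
#' @param times Optional sample times, ps.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(values, bias_center, force_constant,
                            discard_fraction = 0, times = NULL) {
  if (is.data.frame(values)) {
    if (is.null(times) && "time" %in% names(values)) times <- values$time
    values <- values$value
  }
  stopifnot(is.numeric(values), length(values) > 0, all(is.finite(values)))
  if (force_constant < 0) {
    stop("validation error: force_constant must be >= 0", call. = FALSE)
  }
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("validation error: discard_fraction must be in [0, 1)",
         call. = FALSE)
  }
  structure(list(values = as.numeric(values),
                 bias_center = as.numeric(bias_center),
                 force_constant = as.numeric(force_constant),
                 discard_fraction = discard_fraction,
                 times = times),
            class = "umbrella_window")
}

retained_values <- function(window) {
  v <- window$values
  n0 <- floor(length(v) * window$discard_fraction)
  v[(n0 + 1L):length(v)]
}

#' Time-block stationarity check for an umbrella window
#'
#' Splits the retained series into `n_blocks` equal blocks and compares
#' each block's histogram with the pooled histogram through the
#' Bhattacharyya coefficient `sum_b sqrt(p_b q_b)` (1 for identical
#' distributions). The window counts as equilibrated when every block
#' reaches `overlap_min`.
#'
#' @param window An [umbrella_window()].
#' @param n_blocks Number of equal time blocks.
#' @param overlap_min Minimum per-block Bhattacharyya coefficient.
#' @param bin_width Histogram bin width, A.
#' @return List with `equilibrated` (flag) and `block_overlap` (numeric,
#'   one coefficient per block).
#' @export
time_block_check <- function(window, n_blocks = 4, overlap_min = 0.9,
                             bin_width = 0.05) {
  v <- retained_values(window)
  if (length(v) < n_blocks * 10) {
    stop("validation error: retained series too short for ", n_blocks,
         " blocks (need >= ", n_blocks * 10, " samples)", call. = FALSE)
  }
  breaks <- seq(min(v) - bin_width, max(v) + bin_width, by = bin_width)
  pooled <- tabulate(findInterval(v, breaks), nbins = length(breaks))
  p <- pooled / sum(pooled)
  blocks <- split(v, cut(seq_along(v), n_blocks, labels = FALSE))
  bc <- vapply(blocks, function(b) {
    q <- tabulate(findInterval(b, breaks), nbins = length(breaks))
    sum(sqrt(p * q / sum(q)))
  }, numeric(1))
  list(equilibrated = all(bc >= overlap_min),
       block_overlap = unname(bc))
}

#' Reconstruct a 1-D free-energy profile by WHAM
#'
#' Iterates the weighted-histogram self-consistency equations
#' \deqn{P(\xi_b) = \frac{\sum_i n_i(\xi_b)}{\sum_i N_i \exp[(f_i - w_i(\xi_b))/RT]},\qquad
#'       f_i = -RT \ln \sum_b P(\xi_b) e^{-w_i(\xi_b)/RT}}
#' with harmonic biases `w_i`, until the largest change in any window
#' offset `f_i` falls below `tol`. The profile is `F = -RT ln P`, shifted
#' so its minimum is zero.
#'
#' @param windows List of [umbrella_window()] objects (>= 1).
#' @param bin_width Histogram bin width, A.
#' @param temperature Temperature, K.
#' @param tol Convergence tolerance on the window offsets, kcal mol^-1.
#' @param max_iter Maximum iterations.
#' @return A `free_energy_profile`: tibble with columns `xi` (bin centers,
#'   A) and `F` (kcal mol^-1), plus attributes `offsets`, `iterations`,
#'   `residual`, `temperature`, `bin_width`. Interior bins never visited are
#'   kept as `NA` with a warning; empty terminal bins are truncated.
#' @examples
#' w <- umbrella_window(rnorm(5000, sd = 0.5), 0, 0)
#' prof <- wham_solve(list(w), bin_width = 0.1)
#' @export
wham_solve <- function(windows, bin_width = 0.05,
                       temperature = spla2_constants$temperature_K,
                       tol = 1e-7, max_iter = 1e5) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, logical(1), "umbrella_window")))
  rt <- rt_kcal(temperature)
  vals <- lapply(windows, retained_values)
  lo <- min(vapply(vals, min, numeric(1)))
  hi <- max(vapply(vals, max, numeric(1)))
  edges <- seq(lo - bin_width / 2, hi + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  nb <- length(centers)
  nw <- length(windows)
  counts <- t(vapply(vals, function(v)
    tabulate(findInterval(v, edges), nbins = nb), numeric(nb)))
  counts <- matrix(counts, nrow = nw)
  n_tot <- rowSums(counts)
  pooled <- colSums(counts)
  check_window_overlap(windows, counts)
  # bias Boltzmann factors, windows x bins
  w_mat <- t(vapply(windows, function(w)
    0.5 * w$force_constant * (centers - w$bias_center)^2, numeric(nb)))
  w_mat <- matrix(w_mat, nrow = nw)
  bias_fac <- exp(-w_mat / rt)
  f <- numeric(nw)
  occupied <- pooled > 0
  iter <- 0L
  residual <- Inf
  p <- numeric(nb)
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- colSums((n_tot * exp(f / rt)) * bias_fac)
    p[] <- 0
    p[occupied] <- pooled[occupied] / denom[occupied]
    f_new <- -rt * log(bias_fac %*% p)
    f_new <- f_new - f_new[1]
    residual <- max(abs(f_new - f))
    f <- as.numeric(f_new)
    if (residual < tol) break
  }
  if (residual >= tol) {
    stop("convergence error: WHAM did not converge in ", max_iter,
         " iterations (residual ", signif(residual, 3), ")", call. = FALSE)
  }
  fe <- rep(NA_real_, nb)
  fe[occupied] <- -rt * log(p[occupied])
  fe <- fe - min(fe, na.rm = TRUE)
  first <- which(occupied)[1]
  last <- max(which(occupied))
  keep <- first:last
  if (any(!occupied[keep])) {
    warning("interior bins with no samples bridged as NA (",
            sum(!occupied[keep]), " bins)", call. = FALSE)
  }
  out <- tibble::tibble(xi = centers[keep], F = fe[keep])
  structure(out,
            offsets = f, iterations = iter, residual = residual,
            temperature = temperature, bin_width = bin_width,
            n_windows = nw,
            class = c("free_energy_profile", class(tibble::tibble())))
}

check_window_overlap <- function(windows, counts) {
  nw <- nrow(counts)
  if (nw == 1) return(invisible(TRUE))
  occ <- counts > 0
  adj <- matrix(FALSE, nw, nw)
  for (i in seq_len(nw - 1)) {
    for (j in (i + 1):nw) {
      adj[i, j] <- adj[j, i] <- any(occ[i, ] & occ[j, ])
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop("disconnected-support error: umbrella windows form ", comp$no,
         " disjoint groups with no histogram overlap", call. = FALSE)
  }
  ord <- order(vapply(windows, `[[`, numeric(1), "bias_center"))
  for (k in seq_len(nw - 1)) {
    i <- ord[k]; j <- ord[k + 1]
    if (!adj[i, j]) {
      warning("no histogram overlap between adjacent windows at centers ",
              windows[[i]]$bias_center, " and ", windows[[j]]$bias_center,
              call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Barrier and reaction free energy from a profile
#'
#' Locates the reactant and product minima inside their stated coordinate
#' ranges, takes the transition state as the profile maximum strictly
#' between them, and reports the activation and reaction free energies.
#'
#' @param profile A `free_energy_profile` (or tibble with `xi`, `F`).
#' @param reactant_range,product_range Length-2 coordinate ranges, A.
#' @return Tibble with `xi_reactant`, `xi_ts`, `xi_product`, `barrier`
#'   (kcal mol^-1) and `delta_g` (kcal mol^-1).
#' @export
profile_features <- function(profile, reactant_range, product_range) {
  xi <- profile$xi
  fe <- profile$F
  ok <- is.finite(fe)
  xi <- xi[ok]; fe <- fe[ok]
  in_r <- xi >= min(reactant_range) & xi <= max(reactant_range)
  in_p <- xi >= min(product_range) & xi <= max(product_range)
  if (!any(in_r) || !any(in_p)) {
    stop("feature error: reactant/product range outside profile support",
         call. = FALSE)
  }
  i_r <- which(in_r)[which.min(fe[in_r])]
  i_p <- which(in_p)[which.min(fe[in_p])]
  lo <- min(i_r, i_p); hi <- max(i_r, i_p)
  if (hi - lo < 2) {
    stop("feature error: no interior points between the two minima",
         call. = FALSE)
  }
  interior <- (lo + 1):(hi - 1)
  i_ts <- interior[which.max(fe[interior])]
  if (fe[i_ts] <= max(fe[i_r], fe[i_p])) {
    stop("feature error: no interior maximum between the minima ",
         "(monotone profile?)", call. = FALSE)
  }
  tibble::tibble(
    xi_reactant = xi[i_r], xi_ts = xi[i_ts], xi_product = xi[i_p],
    barrier = fe[i_ts] - fe[i_r],
    delta_g = fe[i_p] - fe[i_r]
  )
}
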