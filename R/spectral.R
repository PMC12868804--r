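#' Circulant sequence-generator specification
#'
#' A normative view of the attractor network as a continuous-time sequence
#' generator `tau * dU/dt = (O - C) U` on a ring of discrete states, where
#' `O` is a circulant transition operator defined by its first row and `C` a
#' constant sub-diagonal perturbation standing for the lagging adaptation
#' feedback.
#'
#' @param row First row of the circulant operator.
#' @param tau Evolution time constant.
#' @param convention Either `"stochastic"` (the row is a probability row of a
#'   transition matrix `W`; the generator used for evolution is `W - I`) or
#'   `"generator"` (the row already defines a master-equation generator).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(row, tau = 1,
                           convention = c("stochastic", "generator")) {
  convention <- match.arg(convention)
  stopifnot(length(row) >= 2, is.numeric(row))
  structure(list(row = as.numeric(row), N = length(row), tau = tau,
                 convention = convention),
            class = "generator_spec")
}

#' Sub-diagonal perturbation of a circulant generator
#'
#' The matrix `C` with value `eps` on the `s`-th upper (cyclic) diagonal and
#' zeros elsewhere; itself circulant, with first row `eps` at offset `s`.
#'
#' @param s Diagonal offset, `0 <= s < N`.
#' @param eps Amplitude (> 0).
#' @param sign `"subtract"` (default, the operator becomes `O - C`) or
#'   `"add"` (`O + C`).
#' @return An object of class `generator_perturbation`.
#' @export
perturbation <- function(s, eps = 0.01, sign = c("subtract", "add")) {
  sign <- match.arg(sign)
  stopifnot(s >= 0, eps >= 0)
  structure(list(s = as.integer(s), eps = eps, sign = sign),
            class = "generator_perturbation")
}

#' Lazy random walk on a ring
#'
#' Circulant transition row with self-probability 0.5 and probability 0.25 to
#' each ring neighbour; rows sum to 1 and the eigenvalues are
#' `0.5 + 0.5 * cos(2*pi*k/N)`.
#'
#' @param N_states Ring size (>= 4).
#' @inheritParams generator_spec
#' @return A [generator_spec()] object.
#' @export
lazy_random_walk <- function(N_states, tau = 1) {
  stopifnot(N_states >= 4)
  row <- numeric(N_states)
  row[1] <- 0.5
  row[2] <- 0.25
  row[N_states] <- 0.25
  generator_spec(row, tau = tau, convention = "stochastic")
}

#' Wrapped-Gaussian diffusion generator on a ring
#'
#' Circulant row given by a wrapped Gaussian kernel of the given width
#' (in states), normalised to sum to 1.
#'
#' @param N_states Ring size.
#' @param width Kernel width in state units (> 0).
#' @inheritParams generator_spec
#' @return A [generator_spec()] object.
#' @export
gaussian_diffusion_generator <- function(N_states, width, tau = 1) {
  stopifnot(width > 0, N_states >= 4)
  n <- 0:(N_states - 1)
  d <- pmin(n, N_states - n)
  row <- exp(-d^2 / (2 * width^2))
  generator_spec(row / sum(row), tau = tau, convention = "stochastic")
}

#' Reconstruct the dense circulant matrix from a generator spec
#'
#' Row `i` is the first row cyclically shifted right by `i - 1`, so that
#' entry `(i, j)` equals `row[(j - i) mod N + 1]`.
#'
#' @param gen A [generator_spec()] object (or a bare numeric first row).
#' @return An `N x N` matrix.
#' @export
circulant_matrix <- function(gen) {
  row <- if (inherits(gen, "generator_spec")) gen$row else as.numeric(gen)
  N <- length(row)
  idx <- (outer(seq_len(N) - 1, seq_len(N) - 1, function(i, j) (j - i) %% N)) + 1
  matrix(row[idx], N, N)
}

#' Fourier eigenmodes of circulant operators on a ring
#'
#' Column `k + 1` is `(1/sqrt(N)) * (1, w_k, w_k^2, ...)` with
#' `w_k = exp(-2*pi*1i*k/N)`. The columns are orthonormal under the complex
#' inner product and diagonalise every circulant matrix on the ring.
#'
#' @param N_states Ring size (>= 2).
#' @return A complex `N x N` matrix.
#' @export
fourier_modes <- function(N_states) {
  stopifnot(N_states >= 2)
  n <- 0:(N_states - 1)
  k <- 0:(N_states - 1)
  outer(n, k, function(n, k) exp(-2i * pi * n * k / N_states)) / sqrt(N_states)
}

#' Eigenvalues of a circulant generator (and their perturbations)
#'
#' The eigenvalues of a circulant operator are the discrete Fourier
#' transform of its first row, `lambda_k = sum_n a_n * w_k^n`. When a
#' sub-diagonal perturbation `(s, eps)` is supplied, the analytic eigenvalue
#' shifts `delta_k = +/- eps * w_k^s` (all of magnitude `eps`) are included
#' together with the rescaling ratios `|lambda_k'| / |lambda_k|`.
#'
#' @param gen A [generator_spec()] object.
#' @param pert Optional [perturbation()] object.
#' @return A `can_spectrum` tibble with columns `k`, `lambda` (complex) and,
#'   with a perturbation, `delta`, `lambda_pert` and `ratio` (`NA` where the
#'   unperturbed eigenvalue vanishes).
#' @export
circulant_eigenvalues <- function(gen, pert = NULL) {
  lambda <- stats::fft(gen$row)
  out <- tibble::tibble(k = 0:(gen$N - 1), lambda = lambda)
  if (!is.null(pert)) {
    sgn <- if (pert$sign == "subtract") -1 else 1
    delta <- sgn * pert$eps * exp(-2i * pi * out$k * pert$s / gen$N)
    out$delta <- delta
    out$lambda_pert <- out$lambda + delta
    out$ratio <- ifelse(Mod(out$lambda) > 0,
                        Mod(out$lambda_pert) / Mod(out$lambda), NA_real_)
  }
  class(out) <- c("can_spectrum", class(out))
  out
}

#' @rdname circulant_eigenvalues
#' @export
perturbed_eigenvalues <- function(gen, pert) {
  circulant_eigenvalues(gen, pert = pert)
}

#' Offset at which the principal eigenvalue switches from damped to amplified
#'
#' Scans perturbation offsets `s = 1, ..., N-1` and returns the smallest `s`
#' at which the perturbed principal eigenvalue (mode `k = 1`; `k = 0` is the
#' constant mode) exceeds its unperturbed magnitude, together with the
#' symmetric partner `N - s`.
#'
#' @param gen A [generator_spec()] object.
#' @param eps Perturbation amplitude (default 0.01, the small-`eps` regime).
#' @param sign Perturbation sign convention, see [perturbation()].
#' @return A list with `s_star`, `partner` and the scan tibble `profile`
#'   (columns `s`, `mod_pert`, `amplified`); `s_star` is `NA` when no
#'   crossing occurs.
#' @examples
#' amplification_boundary(lazy_random_walk(100))$s_star  # 25
#' @export
amplification_boundary <- function(gen, eps = 0.01,
                                   sign = c("subtract", "add")) {
  sign <- match.arg(sign)
  lambda1 <- stats::fft(gen$row)[2]
  sgn <- if (sign == "subtract") -1 else 1
  s <- seq_len(gen$N - 1)
  mod_pert <- Mod(lambda1 + sgn * eps * exp(-2i * pi * s / gen$N))
  amplified <- mod_pert > Mod(lambda1)
  s_star <- if (any(amplified)) s[which(amplified)[1]] else NA_integer_
  list(s_star = s_star,
       partner = if (is.na(s_star)) NA_integer_ else gen$N - s_star,
       profile = tibble::tibble(s = s, mod_pert = mod_pert,
                                amplified = amplified))
}

#' Eigenvalue rescaling profile under perturbation
#'
#' Ratios between perturbed and unperturbed eigenvalue magnitudes for the
#' top-`K` modes (ordered by decreasing unperturbed magnitude). Modes whose
#' unperturbed eigenvalue vanishes are omitted with a warning. Small offsets
#' suppress the low-frequency (large-spatial-scale) modes; large offsets
#' produce an oscillatory rescaling pattern over modes.
#'
#' @param gen A [generator_spec()] object.
#' @param pert A [perturbation()] object.
#' @param top_k Number of leading modes to report (default 20).
#' @return A tibble with columns `rank`, `k`, `mod0`, `ratio`.
#' @export
rescaling_spectrum <- function(gen, pert, top_k = 20) {
  sp <- circulant_eigenvalues(gen, pert)
  zero <- Mod(sp$lambda) == 0
  if (any(zero)) {
    warning(sum(zero), " mode(s) with zero unperturbed eigenvalue omitted")
    sp <- sp[!zero, ]
  }
  sp |>
    dplyr::mutate(mod0 = Mod(.data$lambda)) |>
    dplyr::arrange(dplyr::desc(.data$mod0), .data$k) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "k", "mod0", "ratio")
}

#' Evolve a state distribution under the perturbed generator
#'
#' Euler integration of `tau * dU/dt = (O - I - C) U` (stochastic-row
#' convention; the identity is not subtracted when the generator uses the
#' `"generator"` convention). After each step negative entries are clipped
#' to zero and the vector renormalised to total mass 1 so it remains a valid
#' probability distribution.
#'
#' @param gen A [generator_spec()] object.
#' @param pert A [perturbation()] object (use `eps = 0` for no perturbation).
#' @param U0 Initial distribution (nonnegative, sums to 1).
#' @param dt Euler step (same units as `gen$tau`).
#' @param n_steps Number of steps.
#' @return A list with `times` and `states` (matrix `(n_steps + 1) x N`,
#'   each row a distribution).
#' @export
evolve_states <- function(gen, pert, U0, dt, n_steps) {
  stopifnot(length(U0) == gen$N, all(U0 >= 0))
  stopifnot(abs(sum(U0) - 1) < 1e-8)
  A <- circulant_matrix(gen)
  if (gen$convention == "stochastic") A <- A - diag(gen$N)
  if (pert$eps > 0) {
    crow <- numeric(gen$N)
    crow[pert$s + 1] <- pert$eps
    C <- circulant_matrix(crow)
    A <- if (pert$sign == "subtract") A - C else A + C
  }
  states <- matrix(0, n_steps + 1, gen$N)
  U <- as.numeric(U0)
  states[1, ] <- U
  for (i in seq_len(n_steps)) {
    U <- U + (dt / gen$tau) * as.numeric(A %*% U)
    U[U < 0] <- 0
    tot <- sum(U)
    if (tot <= 0) stop("state mass collapsed to zero during evolution",
                       call. = FALSE)
    U <- U / tot
    states[i + 1, ] <- U
  }
  list(times = (0:n_steps) * dt, states = states)
}

#' Sample a state trajectory from evolving distributions
#'
#' Draws one categorical sample per `stride`-th distribution, producing a
#' discrete trajectory over ring states.
#'
#' @param evolution Result of [evolve_states()] (or a bare state matrix).
#' @param stride Sample every `stride`-th distribution (default 1).
#' @param seed Optional integer seed.
#' @return A tibble with columns `time` and `state` (0-based ring state).
#' @export
sample_trajectory <- function(evolution, stride = 1L, seed = NULL) {
  states <- if (is.list(evolution)) evolution$states else evolution
  times <- if (is.list(evolution)) evolution$times else seq_len(nrow(states)) - 1
  if (!is.null(seed)) set.seed(seed)
  idx <- seq(1, nrow(states), by = stride)
  state <- vapply(idx, function(i) {
    p <- states[i, ]
    sample.int(ncol(states), 1, prob = p) - 1L
  }, integer(1))
  tibble::tibble(time = times[idx], state = state)
}
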