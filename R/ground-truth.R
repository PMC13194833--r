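#' Ground-truth generative specification for a synthetic EEG subject
#'
#' Defines the stable MVAR(p) source process, the instantaneous (zero-lag)
#' mixing matrix standing in for volume conduction, the innovation covariance,
#' artifact rates/amplitudes and the intended group topology shift. The
#' companion matrix of the coupling stack must have spectral radius < 1.
#'
#' @param coupling numeric array `n_channels x n_channels x p`;
#'   `coupling[i, j, k]` is the influence of channel `j` at lag `k` on
#'   channel `i`.
#' @param noise_cov innovation covariance, symmetric positive definite
#'   (default identity).
#' @param mixing zero-lag mixing matrix with unit diagonal (default identity:
#'   no volume conduction).
#' @param artifact_spec list with optional entries `line` (list: `amplitude`
#'   in uV), `blink` (list: `rate` per s, `amplitude`), `emg` (list: `rate`
#'   per s, `amplitude`). Missing entries mean the artifact is not injected.
#' @param group_effect list describing the topology shift applied to the
#'   exposed group: `list(type = "edge_removal", fraction = f)` deletes a
#'   fraction of coupling edges; `list(type = "desegregation", fraction = f)`
#'   rewires a fraction of within-module edges to random cross-module
#'   positions (lowering true clustering/modularity while preserving edge
#'   count); `NULL` for none.
#' @param modules optional integer module label per channel (used by the
#'   desegregation effect; set by [template_coupling()]).
#' @param seed integer seed governing all randomness derived from this spec.
#' @return Object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(coupling,
                              noise_cov = NULL,
                              mixing = NULL,
                              artifact_spec = list(),
                              group_effect = NULL,
                              modules = NULL,
                              seed = 1L) {
  if (length(dim(coupling)) == 2L) coupling <- array(coupling, c(dim(coupling), 1L))
  stopifnot(length(dim(coupling)) == 3L, dim(coupling)[1L] == dim(coupling)[2L])
  n <- dim(coupling)[1L]
  if (is.null(noise_cov)) noise_cov <- diag(n)
  if (is.null(mixing)) mixing <- diag(n)
  if (!isTRUE(all.equal(noise_cov, t(noise_cov))) ||
      any(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("noise_cov must be symmetric positive definite")
  if (any(abs(diag(mixing) - 1) > 1e-12))
    stop("mixing must have unit diagonal")
  sr <- spectral_radius(coupling)
  if (sr >= 1)
    stop(sprintf("unstable MVAR specification: companion spectral radius %.4f >= 1", sr))
  structure(
    list(n_channels = n, mvar_order = dim(coupling)[3L], coupling = coupling,
         noise_cov = noise_cov, mixing = mixing, artifact_spec = artifact_spec,
         group_effect = group_effect, modules = modules,
         seed = as.integer(seed), spectral_radius = sr),
    class = "ground_truth_spec")
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat(sprintf("<ground_truth_spec> %d channels, MVAR(%d), spectral radius %.3f\n",
              x$n_channels, x$mvar_order, x$spectral_radius))
  cat(sprintf("  coupled pairs: %d, artifacts: %s, group effect: %s\n",
              sum(apply(x$coupling != 0, c(1, 2), any)) - sum(diag(apply(x$coupling != 0, c(1, 2), any))),
              if (length(x$artifact_spec)) paste(names(x$artifact_spec), collapse = "+") else "none",
              if (is.null(x$group_effect)) "none" else x$group_effect$type))
  invisible(x)
}

#' Spectral radius of the companion matrix of an MVAR coefficient stack
#'
#' @param coupling array `n x n x p` of lag matrices.
#' @return Largest eigenvalue modulus of the `np x np` companion matrix;
#'   the process is stable iff this is < 1.
#' @export
spectral_radius <- function(coupling) {
  if (length(dim(coupling)) == 2L) coupling <- array(coupling, c(dim(coupling), 1L))
  n <- dim(coupling)[1L]; p <- dim(coupling)[3L]
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1L) * n + 1L):(k * n)] <- coupling[, , k]
  if (p > 1L) comp[(n + 1L):(n * p), 1:(n * (p - 1L))] <- diag(n * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Analytic transfer matrix of a ground-truth MVAR specification
#'
#' H(f) = [I - sum_k A_k exp(-i 2 pi f k / fs)]^{-1}, the frequency-domain
#' transfer function of the specified source process (before mixing). Used as
#' the closed-form oracle the estimated DTF must converge to.
#'
#' @param spec a [ground_truth_spec()] (or a bare coupling array).
#' @param freqs frequency grid in Hz.
#' @param fs sampling rate in Hz.
#' @return Complex array `n x n x length(freqs)`.
#' @export
analytic_transfer <- function(spec, freqs, fs) {
  coupling <- if (inherits(spec, "ground_truth_spec")) spec$coupling else spec
  if (length(dim(coupling)) == 2L) coupling <- array(coupling, c(dim(coupling), 1L))
  n <- dim(coupling)[1L]; p <- dim(coupling)[3L]
  H <- array(complex(real = 0), c(n, n, length(freqs)))
  for (b in seq_along(freqs)) {
    Af <- diag(n) + 0i
    for (k in seq_len(p))
      Af <- Af - coupling[, , k] * exp(-2i * pi * freqs[b] * k / fs)
    H[, , b] <- solve(Af)
  }
  H
}
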