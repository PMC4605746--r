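#' B-spline basis evaluation
#'
#' Standard B-spline basis (Cox–de Boor) on the given knot sequence, with
#' boundary knots repeated to full multiplicity.  Inside the knot span the
#' basis is a partition of unity (each row sums to 1).
#'
#' @param x evaluation points; must lie within \code{[min(knots), max(knots)]}.
#' @param knots ascending knot sequence including the boundary knots.
#' @param order spline order (4 = cubic, the default; 1 = piecewise constant).
#' @return matrix with one row per point and one column per basis function
#'   (\code{length(knots) + order - 2} columns).
#' @examples
#' B <- bspline_basis(seq(0, 1, 0.1), knots = c(0, .25, .5, .75, 1))
#' rowSums(B)  # all 1
#' @export
bspline_basis <- function(x, knots, order = 4) {
  .check(order >= 1, "`order` must be >= 1")
  knots <- sort(as.numeric(knots))
  .check(length(knots) >= 2, "need at least two knots")
  lo <- knots[1]; hi <- knots[length(knots)]
  bad <- which(x < lo - 1e-12 | x > hi + 1e-12)
  if (length(bad))
    stop(sprintf("point %g outside the knot span [%g, %g]",
                 x[bad[1]], lo, hi), call. = FALSE)
  x <- pmin(pmax(x, lo), hi)
  aug <- c(rep(lo, order - 1), knots, rep(hi, order - 1))
  splines::splineDesign(aug, x, ord = order)
}

#' Circular (periodic) spline basis for phase effects
#'
#' Truncated cosine-series basis around equally spaced knots on
#' \eqn{[-\pi, \pi]}:
#' \deqn{r_k(\phi) = \sum_{m=1}^{m_{max}} \frac{2}{(2\pi m)^4}
#'   \cos(m(\phi - \phi_k))}
#' (the \code{"radian"} convention, periodic with period \eqn{2\pi}).  The
#' \code{"literal"} convention instead uses \eqn{\cos(2\pi m(\phi-\phi_k))},
#' the series exactly as printed in the source formulation, which with radian
#' phases has period 1; it is retained for textual fidelity only.
#'
#' @param phi phases in radians (wrapped to \eqn{[-\pi,\pi)} internally).
#' @param knots knot phases; default \code{n_knots} equally spaced on
#'   \eqn{[-\pi, \pi)}.
#' @param n_knots number of equally spaced knots used when \code{knots} is
#'   NULL (default 6).
#' @param m_max number of harmonics kept (default 4; the term amplitude decays
#'   as \eqn{m^{-4}}).
#' @param convention \code{"radian"} (default) or \code{"literal"}.
#' @return matrix with one row per phase and one column per knot.
#' @examples
#' R <- circular_basis(seq(-pi, pi, length.out = 9))
#' @export
circular_basis <- function(phi, knots = NULL, n_knots = 6, m_max = 4,
                           convention = c("radian", "literal")) {
  convention <- match.arg(convention)
  .check(m_max >= 1, "`m_max` must be at least 1")
  if (is.null(knots)) knots <- phase_knots(n_knots)
  phi <- wrap_phase(phi)
  D <- outer(phi, knots, `-`)
  out <- matrix(0, nrow(D), ncol(D))
  for (m in seq_len(m_max)) {
    arg <- if (convention == "radian") m * D else 2 * pi * m * D
    out <- out + (2 / (2 * pi * m)^4) * cos(arg)
  }
  dimnames(out) <- list(NULL, sprintf("phi%d", seq_along(knots)))
  out
}

#' Equally spaced phase knots on \eqn{[-\pi, \pi)}
#'
#' @param n number of knots.
#' @return numeric vector of length \code{n}.
#' @export
phase_knots <- function(n = 6) {
  seq(-pi, pi, length.out = n + 1)[seq_len(n)]
}

#' Default knot sequences for the three model terms
#'
#' Stimulus knots are equally spaced over the trial; history knots are
#' log-spaced over the short-lag span (default 200 ms, where post-spike
#' effects act); phase knots are equally spaced on \eqn{[-\pi,\pi)}.  All are
#' conventional starting points and can be overridden in \code{\link{ppm}}.
#'
#' @param trial_length trial duration in seconds.
#' @param n_stimulus number of stimulus knots (default 10).
#' @param n_history number of history knots (default 8).
#' @param history_span history lag span in seconds (default 0.2).
#' @param n_phase number of phase knots (default 6).
#' @return list with components \code{stimulus}, \code{history}, \code{phase}.
#' @export
default_knots <- function(trial_length, n_stimulus = 10, n_history = 8,
                          history_span = 0.2, n_phase = 6) {
  list(stimulus = seq(0, trial_length, length.out = n_stimulus),
       history = c(0, exp(seq(log(history_span / 50), log(history_span),
                              length.out = n_history - 1))),
       phase = phase_knots(n_phase))
}

#' Serialize a basis definition to JSON
#'
#' @param kind \code{"bspline"} or \code{"circular"}.
#' @param knots knot sequence.
#' @param order B-spline order (ignored for circular).
#' @param m_max harmonic cutoff (circular only).
#' @return JSON string.
#' @export
basis_to_json <- function(kind, knots, order = 4, m_max = 4) {
  jsonlite::toJSON(list(kind = kind, knots = knots, order = order,
                        m_max = m_max), auto_unbox = TRUE, digits = NA)
}
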