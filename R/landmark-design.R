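#' Landmark analysis design
#'
#' Fixes the prediction window `w`, the landmark grid `s_1..s_L`, and the
#' time-function bases: `f_j(s)` carry the landmark-varying coefficients
#' `beta_LM(s) = sum_j theta_j f_j(s)`, and `g_j(s)` carry the landmark
#' main effect `gamma(s)` of the proportional-baselines supermodel (each
#' `g_j` must vanish at `s_1` for identifiability). Default bases are the
#' polynomial functions of the normalized landmark `s / s_L`: `f = {1,
#' s/s_L, (s/s_L)^2}` and `g = {s/s_L, (s/s_L)^2}` — with the default grid
#' `0, 0.1, ..., 3` these are `1, s/3, (s/3)^2`. The normalization constant
#' is taken from the grid, so other grids generalize unchanged.
#'
#' @param w window width in years (> 0, may be `Inf`)
#' @param grid nondecreasing landmark points
#' @param f_basis list of functions of `s` (default polynomial in `s/s_L`)
#' @param g_basis list of functions of `s`, each zero at `grid[1]`
#' @param f_labels,g_labels names for the basis columns
#' @return object of class `landmark_design`
#' @export
landmark_design <- function(w = 5, grid = seq(0, 3, by = 0.1),
                            f_basis = NULL, g_basis = NULL,
                            f_labels = NULL, g_labels = NULL) {
  if (w <= 0) stop("window width w must be positive")
  if (!length(grid) || any(diff(grid) < 0)) stop("grid must be nondecreasing")
  sL <- max(grid)
  norm <- if (sL > 0) sL else 1
  if (is.null(f_basis)) {
    f_basis <- list(function(s) rep(1, length(s)),
                    function(s) s / norm,
                    function(s) (s / norm)^2)
    if (is.null(f_labels)) f_labels <- c("constant", "linear", "quadratic")
  }
  if (is.null(g_basis)) {
    g_basis <- list(function(s) s / norm,
                    function(s) (s / norm)^2)
    if (is.null(g_labels)) g_labels <- c("linear", "quadratic")
  }
  if (is.null(f_labels)) f_labels <- paste0("f", seq_along(f_basis))
  if (is.null(g_labels)) g_labels <- paste0("g", seq_along(g_basis))
  structure(list(w = w, grid = grid, s_max = sL,
                 f_basis = f_basis, g_basis = g_basis,
                 f_labels = f_labels, g_labels = g_labels),
            class = "landmark_design")
}

#' One-indicator-per-landmark ("saturated") coefficient basis
#'
#' With this `f_basis` the stratified supermodel places a free coefficient
#' at every landmark and therefore reproduces the separate per-landmark
#' ("crude") Cox fits exactly.
#' @param grid landmark points
#' @return list of indicator functions of `s`
#' @export
saturated_basis <- function(grid) {
  lapply(grid, function(s0) {
    force(s0)
    function(s) as.numeric(abs(s - s0) < 1e-9)
  })
}

# evaluate a basis list at landmark values: length(s) x nbasis matrix
eval_basis <- function(basis, s) {
  m <- vapply(basis, function(f) as.numeric(f(s)), numeric(length(s)))
  matrix(m, nrow = length(s), ncol = length(basis))
}

#' @export
print.landmark_design <- function(x, ...) {
  cat(sprintf("landmark design: w=%g, %d landmarks in [%g, %g], %d f-basis, %d g-basis\n",
              x$w, length(x$grid), min(x$grid), max(x$grid),
              length(x$f_basis), length(x$g_basis)))
  invisible(x)
}
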