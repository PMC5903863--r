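#' Parameters of the GAT1--DAL80--MEP2 incoherent feedforward loop
#'
#' Constructs a validated parameter set for the linear I1-FFL model
#' \deqn{dGAT1/dt = 0}
#' \deqn{dDAL80/dt = A X \cdot GAT1 - c \cdot DAL80}
#' \deqn{dMEP2/dt = A \cdot GAT1 - R \cdot DAL80 - c \cdot MEP2}
#' where GAT1 activates both the target gene MEP2 (strength `A`) and the
#' repressor DAL80 (strength `A * X`), and DAL80 represses MEP2
#' (strength `R`). All species decay with first-order rate `c`.
#'
#' @param A Activation strength of the MEP2 promoter by GAT1 (rate units,
#'   arbitrary). Must be >= 0.
#' @param X Dimensionless multiplier: the DAL80 promoter is activated at rate
#'   `A * X`. Must be >= 0.
#' @param R Strength of MEP2 repression by DAL80 (rate units). Must be >= 0.
#' @param c First-order degradation rate constant (1/time). Must be > 0.
#' @param gat1 Constant GAT1 level (arbitrary concentration units). Must
#'   be >= 0.
#' @return An object of class `ffl_params` (a named list of the five values).
#' @examples
#' p <- ffl_params(A = 1, X = 0.4, R = 2, c = 1, gat1 = 1)
#' analytic_steady_state(p)
#' @export
ffl_params <- function(A = 1, X = 0.4, R = 2, c = 1, gat1 = 1) {
  vals <- c(A = A, X = X, R = R, c = c, gat1 = gat1)
  if (!all(is.finite(vals)))
    stop("all FFL parameters must be finite numbers", call. = FALSE)
  if (A < 0 || X < 0 || R < 0 || gat1 < 0)
    stop("A, X, R and gat1 must be non-negative", call. = FALSE)
  if (c <= 0)
    stop("degradation rate constant 'c' must be strictly positive",
         call. = FALSE)
  structure(list(A = A, X = X, R = R, c = c, gat1 = gat1),
            class = "ffl_params")
}

as_ffl_params <- function(x) {
  if (inherits(x, "ffl_params")) return(x)
  if (is.list(x) && all(c("A", "X", "R", "c", "gat1") %in% names(x)))
    return(ffl_params(x$A, x$X, x$R, x$c, x$gat1))
  stop("expected an 'ffl_params' object", call. = FALSE)
}

#' @export
print.ffl_params <- function(x, ...) {
  cat("I1-FFL parameters: A =", x$A, " X =", x$X, " R =", x$R,
      " c =", x$c, " GAT1 =", x$gat1, "\n")
  invisible(x)
}

#' Closed-form steady state of the I1-FFL
#'
#' Setting the time derivatives to zero gives
#' `dal80_ss = A * X * gat1 / c` and
#' `mep2_ss = (A * gat1 - R * dal80_ss) / c`.
#' The model is linear, so `mep2_ss` can be negative when repression outweighs
#' activation (`X > c / R`); the raw value is reported and flagged, never
#' clamped.
#'
#' @param params An [ffl_params()] object.
#' @return A list of class `ffl_steady_state` with elements `dal80_ss`,
#'   `mep2_ss`, `method` (`"analytic"`), `residual` (0 exactly), `converged`
#'   (`TRUE`) and `negative_mep2` flag.
#' @examples
#' analytic_steady_state(ffl_params(A = 1, X = 0.4, R = 2, c = 1, gat1 = 1))
#' @export
analytic_steady_state <- function(params) {
  p <- as_ffl_params(params)
  dal80_ss <- p$A * p$X * p$gat1 / p$c
  mep2_ss <- (p$A * p$gat1 - p$R * dal80_ss) / p$c
  structure(list(dal80_ss = dal80_ss, mep2_ss = mep2_ss,
                 method = "analytic", residual = 0, converged = TRUE,
                 negative_mep2 = mep2_ss < 0),
            class = "ffl_steady_state")
}

#' @export
print.ffl_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s): DAL80 = %.6g, MEP2 = %.6g%s\n",
              x$method, x$dal80_ss, x$mep2_ss,
              if (isTRUE(x$negative_mep2)) " [negative MEP2]" else ""))
  invisible(x)
}

ffl_derivs <- function(t, y, p) {
  list(c(gat1 = 0,
         dal80 = p$A * p$X * y[["gat1"]] - p$c * y[["dal80"]],
         mep2 = p$A * y[["gat1"]] - p$R * y[["dal80"]] - p$c * y[["mep2"]]))
}

#' Numerically integrate the I1-FFL
#'
#' Integrates the three coupled ODEs with an adaptive-step, stiff-capable
#' solver ([deSolve::ode()], `lsoda`, absolute and relative tolerance 1e-9).
#' The final state is reported as a numeric steady state when the maximum
#' absolute time derivative falls at or below `tol`.
#'
#' @param params An [ffl_params()] object; its `gat1` is ignored in favour of
#'   the initial condition (GAT1 is conserved: `dGAT1/dt = 0`).
#' @param initial Named numeric vector `c(gat1 =, dal80 =, mep2 =)`; defaults
#'   to `c(1, 0, 0)`, the induction condition.
#' @param t_end End time; defaults to `100 / c` (many decay half-lives, ample
#'   for relaxation of a linear system).
#' @param tol Residual threshold below which the final state counts as a
#'   steady state (default 1e-8).
#' @param n_steps Number of output time points along the trajectory.
#' @return A list of class `ffl_trajectory`: `trajectory` (data.frame with
#'   columns `time`, `gat1`, `dal80`, `mep2`) and `steady_state` (class
#'   `ffl_steady_state`, `method = "numeric"`).
#' @examples
#' tr <- integrate_ffl(ffl_params(A = 1, X = 0.4, R = 2, c = 1))
#' tr$steady_state
#' max(tr$trajectory$mep2)  # transient pulse above the steady state
#' @export
integrate_ffl <- function(params, initial = c(gat1 = 1, dal80 = 0, mep2 = 0),
                          t_end = NULL, tol = 1e-8, n_steps = 201) {
  p <- as_ffl_params(params)
  if (is.null(t_end)) t_end <- 100 / p$c
  if (t_end < 0) stop("t_end must be >= 0", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  y0 <- c(gat1 = unname(initial[["gat1"]]),
          dal80 = unname(initial[["dal80"]]),
          mep2 = unname(initial[["mep2"]]))
  if (t_end == 0) {
    traj <- data.frame(time = 0, gat1 = y0[["gat1"]], dal80 = y0[["dal80"]],
                       mep2 = y0[["mep2"]])
  } else {
    times <- seq(0, t_end, length.out = max(2L, n_steps))
    sol <- deSolve::ode(y = y0, times = times, func = ffl_derivs, parms = p,
                        rtol = 1e-9, atol = 1e-9)
    traj <- as.data.frame(sol)
    if (!all(is.finite(as.matrix(traj))))
      stop("integration produced non-finite state", call. = FALSE)
  }
  fin <- traj[nrow(traj), ]
  d <- ffl_derivs(fin$time, c(gat1 = fin$gat1, dal80 = fin$dal80,
                              mep2 = fin$mep2), p)[[1]]
  residual <- max(abs(d))
  ss <- structure(list(dal80_ss = fin$dal80, mep2_ss = fin$mep2,
                       method = "numeric", residual = residual,
                       converged = residual <= tol,
                       negative_mep2 = fin$mep2 < 0),
                  class = "ffl_steady_state")
  structure(list(trajectory = traj, steady_state = ss, params = p),
            class = "ffl_trajectory")
}

#' Sweep MEP2 steady state over a grid of activation parameters
#'
#' Evaluates the closed-form MEP2 steady state over an (A, X) grid at fixed
#' `R`, `c` and `gat1`, and expresses every cell relative to a reference
#' (ancestral) parameter pair. Cells with relative value above 1 mark
#' mutant parameter combinations that increase MEP2 output -- including the
#' characteristic region where both `A` and `X` decrease yet MEP2 rises.
#'
#' @param a_values Ordered numeric grid of A values (non-empty).
#' @param x_values Ordered numeric grid of X values (non-empty).
#' @param R,c,gat1 Fixed remaining parameters (defaults 2, 1, 1).
#' @param reference Length-2 numeric `c(A, X)` taken as the ancestral state;
#'   evaluated exactly whether or not it lies on the grid. Default
#'   `c(1, 0.4)`, an ancestral state in which MEP2 promoter activation
#'   exceeds DAL80 promoter activation.
#' @return A list of class `ffl_sweep`: `a_values`, `x_values`,
#'   `mep2_matrix` (|A| x |X|), `reference`, `reference_mep2`,
#'   `relative_matrix` (`NULL` with a warning when the reference steady state
#'   is 0), `increased_mask` (logical, `relative_matrix > 1`) and
#'   `reference_undefined` flag.
#' @examples
#' sw <- sweep_parameter_grid(seq(0, 2, length.out = 21),
#'                            seq(0, 1, length.out = 21))
#' mean(sw$increased_mask)  # fraction of parameter space raising MEP2
#' @export
sweep_parameter_grid <- function(a_values = seq(0, 2, length.out = 101),
                                 x_values = seq(0, 1, length.out = 101),
                                 R = 2, c = 1, gat1 = 1,
                                 reference = c(1, 0.4)) {
  if (length(a_values) < 1 || length(x_values) < 1)
    stop("parameter grids must be non-empty", call. = FALSE)
  mep2_ss_closed <- function(A, X) (A * gat1 - R * A * X * gat1 / c) / c
  if (c <= 0) stop("degradation rate constant 'c' must be > 0", call. = FALSE)
  mep2_matrix <- outer(a_values, x_values, mep2_ss_closed)
  dimnames(mep2_matrix) <- list(A = signif(a_values, 8),
                                X = signif(x_values, 8))
  ref_mep2 <- mep2_ss_closed(reference[1], reference[2])
  if (ref_mep2 == 0) {
    warning("reference steady state is 0; relative matrix undefined, ",
            "reporting absolute MEP2 only", call. = FALSE)
    relative_matrix <- NULL
    increased_mask <- NULL
    undefined <- TRUE
  } else {
    relative_matrix <- mep2_matrix / ref_mep2
    increased_mask <- relative_matrix > 1
    undefined <- FALSE
  }
  structure(list(a_values = a_values, x_values = x_values,
                 mep2_matrix = mep2_matrix, reference = reference,
                 reference_mep2 = ref_mep2,
                 relative_matrix = relative_matrix,
                 increased_mask = increased_mask,
                 reference_undefined = undefined,
                 R = R, c = c, gat1 = gat1),
            class = "ffl_sweep")
}

#' @export
print.ffl_sweep <- function(x, ...) {
  cat(sprintf("I1-FFL sweep: %d x %d (A, X) grid, R = %g, c = %g, gat1 = %g\n",
              length(x$a_values), length(x$x_values), x$R, x$c, x$gat1))
  if (x$reference_undefined) {
    cat("reference MEP2 steady state is 0; absolute values only\n")
  } else {
    cat(sprintf("reference (A = %g, X = %g): MEP2 = %g; %.1f%% of cells increased\n",
                x$reference[1], x$reference[2], x$reference_mep2,
                100 * mean(x$increased_mask)))
  }
  invisible(x)
}

#' MEP2 steady-state expression of a mutant relative to an ancestor
#'
#' @param mutant,ancestor [ffl_params()] objects.
#' @return `mep2_ss(mutant) / mep2_ss(ancestor)`.
#' @examples
#' anc <- ffl_params(A = 1, X = 0.4, R = 2, c = 1)
#' mut <- ffl_params(A = 0.8, X = 0.2, R = 2, c = 1)
#' relative_mep2(mut, anc)  # 2.4: both activations down, MEP2 up
#' @export
relative_mep2 <- function(mutant, ancestor) {
  anc <- analytic_steady_state(ancestor)
  if (anc$mep2_ss == 0)
    stop("ancestor MEP2 steady state is 0; relative expression undefined",
         call. = FALSE)
  analytic_steady_state(mutant)$mep2_ss / anc$mep2_ss
}

#' MEP2 steady state as a function of the GAT1 level
#'
#' The steady state is exactly linear in `gat1`:
#' `mep2_ss = A * gat1 * (1 - R * X / c) / c`, so raising GAT1 raises MEP2
#' whenever net activation is positive (`X < c / R`).
#'
#' @param params An [ffl_params()] object; its `gat1` field is replaced by
#'   each level in turn.
#' @param gat1_levels Non-negative numeric vector of GAT1 levels.
#' @return Numeric vector of `mep2_ss`, one per level.
#' @examples
#' gat1_dose_response(ffl_params(A = 1, X = 0.4, R = 2, c = 1), c(1, 2, 4))
#' @export
gat1_dose_response <- function(params, gat1_levels) {
  p <- as_ffl_params(params)
  if (any(gat1_levels < 0))
    stop("gat1_levels must be non-negative", call. = FALSE)
  vapply(gat1_levels, function(g)
    analytic_steady_state(ffl_params(p$A, p$X, p$R, p$c, g))$mep2_ss,
    numeric(1))
}
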