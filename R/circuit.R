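#' Build the default miR-520c-3p synthetic circuit
#'
#' The circuit couples a three-gene repressilator ring with a
#' Lac-operon-style toggle: `r1 -| r2 -| LacR -| r1`, and active LacR
#' (the fraction not sequestered by IPTG) additionally represses the
#' polycistronic output promoter transcribing miR-520c-3p together with
#' its GFP reporter. IPTG is an external input treated as an instantaneous
#' equilibrium: `LacR_free = LacR / (1 + (IPTG / K_I)^h)`.
#'
#' Each gene follows
#' `d[x]/dt = alpha0 + alpha * Kd^n / (Kd^n + R^n) - delta * x`
#' where `R` is the concentration of its (active) repressor. Defaults are
#' nominal dimensionless repressilator-style values (`alpha = 50`,
#' `alpha0 = 0.05`, `n = 2`, `Kd = 10` for the ring, `delta = 1`,
#' `K_I = 1`, `h = 2`); the output promoter uses a tighter operator
#' (`Kd_out = 2`) so that basal ring-level LacR keeps the output firmly
#' OFF without IPTG, and the GFP reporter degrades more slowly than the
#' miRNA (`delta_gfp = 0.5`), as fluorescent reporter proteins are far
#' more stable than small RNAs.
#'
#' @param overrides named list of parameter overrides (`alpha`, `alpha0`,
#'   `n`, `Kd`, `Kd_out`, `delta`, `delta_gfp`, `K_I`, `h`).
#' @return list of class `circuit_model` with elements `species`,
#'   `params`.
#' @examples
#' model <- build_default_circuit()
#' model$species
#' @export
build_default_circuit <- function(overrides = list()) {
  params <- list(alpha = 50, alpha0 = 0.05, n = 2, Kd = 10, Kd_out = 2,
                 delta = 1, delta_gfp = 0.5, K_I = 1, h = 2)
  unknown <- setdiff(names(overrides), names(params))
  abort_if(length(unknown) > 0,
           paste0("unknown circuit parameter(s): ",
                  paste(unknown, collapse = ", ")))
  params[names(overrides)] <- overrides
  with(params, {
    abort_if(alpha < 0 || alpha0 < 0 || delta < 0 || delta_gfp < 0,
             "rates must be non-negative")
    abort_if(n < 1 || h < 1, "Hill coefficients must be >= 1")
    abort_if(Kd <= 0 || Kd_out <= 0 || K_I <= 0,
             "dissociation constants must be positive")
  })
  structure(list(
    species = c("r1", "r2", "LacR", "miR520c", "GFP"),
    inputs = "IPTG",
    params = params
  ), class = "circuit_model")
}

lacr_free <- function(lacr, iptg, params) {
  lacr / (1 + (iptg / params$K_I)^params$h)
}

hill_repress <- function(R, Kd, n) Kd^n / (Kd^n + R^n)

circuit_derivs <- function(t, state, parms) {
  p <- parms$params
  iptg <- parms$iptg_fun(t)
  lf <- lacr_free(state[["LacR"]], iptg, p)
  act_ring <- function(R) p$alpha0 + p$alpha * hill_repress(R, p$Kd, p$n)
  act_out <- p$alpha0 + p$alpha * hill_repress(lf, p$Kd_out, p$n)
  list(c(
    r1 = act_ring(lf) - p$delta * state[["r1"]],
    r2 = act_ring(state[["r1"]]) - p$delta * state[["r2"]],
    LacR = act_ring(state[["r2"]]) - p$delta * state[["LacR"]],
    miR520c = act_out - p$delta * state[["miR520c"]],
    GFP = act_out - p$delta_gfp * state[["GFP"]]
  ))
}

#' Deterministic simulation of the circuit
#'
#' Integrates the circuit ODEs with a stiff-capable solver
#' (`deSolve::lsoda`, relative tolerance `1e-8`) and samples the solution
#' on a uniform grid. Tiny negative solver excursions are clamped to zero.
#'
#' @param model a [build_default_circuit()] model.
#' @param t_end final time (> 0).
#' @param n_points number of equally spaced output times (>= 2).
#' @param init named numeric vector of initial concentrations (defaults to
#'   all zero).
#' @param iptg IPTG level: a single number, or a function of time for
#'   switching inputs.
#' @return data frame of class `circuit_trajectory`: column `time` plus one
#'   column per species; attributes record the parameters and IPTG input.
#' @export
simulate_circuit <- function(model, t_end = 100, n_points = 100L,
                             init = NULL, iptg = 0) {
  abort_if(t_end <= 0, "`t_end` must be positive")
  abort_if(!is_count(n_points) || n_points < 2,
           "`n_points` must be an integer >= 2")
  if (is.null(init)) {
    init <- stats::setNames(rep(0, length(model$species)), model$species)
  }
  abort_if(!all(model$species %in% names(init)),
           "`init` must name every species")
  init <- init[model$species]
  iptg_fun <- if (is.function(iptg)) iptg else function(t) iptg
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::ode(y = init, times = times, func = circuit_derivs,
                      parms = list(params = model$params,
                                   iptg_fun = iptg_fun),
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  abort_if(nrow(sol) < n_points,
           "ODE integration failed before reaching t_end",
           class = "mirhub_integration_error")
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  for (sp in model$species) out[[sp]] <- pmax(out[[sp]], 0)
  attr(out, "params") <- model$params
  attr(out, "iptg") <- if (is.function(iptg)) "time-varying" else iptg
  class(out) <- c("circuit_trajectory", "data.frame")
  out
}

#' ON/OFF case analysis of the toggle
#'
#' Runs the two canonical induction cases and labels the steady output
#' state. `off_case1` keeps IPTG at zero so LacR is fully active and the
#' output promoter sees maximal repression; `on_case2` raises IPTG to
#' `100 * K_I`, sequestering LacR and de-repressing the output. The steady
#' GFP level (mean of the last 10% of the trajectory) is compared with the
#' unrepressed plateau `alpha / delta`: below `theta_low` of it the state
#' is OFF, above `theta_high` it is ON, between the two the result is
#' `indeterminate`. miR-520c-3p and GFP share the promoter and co-switch.
#'
#' @param model a [build_default_circuit()] model.
#' @param case `"off_case1"` or `"on_case2"`.
#' @param t_end,n_points simulation grid (long enough to settle).
#' @param theta_low,theta_high OFF/ON thresholds as fractions of
#'   `alpha / delta`.
#' @return list with `trajectory`, `case`, `state` (`"OFF"`, `"ON"` or
#'   `"indeterminate"`), `steady_gfp`, `steady_mir`.
#' @export
run_case <- function(model, case = c("off_case1", "on_case2"),
                     t_end = 100, n_points = 100L,
                     theta_low = 0.1, theta_high = 0.5) {
  case <- match.arg(case)
  abort_if(theta_low > theta_high, "`theta_low` must be <= `theta_high`")
  iptg <- if (case == "off_case1") 0 else 100 * model$params$K_I
  traj <- simulate_circuit(model, t_end = t_end, n_points = n_points,
                           iptg = iptg)
  tail_idx <- which(traj$time >= 0.9 * t_end)
  steady_gfp <- mean(traj$GFP[tail_idx])
  steady_mir <- mean(traj$miR520c[tail_idx])
  plateau <- model$params$alpha / model$params$delta_gfp
  state <- if (steady_gfp < theta_low * plateau) "OFF"
           else if (steady_gfp > theta_high * plateau) "ON"
           else "indeterminate"
  list(trajectory = traj, case = case, state = state,
       steady_gfp = steady_gfp, steady_mir = steady_mir)
}

#' Binarize trajectories by per-species midrange threshold
#'
#' Each species is thresholded at `(min + max) / 2` of its observed range.
#' When several trajectories are supplied (e.g. the OFF and ON induction
#' cases) the threshold is shared across them, so a species that merely
#' idles at a low basal level in one condition is not artificially split.
#' Species whose range is below `1e-9 * max` are treated as constant at
#' their rounded binary level.
#'
#' @param traj a `circuit_trajectory` (or plain data frame with a `time`
#'   column), or a list of them.
#' @param species columns to binarize (default: all but `time`).
#' @return a binary (0/1) matrix per input trajectory (a list when a list
#'   was supplied), with species as columns.
#' @export
binarize <- function(traj, species = NULL) {
  single <- !is.null(dim(traj)) || is.data.frame(traj)
  trajs <- if (single) list(traj) else traj
  abort_if(length(trajs) == 0, "no trajectories supplied")
  trajs <- lapply(trajs, as.data.frame)
  if (is.null(species)) species <- setdiff(names(trajs[[1]]), "time")
  abort_if(any(vapply(trajs, nrow, integer(1)) < 2),
           "each trajectory needs >= 2 time points")
  all_vals <- do.call(rbind, lapply(trajs, function(d) as.matrix(d[species])))
  lo <- apply(all_vals, 2, min); hi <- apply(all_vals, 2, max)
  out <- lapply(trajs, function(d) {
    m <- as.matrix(d[species])
    b <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
    for (j in seq_along(species)) {
      if (hi[j] - lo[j] < 1e-9 * max(abs(hi[j]), 1e-300)) {
        b[, j] <- as.integer(round(min(max(lo[j], 0), 1)))
      } else {
        b[, j] <- as.integer(m[, j] > (lo[j] + hi[j]) / 2)
      }
    }
    b
  })
  if (single) out[[1]] else out
}

#' Simulated OFF-to-ON switching series for network inference
#'
#' Simulates the default induction experiment used for dynamic network
#' inference: the circuit starts uninduced, and IPTG steps from 0 to
#' `100 * K_I` halfway through the run. The `LacR` column records the
#' ACTIVE (IPTG-free) repressor concentration, which is the biologically
#' effective quantity: total LacR is insensitive to IPTG and carries no
#' switching signal.
#'
#' @param model a [build_default_circuit()] model.
#' @param n_points number of sampled time points.
#' @param t_end final time; the IPTG step occurs at `t_end / 2`.
#' @return a `circuit_trajectory` whose `LacR` column is active LacR.
#' @export
circuit_switch_series <- function(model, n_points = 100L, t_end = 100) {
  t_switch <- t_end / 2
  iptg_level <- 100 * model$params$K_I
  iptg_fun <- function(t) ifelse(t < t_switch, 0, iptg_level)
  traj <- simulate_circuit(model, t_end = t_end, n_points = n_points,
                           iptg = iptg_fun)
  traj$LacR <- lacr_free(traj$LacR, iptg_fun(traj$time), model$params)
  attr(traj, "iptg") <- sprintf("step 0 -> %g at t = %g", iptg_level,
                                t_switch)
  attr(traj, "lacr_column") <- "active (IPTG-free) LacR"
  traj
}
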