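#' Best-fit Boolean network inference from binary time series
#'
#' For every variable, exhaustively searches candidate input sets of size
#' `0..max_inputs` (drawn from the other variables plus any external
#' inputs) and keeps the truth table minimizing the number of transition
#' mismatches across the supplied series. Ties are broken by fewer inputs,
#' then by lexicographically smallest input index set, then by fewest
#' 1-entries in the table. Input combinations never observed in the data
#' are filled with 0.
#'
#' @param series a binary matrix (time x variables, named columns) or a
#'   list of such matrices (several experimental conditions; transitions
#'   are counted within each).
#' @param max_inputs maximal in-degree searched (clamped with a warning if
#'   it exceeds the number of available regulators).
#' @param external character vector of column names that act as frozen
#'   external inputs: they may regulate others but no rule is learned for
#'   them.
#' @return list of class `boolean_network` with elements `variables`,
#'   `external`, and `rules` (per variable: `inputs`, `table` — output for
#'   each input combination in canonical binary order, first input = most
#'   significant bit — and `mismatches`).
#' @examples
#' ser <- cbind(x1 = c(0, 1, 0, 1, 0), x2 = c(1, 1, 0, 1, 0))
#' bestfit_boolean(ser, max_inputs = 1)$rules$x2
#' @export
bestfit_boolean <- function(series, max_inputs = 3L, external = character(0)) {
  if (!is.list(series)) series <- list(series)
  series <- lapply(series, function(m) {
    m <- as.matrix(m)
    abort_if(is.null(colnames(m)), "series columns must be named")
    abort_if(!all(m %in% c(0, 1)), "series must be binary (0/1)")
    abort_if(nrow(m) < 2, "each series needs >= 2 time points")
    storage.mode(m) <- "integer"
    m
  })
  vars_all <- colnames(series[[1]])
  abort_if(!all(vapply(series, function(m)
    identical(colnames(m), vars_all), logical(1))),
    "all series must share the same columns")
  abort_if(!all(external %in% vars_all),
           "`external` must name columns of the series")
  variables <- setdiff(vars_all, external)
  abort_if(!is_count(max_inputs) || max_inputs < 1,
           "`max_inputs` must be a positive integer")

  # stacked transitions: predictors at t, responses at t+1
  X <- do.call(rbind, lapply(series, function(m) m[-nrow(m), , drop = FALSE]))
  Y <- do.call(rbind, lapply(series, function(m) m[-1, , drop = FALSE]))

  rules <- list()
  for (v in variables) {
    cand <- setdiff(vars_all, v)  # self-input excluded; externals allowed
    k_max <- max_inputs
    if (k_max > length(cand)) {
      warning(sprintf("max_inputs clamped to %d for variable %s",
                      length(cand), v))
      k_max <- length(cand)
    }
    best <- NULL
    for (k in 0:k_max) {
      combos <- if (k == 0) list(character(0)) else
        utils::combn(cand, k, simplify = FALSE)
      for (inp in combos) {
        fit <- fit_truth_table(X[, inp, drop = FALSE], Y[, v])
        cand_rule <- list(inputs = inp, table = fit$table,
                          mismatches = fit$mismatches)
        if (is.null(best) || rule_better(cand_rule, best, vars_all)) {
          best <- cand_rule
        }
      }
      # a perfect smaller rule can never be beaten by a larger one
      if (!is.null(best) && best$mismatches == 0 &&
          length(best$inputs) <= k) break
    }
    rules[[v]] <- best
  }
  structure(list(variables = variables, external = external, rules = rules),
            class = "boolean_network")
}

# Majority-vote truth table for a fixed input set; ties and unobserved
# combinations default to 0.
fit_truth_table <- function(Xin, y) {
  k <- ncol(Xin)
  n_comb <- 2L^k
  if (k == 0) {
    ones <- sum(y); zeros <- length(y) - ones
    out <- as.integer(ones > zeros)
    return(list(table = out, mismatches = min(ones, zeros)))
  }
  # canonical combination index: first input = most significant bit
  idx <- as.integer(Xin %*% 2L^((k - 1):0)) + 1L
  ones <- tabulate(idx[y == 1L], nbins = n_comb)
  zeros <- tabulate(idx[y == 0L], nbins = n_comb)
  tab <- as.integer(ones > zeros)
  list(table = tab, mismatches = sum(pmin(ones, zeros)))
}

rule_better <- function(a, b, var_order) {
  if (a$mismatches != b$mismatches) return(a$mismatches < b$mismatches)
  if (length(a$inputs) != length(b$inputs)) {
    return(length(a$inputs) < length(b$inputs))
  }
  ia <- match(a$inputs, var_order); ib <- match(b$inputs, var_order)
  if (!identical(ia, ib)) {
    cmp <- ia - ib
    return(cmp[which(cmp != 0)[1]] < 0)
  }
  sum(a$table) < sum(b$table)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("boolean_network with", length(x$variables), "variables")
  if (length(x$external)) {
    cat(" and external input(s)", paste(x$external, collapse = ", "))
  }
  cat("\n")
  for (v in x$variables) {
    r <- x$rules[[v]]
    cat(sprintf("  %s' <- f(%s)  table [%s]  mismatches %d\n", v,
                paste(r$inputs, collapse = ","),
                paste(r$table, collapse = ""), r$mismatches))
  }
  invisible(x)
}

# Synchronous image of one state (named integer vector incl. externals).
boolean_step <- function(bn, state) {
  nxt <- state
  for (v in bn$variables) {
    r <- bn$rules[[v]]
    k <- length(r$inputs)
    idx <- if (k == 0) 1L else
      as.integer(sum(state[r$inputs] * 2L^((k - 1):0))) + 1L
    nxt[[v]] <- r$table[idx]
  }
  nxt[bn$external] <- state[bn$external]
  nxt
}

#' Exhaustive synchronous attractor enumeration
#'
#' Enumerates all `2^n` states of the non-external variables (for each
#' frozen assignment of the external inputs), follows the synchronous
#' update map, and reports every attractor with its basin size. Basin
#' sizes sum to the state-space size within each input condition.
#'
#' @param bn a [bestfit_boolean()] network.
#' @param frozen_inputs a named list/vector of external input values, or a
#'   list of several such assignments (one enumeration per condition). If
#'   `NULL` and the network has externals, all their combinations are
#'   enumerated.
#' @param max_vars refuse exhaustive enumeration beyond this many
#'   variables.
#' @return list of class `attractor_set`: one element per input condition
#'   with `inputs` and `attractors` (each has `states` — a matrix, one row
#'   per cycle state — and `basin_size`).
#' @examples
#' bn <- bestfit_boolean(cbind(x = c(0, 1, 0, 1, 0)), max_inputs = 1)
#' boolean_attractors(bn)
#' @export
boolean_attractors <- function(bn, frozen_inputs = NULL, max_vars = 20L) {
  nv <- length(bn$variables)
  abort_if(nv > max_vars,
           sprintf(paste("state space 2^%d exceeds the exhaustive limit;",
                         "reduce the network or raise `max_vars`"), nv),
           class = "mirhub_capacity_error")
  conds <- normalize_conditions(bn, frozen_inputs)
  out <- lapply(conds, function(cond) {
    enumerate_attractors(bn, cond)
  })
  structure(out, class = "attractor_set")
}

normalize_conditions <- function(bn, frozen_inputs) {
  if (length(bn$external) == 0) return(list(stats::setNames(integer(0),
                                                            character(0))))
  if (is.null(frozen_inputs)) {
    grid <- expand.grid(rep(list(0:1), length(bn$external)))
    names(grid) <- bn$external
    return(lapply(seq_len(nrow(grid)), function(i) {
      v <- as.integer(grid[i, ]); names(v) <- bn$external; v
    }))
  }
  if (!is.list(frozen_inputs) || !is.null(names(frozen_inputs))) {
    frozen_inputs <- list(frozen_inputs)
  }
  lapply(frozen_inputs, function(ci) {
    ci <- unlist(ci)
    abort_if(!all(bn$external %in% names(ci)),
             "frozen inputs must assign every external input")
    v <- as.integer(ci[bn$external]); names(v) <- bn$external; v
  })
}

enumerate_attractors <- function(bn, cond) {
  vars <- bn$variables
  nv <- length(vars)
  n_states <- 2L^nv
  code_of <- function(state) {
    as.integer(sum(state[vars] * 2L^((nv - 1):0))) + 1L
  }
  state_of <- function(code) {
    bits <- as.integer(intToBits(code - 1L))[nv:1]
    stats::setNames(c(bits, cond), c(vars, names(cond)))
  }
  succ <- integer(n_states)
  for (code in seq_len(n_states)) {
    succ[code] <- code_of(boolean_step(bn, state_of(code)))
  }
  # attractor = cycle of the functional graph; basin via membership
  attr_id <- integer(n_states)  # 0 = unassigned
  cycles <- list()
  for (start in seq_len(n_states)) {
    if (attr_id[start] != 0) next
    path <- integer(0)
    seen <- integer(0)
    code <- start
    while (attr_id[code] == 0 && !(code %in% seen)) {
      seen <- c(seen, code)
      path <- c(path, code)
      code <- succ[code]
    }
    if (attr_id[code] != 0) {
      aid <- attr_id[code]
    } else {
      # new cycle starting at `code`
      cyc_start <- match(code, path)
      cyc <- path[cyc_start:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      aid <- length(cycles)
      path <- path[seq_len(cyc_start - 1L)]
      attr_id[cyc] <- aid
    }
    attr_id[path] <- aid
  }
  attractors <- lapply(seq_along(cycles), function(aid) {
    cyc <- cycles[[aid]]
    states <- do.call(rbind, lapply(cyc, function(code) {
      state_of(code)[vars]
    }))
    colnames(states) <- vars
    list(states = states, basin_size = sum(attr_id == aid))
  })
  list(inputs = cond, attractors = attractors)
}

#' @export
print.attractor_set <- function(x, ...) {
  for (cond in x) {
    if (length(cond$inputs)) {
      cat("inputs:", paste(names(cond$inputs), cond$inputs, sep = "=",
                           collapse = ", "), "\n")
    }
    for (a in cond$attractors) {
      lab <- apply(a$states, 1, paste, collapse = "")
      cat(sprintf("  attractor (%d-cycle, basin %d): %s\n",
                  nrow(a$states), a$basin_size, paste(lab, collapse = " -> ")))
    }
  }
  invisible(x)
}

#' Boolean validation of the synthetic circuit
#'
#' Runs the full qualitative validation chain: simulate the circuit in the
#' uninduced (IPTG = 0) and induced (IPTG = 100 K_I) conditions, binarize
#' the two trajectories with shared per-species thresholds, learn a
#' best-fit Boolean network with IPTG as a frozen external input, and
#' exhaustively enumerate synchronous attractors under both IPTG
#' conditions. Distinct attractor cycles are counted across the two
#' conditions; a bistable toggle yields exactly two — the OFF state with
#' LacR active and miR-520c-3p/GFP low, and the ON state with
#' miR-520c-3p/GFP high.
#'
#' @param model a [build_default_circuit()] model.
#' @param t_end,n_points simulation grid per condition.
#' @param max_inputs maximal Boolean in-degree searched.
#' @return list with `network`, `attractors` (an `attractor_set` over both
#'   IPTG conditions), `n_attractors` (distinct cycles across conditions),
#'   `off_state`, `on_state` (named 0/1 vectors of the single fixed point
#'   per condition when unique, else `NULL`).
#' @export
validate_circuit_boolean <- function(model = build_default_circuit(),
                                     t_end = 100, n_points = 100L,
                                     max_inputs = 3L) {
  iptg_on <- 100 * model$params$K_I
  off <- simulate_circuit(model, t_end = t_end, n_points = n_points, iptg = 0)
  on <- simulate_circuit(model, t_end = t_end, n_points = n_points,
                         iptg = iptg_on)
  # the functional repressor state is ACTIVE (IPTG-free) LacR; total LacR
  # is insensitive to induction and would invert the toggle's logic
  off$LacR <- lacr_free(off$LacR, 0, model$params)
  on$LacR <- lacr_free(on$LacR, iptg_on, model$params)
  bins <- binarize(list(off, on))
  series <- list(cbind(bins[[1]], IPTG = 0L), cbind(bins[[2]], IPTG = 1L))
  bn <- bestfit_boolean(series, max_inputs = max_inputs, external = "IPTG")
  att <- boolean_attractors(bn, frozen_inputs = list(c(IPTG = 0L),
                                                     c(IPTG = 1L)))
  keys <- unlist(lapply(att, function(cond) {
    vapply(cond$attractors, function(a) {
      rows <- apply(a$states, 1, paste, collapse = "")
      # rotate cycle to its lexicographically smallest state
      shift <- which.min(rows)
      paste(rows[c(shift:length(rows), seq_len(shift - 1))[seq_along(rows)]],
            collapse = "|")
    }, character(1))
  }))
  fixed_point <- function(cond) {
    fp <- Filter(function(a) nrow(a$states) == 1, cond$attractors)
    if (length(cond$attractors) == 1 && length(fp) == 1) {
      stats::setNames(as.integer(fp[[1]]$states[1, ]),
                      colnames(fp[[1]]$states))
    } else NULL
  }
  list(network = bn, attractors = att,
       n_attractors = length(unique(keys)),
       off_state = fixed_point(att[[1]]),
       on_state = fixed_point(att[[2]]))
}
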