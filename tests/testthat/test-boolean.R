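# Best-fit Boolean inference and synchronous attractor enumeration.

test_that("best-fit recovers a NOT rule from covering data", {
  ser <- cbind(x1 = c(0, 1, 0, 1, 0), x2 = c(1, 1, 0, 1, 0))
  bn <- bestfit_boolean(ser, max_inputs = 1)
  r <- bn$rules$x2
  expect_equal(r$inputs, "x1")
  expect_equal(r$table, c(1L, 0L))  # NOT
  expect_equal(r$mismatches, 0L)
})

test_that("constant variables get the empty-input constant rule", {
  ser <- cbind(a = c(0, 1, 1, 0, 1), k = c(1, 1, 1, 1, 1))
  bn <- bestfit_boolean(ser, max_inputs = 1)
  expect_equal(bn$rules$k$inputs, character(0))
  expect_equal(bn$rules$k$table, 1L)
})

test_that("conflicting transitions resolve by majority under the tie rules", {
  # k' = a except one conflicting transition: the majority table still
  # beats any constant rule (1 mismatch vs 2)
  ser <- cbind(a = c(0, 1, 0, 1, 1, 1), k = c(0, 0, 1, 0, 1, 0))
  r <- bestfit_boolean(ser, max_inputs = 1)$rules$k
  expect_equal(r$inputs, "a")
  expect_equal(r$table, c(0L, 1L))
  expect_equal(r$mismatches, 1L)

  # fully balanced outputs: every candidate has 2 mismatches, so the tie
  # rules pick the smaller input set, then the all-zero table
  ser2 <- cbind(a = c(0, 1, 1, 0, 1), k = c(0, 0, 1, 0, 1))
  r2 <- bestfit_boolean(ser2, max_inputs = 1)$rules$k
  expect_equal(r2$inputs, character(0))
  expect_equal(r2$table, 0L)
  expect_equal(r2$mismatches, 2L)
})

test_that("max_inputs clamps with a warning", {
  ser <- cbind(x = c(0, 1, 0), y = c(1, 0, 1))
  # one clamp warning per variable with too few candidate regulators
  expect_warning(expect_warning(bestfit_boolean(ser, max_inputs = 3),
                                "clamped"), "clamped")
})

test_that("best-fit is exact on data generated within its search class", {
  for (k in 1:10) {
    bn_true <- random_boolean_network(3, max_inputs = 2, seed = 400 + k)
    # cover the state space: short trajectories from every initial state
    grid <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1)
    series <- lapply(seq_len(nrow(grid)), function(i) {
      st <- stats::setNames(as.integer(grid[i, ]), bn_true$variables)
      rows <- list(st)
      for (s in 1:3) {
        st <- oracle_rule_eval(bn_true, st)
        rows[[length(rows) + 1]] <- st
      }
      do.call(rbind, rows)
    })
    bn_fit <- bestfit_boolean(series, max_inputs = 2)
    expect_true(all(vapply(bn_fit$rules, function(r) r$mismatches,
                           integer(1)) == 0L))
    # functional equivalence on every state
    for (i in seq_len(nrow(grid))) {
      st <- stats::setNames(as.integer(grid[i, ]), bn_true$variables)
      expect_equal(oracle_rule_eval(bn_fit, st),
                   oracle_rule_eval(bn_true, st))
    }
  }
})

test_that("canonical attractors: NOT cycle and identity fixed points", {
  bn_not <- structure(list(
    variables = "x", external = character(0),
    rules = list(x = list(inputs = "x", table = c(1L, 0L),
                          mismatches = 0L))), class = "boolean_network")
  att <- boolean_attractors(bn_not)
  expect_length(att[[1]]$attractors, 1)
  expect_equal(nrow(att[[1]]$attractors[[1]]$states), 2)  # a 2-cycle
  expect_equal(att[[1]]$attractors[[1]]$basin_size, 2)

  bn_id <- structure(list(
    variables = c("x", "y"), external = character(0),
    rules = list(x = list(inputs = "x", table = c(0L, 1L), mismatches = 0L),
                 y = list(inputs = "y", table = c(0L, 1L),
                          mismatches = 0L))), class = "boolean_network")
  att_id <- boolean_attractors(bn_id)
  expect_length(att_id[[1]]$attractors, 4)
  expect_true(all(vapply(att_id[[1]]$attractors,
                         function(a) nrow(a$states), integer(1)) == 1))
})

test_that("attractor enumeration matches the per-state walking oracle", {
  for (k in 1:20) {
    nv <- sample(3:6, 1)
    bn <- random_boolean_network(nv, max_inputs = 3, seed = 700 + k)
    got <- attractor_summary(boolean_attractors(bn)[[1]])
    want <- oracle_attractors(bn)
    expect_setequal(names(got), names(want$basins))
    expect_equal(got[names(want$basins)], want$basins,
                 ignore_attr = TRUE)
    expect_equal(sum(got), 2^nv)  # basins tile the state space
  }
})

test_that("capacity guard refuses oversized exhaustive enumeration", {
  bn <- random_boolean_network(12, max_inputs = 2, seed = 1)
  expect_error(boolean_attractors(bn, max_vars = 10), "exhaustive")
})

test_that("circuit Boolean validation is bistable with the right phenotypes", {
  val <- validate_circuit_boolean()
  expect_equal(val$n_attractors, 2)
  expect_equal(unname(val$off_state[c("LacR", "miR520c", "GFP")]),
               c(1L, 0L, 0L))
  expect_equal(unname(val$on_state[c("miR520c", "GFP")]), c(1L, 1L))
  # every rule in the learned network fits its condition data perfectly
  expect_true(all(vapply(val$network$rules, function(r) r$mismatches,
                         integer(1)) == 0L))
})
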