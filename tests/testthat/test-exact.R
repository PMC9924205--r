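test_that("min_required_send and max_receive_cap match hand-worked cases", {
  inst <- table2_row(8, 2) # seniors booked 36, associates 18, caps 360
  expect_equal(min_required_send(inst, 1, candidate_lwt = 272), 11L)
  expect_equal(max_receive_cap(inst, 11, candidate_lwt = 272), 11L)

  inst55 <- table2_row(5, 5)
  expect_equal(min_required_send(inst55, 1, candidate_lwt = 360), 0L)
  expect_equal(max_receive_cap(inst55, 11, candidate_lwt = 180), 0L)

  sc4 <- table4_scenario(4) # senior 2 booked 30, associate 2 booked 24
  expect_equal(min_required_send(sc4, 2, candidate_lwt = 265), 7L)
  expect_equal(max_receive_cap(sc4, 12, candidate_lwt = 285), 9L)

  # the work_time cap binds when tighter than the candidate
  tight <- small_clinic(work_time = 300)
  expect_equal(min_required_send(tight, 1, candidate_lwt = 1000),
               ceiling((360 - 300) / 5))
})

test_that("feasible_at flips exactly at the optimum of the time sweep", {
  inst <- table2_row(8, 2)
  cert <- feasible_at(inst, 272)
  expect_true(cert$feasible)
  expect_equal(sum(cert$required_sends), 110L)
  expect_equal(sum(cert$receive_caps), 110L)

  cert271 <- feasible_at(inst, 271)
  expect_false(cert271$feasible)
  expect_equal(sum(cert271$required_sends), 120L)
  expect_equal(sum(cert271$receive_caps), 110L)

  # at the largest base workload nothing needs to move
  ub <- max(base_workload(inst))
  cert_ub <- feasible_at(inst, ub)
  expect_true(cert_ub$feasible)
  expect_true(all(cert_ub$required_sends == 0L))
})

test_that("solve_exact reproduces the printed sweep extremes", {
  r55 <- solve_exact(table2_row(5, 5))
  expect_equal(r55$lwt, 270L)
  expect_equal(r55$status, "optimal")

  r28 <- solve_exact(table2_row(2, 8))
  expect_equal(r28$lwt, 288L)
  # senders are capped at their booked count: every senior sheds all 36
  expect_equal(r28$npp[1:10], rep(-36L, 10))
})

test_that("solve_exact agrees with a three-doctor brute force by hand", {
  inst <- clinic_instance(
    tibble::tibble(id = c("S1", "A1"), rank = c("senior", "associate"),
                   booked = c(2L, 1L), work_time = 100L),
    et = 1, dt = 1
  )
  # npp in {0,-1,-2}: workloads (4,2) -> 4, (3,3) -> 3, (2,4) -> 4
  expect_equal(solve_exact(inst)$lwt, 3L)
})

test_that("canonical plan sheds minimally and fills receivers in roster order", {
  inst <- table2_row(8, 2)
  plan <- canonical_plan(inst, 272)
  expect_equal(plan[1:10], rep(-11L, 10))
  expect_equal(sum(plan[11:20]), 110L)
  expect_true(all(plan[11:20] <= 11L))
  expect_length(check_plan(inst, plan, "lean", 272), 0)

  # greedy fill by hand: at candidate 23 the senders must shed (3, 5) and
  # each receiver can absorb 7; roster order fills A1 first: (+7, +1)
  inst2 <- clinic_instance(
    tibble::tibble(
      id = c("S1", "S2", "A1", "A2"),
      rank = c("senior", "senior", "associate", "associate"),
      booked = c(13L, 14L, 8L, 8L), work_time = 100L
    ),
    et = 1, dt = 1
  )
  plan2 <- canonical_plan(inst2, 23)
  expect_equal(plan2[1:2], c(-3L, -5L))
  expect_equal(plan2[3:4], c(7L, 1L))
  expect_length(check_plan(inst2, plan2, "lean", 23), 0)

  expect_error(canonical_plan(table2_row(8, 2), 100), "no feasible plan")

  # no sender above the candidate -> all-zero plan
  expect_equal(canonical_plan(table2_row(5, 5), 360), integer(20))
})

test_that("instances whose caps no transfer can satisfy come back infeasible", {
  # senior's diagnosis load alone exceeds its cap
  inst <- clinic_instance(
    tibble::tibble(id = c("S1", "A1"), rank = c("senior", "associate"),
                   booked = c(10L, 0L), work_time = c(50L, 400L)),
    et = 2, dt = 8
  )
  res <- solve_exact(inst)
  expect_equal(res$status, "infeasible")
  expect_true(is.na(res$lwt))

  # associate over its own cap: lean mode cannot shed from an associate
  inst2 <- clinic_instance(
    tibble::tibble(id = c("S1", "A1"), rank = c("senior", "associate"),
                   booked = c(1L, 10L), work_time = c(400L, 50L)),
    et = 2, dt = 8
  )
  expect_equal(solve_exact(inst2)$status, "infeasible")
})

test_that("feasibility is monotone in the candidate LWT", {
  for (seed in 1:40) {
    inst <- tiny_instance(seed)
    for (mode in c("lean", "as_printed")) {
      lo <- min(instv <- base_workload(inst)) %/% 2L
      hi <- max(instv)
      feas <- vapply(lo:hi, function(L) feasible_at(inst, L, mode)$feasible,
                     logical(1))
      # once feasible, stays feasible
      expect_true(all(diff(feas) >= 0),
                  label = sprintf("seed %d mode %s monotone", seed, mode))
    }
  }
})

test_that("exact optimum equals exhaustive enumeration on tiny instances", {
  for (seed in 1:60) {
    inst <- tiny_instance(seed)
    for (mode in c("lean", "as_printed")) {
      expect_equal(solve_exact(inst, mode)$lwt, brute_force_lwt(inst, mode),
                   label = sprintf("seed %d mode %s", seed, mode))
    }
  }
})

test_that("the optimum respects its structural lower bounds (lean mode)", {
  for (seed in 1:40) {
    inst <- tiny_instance(seed)
    res <- solve_exact(inst)
    doc <- inst$doctors
    receivers <- doc$rank == "associate"
    expect_gte(res$lwt, max(0L, base_workload(inst)[receivers]))
    expect_gte(res$lwt, max(0L, inst$dt * doc$booked[!receivers]))
    # returned plan certifies the optimum
    expect_length(check_plan(inst, res$npp, "lean", res$lwt), 0)
    expect_equal(max(post_workload(inst, res$npp)), res$lwt)
  }
})

test_that("spare capacity never hurts and tighter caps never help", {
  for (seed in 1:25) {
    inst <- tiny_instance(seed)
    base_lwt <- solve_exact(inst)$lwt

    plus_assoc <- clinic_instance(
      dplyr::bind_rows(inst$doctors,
                       tibble::tibble(id = "A_extra", rank = "associate",
                                      booked = 0L,
                                      work_time = max(inst$doctors$work_time))),
      et = inst$et, dt = inst$dt
    )
    expect_lte(solve_exact(plus_assoc)$lwt, base_lwt)

    tighter <- inst
    tighter$doctors$work_time <- pmax(base_workload(inst),
                                      tighter$doctors$work_time - inst$et)
    res_t <- solve_exact(tighter)
    if (identical(res_t$status, "optimal")) expect_gte(res_t$lwt, base_lwt)
  }
})
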