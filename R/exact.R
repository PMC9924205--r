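#' Minimum number of examination services a sender must shed
#'
#' At a candidate maximum working time `L`, a sending doctor with base
#' workload `(et + dt) * booked` must come down to
#' `min(L, work_time)`; each shed examination service saves `et` time
#' units, so the least number of services to shed is
#' `ceil(((et + dt) * booked - min(L, work_time)) / et)`, floored at zero.
#'
#' @param instance A `clinic_instance`.
#' @param doctor_index Sender position(s) in the roster.
#' @param candidate_lwt Candidate maximum working time, time units.
#' @return Integer count(s) of examination services to shed.
#' @export
min_required_send <- function(instance, doctor_index, candidate_lwt) {
  doctor_index <- check_index(instance, doctor_index)
  doc <- instance$doctors
  cap <- pmin(candidate_lwt, doc$work_time[doctor_index])
  excess <- (instance$et + instance$dt) * doc$booked[doctor_index] - cap
  pmax(0L, as.integer(ceiling(excess / instance$et)))
}

#' Maximum number of examination services a receiver can absorb
#'
#' The slack below `min(L, work_time)` divided by `et`, floored at zero:
#' `floor((min(L, work_time) - (et + dt) * booked) / et)`.
#'
#' @inheritParams min_required_send
#' @param doctor_index Receiver position(s) in the roster.
#' @return Integer count(s) of examination services the receiver can take.
#' @export
max_receive_cap <- function(instance, doctor_index, candidate_lwt) {
  doctor_index <- check_index(instance, doctor_index)
  doc <- instance$doctors
  cap <- pmin(candidate_lwt, doc$work_time[doctor_index])
  slack <- cap - (instance$et + instance$dt) * doc$booked[doctor_index]
  pmax(0L, as.integer(floor(slack / instance$et)))
}

#' Feasibility certificate at a fixed candidate LWT
#'
#' Decides whether some conservation-satisfying integer transfer plan keeps
#' every doctor at or below `candidate_lwt` and its own working-time cap.
#' Because transfers in this model are fungible (every examination service
#' costs the same `et` on either side), feasibility reduces to three checks:
#' every sender can actually shed what it must (`min_required_send` at most
#' its booked count), every receiver's untouched base workload already fits
#' under `min(candidate_lwt, work_time)`, and total required sends do not
#' exceed total receive capacity.
#'
#' @inheritParams min_required_send
#' @param mode Sign mode, see [doctor_roles()].
#' @return A `feasibility_certificate`: list with `candidate_lwt`,
#'   `required_sends` (named integer vector over senders), `receive_caps`
#'   (over receivers), and logical `feasible`.
#' @export
feasible_at <- function(instance, candidate_lwt, mode = c("lean", "as_printed")) {
  mode <- match.arg(mode)
  roles <- doctor_roles(instance, mode)
  doc <- instance$doctors
  senders <- which(roles == "sender")
  receivers <- which(roles == "receiver")

  sends <- if (length(senders)) {
    min_required_send(instance, senders, candidate_lwt)
  } else integer(0)
  caps <- if (length(receivers)) {
    max_receive_cap(instance, receivers, candidate_lwt)
  } else integer(0)
  names(sends) <- doc$id[senders]
  names(caps) <- doc$id[receivers]

  receiver_fits <- length(receivers) == 0 ||
    all((instance$et + instance$dt) * doc$booked[receivers] <=
          pmin(candidate_lwt, doc$work_time[receivers]))

  structure(
    list(
      candidate_lwt = as.integer(candidate_lwt),
      required_sends = sends,
      receive_caps = caps,
      feasible = all(sends <= doc$booked[senders]) &&
        receiver_fits &&
        sum(sends) <= sum(caps)
    ),
    class = "feasibility_certificate"
  )
}

#' @export
print.feasibility_certificate <- function(x, ...) {
  cat(sprintf("<feasibility_certificate> candidate LWT %d: %s\n",
              x$candidate_lwt,
              if (x$feasible) "feasible" else "infeasible"))
  cat(sprintf("  required sends: %d total; receive capacity: %d total\n",
              sum(x$required_sends), sum(x$receive_caps)))
  invisible(x)
}

#' Canonical optimal transfer plan
#'
#' Many transfer plans can attain the optimal maximum working time; this
#' function returns one deterministic representative: every sender sheds
#' exactly its minimum required number of examination services (senders
#' already at or below the target shed nothing), and the total is handed to
#' receivers in roster order, each filled up to its capacity until the pool
#' is exhausted. The result always passes [check_plan()] at `optimal_lwt`.
#'
#' @inheritParams feasible_at
#' @param optimal_lwt A maximum working time at which the instance is
#'   feasible (normally the optimum from [solve_exact()]).
#' @return Integer vector of signed per-doctor transfer counts.
#' @export
canonical_plan <- function(instance, optimal_lwt, mode = c("lean", "as_printed")) {
  mode <- match.arg(mode)
  cert <- feasible_at(instance, optimal_lwt, mode)
  if (!cert$feasible) {
    rlang::abort(sprintf(
      "no feasible plan exists at LWT %d; canonical_plan needs a feasible target",
      optimal_lwt))
  }
  roles <- doctor_roles(instance, mode)
  npp <- integer(n_doctors(instance))
  senders <- which(roles == "sender")
  receivers <- which(roles == "receiver")
  npp[senders] <- -unname(cert$required_sends)
  pool <- sum(cert$required_sends)
  for (k in seq_along(receivers)) {
    take <- min(pool, unname(cert$receive_caps[k]))
    npp[receivers[k]] <- take
    pool <- pool - take
    if (pool == 0L) break
  }
  npp
}

#' Exact min-max transfer optimizer
#'
#' Minimizes the largest post-transfer working time (LWT) over all integer
#' transfer plans by binary search on the candidate LWT, using
#' [feasible_at()] as the decision oracle. Feasibility is monotone in the
#' candidate (required sends shrink, receive capacity grows), so the search
#' is exact. The search interval is bounded below by the best workload any
#' doctor could ever reach — `dt * booked` for a sender that sheds every
#' examination service, the untouched `(et + dt) * booked` for a receiver —
#' and above by the largest pre-plan workload.
#'
#' The instance is infeasible only when a working-time cap cannot be met by
#' any transfer: a sender whose diagnosis load alone exceeds its cap, a
#' receiver already over its cap, or senders forced to shed with no
#' receiver capacity to absorb.
#'
#' @inheritParams feasible_at
#' @return A `solve_result`: list with integer `lwt`, integer `npp` plan,
#'   `mode`, `backend = "exact"`, `status` (`"optimal"` or `"infeasible"`),
#'   and the solved `instance`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' inst <- table4_scenario(1)
#' res <- solve_exact(inst)
#' res$lwt # 270
#' @export
solve_exact <- function(instance, mode = c("lean", "as_printed")) {
  mode <- match.arg(mode)
  stop_if_invalid(instance)

  roles <- doctor_roles(instance, mode)
  doc <- instance$doctors
  best_possible <- ifelse(roles == "sender",
                          instance$dt * doc$booked,
                          (instance$et + instance$dt) * doc$booked)
  lb <- max(0L, best_possible)
  ub <- max(0L, base_workload(instance))

  if (!feasible_at(instance, max(lb, ub), mode)$feasible) {
    return(new_solve_result(
      lwt = NA_integer_, npp = NULL, mode = mode, backend = "exact",
      status = "infeasible", instance = instance
    ))
  }

  lo <- lb
  hi <- max(lb, ub)
  while (lo < hi) {
    mid <- lo + (hi - lo) %/% 2L
    if (feasible_at(instance, mid, mode)$feasible) hi <- mid else lo <- mid + 1L
  }
  new_solve_result(
    lwt = as.integer(lo),
    npp = canonical_plan(instance, lo, mode),
    mode = mode, backend = "exact", status = "optimal", instance = instance
  )
}

new_solve_result <- function(lwt, npp, mode, backend, status, instance) {
  structure(
    list(lwt = lwt, npp = npp, mode = mode, backend = backend,
         status = status, instance = instance),
    class = "solve_result"
  )
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result> %s (%s backend, %s mode)\n",
              x$status, x$backend, x$mode))
  if (identical(x$status, "optimal")) {
    cat(sprintf("  minimized maximum working time (LWT): %d\n", x$lwt))
    cat("  transfers:", paste(sprintf("%+d", x$npp), collapse = " "), "\n")
  }
  invisible(x)
}
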