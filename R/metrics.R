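#' Relative time saving of senior doctors (RTS)
#'
#' The fractional reduction in senior working time when every senior doctor
#' keeps the same caseload but works at most `lwt`:
#' `RTS = 1 - lwt * SD / sum(senior booked * (et + dt))`, where SD is the
#' number of senior doctors. A value of 0.25 means seniors spend 25% less
#' time serving the same booked patients.
#'
#' @param instance A `clinic_instance`.
#' @param lwt Maximum working time after planning, time units.
#' @return Unrounded fraction.
#' @export
rts <- function(instance, lwt) {
  doc <- instance$doctors
  sen <- doc$rank == "senior"
  denom <- sum(doc$booked[sen]) * (instance$et + instance$dt)
  if (sum(sen) < 1 || denom <= 0) {
    rlang::abort("RTS is undefined without senior doctors carrying booked time")
  }
  1 - lwt * sum(sen) / denom
}

#' Relative throughput gain of associate doctors (RTDS)
#'
#' The fractional increase in associate patient flow implied by filling
#' each associate up to `lwt`:
#' `RTDS = lwt * ASD / sum(associate booked * (et + dt)) - 1`. The formula
#' deliberately uses the planned ceiling `lwt`, not the realized associate
#' workloads, so it can exceed the realized gain when associates are not
#' all binding.
#'
#' @inheritParams rts
#' @return Unrounded fraction.
#' @export
rtds <- function(instance, lwt) {
  doc <- instance$doctors
  assoc <- doc$rank == "associate"
  denom <- sum(doc$booked[assoc]) * (instance$et + instance$dt)
  if (sum(assoc) < 1 || denom <= 0) {
    rlang::abort("RTDS is undefined without associate doctors carrying booked time")
  }
  lwt * sum(assoc) / denom - 1
}

#' Round half away from zero
#'
#' Two-decimal table values in the benchmark results round halves up
#' (0.245 -> 0.25), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Extreme per-group transfer counts (SNPP / ANPP)
#'
#' SNPP is the most negative transfer among senior doctors (largest number
#' of examination services shed by any one senior); ANPP is the largest
#' transfer among associates (most services absorbed by any one associate).
#' In lean mode `snpp <= 0 <= anpp`.
#'
#' @param plan Integer per-doctor transfer vector or a `solve_result`.
#' @param instance A `clinic_instance`.
#' @return Named list with integer `snpp` and `anpp`.
#' @export
group_transfer_summary <- function(plan, instance) {
  npp <- check_plan_aligned(instance, plan)
  sen <- instance$doctors$rank == "senior"
  list(
    snpp = if (any(sen)) min(npp[sen]) else NA_integer_,
    anpp = if (any(!sen)) max(npp[!sen]) else NA_integer_
  )
}

#' Per-doctor before/after workload table
#'
#' One row per doctor with its id, rank, booked count, transfer, and the
#' working time before and after the plan, plus a closing `total` row. For
#' any conservation-satisfying plan the before and after totals are equal:
#' transfers move examination time around, they never create or destroy it.
#'
#' @param instance A `clinic_instance`.
#' @param result A `solve_result` (or a bare transfer vector).
#' @return A tibble with columns `doctor_id`, `rank`, `booked`, `npp`,
#'   `workload_before`, `workload_after`.
#' @export
before_after_table <- function(instance, result) {
  npp <- check_plan_aligned(instance, result)
  doc <- instance$doctors
  tab <- tibble::tibble(
    doctor_id = doc$id,
    rank = doc$rank,
    booked = doc$booked,
    npp = npp,
    workload_before = base_workload(instance),
    workload_after = post_workload(instance, npp)
  )
  dplyr::bind_rows(tab, tibble::tibble(
    doctor_id = "total", rank = NA_character_,
    booked = sum(tab$booked), npp = sum(tab$npp),
    workload_before = sum(tab$workload_before),
    workload_after = sum(tab$workload_after)
  ))
}

#' Full metrics report for a solved instance
#'
#' Bundles the optimal LWT with the efficiency metric RTS, the throughput
#' metric RTDS, the extreme transfers SNPP/ANPP, and the before/after
#' workload table.
#'
#' @param instance A `clinic_instance`.
#' @param result An optimal `solve_result` for that instance.
#' @return A `metrics_report` list: `lwt`, unrounded `rts`/`rtds`, `snpp`,
#'   `anpp`, and `table` (see [before_after_table()]).
#' @export
metrics_report <- function(instance, result) {
  stopifnot(inherits(result, "solve_result"))
  if (!identical(result$status, "optimal")) {
    rlang::abort("metrics need an optimal solve_result")
  }
  grp <- group_transfer_summary(result$npp, instance)
  structure(
    list(
      lwt = result$lwt,
      rts = rts(instance, result$lwt),
      rtds = rtds(instance, result$lwt),
      snpp = grp$snpp,
      anpp = grp$anpp,
      table = before_after_table(instance, result)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> LWT %d | RTS %.2f | RTDS %.2f | SNPP %d | ANPP %d\n",
    x$lwt, round_half_up(x$rts), round_half_up(x$rtds), x$snpp, x$anpp))
  print(x$table, n = Inf)
  invisible(x)
}

#' Write a metrics report
#'
#' The per-doctor table goes to CSV (columns `doctor_id`, `rank`, `booked`,
#' `npp`, `workload_before`, `workload_after`); the scalar metrics go to
#' JSON as `{"lwt", "rts", "rtds", "snpp", "anpp"}` with unrounded
#' fractions.
#'
#' @param report A `metrics_report`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$table, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(lwt = report$lwt, rts = report$rts, rtds = report$rtds,
           snpp = report$snpp, anpp = report$anpp),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solve result into a per-doctor tibble
#'
#' @param x A `solve_result`.
#' @param ... Unused.
#' @return The before/after workload tibble without the totals row.
#' @export
tidy.solve_result <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    rlang::abort("cannot tidy an infeasible solve_result")
  }
  tab <- before_after_table(x$instance, x)
  tab[tab$doctor_id != "total", ]
}

#' One-row summary of a solve result
#'
#' @param x A `solve_result`.
#' @param ... Unused.
#' @return A one-row tibble: `status`, `mode`, `backend`, `lwt`, unrounded
#'   `rts`/`rtds`, `snpp`, `anpp`.
#' @export
glance.solve_result <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    return(tibble::tibble(status = x$status, mode = x$mode,
                          backend = x$backend, lwt = NA_integer_,
                          rts = NA_real_, rtds = NA_real_,
                          snpp = NA_integer_, anpp = NA_integer_))
  }
  grp <- group_transfer_summary(x$npp, x$instance)
  tibble::tibble(
    status = x$status, mode = x$mode, backend = x$backend, lwt = x$lwt,
    rts = rts(x$instance, x$lwt), rtds = rtds(x$instance, x$lwt),
    snpp = grp$snpp, anpp = grp$anpp
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Before/after workload plot
#'
#' Per-doctor working time before (dashed) and after (solid) the transfer
#' plan, doctors in roster order with seniors first, plus a horizontal line
#' at the optimized LWT.
#'
#' @param object An optimal `solve_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.solve_result <- function(object, ...) {
  tab <- tidy.solve_result(object)
  tab$position <- seq_len(nrow(tab))
  long <- tidyr::pivot_longer(
    tab, c("workload_before", "workload_after"),
    names_to = "stage", values_to = "workload"
  )
  long$stage <- factor(long$stage, c("workload_before", "workload_after"),
                       c("before plan", "after plan"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$position, y = .data$workload,
    colour = .data$stage, linetype = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$lwt, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = tab$position, labels = tab$doctor_id) +
    ggplot2::labs(
      x = NULL, y = "working time (time units)",
      colour = NULL, linetype = NULL,
      title = sprintf("Workload leveling: LWT %d (%s mode)",
                      object$lwt, object$mode)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
plot.solve_result <- function(x, ...) print(autoplot(x, ...))
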