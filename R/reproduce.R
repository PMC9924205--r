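# Published benchmark results the reproduction harness compares against.
# The service-time sweep (rows 1-7) and the uneven-booking scenarios 1-5 are
# reproducible from their stated inputs; the staffing-ratio sweep rows and
# scenario 6 are carried only as published, flagged excluded, because the
# printed solutions contradict the model's own conservation/LWT constraints.
table2_printed <- function() {
  tibble::tibble(
    row = 1:15,
    factor = rep(c("et_dt", "sd_asd"), c(7, 8)),
    et = c(8:2, rep(5L, 8)),
    dt = c(2:8, rep(5L, 8)),
    sd = c(rep(10L, 7), c(2L, 4L, 6L, 8L, 12L, 14L, 16L, 18L)),
    asd = c(rep(10L, 7), c(18L, 16L, 14L, 12L, 8L, 6L, 4L, 2L)),
    lwt_printed = c(272L, 271L, 270L, 270L, 272L, 270L, 288L,
                    210L, 235L, 250L, 260L, 280L, 295L, 310L, 330L),
    snpp_printed = c(-11L, -13L, -15L, -18L, -22L, -30L, -36L,
                     -30L, -26L, -22L, -20L, -16L, -13L, -10L, -6L),
    anpp_printed = c(11L, 13L, 15L, 18L, 22L, 30L, 36L,
                     6L, 10L, 14L, 16L, 20L, 23L, 26L, 30L),
    rts_printed = c(0.24, 0.25, 0.25, 0.25, 0.24, 0.25, 0.20,
                    0.42, 0.35, 0.31, 0.28, 0.22, 0.18, 0.14, 0.08),
    rtds_printed = c(0.51, 0.51, 0.50, 0.50, 0.51, 0.50, 0.60,
                     0.17, 0.31, 0.39, 0.44, 0.56, 0.64, 0.72, 0.83)
  )
}

table4_printed <- function() {
  tibble::tibble(
    scenario = 1:6,
    lwt_printed = c(270L, 240L, 250L, 265L, 285L, 280L)
  )
}

#' Reproduce the published benchmark tables
#'
#' Re-solves every reproducible benchmark row from its stated inputs and
#' lines the computed optimum up against the published value.
#' `which = "table2"` covers the examination/diagnosis time sweep: the
#' seven rows with `et + dt = 10` are solved and matched on LWT, RTS, and
#' RTDS (two-decimal rounding); the eight staffing-ratio rows are listed
#' but marked `excluded: inconsistent in source`, since their published
#' solutions violate the model's own constraints. `which = "table4"`
#' covers the five uneven-booking scenarios (matched on LWT) plus the
#' excluded sixth.
#'
#' @param which `"table2"` or `"table4"`.
#' @param backend Solver backend, see [solve_capacity()].
#' @return A tibble with columns `case_id`, `parameterization`,
#'   `lwt_computed`, `lwt_printed`, `match`, `note` (plus computed and
#'   published RTS/RTDS for the time sweep).
#' @export
reproduce_table <- function(which = c("table2", "table4"),
                            backend = c("exact", "milp")) {
  which <- match.arg(which)
  backend <- match.arg(backend)
  if (which == "table2") {
    ref <- table2_printed()
    purrr::pmap_dfr(ref, function(row, factor, et, dt, sd, asd, lwt_printed,
                                  snpp_printed, anpp_printed,
                                  rts_printed, rtds_printed) {
      if (factor != "et_dt") {
        return(tibble::tibble(
          case_id = sprintf("table2_row%d", row),
          parameterization = sprintf("et=%d dt=%d sd=%d asd=%d", et, dt, sd, asd),
          lwt_computed = NA_integer_, lwt_printed = lwt_printed,
          rts_computed = NA_real_, rts_printed = rts_printed,
          rtds_computed = NA_real_, rtds_printed = rtds_printed,
          match = NA, note = "excluded: inconsistent in source"
        ))
      }
      inst <- table2_row(et, dt)
      res <- solve_capacity(inst, mode = "lean", backend = backend)
      rts_c <- round_half_up(rts(inst, res$lwt))
      rtds_c <- round_half_up(rtds(inst, res$lwt))
      tibble::tibble(
        case_id = sprintf("table2_row%d", row),
        parameterization = sprintf("et=%d dt=%d sd=%d asd=%d", et, dt, sd, asd),
        lwt_computed = res$lwt, lwt_printed = lwt_printed,
        rts_computed = rts_c, rts_printed = rts_printed,
        rtds_computed = rtds_c, rtds_printed = rtds_printed,
        match = res$lwt == lwt_printed && rts_c == rts_printed &&
          rtds_c == rtds_printed,
        note = ""
      )
    })
  } else {
    ref <- table4_printed()
    purrr::pmap_dfr(ref, function(scenario, lwt_printed) {
      if (scenario == 6) {
        return(tibble::tibble(
          case_id = "table4_scenario6",
          parameterization = "descending seniors, descending associates",
          lwt_computed = NA_integer_, lwt_printed = lwt_printed,
          match = NA, note = "excluded: inconsistent in source"
        ))
      }
      res <- solve_capacity(table4_scenario(scenario), mode = "lean",
                            backend = backend)
      tibble::tibble(
        case_id = sprintf("table4_scenario%d", scenario),
        parameterization = sprintf("scenario %d, et=5 dt=5", scenario),
        lwt_computed = res$lwt, lwt_printed = lwt_printed,
        match = res$lwt == lwt_printed,
        note = ""
      )
    })
  }
}

#' Command-line entry points
#'
#' Thin, file-oriented wrappers used by the bundled `leanclinic` CLI script
#' (`system.file("cli", "leanclinic", package = "leanclinic")`). Each
#' returns a process-style exit code invisibly (0 on success) and writes
#' diagnostics to standard error rather than throwing, so the script can
#' exit cleanly.
#'
#' `cmd_solve()` reads an instance JSON, solves it, and writes
#' `result.json`, `report.csv`, and `metrics.json` into `out_dir`.
#' `cmd_generate()` writes the instance named by a preset:
#' `"table2:et=E,dt=D"`, `"table4:N"`, or `"random:seed=S"`.
#' `cmd_reproduce()` writes the benchmark comparison CSV.
#'
#' @param instance_path Path to an instance JSON file.
#' @param out_dir Output directory for `cmd_solve`.
#' @param mode,backend,solver Passed to [solve_capacity()].
#' @return Integer exit code, invisibly: 0 success, 1 infeasible or failed,
#'   2 invalid input.
#' @export
cmd_solve <- function(instance_path, out_dir = ".",
                      mode = c("lean", "as_printed"),
                      backend = c("exact", "milp"), solver = "highs") {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  inst <- tryCatch(read_instance(instance_path), error = function(e) e)
  if (inherits(inst, "error")) {
    message("error: cannot read instance: ", conditionMessage(inst))
    return(invisible(2L))
  }
  violations <- validate_instance(inst)
  if (length(violations) > 0) {
    message("invalid instance:\n", paste(" -", violations, collapse = "\n"))
    return(invisible(2L))
  }
  res <- tryCatch(
    solve_capacity(inst, mode = mode, backend = backend, solver = solver),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(1L))
  }
  if (!identical(res$status, "optimal")) {
    message("infeasible: no transfer plan satisfies every working-time cap")
    return(invisible(1L))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_result(res, file.path(out_dir, "result.json"))
  write_metrics(metrics_report(inst, res),
                csv_path = file.path(out_dir, "report.csv"),
                json_path = file.path(out_dir, "metrics.json"))
  message(sprintf("optimal LWT %d (%s backend, %s mode) -> %s",
                  res$lwt, backend, mode, out_dir))
  invisible(0L)
}

#' @rdname cmd_solve
#' @param preset Preset string, see Details.
#' @param out Output file path.
#' @param seed Seed for `random:` presets (overrides one given in the
#'   preset string).
#' @export
cmd_generate <- function(preset, out, seed = NULL) {
  inst <- tryCatch({
    if (grepl("^table2:", preset)) {
      kv <- parse_kv(sub("^table2:", "", preset))
      table2_row(as.integer(kv[["et"]]), as.integer(kv[["dt"]]))
    } else if (grepl("^table4:", preset)) {
      table4_scenario(as.integer(sub("^table4:", "", preset)))
    } else if (grepl("^random", preset)) {
      kv <- parse_kv(sub("^random:?", "", preset))
      s <- if (!is.null(seed)) seed else as.integer(kv[["seed"]])
      random_instance(s)
    } else {
      rlang::abort(sprintf("unknown preset '%s'", preset))
    }
  }, error = function(e) e)
  if (inherits(inst, "error")) {
    message("error: ", conditionMessage(inst))
    return(invisible(2L))
  }
  write_instance(inst, out)
  message("wrote ", out)
  invisible(0L)
}

parse_kv <- function(s) {
  if (!nzchar(s)) return(list())
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

#' @rdname cmd_solve
#' @param which `"table2"` or `"table4"`.
#' @export
cmd_reproduce <- function(which, out, backend = "exact") {
  tab <- tryCatch(reproduce_table(which, backend = backend),
                  error = function(e) e)
  if (inherits(tab, "error")) {
    message("error: ", conditionMessage(tab))
    return(invisible(1L))
  }
  utils::write.csv(tab, out, row.names = FALSE)
  n_match <- sum(tab$match, na.rm = TRUE)
  n_excl <- sum(is.na(tab$match))
  message(sprintf("%s: %d rows matched, %d excluded -> %s",
                  which, n_match, n_excl, out))
  invisible(0L)
}
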