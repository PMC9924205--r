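#' Build the min-max transfer model as an explicit MILP
#'
#' Lays out the integer linear program exactly as the capacity-planning
#' model states it, with one integer transfer variable per doctor and one
#' continuous LWT variable:
#' \itemize{
#'   \item cap rows: `(et + dt) * booked[i] + et * npp[i] <= work_time[i]`
#'     for every doctor;
#'   \item LWT rows: `(et + dt) * booked[i] + et * npp[i] <= LWT` for every
#'     doctor;
#'   \item conservation: `sum(npp) == 0`;
#'   \item sign bounds per mode: senders `-booked[i] <= npp[i] <= 0`,
#'     receivers `npp[i] >= 0` (see [doctor_roles()]);
#'   \item objective: minimize LWT.
#' }
#' LWT is declared continuous but is integral at the optimum for integer
#' data; the solve step verifies and reports it as an integer.
#'
#' @inheritParams feasible_at
#' @return A `milp_model`: objective vector, dense constraint matrix with
#'   row bounds, variable bounds, integrality flags, plus the mode and the
#'   originating instance.
#' @export
build_model <- function(instance, mode = c("lean", "as_printed")) {
  mode <- match.arg(mode)
  stop_if_invalid(instance)
  doc <- instance$doctors
  td <- n_doctors(instance)
  et <- instance$et
  base <- base_workload(instance)
  roles <- doctor_roles(instance, mode)

  nv <- td + 1L # npp_1..npp_td, LWT
  obj <- c(rep(0, td), 1)

  a_cap <- cbind(diag(et, td), 0)
  a_lwt <- cbind(diag(et, td), -1)
  a_con <- matrix(c(rep(1, td), 0), nrow = 1)
  A <- rbind(a_cap, a_lwt, a_con)
  con_ub <- c(doc$work_time - base, -base, 0)
  con_lb <- c(rep(-Inf, 2L * td), 0)

  lb <- c(ifelse(roles == "sender", -doc$booked, 0), 0)
  ub <- c(ifelse(roles == "sender", 0, total_patients(instance)), Inf)

  structure(
    list(
      obj = obj, A = A, con_lb = con_lb, con_ub = con_ub,
      lb = lb, ub = ub,
      integrality = c(rep(1L, td), 0L),
      var_names = c(paste0("npp_", doc$id), "LWT"),
      row_names = c(paste0("cap_", doc$id), paste0("lwt_", doc$id), "conserve"),
      mode = mode, instance = instance
    ),
    class = "milp_model"
  )
}

#' @export
print.milp_model <- function(x, ...) {
  cat(sprintf("<milp_model> %d variables (%d integer), %d constraint rows, mode %s\n",
              length(x$obj), sum(x$integrality == 1L), nrow(x$A), x$mode))
  invisible(x)
}

#' Export a MILP model in LP text format
#'
#' Writes a model built by [build_model()] in the plain-text LP format most
#' solvers read, mainly for debugging and external cross-checks.
#'
#' @param model A `milp_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  stopifnot(inherits(model, "milp_model"))
  term <- function(coefs) {
    idx <- which(coefs != 0)
    paste(sprintf("%+g %s", coefs[idx], model$var_names[idx]), collapse = " ")
  }
  lines <- c("Minimize", paste(" obj:", term(model$obj)), "Subject To")
  for (r in seq_len(nrow(model$A))) {
    lhs <- term(model$A[r, ])
    if (is.finite(model$con_lb[r]) && model$con_lb[r] == model$con_ub[r]) {
      lines <- c(lines, sprintf(" %s: %s = %g", model$row_names[r], lhs,
                                model$con_ub[r]))
    } else {
      if (is.finite(model$con_ub[r])) {
        lines <- c(lines, sprintf(" %s: %s <= %g", model$row_names[r], lhs,
                                  model$con_ub[r]))
      }
      if (is.finite(model$con_lb[r])) {
        lines <- c(lines, sprintf(" %s_lo: %s >= %g", model$row_names[r], lhs,
                                  model$con_lb[r]))
      }
    }
  }
  lines <- c(lines, "Bounds")
  for (v in seq_along(model$obj)) {
    ub_txt <- if (is.finite(model$ub[v])) sprintf("%g", model$ub[v]) else "+inf"
    lines <- c(lines, sprintf(" %g <= %s <= %s", model$lb[v],
                              model$var_names[v], ub_txt))
  }
  ints <- model$var_names[model$integrality == 1L]
  if (length(ints)) lines <- c(lines, "General", paste("", paste(ints, collapse = " ")))
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}

milp_runner_path <- function() {
  p <- system.file("python", "milp_solve.py", package = "leanclinic")
  if (!nzchar(p)) rlang::abort("bundled MILP runner script not found")
  p
}

find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}

model_payload <- function(model) {
  big <- 1e30
  clamp <- function(v) ifelse(is.infinite(v), sign(v) * big, v)
  list(
    obj = model$obj,
    A = unname(apply(model$A, 1, as.numeric, simplify = FALSE)),
    con_lb = clamp(model$con_lb), con_ub = clamp(model$con_ub),
    lb = clamp(model$lb), ub = clamp(model$ub),
    integrality = model$integrality
  )
}

# Solve a list of milp_model objects in one solver subprocess; returns a
# list of raw results (status, objective, x).
solve_milp_batch <- function(models, solver = "highs") {
  if (!identical(solver, "highs")) {
    rlang::abort(sprintf(
      "unsupported solver '%s'; available backend: 'highs' (via SciPy)", solver))
  }
  py <- find_python()
  if (!nzchar(py)) {
    rlang::abort(paste(
      "MILP backend needs a `python` with SciPy on the PATH (solver 'highs');",
      "none found. Use backend = 'exact' or install python + scipy."))
  }
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(
    list(models = lapply(models, model_payload)),
    infile, auto_unbox = FALSE, digits = NA
  )
  status <- system2(py, c(milp_runner_path(), infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(outfile)) {
    rlang::abort(sprintf("MILP solver subprocess failed (exit status %d)", status))
  }
  jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Solve a built MILP model through an external mixed-integer solver
#'
#' Hands the model from [build_model()] to a mixed-integer solver (currently
#' the HiGHS solver through SciPy's `milp` interface, run in a `python`
#' subprocess) and returns the same `solve_result` shape as [solve_exact()].
#' The optimal LWT is checked to be integral within 1e-6 and reported as an
#' integer; the returned plan always satisfies [check_plan()] at that LWT.
#'
#' @param model A `milp_model` from [build_model()].
#' @param solver Solver name; `"highs"` is the supported backend.
#' @return A `solve_result` with `backend = "milp"`.
#' @export
solve_milp <- function(model, solver = "highs") {
  stopifnot(inherits(model, "milp_model"))
  raw <- solve_milp_batch(list(model), solver)[[1]]
  milp_result_from_raw(raw, model)
}

milp_result_from_raw <- function(raw, model) {
  instance <- model$instance
  if (!identical(raw$status, "optimal")) {
    return(new_solve_result(
      lwt = NA_integer_, npp = NULL, mode = model$mode, backend = "milp",
      status = "infeasible", instance = instance
    ))
  }
  x <- as.numeric(raw$x)
  td <- n_doctors(instance)
  npp <- as.integer(round(x[seq_len(td)]))
  lwt <- x[td + 1L]
  if (abs(lwt - round(lwt)) > 1e-6) {
    rlang::abort(sprintf("solver returned non-integral LWT %.8f", lwt))
  }
  new_solve_result(
    lwt = as.integer(round(lwt)), npp = npp, mode = model$mode,
    backend = "milp", status = "optimal", instance = instance
  )
}

#' Solve a clinic instance with a chosen backend
#'
#' One front door over the two solvers: `backend = "exact"` runs the
#' dependency-free binary-search optimizer ([solve_exact()]), and
#' `backend = "milp"` builds the explicit integer program and hands it to a
#' mixed-integer solver ([build_model()] + [solve_milp()]). Both return the
#' same `solve_result` and, for `"lean"` mode, the same optimal LWT.
#'
#' @inheritParams feasible_at
#' @param backend `"exact"` (default) or `"milp"`.
#' @param solver Solver name for the MILP backend.
#' @return A `solve_result`.
#' @export
solve_capacity <- function(instance, mode = c("lean", "as_printed"),
                           backend = c("exact", "milp"), solver = "highs") {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  if (backend == "exact") {
    solve_exact(instance, mode)
  } else {
    solve_milp(build_model(instance, mode), solver = solver)
  }
}
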