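#' Build a clinic instance
#'
#' A clinic instance bundles a doctor roster with the two per-patient service
#' durations of the refined outpatient pathway: the examination stage (chief
#' complaint plus first medical order, `et` time units per patient) and the
#' diagnosis stage (interpretation of results and treatment plan, `dt` time
#' units per patient). Each doctor has a rank (`"senior"` or `"associate"`),
#' a booked patient count, and a working-time cap. Transfers move examination
#' services between doctors; diagnosis services stay with the booked doctor.
#'
#' The roster is stored with all senior doctors before all associates
#' (stable within rank); the constructor reorders if needed. An optional
#' binary doctor-by-patient appointment matrix can be attached: each column
#' (patient) must sum to 1 and row sums must equal the booked counts.
#'
#' @param doctors Data frame with columns `id` (character), `rank`
#'   (`"senior"` or `"associate"`), `booked` (non-negative integer count of
#'   appointed patients), and `work_time` (non-negative integer cap in time
#'   units). Extra columns are dropped.
#' @param et Integer examination time per patient, > 0.
#' @param dt Integer diagnosis time per patient, > 0.
#' @param appointments Optional binary matrix, one row per doctor and one
#'   column per patient.
#' @return An object of class `clinic_instance`.
#' @examples
#' roster <- tibble::tibble(
#'   id = c("S1", "S2", "A1", "A2"),
#'   rank = c("senior", "senior", "associate", "associate"),
#'   booked = c(36L, 36L, 18L, 18L),
#'   work_time = 360L
#' )
#' inst <- clinic_instance(roster, et = 5, dt = 5)
#' base_workload(inst)
#' @export
clinic_instance <- function(doctors, et, dt, appointments = NULL) {
  stopifnot(is.data.frame(doctors))
  needed <- c("id", "rank", "booked", "work_time")
  missing_cols <- setdiff(needed, names(doctors))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "`doctors` is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  doctors <- tibble::as_tibble(doctors)[needed]
  doctors$id <- as.character(doctors$id)
  doctors$rank <- as.character(doctors$rank)
  for (col in c("booked", "work_time")) {
    v <- doctors[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v))) {
      rlang::abort(paste0("`doctors$", col, "` must be whole numbers"))
    }
    doctors[[col]] <- as.integer(v)
  }
  check_scalar_time <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x)) {
      rlang::abort(paste0("`", name, "` must be a single whole number"))
    }
    as.integer(x)
  }
  et <- check_scalar_time(et, "et")
  dt <- check_scalar_time(dt, "dt")

  # seniors first, stable within rank (index convention used throughout)
  ord <- order(match(doctors$rank, c("senior", "associate")), na.last = TRUE)
  doctors <- doctors[ord, ]
  if (!is.null(appointments)) {
    appointments <- as.matrix(appointments)[ord, , drop = FALSE]
    storage.mode(appointments) <- "integer"
  }

  structure(
    list(doctors = doctors, et = et, dt = dt, appointments = appointments),
    class = "clinic_instance"
  )
}

#' @export
print.clinic_instance <- function(x, ...) {
  n_sen <- sum(x$doctors$rank == "senior")
  n_assoc <- sum(x$doctors$rank == "associate")
  cat(sprintf(
    "<clinic_instance> %d doctors (%d senior, %d associate), %d patients booked\n",
    nrow(x$doctors), n_sen, n_assoc, sum(x$doctors$booked)
  ))
  cat(sprintf(
    "  examination %d + diagnosis %d time units per patient%s\n",
    x$et, x$dt,
    if (is.null(x$appointments)) "" else "; appointment matrix attached"
  ))
  print(x$doctors, ...)
  invisible(x)
}

n_doctors <- function(instance) nrow(instance$doctors)
n_seniors <- function(instance) sum(instance$doctors$rank == "senior")
total_patients <- function(instance) sum(instance$doctors$booked)

#' Validate a clinic instance
#'
#' Checks the structural invariants of a clinic instance and reports every
#' violation found rather than stopping at the first: ranks must be
#' `"senior"` or `"associate"`, booked counts and working-time caps must be
#' non-negative, service times positive, and any attached appointment matrix
#' must be binary with one doctor per patient (column sums 1) and row sums
#' equal to the booked counts.
#'
#' @param instance A `clinic_instance`.
#' @return Character vector of human-readable violation descriptions, each
#'   naming the doctor or patient index involved; `character(0)` when the
#'   instance is valid.
#' @export
validate_instance <- function(instance) {
  stopifnot(inherits(instance, "clinic_instance"))
  doc <- instance$doctors
  out <- character(0)
  bad_rank <- which(!doc$rank %in% c("senior", "associate"))
  for (i in bad_rank) {
    out <- c(out, sprintf("doctor %d (%s): rank '%s' is not senior/associate",
                          i, doc$id[i], doc$rank[i]))
  }
  for (i in which(doc$booked < 0)) {
    out <- c(out, sprintf("doctor %d (%s): booked count %d is negative",
                          i, doc$id[i], doc$booked[i]))
  }
  for (i in which(doc$work_time < 0)) {
    out <- c(out, sprintf("doctor %d (%s): work_time %d is negative",
                          i, doc$id[i], doc$work_time[i]))
  }
  if (instance$et <= 0) out <- c(out, "examination time et must be positive")
  if (instance$dt <= 0) out <- c(out, "diagnosis time dt must be positive")
  if (is.na(match("senior", doc$rank)) || is.na(match("associate", doc$rank))) {
    out <- c(out, "roster needs at least one senior and one associate doctor")
  }

  m <- instance$appointments
  if (!is.null(m)) {
    if (nrow(m) != nrow(doc)) {
      out <- c(out, sprintf(
        "appointment matrix has %d rows but roster has %d doctors",
        nrow(m), nrow(doc)))
    } else {
      if (!all(m %in% c(0L, 1L))) {
        out <- c(out, "appointment matrix entries must be 0 or 1")
      }
      csum <- colSums(m)
      for (j in which(csum != 1L)) {
        out <- c(out, sprintf(
          "patient %d is appointed to %d doctors (must be exactly 1)", j, csum[j]))
      }
      rsum <- rowSums(m)
      for (i in which(rsum != doc$booked)) {
        out <- c(out, sprintf(
          "doctor %d (%s): matrix row sum %d != booked %d",
          i, doc$id[i], rsum[i], doc$booked[i]))
      }
    }
  }
  out
}

stop_if_invalid <- function(instance) {
  v <- validate_instance(instance)
  if (length(v) > 0) {
    rlang::abort(c("invalid clinic instance", v))
  }
  invisible(instance)
}

check_index <- function(instance, doctor_index) {
  if (!is.numeric(doctor_index) ||
      any(doctor_index < 1 | doctor_index > n_doctors(instance))) {
    rlang::abort(sprintf(
      "doctor_index must lie in 1..%d", n_doctors(instance)))
  }
  as.integer(doctor_index)
}

check_plan_aligned <- function(instance, plan) {
  npp <- plan_npp(plan)
  if (length(npp) != n_doctors(instance)) {
    rlang::abort(sprintf(
      "plan has %d entries but instance has %d doctors",
      length(npp), n_doctors(instance)))
  }
  if (anyNA(npp) || any(npp != floor(npp))) {
    rlang::abort("transfer counts must be whole numbers")
  }
  as.integer(npp)
}

plan_npp <- function(plan) {
  if (inherits(plan, "solve_result")) return(plan$npp)
  if (is.list(plan) && !is.null(plan$npp)) return(plan$npp)
  plan
}

#' Pre-plan working time per doctor
#'
#' The working time of a doctor before any reallocation: each booked patient
#' takes the full refined pathway, `(et + dt) * booked`.
#'
#' @param instance A `clinic_instance`.
#' @param doctor_index Doctor position(s) in the roster (1-based); defaults
#'   to all doctors.
#' @return Integer vector of working times, in the instance's time units.
#' @export
base_workload <- function(instance, doctor_index = seq_len(n_doctors(instance))) {
  doctor_index <- check_index(instance, doctor_index)
  (instance$et + instance$dt) * instance$doctors$booked[doctor_index]
}

#' Post-plan working time per doctor
#'
#' Working time after a transfer plan is applied: the base workload plus
#' `et` for every examination service transferred in (or minus `et` per
#' service transferred out). No cap checking happens here — see
#' [check_plan()].
#'
#' @inheritParams base_workload
#' @param plan Integer vector of signed per-doctor transfer counts (negative
#'   = examination services shed, positive = absorbed), aligned with the
#'   roster, or a `solve_result`.
#' @return Integer vector of post-plan working times.
#' @export
post_workload <- function(instance, plan,
                          doctor_index = seq_len(n_doctors(instance))) {
  npp <- check_plan_aligned(instance, plan)
  doctor_index <- check_index(instance, doctor_index)
  base_workload(instance, doctor_index) + instance$et * npp[doctor_index]
}

#' Check a transfer plan against the model constraints
#'
#' Verifies a candidate plan against every constraint of the min-max transfer
#' model at a given maximum working time: per-doctor working-time caps,
#' post-plan workload at most `lwt` for every doctor, conservation of the
#' total number of examination services (transfers sum to zero), the bound
#' that no doctor sheds more services than it has booked, and the
#' mode-dependent sign constraints (see [doctor_roles()]).
#'
#' @inheritParams post_workload
#' @param mode `"lean"` (seniors shed, associates absorb) or `"as_printed"`
#'   (sign set by each doctor's booked count versus the global average).
#' @param lwt Candidate maximum working time, in time units.
#' @return Character vector of violation descriptions; `character(0)` when
#'   the plan is feasible at `lwt`.
#' @export
check_plan <- function(instance, plan, mode = c("lean", "as_printed"), lwt) {
  mode <- match.arg(mode)
  npp <- check_plan_aligned(instance, plan)
  doc <- instance$doctors
  post <- base_workload(instance) + instance$et * npp
  out <- character(0)
  for (i in which(post > doc$work_time)) {
    out <- c(out, sprintf(
      "doctor %d (%s): post-plan workload %d exceeds work_time cap %d",
      i, doc$id[i], post[i], doc$work_time[i]))
  }
  for (i in which(post > lwt)) {
    out <- c(out, sprintf(
      "doctor %d (%s): post-plan workload %d exceeds LWT %d",
      i, doc$id[i], post[i], lwt))
  }
  for (i in which(npp < -doc$booked)) {
    out <- c(out, sprintf(
      "doctor %d (%s): sheds %d services but has only %d booked",
      i, doc$id[i], -npp[i], doc$booked[i]))
  }
  roles <- doctor_roles(instance, mode)
  for (i in which(roles == "sender" & npp > 0)) {
    out <- c(out, sprintf(
      "doctor %d (%s): positive transfer %d but mode '%s' only lets this doctor shed",
      i, doc$id[i], npp[i], mode))
  }
  for (i in which(roles == "receiver" & npp < 0)) {
    out <- c(out, sprintf(
      "doctor %d (%s): negative transfer %d but mode '%s' only lets this doctor absorb",
      i, doc$id[i], npp[i], mode))
  }
  if (sum(npp) != 0L) {
    out <- c(out, sprintf(
      "transfers sum to %d, not 0 (examination services must be conserved)",
      sum(npp)))
  }
  out
}

#' Sender/receiver role of each doctor under a sign mode
#'
#' In `"lean"` mode the refined pathway is one-directional: senior doctors
#' only shed examination services (`sender`) and associate doctors only
#' absorb them (`receiver`). In `"as_printed"` mode the sign of each
#' doctor's transfer is set by comparing its booked count with the global
#' average caseload `tp / td` using exact integer arithmetic: strictly above
#' average means shed, at or below average means absorb, regardless of rank.
#'
#' @inheritParams check_plan
#' @return Character vector, `"sender"` or `"receiver"` per doctor.
#' @export
doctor_roles <- function(instance, mode = c("lean", "as_printed")) {
  mode <- match.arg(mode)
  doc <- instance$doctors
  if (mode == "lean") {
    ifelse(doc$rank == "senior", "sender", "receiver")
  } else {
    # booked > tp/td  <=>  booked * td > tp, exactly, no rounding
    ifelse(doc$booked * n_doctors(instance) > total_patients(instance),
           "sender", "receiver")
  }
}

#' Read / write clinic instances as JSON
#'
#' The on-disk format is a small JSON object:
#' `{"et": int, "dt": int, "doctors": [{"id", "rank", "booked",
#' "work_time"}, ...], "dpat": optional binary matrix}`. A round trip
#' through [write_instance()] and [read_instance()] reproduces an identical
#' instance.
#'
#' @param path File path.
#' @return `read_instance()` returns a `clinic_instance`;
#'   `write_instance()` returns `path` invisibly.
#' @export
read_instance <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("instance file %s does not exist", path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("et", "dt", "doctors")) {
    if (is.null(x[[key]])) {
      rlang::abort(sprintf("instance file %s: missing field '%s'", path, key))
    }
  }
  m <- x$dpat
  if (!is.null(m)) m <- matrix(as.integer(m), nrow = nrow(x$doctors))
  clinic_instance(x$doctors, et = x$et, dt = x$dt, appointments = m)
}

#' @rdname read_instance
#' @param instance A `clinic_instance`.
#' @export
write_instance <- function(instance, path) {
  stopifnot(inherits(instance, "clinic_instance"))
  x <- list(
    et = instance$et,
    dt = instance$dt,
    doctors = instance$doctors
  )
  if (!is.null(instance$appointments)) {
    x$dpat <- unname(instance$appointments)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write solve results as JSON
#'
#' Format: `{"lwt": int, "mode": str, "backend": str, "status": str,
#' "npp": [int, ...]}`.
#'
#' @param result A `solve_result`.
#' @param path File path.
#' @return `write_result()` returns `path` invisibly; `read_result()`
#'   returns the parsed fields as a list.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "solve_result"))
  jsonlite::write_json(
    list(lwt = result$lwt, mode = result$mode, backend = result$backend,
         status = result$status, npp = as.list(result$npp)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$npp <- as.integer(x$npp)
  x
}
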