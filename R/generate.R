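#' Benchmark instance for the examination/diagnosis time sweep
#'
#' The 20-doctor clinic used for the service-time sweep: 10 senior doctors
#' booked 36 patients each, 10 associates booked 18 each, a 360-time-unit
#' cap for everyone, and a total pathway time of 10 units split between
#' examination and diagnosis. The sweep varies the split from `et = 8,
#' dt = 2` down to `et = 2, dt = 8`.
#'
#' @param et Examination time per patient, 2..8.
#' @param dt Diagnosis time per patient; `et + dt` must equal 10.
#' @return A `clinic_instance`.
#' @export
table2_row <- function(et, dt) {
  if (et + dt != 10 || et < 2 || et > 8) {
    rlang::abort("the service-time sweep uses et + dt = 10 with et in 2..8")
  }
  uniform_clinic(sd = 10, asd = 10, senior_booked = 36, associate_booked = 18,
                 et = et, dt = dt, work_time = 360)
}

#' Benchmark scenarios with uneven bookings
#'
#' Six 20-doctor scenarios (10 seniors, 10 associates, `et = dt = 5`,
#' work-time cap 360) that vary how busy each group is:
#' \enumerate{
#'   \item uniform: seniors booked 36, associates 18;
#'   \item alternating seniors 36/18, associates 18;
#'   \item descending seniors (36,30,36,28,36,26,36,24,36,22), associates 18;
#'   \item seniors as (3), alternating associates 18/24;
#'   \item uniform seniors 36, alternating associates 18/24;
#'   \item seniors as (3), descending associates (18,30,18,28,18,26,18,24,18,22).
#' }
#'
#' @param n Scenario number, 1..6.
#' @return A `clinic_instance`.
#' @export
table4_scenario <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || !n %in% 1:6) {
    rlang::abort("scenario number must be one of 1..6")
  }
  desc_sen <- c(36L, 30L, 36L, 28L, 36L, 26L, 36L, 24L, 36L, 22L)
  sen <- switch(n,
    rep(36L, 10),
    rep(c(36L, 18L), 5),
    desc_sen,
    desc_sen,
    rep(36L, 10),
    desc_sen
  )
  assoc <- switch(n,
    rep(18L, 10),
    rep(18L, 10),
    rep(18L, 10),
    rep(c(18L, 24L), 5),
    rep(c(18L, 24L), 5),
    c(18L, 30L, 18L, 28L, 18L, 26L, 18L, 24L, 18L, 22L)
  )
  uniform_clinic(sd = 10, asd = 10, senior_booked = sen,
                 associate_booked = assoc, et = 5, dt = 5, work_time = 360)
}

#' Build a clinic from group-level settings
#'
#' Convenience constructor used by the benchmark generators and available
#' for custom scenarios: counts of doctors per rank, booked caseloads given
#' either as a single value per group or a full vector, and one shared
#' working-time cap.
#'
#' @param sd,asd Number of senior / associate doctors.
#' @param senior_booked,associate_booked Booked counts, length 1 or
#'   `sd` / `asd`.
#' @param et,dt Service times per patient.
#' @param work_time Working-time cap applied to every doctor.
#' @return A `clinic_instance`.
#' @export
uniform_clinic <- function(sd, asd, senior_booked, associate_booked,
                           et, dt, work_time) {
  stopifnot(sd >= 1, asd >= 1)
  sen <- rep_len(as.integer(senior_booked), sd)
  assoc <- rep_len(as.integer(associate_booked), asd)
  if (!length(senior_booked) %in% c(1L, sd) ||
      !length(associate_booked) %in% c(1L, asd)) {
    rlang::abort("booked vectors must have length 1 or match the group size")
  }
  clinic_instance(
    tibble::tibble(
      id = c(sprintf("S%02d", seq_len(sd)), sprintf("A%02d", seq_len(asd))),
      rank = rep(c("senior", "associate"), c(sd, asd)),
      booked = c(sen, assoc),
      work_time = as.integer(work_time)
    ),
    et = et, dt = dt
  )
}

#' Seeded random clinic instance
#'
#' Draws a reproducible instance for property tests: doctor count, per-rank
#' split, booked counts, and service times all uniform over the given
#' ranges, with at least one doctor of each rank. Working-time caps are
#' drawn between the largest base workload implied by the draw and twice
#' that, so most instances are feasible while some caps bind. The caller's
#' RNG state is left untouched.
#'
#' @param seed Integer seed; identical seed and ranges give an identical
#'   instance.
#' @param td_range,booked_range,et_range,dt_range Inclusive integer ranges
#'   `c(lo, hi)` for total doctors (lo >= 2), per-doctor booked counts,
#'   and service times (lo >= 1).
#' @return A `clinic_instance`.
#' @export
random_instance <- function(seed, td_range = c(2, 10),
                            booked_range = c(0, 40),
                            et_range = c(1, 10), dt_range = c(1, 10)) {
  check_range <- function(r, name, lo_min) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo_min) {
      rlang::abort(sprintf("`%s` must be c(lo, hi) with lo >= %d and lo <= hi",
                           name, lo_min))
    }
  }
  check_range(td_range, "td_range", 2)
  check_range(booked_range, "booked_range", 0)
  check_range(et_range, "et_range", 1)
  check_range(dt_range, "dt_range", 1)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)

  rint <- function(r, n = 1) {
    v <- seq.int(r[1], r[2])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  td <- rint(td_range)
  tds <- sample.int(td - 1L, 1)
  booked <- rint(booked_range, td)
  et <- rint(et_range)
  dt <- rint(dt_range)
  max_base <- max(1L, (et + dt) * max(booked))
  work_time <- rint(c(max_base, 2L * max_base), td)

  clinic_instance(
    tibble::tibble(
      id = c(sprintf("S%02d", seq_len(tds)), sprintf("A%02d", seq_len(td - tds))),
      rank = rep(c("senior", "associate"), c(tds, td - tds)),
      booked = as.integer(booked),
      work_time = as.integer(work_time)
    ),
    et = et, dt = dt
  )
}

#' Attach an explicit appointment matrix
#'
#' Expands booked counts into the binary doctor-by-patient matrix form:
#' patients are numbered doctor by doctor in roster order, so row sums
#' equal the booked counts and each column has exactly one 1. Idempotent on
#' instances already carrying a consistent matrix; an inconsistent existing
#' matrix is an error.
#'
#' @param instance A `clinic_instance`.
#' @return The instance with `appointments` filled in.
#' @export
expand_matrix <- function(instance) {
  stopifnot(inherits(instance, "clinic_instance"))
  if (!is.null(instance$appointments)) {
    m <- instance$appointments
    if (!all(rowSums(m) == instance$doctors$booked) ||
        !all(colSums(m) == 1L) || !all(m %in% c(0L, 1L))) {
      rlang::abort("existing appointment matrix is inconsistent with booked counts")
    }
    return(instance)
  }
  booked <- instance$doctors$booked
  tp <- sum(booked)
  m <- matrix(0L, nrow = length(booked), ncol = tp)
  if (tp > 0) {
    m[cbind(rep(seq_along(booked), booked), seq_len(tp))] <- 1L
  }
  instance$appointments <- m
  instance
}
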