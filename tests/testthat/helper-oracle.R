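# Exhaustive enumeration oracle for tiny instances: tries every integer
# transfer vector allowed by the mode's sign pattern, keeps those that
# conserve the total and respect every work_time cap, and returns the
# smallest attainable maximum workload. Independent of the binary-search
# and MILP code paths.
brute_force_lwt <- function(instance, mode = "lean") {
  doc <- instance$doctors
  roles <- doctor_roles(instance, mode)
  sendable <- sum(doc$booked[roles == "sender"])
  ranges <- lapply(seq_len(nrow(doc)), function(i) {
    if (roles[i] == "sender") seq.int(-doc$booked[i], 0L)
    else seq.int(0L, sendable)
  })
  grid <- as.matrix(expand.grid(ranges))
  grid <- grid[rowSums(grid) == 0L, , drop = FALSE]
  base <- base_workload(instance)
  post <- sweep(grid * instance$et, 2, base, "+")
  ok <- rowSums(sweep(post, 2, doc$work_time, ">")) == 0L
  if (!any(ok)) return(NA_integer_)
  min(apply(post[ok, , drop = FALSE], 1, max))
}

tiny_instance <- function(seed) {
  random_instance(seed, td_range = c(2, 4), booked_range = c(0, 5),
                  et_range = c(1, 6), dt_range = c(1, 6))
}

# Four-doctor fixture used across unit tests (scenario-style numbers).
small_clinic <- function(et = 5, dt = 5, work_time = 360) {
  clinic_instance(
    tibble::tibble(
      id = c("S1", "S2", "A1", "A2"),
      rank = c("senior", "senior", "associate", "associate"),
      booked = c(36L, 30L, 18L, 24L),
      work_time = as.integer(work_time)
    ),
    et = et, dt = dt
  )
}
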