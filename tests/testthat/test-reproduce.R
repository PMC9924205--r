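test_that("the time-sweep reproduction matches seven rows and excludes the rest", {
  tab <- reproduce_table("table2")
  expect_equal(nrow(tab), 15)
  solved <- tab[!is.na(tab$match), ]
  expect_equal(nrow(solved), 7)
  expect_true(all(solved$match))
  expect_equal(solved$lwt_computed,
               c(272L, 271L, 270L, 270L, 272L, 270L, 288L))
  excluded <- tab[is.na(tab$match), ]
  expect_equal(unique(excluded$note), "excluded: inconsistent in source")
  expect_true(all(is.na(excluded$lwt_computed)))
})

test_that("the scenario reproduction matches 1-5 and excludes scenario 6", {
  tab <- reproduce_table("table4")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$lwt_computed[1:5], c(270L, 240L, 250L, 265L, 285L))
  expect_true(all(tab$match[1:5]))
  expect_true(is.na(tab$match[6]))
  expect_match(tab$note[6], "excluded")

  # deterministic across runs
  expect_identical(tab, reproduce_table("table4"))
})

test_that("cmd_solve writes result, report, and metrics for a valid instance", {
  dir <- withr::local_tempdir()
  inst_path <- file.path(dir, "instance.json")
  write_instance(table4_scenario(1), inst_path)
  out_dir <- file.path(dir, "out")
  expect_message(code <- cmd_solve(inst_path, out_dir = out_dir), "optimal LWT 270")
  expect_equal(code, 0L)
  res <- read_result(file.path(out_dir, "result.json"))
  expect_equal(res$lwt, 270L)
  expect_true(file.exists(file.path(out_dir, "report.csv")))
  metrics <- jsonlite::read_json(file.path(out_dir, "metrics.json"),
                                 simplifyVector = TRUE)
  expect_equal(metrics$snpp, -18L)
})

test_that("cmd_solve signals invalid and infeasible inputs via exit codes", {
  dir <- withr::local_tempdir()
  bad <- table4_scenario(1)
  bad$doctors$booked[1] <- -1L
  bad_path <- file.path(dir, "bad.json")
  write_instance(bad, bad_path)
  expect_message(code <- cmd_solve(bad_path, out_dir = dir), "invalid instance")
  expect_equal(code, 2L)

  infeasible <- clinic_instance(
    tibble::tibble(id = c("S1", "A1"), rank = c("senior", "associate"),
                   booked = c(10L, 0L), work_time = c(50L, 400L)),
    et = 2, dt = 8
  )
  inf_path <- file.path(dir, "infeasible.json")
  write_instance(infeasible, inf_path)
  expect_message(code <- cmd_solve(inf_path, out_dir = dir), "infeasible")
  expect_equal(code, 1L)

  expect_message(code <- cmd_solve(file.path(dir, "nope.json"), out_dir = dir),
                 "cannot read")
  expect_equal(code, 2L)
})

test_that("cmd_generate understands the preset grammar", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "sweep.json")
  expect_message(cmd_generate("table2:et=6,dt=4", out = f1), "wrote")
  expect_equal(read_instance(f1)$et, 6L)

  f2 <- file.path(dir, "scenario.json")
  cmd_generate("table4:3", out = f2)
  expect_equal(read_instance(f2)$doctors$booked[2], 30L)

  f3 <- file.path(dir, "rand.json")
  f4 <- file.path(dir, "rand2.json")
  cmd_generate("random:seed=11", out = f3)
  cmd_generate("random", out = f4, seed = 11)
  expect_identical(readLines(f3), readLines(f4))

  expect_message(code <- cmd_generate("bogus:1", out = f1), "unknown preset")
  expect_equal(code, 2L)
})

test_that("cmd_reproduce writes the comparison CSV", {
  out <- withr::local_tempfile(fileext = ".csv")
  expect_message(code <- cmd_reproduce("table4", out = out), "5 rows matched")
  expect_equal(code, 0L)
  tab <- utils::read.csv(out)
  expect_true(all(c("case_id", "parameterization", "lwt_computed",
                    "lwt_printed", "match", "note") %in% names(tab)))
})

test_that("the bundled CLI script solves an instance end to end", {
  script <- system.file("cli", "leanclinic", package = "leanclinic")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  inst_path <- file.path(dir, "instance.json")
  write_instance(table4_scenario(2), inst_path)
  # child process must see the library this package is installed in
  withr::local_envvar(R_LIBS = paste(.libPaths(),
                                     collapse = .Platform$path.sep))
  status <- system2("Rscript", c(script, "solve", "--instance", inst_path,
                                 "--out", file.path(dir, "out")),
                    stdout = TRUE, stderr = TRUE)
  expect_equal(attr(status, "status"), NULL) # exit 0
  expect_equal(read_result(file.path(dir, "out", "result.json"))$lwt, 240L)
})
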