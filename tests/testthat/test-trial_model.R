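test_that("a repository round-trips through write and load", {
  dir <- withr::local_tempdir()
  trials <- list(example_trial("rt-1"), two_arm_trial("rt-2"))
  names(trials) <- c("rt-1", "rt-2")
  write_repository(trials, dir)

  repo <- load_repository(dir)
  expect_equal(nrow(repo$errors), 0L)
  expect_setequal(names(repo$trials), c("rt-1", "rt-2"))
  back <- repo$trials[["rt-1"]]
  orig <- trials[["rt-1"]]
  expect_equal(back$trial_id, orig$trial_id)
  expect_equal(back$coding, orig$coding)
  expect_equal(back$cells$mean, orig$cells$mean)
  expect_equal(back$cells$sd, orig$cells$sd)
  expect_equal(back$measures$direction, orig$measures$direction)

  # writing the re-loaded trials again gives byte-identical files
  dir2 <- withr::local_tempdir()
  write_repository(repo$trials, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("loading an empty directory yields an empty repository", {
  dir <- withr::local_tempdir()
  repo <- load_repository(dir)
  expect_length(repo$trials, 0)
  expect_equal(nrow(repo$errors), 0L)
})

test_that("a trial with sd = 0 is rejected with the violated invariant named", {
  dir <- withr::local_tempdir()
  bad <- two_arm_trial("bad-sd")
  bad$cells$sd[1] <- 0
  write_repository(list(bad, two_arm_trial("ok-1")), dir)
  repo <- load_repository(dir)
  expect_setequal(names(repo$trials), "ok-1")
  expect_equal(nrow(repo$errors), 1L)
  expect_equal(repo$errors$rule, "sd > 0")
  expect_equal(repo$errors$file, "bad-sd.yaml")
})

test_that("duplicate trial ids across files are a hard error", {
  dir <- withr::local_tempdir()
  tr <- two_arm_trial("dup-1")
  write_repository(list(tr), dir)
  yaml::write_yaml(yaml::read_yaml(file.path(dir, "dup-1.yaml")),
                   file.path(dir, "copy.yaml"))
  expect_error(load_repository(dir), class = "cotmeta_duplicate_id")
})

test_that("validate_trial flags structural violations as data", {
  expect_equal(nrow(validate_trial(example_trial())), 0L)

  no_ctl <- two_arm_trial("v1")
  no_ctl$arms <- no_ctl$arms[no_ctl$arms$role != "control", ]
  no_ctl$cells <- no_ctl$cells[no_ctl$cells$arm_id != "ctl", ]
  v <- validate_trial(no_ctl)
  expect_true("no control arm" %in% v$rule)

  dangling <- two_arm_trial("v2")
  dangling$cells$measure_id[1] <- "ghost"
  v <- validate_trial(dangling)
  expect_true(any(v$rule == "cell references existing measure" &
                  grepl("ghost", v$detail)))

  bad_code <- two_arm_trial("v3")
  bad_code$coding$design <- "observational_study"
  v <- validate_trial(bad_code)
  expect_true("code outside vocabulary" %in% v$rule)
})

test_that("validation is monotone: removing a required item adds a violation", {
  tr <- example_trial()
  base_v <- nrow(validate_trial(tr))
  for (item in c("design", "population", "intervention_type")) {
    degraded <- tr
    degraded$coding[[item]] <- NULL
    expect_gt(nrow(validate_trial(degraded)), base_v)
  }
})

test_that("status workflow allows exactly the legal transitions", {
  tr <- example_trial("wf")
  tr$status <- "queued"
  tr <- transition_status(tr, "in_progress")
  expect_equal(tr$status, "in_progress")
  tr <- transition_status(tr, "requirements_met")
  tr_rev <- transition_status(tr, "revisions_required")
  expect_equal(tr_rev$status, "revisions_required")
  tr_rev <- transition_status(tr_rev, "in_progress")
  expect_equal(tr_rev$status, "in_progress")
  done <- transition_status(tr, "verified")
  expect_equal(done$status, "verified")
  expect_true(any(grepl("requirements_met -> verified", done$audit)))

  fresh <- example_trial("wf2")
  fresh$status <- "queued"
  err <- tryCatch(transition_status(fresh, "verified"), error = identity)
  expect_s3_class(err, "cotmeta_status_error")
  expect_match(conditionMessage(err), "queued")
  expect_match(conditionMessage(err), "verified")
  # verified is absorbing
  expect_error(transition_status(done, "in_progress"),
               class = "cotmeta_status_error")
})

test_that("requirements_met is gated on a clean validation", {
  tr <- example_trial("gate")
  tr$status <- "in_progress"
  tr$coding$design <- NULL
  expect_error(transition_status(tr, "requirements_met"),
               class = "cotmeta_status_error")
})

test_that("repository exports to TSV and RIS carry the citation fields", {
  dir <- withr::local_tempdir()
  trials <- list("e1" = example_trial("e1"))
  tsv <- file.path(dir, "trials.tsv")
  export_trials_tsv(trials, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$trial_id, "e1")
  expect_equal(tab$year, 2018L)

  ris <- file.path(dir, "trials.ris")
  export_ris(trials, ris)
  lines <- readLines(ris)
  expect_true("TY  - JOUR" %in% lines)
  expect_true(any(grepl("^AU  - Smith", lines)))
  expect_true(any(grepl("^PY  - 2018", lines)))
  expect_true("ER  - " %in% lines)
})

test_that("catalogue multi-select rules are enforced", {
  tr <- two_arm_trial("multi")
  tr$coding$design <- c("randomized_controlled_trial", "crossover_trial")
  v <- validate_trial(tr)
  expect_true("multi-select not permitted" %in% v$rule)
  tr$coding$design <- "randomized_controlled_trial"
  tr$coding$population <- c("dementia", "mild_cognitive_impairment")
  expect_equal(nrow(validate_trial(tr)), 0L)
})
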